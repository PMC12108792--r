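#' @title End-to-end analysis pipeline
#' @description Orchestrates build -> simulate -> analyze -> cluster ->
#'   interface runs from a single JSON-serializable config, writing CSV/JSON
#'   reports with a provenance block (config hash, package version, seed) so
#'   a run can be reproduced exactly. Config files are JSON (not YAML) so the
#'   pipeline needs no dependency beyond jsonlite.
#' @name pipeline
NULL

#' Validate a pipeline run configuration
#'
#' A config is a plain list (or path to a JSON file) with components:
#' \describe{
#'   \item{sequence / n_bp}{synthetic input: sequence (or random length)}
#'   \item{wrap}{logical: wrap the duplex on the default superhelix}
#'   \item{damage}{list(kind = "ssb"|"uracil-swap"|"flipped-base", chain,
#'     resid, five_cap, motif)}
#'   \item{signals}{list of deformation specs (target, schedule or
#'     from/to/n ramp, sigma, seed)}
#'   \item{n_frames, dt_ps}{trajectory shape}
#'   \item{observables}{character vector from dg, phi, dw}
#'   \item{cluster}{list(cutoff, selection) or NULL}
#'   \item{histogram_bins}{bin count for series histograms}
#'   \item{window_ns}{trailing averaging window for interface reports}
#'   \item{outdir}{output directory}
#'   \item{seed}{master seed; signal seeds default to seed + signal index}
#' }
#'
#' @param config list or path to a JSON config.
#' @return the validated config (class `RunConfig`).
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  config$n_frames <- config$n_frames %||% 50L
  config$dt_ps <- config$dt_ps %||% 10
  config$observables <- config$observables %||% c("dg", "phi")
  config$histogram_bins <- config$histogram_bins %||% 30L
  config$seed <- config$seed %||% 1L
  config$outdir <- config$outdir %||% tempfile("nucdamage_run_")
  if (!is.null(config$traj_path) && !file.exists(config$traj_path))
    stop("validation error: trajectory file not found: ", config$traj_path)
  if (!is.null(config$cluster) && (config$cluster$cutoff %||% 0.45) <= 0)
    stop("validation error: clustering cutoff must be > 0")
  if (config$n_frames < 1L) stop("validation error: n_frames < 1")
  bad <- setdiff(config$observables, c("dg", "phi", "dw"))
  if (length(bad)) stop("validation error: unknown observables: ",
                        paste(bad, collapse = ", "))
  structure(config, class = "RunConfig")
}

expand_schedule <- function(spec, n) {
  if (!is.null(spec$schedule)) return(rep_len(as.numeric(spec$schedule), n))
  seq(spec$from %||% spec$to, spec$to %||% spec$from, length.out = n)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$outdir <- NULL
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Builds (or loads) the input structure, applies the configured damage
#' construct, generates or reads the trajectory, computes the requested
#' observable series with histograms, the dg-phi correlation when both are
#' present, and optional clustering; everything is written under
#' `config$outdir` and returned as a bundle. Deterministic given the config
#' and seed; a failing observable is logged and skipped, the others
#' complete.
#'
#' @param config a [run_config()] (list or JSON path accepted).
#' @return list of class `ReportBundle`: model, site, trajectory, series,
#'   histograms, correlation, clustering, provenance, and the paths written.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run_log.jsonl")
  logit <- function(stage, ...) {
    cat(jsonlite::toJSON(list(stage = stage, ..., elapsed_s = NULL),
                         auto_unbox = TRUE, null = "null"), "\n",
        file = log_path, append = TRUE)
  }
  t0 <- proc.time()[["elapsed"]]
  # ---- input structure
  if (!is.null(config$structure_path)) {
    model <- read_structure(config$structure_path)
  } else {
    seqn <- config$sequence %||% random_sequence(config$n_bp %||% 31L, config$seed)
    model <- build_bdna(seqn)
    if (isTRUE(config$wrap)) model <- wrap_superhelix(model)
  }
  logit("input", atoms = n_atoms(model))
  shlmap <- if (isTRUE(config$wrap)) shl_map(model) else NULL
  # ---- damage construct
  site <- NULL
  if (!is.null(config$damage)) {
    dmg <- config$damage
    spec <- list(chain = dmg$chain %||% "I", resid = as.integer(dmg$resid))
    built <- switch(dmg$kind %||% "ssb",
                    "ssb" = {
                      r <- make_ssb(model, spec,
                                    five_cap = dmg$five_cap %||% "dRP",
                                    shlmap = shlmap)
                      if (isTRUE(dmg$motif))
                        r$model <- set_flank_motif(r$model, r$site)
                      r
                    },
                    "uracil-swap" = swap_base(model, spec, dmg$new_base %||% "U",
                                              shlmap = shlmap),
                    "flipped-base" = flip_base(model, spec,
                                               dmg$angle_deg %||% 180,
                                               shlmap = shlmap),
                    stop("validation error: unknown damage kind: ", dmg$kind))
    model <- built$model
    site <- built$site
    write_damage_site(site, file.path(config$outdir, "site.json"))
    logit("damage", kind = site$kind)
  }
  # ---- trajectory
  if (!is.null(config$traj_path)) {
    traj <- read_trajectory(model, config$traj_path)
  } else {
    signals <- list()
    for (k in seq_along(config$signals %||% list())) {
      sp <- config$signals[[k]]
      signals[[k]] <- deformation_signal(
        target = sp$target, schedule = expand_schedule(sp, config$n_frames),
        noise_sigma = sp$sigma %||% 0,
        seed = sp$seed %||% (config$seed + k),
        site = site, shlmap = shlmap)
    }
    traj <- make_trajectory(model, signals, n_frames = config$n_frames,
                            dt_ps = config$dt_ps)
    truth <- attr(traj, "truth")
    if (nrow(truth)) utils::write.csv(truth, file.path(config$outdir, "truth.csv"),
                                      row.names = FALSE)
  }
  logit("trajectory", frames = n_frames(traj))
  # ---- observables
  series <- list()
  for (obs in config$observables) {
    res <- tryCatch(
      compute_series(traj, which = obs, site = site, shlmap = shlmap),
      error = function(e) e)
    if (inherits(res, "error")) {
      logit("observable_skipped", name = obs, reason = conditionMessage(res))
      next
    }
    series[[obs]] <- res
  }
  if (length(series)) {
    tab <- do.call(rbind, lapply(series, function(s)
      data.frame(time_ps = s$times, name = s$name, value = s$values,
                 units = s$units)))
    utils::write.csv(tab, file.path(config$outdir, "series.csv"),
                     row.names = FALSE)
  }
  hists <- lapply(series, function(s)
    series_stats(s, nbins = config$histogram_bins)$histogram)
  for (nmh in names(hists))
    utils::write.csv(hists[[nmh]],
                     file.path(config$outdir, paste0("hist_", nmh, ".csv")),
                     row.names = FALSE)
  correlation <- NULL
  if (all(c("dg", "phi") %in% names(series))) {
    correlation <- correlate(series$dg, series$phi)
    jsonlite::write_json(correlation, file.path(config$outdir, "correlation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  # ---- clustering
  clustering <- NULL
  if (!is.null(config$cluster)) {
    M <- rmsd_matrix(traj, selection = config$cluster$selection %||% NULL)
    clustering <- gromos_cluster(M, cutoff = config$cluster$cutoff %||% 0.45)
    write_clustering(clustering, file.path(config$outdir, "clusters.json"))
    write_structure(best_cluster_frame(clustering, traj),
                    file.path(config$outdir, "best_cluster.pdb"))
  }
  provenance <- list(config_hash = config_hash(config),
                     package = "nucdamage",
                     version = as.character(utils::packageVersion("nucdamage")),
                     seed = config$seed)
  jsonlite::write_json(provenance, file.path(config$outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  logit("done", seconds = proc.time()[["elapsed"]] - t0)
  structure(list(model = model, site = site, trajectory = traj,
                 series = series, histograms = hists,
                 correlation = correlation, clustering = clustering,
                 provenance = provenance, outdir = config$outdir),
            class = "ReportBundle")
}

random_sequence <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Interface report averaged over a trailing window
#'
#' Computes a per-frame interface report over the last `window_ns` of the
#' trajectory and averages: the area as a mean, the contact counts as
#' rounded means (site counts are additionally clipped at the rounded
#' totals so site <= total holds row-wise).
#'
#' @param traj a Trajectory.
#' @param part_a,part_b partner selections.
#' @param site optional lesion residue for site splits.
#' @param window_ns trailing window, ns; must not exceed the trajectory
#'   span.
#' @param stride analyze every `stride`-th frame of the window.
#' @param ... SASA parameters forwarded to [interface_report()].
#' @return list mirroring an `InterfaceReport` with averaged fields plus
#'   `n_frames_used`.
#' @export
table1_report <- function(traj, part_a, part_b, site = NULL, window_ns = 10,
                          stride = 1L, ...) {
  span_ps <- traj$times[n_frames(traj)] - traj$times[1L]
  if (window_ns * 1000 > span_ps && n_frames(traj) > 1L)
    stop("argument error: window (", window_ns, " ns) exceeds trajectory span (",
         span_ps / 1000, " ns)")
  t_from <- traj$times[n_frames(traj)] - window_ns * 1000
  use <- which(traj$times >= t_from - 1e-9)
  use <- use[seq(1L, length(use), by = stride)]
  reps <- lapply(use, function(i)
    interface_report(frame_model(traj, i), part_a, part_b, site = site, ...))
  avg <- function(f) mean(vapply(reps, function(r) as.numeric(r[[f]]), 0))
  counts <- function(f) as.integer(round(avg(f)))
  out <- list(interface_area = avg("interface_area"),
              hbonds_total = counts("hbonds_total"),
              hbonds_site = counts("hbonds_site"),
              salt_bridges_total = counts("salt_bridges_total"),
              salt_bridges_site = counts("salt_bridges_site"),
              hydrophobic_total = counts("hydrophobic_total"),
              hydrophobic_site = counts("hydrophobic_site"),
              n_frames_used = length(use))
  for (f in c("hbonds", "salt_bridges", "hydrophobic")) {
    st <- paste0(f, "_site"); tt <- paste0(f, "_total")
    out[[st]] <- min(out[[st]], out[[tt]])
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `build-damage`, `simulate`, `analyze`,
#' `cluster`, `interface` and `report` (see the `nucdamage` script under
#' `inst/cli`). Arguments are plain `--key value` pairs.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
nucdamage_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: nucdamage <build-damage|simulate|analyze|cluster|interface|report> [--key value ...]\n")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- parse_cli_args(args[-1L])
  switch(cmd,
         "build-damage" = cli_build_damage(opt),
         "simulate" = ,
         "analyze" = ,
         "report" = {
           bundle <- run_pipeline(opt$config %||% opt)
           cat("outputs written to", bundle$outdir, "\n")
         },
         "cluster" = {
           top <- read_structure(opt$top)
           traj <- read_trajectory(top, opt$traj)
           M <- rmsd_matrix(traj, selection = opt$selection)
           cl <- gromos_cluster(M, cutoff = as.numeric(opt$cutoff %||% 0.45))
           write_clustering(cl, opt$out %||% "clusters.json")
           if (!is.null(opt$`center-pdb`))
             write_structure(best_cluster_frame(cl, traj), opt$`center-pdb`)
         },
         "interface" = {
           m <- read_structure(opt$pdb)
           site <- if (!is.null(opt$site)) parse_site(opt$site)
           rep <- interface_report(m, opt$a, opt$b, site = site)
           write_interface_report(rep, opt$out %||% "interface.json")
         },
         stop("unknown subcommand: ", cmd))
  invisible(0L)
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("expected --key, got: ", args[i])
    key <- substring(args[i], 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

parse_site <- function(s) {
  kv <- strsplit(s, ":", fixed = TRUE)[[1L]]
  if (length(kv) != 2L) stop("site must be chain:resid, got: ", s)
  list(chain = kv[1L], resid = as.integer(kv[2L]))
}

cli_build_damage <- function(opt) {
  m <- read_structure(opt$`in`)
  site <- parse_site(opt$site)
  kind <- opt$kind %||% "ssb"
  built <- switch(kind,
                  "uracil" = swap_base(m, site, "U"),
                  "uracil-flip" = {
                    r <- swap_base(m, site, "U")
                    f <- flip_base(r$model, site)
                    list(model = f$model, site = f$site)
                  },
                  "flip" = flip_base(m, site),
                  "ssb" = {
                    r <- make_ssb(m, site, five_cap = opt$`five-cap` %||% "dRP")
                    if (identical(opt$motif, "default"))
                      r$model <- set_flank_motif(r$model, r$site)
                    r
                  },
                  stop("unknown damage kind: ", kind))
  write_structure(built$model, opt$out %||% "damaged.pdb")
  if (!is.null(opt$`site-json`)) write_damage_site(built$site, opt$`site-json`)
  invisible(0L)
}
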