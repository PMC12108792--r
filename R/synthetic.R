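#' @title Synthetic nucleosomal DNA structures and trajectories
#' @description Coarse-grained, fully deterministic generator of idealized
#'   B-DNA duplexes, left-handed nucleosomal superhelices, and seeded
#'   "trajectories" in which geometric deformation schedules (gap distance
#'   dg, local twist Phi, gyre gaping dw, probe distances) are injected
#'   exactly and logged, so that every analysis stage can be validated
#'   against known ground truth. This is a geometric ensemble generator, not
#'   molecular dynamics: there is no force field, solvent or thermostat.
#' @name synthetic-data
NULL

# Azimuthal half-separation of the two backbones across the minor groove.
# Calibrated once so that the four-C3' local-twist dihedral of a relaxed
# duplex at 10.4 bp/turn falls mid-way in the canonical 60-70 degree band.
GROOVE_HALF_DEG <- 45

# Cylindrical placement of the coarse backbone atom set: radius (A), azimuth
# offset (deg) and axial offset (A), both taken in the strand's 5'->3' sense.
BACKBONE_GEOM <- data.frame(
  name = c("P", "O5'", "C5'", "C4'", "C3'", "O3'", "C1'"),
  r    = c(9.2, 8.9, 8.7, 8.9, 9.0, 9.1, 5.9),
  daz  = c(-15, -10, -6, 0, 2, 8, -5),
  dz   = c(-1.9, -1.2, -0.7, 0, 0.6, 1.2, 0),
  stringsAsFactors = FALSE)

#' Helical parameters of the idealized duplex
#'
#' @param rise axial rise per base pair, Angstrom (default 3.4).
#' @param bp_per_turn base pairs per double-helical turn (default 10.4, the
#'   relaxed value for nucleosomal DNA).
#' @param twist twist per base pair in degrees; defaults to
#'   `360 / bp_per_turn` (~34.6).
#' @return list of class `HelixParams`.
#' @export
helix_params <- function(rise = 3.4, bp_per_turn = 10.4,
                         twist = 360 / bp_per_turn) {
  stopifnot(rise > 0, twist > 0, twist < 60)
  structure(list(rise = rise, twist = twist, bp_per_turn = bp_per_turn),
            class = "HelixParams")
}

#' Superhelical (nucleosome wrap) parameters
#'
#' Defaults follow canonical nucleosome crystallography (superhelix radius
#' 41.8 A, pitch 25.9 A, left-handed); they are implementation defaults, not
#' values measured in any particular study.
#'
#' @param radius superhelix radius, Angstrom.
#' @param pitch axial advance per superhelical turn, Angstrom.
#' @param handedness only "left" is supported (nucleosome mimic).
#' @return list of class `SuperhelixParams`.
#' @export
superhelix_params <- function(radius = 41.8, pitch = 25.9, handedness = "left") {
  stopifnot(radius > 0)
  handedness <- match.arg(handedness, "left")
  structure(list(radius = radius, pitch = pitch, handedness = handedness),
            class = "SuperhelixParams")
}

#' Build an idealized straight B-DNA duplex
#'
#' Chains are named "I" (the given sequence, resid 1..N in 5'->3' order) and
#' "J" (its reverse complement, resid 1..N in its own 5'->3' order), so that
#' chain I residue i pairs with chain J residue N+1-i. Each nucleotide
#' carries the coarse backbone set (P except at the 5' terminus, O5', C5',
#' C4', C3', O3', C1'), the full idealized heavy-atom base, and a `CEN`
#' base-centroid pseudo-atom. Geometry follows `params` exactly, with the
#' duplex axis along +z.
#'
#' @param sequence character string over A/C/G/T/U (chain I, 5'->3').
#' @param params a [helix_params()].
#' @return a [structure_model()] with a `build_info` attribute recording the
#'   generator's ground truth.
#' @export
build_bdna <- function(sequence, params = helix_params()) {
  seq1 <- strsplit(toupper(sequence), "")[[1L]]
  if (length(seq1) < 2L) stop("sequence must have length >= 2")
  if (!all(seq1 %in% c("A", "C", "G", "T", "U")))
    stop("invalid sequence character: ",
         paste(setdiff(seq1, c("A", "C", "G", "T", "U")), collapse = ""))
  n <- length(seq1)
  seq2 <- vapply(rev(seq1), complement_base, "")   # chain J, 5'->3'
  rows <- vector("list", 2L * n)
  k <- 0L
  for (strand in 1:2) {
    dirn <- if (strand == 1L) 1 else -1
    chain <- if (strand == 1L) "I" else "J"
    sq <- if (strand == 1L) seq1 else seq2
    for (res in seq_len(n)) {
      bp <- if (strand == 1L) res else n + 1L - res   # base-pair index
      theta <- (bp - 1) * params$twist
      z0 <- (bp - 1) * params$rise
      az0 <- theta + dirn * GROOVE_HALF_DEG
      bg <- BACKBONE_GEOM
      if (res == 1L) bg <- bg[bg$name != "P", ]      # no 5'-terminal phosphate
      az <- deg2rad(az0 + dirn * bg$daz)
      bk <- data.frame(name = bg$name, element = substr(bg$name, 1L, 1L),
                       x = bg$r * cos(az), y = bg$r * sin(az),
                       z = z0 + dirn * bg$dz, stringsAsFactors = FALSE)
      c1 <- as.numeric(bk[bk$name == "C1'", c("x", "y", "z")])
      e1 <- vunit(c(-c1[1L], -c1[2L], 0))            # toward the helix axis
      base <- place_base_template(sq[res], c1, e1, c(0, 0, dirn),
                                  with_centroid = TRUE)
      at <- rbind(bk, base)
      # glycosidic N first so the residue reads backbone, N, ring
      at$resname <- base_resname(sq[res])
      at$chain <- chain
      at$resid <- res
      k <- k + 1L
      rows[[k]] <- at
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  m <- structure_model(atoms, title = sprintf("ideal B-DNA %d bp", n))
  attr(m, "build_info") <- list(kind = "straight", n_bp = n, params = params,
                                groove_half_deg = GROOVE_HALF_DEG)
  m
}

#' Wrap a straight duplex onto a left-handed nucleosomal superhelix
#'
#' The duplex axis (built along +z by [build_bdna()]) is mapped onto a
#' left-handed circular helix with the superhelical symmetry axis along +z,
#' preserving arc length. Cross-sections are transported in the radial frame
#' and the helical phase is registered so that at the dyad (the midpoint
#' base pair) the minor groove faces radially outward, as in the nucleosome;
#' minor grooves then face the core once per double-helical turn, giving the
#' canonical inward contact points at half-integer superhelical locations.
#'
#' @param duplex a model from [build_bdna()].
#' @param params a [superhelix_params()].
#' @return wrapped [structure_model()] with updated `build_info`.
#' @export
wrap_superhelix <- function(duplex, params = superhelix_params()) {
  info <- attr(duplex, "build_info")
  if (is.null(info) || info$kind != "straight")
    stop("wrap_superhelix expects an unwrapped duplex from build_bdna()")
  R <- params$radius
  if (R < 15) stop("superhelix radius too small: duplex would self-intersect")
  cc <- params$pitch / (2 * pi)
  k <- sqrt(R^2 + cc^2)
  hp <- info$params
  n <- info$n_bp
  s_mid <- ((n + 1) / 2 - 1) * hp$rise               # dyad arc position
  th_mid <- ((n + 1) / 2 - 1) * hp$twist             # dyad helical phase
  xyz <- coords(duplex)
  s <- xyz[, 3L]
  phi <- (s - s_mid) / k
  alpha <- -phi                                       # left-handed about +z
  # register cross-sections so the dyad minor groove (azimuth th_mid in the
  # build frame) points along +U (radially outward)
  reg <- deg2rad(th_mid)
  xr <- xyz[, 1L] * cos(reg) + xyz[, 2L] * sin(reg)
  yr <- -xyz[, 1L] * sin(reg) + xyz[, 2L] * cos(reg)
  ca <- cos(alpha); sa <- sin(alpha)
  Ux <- ca; Uy <- sa                                  # outward radial
  # tangent T = (R*sa/k, -R*ca/k, cc/k); V = T x U completes a proper
  # right-handed frame so the embedding preserves the duplex handedness
  Vx <- -cc * sa / k; Vy <- cc * ca / k; Vz <- R / k
  out <- cbind(R * ca + xr * Ux + yr * Vx,
               R * sa + xr * Uy + yr * Vy,
               cc * phi + yr * Vz)
  coords(duplex) <- out
  info$kind <- "superhelix"
  info$superhelix <- params
  info$axis <- c(0, 0, 1)
  info$center <- c(0, 0, 0)
  info$dyad_bp <- (n + 1) / 2
  attr(duplex, "build_info") <- info
  duplex
}

## ------------------------------------------------------- deformation model

#' Declare a per-frame deformation schedule
#'
#' @param target one of "dg", "phi", "dw", "probe_distance".
#' @param schedule per-frame target values (nm for dg/dw/probe_distance,
#'   degrees for phi); length must equal the trajectory frame count.
#' @param noise_sigma standard deviation of seeded Gaussian noise added to
#'   the target value of each frame, in the same units as `schedule`.
#' @param seed integer seed making the noise reproducible.
#' @param site a `DamageSite` (for dg/phi/dw) created by [make_ssb()].
#' @param probe for "probe_distance": list(chain, resid, anchor) naming a
#'   probe residue placed by [place_probe_residues()] and its anchor atom.
#' @param partner optional (chain, resid) of the fixed gyre partner for dw;
#'   computed from `shlmap` when omitted.
#' @param shlmap optional [shl_map()] used to find the dw partner.
#' @param ar_rho optional AR(1) autocorrelation coefficient for the noise
#'   (0 = white, the default), mimicking the frame-to-frame correlation of
#'   molecular-dynamics output.
#' @return list of class `DeformationSignal`.
#' @export
deformation_signal <- function(target, schedule, noise_sigma = 0, seed = 1L,
                               site = NULL, probe = NULL, partner = NULL,
                               shlmap = NULL, ar_rho = 0) {
  target <- match.arg(target, c("dg", "phi", "dw", "probe_distance"))
  stopifnot(is.numeric(schedule), length(schedule) >= 1L, noise_sigma >= 0,
            ar_rho >= 0, ar_rho < 1)
  if (target == "probe_distance") {
    if (is.null(probe)) stop("probe_distance signal needs a `probe` spec")
    if (any(schedule <= 0)) stop("infeasible probe schedule: non-positive distance")
  } else if (is.null(site)) {
    stop(target, " signal needs a DamageSite in `site`")
  }
  structure(list(target = target, schedule = schedule,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 site = site, probe = probe, partner = partner,
                 shlmap = shlmap, ar_rho = ar_rho),
            class = "DeformationSignal")
}

signal_noise <- function(sig, n) {
  if (sig$noise_sigma == 0) return(rep(0, n))
  eps <- stats::rnorm(n, 0, sig$noise_sigma)
  if (sig$ar_rho > 0) {
    eps <- as.numeric(stats::filter(eps * sqrt(1 - sig$ar_rho^2), sig$ar_rho,
                                    method = "recursive"))
  }
  eps
}

# Exact operators ------------------------------------------------------------
# Each hits its (possibly noise-shifted) target value exactly on the atoms it
# owns; composition of several signals is resolved by alternating projection.

apply_dg_target <- function(model, site, target_nm) {
  e <- ssb_end_atoms(model, site)
  u <- coords(model)[e$five, ] - coords(model)[e$three, ]
  d <- vnorm(u)
  mob <- select_atoms(model, chain = site$ends$five$chain,
                      resid = site$ends$five$resid)
  xyz <- coords(model)
  xyz[mob, ] <- sweep(xyz[mob, , drop = FALSE], 2L,
                      (target_nm / NM_PER_ANGSTROM - d) * (u / d), `+`)
  coords(model) <- xyz
  model
}

apply_phi_target <- function(model, site, target_deg) {
  an <- local_twist_anchors(model, site)
  xyz <- coords(model)
  cur <- dihedral_deg(xyz[an[1L], ], xyz[an[2L], ], xyz[an[3L], ], xyz[an[4L], ])
  want <- if (cur < 0) -abs(target_deg) else abs(target_deg)
  mob <- c(select_atoms(model, chain = site$flank3$chain, resid = site$flank3$resid),
           select_atoms(model, chain = site$partner3$chain, resid = site$partner3$resid))
  axis <- xyz[an[3L], ] - xyz[an[2L], ]
  trial <- xyz
  trial[mob, ] <- rotate_about_axis(xyz[mob, , drop = FALSE], xyz[an[2L], ],
                                    axis, want - cur)
  new <- dihedral_deg(trial[an[1L], ], trial[an[2L], ], trial[an[3L], ], trial[an[4L], ])
  if (abs(new - want) > abs(cur - want)) {
    trial <- xyz
    trial[mob, ] <- rotate_about_axis(xyz[mob, , drop = FALSE], xyz[an[2L], ],
                                      axis, cur - want)
  }
  coords(model) <- trial
  model
}

apply_dw_target <- function(model, site, partner, target_nm, halfwidth = 3L) {
  pi_ <- anchor_atom(model, site$unpaired$chain, site$unpaired$resid, "P")
  pj <- anchor_atom(model, partner$chain, partner$resid, "P")
  xyz <- coords(model)
  u <- xyz[pi_, ] - xyz[pj, ]
  d <- vnorm(u)
  mob <- gyre_segment_atoms(model, site, halfwidth)
  xyz[mob, ] <- sweep(xyz[mob, , drop = FALSE], 2L,
                      (target_nm / NM_PER_ANGSTROM - d) * (u / d), `+`)
  coords(model) <- xyz
  model
}

# Residues of the cut strand around the break plus the unpaired nucleotide's
# neighborhood on the intact strand: the rigid segment displaced by dw.
gyre_segment_atoms <- function(model, site, halfwidth = 3L) {
  res_cut <- (site$anchor$resid - halfwidth):(site$anchor$resid + halfwidth)
  res_opp <- (site$unpaired$resid - halfwidth):(site$unpaired$resid + halfwidth)
  c(select_atoms(model, chain = site$anchor$chain, resid = res_cut),
    select_atoms(model, chain = site$unpaired$chain, resid = res_opp))
}

apply_probe_target <- function(model, probe, target_nm) {
  ca <- anchor_atom(model, probe$chain, probe$resid, "CA")
  an <- anchor_atom(model, probe$anchor$chain, probe$anchor$resid,
                    probe$anchor$name %||% "C3'")
  xyz <- coords(model)
  u <- xyz[ca, ] - xyz[an, ]
  d <- vnorm(u)
  mob <- select_atoms(model, chain = probe$chain, resid = probe$resid)
  xyz[mob, ] <- sweep(xyz[mob, , drop = FALSE], 2L,
                      (target_nm / NM_PER_ANGSTROM - d) * (u / d), `+`)
  coords(model) <- xyz
  model
}

measure_signal <- function(model, sig, partner = NULL) {
  switch(sig$target,
         dg = gap_distance(model, sig$site),
         phi = local_twist(model, sig$site),
         dw = {
           pi_ <- anchor_atom(model, sig$site$unpaired$chain,
                              sig$site$unpaired$resid, "P")
           pj <- anchor_atom(model, partner$chain, partner$resid, "P")
           vnorm(coords(model)[pi_, ] - coords(model)[pj, ]) * NM_PER_ANGSTROM
         },
         probe_distance = {
           ca <- anchor_atom(model, sig$probe$chain, sig$probe$resid, "CA")
           an <- anchor_atom(model, sig$probe$anchor$chain,
                             sig$probe$anchor$resid,
                             sig$probe$anchor$name %||% "C3'")
           vnorm(coords(model)[ca, ] - coords(model)[an, ]) * NM_PER_ANGSTROM
         })
}

apply_signal <- function(model, sig, value, partner = NULL) {
  switch(sig$target,
         dg = apply_dg_target(model, sig$site, value),
         phi = apply_phi_target(model, sig$site, value),
         dw = apply_dw_target(model, sig$site, partner, value),
         probe_distance = apply_probe_target(model, sig$probe, value))
}

#' Generate a synthetic trajectory with injected deformation schedules
#'
#' Every frame starts from `model`; each signal's exact geometric operator
#' (terminus translation along the gap vector for dg, rigid rotation of the
#' 3'-flank base pair about the flank-pair axis for phi, rigid axial
#' displacement of the gyre segment for dw, rigid probe translation for
#' probe distances) drives its observable to the scheduled value plus seeded
#' Gaussian noise. When several signals share atoms the operators are
#' alternated to convergence; failure to converge raises a composition
#' error. The pre-noise schedules are recorded in the `truth` attribute.
#'
#' @param model base StructureModel (all signal anchors must exist in it).
#' @param signals list of [deformation_signal()] objects (may be empty).
#' @param n_frames number of frames.
#' @param dt_ps frame spacing, ps.
#' @param max_iter maximum alternating-projection sweeps per frame.
#' @param tol convergence tolerance in each signal's own units.
#' @return a [trajectory()]; `attr(, "truth")` holds a data.frame with
#'   columns frame, time_ps, target, scheduled.
#' @export
make_trajectory <- function(model, signals = list(), n_frames,
                            dt_ps = 10, max_iter = 40L, tol = 1e-6) {
  stopifnot(n_frames >= 1L)
  if (inherits(signals, "DeformationSignal")) signals <- list(signals)
  for (sig in signals) {
    if (length(sig$schedule) != n_frames)
      stop("signal schedule length (", length(sig$schedule),
           ") != n_frames (", n_frames, ")")
  }
  # resolve fixed dw partners once, on the base model (frame 0 convention)
  partners <- lapply(signals, function(sig) {
    if (sig$target != "dw") return(NULL)
    if (!is.null(sig$partner)) return(sig$partner)
    if (is.null(sig$shlmap)) stop("dw signal needs `partner` or `shlmap`")
    gyre_partner(model, sig$site, sig$shlmap)
  })
  noises <- lapply(signals, function(sig) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(sig$seed)
    signal_noise(sig, n_frames)
  })
  frames <- vector("list", n_frames)
  truth <- list()
  for (f in seq_len(n_frames)) {
    m <- model
    if (length(signals)) {
      targets <- vapply(seq_along(signals), function(j)
        signals[[j]]$schedule[f] + noises[[j]][f], 0)
      for (it in seq_len(max_iter)) {
        for (j in seq_along(signals))
          m <- apply_signal(m, signals[[j]], targets[j], partners[[j]])
        resid <- vapply(seq_along(signals), function(j)
          abs(measure_signal(m, signals[[j]], partners[[j]]) - targets[j]), 0)
        if (all(resid < tol)) break
      }
      if (!all(resid < tol))
        stop("composition error: conflicting signals did not converge ",
             "(max residual ", format(max(resid)), ")")
    }
    frames[[f]] <- coords(m)
    for (j in seq_along(signals)) {
      truth[[length(truth) + 1L]] <-
        data.frame(frame = f, time_ps = (f - 1) * dt_ps,
                   target = signals[[j]]$target,
                   scheduled = signals[[j]]$schedule[f])
    }
  }
  stopifnot(dt_ps > 0)
  traj <- trajectory(model, frames, times = (seq_len(n_frames) - 1) * dt_ps)
  attr(traj, "truth") <- if (length(truth)) do.call(rbind, truth) else
    data.frame(frame = integer(), time_ps = numeric(), target = character(),
               scheduled = numeric())
  traj
}

#' Place pseudo amino-acid probe residues at prescribed distances
#'
#' Adds one coarse residue (CA plus two flanking carbons arranged so the
#' centroid coincides with CA) per probe, on the outward radial direction
#' from its anchor atom, at the first value of the probe's distance
#' schedule. Per-frame schedules are then driven by [make_trajectory()] with
#' `probe_distance` signals.
#'
#' @param model a StructureModel.
#' @param probes list of specs: `list(resname = "LEU", chain = "P", resid =
#'   151, anchor = list(chain, resid, name), distance = <nm>)`.
#' @return model with probe residues appended.
#' @export
place_probe_residues <- function(model, probes) {
  ctr <- colMeans(coords(model))
  for (pb in probes) {
    if (is.null(pb$distance) || pb$distance <= 0)
      stop("infeasible probe schedule: non-positive distance")
    an <- anchor_atom(model, pb$anchor$chain, pb$anchor$resid,
                      pb$anchor$name %||% "C3'")
    apos <- coords(model)[an, ]
    u <- apos - ctr
    if (vnorm(u) < 1e-9) u <- c(0, 0, 1)
    u <- vunit(u)
    w <- vunit(vcross(u, if (abs(u[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
    ca <- apos + (pb$distance / NM_PER_ANGSTROM) * u
    at <- data.frame(name = c("CA", "CB", "CG"), element = "C",
                     x = ca[1L] + c(0, 0.9, -0.9) * w[1L],
                     y = ca[2L] + c(0, 0.9, -0.9) * w[2L],
                     z = ca[3L] + c(0, 0.9, -0.9) * w[3L],
                     resname = pb$resname %||% "LEU", chain = pb$chain,
                     resid = pb$resid, stringsAsFactors = FALSE)
    atoms <- model$atoms
    at$serial <- max(atoms$serial) + seq_len(nrow(at))
    at$insert <- ""; at$altloc <- ""; at$occ <- 1; at$bfac <- 0
    bi <- attr(model, "build_info")
    model <- structure_model(rbind(atoms, at[, names(atoms)]), title = model$title)
    attr(model, "build_info") <- bi
  }
  model
}
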