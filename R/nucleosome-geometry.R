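#' @title Superhelical coordinate system of a nucleosome
#' @description Fits the superhelical symmetry axis, assigns per-nucleotide
#'   superhelical locations (SHL; dyad = 0, DNA entry/exit ~ +/-7 at 10.4 bp
#'   per turn), labels the two gyres, detects the inward-facing minor-groove
#'   histone contact points, and classifies damage-site accessibility.
#' @name nucleosome-geometry
NULL

phosphate_indices <- function(model, dna_chains) {
  select_atoms(model, chain = dna_chains, name = "P")
}

# Cylinder fit: axis direction (2 tilt parameters about the seed) and axis
# position (2 in-plane offsets) minimizing the variance of point-to-axis
# distances. Degenerate inputs (planar circles: zero residual already) keep
# the seed normal.
refine_cylinder_axis <- function(xyz, u0, c0) {
  u0 <- vunit(u0)
  e1 <- vunit(vcross(u0, if (abs(u0[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
  e2 <- vcross(u0, e1)
  obj <- function(par) {
    u <- vunit(u0 + par[1L] * e1 + par[2L] * e2)
    q <- c0 + par[3L] * e1 + par[4L] * e2
    X <- sweep(xyz, 2L, q)
    perp <- X - outer(as.vector(X %*% u), u)
    r <- sqrt(rowSums(perp^2))
    stats::var(r)
  }
  fit <- stats::optim(c(0, 0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  u <- vunit(u0 + fit$par[1L] * e1 + fit$par[2L] * e2)
  if (sum(u * u0) < 0) u <- -u
  attr(u, "axis_point") <- c0 + fit$par[3L] * e1 + fit$par[4L] * e2
  u
}

# Point on the axis line nearest the centroid of xyz.
axis_foot <- function(xyz, axis, fallback) {
  q <- attr(axis, "axis_point") %||% fallback
  ctr <- colMeans(xyz)
  as.numeric(q + sum((ctr - q) * axis) * axis)
}

#' Fit the superhelical symmetry axis of a wrapped DNA duplex
#'
#' The normal of the least-squares plane through the backbone phosphate
#' positions (the two DNA gyres lie in two nearly parallel planes) seeds
#' the axis, which is then refined by a cylinder fit — the axis direction
#' and position minimizing the variance of the phosphates' distances to the
#' axis line. The refinement matters because the wrap is partial (~1.85
#' turns): a raw plane normal is biased several degrees by the correlation
#' between pitch and azimuthal coverage. The center is the point on the
#' fitted axis nearest the phosphate centroid. The axis sign is chosen so
#' that the wrap is left-handed about +axis, i.e. the DNA path rotates
#' clockwise about +axis when traversed along chain order.
#'
#' @param model a StructureModel.
#' @param dna_chains character vector (usually two) of DNA chain ids.
#' @param min_phosphates minimum number of P atoms required.
#' @return list with `axis` (unit 3-vector) and `center` (Angstrom).
#' @export
fit_superhelix <- function(model, dna_chains = c("I", "J"), min_phosphates = 30L) {
  ip <- phosphate_indices(model, dna_chains)
  if (length(ip) < min_phosphates)
    stop("geometry error: only ", length(ip), " phosphate atoms found (need >= ",
         min_phosphates, ")")
  xyz <- coords(model)[ip, , drop = FALSE]
  pl <- fit_plane(xyz)
  axis <- refine_cylinder_axis(xyz, pl$normal, pl$center)
  pl$center <- axis_foot(xyz, axis, pl$center)
  # handedness: signed rotation of successive P positions about the axis
  X <- sweep(xyz, 2L, pl$center)
  perp <- X - outer(as.vector(X %*% axis), axis)
  sweep_sign <- sum(vapply(seq_len(nrow(perp) - 1L), function(i)
    sum(vcross(perp[i, ], perp[i + 1L, ]) * axis), 0))
  if (sweep_sign > 0) axis <- -axis
  if (abs(sweep_sign) < 1e-9 && axis[3L] < 0) axis <- -axis  # degenerate: fix sign
  list(axis = as.numeric(vunit(axis)), center = as.numeric(pl$center))
}

bp_pairing <- function(model, dna_chains) {
  rt <- residue_table(model)
  ri <- rt[rt$chain == dna_chains[1L] & rt$kind == "nucleotide", ]
  rj <- rt[rt$chain == dna_chains[2L] & rt$kind == "nucleotide", ]
  if (nrow(ri) != nrow(rj))
    stop("pairing error: chains ", dna_chains[1L], " and ", dna_chains[2L],
         " have unequal nucleotide counts (", nrow(ri), " vs ", nrow(rj),
         "); supply an explicit pairing table")
  n <- nrow(ri)
  data.frame(bp = seq_len(n),
             chain_i = ri$chain, resid_i = ri$resid,
             chain_j = rev(rj$chain), resid_j = rev(rj$resid),
             stringsAsFactors = FALSE)
}

residue_centroid <- function(model, chain, resid, names = NULL) {
  i <- select_atoms(model, chain = chain, resid = resid, name = names)
  if (length(i) == 0L) return(c(NA_real_, NA_real_, NA_real_))
  colMeans(coords(model)[i, , drop = FALSE])
}

#' Map nucleotides to superhelical locations
#'
#' Base pairs are formed by antiparallel index pairing of the two DNA chains
#' (or an explicit `pairing` table). The dyad is the midpoint base pair of
#' the wrapped path; SHL(bp) = (bp index - dyad index) / `bp_per_turn`, so a
#' 145-bp wrap at 10.4 bp/turn spans about [-7, +7]. Positive SHL lies on
#' the 3' side of the dyad along the first chain (flip with `flip_sign`).
#' Gyres are labelled "upper"/"lower" by the mean axis projection of each
#' half of the path.
#'
#' @param model a StructureModel.
#' @param dna_chains pair of DNA chain ids.
#' @param bp_per_turn relaxed double-helical repeat (default 10.4 bp).
#' @param pairing optional data.frame(chain_i, resid_i, chain_j, resid_j).
#' @param flip_sign flip the SHL sign convention.
#' @return object of class `SHLMap`: axis/center, dyad, per-nucleotide table
#'   `shl_of` (chain, resid, shl, gyre), and per-base-pair table `bp_table`.
#' @export
shl_map <- function(model, dna_chains = c("I", "J"), bp_per_turn = 10.4,
                    pairing = NULL, flip_sign = FALSE) {
  fit <- fit_superhelix(model, dna_chains)
  pr <- if (is.null(pairing)) bp_pairing(model, dna_chains) else {
    pairing$bp <- seq_len(nrow(pairing)); pairing
  }
  n <- nrow(pr)
  dyad_idx <- (n + 1) / 2
  shl <- (pr$bp - dyad_idx) / bp_per_turn
  if (flip_sign) shl <- -shl
  # gyre labels: split at the dyad; name halves by mean axis projection
  ctrs <- t(vapply(seq_len(n), function(k) {
    a <- residue_centroid(model, pr$chain_i[k], pr$resid_i[k])
    b <- residue_centroid(model, pr$chain_j[k], pr$resid_j[k])
    (a + b) / 2
  }, numeric(3L)))
  proj <- as.vector(sweep(ctrs, 2L, fit$center) %*% fit$axis)
  neg_half_higher <- mean(proj[shl < 0], na.rm = TRUE) >
    mean(proj[shl > 0], na.rm = TRUE)
  gyre <- ifelse(shl < 0,
                 if (isTRUE(neg_half_higher)) "upper" else "lower",
                 if (isTRUE(neg_half_higher)) "lower" else "upper")
  dyad_bp <- round(dyad_idx)
  shl_of <- rbind(
    data.frame(chain = pr$chain_i, resid = pr$resid_i, bp = pr$bp,
               shl = shl, gyre = gyre, stringsAsFactors = FALSE),
    data.frame(chain = pr$chain_j, resid = pr$resid_j, bp = pr$bp,
               shl = shl, gyre = gyre, stringsAsFactors = FALSE))
  structure(list(axis = fit$axis, center = fit$center,
                 dyad = list(chain = pr$chain_i[dyad_bp],
                             resid = pr$resid_i[dyad_bp]),
                 bp_per_turn = bp_per_turn,
                 shl_of = shl_of, bp_table = pr, bp_centers = ctrs,
                 dna_chains = dna_chains),
            class = "SHLMap")
}

#' @export
print.SHLMap <- function(x, ...) {
  rng <- range(x$shl_of$shl)
  cat(sprintf("<SHLMap> %d bp, SHL in [%.2f, %.2f], dyad %s:%d\n",
              nrow(x$bp_table), rng[1L], rng[2L], x$dyad$chain, x$dyad$resid))
  invisible(x)
}

#' Look up the SHL coordinate of a nucleotide
#' @param shlmap an SHLMap.
#' @param chain,resid residue identifier.
#' @export
shl_of <- function(shlmap, chain, resid) {
  i <- which(shlmap$shl_of$chain == chain & shlmap$shl_of$resid == resid)
  if (length(i) == 0L) stop("residue ", chain, ":", resid, " not in SHL map")
  shlmap$shl_of$shl[i[1L]]
}

# Local double-helical axis point at base pair k: windowed mean of bp
# centers (a window of about one helical turn averages out the azimuthal
# offset of any single atom class).
local_axis_points <- function(shlmap, window = 11L) {
  ctrs <- shlmap$bp_centers
  n <- nrow(ctrs)
  hw <- window %/% 2L
  t(vapply(seq_len(n), function(k) {
    idx <- max(1L, k - hw):min(n, k + hw)
    colMeans(ctrs[idx, , drop = FALSE], na.rm = TRUE)
  }, numeric(3L)))
}

#' Detect inward-facing minor-groove contact points
#'
#' For each base pair the minor-groove direction (from the local helical
#' axis toward the midpoint of the two backbone phosphates) is compared with
#' the inward radial direction of the superhelix; contiguous runs of base
#' pairs whose grooves face the core within `angle_cutoff_deg` are reduced
#' to one contact each, reported at the SHL of the best-facing base pair. A
#' structure without a substantial wrap (total azimuthal sweep < 270 deg)
#' has no inward grooves and yields an empty list.
#'
#' @param shlmap an [shl_map()].
#' @param model the StructureModel the map was computed from.
#' @param angle_cutoff_deg maximum angle between the groove direction and
#'   the inward radial direction (default 60).
#' @return sorted numeric vector of contact-point SHL values.
#' @export
contact_points <- function(shlmap, model, angle_cutoff_deg = 60) {
  pr <- shlmap$bp_table
  n <- nrow(pr)
  ctrs <- shlmap$bp_centers
  axp <- local_axis_points(shlmap)
  # wrap guard: unwrapped azimuthal sweep of bp centers about the axis
  rel <- sweep(ctrs, 2L, shlmap$center)
  proj <- rel - outer(as.vector(rel %*% shlmap$axis), shlmap$axis)
  ref1 <- vunit(proj[which.max(rowSums(proj^2)), ])
  ref2 <- vcross(shlmap$axis, ref1)
  az <- atan2(proj %*% ref2, proj %*% ref1)
  sweep_deg <- sum(abs(rad2deg(diff(as.vector(az))))[
    abs(rad2deg(diff(as.vector(az)))) < 180])
  if (!is.finite(sweep_deg) || sweep_deg < 270) return(numeric(0L))
  # cylindricality guard: a straight duplex "fitted" side-on has wildly
  # varying point-to-axis distances, a genuine wrap keeps them near the
  # superhelix radius
  ipho <- phosphate_indices(model, shlmap$dna_chains)
  prel <- sweep(coords(model)[ipho, , drop = FALSE], 2L, shlmap$center)
  pperp <- prel - outer(as.vector(prel %*% shlmap$axis), shlmap$axis)
  rr <- sqrt(rowSums(pperp^2))
  if (stats::sd(rr) / mean(rr) > 0.3) return(numeric(0L))
  score <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    p1 <- residue_centroid(model, pr$chain_i[k], pr$resid_i[k], "P")
    p2 <- residue_centroid(model, pr$chain_j[k], pr$resid_j[k], "P")
    if (anyNA(p1) || anyNA(p2)) next
    g <- (p1 + p2) / 2 - axp[k, ]
    if (vnorm(g) < 1e-6) next
    c_rel <- axp[k, ] - shlmap$center
    outward <- c_rel - sum(c_rel * shlmap$axis) * shlmap$axis
    # a bp whose local axis point sits on the superhelix axis (straight DNA
    # seen around its own axis) has no defined radial direction
    if (vnorm(outward) < 3) next
    score[k] <- -sum(vunit(g) * vunit(outward))      # 1 = fully inward
  }
  thr <- cos(deg2rad(angle_cutoff_deg))
  hit <- !is.na(score) & score > thr
  if (!any(hit)) return(numeric(0L))
  runs <- rle(hit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  shl <- shlmap$shl_of$shl[match(paste(pr$chain_i, pr$resid_i),
                                 paste(shlmap$shl_of$chain, shlmap$shl_of$resid))]
  out <- numeric(0L)
  for (r in which(runs$values)) {
    idx <- starts[r]:ends[r]
    out <- c(out, shl[idx[which.max(score[idx])]])
  }
  sort(out)
}

#' Classify the accessibility of a nucleotide on the nucleosome surface
#'
#' The class follows the angle theta between the base's radial vector (base
#' centroid minus the local double-helical axis point) and the outward
#' radial direction of the superhelix: theta < `easy_deg` is "easy"
#' (solvent-facing), theta > `hard_deg` is "hard" (core-facing), in between
#' is "medium". Histone-tail proximity is any heavy atom of the given tail
#' residue ranges within `tail_cutoff` Angstrom of the nucleotide.
#'
#' @param model a StructureModel.
#' @param site list(chain, resid) of the nucleotide.
#' @param shlmap an [shl_map()].
#' @param tail_ranges named list: chain id -> integer resid vector of tail
#'   residues (see [canonical_tail_ranges()]); empty means no tail test.
#' @param tail_cutoff heavy-atom distance cutoff, Angstrom (default 5).
#' @param easy_deg,hard_deg class thresholds in degrees (default 60/120,
#'   chosen to split a uniform orientation distribution in three).
#' @return object of class `AccessibilityCall`: site, class, theta_deg,
#'   tail_proximal, tail_id.
#' @export
classify_accessibility <- function(model, site, shlmap, tail_ranges = list(),
                                   tail_cutoff = 5, easy_deg = 60, hard_deg = 120) {
  so <- shlmap$shl_of
  row <- which(so$chain == site$chain & so$resid == site$resid)
  if (length(row) == 0L)
    stop("site ", site$chain, ":", site$resid, " is not a mapped DNA nucleotide")
  k <- so$bp[row[1L]]
  axp <- local_axis_points(shlmap)[k, ]
  ai <- select_atoms(model, chain = site$chain, resid = site$resid)
  nm <- model$atoms$name[ai]
  bi <- ai[is_base_atom(nm)]
  if (length(bi) == 0L) stop("site has no base atoms")
  bc <- colMeans(coords(model)[bi, , drop = FALSE])
  c_rel <- axp - shlmap$center
  outward <- c_rel - sum(c_rel * shlmap$axis) * shlmap$axis
  v <- bc - axp
  theta <- rad2deg(acos(max(-1, min(1, sum(vunit(v) * vunit(outward))))))
  cls <- if (theta < easy_deg) "easy" else if (theta > hard_deg) "hard" else "medium"
  tail_proximal <- FALSE
  tail_id <- NA_character_
  if (length(tail_ranges)) {
    xyz <- coords(model)
    heavy <- toupper(model$atoms$element) != "H"
    site_xyz <- xyz[ai[heavy[ai]], , drop = FALSE]
    for (ch in names(tail_ranges)) {
      ti <- select_atoms(model, chain = ch, resid = tail_ranges[[ch]])
      ti <- ti[heavy[ti]]
      if (length(ti) == 0L) next
      d2 <- min(outer(rowSums(site_xyz^2), rowSums(xyz[ti, , drop = FALSE]^2), `+`) -
                  2 * site_xyz %*% t(xyz[ti, , drop = FALSE]))
      if (d2 <= tail_cutoff^2) {
        tail_proximal <- TRUE
        tail_id <- ch
        break
      }
    }
  }
  structure(list(site = site, class = cls, theta_deg = theta,
                 tail_proximal = tail_proximal, tail_id = tail_id),
            class = "AccessibilityCall")
}

#' Canonical histone N-terminal tail residue ranges
#'
#' Default residue ranges for the flexible histone tails (H3 1-44, H4 1-24,
#' H2A 1-16 plus C-tail 118-129, H2B 1-30), to be keyed by chain via
#' `chain_map`.
#'
#' @param chain_map named character vector mapping chain id -> histone type
#'   ("H3", "H4", "H2A", "H2B").
#' @return named list chain id -> integer resid vector, suitable for
#'   [classify_accessibility()].
#' @export
canonical_tail_ranges <- function(chain_map) {
  ranges <- list(H3 = 1:44, H4 = 1:24, H2A = c(1:16, 118:129), H2B = 1:30)
  out <- lapply(chain_map, function(h) ranges[[toupper(h)]])
  names(out) <- names(chain_map)
  out[!vapply(out, is.null, TRUE)]
}

#' Export an SHL map as a data.frame / CSV
#' @param shlmap an SHLMap.
#' @param path optional CSV output path.
#' @return the per-nucleotide table (chain, resid, shl, gyre), invisibly
#'   when written to file.
#' @export
shl_table <- function(shlmap, path = NULL) {
  tab <- shlmap$shl_of[, c("chain", "resid", "shl", "gyre")]
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
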