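#' @title Per-frame geometric observables
#' @description The recognition-relevant geometry of a damage site: gap
#'   distance dg between the break termini C3' atoms, the local-twist
#'   dihedral Phi over the four C3' atoms of the flanking base pairs,
#'   inter-gyre gaping dw, probe/H-bond distances, and RMSD to a reference.
#'   Distances are reported in nm, angles in degrees; frame-level functions
#'   take a StructureModel, series-level wrappers map them over a
#'   Trajectory and return an `ObservableSeries`.
#' @name observables
NULL

#' Per-frame scalar series with units
#'
#' @param name observable name (dg, phi, dw, dref, pair_distance,
#'   com_distance, hbond_distance, rmsd).
#' @param values numeric per-frame values.
#' @param units "nm" or "degrees".
#' @param times frame times, ps.
#' @param anchors free-form description of the atoms/residues used.
#' @return object of class `ObservableSeries`.
#' @export
observable_series <- function(name, values, units, times = seq_along(values) - 1,
                              anchors = NULL) {
  stopifnot(length(values) == length(times))
  structure(list(name = name, values = as.numeric(values), units = units,
                 times = as.numeric(times), anchors = anchors),
            class = "ObservableSeries")
}

#' @export
print.ObservableSeries <- function(x, ...) {
  cat(sprintf("<ObservableSeries> %s [%s], %d frames, mean %.4g\n",
              x$name, x$units, length(x$values), mean(x$values)))
  invisible(x)
}

ssb_end_atoms <- function(model, ssb) {
  if (!inherits(ssb, "DamageSite") || is.null(ssb$ends))
    stop("expected an ssb DamageSite with recorded ends")
  list(three = anchor_atom(model, ssb$ends$three$chain, ssb$ends$three$resid, "C3'"),
       five = anchor_atom(model, ssb$ends$five$chain, ssb$ends$five$resid, "C3'"))
}

#' Gap distance dg of a single-strand break
#'
#' Euclidean distance between the instantaneous positions of the C3' atoms
#' of the 5' and 3' break termini.
#'
#' @param model a StructureModel (one frame).
#' @param ssb an ssb `DamageSite`.
#' @return distance in nm.
#' @export
gap_distance <- function(model, ssb) {
  e <- ssb_end_atoms(model, ssb)
  xyz <- coords(model)
  vnorm(xyz[e$five, ] - xyz[e$three, ]) * NM_PER_ANGSTROM
}

# Resolve the ordered C3' quadruple for the local-twist dihedral:
# (cut-strand 5'-flank, its partner, the 3'-flank's partner, 3'-flank).
# Accepts an ssb DamageSite or a plain list(chain, resid) site on an intact
# duplex (flanks = resid +/- 1, partners by antiparallel index pairing).
local_twist_anchors <- function(model, site, dna_chains = NULL) {
  if (inherits(site, "DamageSite") && !is.null(site$flank5)) {
    f5 <- site$flank5; f3 <- site$flank3
    p5 <- site$partner5; p3 <- site$partner3
  } else {
    f5 <- list(chain = site$chain, resid = site$resid - 1L)
    f3 <- list(chain = site$chain, resid = site$resid + 1L)
    p5 <- duplex_partner(model, f5$chain, f5$resid, dna_chains)
    p3 <- duplex_partner(model, f3$chain, f3$resid, dna_chains)
  }
  c(anchor_atom(model, f5$chain, f5$resid, "C3'"),
    anchor_atom(model, p5$chain, p5$resid, "C3'"),
    anchor_atom(model, p3$chain, p3$resid, "C3'"),
    anchor_atom(model, f3$chain, f3$resid, "C3'"))
}

#' Local twist dihedral Phi at a (damaged or intact) site
#'
#' Signed dihedral over the C3' atoms of the two base pairs flanking the
#' site, in the fixed order (5'-flank, 5'-flank partner, 3'-flank partner,
#' 3'-flank), reported as an unsigned angle in [0, 180] degrees. On relaxed
#' ideal B-DNA at 10.4 bp/turn this convention lands in the canonical 60-70
#' degree band (asserted by a calibration test).
#'
#' @param model a StructureModel.
#' @param site an ssb `DamageSite`, or list(chain, resid) for an intact
#'   nucleotide.
#' @param dna_chains optional duplex chain ids for partner lookup.
#' @return angle in degrees, in [0, 180].
#' @export
local_twist <- function(model, site, dna_chains = NULL) {
  an <- local_twist_anchors(model, site, dna_chains)
  xyz <- coords(model)
  abs(dihedral_deg(xyz[an[1L], ], xyz[an[2L], ], xyz[an[3L], ], xyz[an[4L], ]))
}

#' Fixed inter-gyre partner of a break's unpaired nucleotide
#'
#' The nearest phosphorus among nucleotides of the other gyre, chosen once
#' (frame-0 convention) and then held fixed for a paired time series.
#'
#' @param model frame on which to choose (typically frame 0).
#' @param site an ssb `DamageSite`.
#' @param shlmap an [shl_map()].
#' @return list(chain, resid) of the partner nucleotide.
#' @export
gyre_partner <- function(model, site, shlmap) {
  so <- shlmap$shl_of
  row <- which(so$chain == site$unpaired$chain & so$resid == site$unpaired$resid)
  if (length(row) == 0L) stop("unpaired nucleotide not in SHL map")
  my_shl <- so$shl[row[1L]]
  my_gyre <- so$gyre[row[1L]]
  if (abs(my_shl) < 0.5)
    stop("geometry error: no adjacent winding at the dyad (|SHL| < 0.5)")
  cand <- so[so$gyre != my_gyre, ]
  if (nrow(cand) == 0L) stop("geometry error: no adjacent winding")
  ip <- anchor_atom(model, site$unpaired$chain, site$unpaired$resid, "P")
  p0 <- coords(model)[ip, ]
  best <- NULL; bestd <- Inf
  for (k in seq_len(nrow(cand))) {
    j <- select_atoms(model, chain = cand$chain[k], resid = cand$resid[k], name = "P")
    if (length(j) == 0L) next
    d <- vnorm(coords(model)[j[1L], ] - p0)
    if (d < bestd) { bestd <- d; best <- list(chain = cand$chain[k], resid = cand$resid[k]) }
  }
  if (is.null(best)) stop("geometry error: no phosphate found in the adjacent gyre")
  best
}

#' Gyre gaping distance dw
#'
#' "Vertical" distance between the P atom of the break's unpaired
#' nucleotide and the P of a fixed nucleotide in the adjacent DNA winding.
#' The partner defaults to the frame-0 nearest other-gyre phosphate (see
#' [gyre_partner()]); pass `partner` to hold a precomputed one, or set
#' `reselect = TRUE` to re-pick the nearest phosphate on this frame within
#' +/- `window_shl` SHL of the frame-0 partner.
#'
#' @param model a StructureModel (one frame).
#' @param site an ssb `DamageSite` (or list(unpaired = list(chain, resid))
#'   for a reference pair).
#' @param shlmap an [shl_map()].
#' @param partner optional fixed list(chain, resid).
#' @param reselect re-pick the nearest phosphate on this frame.
#' @param window_shl SHL window for re-selection (default 1).
#' @return distance in nm.
#' @export
gyre_gaping <- function(model, site, shlmap, partner = NULL, reselect = FALSE,
                        window_shl = 1) {
  if (is.null(partner)) partner <- gyre_partner(model, site, shlmap)
  ip <- anchor_atom(model, site$unpaired$chain, site$unpaired$resid, "P")
  if (reselect) {
    so <- shlmap$shl_of
    p_shl <- shl_of(shlmap, partner$chain, partner$resid)
    cand <- so[abs(so$shl - p_shl) <= window_shl &
                 so$gyre == so$gyre[so$chain == partner$chain &
                                      so$resid == partner$resid][1L], ]
    p0 <- coords(model)[ip, ]
    bestd <- Inf
    for (k in seq_len(nrow(cand))) {
      j <- select_atoms(model, chain = cand$chain[k], resid = cand$resid[k], name = "P")
      if (length(j) == 0L) next
      d <- vnorm(coords(model)[j[1L], ] - p0)
      if (d < bestd) { bestd <- d; partner <- list(chain = cand$chain[k], resid = cand$resid[k]) }
    }
  }
  jp <- anchor_atom(model, partner$chain, partner$resid, "P")
  xyz <- coords(model)
  vnorm(xyz[ip, ] - xyz[jp, ]) * NM_PER_ANGSTROM
}

#' Distance between two atom selections
#'
#' @param model a StructureModel.
#' @param a,b selections: integer atom indices, or lists of arguments for
#'   [select_atoms()] (e.g. `list(chain = "P", resid = 151)`).
#' @param mode "min" (minimum heavy-atom distance) or "com" (centroid
#'   distance; atoms are weighted by standard atomic masses).
#' @return distance in nm.
#' @export
pair_distance <- function(model, a, b, mode = c("min", "com")) {
  mode <- match.arg(mode)
  ia <- resolve_selection(model, a)
  ib <- resolve_selection(model, b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("anchor error: empty selection in pair_distance")
  xyz <- coords(model)
  if (mode == "min") {
    heavy <- toupper(model$atoms$element) != "H"
    ia <- ia[heavy[ia]]; ib <- ib[heavy[ib]]
    if (length(ia) == 0L || length(ib) == 0L)
      stop("anchor error: selection has no heavy atoms")
    d2 <- outer(rowSums(xyz[ia, , drop = FALSE]^2),
                rowSums(xyz[ib, , drop = FALSE]^2), `+`) -
      2 * xyz[ia, , drop = FALSE] %*% t(xyz[ib, , drop = FALSE])
    sqrt(max(0, min(d2))) * NM_PER_ANGSTROM
  } else {
    wa <- atomic_mass(model$atoms$element[ia])
    wb <- atomic_mass(model$atoms$element[ib])
    ca <- colSums(xyz[ia, , drop = FALSE] * wa) / sum(wa)
    cb <- colSums(xyz[ib, , drop = FALSE] * wb) / sum(wb)
    vnorm(ca - cb) * NM_PER_ANGSTROM
  }
}

resolve_selection <- function(model, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  if (is.character(sel)) return(select_atoms(model, query = sel))
  do.call(select_atoms, c(list(model), sel))
}

atomic_mass <- function(element) {
  m <- c(1.008, 12.011, 14.007, 15.999, 30.974, 32.06, 65.38, 24.305,
         22.990, 35.45, 55.845, 39.098, 54.938, 79.904)
  names(m) <- c("H", "C", "N", "O", "P", "S", "ZN", "MG", "NA", "CL",
                "FE", "K", "MN", "BR")
  out <- m[toupper(element)]
  out[is.na(out)] <- 12.011
  unname(out)
}

#' Hydrogen-bond distance criteria
#'
#' The paper-style default is a donor-acceptor heavy-atom distance cutoff of
#' 3.5 A; the angle test applies only when hydrogens are present and
#' `heavy_only` is FALSE.
#'
#' @param max_DA_distance donor-acceptor cutoff, Angstrom.
#' @param max_H_angle_dev maximum deviation of the D-H...A angle from
#'   linearity, degrees.
#' @param heavy_only skip the angle test.
#' @export
hbond_criteria <- function(max_DA_distance = 3.5, max_H_angle_dev = 30,
                           heavy_only = TRUE) {
  stopifnot(max_DA_distance > 0, max_H_angle_dev > 0, max_H_angle_dev <= 90)
  structure(list(max_DA_distance = max_DA_distance,
                 max_H_angle_dev = max_H_angle_dev, heavy_only = heavy_only),
            class = "HBondCriteria")
}

#' Track a single hydrogen bond over a trajectory
#'
#' Both selections must resolve to exactly one heavy atom. The bond is
#' present in a frame iff the donor-acceptor distance is within the cutoff;
#' the distance series is always returned.
#'
#' @param traj a Trajectory.
#' @param donor_sel,acceptor_sel selections resolving to single atoms.
#' @param criteria an [hbond_criteria()].
#' @return list(present = logical per frame, distance = ObservableSeries in
#'   nm).
#' @export
hbond_series <- function(traj, donor_sel, acceptor_sel,
                         criteria = hbond_criteria()) {
  m <- traj$topology
  ia <- resolve_selection(m, donor_sel)
  ib <- resolve_selection(m, acceptor_sel)
  if (length(ia) != 1L || length(ib) != 1L)
    stop("anchor error: hbond selections must resolve to single atoms")
  d <- vapply(traj$frames, function(x) vnorm(x[ia, ] - x[ib, ]), 0)
  list(present = d <= criteria$max_DA_distance,
       distance = observable_series("hbond_distance", d * NM_PER_ANGSTROM,
                                    "nm", traj$times,
                                    anchors = list(donor = ia, acceptor = ib)))
}

#' RMSD of a frame to a reference structure
#'
#' @param model a StructureModel (the frame).
#' @param reference reference StructureModel.
#' @param selection selection applied to both (indices or selector list);
#'   must map 1:1 by order.
#' @param ref_selection optional separate selection on the reference.
#' @param superpose optimal least-squares superposition before the RMSD?
#' @return RMSD in nm.
#' @export
rmsd_to_reference <- function(model, reference, selection = NULL,
                              ref_selection = selection, superpose = TRUE) {
  ia <- if (is.null(selection)) seq_len(n_atoms(model)) else
    resolve_selection(model, selection)
  ib <- if (is.null(ref_selection)) seq_len(n_atoms(reference)) else
    resolve_selection(reference, ref_selection)
  if (length(ia) != length(ib) || length(ia) == 0L)
    stop("anchor error: selections do not map 1:1 (", length(ia), " vs ",
         length(ib), " atoms)")
  A <- coords(model)[ia, , drop = FALSE]
  B <- coords(reference)[ib, , drop = FALSE]
  if (superpose) kabsch(A, B)$rmsd * NM_PER_ANGSTROM
  else raw_rmsd(A, B) * NM_PER_ANGSTROM
}

## ------------------------------------------------------------ series level

#' Compute an observable series over a trajectory
#'
#' @param traj a Trajectory.
#' @param which one of "dg", "phi", "dw", "pair", "rmsd".
#' @param site a `DamageSite` (dg/phi/dw) or list(chain, resid) (phi).
#' @param shlmap an [shl_map()], required for "dw".
#' @param partner fixed dw partner; defaults to the frame-1 nearest
#'   other-gyre phosphate.
#' @param ... further arguments for [pair_distance()] /
#'   [rmsd_to_reference()].
#' @return an [observable_series()].
#' @export
compute_series <- function(traj, which = c("dg", "phi", "dw", "pair", "rmsd"),
                           site = NULL, shlmap = NULL, partner = NULL, ...) {
  which <- match.arg(which)
  if (which == "dw" && is.null(partner)) {
    partner <- gyre_partner(frame_model(traj, 1L), site, shlmap)
  }
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    fm <- frame_model(traj, i)
    switch(which,
           dg = gap_distance(fm, site),
           phi = local_twist(fm, site),
           dw = gyre_gaping(fm, site, shlmap, partner = partner),
           pair = pair_distance(fm, ...),
           rmsd = rmsd_to_reference(fm, ...))
  }, 0)
  units <- if (which == "phi") "degrees" else "nm"
  nm <- switch(which, pair = "pair_distance", rmsd = "rmsd", which)
  observable_series(nm, vals, units, traj$times,
                    anchors = list(site = site, partner = partner))
}

#' Histogram and summary statistics of a series
#'
#' @param series an ObservableSeries (or numeric vector).
#' @param window running-average window, frames (default 1 = none).
#' @param nbins histogram bin count.
#' @param breaks optional explicit break points.
#' @return list with `histogram` (data.frame mid/count/prob summing to 1),
#'   `mean`, `min`, `max`, and `running` (running mean over `window`).
#' @export
series_stats <- function(series, window = 1L, nbins = 50L, breaks = NULL) {
  v <- if (inherits(series, "ObservableSeries")) series$values else as.numeric(series)
  if (length(v) == 0L) stop("empty series")
  if (is.null(breaks)) {
    rng <- range(v)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  }
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  run <- if (window > 1L)
    stats::filter(v, rep(1 / window, window), sides = 1L) else v
  list(histogram = data.frame(mid = h$mids, count = h$counts,
                              prob = h$counts / sum(h$counts)),
       mean = mean(v), min = min(v), max = max(v),
       running = as.numeric(run))
}

#' Linear relation between two observable series
#'
#' Least-squares line y ~ x plus the Pearson correlation coefficient, for
#' e.g. the coupling between gap opening dg and local over-twisting Phi.
#'
#' @param x,y ObservableSeries (or numeric vectors) of equal length >= 3.
#' @return list(slope, intercept, r, n).
#' @export
correlate <- function(x, y) {
  xv <- if (inherits(x, "ObservableSeries")) x$values else as.numeric(x)
  yv <- if (inherits(y, "ObservableSeries")) y$values else as.numeric(y)
  if (length(xv) != length(yv) || length(xv) < 3L)
    stop("series must have equal length >= 3")
  if (stats::var(xv) == 0) stop("undefined slope: zero variance in x")
  fit <- stats::lm.fit(cbind(1, xv), yv)
  list(slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       r = if (stats::var(yv) == 0) 0 else stats::cor(xv, yv),
       n = length(xv))
}
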