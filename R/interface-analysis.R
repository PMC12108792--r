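#' @title Protein-DNA interface descriptors
#' @description Numerical solvent-accessible surface area (Shrake-Rupley
#'   style, deterministic golden-spiral sphere points), buried interface
#'   area, and hydrogen-bond / salt-bridge / hydrophobic contact counts with
#'   optional restriction to a single site residue (e.g. the flipped
#'   nucleotide). The PISA-style solvation free-energy gain is deliberately
#'   not recomputed; the report keeps an optional field for externally
#'   imported values.
#' @name interface-analysis
NULL

VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
               ZN = 1.39, MG = 1.73, CL = 1.75, BR = 1.85, FE = 1.56,
               K = 2.75, MN = 1.61)
VDW_RADII["NA"] <- 2.27

atom_radii <- function(model, idx) {
  el <- toupper(model$atoms$element[idx])
  r <- VDW_RADII[el]
  if (anyNA(r)) {
    bad <- idx[is.na(r)]
    stop("no van der Waals radius for atom(s): ",
         paste(sprintf("%s %s:%d %s", model$atoms$name[bad],
                       model$atoms$chain[bad], model$atoms$resid[bad],
                       model$atoms$element[bad]), collapse = "; "))
  }
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a deterministic golden-spiral point set, so results
#' are exactly reproducible for a fixed `n_sphere_points`. Neighbors of the
#' selection outside it do NOT occlude (the selection is treated as an
#' isolated structure), which is what the buried-interface-area difference
#' formula requires.
#'
#' @param model a StructureModel.
#' @param selection atom selection (default: all atoms).
#' @param probe_radius solvent probe radius, Angstrom (default 1.4).
#' @param n_sphere_points points per atom sphere (default 960).
#' @return list(total = total area in A^2, per_atom = per-atom areas).
#' @export
sasa <- function(model, selection = NULL, probe_radius = 1.4,
                 n_sphere_points = 960L) {
  idx <- if (is.null(selection)) seq_len(n_atoms(model)) else
    resolve_selection(model, selection)
  if (length(idx) == 0L) stop("anchor error: empty selection")
  xyz <- coords(model)[idx, , drop = FALSE]
  rads <- atom_radii(model, idx) + probe_radius
  n <- length(idx)
  pts <- fibonacci_sphere(n_sphere_points)
  sq <- rowSums(xyz^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  per <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rads[i] + rads)^2)
    nb <- nb[nb != i]
    # exact duplicates: the lowest-index copy owns the surface
    dup <- nb[d2[i, nb] < 1e-12 & abs(rads[nb] - rads[i]) < 1e-12 & nb < i]
    if (length(dup)) { per[i] <- 0; next }
    sp <- sweep(pts * rads[i], 2L, xyz[i, ], `+`)
    if (length(nb)) {
      # points x neighbors squared distances in one shot; a point is
      # occluded only when strictly inside a neighbor sphere
      M <- outer(rowSums(sp^2), sq[nb], `+`) - 2 * sp %*% t(xyz[nb, , drop = FALSE])
      blocked <- sweep(M, 2L, rads[nb]^2 - 1e-9, `<`)
      frac <- mean(rowSums(blocked) == 0L)
    } else frac <- 1
    per[i] <- 4 * pi * rads[i]^2 * frac
  }
  list(total = sum(per), per_atom = per)
}

#' Buried interface area between two selections
#'
#' Half the solvent-accessible area buried on complex formation:
#' (SASA(a) + SASA(b) - SASA(a u b)) / 2, clipped at zero.
#'
#' @param model a StructureModel containing both partners.
#' @param part_a,part_b disjoint atom selections.
#' @param probe_radius,n_sphere_points passed to [sasa()].
#' @return interface area in A^2.
#' @export
interface_area <- function(model, part_a, part_b, probe_radius = 1.4,
                           n_sphere_points = 960L) {
  ia <- resolve_selection(model, part_a)
  ib <- resolve_selection(model, part_b)
  if (length(intersect(ia, ib)))
    stop("partner selections overlap (", length(intersect(ia, ib)), " atoms)")
  sa <- sasa(model, ia, probe_radius, n_sphere_points)$total
  sb <- sasa(model, ib, probe_radius, n_sphere_points)$total
  sab <- sasa(model, c(ia, ib), probe_radius, n_sphere_points)$total
  max(0, (sa + sb - sab) / 2)
}

# donor / acceptor / charge typing tables (community-default heuristics)
HB_DONOR_NAMES <- c("N", "NE", "NH1", "NH2", "NZ", "ND1", "NE1", "NE2",
                    "ND2", "OG", "OG1", "OH", "SG", "OW",
                    "N1", "N2", "N3", "N4", "N6", "O2'", "O3'", "O5'")
HB_ACCEPTOR_ELEMENTS <- c("O")
HB_ACCEPTOR_NAMES <- c("N1", "N3", "N7", "ND1", "NE2", "OD1", "OD2", "OE1",
                       "OE2", "O", "OXT")
CATION_NAMES <- c("NH1", "NH2", "NE", "NZ", "ND1", "NE2")
CATION_RESNAMES <- c("ARG", "LYS", "HIS", "HID", "HIE", "HIP")
ANION_NAMES <- c("OP1", "OP2", "O1P", "O2P", "OD1", "OD2", "OE1", "OE2", "OXT")
APOLAR_RESNAMES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")

#' Count interface contacts of a given kind
#'
#' Heuristic community-default criteria: hydrogen bonds are donor/acceptor
#' heavy-atom pairs within 3.5 A; salt bridges are basic-nitrogen vs
#' phosphate/carboxylate-oxygen pairs within 4.0 A; hydrophobic contacts
#' are carbon-carbon pairs within 4.5 A between apolar residues (or the
#' thymine methyl), counted once per residue pair. The `site_filter`
#' restricts one side of each pair to a single residue, giving the
#' "site-only" split reported alongside totals.
#'
#' @param model a StructureModel.
#' @param part_a,part_b atom selections of the two partners.
#' @param kind "hbond", "salt_bridge" or "hydrophobic".
#' @param site_filter optional list(chain, resid).
#' @param cutoff override the default distance cutoff, Angstrom.
#' @return list(total, site, pairs) where pairs is a data.frame of
#'   contributing residue/atom pairs with distances (A).
#' @export
count_contacts <- function(model, part_a, part_b,
                           kind = c("hbond", "salt_bridge", "hydrophobic"),
                           site_filter = NULL, cutoff = NULL) {
  kind <- match.arg(kind)
  ia <- resolve_selection(model, part_a)
  ib <- resolve_selection(model, part_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("anchor error: empty selection")
  if (is.null(cutoff))
    cutoff <- c(hbond = 3.5, salt_bridge = 4.0, hydrophobic = 4.5)[[kind]]
  a <- model$atoms
  heavy <- toupper(a$element) != "H"
  ia <- ia[heavy[ia]]; ib <- ib[heavy[ib]]
  ok_a <- contact_typed(a, ia, kind, end = "either")
  ok_b <- contact_typed(a, ib, kind, end = "either")
  ia <- ia[ok_a]; ib <- ib[ok_b]
  if (length(ia) == 0L || length(ib) == 0L)
    return(list(total = 0L, site = 0L, pairs = empty_pairs()))
  xyz <- coords(model)
  d2 <- outer(rowSums(xyz[ia, , drop = FALSE]^2),
              rowSums(xyz[ib, , drop = FALSE]^2), `+`) -
    2 * xyz[ia, , drop = FALSE] %*% t(xyz[ib, , drop = FALSE])
  hits <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(list(total = 0L, site = 0L, pairs = empty_pairs()))
  pi_ <- ia[hits[, 1L]]; pj <- ib[hits[, 2L]]
  valid <- vapply(seq_along(pi_), function(k)
    pair_is_contact(a, pi_[k], pj[k], kind), TRUE)
  pi_ <- pi_[valid]; pj <- pj[valid]
  if (length(pi_) == 0L) return(list(total = 0L, site = 0L, pairs = empty_pairs()))
  dd <- sqrt(pmax(0, d2[cbind(match(pi_, ia), match(pj, ib))]))
  pairs <- data.frame(
    chain_a = a$chain[pi_], resid_a = a$resid[pi_], atom_a = a$name[pi_],
    chain_b = a$chain[pj], resid_b = a$resid[pj], atom_b = a$name[pj],
    distance = dd, stringsAsFactors = FALSE)
  if (kind == "hydrophobic") {
    key <- paste(pairs$chain_a, pairs$resid_a, pairs$chain_b, pairs$resid_b)
    pairs <- pairs[order(key, pairs$distance), ]
    pairs <- pairs[!duplicated(paste(pairs$chain_a, pairs$resid_a,
                                     pairs$chain_b, pairs$resid_b)), ]
  }
  in_site <- function(ch, rs) {
    if (is.null(site_filter)) rep(FALSE, length(ch))
    else ch == site_filter$chain & rs == site_filter$resid
  }
  site_n <- sum(in_site(pairs$chain_a, pairs$resid_a) |
                  in_site(pairs$chain_b, pairs$resid_b))
  list(total = nrow(pairs), site = as.integer(site_n), pairs = pairs)
}

tag_pairs <- function(kind, pairs) {
  if (nrow(pairs) == 0L) return(cbind(data.frame(kind = character()), empty_pairs()))
  cbind(kind = kind, pairs)
}

empty_pairs <- function() {
  data.frame(chain_a = character(), resid_a = integer(), atom_a = character(),
             chain_b = character(), resid_b = integer(), atom_b = character(),
             distance = numeric(), stringsAsFactors = FALSE)
}

contact_typed <- function(atoms, idx, kind, end) {
  nm <- normalize_atom_name(atoms$name[idx])
  el <- toupper(atoms$element[idx])
  rn <- toupper(atoms$resname[idx])
  switch(kind,
         hbond = (nm %in% HB_DONOR_NAMES) | (el %in% HB_ACCEPTOR_ELEMENTS) |
           (nm %in% HB_ACCEPTOR_NAMES),
         salt_bridge = (nm %in% CATION_NAMES & rn %in% CATION_RESNAMES) |
           (nm %in% ANION_NAMES),
         hydrophobic = el == "C" &
           (rn %in% APOLAR_RESNAMES | nm %in% c("C7", "C5M")))
}

pair_is_contact <- function(atoms, i, j, kind) {
  nmi <- normalize_atom_name(atoms$name[i]); nmj <- normalize_atom_name(atoms$name[j])
  eli <- toupper(atoms$element[i]); elj <- toupper(atoms$element[j])
  rni <- toupper(atoms$resname[i]); rnj <- toupper(atoms$resname[j])
  don <- function(nm) nm %in% HB_DONOR_NAMES
  acc <- function(nm, el) el %in% HB_ACCEPTOR_ELEMENTS | nm %in% HB_ACCEPTOR_NAMES
  cat_ <- function(nm, rn) nm %in% CATION_NAMES & rn %in% CATION_RESNAMES
  ani <- function(nm) nm %in% ANION_NAMES
  switch(kind,
         hbond = (don(nmi) & acc(nmj, elj)) | (don(nmj) & acc(nmi, eli)),
         salt_bridge = (cat_(nmi, rni) & ani(nmj)) | (cat_(nmj, rnj) & ani(nmi)),
         hydrophobic = TRUE)
}

#' Table-style interface report for a complex
#'
#' Combines buried interface area with total and site-restricted contact
#' counts, mirroring the usual per-row interface summary (the solvation
#' free-energy column is not recomputed; pass `delta_gs` to import an
#' external value).
#'
#' @param model a StructureModel.
#' @param part_a,part_b partner selections.
#' @param site optional list(chain, resid) of the lesion nucleotide for the
#'   site-only splits.
#' @param delta_gs optional externally computed solvation free-energy gain
#'   (kcal/mol); stored, never derived.
#' @param probe_radius,n_sphere_points SASA parameters.
#' @return object of class `InterfaceReport`.
#' @export
interface_report <- function(model, part_a, part_b, site = NULL,
                             delta_gs = NA_real_, probe_radius = 1.4,
                             n_sphere_points = 960L) {
  hb <- count_contacts(model, part_a, part_b, "hbond", site)
  sb <- count_contacts(model, part_a, part_b, "salt_bridge", site)
  hp <- count_contacts(model, part_a, part_b, "hydrophobic", site)
  area <- interface_area(model, part_a, part_b, probe_radius, n_sphere_points)
  structure(list(partner_a = part_a, partner_b = part_b, site = site,
                 interface_area = area,
                 hbonds_total = hb$total, hbonds_site = hb$site,
                 salt_bridges_total = sb$total, salt_bridges_site = sb$site,
                 hydrophobic_total = hp$total, hydrophobic_site = hp$site,
                 delta_gs = delta_gs,
                 per_contact = rbind(tag_pairs("hbond", hb$pairs),
                                     tag_pairs("salt_bridge", sb$pairs),
                                     tag_pairs("hydrophobic", hp$pairs))),
            class = "InterfaceReport")
}

#' @export
print.InterfaceReport <- function(x, ...) {
  cat(sprintf(paste0("<InterfaceReport> area %.1f A^2 | H-bonds %d/%d | ",
                     "salt bridges %d/%d | hydrophobic %d/%d (total/site)\n"),
              x$interface_area, x$hbonds_total, x$hbonds_site,
              x$salt_bridges_total, x$salt_bridges_site,
              x$hydrophobic_total, x$hydrophobic_site))
  invisible(x)
}

#' Serialize an interface report as JSON
#' @param report an InterfaceReport.
#' @param path output path.
#' @export
write_interface_report <- function(report, path) {
  out <- unclass(report)
  out$per_contact <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
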