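#' @title Damage constructs: uracil swap, extrahelical flip, single-strand break
#' @description Introduces the three lesion constructs into a structure
#'   purely geometrically (no energy minimization — relaxation is the job of
#'   a simulation engine, which is out of scope here): base substitution on
#'   the existing glycosidic frame, nucleoside rotation about the flanking
#'   phosphate axis, and nucleotide deletion with defined 3'-OH / 5'-dRP
#'   break termini.
#' @name damage-builder
NULL

residue_atoms <- function(model, chain, resid) {
  select_atoms(model, chain = chain, resid = resid)
}

new_damage_site <- function(kind, anchor, shl = NA_real_, ...) {
  structure(c(list(kind = kind, anchor = anchor, shl = shl), list(...)),
            class = "DamageSite")
}

#' @export
print.DamageSite <- function(x, ...) {
  cat(sprintf("<DamageSite> %s at %s:%d (SHL %s)\n", x$kind, x$anchor$chain,
              x$anchor$resid, ifelse(is.na(x$shl), "?", sprintf("%+.2f", x$shl))))
  invisible(x)
}

# Antiparallel index partner of a nucleotide within a two-chain duplex.
duplex_partner <- function(model, chain, resid, dna_chains = NULL) {
  rt <- residue_table(model)
  nuc <- rt[rt$kind == "nucleotide", ]
  if (is.null(dna_chains)) {
    chains <- unique(nuc$chain)
    if (length(chains) != 2L)
      stop("cannot infer the duplex chains; pass dna_chains explicitly")
    dna_chains <- chains
  }
  other <- setdiff(dna_chains, chain)
  a <- nuc[nuc$chain == chain, ]
  b <- nuc[nuc$chain == other, ]
  if (nrow(a) != nrow(b)) stop("pairing error: unequal strand lengths")
  k <- match(resid, a$resid)
  if (is.na(k)) stop("residue ", chain, ":", resid, " not found")
  list(chain = other, resid = b$resid[nrow(b) + 1L - k])
}

base_plane_normal <- function(xyz_base, fallback = c(0, 0, 1)) {
  if (nrow(xyz_base) < 3L) return(fallback)
  fit_plane(xyz_base)$normal
}

#' Substitute the base of a nucleotide
#'
#' Backbone and sugar atoms are untouched; the base atoms are replaced by
#' the idealized template of `new_base` placed on the existing glycosidic
#' frame (C1' position, C1'->N direction, base-plane orientation). T -> U
#' removes exactly the C7 methyl carbon and renames DT to DU. A
#' purine/pyrimidine cross-swap that clashes with the residue's own backbone
#' closer than 0.5 A raises a warning, not an error.
#'
#' @param model a StructureModel.
#' @param site list(chain, resid).
#' @param new_base one of "A", "C", "G", "T", "U".
#' @param shlmap optional [shl_map()] used to record the site's SHL.
#' @return list(model, site) with the modified model and a `DamageSite` of
#'   kind "uracil-swap".
#' @export
swap_base <- function(model, site, new_base, shlmap = NULL) {
  new_base <- toupper(new_base)
  ai <- residue_atoms(model, site$chain, site$resid)
  if (length(ai) == 0L) stop("residue ", site$chain, ":", site$resid, " not found")
  a <- model$atoms
  if (residue_kind(a$resname[ai[1L]])[1L] != "nucleotide")
    stop("site is not a nucleotide")
  old_base <- base_letter(a$resname[ai[1L]])
  nm <- a$name[ai]
  base_rows <- ai[is_base_atom(nm)]
  ic1 <- ai[nm == "C1'"]
  if (length(ic1) != 1L) stop("backbone atom C1' missing at the site")
  xyz <- coords(model)
  had_cen <- "CEN" %in% nm
  glyc <- c("N1", "N9")
  ign <- ai[nm %in% glyc]
  if (length(ign) == 0L) stop("glycosidic nitrogen missing at the site")
  c1 <- xyz[ic1, ]
  e1 <- vunit(xyz[ign[1L], ] - c1)
  bxyz <- xyz[base_rows, , drop = FALSE]
  n0 <- base_plane_normal(bxyz)
  # the plane normal sign is ambiguous; keep the orientation that best
  # reproduces the existing base atoms (deterministic ties -> +n0)
  cand <- lapply(c(1, -1), function(s)
    place_base_template(new_base, c1, e1, s * n0, with_centroid = had_cen))
  score <- vapply(cand, function(tp) {
    common <- intersect(tp$name, nm[is_base_atom(nm)])
    if (length(common) == 0L) return(0)
    sum(vapply(common, function(an) {
      sum((as.numeric(tp[tp$name == an, c("x", "y", "z")]) -
             xyz[ai[nm == an][1L], ])^2)
    }, 0))
  }, 0)
  tp <- if (score[2L] < score[1L]) cand[[2L]] else cand[[1L]]
  # clash check against own backbone (cross-class swaps can collide)
  bb <- ai[!is_base_atom(nm) & nm != "C1'"]
  if (length(bb)) {
    dmin <- min(sqrt(outer(rowSums(as.matrix(tp[, c("x", "y", "z")])^2),
                           rowSums(xyz[bb, , drop = FALSE]^2), `+`) -
                       2 * as.matrix(tp[, c("x", "y", "z")]) %*%
                       t(xyz[bb, , drop = FALSE])))
    if (is.finite(dmin) && dmin < 0.5)
      warning("geometry warning: swapped base clashes with its backbone (",
              sprintf("%.2f", dmin), " A)")
  }
  keep <- setdiff(seq_len(nrow(a)), base_rows)
  newrows <- data.frame(serial = NA_integer_, name = tp$name, altloc = "",
                        resname = base_resname(new_base), chain = site$chain,
                        resid = site$resid, insert = a$insert[ai[1L]],
                        x = tp$x, y = tp$y, z = tp$z, occ = 1, bfac = 0,
                        element = tp$element, stringsAsFactors = FALSE)
  # reinsert at the residue position, after its surviving atoms
  pre <- keep[keep <= max(ai)]
  post <- keep[keep > max(ai)]
  out <- rbind(a[pre, ], newrows[, names(a)], a[post, ])
  out$resname[out$chain == site$chain & out$resid == site$resid &
                out$insert == a$insert[ai[1L]]] <- base_resname(new_base)
  out$serial <- seq_len(nrow(out))
  bi <- attr(model, "build_info")
  m2 <- structure_model(out, title = model$title)
  attr(m2, "build_info") <- bi
  shl <- if (!is.null(shlmap)) shl_of(shlmap, site$chain, site$resid) else NA_real_
  list(model = m2,
       site = new_damage_site("uracil-swap", site, shl,
                              from_base = old_base, to_base = new_base))
}

#' Flip a nucleoside into an extrahelical position
#'
#' Rotates the nucleoside (sugar + base; everything except the 5' phosphate
#' group) of the site by `angle_deg` about the axis through the two flanking
#' backbone phosphorus atoms (the residue's own P and the next residue's P).
#' Both phosphate positions are unchanged. The default 180 degrees places
#' the base fully extrahelically.
#'
#' @param model a StructureModel.
#' @param site list(chain, resid); must not be a chain terminus.
#' @param angle_deg rotation angle (default 180).
#' @param shlmap optional [shl_map()] for SHL bookkeeping.
#' @return list(model, site) with a `DamageSite` of kind "flipped-base"
#'   recording the applied rotation.
#' @export
flip_base <- function(model, site, angle_deg = 180, shlmap = NULL) {
  ai <- residue_atoms(model, site$chain, site$resid)
  if (length(ai) == 0L) stop("residue ", site$chain, ":", site$resid, " not found")
  nm <- model$atoms$name[ai]
  ip1 <- ai[nm == "P"]
  ip2 <- select_atoms(model, chain = site$chain, resid = site$resid + 1L, name = "P")
  if (length(ip1) != 1L || length(ip2) != 1L)
    stop("terminal nucleotide (missing flanking phosphate): cannot flip ",
         site$chain, ":", site$resid)
  xyz <- coords(model)
  axis <- xyz[ip2[1L], ] - xyz[ip1, ]
  mob <- ai[!nm %in% c("P", "OP1", "OP2", "O1P", "O2P")]
  xyz[mob, ] <- rotate_about_axis(xyz[mob, , drop = FALSE], xyz[ip1, ],
                                  axis, angle_deg)
  coords(model) <- xyz
  shl <- if (!is.null(shlmap)) shl_of(shlmap, site$chain, site$resid) else NA_real_
  list(model = model,
       site = new_damage_site("flipped-base", site, shl,
                              rotation_deg = angle_deg,
                              flip_axis = "P-P (flanking phosphates)"))
}

#' Construct a single-strand break by nucleotide deletion
#'
#' Removes the whole nucleotide at `site`, leaving a resid gap of exactly 1
#' in the author numbering of the cut strand. The 3' neighbor (resid - 1)
#' becomes the 3'-OH terminus (its O3' is the capping oxygen; a hydrogen is
#' added only when the input structure carries hydrogens). The 5' neighbor
#' (resid + 1) carries the chosen 5' cap: "dRP" adds an abasic
#' deoxyribose-phosphate group (atoms C1R/C2R/C3R/C4R/O4R, placed at the
#' deleted residue's sugar positions) ahead of its phosphate, "phosphate"
#' keeps the plain 5' phosphate. The opposite-strand partner is flagged
#' unpaired. All other atoms are bit-identical.
#'
#' @param model a StructureModel.
#' @param site list(chain, resid) of the nucleotide to delete (not a chain
#'   terminus).
#' @param five_cap "dRP" (default) or "phosphate".
#' @param three_cap only "OH".
#' @param dna_chains optional pair of duplex chain ids (inferred when the
#'   model has exactly two nucleotide chains).
#' @param shlmap optional [shl_map()] for SHL bookkeeping.
#' @return list(model, site) where site is a `DamageSite` of kind "ssb" with
#'   `ends` (5'/3' termini and caps) and `unpaired` (opposite-strand
#'   residue), plus flank/partner bookkeeping used by the observables.
#' @export
make_ssb <- function(model, site, five_cap = c("dRP", "phosphate"),
                     three_cap = "OH", dna_chains = NULL, shlmap = NULL) {
  five_cap <- match.arg(five_cap)
  three_cap <- match.arg(three_cap, "OH")
  ai <- residue_atoms(model, site$chain, site$resid)
  if (length(ai) == 0L) stop("residue ", site$chain, ":", site$resid, " not found")
  up <- residue_atoms(model, site$chain, site$resid - 1L)
  dn <- residue_atoms(model, site$chain, site$resid + 1L)
  if (length(up) == 0L || length(dn) == 0L)
    stop("cannot break at a chain terminus: ", site$chain, ":", site$resid)
  nm_all <- model$atoms$name
  if (!"O3'" %in% nm_all[up] || !"C3'" %in% nm_all[up] || !"C3'" %in% nm_all[dn])
    stop("topology error: missing backbone atoms flanking the break")
  # partners resolved on the intact duplex, before the deletion breaks the
  # index pairing
  partner <- duplex_partner(model, site$chain, site$resid, dna_chains)
  partner5 <- duplex_partner(model, site$chain, site$resid - 1L, dna_chains)
  partner3 <- duplex_partner(model, site$chain, site$resid + 1L, dna_chains)
  a <- model$atoms
  xyz <- coords(model)
  keep <- setdiff(seq_len(nrow(a)), ai)
  add <- NULL
  if (five_cap == "dRP") {
    sugar <- c("C1'", "C2'", "C3'", "C4'", "O4'")
    names_new <- c("C1R", "C2R", "C3R", "C4R", "O4R")
    have <- nm_all[ai] %in% sugar
    src <- ai[have]
    if (length(src)) {
      add <- data.frame(serial = NA_integer_,
                        name = names_new[match(nm_all[src], sugar)],
                        altloc = "", resname = a$resname[dn[1L]],
                        chain = site$chain, resid = site$resid + 1L,
                        insert = a$insert[dn[1L]],
                        x = xyz[src, 1L], y = xyz[src, 2L], z = xyz[src, 3L],
                        occ = 1, bfac = 0,
                        element = substr(names_new[match(nm_all[src], sugar)], 1L, 1L),
                        stringsAsFactors = FALSE)
    }
  }
  pre <- keep[keep < dn[1L]]
  post <- keep[keep >= dn[1L]]
  out <- rbind(a[pre, ], if (!is.null(add)) add[, names(a)], a[post, ])
  out$serial <- seq_len(nrow(out))
  bi <- attr(model, "build_info")
  m2 <- structure_model(out, title = model$title)
  attr(m2, "build_info") <- bi
  shl <- if (!is.null(shlmap)) shl_of(shlmap, site$chain, site$resid) else NA_real_
  flank5 <- list(chain = site$chain, resid = site$resid - 1L)
  flank3 <- list(chain = site$chain, resid = site$resid + 1L)
  ds <- new_damage_site(
    "ssb", site, shl,
    ends = list(three = c(flank5, list(cap = "OH")),     # 3'-OH upstream
                five = c(flank3, list(cap = five_cap))), # 5' cap downstream
    unpaired = partner,
    flank5 = flank5, flank3 = flank3,
    partner5 = partner5, partner3 = partner3)
  list(model = m2, site = ds)
}

#' Enforce the break-flanking sequence motif
#'
#' Sets the nucleotides flanking the gap on the cut strand to guanine and
#' the opposite triplet to C-T-C (the unpaired nucleotide's partner becomes
#' the central T), i.e. 5'-G*G-3' over 3'-CTC-5' around the missing
#' nucleotide '*'. Applying the motif twice is a no-op.
#'
#' @param model a StructureModel containing the break.
#' @param ssb_site a `DamageSite` of kind "ssb".
#' @param motif only the default "G*G/CTC" is supported.
#' @return the modified StructureModel.
#' @export
set_flank_motif <- function(model, ssb_site, motif = "G*G/CTC") {
  if (!identical(motif, "G*G/CTC")) stop("motif length mismatch: only G*G/CTC supported")
  if (!inherits(ssb_site, "DamageSite") || ssb_site$kind != "ssb")
    stop("ssb_site must be a DamageSite of kind 'ssb'")
  plan <- list(list(ssb_site$flank5, "G"), list(ssb_site$flank3, "G"),
               list(ssb_site$partner5, "C"), list(ssb_site$partner3, "C"),
               list(ssb_site$unpaired, "T"))
  for (p in plan) {
    at <- residue_atoms(model, p[[1L]]$chain, p[[1L]]$resid)
    if (length(at) == 0L) stop("motif residue missing: ",
                               p[[1L]]$chain, ":", p[[1L]]$resid)
    if (identical(base_letter(model$atoms$resname[at[1L]]), p[[2L]])) next
    model <- swap_base(model, p[[1L]], p[[2L]])$model
  }
  model
}

#' Serialize / restore a DamageSite as JSON
#' @param site a DamageSite.
#' @param path output path.
#' @export
write_damage_site <- function(site, path) {
  jsonlite::write_json(unclass(site), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_damage_site
#' @export
read_damage_site <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "DamageSite")
}
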