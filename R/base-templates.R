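# Idealized planar heavy-atom base templates, built from regular-polygon
# geometry (ring bond 1.38 A, exocyclic substituents radial). Coordinates are
# 2-D in the base plane with the glycosidic nitrogen (N1 pyrimidine / N9
# purine) at the origin and the ring interior along +x. These are generic
# nucleic-acid geometries bundled with the package; no external template
# library is required.

BASE_RING_BOND <- 1.38
GLYCOSIDIC_BOND <- 1.47

polygon_ring <- function(names, center, start_angle_deg, step_deg) {
  r <- BASE_RING_BOND / (2 * sin(pi / length(names)))
  ang <- deg2rad(start_angle_deg + step_deg * (seq_along(names) - 1L))
  data.frame(name = names,
             x = center[1L] + r * cos(ang),
             y = center[2L] + r * sin(ang),
             stringsAsFactors = FALSE)
}

add_substituent <- function(ring, center, at, name, bond) {
  i <- match(at, ring$name)
  u <- c(ring$x[i] - center[1L], ring$y[i] - center[2L])
  u <- u / sqrt(sum(u^2))
  rbind(ring, data.frame(name = name,
                         x = ring$x[i] + bond * u[1L],
                         y = ring$y[i] + bond * u[2L]))
}

pyrimidine_ring <- function() {
  ctr <- c(BASE_RING_BOND, 0)
  ring <- polygon_ring(c("N1", "C2", "N3", "C4", "C5", "C6"), ctr, 180, -60)
  list(ring = ring, center = ctr)
}

purine_rings <- function() {
  r5 <- BASE_RING_BOND / (2 * sin(pi / 5))
  ctr5 <- c(r5, 0)
  pent <- polygon_ring(c("N9", "C4", "C5", "N7", "C8"), ctr5, 180, -72)
  m <- c(mean(pent$x[2:3]), mean(pent$y[2:3]))          # C4-C5 midpoint
  u <- (m - ctr5) / sqrt(sum((m - ctr5)^2))
  ctr6 <- m + (BASE_RING_BOND * sqrt(3) / 2) * u        # hexagon apothem
  a4 <- rad2deg(atan2(pent$y[2L] - ctr6[2L], pent$x[2L] - ctr6[1L]))
  a5 <- rad2deg(atan2(pent$y[3L] - ctr6[2L], pent$x[3L] - ctr6[1L]))
  # step direction that walks from C4 away from C5 around the hexagon
  step <- if (abs(((a4 + 60 - a5 + 180) %% 360) - 180) < 1) -60 else 60
  hexr <- polygon_ring(c("C4x", "N3", "C2", "N1", "C6", "C5x"), ctr6, a4, step)
  hexr <- hexr[!hexr$name %in% c("C4x", "C5x"), ]
  list(ring = rbind(pent, hexr), center5 = ctr5, center6 = ctr6)
}

#' Idealized base template
#'
#' @param base one of "A", "C", "G", "T", "U".
#' @return data.frame with columns name, x, y, element; glycosidic N at the
#'   origin, ring interior along +x, all atoms in the z = 0 plane.
#' @export
base_template <- function(base) {
  base <- toupper(base)
  if (base %in% c("T", "U", "C")) {
    p <- pyrimidine_ring()
    ring <- add_substituent(p$ring, p$center, "C2", "O2", 1.23)
    if (base == "T") {
      ring <- add_substituent(ring, p$center, "C4", "O4", 1.23)
      ring <- add_substituent(ring, p$center, "C5", "C7", 1.50)
    } else if (base == "U") {
      ring <- add_substituent(ring, p$center, "C4", "O4", 1.23)
    } else {
      ring <- add_substituent(ring, p$center, "C4", "N4", 1.34)
    }
  } else if (base %in% c("A", "G")) {
    p <- purine_rings()
    ring <- p$ring
    if (base == "A") {
      ring <- add_substituent(ring, p$center6, "C6", "N6", 1.34)
    } else {
      ring <- add_substituent(ring, p$center6, "C6", "O6", 1.23)
      ring <- add_substituent(ring, p$center6, "C2", "N2", 1.34)
    }
  } else stop("unknown base: ", base)
  ring$element <- substr(ring$name, 1L, 1L)
  rownames(ring) <- NULL
  ring
}

glycosidic_atom <- function(base) if (toupper(base) %in% c("A", "G")) "N9" else "N1"

base_resname <- function(base) paste0("D", toupper(base))

base_letter <- function(resname) {
  rn <- toupper(resname)
  map <- c(DA = "A", DT = "T", DG = "G", DC = "C", DU = "U",
           A = "A", T = "T", G = "G", C = "C", U = "U",
           ADE = "A", THY = "T", GUA = "G", CYT = "C", URA = "U")
  unname(map[rn])
}

complement_base <- function(base) {
  c(A = "T", T = "A", G = "C", C = "G", U = "A")[[toupper(base)]]
}

# Atom names considered part of the base moiety (vs backbone + sugar).
BACKBONE_SUGAR_NAMES <- c("P", "OP1", "OP2", "O1P", "O2P", "O5'", "C5'",
                          "C4'", "O4'", "C3'", "O3'", "C2'", "C1'",
                          "HO3'", "C1R", "C2R", "C3R", "C4R", "O4R", "O5R")

is_base_atom <- function(name) !(normalize_atom_name(name) %in% BACKBONE_SUGAR_NAMES) &
  !grepl("'", normalize_atom_name(name), fixed = TRUE)

# Place a base template in 3-D. origin = C1' position, e1 = unit vector from
# C1' toward the glycosidic N, normal = base-plane normal. Returns a
# data.frame of name/element/x/y/z. `with_centroid` adds the CEN pseudo-atom
# (ring centroid) used by the coarse builder.
place_base_template <- function(base, c1_pos, e1, normal, with_centroid = FALSE) {
  tpl <- base_template(base)
  e1 <- vunit(e1)
  n <- vunit(normal - sum(normal * e1) * e1)
  e2 <- vcross(n, e1)
  npos <- c1_pos + GLYCOSIDIC_BOND * e1
  xyz <- t(apply(tpl[, c("x", "y")], 1L, function(p) npos + p[1L] * e1 + p[2L] * e2))
  out <- data.frame(name = tpl$name, element = tpl$element,
                    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                    stringsAsFactors = FALSE)
  if (with_centroid) {
    ring <- !out$name %in% c("O2", "O4", "N4", "C7", "N6", "O6", "N2")
    out <- rbind(out, data.frame(name = "CEN", element = "C",
                                 x = mean(out$x[ring]), y = mean(out$y[ring]),
                                 z = mean(out$z[ring])))
  }
  out
}
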