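# Shared fixtures, built in code and cached per test run. Sizes are kept
# small so the whole suite stays well inside the time budget; the 145-bp
# nucleosome wrap is built once.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

tiny_duplex <- function(n = 10L, seq = NULL) {
  build_bdna(seq %||% strrep("A", n))
}

mixed_duplex <- function() fixture("mixed35", function() build_bdna(strrep("ACGTG", 7)))

nucleosome_wrap <- function() fixture("wrap145", function()
  wrap_superhelix(build_bdna(strrep("ACGTG", 29))))

wrap_shlmap <- function() fixture("shl145", function()
  shl_map(nucleosome_wrap()))

# SSB at SHL -5 (bp 21) on the wrapped nucleosome, with its map
wrap_ssb <- function() fixture("ssb145", function()
  make_ssb(nucleosome_wrap(), list(chain = "I", resid = 21),
           shlmap = wrap_shlmap()))

`%||%` <- function(a, b) if (is.null(a)) b else a

rigid_transform <- function(model, axis = c(1, 2, 3), angle = 63,
                            shift = c(10, -4, 7)) {
  R <- rot3(axis, angle)
  coords(model) <- sweep(coords(model) %*% t(R), 2L, shift, `+`)
  model
}

rot3 <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * tcrossprod(u)
}

kabsch_rmsd_nm <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(Ac, Bc))
  R <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
  sqrt(mean(rowSums((Ac %*% t(R) - Bc)^2))) / 10
}

dihedral_oracle <- function(p1, p2, p3, p4) {
  # independent textbook implementation (atan2-free variant) used as oracle
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  acos(max(-1, min(1, cosphi))) * 180 / pi
}
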