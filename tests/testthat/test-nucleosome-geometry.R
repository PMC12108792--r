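test_that("superhelix axis is recovered within 1 degree on the generator", {
  w <- nucleosome_wrap()
  fit <- fit_superhelix(w)
  ang <- acos(min(1, abs(sum(fit$axis * c(0, 0, 1))))) * 180 / pi
  expect_lt(ang, 1)
  # sign convention: left-handed about +axis, generator wraps about +z
  expect_gt(fit$axis[3L], 0)
})

test_that("axis fit is equivariant under rigid rotation", {
  w <- nucleosome_wrap()
  fit <- fit_superhelix(w)
  R <- rot3(c(1, 2, 3), 77)
  w2 <- w
  coords(w2) <- coords(w) %*% t(R)
  fit2 <- fit_superhelix(w2)
  expect_lt(acos(min(1, abs(sum(fit2$axis * (R %*% fit$axis))))) * 180 / pi, 1)
})

test_that("a planar circle of phosphates yields its normal as axis", {
  th <- seq(0, 2 * pi, length.out = 121L)[-121L]
  atoms <- data.frame(name = "P", resname = "DA", chain = "I",
                      resid = seq_along(th),
                      x = 40 * cos(th), y = 40 * sin(th), z = 0, element = "P")
  m <- structure_model(atoms)
  fit <- fit_superhelix(m, dna_chains = "I")
  expect_lt(acos(min(1, abs(fit$axis[3L]))) * 180 / pi, 1)
})

test_that("too few phosphates is a geometry error", {
  m <- tiny_duplex(5L)
  expect_error(fit_superhelix(m), "geometry error")
})

test_that("SHL is 0 at the dyad and counts bp/10.4 away from it", {
  sm <- wrap_shlmap()
  expect_equal(shl_of(sm, sm$dyad$chain, sm$dyad$resid), 0)
  # dyad of the 145-mer is I:73; 52 steps away -> SHL +/- 5
  expect_equal(shl_of(sm, "I", 73L + 52L), 5, tolerance = 1e-12)
  expect_equal(shl_of(sm, "I", 73L - 52L), -5, tolerance = 1e-12)
  # full wrap spans ~[-7, +7]
  expect_equal(range(sm$shl_of$shl), c(-6.923, 6.923), tolerance = 1e-3)
})

test_that("SHL coordinates are invariant under rigid motion", {
  w <- nucleosome_wrap()
  sm <- wrap_shlmap()
  sm2 <- shl_map(rigid_transform(w))
  expect_equal(sm2$shl_of$shl, sm$shl_of$shl)
  expect_identical(sm2$shl_of$gyre, sm$shl_of$gyre)
})

test_that("SHL is monotone along each strand and gyres split at the dyad", {
  sm <- wrap_shlmap()
  si <- sm$shl_of[sm$shl_of$chain == "I", ]
  expect_true(all(diff(si$shl[order(si$resid)]) > 0))
  expect_setequal(unique(sm$shl_of$gyre), c("upper", "lower"))
  expect_identical(unique(si$gyre[si$shl < -0.1]),
                   setdiff(c("upper", "lower"), unique(si$gyre[si$shl > 0.1])))
})

test_that("unequal strands without pairing hints are a pairing error", {
  r <- wrap_ssb()   # deletion leaves 144 vs 145 nucleotides
  expect_error(shl_map(r$model), "pairing error")
})

test_that("the 145-bp wrap has 14 inward minor-groove contact points", {
  cp <- contact_points(wrap_shlmap(), nucleosome_wrap())
  expect_length(cp, 14L)
  expect_identical(cp, sort(cp))
  # contacts sit near half-integer SHL, symmetric about the dyad
  expect_lt(max(abs(abs(cp) %% 1 - 0.5)), 0.25)
  expect_equal(cp, -rev(cp), tolerance = 0.15)
})

test_that("a straight duplex has no contact points", {
  s <- build_bdna(strrep("A", 60))
  expect_length(contact_points(shl_map(s), s), 0L)
})

test_that("a half wrap has about half the contacts (brute-force oracle)", {
  h <- wrap_superhelix(build_bdna(strrep("A", 72)))
  smh <- shl_map(h)
  got <- length(contact_points(smh, h))
  # oracle: count minor-groove inward windows directly from the generator's
  # phase convention (groove faces outward at the dyad, period 10.4 bp)
  n <- 72
  shl <- ((1:n) - (n + 1) / 2) / 10.4
  # inward events occur at half-integer SHL with a +/-60 deg detection
  # window (1/6 SHL): windows fully inside the wrapped range must all be
  # found; truncated edge windows may or may not survive the superhelical
  # torsion drift
  k <- seq(-6.5, 6.5, by = 1)
  lo <- sum(k - 1 / 6 >= min(shl) & k + 1 / 6 <= max(shl))
  hi <- sum(k - 1 / 6 <= max(shl) & k + 1 / 6 >= min(shl))
  expect_gte(got, lo)
  expect_lte(got, hi)
  expect_lte(abs(got - 7L), 1L)
})

test_that("contact count is stable under 0.5 A coordinate noise", {
  w <- nucleosome_wrap()
  set.seed(42)
  for (rep in 1:3) {
    w2 <- w
    coords(w2) <- coords(w) + matrix(rnorm(3L * n_atoms(w), 0, 0.5),
                                     ncol = 3L)
    got <- length(contact_points(shl_map(w2), w2))
    expect_gte(got, 13L)
    expect_lte(got, 15L)
  }
})

test_that("accessibility classes follow base orientation and flip 180", {
  w <- nucleosome_wrap()
  sm <- wrap_shlmap()
  classes <- vapply(10:135, function(r)
    classify_accessibility(w, list(chain = "I", resid = r), sm)$class, "")
  expect_setequal(unique(classes), c("easy", "medium", "hard"))
  # pick a clearly easy site and rotate its base atoms 180 about the local
  # helix axis: easy and hard must swap
  calls <- lapply(10:135, function(r)
    classify_accessibility(w, list(chain = "I", resid = r), sm))
  th <- vapply(calls, function(x) x$theta_deg, 0)
  r_easy <- (10:135)[which.min(th)]
  site <- list(chain = "I", resid = r_easy)
  a0 <- classify_accessibility(w, site, sm)
  expect_equal(a0$class, "easy")
  # rotate the base atoms 180 deg about the local double-helical axis:
  # axis point = windowed mean of nearby residues (both strands), axis
  # direction = local tangent of the wrapped path
  ai <- select_atoms(w, chain = "I", resid = r_easy)
  nm <- w$atoms$name[ai]
  base <- ai[!nm %in% c("P", "O5'", "C5'", "C4'", "C3'", "O3'", "C1'")]
  xyz <- coords(w)
  near <- c(select_atoms(w, chain = "I", resid = (r_easy - 5):(r_easy + 5)),
            select_atoms(w, chain = "J",
                         resid = (145 + 1 - r_easy - 5):(145 + 1 - r_easy + 5)))
  axp <- colMeans(xyz[near, , drop = FALSE])
  fwd <- colMeans(xyz[select_atoms(w, chain = "I", resid = r_easy + 2), , drop = FALSE])
  bwd <- colMeans(xyz[select_atoms(w, chain = "I", resid = r_easy - 2), , drop = FALSE])
  Rm <- rot3(fwd - bwd, 180)
  xyz[base, ] <- sweep(sweep(xyz[base, , drop = FALSE], 2L, axp) %*% t(Rm),
                       2L, axp, `+`)
  w2 <- w; coords(w2) <- xyz
  a1 <- classify_accessibility(w2, site, sm)
  expect_equal(a1$class, "hard")
})

test_that("accessibility is rigid-motion invariant and flags tail proximity", {
  w <- nucleosome_wrap()
  sm <- wrap_shlmap()
  site <- list(chain = "I", resid = 40L)
  a0 <- classify_accessibility(w, site, sm)
  w2 <- rigid_transform(w, axis = c(0, 1, 1), angle = 120, shift = c(-3, 8, 1))
  a2 <- classify_accessibility(w2, site, shl_map(w2))
  expect_equal(a0$class, a2$class)
  expect_equal(a0$theta_deg, a2$theta_deg, tolerance = 0.1)
  # a pseudo-tail next to the site triggers the proximity flag
  pm <- place_probe_residues(w, list(list(
    resname = "GLY", chain = "T", resid = 3,
    anchor = list(chain = "I", resid = 40, name = "C3'"), distance = 0.4)))
  at <- classify_accessibility(pm, site, shl_map(pm),
                               tail_ranges = list(T = 1:44), tail_cutoff = 5)
  expect_true(at$tail_proximal)
  expect_equal(at$tail_id, "T")
  af <- classify_accessibility(pm, site, shl_map(pm),
                               tail_ranges = list(T = 1:44), tail_cutoff = 1)
  expect_false(af$tail_proximal)
})

test_that("non-DNA sites are rejected", {
  w <- nucleosome_wrap()
  sm <- wrap_shlmap()
  expect_error(classify_accessibility(w, list(chain = "Z", resid = 1), sm),
               "not a mapped DNA nucleotide")
})

test_that("shl_table exports chain/resid/shl/gyre", {
  sm <- wrap_shlmap()
  tab <- shl_table(sm)
  expect_named(tab, c("chain", "resid", "shl", "gyre"))
  f <- withr::local_tempfile(fileext = ".csv")
  shl_table(sm, f)
  expect_equal(nrow(utils::read.csv(f)), nrow(tab))
})
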