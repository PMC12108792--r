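test_that("gap distance is plain Euclidean distance in nm", {
  # two pseudo-termini placed by hand: 12 A apart -> 1.2 nm
  atoms <- data.frame(name = "C3'", resname = "DG", chain = "I",
                      resid = c(9L, 11L),
                      x = c(0, 12), y = 0, z = 0, element = "C")
  m <- structure_model(atoms)
  site <- structure(list(kind = "ssb", anchor = list(chain = "I", resid = 10L),
                         ends = list(three = list(chain = "I", resid = 9L, cap = "OH"),
                                     five = list(chain = "I", resid = 11L, cap = "dRP"))),
                    class = "DamageSite")
  expect_equal(gap_distance(m, site), 1.2)
  # coincident termini -> 0
  m0 <- m; x <- coords(m0); x[2, ] <- x[1, ]; coords(m0) <- x
  expect_equal(gap_distance(m0, site), 0)
  # missing anchor names the residue
  bad <- m; bad$atoms$name[2] <- "C4'"
  expect_error(gap_distance(bad, site), "C3' not found in residue I:11")
})

test_that("local twist is 0 for coplanar cis atoms and matches the oracle", {
  atoms <- data.frame(name = "C3'", resname = "DG", chain = c("I", "J", "J", "I"),
                      resid = c(9L, 12L, 10L, 11L),
                      x = c(0, 0, 1, 1), y = c(1, 0, 0, 1), z = 0, element = "C")
  m <- structure_model(atoms)
  site <- structure(list(kind = "ssb",
                         flank5 = list(chain = "I", resid = 9L),
                         flank3 = list(chain = "I", resid = 11L),
                         partner5 = list(chain = "J", resid = 12L),
                         partner3 = list(chain = "J", resid = 10L)),
                    class = "DamageSite")
  expect_equal(local_twist(m, site), 0)
  # random quadruples agree with an independent dihedral implementation
  set.seed(11)
  for (k in 1:25) {
    xyz <- matrix(rnorm(12, sd = 4), 4L, 3L)
    m2 <- m; coords(m2) <- xyz
    expect_equal(local_twist(m2, site),
                 dihedral_oracle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("relaxed ideal B-DNA at 10.4 bp/turn gives Phi in the 60-70 band", {
  m <- tiny_duplex(11L)
  phi <- local_twist(m, list(chain = "I", resid = 6))
  expect_gte(phi, 60)
  expect_lte(phi, 70)
})

test_that("an injected Phi of 45 degrees is recovered within 1 degree", {
  r <- wrap_ssb()
  tr <- make_trajectory(r$model,
                        list(deformation_signal("phi", schedule = rep(45, 3),
                                                site = r$site)),
                        n_frames = 3)
  got <- compute_series(tr, "phi", site = r$site)$values
  expect_lt(max(abs(got - 45)), 1)
})

test_that("gyre gaping measures the fixed-partner P-P distance", {
  # two parallel straight duplexes 11.5 A apart -> 1.15 nm between nearest P
  m1 <- tiny_duplex(12L)
  a <- m1$atoms
  b <- a
  b$chain <- ifelse(b$chain == "I", "K", "L")
  b$z <- b$z + 11.5
  m <- structure_model(rbind(a, b))
  ip <- select_atoms(m, chain = "I", resid = 6, name = "P")
  # partner: same residue one duplex over -> exactly 11.5 A along z
  site <- structure(list(kind = "ssb", anchor = list(chain = "I", resid = 6L),
                         unpaired = list(chain = "I", resid = 6L)),
                    class = "DamageSite")
  fake_map <- structure(list(shl_of = data.frame(chain = "I", resid = 6L,
                                                 shl = 3, gyre = "lower")),
                        class = "SHLMap")
  d <- gyre_gaping(m, site, fake_map, partner = list(chain = "K", resid = 6L))
  expect_equal(d, 1.15)
})

test_that("dw drift injection is recovered within 0.05 nm at the endpoints", {
  r <- wrap_ssb()
  sm <- wrap_shlmap()
  sched <- seq(1.15, 1.6, length.out = 8)
  tr <- make_trajectory(r$model,
                        list(deformation_signal("dw", schedule = sched,
                                                site = r$site, shlmap = sm)),
                        n_frames = 8)
  got <- compute_series(tr, "dw", site = r$site, shlmap = sm)$values
  expect_lt(abs(got[1] - 1.15), 0.05)
  expect_lt(abs(got[8] - 1.60), 0.05)
})

test_that("dw at the dyad is a geometry error", {
  w <- nucleosome_wrap()
  sm <- wrap_shlmap()
  r <- make_ssb(w, list(chain = "I", resid = 73), shlmap = sm)
  expect_error(gyre_partner(r$model, r$site, sm), "no adjacent winding")
})

test_that("pair_distance handles min and com modes and degenerate inputs", {
  atoms <- data.frame(name = c("CA", "CA"), resname = "GLY", chain = c("A", "B"),
                      resid = 1L, x = c(0, 5), y = 0, z = 0, element = "C")
  m <- structure_model(atoms)
  expect_equal(pair_distance(m, list(chain = "A"), list(chain = "B"), "min"), 0.5)
  expect_equal(pair_distance(m, list(chain = "A"), list(chain = "B"), "com"), 0.5)
  expect_equal(pair_distance(m, list(chain = "A"), list(chain = "A"), "com"), 0)
  expect_error(pair_distance(m, list(chain = "Z"), list(chain = "B")),
               "empty selection")
  # symmetry
  md <- mixed_duplex()
  a <- list(chain = "I", resid = 5); b <- list(chain = "J", resid = 30)
  expect_equal(pair_distance(md, a, b, "min"), pair_distance(md, b, a, "min"))
  expect_equal(pair_distance(md, a, b, "com"), pair_distance(md, b, a, "com"))
})

test_that("hbond presence transitions exactly at the cutoff", {
  top <- structure_model(data.frame(
    name = c("O4", "N"), resname = c("DU", "PHE"), chain = c("I", "A"),
    resid = c(5L, 158L), x = c(0, 2.5), y = 0, z = 0, element = c("O", "N")))
  dists <- seq(2.5, 6.0, by = 0.25)
  frames <- lapply(dists, function(d) { x <- coords(top); x[2, 1] <- d; x })
  tr <- trajectory(top, frames)
  hb <- hbond_series(tr, list(chain = "A", name = "N"), list(chain = "I", name = "O4"))
  expect_identical(hb$present, dists <= 3.5)
  expect_equal(hb$distance$values, dists / 10)
  expect_equal(hb$distance$units, "nm")
  # multi-atom selections are anchor errors
  expect_error(hbond_series(tr, list(chain = "A"), list(resid = c(5, 158))),
               "single atoms")
})

test_that("rmsd matches the closed form and superposition never increases it", {
  m0 <- tiny_duplex(8L)
  N <- n_atoms(m0)
  m1 <- m0
  x <- coords(m1); x[3, ] <- x[3, ] + c(0, 4, 0); coords(m1) <- x
  expect_equal(rmsd_to_reference(m1, m0, superpose = FALSE), 0.4 / sqrt(N))
  expect_equal(rmsd_to_reference(m0, m0, superpose = FALSE), 0)
  mt <- m0
  coords(mt) <- sweep(coords(m0) %*% t(rot3(c(1, 1, 0), 30)), 2L, c(7, 1, -2), `+`)
  expect_lt(rmsd_to_reference(mt, m0, superpose = TRUE), 1e-6)
  set.seed(5)
  for (k in 1:10) {
    mr <- m0
    coords(mr) <- coords(m0) + matrix(rnorm(3 * N), ncol = 3L)
    expect_lte(rmsd_to_reference(mr, m0, superpose = TRUE),
               rmsd_to_reference(mr, m0, superpose = FALSE) + 1e-12)
  }
  expect_error(rmsd_to_reference(m0, m0, selection = list(name = "P"),
                                 ref_selection = list(name = "C1'")),
               "1:1")
})

test_that("all distance and dihedral observables are rigid-motion invariant", {
  r <- wrap_ssb()
  sm <- wrap_shlmap()
  partner <- gyre_partner(r$model, r$site, sm)
  m2 <- rigid_transform(r$model, axis = c(3, -1, 2), angle = 147,
                        shift = c(-20, 13, 5))
  expect_equal(gap_distance(m2, r$site), gap_distance(r$model, r$site),
               tolerance = 1e-9)
  expect_equal(local_twist(m2, r$site), local_twist(r$model, r$site),
               tolerance = 1e-9)
  expect_equal(gyre_gaping(m2, r$site, sm, partner = partner),
               gyre_gaping(r$model, r$site, sm, partner = partner),
               tolerance = 1e-9)
  # reflection flips the dihedral sign but not its reported magnitude
  m3 <- r$model
  x <- coords(m3); x[, 1] <- -x[, 1]; coords(m3) <- x
  expect_equal(local_twist(m3, r$site), local_twist(r$model, r$site),
               tolerance = 1e-9)
})

test_that("series stats normalize and summarize", {
  s <- observable_series("dg", rep(1.4, 25), "nm")
  st <- series_stats(s, nbins = 10)
  expect_equal(sum(st$histogram$prob), 1)
  expect_equal(sum(st$histogram$prob > 0), 1L)   # one occupied bin
  expect_equal(st$mean, 1.4)
  set.seed(9)
  u <- runif(4000)
  stu <- series_stats(u, nbins = 10)
  expect_equal(sum(stu$histogram$prob), 1)
  # flat within multinomial noise: sd of bin mass ~ sqrt(p(1-p)/n)
  expect_lt(max(abs(stu$histogram$prob - 0.1)), 5 * sqrt(0.1 * 0.9 / 4000))
  expect_error(series_stats(numeric(0)), "empty")
  # running average over a window
  st2 <- series_stats(1:10, window = 2L)
  expect_equal(st2$running[3], 2.5)
})

test_that("correlate recovers exact and injected linear relations", {
  x <- observable_series("dg", seq(1, 2, length.out = 20), "nm")
  y2 <- observable_series("phi", 2 * x$values, "degrees")
  co <- correlate(x, y2)
  expect_equal(co$slope, 2)
  expect_equal(co$r, 1)
  co_neg <- correlate(x$values, -x$values)
  expect_equal(co_neg$r, -1)
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
  # coupled injection with noise at fixed seed: recover a and b within 2 SE
  set.seed(31)
  a <- 31.25; b <- 2.5; sigma <- 3
  xg <- seq(1.2, 2.0, length.out = 60)
  yg <- a * xg + b + rnorm(60, 0, sigma)
  fit <- correlate(xg, yg)
  se_a <- sigma / (sd(xg) * sqrt(59))
  expect_lt(abs(fit$slope - a), 2 * se_a)
  expect_lt(abs(fit$intercept - b), 2 * se_a * mean(xg) * 1.5 + 2 * sigma / sqrt(60))
})

test_that("injected schedules are recovered within 3x the injected noise", {
  r <- wrap_ssb()
  sm <- wrap_shlmap()
  sched_dg <- seq(1.2, 2.2, length.out = 40)
  sig <- deformation_signal("dg", schedule = sched_dg, noise_sigma = 0.02,
                            seed = 17, site = r$site)
  tr <- make_trajectory(r$model, list(sig), n_frames = 40)
  got <- compute_series(tr, "dg", site = r$site)$values
  resid <- got - sched_dg
  # the analysis recovers the injected signal exactly up to the injected
  # noise: residuals reproduce the seeded noise draw itself
  set.seed(17)
  expect_equal(resid, rnorm(40, 0, 0.02), tolerance = 1e-6)
  expect_gt(sd(resid), 0.01)
  expect_lt(sd(resid), 0.04)
})
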