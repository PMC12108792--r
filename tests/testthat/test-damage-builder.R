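test_that("T -> U removes exactly the C7 methyl and renames the residue", {
  m <- mixed_duplex()                     # ACGTG x 7: I:9 is a T
  r <- swap_base(m, list(chain = "I", resid = 9), "U")
  expect_equal(n_atoms(r$model), n_atoms(m) - 1L)
  i9 <- select_atoms(r$model, chain = "I", resid = 9)
  expect_false("C7" %in% r$model$atoms$name[i9])
  expect_equal(unique(r$model$atoms$resname[i9]), "DU")
  expect_equal(r$site$kind, "uracil-swap")
  # backbone untouched
  bb0 <- select_atoms(m, chain = "I", resid = 9, name = c("P", "C3'", "C1'"))
  bb1 <- select_atoms(r$model, chain = "I", resid = 9, name = c("P", "C3'", "C1'"))
  expect_equal(coords(r$model)[bb1, ], coords(m)[bb0, ], ignore_attr = TRUE)
})

test_that("identity swap leaves coordinates unchanged; U->T round trip < 0.1 A", {
  m <- mixed_duplex()
  s3 <- swap_base(m, list(chain = "I", resid = 9), "T")
  expect_equal(coords(s3$model), coords(m), tolerance = 1e-10)
  s1 <- swap_base(m, list(chain = "I", resid = 9), "U")
  s2 <- swap_base(s1$model, list(chain = "I", resid = 9), "T")
  i0 <- select_atoms(m, chain = "I", resid = 9)
  i2 <- select_atoms(s2$model, chain = "I", resid = 9)
  expect_setequal(m$atoms$name[i0], s2$model$atoms$name[i2])
  common <- intersect(m$atoms$name[i0], s2$model$atoms$name[i2])
  a0 <- coords(m)[i0, , drop = FALSE][match(common, m$atoms$name[i0]), ]
  a2 <- coords(s2$model)[i2, , drop = FALSE][match(common, s2$model$atoms$name[i2]), ]
  expect_lt(sqrt(mean(rowSums((a0 - a2)^2))), 0.1)
})

test_that("swap changes only the documented residue; all other atoms bit-identical", {
  m <- mixed_duplex()
  r <- swap_base(m, list(chain = "I", resid = 9), "U")
  other0 <- m$atoms[!(m$atoms$chain == "I" & m$atoms$resid == 9), ]
  other1 <- r$model$atoms[!(r$model$atoms$chain == "I" & r$model$atoms$resid == 9), ]
  expect_identical(other0[, c("name", "resname", "chain", "resid", "x", "y", "z")],
                   other1[, c("name", "resname", "chain", "resid", "x", "y", "z")],
                   ignore_attr = TRUE)
})

test_that("flip of angle 0 is the identity; 180 twice is an involution", {
  m <- mixed_duplex()
  site <- list(chain = "I", resid = 18)
  f0 <- flip_base(m, site, angle_deg = 0)
  expect_equal(coords(f0$model), coords(m), tolerance = 1e-12)
  f1 <- flip_base(m, site)
  f2 <- flip_base(f1$model, site)
  expect_lt(max(abs(coords(f2$model) - coords(m))), 1e-3)
  expect_equal(f1$site$rotation_deg, 180)
})

test_that("flip keeps the flanking phosphates fixed and ejects the base", {
  m <- mixed_duplex()
  site <- list(chain = "I", resid = 18)
  f <- flip_base(m, site)
  p_self0 <- coords(m)[select_atoms(m, chain = "I", resid = 18, name = "P"), ]
  p_self1 <- coords(f$model)[select_atoms(f$model, chain = "I", resid = 18, name = "P"), ]
  p_next0 <- coords(m)[select_atoms(m, chain = "I", resid = 19, name = "P"), ]
  p_next1 <- coords(f$model)[select_atoms(f$model, chain = "I", resid = 19, name = "P"), ]
  expect_equal(p_self1, p_self0, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(p_next1, p_next0, tolerance = 1e-12, ignore_attr = TRUE)
  # base centroid ends extrahelical: radial distance from the (z) helix
  # axis of the straight builder grows by > 3 A
  rad <- function(mm) {
    i <- select_atoms(mm, chain = "I", resid = 18, name = "CEN")
    sqrt(sum(coords(mm)[i, 1:2]^2))
  }
  expect_gt(rad(f$model) - rad(m), 3)
})

test_that("flipping a terminal nucleotide errors", {
  m <- mixed_duplex()
  expect_error(flip_base(m, list(chain = "I", resid = 35)), "terminal")
  expect_error(flip_base(m, list(chain = "I", resid = 1)), "terminal")
})

test_that("make_ssb deletes one nucleotide and fixes the documented termini", {
  m <- tiny_duplex(20L)
  r <- make_ssb(m, list(chain = "I", resid = 10))
  rt <- residue_table(r$model)
  expect_equal(sum(rt$chain == "I"), 19L)
  expect_equal(sum(rt$chain == "J"), 20L)
  expect_false(10L %in% rt$resid[rt$chain == "I"])   # resid gap of exactly 1
  expect_equal(r$site$ends$three, list(chain = "I", resid = 9L, cap = "OH"))
  expect_equal(r$site$ends$five, list(chain = "I", resid = 11L, cap = "dRP"))
  expect_equal(r$site$unpaired, list(chain = "J", resid = 11L))
  # dRP cap atoms live on the 5' neighbor
  i11 <- select_atoms(r$model, chain = "I", resid = 11)
  expect_true(all(c("C1R", "C3R", "C4R") %in% r$model$atoms$name[i11]))
  # plain-phosphate cap adds nothing
  r2 <- make_ssb(m, list(chain = "I", resid = 10), five_cap = "phosphate")
  i11b <- select_atoms(r2$model, chain = "I", resid = 11)
  expect_false(any(grepl("R$", r2$model$atoms$name[i11b])))
})

test_that("ssb construction refuses termini and all untouched atoms are identical", {
  m <- tiny_duplex(20L)
  expect_error(make_ssb(m, list(chain = "I", resid = 1)), "terminus")
  expect_error(make_ssb(m, list(chain = "I", resid = 20)), "terminus")
  r <- make_ssb(m, list(chain = "I", resid = 10), five_cap = "phosphate")
  kept0 <- m$atoms[!(m$atoms$chain == "I" & m$atoms$resid == 10),
                   c("name", "chain", "resid", "x", "y", "z")]
  kept1 <- r$model$atoms[, c("name", "chain", "resid", "x", "y", "z")]
  expect_identical(kept0, kept1, ignore_attr = TRUE)
})

test_that("initial dg matches the closed form from the builder's helix", {
  m <- tiny_duplex(20L)
  r <- make_ssb(m, list(chain = "I", resid = 10))
  dg <- gap_distance(r$model, r$site)
  # C3' atoms of bp i-1 and i+1 on the same strand: chord of 2 helical
  # steps at the builder's C3' radius plus 2 rises
  rad <- 9.0; omega <- 2 * 360 / 10.4 * pi / 180; rise <- 3.4
  analytic <- sqrt((2 * rad * sin(omega / 2))^2 + (2 * rise)^2) / 10
  expect_lt(abs(dg - analytic), 0.2)
  expect_equal(dg, 1.23, tolerance = 0.02)   # ~ the 1.2 nm docked separation
})

test_that("construct-then-save equals save-then-construct", {
  m <- tiny_duplex(20L)
  r <- make_ssb(m, list(chain = "I", resid = 10))
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(r$model, f1)
  f0 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f0)
  r2 <- make_ssb(read_structure(f0), list(chain = "I", resid = 10))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(r2$model, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and dg is computable on the reloaded structure
  expect_equal(gap_distance(read_structure(f1), r$site),
               gap_distance(r$model, r$site), tolerance = 1e-3)
})

test_that("the damage-site record locates every observable anchor atom", {
  r <- wrap_ssb()
  m <- r$model; s <- r$site
  for (res in list(s$ends$three, s$ends$five)) {
    expect_length(select_atoms(m, chain = res$chain, resid = res$resid,
                               name = "C3'"), 1L)
  }
  expect_length(select_atoms(m, chain = s$unpaired$chain,
                             resid = s$unpaired$resid, name = "P"), 1L)
  json <- withr::local_tempfile(fileext = ".json")
  write_damage_site(s, json)
  s2 <- read_damage_site(json)
  expect_equal(s2$kind, "ssb")
  expect_equal(s2$ends$five$resid, s$ends$five$resid)
  expect_equal(gap_distance(m, s2), gap_distance(m, s))
})

test_that("flank motif forces G*G over CTC and is idempotent", {
  m <- build_bdna(strrep("A", 21))
  r <- make_ssb(m, list(chain = "I", resid = 11))
  m1 <- set_flank_motif(r$model, r$site)
  rt <- residue_table(m1)
  expect_equal(rt$resname[rt$chain == "I" & rt$resid %in% c(10, 12)],
               c("DG", "DG"))
  # opposite triplet (J partners of 12, 11, 10) must read C, T, C
  jres <- 21 + 1 - c(12, 11, 10)
  expect_equal(rt$resname[rt$chain == "J" & rt$resid %in% sort(jres)],
               c("DC", "DT", "DC"))
  m2 <- set_flank_motif(m1, r$site)
  expect_identical(m1$atoms[, -1], m2$atoms[, -1])   # serials aside
  # already-G flanks are a no-op
  g <- build_bdna(strrep("G", 15))
  rg <- make_ssb(g, list(chain = "I", resid = 8))
  flanks_before <- residue_table(rg$model)
  mg <- set_flank_motif(rg$model, rg$site)
  expect_equal(residue_table(mg)$resname[residue_table(mg)$chain == "I" &
                                           residue_table(mg)$resid %in% c(7, 9)],
               c("DG", "DG"))
})

test_that("ssb SHL bookkeeping flows from the map", {
  r <- wrap_ssb()
  expect_equal(r$site$shl, -5, tolerance = 1e-9)
})
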