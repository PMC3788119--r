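test_that("isolated atoms recover the closed-form sphere area", {
  a <- atom_table("A", 1, "ALA", "CA", "C", 0, 0, 0)
  expect_equal(sasa(a)$area, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-12)
  # two atoms far apart: no occlusion, areas additive
  two <- atom_table("A", 1:2, "ALA", "CA", c("C", "O"),
                    c(0, 100), c(0, 0), c(0, 0))
  got <- sasa(two)$area
  expect_equal(got[1], 4 * pi * 3.1^2, tolerance = 1e-12)
  expect_equal(got[2], 4 * pi * (1.52 + 1.4)^2, tolerance = 1e-12)
  expect_error(sasa(atom_table("A", integer(), character(), character(),
                               character(), numeric(), numeric(), numeric())),
               "at least one atom")
})

test_that("960-point sampling agrees with a 10000-point refinement within 2%", {
  cl <- random_cluster(n = 10, seed = 7)
  coarse <- sum(sasa(cl, n_points = 960)$area)
  fine <- sum(sasa(cl, n_points = 10000)$area)
  expect_lt(abs(coarse - fine) / fine, 0.02)
  # and with an independent Monte-Carlo direction oracle within 2%
  mc <- mc_sasa_total(cl, n_points = 20000)
  expect_lt(abs(coarse - mc) / mc, 0.02)
})

test_that("SASA and burial are invariant under rigid motion", {
  cl <- c2_dimer()
  theta <- 0.83
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(cl[, c("x", "y", "z")]) %*% t(rot)
  moved <- cl
  moved$x <- xyz[, 1] + 11.3
  moved$y <- xyz[, 2] - 4.2
  moved$z <- xyz[, 3] + 0.7
  b0 <- buried_surface(cl)
  b1 <- buried_surface(moved)
  expect_lt(abs(b0$total - b1$total) / max(b0$total, 1), 0.02)
  s0 <- sum(sasa(cl)$area)
  s1 <- sum(sasa(moved)$area)
  expect_lt(abs(s0 - s1) / s0, 0.01)
})

test_that("buried surface is zero without contact and symmetric for a C2 dimer", {
  apart <- atom_table(c("A", "B"), c(1, 1), "ALA", "CA", "C",
                      c(0, 100), c(0, 0), c(0, 0))
  b <- buried_surface(apart)
  expect_equal(b$total, 0)
  dimer <- c2_dimer()
  bd <- buried_surface(dimer)
  expect_gt(bd$total, 50)
  per <- bd$per_chain$buried
  expect_lt(abs(per[1] - per[2]) / mean(per), 0.05)
  # chain relabeling leaves the total unchanged
  relab <- dimer
  relab$chain <- ifelse(dimer$chain == "A", "B", "A")
  expect_equal(buried_surface(relab)$total, bd$total, tolerance = 1e-9)
  expect_error(buried_surface(dimer[dimer$chain == "A", ]), "two chains")
})

test_that("buried surface equals a direct recomputation with the MC oracle", {
  dimer <- c2_dimer(n = 18, seed = 5)
  got <- buried_surface(dimer, n_points = 2000)$total
  iso <- mc_sasa_total(dimer[dimer$chain == "A", ]) +
    mc_sasa_total(dimer[dimer$chain == "B", ])
  cx <- mc_sasa_total(dimer)
  expect_lt(abs(got - (iso - cx)) / max(iso - cx, 1), 0.05)
})

test_that("ensemble burial averages snapshots with an SD", {
  snaps <- lapply(c(11, 12, 13), function(s) c2_dimer(seed = s))
  ens <- buried_surface_ensemble(snaps, n_points = 480)
  expect_equal(ens$n_snapshots, 3L)
  expect_gt(ens$mean_buried, 0)
  expect_gte(ens$sd_buried, 0)
})

test_that("burial energy scales linearly with the calibrated coefficient", {
  expect_equal(burial_energy(900), 9.99, tolerance = 0.01)
  expect_equal(burial_energy(0), 0)
  expect_equal(burial_energy(1800), 2 * burial_energy(900))
  dimer <- c2_dimer()
  bp <- buried_surface(dimer, n_points = 480)
  hydro <- sum(bp$profile$delta_sasa[bp$profile$hydrophobic])
  expect_equal(burial_energy(bp), 11.1 * hydro / 1000)
  expect_equal(burial_energy(bp, hydrophobic_only = FALSE),
               11.1 * bp$total / 1000)
})

test_that("contact profiles find boundary contacts and salt bridges", {
  far <- atom_table(c("A", "B"), c(1, 1), c("ALA", "ALA"), "CA", "C",
                    c(0, 100), c(0, 0), c(0, 0))
  expect_equal(nrow(contact_profile(far, "A", "B")), 0L)
  near <- atom_table(c("A", "B"), c(5, 9), c("LEU", "VAL"), "CA", "C",
                     c(0, 4.4), c(0, 0), c(0, 0))
  cp <- contact_profile(near, "A", "B")
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$min_dist, 4.4)
  expect_false(cp$salt_bridge)
  # Arg guanidinium N 3.5 A from Glu carboxylate O
  sb <- atom_table(c("A", "A", "B", "B"), c(200, 200, 231, 231),
                   c("ARG", "ARG", "GLU", "GLU"),
                   c("CZ", "NH1", "CD", "OE1"), c("C", "N", "C", "O"),
                   c(0, 1.3, 6, 4.8), c(0, 0, 0, 0), c(0, 0, 0, 0))
  cps <- contact_profile(sb, "A", "B")
  expect_true(any(cps$salt_bridge))
  expect_error(contact_profile(near, "A", "Z"), "unknown chain")
})

test_that("regions map onto structures with hydrophobic classification", {
  atoms <- atom_table("A", rep(227:231, each = 2), rep(c("PRO", "ARG", "VAL", "TRP", "GLU"), each = 2),
                      rep(c("N", "CA"), 5), rep(c("N", "C"), 5),
                      seq(0, 9), rep(0, 10), rep(0, 10))
  m <- map_regions_to_structure(tibble::tibble(start = 227L, end = 231L), atoms)
  expect_equal(nrow(m), 5L)
  expect_true(all(m$in_structure))
  expect_equal(sum(m$hydrophobic), 3L)  # PRVWE: P, V, W hydrophobic
  # a region extending past the coordinates maps partially with a warning
  expect_warning(
    part <- map_regions_to_structure(tibble::tibble(start = 229L, end = 234L), atoms),
    "partial"
  )
  expect_equal(sum(part$in_structure), 3L)
  expect_equal(sum(!part$in_structure), 3L)
  # all-hydrophobic toy region
  toy <- atom_table("A", 1:5, c("VAL", "LEU", "PRO", "VAL", "TRP"), "CA", "C",
                    1:5, rep(0, 5), rep(0, 5))
  mt <- map_regions_to_structure(tibble::tibble(start = 1L, end = 5L), toy)
  expect_equal(sum(mt$hydrophobic), 5L)
})

test_that("PDB ingestion keeps first-altloc heavy atoms only", {
  df <- data.frame(
    chain = c("A", "A", "B"), resno = c(1L, 2L, 1L),
    resid = c("ALA", "GLU", "LEU"), atom = c("CA", "CA", "CA"),
    element = c("C", "C", "C"), x = c(0, 3.8, 10), y = 0, z = 0
  )
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(df, path)
  at <- read_structure(path)
  expect_s3_class(at, "atom_table")
  expect_equal(nrow(at), 3L)
  expect_equal(sort(unique(at$chain)), c("A", "B"))
  expect_equal(at$radius, rep(1.7, 3))
  expect_equal(at$x, c(0, 3.8, 10), tolerance = 1e-6)
})
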