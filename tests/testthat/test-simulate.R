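test_that("site deuteration follows EX2 kinetics", {
  expect_equal(simulate_site_deuteration(1, Inf, 5), 0)
  expect_equal(simulate_site_deuteration(log(2), 1, 1), 0.5)
  expect_equal(simulate_site_deuteration(1, 1, 0), 0)
  expect_equal(simulate_site_deuteration(1, 1, 1e9), 1)
  # monotone non-decreasing in t
  d <- simulate_site_deuteration(0.3, 4, c(0, 1, 10, 100, 1e4))
  expect_true(all(diff(d) >= 0))
  expect_error(simulate_site_deuteration(1, 1, -1), "non-negative")
  expect_error(simulate_site_deuteration(1, 0.5, 1), ">= 1")
})

test_that("peptide uptake counts exchangeable amides correctly", {
  pars <- function(P) data.frame(position = 2:6, k_int = 1, P = P)
  # all infinitely protected -> 0 at any time
  expect_equal(simulate_peptide_uptake("ASELK", 2, pars(Inf), c(1, 1e6)), c(0, 0))
  # saturation -> N = 4 (5 residues, minus N-terminus, no prolines)
  expect_equal(simulate_peptide_uptake("ASELK", 2, pars(1), 1e9), 4)
  # 5-residue peptide with two non-exchanging residues: D = N - 2
  mix <- data.frame(position = 3:6, k_int = 1, P = c(Inf, Inf, 1, 1))
  expect_equal(simulate_peptide_uptake("AAAAA", 2, mix, 1e9), 2)
  # prolines drop out of the count: PRVWEPVPLEE has N = 8
  expect_equal(n_exchangeable("PRVWEPVPLEE"), 8L)
  prv <- data.frame(position = 227:237, k_int = 1, P = 1)
  expect_equal(simulate_peptide_uptake("PRVWEPVPLEE", 227, prv, 1e9), 8)
  # zero exchangeable amides: 0 with a warning
  expect_warning(
    out <- simulate_peptide_uptake("GP", 1, data.frame(position = 1:2, k_int = 1, P = 1), 10),
    "no exchangeable"
  )
  expect_equal(out, 0)
  # floor/ceiling from in- and back-exchange
  u <- simulate_peptide_uptake("ASELK", 2, pars(1), c(0, 1e9), alpha = 0.05, beta = 0.2)
  expect_equal(u, c(0.05 * 4, 0.8 * 4))
  expect_error(
    simulate_peptide_uptake("ASELK", 2, pars(1), 1, alpha = 0.5, beta = 0.6),
    "bracket"
  )
})

test_that("scenario validation rejects inconsistent designs", {
  expect_error(hdx_scenario("ASELKW", states = "only_one"), "two state")
  expect_error(
    hdx_scenario("ASELKW", protected_regions = tibble::tibble(
      state = "dimer", start = 1L, end = 99L, multiplier = 2
    )),
    "bounds"
  )
  expect_error(hdx_scenario("ASELKW", in_exchange = 0.6, back_exchange = 0.5),
               "bracket")
  sc <- rage_scenario(seed = 1)
  expect_error(simulate_hdx_dataset({ s <- sc; s$n_replicates <- 1L; s }),
               "2 replicates")
})

test_that("simulated datasets are deterministic and bracketed by the controls", {
  sc <- rage_scenario(seed = 123, noise_sd = 0)
  ds1 <- simulate_hdx_dataset(sc)
  ds2 <- simulate_hdx_dataset(rage_scenario(seed = 123, noise_sd = 0))
  expect_identical(ds1$uptake, ds2$uptake)
  expect_identical(ds1$peptides, ds2$peptides)
  # noise-free: every Mex lies within [Mex0, Mex100]
  ctrl <- ds1$uptake |>
    dplyr::filter(state %in% c("IN_CONTROL", "OUT_CONTROL")) |>
    tidyr::pivot_wider(names_from = state, values_from = centroid_mass)
  obs <- ds1$uptake |>
    dplyr::filter(!state %in% c("IN_CONTROL", "OUT_CONTROL")) |>
    dplyr::inner_join(ctrl[, c("peptide_sequence", "charge", "IN_CONTROL", "OUT_CONTROL")],
                      by = c("peptide_sequence", "charge"))
  expect_true(all(obs$centroid_mass >= obs$IN_CONTROL - 1e-9))
  expect_true(all(obs$centroid_mass <= obs$OUT_CONTROL + 1e-9))
  # different seed changes the noise but not the design
  ds3 <- simulate_hdx_dataset(rage_scenario(seed = 124))
  expect_identical(ds1$peptides, ds3$peptides)
})

test_that("identical protection in both states gives exactly zero deltas without noise", {
  ds <- simulate_hdx_dataset(rage_scenario(multiplier = 1, seed = 5, noise_sd = 0))
  fr <- exchange_fractions(ds$uptake)
  calls <- differential_calls(fr, "monomer", "dimer")
  expect_true(all(calls$delta == 0))
  expect_true(all(!calls$significant))
})

test_that("boosted regions lower the dimer fraction for exactly the overlapping peptides", {
  ds <- simulate_hdx_dataset(rage_scenario(multiplier = 20, seed = 5, noise_sd = 0))
  fr <- exchange_fractions(ds$uptake)
  calls <- differential_calls(fr, "monomer", "dimer") |>
    dplyr::filter(time_s == 10)
  truth <- ds$truth
  overlaps <- function(s, e) {
    any(s <= truth$end & e >= truth$start)
  }
  hit <- mapply(overlaps, calls$start, calls$end)
  expect_true(all(calls$delta[hit] > 0))
  # analytic expectation: monomer P = 5, dimer P = 100 at k_int = 1, t = 10
  d_m <- 1 - exp(-10 / 5)
  d_d <- 1 - exp(-10 / 100)
  asel <- dplyr::filter(calls, peptide_sequence == "ASEL")
  expect_equal(asel$delta, rep(d_m - d_d, nrow(asel)), tolerance = 1e-9)
  expect_true(all(abs(calls$delta[!hit]) < 1e-9))
})

test_that("fractions are invariant across charge states of the same peptide", {
  ds <- simulate_hdx_dataset(rage_scenario(seed = 9, noise_sd = 0))
  fr <- exchange_fractions(ds$uptake)
  spread <- fr |>
    dplyr::group_by(peptide_sequence, start, state, time_s) |>
    dplyr::summarise(range = max(f) - min(f), n_charges = dplyr::n(), .groups = "drop") |>
    dplyr::filter(n_charges > 1)
  expect_gt(nrow(spread), 0)
  expect_true(all(spread$range < 1e-9))
})

test_that("the interface scenario carries the expected motifs and digest", {
  sc <- rage_scenario()
  off <- sc$offset
  expect_equal(substr(sc$sequence, 129 - off + 1, 133 - off + 1), "SASEL")
  expect_equal(substr(sc$sequence, 227 - off + 1, 237 - off + 1), "PRVWEPVPLEE")
  expect_equal(substr(sc$sequence, 196 - off + 1, 203 - off + 1), "PARGGDPR")
  expect_equal(substr(sc$sequence, 238 - off + 1, 241 - off + 1), "VQLV")
  # only the four interface peptides overlap the boosted regions
  dig <- dplyr::distinct(sc$digest, sequence, start, end)
  ov <- dig$start <= 133 & dig$end >= 129 | dig$start <= 237 & dig$end >= 227
  expect_setequal(dig$sequence[ov], c("ASEL", "SASEL", "PRVWEPVPLE", "PRVWEPVPLEE"))
})
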