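fractions_row <- function(state, f, sd, sequence = "ASEL", start = 130L,
                          charge = 1L, time_s = 10) {
  tibble::tibble(
    peptide_sequence = sequence, start = start,
    end = start + nchar(sequence) - 1L, charge = charge, state = state,
    time_s = time_s, f = f, sd = sd, n = 3L, out_of_range = FALSE
  )
}

test_that("delta, summed-SD sigma and the 2-sigma rule follow the definitions", {
  fr <- dplyr::bind_rows(fractions_row("monomer", 0.60, 0.03),
                         fractions_row("dimer", 0.40, 0.02))
  call <- differential_calls(fr, "monomer", "dimer")
  expect_equal(call$delta, 0.20)
  expect_equal(call$sigma, 0.05)
  expect_true(call$significant)
  expect_equal(call$direction, "protected")

  fr2 <- dplyr::bind_rows(fractions_row("monomer", 0.50, 0.04),
                          fractions_row("dimer", 0.45, 0.04))
  call2 <- differential_calls(fr2, "monomer", "dimer")
  expect_equal(call2$delta, 0.05)
  expect_equal(call2$sigma, 0.08)
  expect_false(call2$significant)

  fr3 <- dplyr::bind_rows(fractions_row("monomer", 0.5, 0.02),
                          fractions_row("dimer", 0.5, 0.02))
  call3 <- differential_calls(fr3, "monomer", "dimer")
  expect_equal(call3$delta, 0)
  expect_false(call3$significant)
  expect_equal(call3$direction, "none")
})

test_that("swapping states negates delta and flips the direction", {
  ds <- simulate_hdx_dataset(rage_scenario(seed = 31))
  fr <- exchange_fractions(ds$uptake)
  ab <- differential_calls(fr, "monomer", "dimer", sided = "two")
  ba <- differential_calls(fr, "dimer", "monomer", sided = "two")
  key <- c("peptide_sequence", "start", "charge", "time_s")
  m <- dplyr::inner_join(ab, ba, by = key, suffix = c("_ab", "_ba"))
  expect_equal(m$delta_ab, -m$delta_ba)
  expect_equal(m$sigma_ab, m$sigma_ba)
  expect_equal(m$significant_ab, m$significant_ba)
  flipped <- m$direction_ab == "protected" & m$direction_ba == "deprotected" |
    m$direction_ab == "deprotected" & m$direction_ba == "protected" |
    m$direction_ab == "none" & m$direction_ba == "none"
  expect_true(all(flipped))
})

test_that("linear-sum sigma dominates quadrature, making calls conservative", {
  ds <- simulate_hdx_dataset(rage_scenario(seed = 33))
  fr <- exchange_fractions(ds$uptake)
  lin <- differential_calls(fr, "monomer", "dimer", error_model = "sum")
  quad <- differential_calls(fr, "monomer", "dimer", error_model = "quadrature")
  expect_true(all(lin$sigma >= quad$sigma - 1e-12))
  expect_true(all(lin$sigma >= pmax(lin$sd_ref, lin$sd_test) - 1e-12))
  # anything significant under the sum rule is significant under quadrature
  expect_true(all(!lin$significant | quad$significant))
})

test_that("mismatched state labels are rejected", {
  fr <- fractions_row("monomer", 0.5, 0.02)
  expect_error(differential_calls(fr, "monomer", "dimer"), "not present")
  expect_error(differential_calls(fr, "monomer", "monomer"), "must differ")
})

test_that("null identical-state comparisons stay below the one-sided 5% call rate", {
  n_calls <- 0L
  n_sig <- 0L
  for (seed in 1:5) {
    ds <- simulate_hdx_dataset(rage_scenario(multiplier = 1, seed = 4000 + seed))
    fr <- exchange_fractions(ds$uptake)
    calls <- differential_calls(fr, "monomer", "dimer")
    n_calls <- n_calls + nrow(calls)
    n_sig <- n_sig + sum(calls$significant)
  }
  expect_gt(n_calls, 500)
  expect_lte(n_sig / n_calls, 0.05)
})

test_that("control equivalence reports the max deviation and flags outliers", {
  ds <- simulate_hdx_dataset(rage_scenario(multiplier = 1, seed = 77))
  fr <- exchange_fractions(ds$uptake)
  eq_self <- control_equivalence(fr, fr, state_a = "monomer", state_b = "monomer")
  expect_equal(eq_self$max_abs_diff, 0)
  expect_true(eq_self$pass)
  eq <- control_equivalence(fr, fr, state_a = "monomer", state_b = "dimer")
  expect_lte(eq$max_abs_diff, 0.10)
  # a shifted peptide tops the table and fails the bound
  fr_shift <- fr |>
    dplyr::mutate(f = ifelse(peptide_sequence == "SASEL" & state == "dimer",
                             f + 0.2, f))
  eq_bad <- control_equivalence(fr, fr_shift, state_a = "monomer", state_b = "dimer")
  expect_false(eq_bad$pass)
  expect_equal(eq_bad$table$peptide_sequence[1], "SASEL")
})

test_that("screen consolidates charge states and honours confirm_next", {
  ds <- simulate_hdx_dataset(rage_scenario(seed = 13))
  fr <- exchange_fractions(ds$uptake)
  sc1 <- differential_screen(fr, "monomer", "dimer", confirm_next = TRUE)
  expect_s3_class(sc1, "hdx_screen")
  expect_setequal(sc1$differential$peptide_sequence,
                  c("ASEL", "SASEL", "PRVWEPVPLE", "PRVWEPVPLEE"))
  expect_equal(sc1$screen_time_s, 10)
  # single-time rule is a superset of the confirmed rule
  sc0 <- differential_screen(fr, "monomer", "dimer", confirm_next = FALSE)
  expect_true(all(sc1$differential$peptide_sequence %in%
                    sc0$differential$peptide_sequence))
  g <- glance(sc1)
  expect_equal(g$n_differential, 4L)
  expect_equal(nrow(tidy(sc1)), nrow(sc1$calls))
})
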