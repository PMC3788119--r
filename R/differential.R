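# Monomer-vs-oligomer comparison: the Delta statistic, summed-SD error
# propagation, the 2-sigma protection call, and the control-equivalence
# check.

#' Differential protection calls per peptide and time point
#'
#' For every peptide, charge state and time point measured in both states,
#' computes `delta = f_ref - f_test` (positive = more protected in the test
#' state), the propagated error `sigma`, and the significance call
#' `delta > sigma_multiplier * sigma` (one-sided protection by default; the
#' two-sided mode also calls deprotection with `|delta|`).
#'
#' Error propagation defaults to the linear SD sum `sigma = sd_ref + sd_test`,
#' the simplest and most conservative model; `"quadrature"` gives
#' `sqrt(sd_ref^2 + sd_test^2)`. Since the linear sum always dominates
#' quadrature, calls under the default are conservative.
#'
#' @param fractions Output of [exchange_fractions()] containing both states.
#' @param state_ref Reference state label (e.g. the monomer).
#' @param state_test Test state label (e.g. the dimer).
#' @param sigma_multiplier Significance multiplier (default 2).
#' @param sided `"one"` (protection only, default) or `"two"`.
#' @param error_model `"sum"` (default) or `"quadrature"`.
#' @return Tibble with `peptide_sequence`, `start`, `end`, `charge`,
#'   `time_s`, `f_ref`, `sd_ref`, `f_test`, `sd_test`, `delta`, `sigma`,
#'   `significant`, `direction`.
#' @export
#' @examples
#' ds <- simulate_hdx_dataset(rage_scenario(seed = 5))
#' fr <- exchange_fractions(ds$uptake)
#' calls <- differential_calls(fr, "monomer", "dimer")
#' dplyr::filter(calls, significant)
differential_calls <- function(fractions, state_ref, state_test,
                               sigma_multiplier = 2,
                               sided = c("one", "two"),
                               error_model = c("sum", "quadrature")) {
  sided <- match.arg(sided)
  error_model <- match.arg(error_model)
  if (identical(state_ref, state_test)) abort("reference and test state must differ")
  have <- unique(fractions$state)
  missing <- setdiff(c(state_ref, state_test), have)
  if (length(missing) > 0) {
    abort(paste0("state(s) not present in fraction table: ",
                 paste(missing, collapse = ", ")))
  }
  key <- c("peptide_sequence", "start", "end", "charge", "time_s")
  fr <- select(fractions, all_of(key), "state", "f", "sd")
  ref <- fr %>% filter(.data$state == state_ref) %>%
    select(-"state") %>% rename(f_ref = "f", sd_ref = "sd")
  tst <- fr %>% filter(.data$state == state_test) %>%
    select(-"state") %>% rename(f_test = "f", sd_test = "sd")
  paired <- inner_join(ref, tst, by = key)
  if (nrow(paired) == 0) abort("no shared (peptide, time) measurements between states")
  paired %>%
    mutate(
      delta = .data$f_ref - .data$f_test,
      sigma = if (error_model == "sum") .data$sd_ref + .data$sd_test
              else sqrt(.data$sd_ref^2 + .data$sd_test^2),
      significant = if (sided == "one") .data$delta > sigma_multiplier * .data$sigma
                    else abs(.data$delta) > sigma_multiplier * .data$sigma,
      direction = case_when(
        .data$significant & .data$delta > 0 ~ "protected",
        .data$significant & .data$delta < 0 ~ "deprotected",
        TRUE ~ "none"
      )
    ) %>%
    arrange(.data$start, .data$peptide_sequence, .data$charge, .data$time_s)
}

#' Screen a state pair for differentially protected peptides
#'
#' Runs [differential_calls()] over the full time grid and derives the
#' headline set of differential peptides. A peptide (identified by sequence
#' and span; charge states are consolidated by requiring at least one
#' significant charge form) is called differential when it is significant
#' at the earliest measured time point and, when `confirm_next = TRUE`
#' (default) and a second time point exists, also at the next one —
#' genuine protection persists into the following time point, while
#' single-point excursions at the replicate noise level do not.
#'
#' @inheritParams differential_calls
#' @param confirm_next Require confirmation at the second-earliest time
#'   point (default `TRUE`); `FALSE` screens on the earliest time alone.
#' @return An object of class `hdx_screen`: list with `calls` (all
#'   per-time-point calls), `differential` (unique differential peptides
#'   with spans and earliest significant time), `screen_time_s`, `summary`
#'   and the settings used. Supports [tidy()], [glance()] and [autoplot()].
#' @export
differential_screen <- function(fractions, state_ref, state_test,
                                sigma_multiplier = 2,
                                sided = c("one", "two"),
                                error_model = c("sum", "quadrature"),
                                confirm_next = TRUE) {
  sided <- match.arg(sided)
  error_model <- match.arg(error_model)
  calls <- differential_calls(fractions, state_ref, state_test,
                              sigma_multiplier, sided, error_model)
  times <- sort(unique(calls$time_s))
  t1 <- times[1]
  screen_times <- if (confirm_next && length(times) >= 2) times[1:2] else t1

  per_pep <- calls %>%
    filter(.data$time_s %in% screen_times) %>%
    group_by(.data$peptide_sequence, .data$start, .data$end, .data$charge) %>%
    summarise(hit = all(screen_times %in% .data$time_s[.data$significant]),
              .groups = "drop")
  differential <- per_pep %>%
    filter(.data$hit) %>%
    distinct(.data$peptide_sequence, .data$start, .data$end) %>%
    left_join(
      calls %>% filter(.data$significant) %>%
        group_by(.data$peptide_sequence, .data$start, .data$end) %>%
        summarise(earliest_significant_s = min(.data$time_s, Inf), .groups = "drop"),
      by = c("peptide_sequence", "start", "end")
    ) %>%
    arrange(.data$start, .data$peptide_sequence)

  structure(list(
    calls = calls,
    differential = differential,
    screen_time_s = t1,
    confirm_next = confirm_next,
    state_ref = state_ref,
    state_test = state_test,
    sigma_multiplier = sigma_multiplier,
    sided = sided,
    error_model = error_model,
    multiple_testing = "none (per-peptide 2-sigma calls, uncorrected)",
    summary = tibble(
      n_peptides = dplyr::n_distinct(paste(calls$peptide_sequence, calls$start)),
      n_differential = nrow(differential),
      spans = paste(sprintf("%d-%d", differential$start, differential$end),
                    collapse = "; ")
    )
  ), class = "hdx_screen")
}

#' @export
print.hdx_screen <- function(x, ...) {
  cat("HDX differential screen:", x$state_ref, "vs", x$state_test, "\n")
  cat("  rule: delta >", x$sigma_multiplier, "* sigma (", x$sided, "-sided,",
      x$error_model, "SD propagation),", "screened at", x$screen_time_s, "s",
      if (x$confirm_next) "with next-time confirmation" else "", "\n")
  cat("  multiple testing:", x$multiple_testing, "\n")
  cat("  differential peptides:", nrow(x$differential), "\n")
  if (nrow(x$differential) > 0) {
    print(x$differential, ...)
  }
  invisible(x)
}

#' @rdname differential_screen
#' @param x An `hdx_screen` object.
#' @param ... Unused.
#' @method tidy hdx_screen
#' @export
tidy.hdx_screen <- function(x, ...) x$calls

#' @rdname differential_screen
#' @method glance hdx_screen
#' @export
glance.hdx_screen <- function(x, ...) {
  tibble(
    state_ref = x$state_ref, state_test = x$state_test,
    screen_time_s = x$screen_time_s,
    sigma_multiplier = x$sigma_multiplier,
    n_peptides = x$summary$n_peptides,
    n_differential = x$summary$n_differential
  )
}

#' Control-equivalence check between two conditions
#'
#' Compares two fraction-of-exchange tables measured under conditions that
#' should be equivalent (e.g. technical control variants of the same
#' state) and reports the per-peptide absolute differences and their
#' maximum, against a pass/fail threshold of 0.10 fraction units by
#' default (deviations between equivalent conditions should not exceed
#' 10%).
#'
#' @param fa,fb Fraction tables from [exchange_fractions()] (single
#'   condition each, or pass `state_a`/`state_b` to select).
#' @param state_a,state_b Optional state labels to select from `fa`/`fb`.
#' @param threshold Pass/fail bound on max `|delta_f|` (default 0.10).
#' @return List of class `hdx_equivalence`: `table` (per peptide, charge
#'   and time `|delta_f|`, descending), `max_abs_diff`, `threshold`,
#'   `pass`.
#' @export
control_equivalence <- function(fa, fb, state_a = NULL, state_b = NULL,
                                threshold = 0.10) {
  if (!is.null(state_a)) fa <- filter(fa, .data$state == state_a)
  if (!is.null(state_b)) fb <- filter(fb, .data$state == state_b)
  key <- c("peptide_sequence", "start", "end", "charge", "time_s")
  tab <- inner_join(
    select(fa, all_of(key), f_a = "f"),
    select(fb, all_of(key), f_b = "f"),
    by = key
  )
  if (nrow(tab) == 0) abort("no shared peptides between the two conditions")
  tab <- tab %>%
    mutate(abs_diff = abs(.data$f_a - .data$f_b)) %>%
    arrange(dplyr::desc(.data$abs_diff))
  structure(list(
    table = tab,
    max_abs_diff = max(tab$abs_diff),
    threshold = threshold,
    pass = max(tab$abs_diff) <= threshold
  ), class = "hdx_equivalence")
}

#' @export
print.hdx_equivalence <- function(x, ...) {
  cat("Control equivalence: max |delta f| =", format(x$max_abs_diff, digits = 3),
      "(threshold", x$threshold, "->", if (x$pass) "PASS" else "FAIL", ")\n")
  print(head(x$table, 5), ...)
  invisible(x)
}
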