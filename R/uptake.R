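# From replicate centroid masses and the two technical controls to the
# normalized fraction-of-exchange statistic and kinetics curves.

#' Fraction of exchange
#'
#' Normalizes an observed centroid mass against the in-exchange control
#' (0% reference, deuterium unavoidably acquired during quench/digestion)
#' and the full-deuteration out-exchange control (100% reference,
#' incorporating back-exchange losses):
#' `f = (Mex - Mex0) / (Mex100 - Mex0)`.
#'
#' Noise can push `f` slightly outside `[0, 1]`; such values are retained
#' for statistics (clipping, if any, is a plotting concern). Peptides whose
#' control span `Mex100 - Mex0` does not exceed `min_span` are uninformative
#' and yield `NA`.
#'
#' @param mex Observed centroid mass(es), Da.
#' @param mex0 In-exchange control mass, Da.
#' @param mex100 Out-exchange (full-deuteration) control mass, Da.
#' @param min_span Minimum control span in Da (default 0.1).
#' @return Numeric vector of fractions; `NA` where controls are degenerate.
#' @export
#' @examples
#' fraction_of_exchange(803, 800, 806)  # 0.5
fraction_of_exchange <- function(mex, mex0, mex100, min_span = 0.1) {
  span <- mex100 - mex0
  ifelse(span > min_span, (mex - mex0) / span, NA_real_)
}

# split a long uptake table (the on-disk dialect) into exchange observations
# and per-peptide control pairs; peptides with degenerate controls excluded
control_pairs <- function(uptake, min_span = 0.1) {
  ctrl <- uptake %>%
    filter(.data$state %in% c("IN_CONTROL", "OUT_CONTROL")) %>%
    group_by(.data$peptide_sequence, .data$start, .data$end, .data$charge, .data$state) %>%
    summarise(mass = mean(.data$centroid_mass), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "state", values_from = "mass") %>%
    rename(mex0 = "IN_CONTROL", mex100 = "OUT_CONTROL")
  ctrl$span <- ctrl$mex100 - ctrl$mex0
  ctrl
}

#' Replicate fraction-of-exchange statistics
#'
#' Computes the per-replicate fraction of exchange for every observation in
#' a long uptake table (using that peptide and charge state's own control
#' pair) and summarises replicates into mean `f`, sample SD (`n - 1`
#' denominator) and replicate count per (peptide, charge, state, time).
#'
#' Peptides whose controls are degenerate (span below `min_span` Da) or
#' missing are excluded; the excluded set with reasons is attached as
#' attribute `"excluded"`. Mean fractions outside `[-flag_limit,
#' 1 + flag_limit]` are flagged in the `out_of_range` column. Groups with
#' fewer than `min_replicates` observations are dropped (SD would be
#' undefined or meaningless).
#'
#' @param uptake Long uptake table with columns `peptide_sequence`, `start`,
#'   `end`, `charge`, `state`, `time_s`, `replicate`, `centroid_mass`;
#'   control rows carry `state` `"IN_CONTROL"` / `"OUT_CONTROL"`.
#' @param min_span Minimum control span, Da.
#' @param flag_limit Tolerated excursion of mean `f` beyond `[0, 1]`.
#' @param min_replicates Minimum replicates per group (default 2).
#' @return Tibble with `peptide_sequence`, `start`, `end`, `charge`,
#'   `state`, `time_s`, `f`, `sd`, `n`, `out_of_range`; attribute
#'   `"excluded"` lists dropped peptides with reasons.
#' @export
#' @examples
#' ds <- simulate_hdx_dataset(rage_scenario(seed = 3))
#' head(exchange_fractions(ds$uptake))
exchange_fractions <- function(uptake, min_span = 0.1, flag_limit = 0.15,
                               min_replicates = 2L) {
  required <- c("peptide_sequence", "start", "end", "charge", "state",
                "time_s", "replicate", "centroid_mass")
  missing <- setdiff(required, names(uptake))
  if (length(missing) > 0) {
    abort(paste0("uptake table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  ctrl <- control_pairs(uptake)
  bad <- ctrl %>%
    filter(is.na(.data$mex0) | is.na(.data$mex100) | .data$span <= min_span) %>%
    mutate(reason = case_when(
      is.na(.data$mex0) ~ "missing IN_CONTROL",
      is.na(.data$mex100) ~ "missing OUT_CONTROL",
      TRUE ~ paste0("degenerate controls (span <= ", min_span, " Da)")
    )) %>%
    select("peptide_sequence", "start", "end", "charge", "reason")
  good <- ctrl %>% anti_join(bad, by = c("peptide_sequence", "start", "end", "charge"))

  exch <- uptake %>%
    filter(!.data$state %in% c("IN_CONTROL", "OUT_CONTROL")) %>%
    inner_join(select(good, "peptide_sequence", "start", "end", "charge",
                      "mex0", "mex100"),
               by = c("peptide_sequence", "start", "end", "charge"))
  no_ctrl <- uptake %>%
    filter(!.data$state %in% c("IN_CONTROL", "OUT_CONTROL")) %>%
    anti_join(ctrl, by = c("peptide_sequence", "start", "end", "charge")) %>%
    distinct(.data$peptide_sequence, .data$start, .data$end, .data$charge) %>%
    mutate(reason = "missing controls")
  bad <- bind_rows(bad, no_ctrl)

  out <- exch %>%
    mutate(f_rep = fraction_of_exchange(.data$centroid_mass, .data$mex0, .data$mex100,
                                        min_span = min_span)) %>%
    group_by(.data$peptide_sequence, .data$start, .data$end, .data$charge,
             .data$state, .data$time_s) %>%
    summarise(f = mean(.data$f_rep), sd = sd(.data$f_rep), n = dplyr::n(),
              .groups = "drop") %>%
    filter(.data$n >= min_replicates) %>%
    mutate(out_of_range = .data$f < -flag_limit | .data$f > 1 + flag_limit) %>%
    arrange(.data$start, .data$peptide_sequence, .data$charge, .data$state, .data$time_s)
  attr(out, "excluded") <- bad
  out
}

#' Exchange kinetics curve for one peptide and state
#'
#' Orders the fraction-of-exchange series of a peptide over the time grid
#' and flags whether exchange is close to completion (mean `f` at the last
#' measured time at or above `complete_at`).
#'
#' @param fractions Output of [exchange_fractions()].
#' @param peptide Peptide sequence to select (optional; all if `NULL`).
#' @param state State label to select (optional).
#' @param complete_at Completion threshold on `f` (default 0.9).
#' @return Tibble sorted by time with a `close_to_completion` flag
#'   (constant within each peptide x charge x state series); missing time
#'   points relative to the full grid are reported in attribute
#'   `"missing_times"`.
#' @export
kinetics_curve <- function(fractions, peptide = NULL, state = NULL,
                           complete_at = 0.9) {
  if (nrow(fractions) == 0) abort("no fraction data supplied")
  grid <- sort(unique(fractions$time_s))
  out <- fractions
  if (!is.null(peptide)) out <- filter(out, .data$peptide_sequence %in% .env$peptide)
  if (!is.null(state)) out <- filter(out, .data$state %in% .env$state)
  out <- out %>%
    group_by(.data$peptide_sequence, .data$start, .data$end, .data$charge, .data$state) %>%
    arrange(.data$time_s, .by_group = TRUE) %>%
    mutate(close_to_completion = .data$f[dplyr::n()] >= complete_at) %>%
    ungroup()
  miss <- out %>%
    group_by(.data$peptide_sequence, .data$start, .data$end, .data$charge, .data$state) %>%
    summarise(missing_times = list(setdiff(grid, .data$time_s)), .groups = "drop") %>%
    filter(lengths(.data$missing_times) > 0)
  attr(out, "missing_times") <- miss
  out
}
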