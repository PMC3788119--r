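# Peptide-table quality filtering, identification/observation matching,
# sequence coverage, and residue-level merging of significant peptides.

#' Filter a peptide identification table
#'
#' Applies the standard peptide-list acceptance criteria: minimum intensity
#' 3000, minimum fragment products 2, minimum products per amino acid 0.15,
#' and minimum consecutive products 1. All thresholds are overridable.
#' Rows are kept when every criterion holds (with `>=` comparisons).
#'
#' @param ids Identification tibble with columns `sequence`, `intensity`,
#'   `n_products`, `n_consecutive_products`.
#' @param min_intensity Minimum intensity (default 3000).
#' @param min_products Minimum fragment count (default 2).
#' @param min_products_per_aa Minimum `n_products / peptide length`
#'   (default 0.15).
#' @param min_consecutive_products Minimum consecutive fragment count
#'   (default 1).
#' @return The accepted rows; the rejected rows, with a `reason` column
#'   listing every failed criterion, are attached as attribute
#'   `"rejected"`.
#' @export
#' @examples
#' ids <- simulate_hdx_dataset(rage_scenario(seed = 2))$peptides
#' acc <- filter_identifications(ids)
#' attr(acc, "rejected")$reason
filter_identifications <- function(ids,
                                   min_intensity = 3000,
                                   min_products = 2,
                                   min_products_per_aa = 0.15,
                                   min_consecutive_products = 1) {
  required <- c("sequence", "intensity", "n_products", "n_consecutive_products")
  missing <- setdiff(required, names(ids))
  if (length(missing) > 0) {
    abort(paste0("identification table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(ids) == 0) {
    out <- ids
    attr(out, "rejected") <- mutate(ids, reason = character(0))
    return(out)
  }
  len <- nchar(ids$sequence)
  fails <- cbind(
    intensity = ids$intensity < min_intensity,
    products = ids$n_products < min_products,
    products_per_aa = ids$n_products / len < min_products_per_aa,
    consecutive = ids$n_consecutive_products < min_consecutive_products
  )
  keep <- rowSums(fails) == 0
  rejected <- ids[!keep, , drop = FALSE]
  rejected$reason <- apply(fails[!keep, , drop = FALSE], 1, function(r) {
    paste(colnames(fails)[r], collapse = ", ")
  })
  out <- ids[keep, , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Match observations to identified peptides
#'
#' Assigns each observation to an identification when all three tolerances
#' hold: retention-time deviation within `rt_tol_s` (default 9 s), m/z
#' deviation within `mz_tol_ppm` (default 15 ppm), and ion-mobility drift
#' deviation within `drift_tol_bins` (default 2 bins). Among candidate
#' identifications the smallest m/z deviation wins, then the smallest RT
#' deviation.
#'
#' @param ids Identification table with `sequence`, `start`, `end`,
#'   `charge`, `mass`, `rt_s`, `drift_bins`.
#' @param obs Observation table with `mz`, `charge`, `rt_s`, `drift_bins`
#'   (plus any payload columns, carried through).
#' @param mz_tol_ppm,rt_tol_s,drift_tol_bins Matching tolerances.
#' @return The observations with matched identification columns
#'   (`sequence`, `start`, `end`) and the deviations (`ppm_dev`,
#'   `rt_dev_s`, `drift_dev_bins`); unmatched observations are attached as
#'   attribute `"unmatched"`.
#' @export
match_observations <- function(ids, obs, mz_tol_ppm = 15, rt_tol_s = 9,
                               drift_tol_bins = 2) {
  if (nrow(ids) == 0 || nrow(obs) == 0) abort("both tables must be non-empty")
  obs$.obs_id <- seq_len(nrow(obs))
  cand <- inner_join(
    obs,
    ids %>%
      mutate(id_mz = mass_to_mz(.data$mass, .data$charge)) %>%
      select("sequence", "start", "end", "charge", "id_mz",
             id_rt_s = "rt_s", id_drift = "drift_bins"),
    by = "charge", relationship = "many-to-many"
  ) %>%
    mutate(
      ppm_dev = abs(.data$mz - .data$id_mz) / .data$id_mz * 1e6,
      rt_dev_s = abs(.data$rt_s - .data$id_rt_s),
      drift_dev_bins = abs(.data$drift_bins - .data$id_drift)
    ) %>%
    filter(.data$ppm_dev <= mz_tol_ppm,
           .data$rt_dev_s <= rt_tol_s,
           .data$drift_dev_bins <= drift_tol_bins) %>%
    group_by(.data$.obs_id) %>%
    arrange(.data$ppm_dev, .data$rt_dev_s, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup()
  matched <- cand %>% select(-"id_mz", -"id_rt_s", -"id_drift")
  unmatched <- obs[!obs$.obs_id %in% matched$.obs_id, , drop = FALSE]
  matched$.obs_id <- NULL
  unmatched$.obs_id <- NULL
  attr(matched, "unmatched") <- unmatched
  matched
}

#' Sequence coverage of a peptide set
#'
#' Fraction of construct residues covered by the union of the peptide
#' spans.
#'
#' @param peptides Tibble with `start` and `end` residue numbers
#'   (reporting numbering).
#' @param seq_length Construct length in residues.
#' @param offset Residue number of the first construct position (default 1).
#' @return Coverage fraction in `[0, 1]`.
#' @export
#' @examples
#' sequence_coverage(tibble::tibble(start = 1, end = 50), seq_length = 100)
sequence_coverage <- function(peptides, seq_length, offset = 1L) {
  if (seq_length <= 0) abort("sequence length must be positive")
  if (nrow(peptides) == 0) return(0)
  first <- as.integer(offset)
  last <- first + as.integer(seq_length) - 1L
  if (any(peptides$start < first | peptides$end > last)) {
    abort("peptide spans outside the construct bounds")
  }
  covered <- logical(seq_length)
  for (i in seq_len(nrow(peptides))) {
    covered[(peptides$start[i]:peptides$end[i]) - first + 1L] <- TRUE
  }
  sum(covered) / seq_length
}

#' Merge significant peptide spans into protected regions
#'
#' Takes the spans of significant differential peptides and merges
#' overlapping (and, by default, bookended: `end + 1 == next start`) spans
#' into maximal protected regions. Bookended merging keeps single-residue
#' gaps -- e.g. from proline non-coverage -- from splitting one region in
#' two. The operation is idempotent and order-invariant.
#'
#' @param calls Either an `hdx_screen` (its differential peptides are
#'   used), or a tibble with `start`, `end` (and optionally
#'   `peptide_sequence`, `earliest_significant_s`).
#' @param bookend Merge spans that touch end-to-start (default `TRUE`).
#' @return Tibble with `start`, `end`, `n_peptides`, `peptides`
#'   (supporting sequences, collapsed) and `earliest_time_s`, sorted by
#'   `start`.
#' @export
#' @examples
#' merge_regions(tibble::tibble(start = c(130, 129), end = c(133, 133)))
merge_regions <- function(calls, bookend = TRUE) {
  spans <- if (inherits(calls, "hdx_screen")) calls$differential else calls
  empty <- tibble(start = integer(), end = integer(), n_peptides = integer(),
                  peptides = character(), earliest_time_s = numeric())
  if (nrow(spans) == 0) return(empty)
  if (!"peptide_sequence" %in% names(spans)) spans$peptide_sequence <- NA_character_
  if (!"earliest_significant_s" %in% names(spans)) spans$earliest_significant_s <- NA_real_
  spans <- arrange(spans, .data$start, .data$end)
  gap <- if (bookend) 1L else 0L
  group <- cumsum(c(TRUE, spans$start[-1] > cummax(spans$end)[-nrow(spans)] + gap))
  spans %>%
    mutate(region = group) %>%
    group_by(.data$region) %>%
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_peptides = dplyr::n(),
      peptides = paste(stats::na.omit(.data$peptide_sequence), collapse = ";"),
      earliest_time_s = suppressWarnings(min(.data$earliest_significant_s, na.rm = TRUE)),
      .groups = "drop"
    ) %>%
    mutate(earliest_time_s = ifelse(is.finite(.data$earliest_time_s),
                                    .data$earliest_time_s, NA_real_)) %>%
    select(-"region") %>%
    arrange(.data$start)
}
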