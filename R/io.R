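# Readers and writers for the table dialects, FASTA ingestion, and the run
# configuration container.

UPTAKE_COLUMNS <- c("peptide_sequence", "start", "end", "charge", "state",
                    "time_s", "replicate", "centroid_mass")
CONTROL_STATES <- c("IN_CONTROL", "OUT_CONTROL")

#' Read and write the long uptake-table CSV
#'
#' The on-disk dialect is a CSV with header `peptide_sequence, start, end,
#' charge, state, time_s, replicate, centroid_mass`; control rows use
#' `state` values `IN_CONTROL` and `OUT_CONTROL`. Reading validates the
#' header, reports malformed rows with their line numbers, and rejects
#' duplicate `(peptide, charge, state, time, replicate)` keys. Lines
#' starting with `#` are ignored (metadata such as the config hash).
#'
#' @param path File path.
#' @param require_controls Error when a peptide lacks `OUT_CONTROL` rows
#'   (default `TRUE`). With `FALSE` the negligible-in-exchange shortcut can
#'   be applied downstream.
#' @return A tibble in the uptake dialect.
#' @export
read_uptake_table <- function(path, require_controls = TRUE) {
  tbl <- suppressWarnings(readr::read_csv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      peptide_sequence = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      charge = readr::col_integer(),
      state = readr::col_character(),
      time_s = readr::col_double(),
      replicate = readr::col_integer(),
      centroid_mass = readr::col_double()
    )
  ))
  missing <- setdiff(UPTAKE_COLUMNS, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("uptake table missing header field(s): ",
                 paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(paste0(
      "malformed uptake rows at line(s): ",
      paste(unique(probs$row + 1L), collapse = ", ")
    ))
  }
  dup <- tbl %>%
    count(.data$peptide_sequence, .data$start, .data$charge, .data$state,
          .data$time_s, .data$replicate) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate (peptide, charge, state, time, replicate) rows, e.g. ",
                 dup$peptide_sequence[1], " charge ", dup$charge[1],
                 " state ", dup$state[1]))
  }
  if (require_controls) {
    no_out <- tbl %>%
      group_by(.data$peptide_sequence, .data$start, .data$charge) %>%
      summarise(has_out = any(.data$state == "OUT_CONTROL"), .groups = "drop") %>%
      filter(!.data$has_out)
    if (nrow(no_out) > 0) {
      abort(paste0(nrow(no_out), " peptide(s) lack OUT_CONTROL rows (first: ",
                   no_out$peptide_sequence[1],
                   "); supply controls or set require_controls = FALSE"))
    }
  }
  tbl
}

#' @rdname read_uptake_table
#' @param uptake Uptake tibble to write.
#' @param config_hash Optional hash recorded as a `#` comment line.
#' @export
write_uptake_table <- function(uptake, path, config_hash = NULL) {
  missing <- setdiff(UPTAKE_COLUMNS, names(uptake))
  if (length(missing) > 0) {
    abort(paste0("uptake table missing column(s): ", paste(missing, collapse = ", ")))
  }
  write_with_header(uptake[UPTAKE_COLUMNS], path, config_hash, delim = ",")
}

# write a delimited file with an optional leading "# key: value" comment
write_with_header <- function(tbl, path, config_hash = NULL, delim = "\t") {
  header <- if (!is.null(config_hash)) paste0("# config_hash: ", config_hash, "\n") else ""
  body <- readr::format_delim(tbl, delim = delim)
  cat(header, body, file = path, sep = "")
  invisible(path)
}

#' Read a protein sequence from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (usually length one).
#' @export
read_fasta_sequence <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  setNames(as.character(aas), names(aas))
}

#' Write/read ground-truth or result region tables (TSV)
#'
#' @param regions Regions tibble.
#' @param path File path.
#' @param config_hash Optional hash comment.
#' @return The regions tibble (readers) or `path` invisibly (writers).
#' @export
write_regions_table <- function(regions, path, config_hash = NULL) {
  write_with_header(regions, path, config_hash)
}

#' @rdname write_regions_table
#' @export
read_regions_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Export differential calls as a Woods-plot-style table
#'
#' One row per peptide, charge and time with `start`, `end`, `length`,
#' `delta`, `sigma`, `significant` -- the tabular mirror of a Woods plot.
#'
#' @param calls Differential call tibble or an `hdx_screen`.
#' @param path Output TSV path.
#' @param config_hash Optional hash comment.
#' @return `path`, invisibly.
#' @export
write_woods_table <- function(calls, path, config_hash = NULL) {
  if (inherits(calls, "hdx_screen")) calls <- calls$calls
  out <- calls %>%
    mutate(length = .data$end - .data$start + 1L) %>%
    select("peptide_sequence", "start", "end", "length", "charge", "time_s",
           "delta", "sigma", "significant")
  write_with_header(out, path, config_hash)
}

#' Export kinetics in long format
#'
#' @param fractions Fraction table from [exchange_fractions()].
#' @param path Output TSV path.
#' @param config_hash Optional hash comment.
#' @export
write_kinetics_table <- function(fractions, path, config_hash = NULL) {
  out <- select(fractions, "peptide_sequence", "start", "end", "charge",
                "state", "time_s", "f", "sd", "n")
  write_with_header(out, path, config_hash)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with defaults equal to the
#' standard workflow values: identification filters (intensity 3000,
#' products 2, products/aa 0.15, consecutive 1), envelope-matching
#' tolerances (15 ppm, 9 s, 2 drift bins), the 2-sigma one-sided
#' significance rule with linear SD-sum propagation, time grid
#' {10, 60, 1200} s, and SASA parameters (probe 1.4 Angstrom, 960 points).
#'
#' @param ... Overrides for any default (must name existing fields).
#' @return A list of class `hdx_config`, with a stable `hash`.
#' @export
#' @examples
#' hdx_config(sigma_multiplier = 3)$sigma_multiplier
hdx_config <- function(...) {
  cfg <- list(
    numbering_offset = 23L,
    time_points_s = c(10, 60, 1200),
    min_intensity = 3000,
    min_products = 2,
    min_products_per_aa = 0.15,
    min_consecutive_products = 1,
    mz_tol_ppm = 15,
    rt_tol_s = 9,
    drift_tol_bins = 2,
    sigma_multiplier = 2,
    sided = "one",
    error_model = "sum",
    confirm_next = TRUE,
    min_span_da = 0.1,
    flag_limit = 0.15,
    bookend_merge = TRUE,
    equivalence_threshold = 0.10,
    probe_radius = 1.4,
    sasa_points = 960L,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  cfg$hash <- rlang::hash(cfg[sort(setdiff(names(cfg), "hash"))])
  class(cfg) <- "hdx_config"
  cfg
}

#' @export
print.hdx_config <- function(x, ...) {
  cat("hdx_config (hash", x$hash, ")\n")
  for (nm in setdiff(names(x), "hash")) {
    cat(" ", nm, "=", paste(format(x[[nm]]), collapse = " "), "\n")
  }
  invisible(x)
}
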