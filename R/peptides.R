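# Peptide-level bookkeeping: exchangeable-amide counting and peptide tables.

#' Count exchangeable backbone amides of a peptide
#'
#' The N-terminal residue and prolines (which have no amide hydrogen) carry
#' no exchangeable backbone amide, so the count is
#' `length - 1 - (# prolines at positions 2..end)`. Some workflows
#' additionally discount the second residue for its fast back-exchange;
#' `exclude_second = TRUE` enables that variant.
#'
#' @param sequence Character vector of peptide sequences.
#' @param exclude_second Also exclude the second residue (default `FALSE`).
#' @return Integer vector of exchangeable-amide counts.
#' @export
#' @examples
#' n_exchangeable("PRVWEPVPLEE")  # 8: minus N-terminus, minus P232/P234
n_exchangeable <- function(sequence, exclude_second = FALSE) {
  vapply(sequence, function(s) {
    length(exchangeable_positions(s, start = 1L, exclude_second = exclude_second))
  }, integer(1), USE.NAMES = FALSE)
}

#' Positions of exchangeable backbone amides
#'
#' @param sequence Peptide sequence.
#' @param start Residue number of the first residue (reporting numbering).
#' @param exclude_second Also exclude the second residue.
#' @return Integer vector of residue numbers carrying exchangeable amides.
#' @export
exchangeable_positions <- function(sequence, start = 1L, exclude_second = FALSE) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  local <- seq_along(aa)
  keep <- local >= 2 & aa != "P"
  if (exclude_second) keep <- keep & local != 2
  as.integer(start + local[keep] - 1L)
}

#' Build a peptide identification table
#'
#' Assembles the peptide-list tibble used throughout the pipeline from
#' sequences and start positions, deriving `end`, monoisotopic `mass` and
#' `n_exchangeable`.
#'
#' @param sequence Character vector of peptide sequences.
#' @param start Integer vector of start residues (1-based, inclusive,
#'   reporting numbering).
#' @param charge Integer charge states (recycled).
#' @param exclude_second Passed to [n_exchangeable()].
#' @return A tibble with columns `sequence`, `start`, `end`, `charge`,
#'   `mass`, `n_exchangeable`.
#' @export
peptide_table <- function(sequence, start, charge = 2L, exclude_second = FALSE) {
  stopifnot(length(sequence) == length(start))
  tibble(
    sequence = toupper(sequence),
    start = as.integer(start),
    end = as.integer(start + nchar(sequence) - 1L),
    charge = as.integer(rep_len(charge, length(sequence))),
    mass = monoisotopic_mass(sequence),
    n_exchangeable = n_exchangeable(sequence, exclude_second = exclude_second)
  )
}

#' Nearest oligomer order consistent with an observed mass
#'
#' A light-scattering consistency check: given a monomer mass, returns the
#' integer oligomer order whose expected mass best matches the observed
#' mass, with the relative deviation.
#'
#' @param observed_kda Observed species mass (kDa).
#' @param monomer_kda Monomer mass (kDa).
#' @return A tibble with `observed_kda`, `order`, `expected_kda`,
#'   `relative_error`.
#' @export
#' @examples
#' oligomer_order(c(69, 104), monomer_kda = 34.6)
oligomer_order <- function(observed_kda, monomer_kda) {
  stopifnot(monomer_kda > 0, all(observed_kda > 0))
  ord <- pmax(1L, as.integer(round(observed_kda / monomer_kda)))
  tibble(
    observed_kda = observed_kda,
    order = ord,
    expected_kda = ord * monomer_kda,
    relative_error = abs(observed_kda - ord * monomer_kda) / (ord * monomer_kda)
  )
}
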