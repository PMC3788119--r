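# Isotopic envelopes of partially deuterated peptides and their
# weighted-average (centroid) masses — the quantity read off as Mex.
#
# An envelope is represented in centroided form: one peak per nominal
# neutron-excess bin, carrying the abundance-weighted exact mass of the
# isotopologues that fall in that bin. Convolution in this representation is
# exact for both abundances and first moments, so centroid additivity holds
# to machine precision.

#' Construct an isotopic envelope
#'
#' An envelope is a tibble with strictly increasing `mass` (Da) and
#' non-negative `intensity` normalized to sum to one.
#'
#' @param mass Numeric vector of isotopologue (peak) masses, Da.
#' @param intensity Non-negative abundances; normalized internally.
#' @return A tibble of class `isotopic_envelope` with columns `mass`,
#'   `intensity`.
#' @export
#' @examples
#' isotopic_envelope(c(500, 501), c(3, 1))
isotopic_envelope <- function(mass, intensity) {
  if (length(mass) == 0 || length(mass) != length(intensity)) {
    abort("mass and intensity must be non-empty vectors of equal length")
  }
  if (any(intensity < 0)) abort("intensities must be non-negative")
  tot <- sum(intensity)
  if (tot <= 0) abort("all-zero intensities: envelope has no signal")
  if (is.unsorted(mass, strictly = TRUE)) abort("masses must be strictly increasing")
  out <- tibble(mass = as.numeric(mass), intensity = intensity / tot)
  class(out) <- c("isotopic_envelope", class(out))
  out
}

# internal pattern: parallel vectors over nominal bins k = 0, 1, ...
# $p  abundance per bin, $m  abundance-weighted mean exact mass per bin
new_pattern <- function(k, mass, abundance) {
  kmax <- max(k)
  p <- numeric(kmax + 1)
  w <- numeric(kmax + 1)
  for (i in seq_along(k)) {
    p[k[i] + 1] <- p[k[i] + 1] + abundance[i]
    w[k[i] + 1] <- w[k[i] + 1] + abundance[i] * mass[i]
  }
  m <- ifelse(p > 0, w / p, 0)
  list(p = p, m = m)
}

# exact convolution of two bin patterns: abundances multiply-convolve, bin
# mean masses combine by abundance weighting (first moments are exact)
convolve_pattern <- function(a, b) {
  na <- length(a$p); nb <- length(b$p)
  p <- numeric(na + nb - 1)
  w <- numeric(na + nb - 1)
  for (i in seq_len(na)) {
    if (a$p[i] == 0) next
    idx <- i:(i + nb - 1)
    pij <- a$p[i] * b$p
    p[idx] <- p[idx] + pij
    w[idx] <- w[idx] + pij * (a$m[i] + b$m)
  }
  list(p = p, m = ifelse(p > 0, w / p, 0))
}

# drop trailing bins once cumulative abundance exceeds 1 - tol (renormalize)
truncate_pattern <- function(pat, tol = 1e-12) {
  keep <- which(cumsum(pat$p) <= 1 - tol)
  n <- min(length(pat$p), max(keep, 0) + 1)
  p <- pat$p[seq_len(n)]
  list(p = p / sum(p), m = pat$m[seq_len(n)])
}

# element pattern raised to the n-th power by exponentiation-by-squaring
element_power <- function(element, n, tol = 1e-12) {
  tab <- ISOTOPE_TABLE[[element]]
  base <- new_pattern(tab$k, tab$mass, tab$abundance)
  result <- NULL
  while (n > 0) {
    if (n %% 2 == 1) {
      result <- if (is.null(result)) base else truncate_pattern(convolve_pattern(result, base), tol)
    }
    n <- n %/% 2
    if (n > 0) base <- truncate_pattern(convolve_pattern(base, base), tol)
  }
  result
}

#' Natural isotope distribution of a peptide
#'
#' Computes the isotopic envelope of an undeuterated peptide from its
#' elemental composition by iterative convolution of per-element isotope
#' patterns, truncated once cumulative abundance exceeds `1 - trunc_tol`.
#'
#' @param sequence Peptide sequence (standard one-letter alphabet).
#' @param trunc_tol Abundance mass discarded in the truncated tail.
#' @return An [isotopic_envelope()].
#' @export
#' @examples
#' env <- natural_isotope_distribution("SASEL")
#' centroid(env) - monoisotopic_mass("SASEL")
natural_isotope_distribution <- function(sequence, trunc_tol = 1e-6) {
  comp <- peptide_formula(sequence)
  pat <- NULL
  for (el in names(comp)) {
    if (comp[[el]] == 0) next
    q <- element_power(el, comp[[el]])
    pat <- if (is.null(pat)) q else convolve_pattern(pat, q)
  }
  pat <- truncate_pattern(pat, trunc_tol)
  keep <- pat$p > 0
  isotopic_envelope(pat$m[keep], pat$p[keep])
}

#' Poisson-binomial number-of-deuterons distribution
#'
#' Probability mass function of the number of incorporated deuterons given
#' independent per-site incorporation probabilities, computed by iterative
#' convolution (exact, no sampling).
#'
#' @param site_probs Vector of per-site deuteration probabilities in
#'   `[0, 1]`.
#' @return Numeric vector `p[k+1] = P(k deuterons)`, `k = 0..length(site_probs)`.
#' @export
#' @examples
#' poisson_binomial(c(0.5, 0.5))
poisson_binomial <- function(site_probs) {
  if (any(site_probs < 0 | site_probs > 1)) {
    abort("site probabilities must lie in [0, 1]")
  }
  p <- 1
  for (d in site_probs) {
    p <- c(p * (1 - d), 0) + c(0, p * d)
  }
  p
}

#' Deuterated envelope of a peptide
#'
#' Convolves the natural isotope pattern with the Poisson-binomial
#' distribution of incorporated deuterons, each adding the D-H mass
#' difference (1.006277 Da). The centroid of the result exceeds the natural
#' centroid by exactly `delta_mass_D * sum(site_probs)`.
#'
#' @param natural An [isotopic_envelope()] of the undeuterated peptide.
#' @param site_probs Per-exchangeable-site deuteration probabilities.
#' @return An [isotopic_envelope()].
#' @export
#' @examples
#' env <- natural_isotope_distribution("SASEL")
#' denv <- deuterated_envelope(env, c(0.2, 0.9, 0.5))
#' centroid(denv) - centroid(env)   # = 1.006277 * 1.6
deuterated_envelope <- function(natural, site_probs) {
  stopifnot(inherits(natural, "isotopic_envelope"))
  pd <- poisson_binomial(site_probs)
  nat <- list(p = natural$intensity, m = natural$mass)
  deut <- list(
    p = pd,
    m = DELTA_MASS_D * (seq_along(pd) - 1)
  )
  out <- convolve_pattern(nat, deut)
  keep <- out$p > 0
  isotopic_envelope(out$m[keep], out$p[keep])
}

#' Centroid (weighted-average) mass of an envelope
#'
#' The intensity-weighted mean of the peak masses; for measured envelopes
#' this is the deuterium-uptake readout Mex.
#'
#' @param envelope An [isotopic_envelope()] (or any tibble with `mass` and
#'   `intensity` columns).
#' @return Weighted-average mass, Da.
#' @export
#' @examples
#' centroid(isotopic_envelope(c(500, 502), c(1, 1)))  # 501
centroid <- function(envelope) {
  if (nrow(envelope) == 0) abort("empty envelope")
  tot <- sum(envelope$intensity)
  if (tot <= 0) abort("all-zero intensities")
  sum(envelope$mass * envelope$intensity) / tot
}

#' Write an envelope as a two-column TSV
#'
#' @param envelope An [isotopic_envelope()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(envelope, path) {
  readr::write_tsv(tibble(mass = envelope$mass, intensity = envelope$intensity), path)
  invisible(path)
}
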