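# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's convolution/sampling
# code paths.

# enumerate all isotopologue combinations with at most `max_heavy` heavy
# replacements for an elemental composition, aggregated by nominal neutron
# excess k; returns absolute probabilities for bins k = 0..max_heavy
brute_force_isotope_bins <- function(comp, max_heavy = 3L) {
  iso <- list(
    C = data.frame(k = c(0, 1), p = c(0.9893, 0.0107)),
    H = data.frame(k = c(0, 1), p = c(0.999885, 0.000115)),
    N = data.frame(k = c(0, 1), p = c(0.99632, 0.00368)),
    O = data.frame(k = c(0, 1, 2), p = c(0.99757, 0.00038, 0.00205)),
    S = data.frame(k = c(0, 1, 2, 4), p = c(0.9493, 0.0076, 0.0429, 0.0002))
  )
  bins <- numeric(max_heavy + 1)
  # per-element: enumerate heavy-isotope count vectors (total heavies small)
  per_element_states <- lapply(names(iso), function(el) {
    n <- comp[[el]]
    if (is.null(n) || n == 0) {
      return(data.frame(k = 0, heavies = 0, p = 1))
    }
    tab <- iso[[el]]
    heavy_idx <- which(tab$k > 0)
    counts <- expand.grid(rep(list(0:max_heavy), length(heavy_idx)))
    counts <- counts[rowSums(counts) <= max_heavy, , drop = FALSE]
    out <- lapply(seq_len(nrow(counts)), function(r) {
      cts <- as.numeric(counts[r, ])
      n0 <- n - sum(cts)
      if (n0 < 0) return(NULL)
      full <- c(n0, cts)
      prob <- dmultinom(full, prob = tab$p)
      data.frame(k = sum(cts * tab$k[heavy_idx]), heavies = sum(cts), p = prob)
    })
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  })
  combos <- Reduce(function(a, b) {
    m <- merge(a, b, by = NULL)
    data.frame(k = m$k.x + m$k.y, heavies = m$heavies.x + m$heavies.y,
               p = m$p.x * m$p.y)
  }, per_element_states)
  combos <- combos[combos$heavies <= max_heavy & combos$k <= max_heavy, ]
  for (i in seq_len(nrow(combos))) {
    bins[combos$k[i] + 1] <- bins[combos$k[i] + 1] + combos$p[i]
  }
  bins
}

# exhaustive 2^N enumeration of deuteration states: mixture of the natural
# envelope shifted by the number of deuterons, aggregated in (bin, mass)
enum_deuterated_envelope <- function(natural, site_probs) {
  n <- length(site_probs)
  dm <- hdx_constants()$delta_mass_D
  nbins <- nrow(natural) + n
  p <- numeric(nbins); w <- numeric(nbins)
  for (mask in 0:(2^n - 1)) {
    on <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    prob <- prod(ifelse(on, site_probs, 1 - site_probs))
    k <- sum(on)
    idx <- seq_len(nrow(natural)) + k
    p[idx] <- p[idx] + prob * natural$intensity
    w[idx] <- w[idx] + prob * natural$intensity * (natural$mass + k * dm)
  }
  keep <- p > 0
  tibble::tibble(mass = w[keep] / p[keep], intensity = p[keep])
}

# Monte-Carlo SASA oracle: random (not lattice) directions, independent of
# the implementation's Fibonacci sampling
mc_sasa_total <- function(atoms, probe = 1.4, n_points = 20000, seed = 99) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n_points), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- atoms$radius + probe
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  total <- 0
  for (i in seq_len(nrow(atoms))) {
    pts <- sweep(u * rad[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in seq_len(nrow(atoms))) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & d2 >= rad[j]^2
    }
    total <- total + 4 * pi * rad[i]^2 * mean(acc)
  }
  total
}

# small random atom cluster (single chain)
random_cluster <- function(n = 10, seed = 7, chain = "A", spread = 6) {
  set.seed(seed)
  atom_table(chain, seq_len(n), "ALA", "CA",
             sample(c("C", "N", "O", "S"), n, replace = TRUE),
             runif(n, 0, spread), runif(n, 0, spread), runif(n, 0, spread))
}

# C2-symmetric homodimer: chain B is chain A rotated 180 degrees about the
# z axis through (cx, 0, .)
c2_dimer <- function(n = 24, seed = 11, cx = 7) {
  set.seed(seed)
  a <- atom_table("A", rep(seq_len(ceiling(n / 3)), each = 3)[seq_len(n)],
                  rep_len(c("LEU", "GLU", "ARG"), n),
                  "CA", "C",
                  runif(n, 0, 6), runif(n, -4, 4), runif(n, 0, 6))
  b <- a
  b$chain <- "B"
  b$x <- 2 * cx - a$x
  b$y <- -a$y
  rbind_atoms <- dplyr::bind_rows(a, b)
  class(rbind_atoms) <- class(a)
  rbind_atoms
}

# minimal hand-built uptake table: one peptide, explicit per-replicate f
make_uptake <- function(f_reps, state = "monomer", time_s = 10,
                        sequence = "ASEL", start = 130L, charge = 1L,
                        mex0 = 500, mex100 = 506) {
  end <- start + nchar(sequence) - 1L
  rows <- tibble::tibble(
    peptide_sequence = sequence, start = start, end = end, charge = charge,
    state = state, time_s = time_s, replicate = seq_along(f_reps),
    centroid_mass = mex0 + f_reps * (mex100 - mex0)
  )
  ctrl <- tibble::tibble(
    peptide_sequence = sequence, start = start, end = end, charge = charge,
    state = c("IN_CONTROL", "OUT_CONTROL"), time_s = 0, replicate = 1L,
    centroid_mass = c(mex0, mex100)
  )
  dplyr::bind_rows(rows, ctrl)
}

# write a minimal but column-correct PDB file; atoms is an atom_table-like
# data frame with chain, resno, resid (3-letter), atom, element, x, y, z
write_toy_pdb <- function(atoms, path, extra_lines = character(0)) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, atoms$atom[i], atoms$resid[i], atoms$chain[i], atoms$resno[i],
            atoms$x[i], atoms$y[i], atoms$z[i], 1, 0, atoms$element[i])
  }, character(1))
  writeLines(c(lines, extra_lines, "END"), path)
  invisible(path)
}
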