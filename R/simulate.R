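# Forward simulation of two-state peptide-level HDX-MS data under the EX2
# regime, with known ground truth, in-exchange floor and back-exchange
# ceiling controls, replicate noise and multiple charge states per peptide.

#' Per-site deuteration probability under EX2 exchange
#'
#' In the EX2 limit a site with intrinsic rate `k_int` and protection factor
#' `P` exchanges with observed rate `k_obs = k_int / P`, giving
#' `d(t) = 1 - exp(-(k_int / P) * t)`. Infinite protection yields 0 at all
#' times.
#'
#' @param k_int Intrinsic amide exchange rate, 1/s (> 0).
#' @param P Protection factor (>= 1, may be `Inf`).
#' @param t Exchange time, seconds (>= 0). Vectors recycle.
#' @return Deuteration probability in `[0, 1]`.
#' @export
#' @examples
#' simulate_site_deuteration(log(2), 1, 1)  # 0.5
simulate_site_deuteration <- function(k_int, P, t) {
  if (any(t < 0)) abort("exchange time must be non-negative")
  if (any(k_int <= 0)) abort("k_int must be positive")
  if (any(P < 1)) abort("protection factors must be >= 1")
  k_obs <- ifelse(is.infinite(P), 0, k_int / P)
  1 - exp(-k_obs * t)
}

#' Expected deuterium uptake of a peptide
#'
#' Sums per-site EX2 deuteration over the exchangeable amides of a peptide
#' and applies the experimental floor and ceiling: the in-exchange fraction
#' `alpha` (deuterium unavoidably acquired during quench and digestion) and
#' the back-exchange fraction `beta` (label lost before detection). Each
#' site's detected probability is `alpha + (1 - alpha - beta) * d_i(t)`, so
#' the total interpolates between the in-exchange floor `alpha * N` and the
#' full-deuteration ceiling `(1 - beta) * N` and the downstream
#' fraction-of-exchange statistic recovers `mean(d_i)` exactly.
#'
#' @param sequence Peptide sequence.
#' @param start First-residue number of the peptide (reporting numbering).
#' @param params Data frame with columns `position`, `k_int`, `P` covering
#'   every exchangeable position of the peptide.
#' @param t Exchange time(s), seconds.
#' @param alpha In-exchange fraction, `[0, 1)`.
#' @param beta Back-exchange fraction, `[0, 1)`; requires `alpha < 1 - beta`.
#' @param exclude_second Passed to [exchangeable_positions()].
#' @return Expected deuterium count (atoms), one value per `t`.
#' @export
#' @examples
#' pars <- data.frame(position = 2:5, k_int = 1, P = 1)
#' simulate_peptide_uptake("ASEL", 2, pars, t = c(0, 1e6))
simulate_peptide_uptake <- function(sequence, start, params, t,
                                    alpha = 0, beta = 0,
                                    exclude_second = FALSE) {
  stopifnot(alpha >= 0, alpha < 1, beta >= 0, beta < 1)
  if (alpha >= 1 - beta) abort("controls must bracket: requires alpha < 1 - beta")
  pos <- exchangeable_positions(sequence, start, exclude_second)
  n_ex <- length(pos)
  if (n_ex == 0) {
    warn(paste0("peptide ", sequence, " has no exchangeable amides; uptake is 0"))
    return(rep(0, length(t)))
  }
  idx <- match(pos, params$position)
  if (anyNA(idx)) {
    abort(paste0("parameter table does not cover positions: ",
                 paste(pos[is.na(idx)], collapse = ", ")))
  }
  vapply(t, function(tt) {
    d <- simulate_site_deuteration(params$k_int[idx], params$P[idx], tt)
    alpha * n_ex + (1 - alpha - beta) * sum(d)
  }, numeric(1))
}

#' Define a two-state HDX simulation scenario
#'
#' Bundles everything the forward simulator needs: the construct sequence
#' and numbering offset, the peptic digest (peptide table with charge
#' states), the per-residue baseline protection landscape, the state labels
#' and the regions whose protection is multiplied in the test state, the
#' exchange time grid, replicate count, centroid noise, and the control
#' levels.
#'
#' @param sequence Construct amino-acid sequence.
#' @param digest Peptide table as from [peptide_table()] (one row per
#'   peptide x charge state). Defaults to a non-overlapping tiling digest.
#' @param offset Residue number of the first sequence position (reporting
#'   numbering), default 1.
#' @param states Two state labels, reference first.
#' @param protected_regions Tibble with `state`, `start`, `end`,
#'   `multiplier`: protection factors inside the region are multiplied for
#'   that state.
#' @param time_points_s Exchange times in seconds; default `c(10, 60, 1200)`.
#' @param n_replicates Replicates per state and time (>= 3 recommended;
#'   < 2 rejected at simulation time).
#' @param noise_sd Gaussian centroid-mass noise SD per replicate.
#' @param noise_units `"fraction"` (SD expressed in fraction-of-exchange
#'   units, scaled per peptide by its control span) or `"Da"`.
#' @param in_exchange In-exchange fraction alpha in `[0, 1)`.
#' @param back_exchange Back-exchange fraction beta in `[0, 1)`;
#'   `alpha < 1 - beta` required.
#' @param k_int Baseline intrinsic rate (1/s) used where `baseline` gives
#'   none.
#' @param baseline Optional tibble `position`, `k_int`, `P` overriding the
#'   default alternating protected/unprotected landscape.
#' @param seed Integer RNG seed for reproducible simulation.
#' @param exclude_second Exchangeable-amide convention flag.
#' @return A list of class `hdx_scenario`.
#' @export
hdx_scenario <- function(sequence,
                         digest = NULL,
                         offset = 1L,
                         states = c("monomer", "dimer"),
                         protected_regions = tibble(
                           state = character(), start = integer(),
                           end = integer(), multiplier = numeric()
                         ),
                         time_points_s = c(10, 60, 1200),
                         n_replicates = 3L,
                         noise_sd = 0.02,
                         noise_units = c("fraction", "Da"),
                         in_exchange = 0.03,
                         back_exchange = 0.15,
                         k_int = 1,
                         baseline = NULL,
                         seed = 1L,
                         exclude_second = FALSE) {
  noise_units <- match.arg(noise_units)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  first <- as.integer(offset)
  last <- first + L - 1L
  if (length(states) != 2) abort("exactly two state labels required")
  if (in_exchange >= 1 - back_exchange) {
    abort("controls must bracket observations: in_exchange < 1 - back_exchange")
  }
  if (nrow(protected_regions) > 0) {
    stopifnot(all(c("state", "start", "end", "multiplier") %in% names(protected_regions)))
    if (any(protected_regions$start < first | protected_regions$end > last)) {
      abort("protected regions must lie within the sequence bounds")
    }
    if (any(!protected_regions$state %in% states)) abort("region state not in `states`")
    if (any(protected_regions$multiplier < 1)) abort("multipliers must be >= 1")
  }
  if (any(time_points_s <= 0)) abort("time points must be positive")
  if (is.null(digest)) digest <- tiling_digest(sequence, offset = first)
  stopifnot(all(c("sequence", "start", "end", "charge") %in% names(digest)))
  if (any(digest$start < first | digest$end > last)) {
    abort("digest peptides must lie within the sequence bounds")
  }
  if (is.null(baseline)) {
    baseline <- default_landscape(L, offset = first, k_int = k_int)
  }
  structure(list(
    sequence = sequence, digest = digest, offset = first, states = states,
    protected_regions = protected_regions,
    time_points_s = sort(unique(time_points_s)),
    n_replicates = as.integer(n_replicates),
    noise_sd = noise_sd, noise_units = noise_units,
    in_exchange = in_exchange, back_exchange = back_exchange,
    k_int = k_int, baseline = baseline, seed = as.integer(seed),
    exclude_second = exclude_second
  ), class = "hdx_scenario")
}

# alternating landscape of unprotected / strongly protected / intermediate
# blocks, emulating the intertwined protected and unprotected stretches of
# a folded multidomain construct
default_landscape <- function(length, offset = 1L, k_int = 1,
                              block = 15L, P_cycle = c(1, 1500, 8, 200)) {
  pos <- seq.int(offset, offset + length - 1L)
  blk <- ((seq_len(length) - 1L) %/% block) %% length(P_cycle) + 1L
  tibble(position = pos, k_int = k_int, P = P_cycle[blk])
}

#' Per-residue protection landscape of a scenario state
#'
#' Applies the state's region multipliers to the baseline landscape.
#'
#' @param scenario An [hdx_scenario()].
#' @param state State label.
#' @return Tibble `position`, `k_int`, `P`.
#' @export
protection_landscape <- function(scenario, state) {
  stopifnot(inherits(scenario, "hdx_scenario"))
  if (!state %in% scenario$states) abort(paste0("unknown state: ", state))
  land <- scenario$baseline
  regs <- dplyr::filter(scenario$protected_regions, .data$state == .env$state)
  for (i in seq_len(nrow(regs))) {
    sel <- land$position >= regs$start[i] & land$position <= regs$end[i]
    land$P[sel] <- land$P[sel] * regs$multiplier[i]
  }
  land
}

# deterministic digest tiling the construct while avoiding `avoid` spans;
# leaves periodic gaps so sequence coverage is partial, as in real peptic maps
tiling_digest <- function(sequence, offset = 1L, avoid = NULL,
                          tile_len = 11L, gap_cycle = c(3L, 6L, 3L, 7L),
                          overlap_every = 2L) {
  L <- nchar(sequence)
  first <- as.integer(offset)
  last <- first + L - 1L
  segments <- tibble(start = first, end = last)
  if (!is.null(avoid) && nrow(avoid) > 0) {
    segments <- complement_spans(avoid, first, last)
  }
  starts <- integer(0); ends <- integer(0)
  k <- 0L
  for (i in seq_len(nrow(segments))) {
    pos <- segments$start[i]
    while (pos + tile_len - 1L <= segments$end[i]) {
      k <- k + 1L
      starts <- c(starts, pos); ends <- c(ends, pos + tile_len - 1L)
      if (k %% overlap_every == 0L && pos + 4L + 8L <= segments$end[i]) {
        starts <- c(starts, pos + 4L); ends <- c(ends, pos + 12L)
      }
      pos <- pos + tile_len + gap_cycle[(k - 1L) %% length(gap_cycle) + 1L]
    }
  }
  seqs <- substring(sequence, starts - first + 1L, ends - first + 1L)
  lens <- ends - starts + 1L
  charges <- ifelse(lens <= 8L, list(c(1L, 2L)), list(c(2L, 3L)))
  out <- tibble(sequence = rep(seqs, lengths(charges)),
                start = rep(starts, lengths(charges)),
                charge = unlist(charges))
  peptide_table(out$sequence, out$start, out$charge)
}

# spans of [first, last] not covered by `spans` (tibble start/end)
complement_spans <- function(spans, first, last) {
  spans <- dplyr::arrange(spans, .data$start)
  out_start <- integer(0); out_end <- integer(0)
  cur <- first
  for (i in seq_len(nrow(spans))) {
    if (spans$start[i] > cur) {
      out_start <- c(out_start, cur); out_end <- c(out_end, spans$start[i] - 1L)
    }
    cur <- max(cur, spans$end[i] + 1L)
  }
  if (cur <= last) { out_start <- c(out_start, cur); out_end <- c(out_end, last) }
  tibble(start = out_start, end = out_end)
}

#' The built-in RAGE-like interface scenario
#'
#' A synthetic extracellular-RAGE-like construct (residues 23-326 in
#' full-length numbering) carrying the interface motifs at their published
#' positions: SASEL at 129-133 and PRVWEPVPLEE at 227-237 followed by
#' V238-Q239-L240 and the C2-domain start V241, plus PARGGDPR at 196-203
#' and GPQESR at 309-314. The background sequence is a fixed pseudo-random
#' fill and is synthetic, not the real RAGE sequence. The digest contains
#' the four interface peptides ASEL, SASEL, PRVWEPVPLE and PRVWEPVPLEE
#' (each in two charge states) and background peptides tiling around the
#' interface regions with deterministic gaps, so that only the four
#' interface peptides overlap the boosted regions. In the test state
#' (`dimer`) the protection factors of regions 129-133 and 227-237 are
#' multiplied by `multiplier`.
#'
#' @param multiplier Dimer-state protection boost for the two interface
#'   regions (default 20; 1 gives two statistically identical states).
#' @param seed RNG seed for the simulation.
#' @param ... Further arguments passed to [hdx_scenario()].
#' @return An [hdx_scenario()].
#' @export
#' @examples
#' sc <- rage_scenario(seed = 7)
#' sc$protected_regions
rage_scenario <- function(multiplier = 20, seed = 1L, ...) {
  seq <- rage_like_sequence()
  offset <- 23L
  regions <- tibble(start = c(129L, 227L), end = c(133L, 237L))
  interface <- peptide_table(
    sequence = rep(c("ASEL", "SASEL", "PRVWEPVPLE", "PRVWEPVPLEE"), each = 2),
    start = rep(c(130L, 129L, 227L, 227L), each = 2),
    charge = c(1L, 2L, 1L, 2L, 2L, 3L, 2L, 3L)
  )
  background <- tiling_digest(seq, offset = offset, avoid = regions)
  digest <- dplyr::bind_rows(interface, background)
  # interface regions moderately protected in the monomer so that exchange
  # is fast but measurable at 10 s; everything else from the default landscape
  land <- default_landscape(nchar(seq), offset = offset)
  sel <- (land$position >= 129 & land$position <= 133) |
    (land$position >= 227 & land$position <= 237)
  land$P[sel] <- 5
  hdx_scenario(
    sequence = seq, digest = digest, offset = offset,
    states = c("monomer", "dimer"),
    protected_regions = tibble(
      state = "dimer", start = c(129L, 227L), end = c(133L, 237L),
      multiplier = multiplier
    ),
    baseline = land, seed = seed, ...
  )
}

# fixed synthetic construct sequence; pseudo-random fill with the interface
# motifs written in at their reporting positions (offset 23)
rage_like_sequence <- function() {
  L <- 304L
  aa <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  fill <- with_seed(201310L, sample(aa, L, replace = TRUE,
                                    prob = c(8, 5, 7, 4, 7, 2, 5, 6, 9, 4,
                                             5, 4, 5, 7, 6, 7, 1, 3)))
  put <- function(x, at, motif) {
    x[at:(at + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
    x
  }
  off <- 23L
  fill <- put(fill, 129L - off + 1L, "SASEL")
  fill <- put(fill, 196L - off + 1L, "PARGGDPR")
  fill <- put(fill, 227L - off + 1L, "PRVWEPVPLEEVQLV")  # ..237 + V238 Q239 L240 V241
  fill <- put(fill, 309L - off + 1L, "GPQESR")
  paste(fill, collapse = "")
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Simulate a full synthetic HDX-MS study
#'
#' Forward-simulates replicate centroid masses for every peptide, charge
#' state, state, and time point of a scenario, together with noise-free
#' in-exchange and out-exchange control rows and the ground-truth protected
#' regions. Output is reproducible under a fixed scenario seed and
#' byte-identical across calls.
#'
#' @param scenario An [hdx_scenario()].
#' @param n_decoys Number of identification-only decoy rows that fail the
#'   standard quality filters (no uptake rows are simulated for them).
#' @return A list of class `hdx_dataset` with elements `peptides`
#'   (identification table), `uptake` (long uptake table including control
#'   rows, the on-disk CSV dialect), `truth` (ground-truth regions) and
#'   `scenario`.
#' @export
#' @examples
#' ds <- simulate_hdx_dataset(rage_scenario(seed = 42))
#' dplyr::count(ds$uptake, state)
simulate_hdx_dataset <- function(scenario, n_decoys = 3L) {
  stopifnot(inherits(scenario, "hdx_scenario"))
  if (scenario$n_replicates < 2) abort("at least 2 replicates required (SD undefined)")
  if (scenario$n_replicates < 3) {
    warn("fewer than 3 replicates: reported SDs will be poorly determined")
  }
  alpha <- scenario$in_exchange
  beta <- scenario$back_exchange
  dm <- DELTA_MASS_D

  peptides <- dplyr::distinct(scenario$digest, .data$sequence, .data$start, .keep_all = FALSE)
  peptides$end <- peptides$start + nchar(peptides$sequence) - 1L
  peptides$n_ex <- n_exchangeable(peptides$sequence, scenario$exclude_second)
  peptides$base_mass <- vapply(peptides$sequence,
                               function(s) centroid(natural_isotope_distribution(s)),
                               numeric(1), USE.NAMES = FALSE)

  landscapes <- lapply(scenario$states, function(st) protection_landscape(scenario, st))
  names(landscapes) <- scenario$states

  # expected uptake per peptide, state, time (deterministic part)
  grid <- tidyr::expand_grid(
    pep = seq_len(nrow(peptides)),
    state = scenario$states,
    time_s = scenario$time_points_s
  )
  grid$D <- purrr::pmap_dbl(grid, function(pep, state, time_s) {
    simulate_peptide_uptake(
      peptides$sequence[pep], peptides$start[pep], landscapes[[state]],
      time_s, alpha = alpha, beta = beta,
      exclude_second = scenario$exclude_second
    )
  })

  charges <- dplyr::distinct(scenario$digest, .data$sequence, .data$start, .data$charge)
  obs <- grid %>%
    mutate(sequence = peptides$sequence[.data$pep],
           start = peptides$start[.data$pep],
           end = peptides$end[.data$pep],
           n_ex = peptides$n_ex[.data$pep],
           base_mass = peptides$base_mass[.data$pep]) %>%
    inner_join(charges, by = c("sequence", "start"),
               relationship = "many-to-many") %>%
    tidyr::expand_grid(replicate = seq_len(scenario$n_replicates)) %>%
    arrange(.data$start, .data$sequence, .data$charge, .data$state,
            .data$time_s, .data$replicate)

  sd_da <- if (scenario$noise_units == "fraction") {
    scenario$noise_sd * obs$n_ex * (1 - alpha - beta) * dm
  } else {
    rep(scenario$noise_sd, nrow(obs))
  }
  noise <- with_seed(scenario$seed, rnorm(nrow(obs), 0, sd_da))
  obs$centroid_mass <- obs$base_mass + dm * obs$D + noise

  uptake <- obs %>%
    select(peptide_sequence = "sequence", "start", "end", "charge",
           "state", "time_s", "replicate", "centroid_mass")

  controls <- peptides %>%
    inner_join(charges, by = c("sequence", "start")) %>%
    mutate(
      in_mass = .data$base_mass + alpha * .data$n_ex * dm,
      out_mass = .data$base_mass + (1 - beta) * .data$n_ex * dm
    )
  control_rows <- dplyr::bind_rows(
    controls %>% mutate(state = "IN_CONTROL", centroid_mass = .data$in_mass),
    controls %>% mutate(state = "OUT_CONTROL", centroid_mass = .data$out_mass)
  ) %>%
    mutate(time_s = 0, replicate = 1L) %>%
    select(peptide_sequence = "sequence", "start", "end", "charge",
           "state", "time_s", "replicate", "centroid_mass") %>%
    arrange(.data$start, .data$peptide_sequence, .data$charge, .data$state)

  ids <- identification_table(scenario, n_decoys = n_decoys)
  truth <- dplyr::filter(scenario$protected_regions, .data$multiplier > 1)

  structure(list(
    peptides = ids,
    uptake = dplyr::bind_rows(uptake, control_rows),
    truth = truth,
    scenario = scenario
  ), class = "hdx_dataset")
}

# identification table in the peptide-list dialect, with deterministic
# retention times, drift times and QC fields; decoy rows fail the filters
identification_table <- function(scenario, n_decoys = 3L) {
  digest <- scenario$digest
  len <- nchar(digest$sequence)
  ids <- digest %>%
    mutate(
      rt_s = round(90 + 2.1 * len + (.data$start %% 37) * 3.7, 1),
      drift_bins = as.integer(20 + round(mass_to_mz(.data$mass, .data$charge) / 40)),
      intensity = 5000 + 211 * (.data$start %% 41),
      n_products = pmax(2L, len - 2L),
      n_consecutive_products = pmax(1L, len - 4L)
    )
  if (n_decoys > 0) {
    seq <- scenario$sequence
    off <- scenario$offset
    dec_start <- off + 3L * seq_len(n_decoys)
    dec_len <- 18L + 2L * seq_len(n_decoys)
    dec <- peptide_table(
      substring(seq, dec_start - off + 1L, dec_start - off + dec_len),
      dec_start, charge = 2L
    ) %>%
      mutate(
        rt_s = 60 + 5 * dplyr::row_number(),
        drift_bins = 25L,
        intensity = c(2500, rep(8000, n_decoys - 1))[seq_len(n_decoys)],
        n_products = c(5L, 1L, rep(2L, max(0, n_decoys - 2)))[seq_len(n_decoys)],
        n_consecutive_products = 1L
      )
    ids <- dplyr::bind_rows(ids, dec)
  }
  ids
}
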