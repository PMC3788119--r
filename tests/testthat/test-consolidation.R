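id_row <- function(sequence = "ASELKWQHDT", intensity = 5000, n_products = 5,
                   n_consecutive_products = 2, start = 10L, charge = 2L) {
  tibble::tibble(
    sequence = sequence, start = start,
    end = start + nchar(sequence) - 1L, charge = charge,
    mass = monoisotopic_mass(sequence), rt_s = 100, drift_bins = 30L,
    intensity = intensity, n_products = n_products,
    n_consecutive_products = n_consecutive_products
  )
}

test_that("identification filters apply the standard acceptance thresholds", {
  # intensity boundary: 2999 rejected, 3000 kept
  low <- id_row(intensity = 2999)
  acc <- filter_identifications(low)
  expect_equal(nrow(acc), 0L)
  expect_match(attr(acc, "rejected")$reason, "intensity")
  ok <- id_row(sequence = "ASELKWQHDTLRN", intensity = 3000, n_products = 2,
               n_consecutive_products = 1)
  # products per amino acid: 2/13 = 0.154 >= 0.15
  expect_equal(nrow(filter_identifications(ok)), 1L)
  # 2/14 = 0.143 < 0.15
  bad_ratio <- id_row(sequence = "ASELKWQHDTLRNG", intensity = 3000,
                      n_products = 2, n_consecutive_products = 1)
  acc2 <- filter_identifications(bad_ratio)
  expect_equal(nrow(acc2), 0L)
  expect_match(attr(acc2, "rejected")$reason, "products_per_aa")
  # empty table passes through without error
  empty <- filter_identifications(id_row()[0, ])
  expect_equal(nrow(empty), 0L)
  # missing columns named in the error
  expect_error(filter_identifications(dplyr::select(id_row(), -intensity)),
               "intensity")
})

test_that("observation matching enforces all three tolerances with ppm tie-break", {
  ids <- dplyr::bind_rows(
    id_row(sequence = "ASELKWQHDT", start = 10L),
    id_row(sequence = "TTTTKWQHDT", start = 40L)
  )
  mz1 <- mass_to_mz(ids$mass[1], 2L)
  obs_exact <- tibble::tibble(mz = mz1, charge = 2L, rt_s = 100, drift_bins = 30L)
  m <- match_observations(ids, obs_exact)
  expect_equal(m$sequence, "ASELKWQHDT")
  expect_equal(nrow(attr(m, "unmatched")), 0L)
  # 16 ppm off in m/z: unmatched even with exact RT and drift
  obs_off <- tibble::tibble(mz = mz1 * (1 + 16e-6), charge = 2L,
                            rt_s = 100, drift_bins = 30L)
  m2 <- match_observations(ids, obs_off)
  expect_equal(nrow(m2), 0L)
  expect_equal(nrow(attr(m2, "unmatched")), 1L)
  # two candidates at 3 and 10 ppm: the 3 ppm one wins
  twin <- ids
  twin$mass[2] <- ids$mass[1] * (1 + 7e-6)
  twin$start[2] <- 40L
  obs_mid <- tibble::tibble(mz = mass_to_mz(ids$mass[1] * (1 + 3e-6), 2L),
                            charge = 2L, rt_s = 100, drift_bins = 30L)
  m3 <- match_observations(twin, obs_mid)
  expect_equal(m3$start, 10L)
  expect_lt(m3$ppm_dev, 4)
  # RT and drift boundaries
  obs_rt <- tibble::tibble(mz = mz1, charge = 2L, rt_s = 110, drift_bins = 30L)
  expect_equal(nrow(match_observations(ids, obs_rt)), 0L)
  obs_drift <- tibble::tibble(mz = mz1, charge = 2L, rt_s = 100, drift_bins = 33L)
  expect_equal(nrow(match_observations(ids, obs_drift)), 0L)
})

test_that("sequence coverage is the union of spans and is monotone", {
  expect_equal(sequence_coverage(tibble::tibble(start = 1L, end = 100L), 100), 1)
  expect_equal(sequence_coverage(tibble::tibble(start = integer(), end = integer()), 100), 0)
  base <- tibble::tibble(start = c(1L, 11L), end = c(10L, 20L))
  expect_equal(sequence_coverage(base, 100), 0.2)
  # overlap does not double count
  ov <- dplyr::bind_rows(base, tibble::tibble(start = 5L, end = 15L))
  expect_equal(sequence_coverage(ov, 100), 0.2)
  # monotone under peptide addition
  set.seed(8)
  peps <- tibble::tibble(start = sample(1:90, 20, TRUE))
  peps$end <- pmin(100L, peps$start + sample(5:15, 20, TRUE))
  cov <- vapply(seq_len(20), function(k) {
    sequence_coverage(peps[seq_len(k), ], 100)
  }, numeric(1))
  expect_true(all(diff(cov) >= 0))
  expect_error(sequence_coverage(base, 0), "positive")
})

test_that("region merging unions overlapping and bookended spans", {
  r1 <- merge_regions(tibble::tibble(start = c(130L, 129L), end = c(133L, 133L)))
  expect_equal(r1$start, 129L)
  expect_equal(r1$end, 133L)
  expect_equal(r1$n_peptides, 2L)
  r2 <- merge_regions(tibble::tibble(start = c(227L, 227L), end = c(236L, 237L)))
  expect_equal(r2$start, 227L)
  expect_equal(r2$end, 237L)
  r3 <- merge_regions(tibble::tibble(start = c(10L, 40L), end = c(20L, 50L)))
  expect_equal(nrow(r3), 2L)
  # bookended spans merge by default but not with bookend = FALSE
  touching <- tibble::tibble(start = c(10L, 21L), end = c(20L, 30L))
  expect_equal(nrow(merge_regions(touching)), 1L)
  expect_equal(nrow(merge_regions(touching, bookend = FALSE)), 2L)
  # idempotent and order-invariant
  set.seed(4)
  spans <- tibble::tibble(start = sample(1:80, 12, TRUE))
  spans$end <- spans$start + sample(3:10, 12, TRUE)
  a <- merge_regions(spans)
  b <- merge_regions(spans[sample(nrow(spans)), ])
  expect_equal(a[c("start", "end", "n_peptides")], b[c("start", "end", "n_peptides")])
  again <- merge_regions(a[c("start", "end")])
  expect_equal(again$start, a$start)
  expect_equal(again$end, a$end)
  expect_equal(nrow(merge_regions(spans[0, ])), 0L)
})

test_that("exchangeable-amide counting matches the DynamX convention", {
  expect_equal(n_exchangeable("ASEL"), 3L)
  expect_equal(n_exchangeable("SASEL"), 4L)
  expect_equal(n_exchangeable("PRVWEPVPLE"), 7L)
  expect_equal(n_exchangeable("PRVWEPVPLEE"), 8L)
  expect_equal(n_exchangeable("GP"), 0L)
  # exclude-second variant drops one more unless position 2 is proline
  expect_equal(n_exchangeable("ASEL", exclude_second = TRUE), 2L)
  expect_equal(n_exchangeable("APEL", exclude_second = TRUE), 2L)
  expect_equal(exchangeable_positions("PRVWEPVPLEE", start = 227L),
               c(228L, 229L, 230L, 231L, 233L, 235L, 236L, 237L))
})
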