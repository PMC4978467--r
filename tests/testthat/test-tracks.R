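prom <- function(strand = "+", tss = 10000) {
  tibble::tibble(transcript_id = "p1", chrom = "chr1", strand = strand,
    tss = tss)
}

test_that("pileup normalizes and orients reads around the TSS", {
  # one read covering genomic positions of offsets +1..+50, library 1e6
  reads <- tibble::tibble(chrom = "chr1", start = 10000, end = 10049)
  tr <- pileup(reads, prom("+"), span = c(-100, 100), library_size = 1e6)
  expect_equal(tr$value[tr$offset %in% 1:50], rep(1, 50))
  expect_equal(sum(tr$value), 50)

  # minus-strand promoter: read genomically upstream appears downstream (+)
  reads2 <- tibble::tibble(chrom = "chr1", start = 9951, end = 10000)
  tr2 <- pileup(reads2, prom("-"), span = c(-100, 100), library_size = 1e6)
  expect_equal(tr2$value[tr2$offset %in% 1:50], rep(1, 50))
  expect_equal(sum(tr2$value), 50)

  # per-base track input reproduced exactly, flipped for minus strand
  offs <- offset_seq(-100, 100)
  bump <- exp(-((seq_along(offs) - 120)^2) / 200)
  track <- tibble::tibble(chrom = "chr1",
    pos = offset_to_pos_for_test(offs, 10000, "+"), value = bump)
  tr3 <- pileup(track, prom("+"), span = c(-100, 100))
  expect_equal(tr3$value, bump)
  # metamorphic: a minus-strand promoter sees the genomic mirror image
  track_m <- tibble::tibble(chrom = "chr1",
    pos = offset_to_pos_for_test(offs, 10000, "-"), value = bump)
  tr4 <- pileup(track_m, prom("-"), span = c(-100, 100))
  expect_equal(tr4$value, bump)
})

test_that("strand-shift estimation recovers planted displacements", {
  set.seed(21)
  base <- as.numeric(stats::filter(rpois(1200, 4), rep(1, 15), sides = 2))
  base[is.na(base)] <- 4
  top <- matrix(base[101:1100], 1)
  bottom <- matrix(base[101:1100 - 70], 1)  # bottom displaced +70
  expect_equal(estimate_strand_shift(top, bottom, max_shift = 100)$shift, 35)
  expect_equal(estimate_strand_shift(top, top, max_shift = 100)$shift, 0)
  expect_error(estimate_strand_shift(matrix(1, 1, 500), matrix(1, 1, 500)),
    "constant")
})

test_that("region signals, standard regions, and pausing index", {
  offs <- offset_seq(-200, 1500)
  vals <- rep(0.4, length(offs))
  expect_equal(region_signal(vals, offs, c(21, 100), "mean"), 0.4)
  # reads/base/1e6 -> RPKM = mean * 1000
  expect_equal(region_signal(vals, offs, c(21, 100), "rpkm"), 400)
  expect_equal(rpkm_from_counts(8, 80, 1e6), 100)
  expect_true(is.na(region_signal(vals, offs, c(1400, 1600))))

  expect_equal(standard_regions("mouse", 2000)$gene_body, c(301, 1300))
  expect_equal(standard_regions("mouse", 900)$gene_body, c(301, 500))
  expect_true(all(is.na(standard_regions("mouse", 400)$gene_body)))
  expect_equal(standard_regions("fly")$pause, c(1, 100))

  expect_equal(pausing_index(10, 2), 5)
  expect_equal(pausing_index(0, 2), 0)
  expect_true(is.na(pausing_index(1, 0)))
})

test_that("quantile normalization matches the brute-force oracle and is idempotent", {
  m <- matrix(c(5, 2, 3, 4, 1, 2), 3)  # contains a within-column tie pattern
  qn <- quantile_normalize(m)
  expect_equal(qn, qn_oracle(m), ignore_attr = TRUE)

  set.seed(22)
  m2 <- matrix(sample(1:8, 50 * 4, replace = TRUE), 50)  # many ties
  qn2 <- quantile_normalize(m2)
  expect_equal(qn2, qn_oracle(m2), ignore_attr = TRUE)
  expect_equal(rank(qn2[, 2], ties.method = "average"),
    rank(m2[, 2], ties.method = "average"))
  # on tie-free data the column distributions become identical and the
  # operation is idempotent (with ties the tie-mean rule perturbs them)
  m3 <- matrix(rnorm(50 * 4), 50)
  qn3 <- quantile_normalize(m3)
  expect_equal(sort(qn3[, 1]), sort(qn3[, 3]))
  expect_equal(quantile_normalize(qn3), qn3)
  # already-identical columns unchanged
  same <- matrix(rep(c(1, 4, 9), 3), 3)
  expect_equal(quantile_normalize(same), same)
})

test_that("trimmed averaging excludes tail quantiles", {
  tracks <- matrix(1, 100, 10)
  tracks <- rbind(tracks, rep(1000, 10))
  expect_equal(unname(trimmed_group_average(tracks, trim = 0.01)), rep(1, 10))
  expect_equal(unname(trimmed_group_average(tracks, trim = 0)),
    rep(mean(c(rep(1, 100), 1000)), 10))
  set.seed(23)
  noisy <- matrix(rnorm(200 * 5, 1, 0.1), 200)
  expect_lt(max(abs(trimmed_group_average(noisy, 0.01) - 1)), 0.03)
  expect_warning(trimmed_group_average(matrix(1, 2, 3)), "plain mean")
})

test_that("phase-binned reordering aligns planted phases", {
  times <- seq(0, 20, by = 4)
  series <- 2 + cos(2 * pi * times / 24)
  vals <- matrix(rep(series, each = 50), 50, byrow = FALSE)
  pb <- phase_bin_reorder(vals, times, phases = rep(0, 50))
  expect_equal(pb$profile$value, series)
  expect_equal(pb$fit$phase, 0, tolerance = 1e-8)

  # a promoter with missing phase is excluded and counted
  pb2 <- phase_bin_reorder(vals, times, phases = c(NA, rep(0, 49)))
  expect_equal(pb2$n_excluded, 1)
  expect_true(all(pb2$profile$n == 49))
})

test_that("circular phase differences map to (-12, 12]", {
  expect_equal(circular_phase_diff(2, 22), 4)
  expect_equal(circular_phase_diff(5, 5), 0)
  expect_equal(circular_phase_diff(0, 12), 12)
  expect_equal(circular_phase_diff(12, 0), 12)
  expect_equal(circular_phase_diff(1, 2), -1)
})

test_that("Watson two-sample permutation test separates shifted phase samples", {
  set.seed(24)
  a <- rvonmises_hours(50, 6, 2)
  b <- rvonmises_hours(50, 18, 2)
  res <- circular_two_sample_test(a, b, n_perm = 2000, seed = 1)
  expect_lt(res$p_value, 0.01)
  same <- circular_two_sample_test(a, a, n_perm = 500, seed = 1)
  expect_gt(same$p_value, 0.9)
  # deterministic under a fixed seed
  r1 <- circular_two_sample_test(a, b, n_perm = 200, seed = 7)
  r2 <- circular_two_sample_test(a, b, n_perm = 200, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
})
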