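test_that("PCM regularization matches the sqrt-N pseudocount formula", {
  u <- matrix(10, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(unname(regularize_pcm(u, background_probs(0.5))),
    matrix(0.25, 4, 3))

  pcm <- matrix(c(97, 0, 1, 2), 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  got <- regularize_pcm(pcm, background_probs(0.5), kappa = 1)
  # N = 100, sqrt(N) = 10: (count + 10 * 0.25) / 110
  expect_equal(as.numeric(got), c(99.5, 2.5, 3.5, 4.5) / 110)
  expect_true(all(got > 0))

  bad <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 4, 2,
    dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(regularize_pcm(bad), "total")
})

test_that("exact score distribution equals exhaustive enumeration", {
  set.seed(7)
  for (w in c(1, 3, 4)) {
    sm <- score_matrix(rand_pcm(w), gc = runif(1, 0.3, 0.7))
    for (model in c("background", "motif")) {
      d <- exact_score_distribution(sm, model)
      expect_lt(abs(sum(d$pmf) - 1), 1e-12)
      oracle <- enum_score_dist(sm, model, d$epsilon)
      keys <- as.character(round(d$grid / d$epsilon))
      tv <- sum(abs(d$pmf[match(names(oracle), keys)] - oracle))
      expect_lt(tv, 1e-9)
      # analytic first moment
      emis <- if (model == "background") matrix(sm$background, 4, w) else sm$motif_probs
      expect_lt(abs(sum(d$grid * d$pmf) - sum(emis * sm$scores)),
        w * d$epsilon)
    }
  }
  # single column with equal scores -> point mass
  pcm1 <- matrix(5, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  d1 <- exact_score_distribution(score_matrix(pcm1), "background")
  expect_equal(sum(d1$pmf > 1e-15), 1)
})

test_that("balanced threshold minimizes |FPR - FNR| with smallest-t ties", {
  # identical distributions: balanced near the median, rates ~ 0.5
  sm <- score_matrix(rand_pcm(4), gc = 0.5)
  bg <- exact_score_distribution(sm, "background")
  bt <- balanced_threshold(bg, bg)
  expect_lt(abs(bt$fpr - bt$fnr), 1e-12)
  expect_gt(bt$fpr, 0.35); expect_lt(bt$fpr, 0.65)

  # perfectly separated: FPR = FNR = 0 at smallest such grid point
  mk_dist <- function(grid, pmf, eps) structure(
    list(grid = grid, pmf = pmf, epsilon = eps, model = "background"),
    class = "score_distribution")
  lo <- mk_dist(c(0, 1) * 0.5, c(0.5, 0.5), 0.5)
  hi <- mk_dist(c(4, 5) * 0.5, c(0.5, 0.5), 0.5)
  bt2 <- balanced_threshold(lo, hi)
  expect_equal(bt2$fpr, 0); expect_equal(bt2$fnr, 0)
  expect_equal(bt2$threshold, 1)  # first grid point above the low support

  # brute-force oracle over all grid thresholds
  set.seed(8)
  sm <- score_matrix(rand_pcm(4), gc = 0.4)
  bgd <- exact_score_distribution(sm, "background")
  mod <- exact_score_distribution(sm, "motif", bgd$epsilon)
  bt3 <- balanced_threshold(bgd, mod)
  cand <- sort(unique(c(bgd$grid, mod$grid)))
  gaps <- vapply(cand, function(t)
    abs(sum(bgd$pmf[bgd$grid >= t - 1e-12]) -
        sum(mod$pmf[mod$grid < t - 1e-12])), numeric(1))
  best <- cand[which.min(gaps)]
  expect_equal(bt3$threshold, best)
})

test_that("FPR/FNR monotone on the grid and threshold stable under epsilon refinement", {
  sm <- score_matrix(bundled_pcm("breu"), gc = 0.5)
  bg <- exact_score_distribution(sm, "background")
  mo <- exact_score_distribution(sm, "motif", bg$epsilon)
  eps <- bg$epsilon
  cand <- sort(unique(c(bg$grid, mo$grid)))
  fpr <- vapply(cand, function(t) sum(bg$pmf[bg$grid >= t - 1e-12]), numeric(1))
  fnr <- vapply(cand, function(t) sum(mo$pmf[mo$grid < t - 1e-12]), numeric(1))
  expect_true(all(diff(fpr) <= 1e-12))
  expect_true(all(diff(fnr) >= -1e-12))

  t_coarse <- balanced_threshold(bg, mo)$threshold
  bg2 <- exact_score_distribution(sm, "background", eps / 4)
  mo2 <- exact_score_distribution(sm, "motif", eps / 4)
  t_fine <- balanced_threshold(bg2, mo2)$threshold
  expect_lt(abs(t_fine - t_coarse), eps + 1e-12)
})

test_that("window scanning reports match-start hits and skips ambiguous bases", {
  pcm <- bundled_pcm("tata")
  det <- motif_detector(pcm, gc = 0.5)
  w <- ncol(pcm)
  consensus <- c("A", "C", "G", "T")[apply(pcm, 2, which.max)]
  set.seed(9)
  offs <- offsets_from(-300, 400)
  seq1 <- strsplit(rand_seq(400), "")[[1]]
  seq1[match(offsets_from(-30, w), offs)] <- consensus
  hits <- scan_window(paste(seq1, collapse = ""), det$score_matrix,
    det$threshold, window = c(-50, -10), seq_start = -300)
  expect_true(-30 %in% hits$start)

  allg <- paste(rep("G", 400), collapse = "")
  expect_equal(nrow(scan_window(allg, det$score_matrix, det$threshold,
    window = c(-50, -10), seq_start = -300)), 0)

  seqn <- seq1
  seqn[match(-40, offs)] <- "N"
  hn <- scan_window(paste(seqn, collapse = ""), det$score_matrix,
    det$threshold, window = c(-50, -10), seq_start = -300)
  expect_gt(attr(hn, "n_skipped"), 0)
  expect_true(-30 %in% hn$start)  # planted hit unaffected
})

test_that("conservation filter keeps the maximal hit median", {
  hits <- tibble::tibble(promoter_id = c("p1", "p1", "p2", "p3"),
    start = c(-40, -30, -30, -30), score = 1)
  w <- 7
  cons <- dplyr::bind_rows(
    tibble::tibble(promoter_id = "p1", offset = offsets_from(-50, 60),
      score = rep(0.6, 60)),
    tibble::tibble(promoter_id = "p2", offset = offsets_from(-50, 60),
      score = rep(1.0, 60)),
    tibble::tibble(promoter_id = "p3", offset = offsets_from(-50, 60),
      score = rep(c(0.7, 0.7, 0.8, 0.8, 0.8, 0.7, 0.7), length.out = 60)))
  # p1: medians 0.6 then raise the -30 hit footprint to 0.8
  cons$score[cons$promoter_id == "p1" &
    cons$offset %in% offsets_from(-30, w)] <- 0.8
  # p3: exact footprint values giving median 0.7
  cons$score[cons$promoter_id == "p3" & cons$offset %in% offsets_from(-30, w)] <-
    c(0.7, 0.7, 0.8, 0.8, 0.8, 0.7, 0.7)
  out <- conservation_filter(hits, cons, width = w, min_median = 0.75)
  keep <- setNames(out$promoters$retained, out$promoters$promoter_id)
  expect_true(keep[["p1"]])    # max over (0.6, 0.8)
  expect_true(keep[["p2"]])    # all 1.0
  expect_false(keep[["p3"]])   # median 0.7 alone
})

test_that("CpG ratio follows CG*N/(G*C) with the zero-denominator convention", {
  expect_equal(cpg_ratio(strrep("CG", 100)), 2.0)
  expect_equal(cpg_ratio(strrep("A", 200)), 0)
  # GC repeat: 99 internal CG dinucleotides
  expect_equal(cpg_ratio(strrep("GC", 100)), 99 * 200 / (100 * 100))
  expect_error(cpg_ratio("ACGT"), "length")
  # reverse complement preserves the CG count, hence the ratio
  set.seed(10)
  for (i in 1:20) {
    s <- rand_seq(200, gc = runif(1, 0.3, 0.7))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(cpg_ratio(s), cpg_ratio(rc))
  }
})
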