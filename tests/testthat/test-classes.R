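test_that("CTF binding uses inclusive +/- window boundaries", {
  prom <- tibble::tibble(transcript_id = c("p1", "p2", "p3"),
    chrom = "chr1", tss = c(10000, 50000, 90000))
  peaks <- tibble::tibble(
    factor = c("BMAL1", "BMAL1", "REV-ERBa"),
    chrom = "chr1",
    center = c(13000,   # exactly at +3000 of p1 -> bound
      53001,            # +3001 of p2 -> unbound
      89000))           # -1000 of p3 -> bound
  out <- assign_ctf_binding(prom, peaks, window = 3000)
  expect_equal(out$ctf_bound, c(TRUE, FALSE, TRUE))
  expect_equal(out$ctf_bmal1, c(TRUE, FALSE, FALSE))
  expect_equal(out$ctf_reverba, c(FALSE, FALSE, TRUE))
  none <- assign_ctf_binding(prom, peaks[0, ])
  expect_equal(none$ctf_bound, rep(FALSE, 3))
})

test_that("LCpG flag splits strictly below the threshold", {
  expect_true(lcpg_flag(0.3))
  expect_false(lcpg_flag(0.5))
  expect_false(lcpg_flag(2.0))
  expect_error(lcpg_flag(-0.1))
})

test_that("promoter taxonomy is definitional, exclusive, and exhaustive", {
  expect_equal(as.character(
    classify_promoter("circadian", TRUE, TRUE, FALSE)), "SCP")
  expect_equal(as.character(
    classify_promoter("circadian", FALSE, FALSE, TRUE)), "circ_type_I")
  expect_equal(as.character(
    classify_promoter("constitutive", FALSE, FALSE, FALSE)), "const_type_II")
  expect_equal(as.character(
    classify_promoter("circadian", TRUE, FALSE, FALSE)), "circ_type_II")
  expect_equal(as.character(
    classify_promoter("constitutive", TRUE, TRUE, TRUE)), "const_other")
  expect_error(classify_promoter("circadian", NA, TRUE, TRUE), "resolved")

  # deterministic recovery of planted labels on a random flag cohort
  set.seed(31)
  n <- 2000
  rl <- sample(c("circadian", "constitutive", "silent", "other"), n, TRUE)
  ctf <- sample(c(TRUE, FALSE), n, TRUE)
  tata <- sample(c(TRUE, FALSE), n, TRUE)
  lcpg <- sample(c(TRUE, FALSE), n, TRUE)
  got <- classify_promoter(rl, ctf, tata, lcpg)
  # independent restatement of the rules
  oracle <- character(n)
  for (i in seq_len(n)) {
    core <- tata[i] || lcpg[i]
    oracle[i] <- if (rl[i] == "silent") "silent"
      else if (rl[i] == "other") "other"
      else if (rl[i] == "circadian") {
        if (ctf[i] && core) "SCP"
        else if (!ctf[i] && core) "circ_type_I"
        else if (ctf[i]) "circ_type_II" else "circ_other"
      } else {
        if (ctf[i]) "const_other"
        else if (core) "const_type_I" else "const_type_II"
      }
  }
  expect_equal(as.character(got), oracle)
  expect_false(anyNA(got))
  expect_equal(sum(table(got)), n)
})

test_that("enrichment tables match Fisher enumeration with guarded odds ratios", {
  flat <- enrichment_table(rep(c(TRUE, FALSE), each = 10),
    rep(c(TRUE, FALSE), each = 10))
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)

  a <- rep(c(TRUE, FALSE), c(20, 5)); b <- rep(c(TRUE, FALSE), c(5, 20))
  et <- enrichment_table(a, b)
  expect_equal(et$odds_ratio, 16)
  expect_equal(et$p_value, fisher_oracle(20, 5, 5, 20), tolerance = 1e-10)

  z <- enrichment_table(rep(TRUE, 10), rep(c(TRUE, FALSE), c(5, 5)))
  expect_true(is.finite(z$odds_ratio))  # zero cell gets the 0.5 correction

  set.seed(32)
  for (i in 1:10) {
    x <- runif(30) < 0.5; y <- runif(25) < 0.3
    et <- enrichment_table(x, y)
    expect_equal(et$p_value,
      fisher_oracle(sum(x), sum(!x), sum(y), sum(!y)), tolerance = 1e-9)
  }
})
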