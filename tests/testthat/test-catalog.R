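ann_row <- function(id, start, end, strand = "+", chrom = "chr1") {
  tibble::tibble(transcript_id = id, chrom = chrom, strand = strand,
    start = start, end = end)
}

test_that("catalog reduction applies the four rules in order", {
  ann <- dplyr::bind_rows(
    ann_row("A1", 1000, 3000),            # identical pair with A2
    ann_row("A2", 1000, 3000),
    ann_row("B1", 10000, 10799),          # shared TSS, 800 bp -> kept
    ann_row("B2", 10000, 11199),          # shared TSS, 1200 bp -> dropped
    ann_row("C1", 20000, 22000),          # overlapping pair, different TSS
    ann_row("C2", 21000, 23000),          # -> both dropped
    ann_row("D1", 30000, 30399),          # 400 bp -> dropped
    ann_row("NR_1", 40000, 41000),        # non-coding -> dropped
    ann_row("E1", 50000, 51000),          # clean
    ann_row("E2", 60000, 61000, strand = "-")  # clean, minus strand
  )
  cat <- build_catalog(ann)
  expect_setequal(cat$transcript_id, c("A1", "B1", "E1", "E2"))
  expect_equal(cat$tss[cat$transcript_id == "E2"], 61000)
  expect_true(all(diff(cat$tss) > 0))  # sorted by (chrom, tss)

  # record-level rejection with reasons
  bad <- dplyr::bind_rows(ann, ann_row("X1", 500, 100),
    ann_row("X2", 100, 200, strand = "*"))
  cat2 <- build_catalog(bad)
  rej <- attr(cat2, "rejected")
  expect_setequal(rej$transcript_id, c("X1", "X2"))
  expect_setequal(rej$reason, c("start > end", "malformed strand"))
  expect_identical(cat2$transcript_id, cat$transcript_id)
})

test_that("catalog is idempotent and pairwise TSS-unambiguous", {
  set.seed(42)
  n <- 150
  start <- sort(sample(1:500000, n))
  ann <- tibble::tibble(
    transcript_id = sprintf("NM_%03d", 1:n),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    start = start,
    end = start + sample(300:20000, n, replace = TRUE)
  )
  cat <- build_catalog(ann)
  # no shared TSS
  expect_false(any(duplicated(cat[c("chrom", "strand", "tss")])))
  # no retained pair overlaps with different TSS (pairwise check)
  for (ch in unique(cat$chrom)) {
    cc <- cat[cat$chrom == ch, ]
    if (nrow(cc) < 2) next
    for (i in seq_len(nrow(cc) - 1)) {
      for (j in (i + 1):nrow(cc)) {
        overlaps <- cc$start[i] <= cc$end[j] && cc$start[j] <= cc$end[i]
        if (overlaps) expect_equal(cc$tss[i], cc$tss[j])
      }
    }
  }
  # idempotence
  again <- build_catalog(cat)
  expect_equal(again$transcript_id, cat$transcript_id)
})

test_that("CAGE adjustment moves to the nearest cluster with documented tie-break", {
  rec <- build_catalog(dplyr::bind_rows(
    ann_row("P1", 10000, 12000), ann_row("P2", 50000, 52000),
    ann_row("P3", 90000, 92000)))
  clusters <- tibble::tibble(
    chrom = "chr1", strand = "+",
    position = c(10120, 49900, 50100, 90301),
    width = c(4, 12, 12, 5)
  )
  out <- adjust_tss_with_cage(rec, clusters)
  expect_equal(out$tss[out$transcript_id == "P1"], 10120)   # moved 120 bp
  expect_equal(out$shape_class[out$transcript_id == "P1"], "focused")
  # +/-100 tie -> smaller genomic coordinate
  expect_equal(out$tss[out$transcript_id == "P2"], 49900)
  # nearest cluster at 301 bp -> unchanged
  expect_equal(out$tss[out$transcript_id == "P3"], 90000)
  expect_true(is.na(out$cage_width[out$transcript_id == "P3"]))

  # never moves farther than max_dist (property)
  set.seed(1)
  cl2 <- tibble::tibble(chrom = "chr1", strand = "+",
    position = sample(9000:95000, 200), width = sample(1:80, 200, TRUE))
  out2 <- adjust_tss_with_cage(rec, cl2, max_dist = 300)
  expect_true(all(abs(out2$tss - rec$tss) <= 300))
})

test_that("promoter shape calling uses the strict width-10 boundary", {
  expect_equal(call_promoter_shape(9), "focused")
  expect_equal(call_promoter_shape(10), "dispersed")
  expect_equal(call_promoter_shape(0), "focused")
  expect_error(call_promoter_shape(-1), "widths")
})
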