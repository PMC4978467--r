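#' Run the promoter classification pipeline on a cohort
#'
#' Executes catalog construction, CAGE TSS adjustment, sequence-feature
#' detection (balanced-threshold TATA scan and CpG ratio), rhythm
#' quantification and classification, CTF binding assignment, the promoter
#' taxonomy, and summary tables (class fractions with binomial confidence
#' intervals, TATA enrichment among circadian versus constitutive promoters,
#' amplitude-by-activity quantile bins, and the expression-matched bootstrap
#' comparing SCPs to constitutive type I promoters).
#'
#' @param cohort A [generate_cohort()] result, or a list with the same
#'   elements loaded from files.
#' @param organism `"mouse"` or `"fly"` (selects thresholds and regions).
#' @param tata_pcm Position count matrix for the TATA scan (default the
#'   bundled synthetic matrix).
#' @param scan_gc `NULL` for per-promoter GC backgrounds or a fixed value.
#' @param n_null,n_outer Matched-bootstrap sizes (defaults scaled for
#'   interactive use; raise to 1e6/1000 for full-precision runs).
#' @param seed Seed for the bootstrap stage.
#' @return Object of class `circprom_report`: list with `catalog` (annotated
#'   promoter table), `class_fractions`, `tata_enrichment`,
#'   `amplitude_by_activity`, `scp_bootstrap`, `params`.
#' @export
run_pipeline <- function(cohort, organism = c("mouse", "fly"),
                         tata_pcm = bundled_pcm("tata"), scan_gc = NULL,
                         n_null = 20000, n_outer = 100, seed = 1L) {
  organism <- match.arg(organism)
  log_counts <- list()

  catalog <- build_catalog(cohort$annotations)
  log_counts$catalog <- nrow(catalog)
  catalog <- adjust_tss_with_cage(catalog, cohort$cage)

  keep <- intersect(catalog$transcript_id, names(cohort$sequences))
  catalog <- catalog[catalog$transcript_id %in% keep, ]
  seqs <- cohort$sequences[catalog$transcript_id]

  # sequence features: CpG over -100..+100 and a TATA scan at -50..-10
  sw <- attr(cohort$sequences, "seq_window") %||% c(-300, 100)
  offs <- offsets_from(sw[1], nchar(seqs[[1]]))
  cpg_idx <- which(offs >= -100 & offs <= 100)
  cpg_seq <- substr(seqs, min(cpg_idx), max(cpg_idx))
  catalog$cpg_ratio <- cpg_ratio(cpg_seq)
  catalog$lcpg <- lcpg_flag(catalog$cpg_ratio)
  hits <- scan_promoters(seqs, tata_pcm, window = c(-50, -10),
    seq_start = sw[1], gc = scan_gc)
  catalog$tata <- catalog$transcript_id %in% hits$promoter_id
  log_counts$tata_hits <- nrow(hits)

  # rhythms from nascent counts
  idx <- match(catalog$transcript_id, rownames(cohort$counts))
  rpkm <- normalize_counts(cohort$counts, cohort$feature_lengths,
    cohort$library_sizes)[idx, , drop = FALSE]
  fits <- harmonic_fit(cohort$times, rpkm)
  fits <- classify_transcripts(fits, organism)
  catalog <- dplyr::bind_cols(catalog,
    dplyr::select(fits, "mean", "relamp", "phase", "pvalue", "bh_p",
      "rhythm_label"))

  catalog <- assign_ctf_binding(catalog, cohort$ctf_peaks)
  catalog$class <- classify_promoter(catalog$rhythm_label,
    catalog$ctf_bound, catalog$tata, catalog$lcpg)

  counts_by_class <- table(catalog$class)
  class_fractions <- dplyr::bind_rows(lapply(names(counts_by_class),
    function(cl) {
      ci <- fraction_with_ci(counts_by_class[[cl]], nrow(catalog))
      tibble(class = cl, n = counts_by_class[[cl]], fraction = ci$fraction,
        lo = ci$lo, hi = ci$hi)
    }))

  circ <- catalog$rhythm_label == "circadian"
  const <- catalog$rhythm_label == "constitutive"
  tata_enrichment <- enrichment_table(catalog$tata[circ], catalog$tata[const])

  expressed <- catalog$mean > rhythm_thresholds(organism)$expressed_min
  amp_by_act <- quantile_bin_summary(
    catalog$relamp[circ], catalog$mean[circ], seed = seed)

  scp <- catalog$class == "SCP"
  ct1 <- catalog$class == "const_type_I"
  scp_bootstrap <- NULL
  if (sum(scp) >= 5 && sum(ct1) >= 5) {
    wts <- expression_matched_weights(catalog$mean[scp], catalog$mean[ct1])
    scp_bootstrap <- matched_bootstrap_test(
      catalog$cpg_ratio[scp], catalog$cpg_ratio[ct1], wts,
      n_null = n_null, n_outer = n_outer, seed = seed)
  }

  structure(
    list(catalog = catalog, class_fractions = class_fractions,
      tata_enrichment = tata_enrichment,
      amplitude_by_activity = amp_by_act, scp_bootstrap = scp_bootstrap,
      log_counts = log_counts,
      params = list(organism = organism, n_null = n_null,
        n_outer = n_outer, seed = seed)),
    class = "circprom_report"
  )
}

#' @export
print.circprom_report <- function(x, ...) {
  cat("circprom pipeline report (", x$params$organism, ")\n", sep = "")
  cat("promoters retained:", nrow(x$catalog), "\n\nclass fractions:\n")
  print(as.data.frame(x$class_fractions), digits = 3)
  cat("\nTATA enrichment (circadian vs constitutive):\n")
  print(as.data.frame(x$tata_enrichment), digits = 3)
  if (!is.null(x$scp_bootstrap)) {
    cat("\nSCP vs expression-matched constitutive type I (CpG ratio):\n")
    print(x$scp_bootstrap)
  }
  invisible(x)
}

#' Medians with bootstrap confidence intervals across covariate quantile bins
#'
#' Ranks the covariate into `n_quantiles` equal-count bins and reports the
#' per-bin median of `values` with a bootstrap 95% confidence interval.
#'
#' @param values,covariate Paired numeric vectors.
#' @param n_quantiles Number of bins (default 5).
#' @param n_boot Bootstrap resamples per bin (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed.
#' @return Tibble with `bin`, `n`, `median`, `lo`, `hi`.
#' @export
quantile_bin_summary <- function(values, covariate, n_quantiles = 5,
                                 n_boot = 2000, conf = 0.95, seed = NULL) {
  stopifnot(length(values) == length(covariate))
  ok <- complete.cases(values, covariate)
  values <- values[ok]; covariate <- covariate[ok]
  if (n_quantiles < 2) abort("need at least 2 quantile bins")
  if (length(values) < 2 * n_quantiles) abort("too few observations for the bins")
  r <- rank(covariate, ties.method = "first")
  bin <- ceiling(r * n_quantiles / length(r))
  alpha <- (1 - conf) / 2
  run_with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_quantiles), function(b) {
      v <- values[bin == b]
      boots <- vapply(seq_len(n_boot), function(i)
        median(sample(v, replace = TRUE)), numeric(1))
      tibble(bin = b, n = length(v), median = median(v),
        lo = unname(quantile(boots, alpha)),
        hi = unname(quantile(boots, 1 - alpha)))
    }))
  })
}

#' Binomial fraction with Clopper-Pearson interval
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials.
#' @param conf Confidence level (default 0.95).
#' @return List with `fraction`, `lo`, `hi` (exact Clopper-Pearson bounds).
#' @export
fraction_with_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(list(fraction = NA_real_, lo = NA_real_, hi = NA_real_))
  stopifnot(k >= 0, k <= n)
  alpha <- 1 - conf
  lo <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  list(fraction = k / n, lo = lo, hi = hi)
}
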