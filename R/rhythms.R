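#' RPKM normalization with trimmed-log-ratio scale factors
#'
#' Computes RPKM values `count * 1e9 / (length * library_size * scale_factor)`
#' where per-sample scale factors come from the trimmed mean of log ratios
#' against a reference (edgeR's calcNormFactors), renormalized so their
#' median is 1.
#'
#' @param counts Integer matrix, transcripts x samples; colnames are taken as
#'   ZT times when numeric.
#' @param feature_lengths Transcript lengths in bp (> 0), length `nrow(counts)`.
#' @param library_sizes Per-sample library sizes (> 0); default `colSums(counts)`.
#' @return Numeric RPKM matrix with the scale factors as attribute
#'   `"scale_factors"` and sampling times (if resolvable) as `"times"`.
#' @export
normalize_counts <- function(counts, feature_lengths,
                             library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(feature_lengths <= 0)) abort("feature lengths must be > 0")
  if (any(library_sizes <= 0)) abort("library sizes must be > 0")
  stopifnot(length(feature_lengths) == nrow(counts),
    length(library_sizes) == ncol(counts))
  sf <- edgeR::calcNormFactors(counts, lib.size = library_sizes)
  sf <- sf / median(sf)
  eff <- library_sizes * sf
  rpkm <- counts * 1e9 / outer(feature_lengths, eff)
  attr(rpkm, "scale_factors") <- sf
  times <- suppressWarnings(as.numeric(colnames(counts)))
  if (!anyNA(times)) attr(rpkm, "times") <- times
  rpkm
}

# least-squares cosinor fit for a matrix of series (rows = units)
hreg_core <- function(times, Y, period) {
  n <- length(times)
  if (n < 4) abort("harmonic regression needs at least 4 time points")
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  if (qr(X)$rank < 3) abort("rank-deficient cosinor design (too few distinct times mod period)")
  XtXi <- solve(crossprod(X))
  B <- Y %*% X %*% XtXi            # units x 3: (m, a, b)
  fitted <- B %*% t(X)
  rss1 <- rowSums((Y - fitted)^2)
  rss0 <- rowSums((Y - rowMeans(Y))^2)
  fstat <- ((rss0 - rss1) / 2) / (rss1 / (n - 3))
  pval <- pf(fstat, 2, n - 3, lower.tail = FALSE)
  # constant series: both models fit perfectly; no evidence of rhythm
  flat <- rss0 <= .Machine$double.eps * n * (1 + rowMeans(Y)^2)
  pval[flat] <- 1
  m <- B[, 1]; a <- B[, 2]; b <- B[, 3]
  amp <- sqrt(a^2 + b^2)
  relamp <- ifelse(m > 0, amp / m, NA_real_)
  phase <- (atan2(b, a) / w) %% period
  phase[period - phase < 1e-9] <- 0
  tibble(mean = m, amplitude = amp, relamp = relamp, phase = phase,
    pvalue = pval, n = n)
}

#' Harmonic regression (cosinor) rhythm fit
#'
#' Fits `y = m + a cos(wt) + b sin(wt)` with `w = 2 pi / period` by least
#' squares. The relative amplitude is `sqrt(a^2+b^2)/m`, the phase is the
#' peak time in `[0, period)`, and the p value comes from the F test of the
#' two harmonic coefficients against the intercept-only model (df 2, n - 3).
#' Times spanning several days are pooled modulo the period by the fit
#' itself (the harmonics are periodic).
#'
#' @param times Sampling times (ZT hours).
#' @param values Numeric vector (one series) or matrix (units x times).
#' @param period Rhythm period in hours (default 24).
#' @return For a vector, an object of class `harmonic_fit` (see [tidy()] and
#'   [glance()] methods); for a matrix, a tibble with one row per unit:
#'   `unit`, `mean`, `amplitude`, `relamp`, `phase`, `pvalue`, `n`.
#' @export
harmonic_fit <- function(times, values, period = 24) {
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(times))
    out <- hreg_core(times, values, period)
    out <- dplyr::bind_cols(
      tibble(unit = rownames(values) %||% as.character(seq_len(nrow(values)))),
      out
    )
    return(out)
  }
  stopifnot(length(values) == length(times))
  res <- hreg_core(times, matrix(values, nrow = 1), period)
  structure(
    list(times = times, values = values, period = period,
      mean = res$mean, amplitude = res$amplitude, relamp = res$relamp,
      phase = res$phase, pvalue = res$pvalue, n = res$n),
    class = "harmonic_fit"
  )
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf(
    "harmonic_fit (period %g h): mean %.4g, relamp %.4g, phase %.2f h, p %.3g\n",
    x$period, x$mean, x$relamp, x$phase, x$pvalue))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH adjustment (monotone, capped at 1).
#'
#' @param pvalues Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}

#' Default rhythm-classification thresholds per organism
#'
#' Mouse: expressed mean nascent RPKM > 0.1, circadian BH p < 0.2 and
#' relative amplitude > 0.1; fly: expressed > 1, circadian BH p < 0.25 with
#' no amplitude gate. Silent: mean < 0.01 in both. The constitutive gate
#' (raw rhythm p >= `p_const`) makes "no signs of rhythmicity" explicit.
#'
#' @param organism `"mouse"` or `"fly"`.
#' @return Named list of thresholds.
#' @export
rhythm_thresholds <- function(organism = c("mouse", "fly")) {
  organism <- match.arg(organism)
  list(
    expressed_min = if (organism == "mouse") 0.1 else 1,
    silent_max = 0.01,
    p_circ = if (organism == "mouse") 0.2 else 0.25,
    amp_circ = if (organism == "mouse") 0.1 else NA_real_,
    p_const = 0.5
  )
}

#' Classify transcripts as circadian / constitutive / silent / other
#'
#' Silent: mean below `silent_max`. Circadian: expressed, BH-adjusted rhythm
#' p below `p_circ`, and (mouse only) relative amplitude above `amp_circ`.
#' Constitutive: expressed, not circadian, and raw rhythm p at or above
#' `p_const` (no signs of rhythmicity). Everything else (including
#' sub-threshold but non-silent expression) is `other`. The four labels
#' partition the input.
#'
#' @param fits Tibble from [harmonic_fit()] matrix form (needs `mean`,
#'   `relamp`, `pvalue`); `bh_p` defaults to [bh_adjust()] of `pvalue`.
#' @param organism `"mouse"` or `"fly"`.
#' @param thresholds See [rhythm_thresholds()].
#' @param bh_p Optional pre-computed adjusted p values.
#' @return Input tibble plus `bh_p` and `rhythm_label` (factor with levels
#'   circadian, constitutive, silent, other).
#' @export
classify_transcripts <- function(fits, organism = c("mouse", "fly"),
                                 thresholds = rhythm_thresholds(organism),
                                 bh_p = NULL) {
  organism <- match.arg(organism)
  fits <- as_tibble(fits)
  if (is.null(bh_p)) bh_p <- bh_adjust(fits$pvalue)
  silent <- fits$mean < thresholds$silent_max
  expressed <- fits$mean > thresholds$expressed_min
  amp_ok <- if (is.na(thresholds$amp_circ)) TRUE else fits$relamp > thresholds$amp_circ
  circadian <- !silent & expressed & bh_p < thresholds$p_circ & amp_ok
  constitutive <- !silent & expressed & !circadian & fits$pvalue >= thresholds$p_const
  label <- rep("other", nrow(fits))
  label[silent] <- "silent"
  label[circadian] <- "circadian"
  label[constitutive] <- "constitutive"
  fits$bh_p <- bh_p
  fits$rhythm_label <- factor(label,
    levels = c("circadian", "constitutive", "silent", "other"))
  fits
}

#' Upper-quantile flag
#'
#' TRUE iff a value reaches the empirical `q` quantile (type-7) of the
#' vector, e.g. the upper 25% of transcriptional activities at `q = 0.75`.
#'
#' @param values Non-empty numeric vector.
#' @param q Quantile in `[0, 1]` (default 0.75).
#' @return Logical vector.
#' @export
quantile_flag <- function(values, q = 0.75) {
  stopifnot(length(values) > 0)
  values >= quantile(values, q, type = 7, na.rm = TRUE)
}
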