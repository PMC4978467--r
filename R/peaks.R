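#' Detect the +1 nucleosome peak downstream of a TSS
#'
#' After moving-average smoothing, a position is a peak candidate iff its
#' smoothed value rises significantly above the track's baseline: it must
#' exceed the lower-quartile level of the smoothed track by more than `k_sd`
#' standard deviations of the smoothed sampling noise (estimated robustly
#' from first differences of the raw track, which a smooth trend barely
#' touches). A local mean/SD flank cannot be used here - a nucleosome-width
#' peak's own shoulders dominate any flank window and mask the peak - and a
#' global median/MAD fails on phased arrays whose nucleosomes elevate most
#' of the span. The first (smallest offset) candidate inside the search
#' window that is also a local maximum within +/- `smooth` bp is called the
#' +1 nucleosome. A flat track yields no detection.
#'
#' @param values,offsets Nucleosome (MNase) pileup and its TSS-relative
#'   offsets; should extend well beyond the search window.
#' @param search_window Offsets searched (default `c(1, 300)`).
#' @param k_sd Threshold in noise standard deviations (default 3).
#' @param smooth Moving-average width in bp (default 20); also the
#'   local-maximum radius.
#' @return List with `detected`, `plus1_offset`, `peak_height` (smoothed).
#' @export
detect_plus1_peak <- function(values, offsets, search_window = c(1, 300),
                              k_sd = 3, smooth = 20) {
  stopifnot(length(values) == length(offsets))
  sm <- moving_average(values, smooth)
  n <- length(sm)
  win <- which(offsets >= search_window[1] & offsets <= search_window[2])
  if (!length(win)) abort("track does not cover the search window")
  half <- max(1L, as.integer(smooth))
  noise_sd <- stats::mad(diff(values)) / sqrt(2)
  sdev <- noise_sd / sqrt(max(1, smooth))  # noise left after smoothing
  thr <- quantile(sm, 0.25, names = FALSE) + k_sd * sdev
  if (diff(range(sm)) < .Machine$double.eps * max(abs(sm), 1)) {
    return(list(detected = FALSE, plus1_offset = NA_integer_,
      peak_height = NA_real_))
  }
  for (i in win) {
    if (sm[i] <= thr) next
    lo <- max(1L, i - half); hi <- min(n, i + half)
    if (sm[i] >= max(sm[lo:hi])) {
      return(list(detected = TRUE, plus1_offset = offsets[i],
        peak_height = sm[i]))
    }
  }
  list(detected = FALSE, plus1_offset = NA_integer_, peak_height = NA_real_)
}

#' Pol II stall fraction upstream of the +1 nucleosome
#'
#' The stall fraction (SF) is the fraction of the 100 positions immediately
#' upstream of the +1 nucleosome whose 3'-end nascent signal rises
#' significantly above its immediate surroundings: a position is stalled iff
#' its value exceeds the mean plus `k_sd` standard deviations of its
#' +/- `flank` bp neighbourhood (center excluded). The criterion is
#' scale-free. Classes: high (SF > 0.6), low (0.05 < SF <= 0.3), other.
#'
#' @param values,offsets 3'-end nascent pileup with TSS-relative offsets
#'   covering `[plus1 - 100 - flank, plus1 - 1 + flank]`.
#' @param plus1_offset +1 nucleosome offset from [detect_plus1_peak()]; `NA`
#'   yields a missing SF.
#' @param flank,k_sd As in [detect_plus1_peak()].
#' @param width Width of the upstream region (default 100 bp).
#' @return List with `stall_fraction`, `sf_class`, `stalled_offsets`.
#' @export
stall_fraction <- function(values, offsets, plus1_offset, flank = 50,
                           k_sd = 3, width = 100) {
  if (is.na(plus1_offset)) {
    return(list(stall_fraction = NA_real_, sf_class = NA_character_,
      stalled_offsets = integer()))
  }
  region <- offsets_before(plus1_offset - 1L, width)
  if (plus1_offset - 1L == 0) region <- offsets_before(-1L, width)
  idx <- match(region, offsets)
  if (anyNA(idx)) abort("track does not cover the upstream region")
  st <- local_flank_stats(values, flank)
  stalled <- !is.na(st$mean[idx]) & st$sd[idx] > 0 &
    values[idx] > st$mean[idx] + k_sd * st$sd[idx]
  sf <- sum(stalled) / width
  list(stall_fraction = sf, sf_class = stall_fraction_class(sf),
    stalled_offsets = region[stalled])
}

#' Stall-fraction class boundaries
#'
#' High: SF > 0.6; low: 0.05 < SF <= 0.3; everything else `other`.
#'
#' @param sf Stall fraction(s) in `[0, 1]`.
#' @return Character vector of classes.
#' @export
stall_fraction_class <- function(sf) {
  ifelse(sf > 0.6, "high", ifelse(sf > 0.05 & sf <= 0.3, "low", "other"))
}

#' Nucleosome-normalized H2A.Z signal at the +1 nucleosome
#'
#' Mean H2A.Z pileup over +/- `halfwidth` bp of the +1 nucleosome peak,
#' divided by the mean nucleosome (MNase) pileup over the same interval.
#'
#' @param h2az_values,nuc_values Pileups on shared `offsets`.
#' @param offsets TSS-relative offsets of both tracks.
#' @param plus1_offset +1 peak offset.
#' @param halfwidth Interval half width (default 80 bp).
#' @return Normalized value; `NA` (with a warning) if the nucleosome mean is
#'   zero or the peak is undetected.
#' @export
h2az_signal <- function(h2az_values, nuc_values, offsets, plus1_offset,
                        halfwidth = 80) {
  if (is.na(plus1_offset)) return(NA_real_)
  lo <- plus1_offset - halfwidth
  hi <- plus1_offset + halfwidth
  if (lo == 0) lo <- -1L
  if (hi == 0) hi <- 1L
  region <- offset_seq(lo, hi)
  idx <- match(region, offsets)
  if (anyNA(idx)) abort("tracks do not cover the +1 interval")
  nuc <- mean(nuc_values[idx])
  if (nuc <= 0) {
    warn("zero nucleosomal signal at the +1 interval")
    return(NA_real_)
  }
  mean(h2az_values[idx]) / nuc
}
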