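#' TSS-anchored, strand-oriented coverage pileup
#'
#' Computes per-base normalized coverage around each promoter's TSS,
#' oriented so that +1 is the first downstream base (minus-strand promoters
#' are flipped). Input is either a read-interval table or a per-base track;
#' values are reads per base per `per` reads (1e6 for ChIP, 1e7 for
#' MNase/H2A.Z conventions).
#'
#' @param x Either reads: tibble with `chrom`, `start`, `end` (1-based,
#'   inclusive), or a per-base track: tibble with `chrom`, `pos`, `value`
#'   (already normalized; no further scaling applied).
#' @param promoters Tibble with `transcript_id`, `chrom`, `strand`, `tss`.
#' @param span TSS-relative window `c(-L, R)` (no position 0).
#' @param library_size Total reads for normalization; default `nrow(x)` for
#'   read input.
#' @param per Normalization denominator (default 1e6).
#' @return Long tibble `promoter_id`, `offset`, `value`. Promoters outside
#'   the track extent get `NA` values.
#' @export
pileup <- function(x, promoters, span = c(-500, 500), library_size = NULL,
                   per = 1e6) {
  stopifnot(span[1] < 0, span[2] > 0)
  is_track <- all(c("pos", "value") %in% names(x))
  offs <- offset_seq(span[1], span[2])
  out <- vector("list", nrow(promoters))
  if (is_track) {
    track_split <- split(x[c("pos", "value")], x$chrom)
  } else {
    if (is.null(library_size)) library_size <- nrow(x)
    covs <- lapply(split(x[c("start", "end")], x$chrom), function(r) {
      IRanges::coverage(IRanges::IRanges(r$start, r$end))
    })
  }
  for (i in seq_len(nrow(promoters))) {
    tss <- promoters$tss[i]; strand <- promoters$strand[i]
    pos <- offset_to_pos(offs, tss, strand)
    if (is_track) {
      tr <- track_split[[promoters$chrom[i]]]
      val <- if (is.null(tr)) rep(NA_real_, length(pos)) else {
        v <- tr$value[match(pos, tr$pos)]
        if (all(is.na(v))) v else { v[is.na(v) & pos >= min(tr$pos) & pos <= max(tr$pos)] <- 0; v }
      }
    } else {
      cov <- covs[[promoters$chrom[i]]]
      if (is.null(cov)) {
        val <- rep(NA_real_, length(pos))
      } else {
        val <- numeric(length(pos))
        ok <- pos >= 1 & pos <= length(cov)
        val[ok] <- as.numeric(cov[pos[ok]])
        val <- val * per / library_size
      }
    }
    out[[i]] <- tibble(promoter_id = promoters$transcript_id[i],
      offset = offs, value = val)
  }
  dplyr::bind_rows(out)
}

#' Estimate the ChIP strand shift
#'
#' Finds the shift `s` (applied +s to the top strand and -s to the bottom
#' strand) maximizing the Pearson correlation between the two strands'
#' coverages over TSS windows; ties break toward the smallest shift. For
#' fragments of length L sequenced from both ends the recovered shift is
#' about L/2.
#'
#' @param top,bottom Numeric matrices (promoters x positions) of strand
#'   coverages over identical windows, or plain vectors for one window.
#' @param max_shift Largest shift tried, bp (default 150).
#' @return List with `shift`, `correlation`, and the full `profile` tibble.
#' @export
estimate_strand_shift <- function(top, bottom, max_shift = 150) {
  if (is.vector(top)) top <- matrix(top, nrow = 1)
  if (is.vector(bottom)) bottom <- matrix(bottom, nrow = 1)
  stopifnot(identical(dim(top), dim(bottom)))
  n <- ncol(top)
  if (2 * max_shift >= n - 2) abort("window too narrow for max_shift")
  if (sd(top) == 0 || sd(bottom) == 0) {
    abort("constant coverage on a strand: correlation undefined")
  }
  shifts <- 0:max_shift
  cors <- vapply(shifts, function(s) {
    a <- as.vector(top[, seq_len(n - 2 * s), drop = FALSE])
    b <- as.vector(bottom[, seq_len(n - 2 * s) + 2 * s, drop = FALSE])
    if (sd(a) == 0 || sd(b) == 0) return(-Inf)
    cor(a, b)
  }, numeric(1))
  best <- which.max(cors)  # first maximum = smallest shift on ties
  list(shift = shifts[best], correlation = cors[best],
    profile = tibble(shift = shifts, correlation = cors))
}

#' Region signal from a normalized pileup track
#'
#' Summarizes a promoter's pileup over a TSS-relative region either as RPKM
#' (for tracks normalized to reads per base per million, RPKM equals the
#' regional mean times 1000) or as the plain mean (occupancy-type regions).
#'
#' @param values,offsets Pileup values and their TSS-relative offsets.
#' @param region `c(from, to)` TSS-relative, inclusive, no position 0.
#' @param type `"rpkm"` or `"mean"`.
#' @param per The normalization denominator of the track (default 1e6).
#' @return Single numeric value (`NA` if the region is not covered).
#' @export
region_signal <- function(values, offsets, region, type = c("rpkm", "mean"),
                          per = 1e6) {
  type <- match.arg(type)
  want <- offset_seq(region[1], region[2])
  v <- values[match(want, offsets)]
  if (anyNA(v)) return(NA_real_)
  m <- mean(v)
  if (type == "mean") m else m * (per / 1e6) * 1000
}

#' RPKM from a read count
#'
#' `count * 1e9 / (region_length * library_size)`.
#'
#' @param count Reads overlapping the region.
#' @param region_length Region length in bp.
#' @param library_size Total mapped reads.
#' @return RPKM value.
#' @export
rpkm_from_counts <- function(count, region_length, library_size) {
  count * 1e9 / (region_length * library_size)
}

#' Standard TSS-relative quantification regions
#'
#' Mouse: pause +21..+100, gene body +301..+1300 (or +301..+500 for
#' transcripts shorter than 1300 bp; undefined below 500 bp), H3K4me3 TSS
#' +1..+200 and body +801..+1000, nucleosome occupancy -101..-1. Fly: pause
#' +1..+100, occupancy -100..-1, gene body +250..+650 relative to the +1
#' nucleosome.
#'
#' @param organism `"mouse"` or `"fly"`.
#' @param transcript_length Needed for the mouse gene-body short form.
#' @return Named list of `c(from, to)` regions (gene body may be `NA`).
#' @export
standard_regions <- function(organism = c("mouse", "fly"),
                             transcript_length = Inf) {
  organism <- match.arg(organism)
  if (organism == "mouse") {
    gb <- if (transcript_length >= 1300) c(301, 1300)
      else if (transcript_length >= 500) c(301, 500)
      else c(NA_real_, NA_real_)
    list(pause = c(21, 100), gene_body = gb, h3k4me3_tss = c(1, 200),
      h3k4me3_body = c(801, 1000), nuc_upstream = c(-101, -1))
  } else {
    list(pause = c(1, 100), nuc_upstream = c(-100, -1),
      gene_body_plus1 = c(250, 650))
  }
}

#' Pausing index
#'
#' Ratio of promoter-proximal to gene-body Pol II signal; `NA` when the
#' gene-body signal is zero or missing.
#'
#' @param pause_value,body_value Region signals.
#' @return PI values.
#' @export
pausing_index <- function(pause_value, body_value) {
  ifelse(is.na(body_value) | body_value == 0, NA_real_,
    pause_value / body_value)
}

#' Quantile normalization across samples
#'
#' Each column's sorted values are replaced by the mean of the columns'
#' sorted values; ties receive the mean of the values they would have taken.
#' Column distributions are identical afterwards and the operation is
#' idempotent and rank-preserving within columns.
#'
#' @param mat Numeric matrix (e.g. promoters x time points), >= 2 columns.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) abort("quantile normalization needs >= 2 columns")
  ref <- rowMeans(apply(mat, 2, sort))
  out <- apply(mat, 2, function(x) {
    ord <- order(x)
    grp <- cumsum(c(TRUE, diff(x[ord]) != 0))
    res <- numeric(length(x))
    res[ord] <- stats::ave(ref, grp)  # tied values share the mean reference
    res
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Trimmed average of promoter tracks
#'
#' Per position, the mean after excluding values beyond the `trim` and
#' `1 - trim` quantiles (outlier-robust metaprofile averaging; the top and
#' bottom 1% are dropped by default).
#'
#' @param tracks Matrix (promoters x positions) or long tibble with
#'   `promoter_id`, `offset`, `value`.
#' @param trim Fraction trimmed from each tail (default 0.01).
#' @return For matrix input a numeric vector per position; for tibble input
#'   a tibble `offset`, `value`, `n`.
#' @export
trimmed_group_average <- function(tracks, trim = 0.01) {
  long <- !is.matrix(tracks)
  if (long) {
    m <- tidyr::pivot_wider(tracks, id_cols = "promoter_id",
      names_from = "offset", values_from = "value")
    offs <- as.numeric(names(m)[-1])
    mat <- as.matrix(m[, -1])
  } else mat <- tracks
  if (nrow(mat) < 3 && trim > 0) {
    warn("fewer than 3 tracks: plain mean used")
    trim <- 0
  }
  avg <- apply(mat, 2, function(x) {
    if (trim <= 0) return(mean(x, na.rm = TRUE))
    q <- quantile(x, c(trim, 1 - trim), na.rm = TRUE, type = 7)
    mean(x[!is.na(x) & x >= q[1] & x <= q[2]])
  })
  if (!long) return(avg)
  tibble(offset = offs, value = unname(avg), n = nrow(mat))
}

#' Phase-binned population reordering of temporal region signals
#'
#' Bins promoters by their transcriptional phase into bins centered at the
#' sampling times (six 4-h bins, i.e. +/- 2 h, for 4-h sampling), circularly
#' rotates each promoter's series so index 0 is its bin's center, and
#' averages across promoters. A population rhythm p value comes from a
#' cosinor fit of the averaged, reordered series.
#'
#' @param values Matrix (promoters x time points) of region signals.
#' @param times Sampling times, evenly spaced over one period.
#' @param phases Per-promoter transcriptional phases in `[0, period)`;
#'   promoters with missing phase are excluded (and counted).
#' @param n_bins Number of phase bins (default: number of distinct times).
#' @param halfwidth Bin half width in hours (default 2); promoters farther
#'   than this from every bin center are excluded.
#' @param period Period in hours (default 24).
#' @return Object of class `phase_binned`: list with `profile` (tibble of
#'   reordered `time`, mean `value`, `n`), `fit` (a `harmonic_fit`),
#'   `bins` (per-promoter assignment), `n_excluded`.
#' @export
phase_bin_reorder <- function(values, times, phases, n_bins = NULL,
                              halfwidth = 2, period = 24) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(times), nrow(values) == length(phases))
  t24 <- times %% period
  centers <- sort(unique(t24))
  if (is.null(n_bins)) n_bins <- length(centers)
  if (n_bins != length(centers)) {
    abort("n_bins must match the number of distinct sampling times mod period")
  }
  # collapse replicate times (e.g. two sampled days) to one cycle
  collapse <- vapply(centers, function(ct) {
    rowMeans(values[, t24 == ct, drop = FALSE])
  }, numeric(nrow(values)))
  miss <- is.na(phases)
  d <- outer(phases[!miss], centers, circ_dist, period = period)
  bin <- apply(d, 1, which.min)
  in_reach <- d[cbind(seq_along(bin), bin)] <= halfwidth + 1e-9
  keep_idx <- which(!miss)[in_reach]
  bin <- bin[in_reach]
  n_excluded <- nrow(values) - length(keep_idx)
  k <- length(centers)
  rotated <- matrix(NA_real_, length(keep_idx), k)
  for (i in seq_along(keep_idx)) {
    sh <- bin[i] - 1L
    rotated[i, ] <- collapse[keep_idx[i], ((seq_len(k) - 1L + sh) %% k) + 1L]
  }
  avg <- colMeans(rotated)
  rel_times <- centers - centers[1]
  fit <- harmonic_fit(rel_times, avg, period = period)
  structure(
    list(
      profile = tibble(time = rel_times, value = avg, n = length(keep_idx)),
      fit = fit,
      bins = tibble(promoter = keep_idx, bin_center = centers[bin]),
      n_excluded = n_excluded
    ),
    class = "phase_binned"
  )
}

#' Signed circular phase difference
#'
#' Maps `a - b` into `(-period/2, period/2]` hours; the antiphase boundary
#' maps to `+period/2`.
#'
#' @param phase_a,phase_b Phases in `[0, period)`.
#' @param period Period (default 24).
#' @return Signed differences in hours.
#' @export
circular_phase_diff <- function(phase_a, phase_b, period = 24) {
  d <- (phase_a - phase_b) %% period
  ifelse(d > period / 2, d - period, d)
}

# Watson's U^2 statistic for two circular samples (phases in hours)
watson_u2 <- function(a, b, period = 24) {
  n <- length(a); m <- length(b); nn <- n + m
  pooled <- c(a, b) %% period
  ord <- order(pooled)
  is_a <- c(rep(TRUE, n), rep(FALSE, m))[ord]
  d <- cumsum(is_a) / n - cumsum(!is_a) / m
  (n * m / nn^2) * (sum(d^2) - sum(d)^2 / nn)
}

#' Watson's two-sample test for circular data (permutation null)
#'
#' Permutation p value for a difference between two circular phase
#' distributions using Watson's U^2 statistic; exact exchangeability-based
#' inference rather than asymptotic tables.
#'
#' @param phases_a,phases_b Phase samples (>= 5 each), hours in `[0, period)`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed for reproducibility.
#' @param period Period (default 24).
#' @return List with `statistic` (U^2), `p_value`, `n_perm`.
#' @export
circular_two_sample_test <- function(phases_a, phases_b, n_perm = 10000,
                                     seed = NULL, period = 24) {
  stopifnot(length(phases_a) >= 5, length(phases_b) >= 5)
  obs <- watson_u2(phases_a, phases_b, period)
  n <- length(phases_a)
  pooled <- c(phases_a, phases_b)
  perm <- run_with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), n)
      watson_u2(pooled[idx], pooled[-idx], period)
    }, numeric(1))
  })
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(statistic = obs, p_value = p, n_perm = n_perm)
}
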