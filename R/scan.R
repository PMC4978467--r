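#' Scan a promoter window for PCM matches
#'
#' Scores every candidate match start position inside a TSS-relative window
#' on the promoter sense strand and reports positions scoring at or above the
#' threshold. Window coordinates bound the match START position and follow
#' the no-position-0 convention (the TSS base is +1). Overlapping hits are
#' all retained; positions whose w-mer contains an ambiguous base are skipped.
#'
#' @param sequence Sense-strand promoter DNA (single string).
#' @param sm A [score_matrix()].
#' @param threshold Score threshold (e.g. from [balanced_threshold()]).
#' @param window Length-2 integer vector `c(a, b)`: allowed match-start
#'   offsets relative to the TSS.
#' @param seq_start TSS-relative offset of the first base of `sequence`
#'   (default -300).
#' @return Tibble with `start` (TSS-relative match start), `score`. Skipped
#'   ambiguous positions are counted in the `"n_skipped"` attribute.
#' @export
scan_window <- function(sequence, sm, threshold, window = c(-50, -10),
                        seq_start = -300) {
  stopifnot(inherits(sm, "score_matrix"), length(window) == 2,
    window[1] <= window[2], window[1] != 0, window[2] != 0)
  offsets <- offsets_from(seq_start, nchar(sequence))
  starts <- offset_seq(window[1], window[2])
  pos_of <- match(starts, offsets)
  if (anyNA(pos_of)) abort("sequence does not cover the scan window")
  w <- sm$width
  if (max(pos_of) + w - 1 > nchar(sequence)) {
    abort("sequence too short for matches starting at the window end")
  }
  code <- match(strsplit(toupper(sequence), "")[[1]], DNA_BASES)
  scores <- score_starts(code, sm$scores, pos_of)
  skipped <- is.na(scores)
  hit <- !skipped & scores >= threshold
  out <- tibble(start = starts[hit], score = scores[hit])
  attr(out, "n_skipped") <- sum(skipped)
  out
}

# total log-odds score of the w-mers starting at string indices `pos`;
# NA where the w-mer contains a non-ACGT base
score_starts <- function(code, scores, pos) {
  w <- ncol(scores)
  total <- numeric(length(pos))
  for (j in seq_len(w)) {
    b <- code[pos + j - 1]
    total <- total + scores[cbind(b, j)]
  }
  total
}

#' Scan many promoters with per-promoter GC-matched thresholds
#'
#' For each promoter the background model uses the promoter's own GC content
#' (rounded to `gc_digits` decimals; detectors are cached per rounded value),
#' the score distributions are computed exactly and the balanced FDR/FNR
#' threshold applied, mirroring per-promoter threshold calibration.
#'
#' @param sequences Named character vector of sense-strand promoter windows.
#' @param pcm 4 x w position count matrix.
#' @param window Match-start window, TSS-relative (default TATA: -50..-10).
#' @param seq_start TSS-relative offset of the first sequence base.
#' @param gc Either `NULL` (compute per promoter from its sequence) or a
#'   single value used for all promoters.
#' @param gc_digits Rounding used for the detector cache (default 2).
#' @param kappa Regularization scale.
#' @return Tibble with `promoter_id`, `start`, `score`, `gc`.
#' @export
scan_promoters <- function(sequences, pcm, window = c(-50, -10),
                           seq_start = -300, gc = NULL, gc_digits = 2,
                           kappa = 1) {
  stopifnot(!is.null(names(sequences)))
  gc_each <- if (is.null(gc)) {
    vapply(sequences, function(s) {
      f <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("G", "C"))
      max(min(sum(f) / nchar(s), 0.99), 0.01)
    }, numeric(1))
  } else rep(gc, length(sequences))
  gc_r <- round(gc_each, gc_digits)
  cache <- new.env(parent = emptyenv())
  res <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    key <- format(gc_r[i])
    det <- cache[[key]]
    if (is.null(det)) {
      det <- motif_detector(pcm, gc = gc_r[i], kappa = kappa)
      cache[[key]] <- det
    }
    hits <- scan_window(sequences[i], det$score_matrix, det$threshold,
      window = window, seq_start = seq_start)
    if (nrow(hits)) {
      hits$promoter_id <- names(sequences)[i]
      hits$gc <- gc_r[i]
      res[[i]] <- hits
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(start = integer(), score = numeric(),
      promoter_id = character(), gc = numeric())
  }
  dplyr::select(out, "promoter_id", "start", "score", "gc")
}

#' Conservation filter for motif hits
#'
#' Annotates each hit with the median per-base conservation score over its
#' footprint and keeps a promoter's motif flag iff the maximum of those
#' medians reaches `min_median`. Hits with missing scores fail the filter.
#'
#' @param hits Tibble from [scan_promoters()] (needs `promoter_id`, `start`).
#' @param conservation Tibble with `promoter_id`, `offset`, `score` giving
#'   per-base conservation at TSS-relative offsets.
#' @param width Motif width in bp (footprint length).
#' @param min_median Minimum median conservation (default 0.75).
#' @return List with `hits` (input plus `median_conservation`) and
#'   `promoters`: tibble of `promoter_id`, `best_median`, `retained`.
#' @export
conservation_filter <- function(hits, conservation, width,
                                min_median = 0.75) {
  hits <- as_tibble(hits)
  med <- numeric(nrow(hits))
  cons_split <- split(conservation[c("offset", "score")], conservation$promoter_id)
  for (i in seq_len(nrow(hits))) {
    cc <- cons_split[[hits$promoter_id[i]]]
    foot <- offsets_from(hits$start[i], width)
    sc <- if (is.null(cc)) rep(NA_real_, width) else cc$score[match(foot, cc$offset)]
    med[i] <- if (anyNA(sc)) NA_real_ else median(sc)
  }
  hits$median_conservation <- med
  prom <- dplyr::summarise(
    dplyr::group_by(hits, .data$promoter_id),
    best_median = if (all(is.na(.data$median_conservation))) NA_real_
      else max(.data$median_conservation, na.rm = TRUE),
    .groups = "drop"
  )
  prom$retained <- !is.na(prom$best_median) & prom$best_median >= min_median
  list(hits = hits, promoters = prom)
}

#' CpG observed/expected ratio of a TSS window
#'
#' Standard formula `CG * N / (G * C)` over the -100..+100 TSS window
#' (N = 200; there is no position 0). `CG` counts overlapping CG
#' dinucleotides. Returns 0 when the sequence has no C or no G.
#'
#' @param sequence DNA string(s) of length `n`.
#' @param n Required window width (default 200).
#' @return Numeric vector of CpG ratios.
#' @export
cpg_ratio <- function(sequence, n = 200) {
  if (any(nchar(sequence) != n)) {
    abort(sprintf("cpg_ratio expects sequences of length %d", n))
  }
  x <- Biostrings::DNAStringSet(toupper(sequence))
  cg <- Biostrings::vcountPattern("CG", x)
  freq <- Biostrings::letterFrequency(x, c("C", "G"))
  denom <- freq[, "C"] * freq[, "G"]
  out <- ifelse(denom == 0, 0, cg * n / denom)
  as.numeric(out)
}
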