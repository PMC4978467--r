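#' Read a position count matrix in JASPAR flat format
#'
#' Accepts the common JASPAR text layouts: a `>` header line followed by four
#' rows, either `A [ 1 2 3 ]` (bracketed) or plain whitespace-separated
#' counts in A, C, G, T order.
#'
#' @param path Path to the matrix file.
#' @return A 4 x w numeric count matrix with rownames A, C, G, T and the
#'   header name (if any) as the `"name"` attribute.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  name <- NULL
  if (startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 4) abort("JASPAR matrix needs 4 count rows")
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("\\[|\\]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  w <- unique(lengths(rows))
  if (length(w) != 1) abort("JASPAR rows have unequal widths")
  pcm <- do.call(rbind, rows)
  rownames(pcm) <- DNA_BASES
  validate_pcm(pcm)
  attr(pcm, "name") <- name
  pcm
}

validate_pcm <- function(pcm) {
  if (!is.matrix(pcm) || nrow(pcm) != 4) abort("a PCM is a 4 x w matrix")
  if (any(pcm < 0) || any(is.na(pcm))) abort("PCM counts must be non-negative")
  if (any(colSums(pcm) <= 0)) abort("every PCM column must have total count > 0")
  invisible(pcm)
}

#' Regularize a position count matrix
#'
#' Converts counts to probabilities with background pseudocounts scaled by
#' the square root of each column total: column `j`'s probability for base
#' `b` is `(count_bj + kappa * sqrt(N_j) * p_b) / (N_j + kappa * sqrt(N_j))`.
#' All probabilities are strictly positive.
#'
#' @param pcm 4 x w count matrix (rows A, C, G, T).
#' @param background Background probabilities, see [background_probs()].
#' @param kappa Pseudocount scale, > 0 (default 1).
#' @return 4 x w column-stochastic probability matrix.
#' @export
regularize_pcm <- function(pcm, background = background_probs(0.5), kappa = 1) {
  validate_pcm(pcm)
  stopifnot(kappa > 0, length(background) == 4, abs(sum(background) - 1) < 1e-9)
  n <- colSums(pcm)
  sweep(pcm + sqrt(n)[col(pcm)] * kappa * background, 2,
    n + kappa * sqrt(n), "/")
}

#' Log-odds score matrix for a PCM and background
#'
#' Scores are `log2(p_motif / p_background)` of the regularized motif
#' probabilities, the background having `p_C = p_G = gc/2`.
#'
#' @inheritParams regularize_pcm
#' @param gc Background GC content (default 0.5).
#' @return An object of class `score_matrix`: list with `scores` (4 x w),
#'   `motif_probs`, `background`, `width`.
#' @export
score_matrix <- function(pcm, gc = 0.5, kappa = 1) {
  bg <- background_probs(gc)
  probs <- regularize_pcm(pcm, bg, kappa)
  scores <- log2(probs / bg)
  structure(
    list(scores = scores, motif_probs = probs, background = bg,
      width = ncol(scores), gc = gc),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix: width", x$width, "gc", x$gc, "\n")
  print(round(x$scores, 3))
  invisible(x)
}

#' Exact distribution of PCM match scores
#'
#' Probability mass function of the total log-odds score of a random w-mer
#' under either the background model (i.i.d. background base probabilities at
#' every column) or the motif model (the regularized motif probabilities),
#' computed by column-wise convolution on a discrete score grid. Per-column
#' scores are rounded to the nearest grid point before convolution, so the
#' pmf is exact for the rounded scores and mass is conserved.
#'
#' @param sm A [score_matrix()].
#' @param model `"background"` or `"motif"`.
#' @param epsilon Grid resolution in score units; default spans the score
#'   range with 4096 points.
#' @return Object of class `score_distribution`: list with ascending `grid`,
#'   `pmf`, `epsilon`, `model`.
#' @export
exact_score_distribution <- function(sm, model = c("background", "motif"),
                                     epsilon = NULL) {
  stopifnot(inherits(sm, "score_matrix"))
  model <- match.arg(model)
  s <- sm$scores
  rng <- sum(apply(s, 2, max)) - sum(apply(s, 2, min))
  if (is.null(epsilon)) epsilon <- max(rng, 1e-6) / 4096
  stopifnot(epsilon > 0)
  if (rng > 0 && rng / epsilon < 1) abort("epsilon too coarse: score grid has < 2 points")

  k <- round(s / epsilon)  # integer grid index of every cell score
  emis <- switch(model,
    background = matrix(sm$background, 4, sm$width),
    motif = sm$motif_probs
  )
  lo <- sum(apply(k, 2, min)); hi <- sum(apply(k, 2, max))
  pmf <- numeric(hi - lo + 1)
  # DP over columns: pmf of partial sums, indexed from current partial min
  cur <- 1   # point mass at partial sum 0
  cur_lo <- 0
  for (j in seq_len(sm$width)) {
    kj <- k[, j]
    new_lo <- cur_lo + min(kj)
    new_hi <- cur_lo + length(cur) - 1 + max(kj)
    nxt <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      sh <- cur_lo + kj[b] - new_lo
      idx <- seq_along(cur) + sh
      nxt[idx] <- nxt[idx] + emis[b, j] * cur
    }
    cur <- nxt
    cur_lo <- new_lo
  }
  grid <- (seq.int(cur_lo, cur_lo + length(cur) - 1)) * epsilon
  structure(
    list(grid = grid, pmf = cur, epsilon = epsilon, model = model),
    class = "score_distribution"
  )
}

#' Balanced FDR/FNR score threshold
#'
#' Finds the grid threshold `t*` minimizing `|FPR(t) - FNR(t)|`, where
#' `FPR(t) = P_bg(score >= t)` and `FNR(t) = P_motif(score < t)`; ties break
#' toward the smallest threshold.
#'
#' @param bg_dist,motif_dist Background and motif [exact_score_distribution()]
#'   results on a common grid spacing.
#' @return List with `threshold`, `fpr`, `fnr`.
#' @export
balanced_threshold <- function(bg_dist, motif_dist) {
  stopifnot(inherits(bg_dist, "score_distribution"),
    inherits(motif_dist, "score_distribution"))
  if (abs(bg_dist$epsilon - motif_dist$epsilon) > 1e-12 * bg_dist$epsilon) {
    abort("distributions must share one grid spacing")
  }
  eps <- bg_dist$epsilon
  ib <- round(bg_dist$grid / eps)
  im <- round(motif_dist$grid / eps)
  lo <- min(ib[1], im[1]); hi <- max(ib[length(ib)], im[length(im)])
  pb <- pm <- numeric(hi - lo + 1)
  pb[ib - lo + 1] <- bg_dist$pmf
  pm[im - lo + 1] <- motif_dist$pmf
  # candidate thresholds: every grid point
  fpr <- rev(cumsum(rev(pb)))          # P_bg(score >= t)
  fnr <- c(0, cumsum(pm))[seq_along(pm)]  # P_motif(score < t)
  gap <- abs(fpr - fnr)
  i <- which.min(gap)  # which.min returns the first (smallest t) minimum
  list(threshold = (lo + i - 1) * eps, fpr = fpr[i], fnr = fnr[i])
}

#' Balanced-threshold hit calling setup for one PCM and GC content
#'
#' Convenience wrapper: regularize, build score matrix and both exact score
#' distributions, and return the balanced threshold alongside.
#'
#' @inheritParams score_matrix
#' @param epsilon Grid resolution passed to [exact_score_distribution()].
#' @return List with `score_matrix`, `background_dist`, `motif_dist`,
#'   `threshold`, `fpr`, `fnr`.
#' @export
motif_detector <- function(pcm, gc = 0.5, kappa = 1, epsilon = NULL) {
  sm <- score_matrix(pcm, gc = gc, kappa = kappa)
  bg <- exact_score_distribution(sm, "background", epsilon)
  mo <- exact_score_distribution(sm, "motif", bg$epsilon)
  bt <- balanced_threshold(bg, mo)
  list(score_matrix = sm, background_dist = bg, motif_dist = mo,
    threshold = bt$threshold, fpr = bt$fpr, fnr = bt$fnr)
}
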