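# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

#' Background base probabilities for a given GC content
#'
#' @param gc GC content in (0, 1); C and G each get `gc/2`, A and T `(1-gc)/2`.
#' @return Named numeric vector over A, C, G, T summing to 1.
#' @export
background_probs <- function(gc = 0.5) {
  stopifnot(is.numeric(gc), length(gc) == 1, gc > 0, gc < 1)
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

#' TSS-relative offset sequences without a zero position
#'
#' Offsets follow the convention that the TSS base is +1, the base upstream
#' of it is -1, and there is no position 0.
#'
#' @param from,to First and last offset (inclusive); neither may be 0.
#' @return Integer vector of offsets from `from` to `to`, skipping 0.
#' @export
offset_seq <- function(from, to) {
  stopifnot(from != 0, to != 0, from <= to)
  out <- seq.int(from, to)
  out[out != 0L]
}

# the `n` consecutive offsets starting at `start` (no position 0)
offsets_from <- function(start, n) {
  stopifnot(start != 0, n >= 1)
  cand <- seq.int(start, start + n + 1L)
  head(cand[cand != 0L], n)
}

# the `n` offsets ending at `end` (inclusive), counted in offset space
offsets_before <- function(end, n) {
  start <- end - n - 1L  # generous lower bound, trimmed below
  if (start == 0L) start <- -1L
  full <- offset_seq(start, end)
  tail(full, n)
}

# genomic position for a TSS-relative offset (no position 0)
offset_to_pos <- function(offset, tss, strand) {
  stopifnot(all(offset != 0))
  strand <- rep(strand, length.out = length(offset))
  ifelse(strand == "+",
    tss + offset - (offset > 0),
    tss - offset + (offset > 0)
  )
}

# TSS-relative offset for a genomic position
pos_to_offset <- function(pos, tss, strand) {
  strand <- rep(strand, length.out = length(pos))
  ifelse(strand == "+",
    ifelse(pos >= tss, pos - tss + 1L, pos - tss),
    ifelse(pos <= tss, tss - pos + 1L, tss - pos)
  )
}

# running mean/sd of the +/- flank neighbourhood of every position, with the
# centre value excluded; returns list(mean, sd) with NAs where the flank is
# incomplete. Used by the peak and stall detectors.
local_flank_stats <- function(x, flank) {
  n <- length(x)
  k <- 2L * flank + 1L
  if (n < k) abort("track shorter than the flank window")
  win_sum <- stats::filter(x, rep(1, k), sides = 2)
  win_sum2 <- stats::filter(x^2, rep(1, k), sides = 2)
  m <- (as.numeric(win_sum) - x) / (k - 1L)
  v <- (as.numeric(win_sum2) - x^2) / (k - 1L) - m^2
  v[v < 0] <- 0
  list(mean = m, sd = sqrt(v * (k - 1L) / (k - 2L)))
}

# centered moving average of odd width
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  out <- as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
  # shrink the window at the edges rather than returning NA
  n <- length(x)
  half <- (width - 1L) %/% 2L
  idx <- which(is.na(out))
  for (i in idx) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# circular distance between phases on [0, period)
circ_dist <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

run_with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (requireNamespace("withr", quietly = TRUE)) {
    withr::with_seed(seed, expr)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
    force(expr)
  }
}
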