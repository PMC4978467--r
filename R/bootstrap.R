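#' Expression-matched sampling weights
#'
#' Bins mean transcriptional activities into `n_bins` logarithmically
#' equispaced bins over the pooled range and assigns each pool member the
#' weight (reference count in its bin) / (pool count in its bin), normalized
#' to sum 1. A weighted resample of the pool then reproduces the reference's
#' binned activity distribution. Reference-occupied bins with an empty pool
#' get their mass moved to the nearest non-empty pool bin (with a warning).
#'
#' @param ref_activity Reference-group activities (> 0), e.g. SCP means.
#' @param pool_activity Pool-group activities (> 0), e.g. constitutive
#'   type I promoter means.
#' @param n_bins Number of log-scale bins (default 55).
#' @return Object of class `matching_weights`: list with `weights` (per pool
#'   member, sums to 1), `edges`, `ref_counts`, `pool_counts`.
#' @export
expression_matched_weights <- function(ref_activity, pool_activity,
                                       n_bins = 55) {
  stopifnot(all(ref_activity > 0), all(pool_activity > 0), n_bins >= 2)
  all_act <- c(ref_activity, pool_activity)
  edges <- exp(seq(log(min(all_act)), log(max(all_act)), length.out = n_bins + 1))
  edges[1] <- edges[1] * (1 - 1e-12)
  edges[n_bins + 1] <- edges[n_bins + 1] * (1 + 1e-12)
  bin_of <- function(x) pmin(pmax(findInterval(x, edges), 1L), n_bins)
  rb <- tabulate(bin_of(ref_activity), n_bins)
  pb <- tabulate(bin_of(pool_activity), n_bins)
  ref_mass <- rb / sum(rb)
  orphan <- which(ref_mass > 0 & pb == 0)
  if (length(orphan)) {
    warn(sprintf(
      "%d reference-occupied bin(s) have no pool members; mass moved to nearest non-empty bin",
      length(orphan)))
    filled <- which(pb > 0)
    for (o in orphan) {
      tgt <- filled[which.min(abs(filled - o))]
      ref_mass[tgt] <- ref_mass[tgt] + ref_mass[o]
      ref_mass[o] <- 0
    }
  }
  pool_bins <- bin_of(pool_activity)
  w <- ifelse(pb[pool_bins] > 0, ref_mass[pool_bins] / pb[pool_bins], 0)
  w <- w / sum(w)
  structure(
    list(weights = w, edges = edges, ref_counts = rb, pool_counts = pb),
    class = "matching_weights"
  )
}

#' Wilcoxon rank-sum statistic
#'
#' Sum of the mid-ranks of `x` in the pooled ranking of `x` and `y`.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return The statistic W.
#' @export
rank_sum_statistic <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  sum(rank(c(x, y), ties.method = "average")[seq_along(x)])
}

#' Expression-matched bootstrap test for a promoter property
#'
#' Decides whether a property differs between a reference group (SCPs) and a
#' weighted pool (expression-matched constitutive type I promoters) beyond
#' what transcriptional activity explains. Stage 1 builds an empirical null
#' of the rank-sum statistic by pooling both groups' properties together
#' with their sampling probabilities (uniform for the reference, matching
#' weights for the pool, groups weighted by size) and repeatedly drawing two
#' samples of the original sizes with replacement. Stage 2 resamples each
#' group from its own population (reference uniform, pool weighted),
#' computing the rank-sum statistic and a median location difference each
#' time; each statistic is converted to a two-sided p value against the
#' stage-1 null (add-one smoothing, `2*min(tails)` capped at 1). The median
#' p value over the outer repeats is reported.
#'
#' @param prop_ref Property values of the reference group.
#' @param prop_pool Property values of the pool group.
#' @param weights [expression_matched_weights()] for the pool (or a plain
#'   probability vector over pool members).
#' @param n_null Stage-1 null draws (default 1e6; scale down for tests).
#' @param n_outer Stage-2 repeats (default 1000).
#' @param seed Optional seed; fixed seed gives bit-identical results.
#' @return Object of class `matched_bootstrap`: list with `median_p`,
#'   `median_location_difference`, `p_distribution`, `n_null`, `n_outer`.
#' @export
matched_bootstrap_test <- function(prop_ref, prop_pool, weights,
                                   n_null = 1e6, n_outer = 1000,
                                   seed = NULL) {
  w <- if (inherits(weights, "matching_weights")) weights$weights else weights
  stopifnot(length(w) == length(prop_pool))
  n1 <- length(prop_ref); n2 <- length(prop_pool)
  if (length(unique(c(prop_ref, prop_pool))) == 1L) {
    warn("degenerate property: all values equal")
    return(structure(
      list(median_p = 1, median_location_difference = 0,
        p_distribution = rep(1, n_outer), n_null = n_null, n_outer = n_outer),
      class = "matched_bootstrap"
    ))
  }
  pooled_vals <- c(prop_ref, prop_pool)
  pooled_probs <- c(rep(1 / n1, n1) * n1, w * n2)
  pooled_probs <- pooled_probs / sum(pooled_probs)

  run_with_seed(seed, {
    null_w <- numeric(n_null)
    chunk <- max(1L, floor(5e6 / (n1 + n2)))
    done <- 0L
    while (done < n_null) {
      k <- min(chunk, n_null - done)
      draws <- matrix(
        sample(pooled_vals, (n1 + n2) * k, replace = TRUE, prob = pooled_probs),
        nrow = n1 + n2)
      null_w[done + seq_len(k)] <- apply(draws, 2, function(v) {
        sum(rank(v, ties.method = "average")[seq_len(n1)])
      })
      done <- done + k
    }
    w_obs <- numeric(n_outer)
    locdiff <- numeric(n_outer)
    for (i in seq_len(n_outer)) {
      xs <- sample(prop_ref, n1, replace = TRUE)
      ys <- sample(prop_pool, n2, replace = TRUE, prob = w)
      w_obs[i] <- rank_sum_statistic(xs, ys)
      locdiff[i] <- median(xs) - median(ys)
    }
    sorted_null <- sort(null_w)
    cnt_le <- findInterval(w_obs, sorted_null)
    cnt_lt <- findInterval(w_obs, sorted_null, left.open = TRUE)
    p_lo <- (1 + cnt_le) / (1 + n_null)
    p_hi <- (1 + (n_null - cnt_lt)) / (1 + n_null)
    pvals <- pmin(1, 2 * pmin(p_lo, p_hi))
    structure(
      list(median_p = median(pvals),
        median_location_difference = median(locdiff),
        p_distribution = pvals, n_null = n_null, n_outer = n_outer,
        null_mean = mean(null_w)),
      class = "matched_bootstrap"
    )
  })
}

#' @export
print.matched_bootstrap <- function(x, ...) {
  cat(sprintf(
    "matched_bootstrap: median p %.4g, median location difference %.4g (n_null %g, n_outer %g)\n",
    x$median_p, x$median_location_difference, x$n_null, x$n_outer))
  invisible(x)
}
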