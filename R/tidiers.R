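# broom-style tidiers and ggplot2 autoplot methods for the fitted objects

#' @describeIn harmonic_fit tidy coefficients (mean, amplitude, phase).
#' @param x A `harmonic_fit` object.
#' @param ... Unused.
#' @method tidy harmonic_fit
#' @export
tidy.harmonic_fit <- function(x, ...) {
  tibble(
    term = c("mean", "amplitude", "relamp", "phase"),
    estimate = c(x$mean, x$amplitude, x$relamp, x$phase)
  )
}

#' @describeIn harmonic_fit one-row model summary.
#' @method glance harmonic_fit
#' @export
glance.harmonic_fit <- function(x, ...) {
  tibble(mean = x$mean, amplitude = x$amplitude, relamp = x$relamp,
    phase = x$phase, p.value = x$pvalue, nobs = x$n, period = x$period)
}

#' @describeIn harmonic_fit data and fitted cosinor curve.
#' @param object A `harmonic_fit` object.
#' @method autoplot harmonic_fit
#' @export
autoplot.harmonic_fit <- function(object, ...) {
  w <- 2 * pi / object$period
  grid <- seq(min(object$times), max(object$times), length.out = 200)
  curve <- object$mean +
    object$amplitude * cos(w * (grid - object$phase))
  ggplot2::ggplot() +
    ggplot2::geom_point(ggplot2::aes(x = object$times, y = object$values)) +
    ggplot2::geom_line(ggplot2::aes(x = grid, y = curve), colour = "#2166ac") +
    ggplot2::labs(x = "time (ZT h)", y = "signal",
      subtitle = sprintf("relamp %.2f, phase %.1f h, p = %.3g",
        object$relamp, object$phase, object$pvalue))
}

#' @describeIn solve_periodic long table of observables over one period.
#' @param x A `periodic_solution`.
#' @param ... Unused.
#' @method tidy periodic_solution
#' @export
tidy.periodic_solution <- function(x, ...) {
  tibble(
    time = rep(x$time, 5),
    observable = rep(c("x1", "x2", "activity", "gene_body", "pausing_index"),
      each = length(x$time)),
    value = c(x$x1, x$x2, x$activity, x$gene_body, x$pausing_index)
  )
}

#' @describeIn solve_periodic per-observable harmonic summaries plus
#'   propagation (when a modulation is active).
#' @method glance periodic_solution
#' @export
glance.periodic_solution <- function(x, ...) {
  out <- tidyr::pivot_wider(x$summaries, names_from = "observable",
    values_from = c("mean", "relamp", "phase"))
  eps <- max(x$params$eps_rec, x$params$eps_rel)
  out$propagation <- if (eps > 0) out$relamp_activity / eps else NA_real_
  out
}

#' @describeIn solve_periodic occupancies and activity over one period.
#' @param object A `periodic_solution`.
#' @method autoplot periodic_solution
#' @export
autoplot.periodic_solution <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$observable %in% c("x2", "activity", "pausing_index"), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (h)", y = NULL)
}

#' @describeIn exact_score_distribution pmf as a tibble.
#' @param x A `score_distribution`.
#' @param ... Unused.
#' @method tidy score_distribution
#' @export
tidy.score_distribution <- function(x, ...) {
  tibble(score = x$grid, probability = x$pmf, model = x$model)
}

#' Plot background and motif score distributions with the balanced threshold
#'
#' @param detector A [motif_detector()] result.
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(detector) {
  d <- dplyr::bind_rows(tidy(detector$background_dist),
    tidy(detector$motif_dist))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$probability,
      colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = detector$threshold, linetype = 2) +
    ggplot2::labs(x = "log-odds score (bits)", y = "probability",
      subtitle = sprintf("balanced threshold %.2f (FPR %.3g, FNR %.3g)",
        detector$threshold, detector$fpr, detector$fnr))
}

#' @describeIn matched_bootstrap_test outer-stage p values.
#' @param x A `matched_bootstrap`.
#' @param ... Unused.
#' @method tidy matched_bootstrap
#' @export
tidy.matched_bootstrap <- function(x, ...) {
  tibble(repeat_index = seq_along(x$p_distribution),
    p_value = x$p_distribution)
}

#' @describeIn matched_bootstrap_test one-row summary.
#' @method glance matched_bootstrap
#' @export
glance.matched_bootstrap <- function(x, ...) {
  tibble(median_p = x$median_p,
    median_location_difference = x$median_location_difference,
    n_null = x$n_null, n_outer = x$n_outer)
}

#' Plot a promoter-group metaprofile
#'
#' @param profile Tibble with `offset`, `value` (e.g. from
#'   [trimmed_group_average()]); an optional `group` column is mapped to
#'   colour.
#' @return A ggplot object.
#' @export
plot_metaprofile <- function(profile) {
  p <- ggplot2::ggplot(profile,
    ggplot2::aes(x = .data$offset, y = .data$value))
  if ("group" %in% names(profile)) {
    p <- p + ggplot2::aes(colour = .data$group)
  }
  p + ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "distance from TSS (bp)", y = "normalized signal")
}

#' @describeIn phase_bin_reorder reordered population profile.
#' @param object A `phase_binned` object.
#' @param ... Unused.
#' @method autoplot phase_binned
#' @export
autoplot.phase_binned <- function(object, ...) {
  ggplot2::ggplot(object$profile,
    ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time after bin phase (h)", y = "mean signal",
      subtitle = sprintf("population rhythm p = %.3g", object$fit$pvalue))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
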