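#' Parameters of the three-state Pol II promoter model
#'
#' The promoter cycles through free (x0), recruited (x1), and paused (x2)
#' states with a single saturable pause site (x0 + x1 + x2 = 1):
#' recruitment at rate `k_rec(t) = k_rec0 * (1 + eps_rec * cos(w(t -
#' phi_rec)))`, initiation (recruited to paused, includes the closed-to-open
#' transition) at constant `k_init`, and pause release into productive
#' elongation at `k_rel(t)` modulated analogously. Transcriptional activity
#' is `f(t) = k_rel(t) * x2(t)`; the quasi-static gene-body observable is
#' `g = f / v` with elongation speed `v`; the pausing index is `PI = x2 / g`.
#' The saturation of the shared pause site is what makes the mean rates
#' matter for rhythm propagation.
#'
#' @param k_rec0 Mean Pol II recruitment rate, per hour (> 0).
#' @param k_init Initiation rate, per hour (> 0, constant).
#' @param k_rel0 Mean pause-release rate, per hour (> 0).
#' @param eps_rec,eps_rel Relative modulation amplitudes in `[0, 1)`.
#' @param phi_rec,phi_rel Modulation peak phases, ZT hours.
#' @param v Elongation speed (bp/h equivalent; scales `g` only).
#' @param period Forcing period in hours (default 24).
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_rec0, k_init, k_rel0, eps_rec = 0, phi_rec = 0,
                           eps_rel = 0, phi_rel = 0, v = 1, period = 24) {
  stopifnot(k_rec0 > 0, k_init > 0, k_rel0 > 0, v > 0,
    eps_rec >= 0, eps_rec < 1, eps_rel >= 0, eps_rel < 1)
  structure(
    list(k_rec0 = k_rec0, k_init = k_init, k_rel0 = k_rel0,
      eps_rec = eps_rec, phi_rec = phi_rec, eps_rel = eps_rel,
      phi_rel = phi_rel, v = v, period = period),
    class = "kinetic_params"
  )
}

# steady state at the mean rates: flux balance k_rec x0 = k_init x1 = k_rel x2
steady_state <- function(p) {
  f0 <- 1 / (1 / p$k_rec0 + 1 / p$k_init + 1 / p$k_rel0)
  c(x0 = f0 / p$k_rec0, x1 = f0 / p$k_init, x2 = f0 / p$k_rel0, f = f0)
}

# first-harmonic summaries of a periodic series on a uniform grid
fourier_summary <- function(y, t, period) {
  w <- 2 * pi / period
  m <- mean(y)
  a <- 2 * mean(y * cos(w * t))
  b <- 2 * mean(y * sin(w * t))
  ph <- (atan2(b, a) / w) %% period
  if (period - ph < 1e-9) ph <- 0
  tibble(mean = m, relamp = if (m > 0) sqrt(a^2 + b^2) / m else NA_real_,
    phase = ph)
}

#' Periodic solution of the promoter kinetic model
#'
#' `method = "numeric"` integrates the linear time-periodic system with a
#' fixed-step RK4 monodromy solve (the unique periodic orbit is obtained
#' exactly from the affine period map, then recorded over one period);
#' `method = "first_harmonic"` returns the analytic perturbation solution to
#' first order in the modulation amplitudes (valid for small eps).
#'
#' @param params A [kinetic_params()] object.
#' @param method `"numeric"` or `"first_harmonic"`.
#' @param tol Periodicity tolerance in sup norm (default 1e-10).
#' @param n_grid Minimum number of grid points per period (default 4096).
#' @return Object of class `periodic_solution`: list with `time`, `x0`,
#'   `x1`, `x2`, `activity` (f), `gene_body` (g), `pausing_index`, a
#'   `summaries` tibble (observable, mean, relamp, phase), `params`,
#'   `method`, `residual`.
#' @export
solve_periodic <- function(params, method = c("numeric", "first_harmonic"),
                           tol = 1e-10, n_grid = 4096) {
  stopifnot(inherits(params, "kinetic_params"))
  method <- match.arg(method)
  p <- params
  w <- 2 * pi / p$period
  if (method == "numeric") {
    kmax <- max(p$k_rec0 * (1 + p$eps_rec), p$k_init, p$k_rel0 * (1 + p$eps_rel))
    n <- max(n_grid, ceiling(p$period * kmax * 20))
    res <- .kinetics_periodic_cpp(p$k_rec0, p$eps_rec, p$phi_rec, p$k_init,
      p$k_rel0, p$eps_rel, p$phi_rel, p$period, as.integer(n))
    if (res$residual > tol) {
      abort(sprintf(
        "periodic orbit residual %.3g exceeds tol %.3g (n_steps = %d)",
        res$residual, tol, n))
    }
    t <- res$time; x1 <- res$x1; x2 <- res$x2
  } else {
    ss <- steady_state(p)
    # linearization around the steady state; e^{iwt} response
    J <- matrix(c(-(p$k_rec0 + p$k_init), -p$k_rec0, p$k_init, -p$k_rel0),
      2, 2, byrow = TRUE)
    b <- c(
      ss["x0"] * p$k_rec0 * p$eps_rec * exp(-1i * w * p$phi_rec),
      -ss["x2"] * p$k_rel0 * p$eps_rel * exp(-1i * w * p$phi_rel)
    )
    A <- solve(diag(2) * 1i * w - J, b)
    t <- seq(0, p$period, length.out = n_grid + 1)[seq_len(n_grid)]
    e <- exp(1i * w * t)
    x1 <- as.numeric(ss["x1"] + Re(A[1] * e))
    x2 <- as.numeric(ss["x2"] + Re(A[2] * e))
    res <- list(residual = 0)
  }
  krel <- p$k_rel0 * (1 + p$eps_rel * cos(w * (t - p$phi_rel)))
  x0 <- 1 - x1 - x2
  f <- krel * x2
  g <- f / p$v
  pi_t <- ifelse(g > 0, x2 / g, NA_real_)
  obs <- list(x1 = x1, x2 = x2, activity = f, gene_body = g,
    pausing_index = pi_t)
  summaries <- dplyr::bind_rows(lapply(obs, fourier_summary, t = t,
    period = p$period), .id = "observable")
  structure(
    list(time = t, x0 = x0, x1 = x1, x2 = x2, activity = f, gene_body = g,
      pausing_index = pi_t, summaries = summaries, params = p,
      method = method, residual = res$residual),
    class = "periodic_solution"
  )
}

#' @export
print.periodic_solution <- function(x, ...) {
  cat(sprintf("periodic_solution (%s), period %g h\n", x$method,
    x$params$period))
  print(as.data.frame(x$summaries), digits = 4)
  invisible(x)
}

#' Rhythm propagation summary
#'
#' Propagation is the relative amplitude of transcriptional activity divided
#' by the largest rate-modulation amplitude; the phase differences are the
#' circular offsets of paused Pol II (x2) versus gene-body signal and versus
#' the pausing index.
#'
#' @param params A [kinetic_params()] with at least one positive modulation.
#' @param solution Optional pre-computed numeric [solve_periodic()] result.
#' @return Tibble with `propagation`, `delta_zt_gb`, `delta_zt_pi`, plus the
#'   component means/relamps/phases.
#' @export
propagation_factor <- function(params, solution = NULL) {
  eps <- max(params$eps_rec, params$eps_rel)
  if (eps <= 0) abort("propagation requires at least one eps > 0")
  sol <- solution %||% solve_periodic(params, "numeric")
  s <- sol$summaries
  get <- function(ob, col) s[[col]][s$observable == ob]
  tibble(
    propagation = get("activity", "relamp") / eps,
    delta_zt_gb = circular_phase_diff(get("x2", "phase"),
      get("gene_body", "phase"), params$period),
    delta_zt_pi = circular_phase_diff(get("x2", "phase"),
      get("pausing_index", "phase"), params$period),
    mean_x2 = get("x2", "mean"),
    mean_pi = get("pausing_index", "mean"),
    relamp_x2 = get("x2", "relamp"),
    relamp_activity = get("activity", "relamp"),
    relamp_pi = get("pausing_index", "relamp")
  )
}

#' Phase signature and regime call of a rhythmic promoter model
#'
#' Computes the paused-vs-gene-body and paused-vs-PI phase differences and
#' calls the regulatory regime: `combined_like` when paused and gene-body
#' Pol II share a phase (|dZT_gb| < 2 h) while paused Pol II and PI are in
#' antiphase (|dZT_PI| > 10 h) - the signature only combined recruitment and
#' release regulation produces; `release_like` when paused and gene-body
#' signals trade off (|dZT_gb| >= 6 h); otherwise `recruitment_like`.
#' Observables with relative amplitude below `min_relamp` give missing phase
#' differences.
#'
#' @param params A [kinetic_params()].
#' @param min_relamp Minimum relative amplitude for a phase to be considered
#'   resolved (default 1e-6).
#' @return Tibble with `delta_zt_gb`, `delta_zt_pi`, `regime_call`.
#' @export
phase_signature <- function(params, min_relamp = 1e-6) {
  sol <- solve_periodic(params, "numeric")
  s <- sol$summaries
  get <- function(ob, col) s[[col]][s$observable == ob]
  if (get("x2", "relamp") < min_relamp || get("gene_body", "relamp") < min_relamp) {
    return(tibble(delta_zt_gb = NA_real_, delta_zt_pi = NA_real_,
      regime_call = NA_character_))
  }
  dgb <- circular_phase_diff(get("x2", "phase"), get("gene_body", "phase"),
    params$period)
  dpi <- if (get("pausing_index", "relamp") >= min_relamp) {
    circular_phase_diff(get("x2", "phase"), get("pausing_index", "phase"),
      params$period)
  } else NA_real_
  regime <- if (!is.na(dpi) && abs(dgb) < 2 && abs(dpi) > 10) {
    "combined_like"
  } else if (abs(dgb) >= 6) {
    "release_like"
  } else {
    "recruitment_like"
  }
  tibble(delta_zt_gb = dgb, delta_zt_pi = dpi, regime_call = regime)
}
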