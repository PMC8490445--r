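# Robbins-Monro stochastic approximation for pairwise threshold root-finding.
#
# For an option pair (d1, d2) and input j, the regression function is the
# conditional expectation g(x) = E[(f_{d1} - f_{d2})(theta) | theta_j = x],
# observed only through the unbiased M-sample Monte Carlo estimate of
# pairwise_diff_estimate().  Iteration happens entirely in the variable's
# transform space (log / logit where applicable), including initialisation
# and step sizes.

#' Step-size schedule for stochastic approximation
#'
#' The schedule is `alpha_t = scale * t^(-exponent)`.  The classical
#' Robbins-Monro conditions (step sizes sum to infinity, squared step sizes
#' summable) require `exponent` in (1/2, 1]; `exponent <= 1/2` (including the
#' default 1/2 used throughout this package) is admissible only together with
#' Polyak-Ruppert averaging, which tolerates more slowly decaying steps.
#'
#' @param scale Positive scale `a` of the schedule.
#' @param exponent Decay exponent `gamma` in (0, 1].
#' @return An object of class `step_schedule`.
#' @export
step_schedule <- function(scale, exponent = 0.5) {
  stopifnot(scale > 0, exponent > 0, exponent <= 1)
  structure(list(scale = scale, exponent = exponent), class = "step_schedule")
}

#' Configuration of one stochastic-approximation run
#'
#' @param n_iter Number of iterations `T` (default 10^4).
#' @param m_inner Conditional samples per iteration `M` (default 1: a single
#'   rough but unbiased estimate of the regression function per step).
#' @param schedule A [step_schedule()], or `NULL` for the default
#'   `alpha_t = step_multiplier * 3 * sigma_j / (2e4 * sqrt(t))`, with
#'   `sigma_j` the transform-space marginal standard deviation of the
#'   iterated variable.
#' @param sign Direction of the regression function through the root:
#'   `+1` when the conditional expectation is negative below and positive
#'   above the root (the standard recursion `theta - alpha * g`), `-1` for
#'   the sign-flipped recursion, or `"auto"` to probe it with
#'   [determine_sign()].
#' @param averaging Report the Polyak-Ruppert running mean of the iterates
#'   (default `TRUE`) instead of the nominal last iterate.
#' @param step_multiplier Constant factor applied to the default schedule's
#'   scale; roots far outside the marginal's bulk may need an enlarged step
#'   to be reached within `n_iter` iterations (e.g. 10 for the built-in
#'   model's treatment-cost input `C_T_d3`).
#' @param init Initial iterate in transform space, or `NULL` to draw it from
#'   the marginal distribution of the variable.
#' @return An object of class `sa_config`.
#' @export
sa_config <- function(n_iter = 1e4, m_inner = 1, schedule = NULL,
                      sign = "auto", averaging = TRUE, step_multiplier = 1,
                      init = NULL) {
  stopifnot(n_iter >= 1, m_inner >= 1, step_multiplier > 0)
  if (!identical(sign, "auto")) {
    sign <- as.numeric(sign)
    stopifnot(sign %in% c(-1, 1))
  }
  if (!is.null(schedule)) stopifnot(inherits(schedule, "step_schedule"))
  structure(list(n_iter = as.integer(n_iter), m_inner = as.integer(m_inner),
                 schedule = schedule, sign = sign,
                 averaging = isTRUE(averaging),
                 step_multiplier = step_multiplier, init = init),
            class = "sa_config")
}

#' Unbiased Monte Carlo estimate of the pairwise conditional difference
#'
#' Estimates `E[(f_{d1} - f_{d2})(theta) | theta_j]` by averaging the utility
#' difference over `m` conditional samples drawn with [sample_conditional()]
#' semantics (both options evaluated on the same samples).  Unbiased for
#' every `m >= 1`.
#'
#' @inheritParams sample_prior
#' @param j Variable name or index.
#' @param d1,d2 Two distinct option identifiers; the estimate targets
#'   `f_{d1} - f_{d2}`.
#' @param theta_j Conditioning value in the variable's *transform* space.
#' @param m Number of conditional samples (default 1).
#' @return Length-one numeric estimate.
#' @export
pairwise_diff_estimate <- function(model, j, d1, d2, theta_j, m = 1,
                                   seed = NULL) {
  stopifnot(inherits(model, "decision_model"), m >= 1)
  if (identical(d1, d2)) stop("d1 and d2 must differ", call. = FALSE)
  j <- var_index(model, j)
  spec <- model$variables[[j]]
  nat <- clamp_support(spec, inv_transform_fun(spec$transform)(theta_j))
  smp <- conditional_sampler(model, j)
  with_seed(seed, {
    th <- smp(rep(nat, m))
    mean(model$utility(d1, th, model$constants) -
           model$utility(d2, th, model$constants))
  })
}

#' One Robbins-Monro update
#'
#' Returns `theta_t - sign * alpha_t * g_hat`: the standard root-finding
#' recursion for `sign = +1` (regression function increasing through the
#' root) and the sign-flipped recursion for `sign = -1`.
#'
#' @param theta_t Current iterate.
#' @param alpha_t Positive step size.
#' @param g_hat Noisy estimate of the regression function at `theta_t`.
#' @param sign `+1` or `-1`.
#' @return Updated iterate.
#' @examples
#' robbins_monro_step(1.0, 0.5, 0.4, +1)  # 0.8
#' @export
robbins_monro_step <- function(theta_t, alpha_t, g_hat, sign = 1) {
  stopifnot(all(alpha_t > 0), all(sign %in% c(-1, 1)))
  theta_t - sign * alpha_t * g_hat
}

# Keep natural-space values strictly inside the family support so that an
# overshooting iterate can still be conditioned on.
clamp_support <- function(spec, x) {
  switch(spec$family,
         lognormal = pmax(x, 1e-300),
         logitnormal = , beta = pmin(pmax(x, 1e-300), 1 - 1e-16),
         x)
}

resolve_schedule <- function(config, spec) {
  if (!is.null(config$schedule)) return(config$schedule)
  sigma_j <- transformed_moments(spec)[["sd"]]
  step_schedule(config$step_multiplier * 3 * sigma_j / 2e4, 0.5)
}

# Vectorised SA engine: advances `n_chains` independent runs in lockstep.
# Returns the raw iterate matrix (n_iter x n_chains; row t = theta^t) plus
# per-chain divergence flags.  Chains whose update overflows are frozen at
# their last finite value and flagged, never raised as errors.
sa_chains <- function(model, j, d1, d2, config, n_chains, sign) {
  j <- var_index(model, j)
  spec <- model$variables[[j]]
  sched <- resolve_schedule(config, spec)
  if (sched$exponent <= 0.5 && !config$averaging)
    warning("step exponent <= 1/2 violates the summable-squares condition; ",
            "enable Polyak-Ruppert averaging", call. = FALSE)
  inv <- inv_transform_fun(spec$transform)
  tf <- transform_fun(spec$transform)
  smp <- conditional_sampler(model, j)
  u <- model$utility; cst <- model$constants
  theta <- if (is.null(config$init)) tf(draw_marginal(spec, n_chains))
           else rep_len(as.numeric(config$init), n_chains)
  n_iter <- config$n_iter; m_inner <- config$m_inner
  raw <- matrix(NA_real_, n_iter, n_chains)
  alive <- rep(TRUE, n_chains)
  raw[1, ] <- theta
  if (n_iter > 1) for (t in seq_len(n_iter - 1)) {
    alpha <- sched$scale * t^(-sched$exponent)
    nat <- clamp_support(spec, inv(theta))
    g <- 0
    for (m in seq_len(m_inner)) {
      th <- smp(nat)
      g <- g + (u(d1, th, cst) - u(d2, th, cst))
    }
    g <- g / m_inner
    prop <- theta - sign * alpha * g
    bad <- alive & !is.finite(prop)
    if (any(bad)) alive[bad] <- FALSE
    keep <- !alive | !is.finite(prop)
    prop[keep] <- theta[keep]
    theta <- prop
    raw[t + 1L, ] <- theta
  }
  list(raw = raw, diverged = !alive, schedule = sched)
}

new_sa_trace <- function(raw, diverged, model, j, d1, d2, config, sign,
                         schedule, seed) {
  j <- var_index(model, j)
  spec <- model$variables[[j]]
  tm <- transformed_moments(spec)
  averaged <- cumsum(raw) / seq_along(raw)
  structure(list(
    raw = as.numeric(raw), averaged = averaged,
    final = if (config$averaging) averaged[length(averaged)]
            else raw[length(raw)],
    diverged = isTRUE(diverged),
    variable = spec$name, transform = spec$transform,
    marginal_mean = unname(tm["mean"]), marginal_sd = unname(tm["sd"]),
    pair = c(d1, d2), sign = sign, config = config, schedule = schedule,
    seed = seed), class = "sa_trace")
}

#' Run one stochastic-approximation search for a pairwise root
#'
#' Iterates the Robbins-Monro recursion for the conditional expectation of
#' `f_{d1} - f_{d2}` given variable `j`, entirely in the variable's transform
#' space, recording raw iterates and their Polyak-Ruppert running mean.
#' Numerical overflow of the iterates flags the trace as diverged instead of
#' raising an error (divergence is the expected behaviour when the pairwise
#' root set is empty).
#'
#' @inheritParams pairwise_diff_estimate
#' @param config An [sa_config()].
#' @return An object of class `sa_trace` with elements `raw`, `averaged`
#'   (exact running mean of `raw`), `final`, `diverged`, `seed` and the
#'   resolved configuration.  [tidy()] returns the iterate history,
#'   [glance()] the one-row summary.
#' @export
run_sa <- function(model, j, d1, d2, config = sa_config(), seed = NULL) {
  stopifnot(inherits(model, "decision_model"), inherits(config, "sa_config"))
  if (identical(d1, d2)) stop("d1 and d2 must differ", call. = FALSE)
  with_seed(seed, {
    sign <- if (identical(config$sign, "auto"))
      sign_probe(model, j, d1, d2)$sign else config$sign
    ch <- sa_chains(model, j, d1, d2, config, 1L, sign)
    new_sa_trace(ch$raw[, 1], ch$diverged[1], model, j, d1, d2, config, sign,
                 ch$schedule, seed)
  })
}

#' @method print sa_trace
#' @export
print.sa_trace <- function(x, ...) {
  cat(sprintf(
    "<sa_trace> %s, pair (%s, %s): %d iterations, final %s = %.6g%s\n",
    x$variable, x$pair[1], x$pair[2], length(x$raw),
    if (x$config$averaging) "Polyak-Ruppert average" else "iterate",
    x$final, if (x$diverged) "  [DIVERGED]" else ""))
  invisible(x)
}

#' @describeIn run_sa Iterate history as a tibble with columns `t`, `raw`,
#'   `averaged`.
#' @param x An `sa_trace`.
#' @param ... Unused.
#' @method tidy sa_trace
#' @export
tidy.sa_trace <- function(x, ...) {
  tibble::tibble(t = seq_along(x$raw), raw = x$raw, averaged = x$averaged)
}

#' @describeIn run_sa One-row summary (final estimate, divergence flag,
#'   iteration count, seed).
#' @method glance sa_trace
#' @export
glance.sa_trace <- function(x, ...) {
  tibble::tibble(variable = x$variable, d1 = x$pair[1], d2 = x$pair[2],
                 final = x$final, diverged = x$diverged,
                 n_iter = length(x$raw), averaging = x$config$averaging,
                 sign = x$sign,
                 seed = if (is.null(x$seed)) NA_integer_
                        else as.integer(x$seed))
}

#' @describeIn run_sa Plot raw and averaged iterates against the iteration
#'   step.
#' @param object An `sa_trace`.
#' @method autoplot sa_trace
#' @export
autoplot.sa_trace <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("raw", "averaged"), names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration t",
                  y = paste0(object$variable, " (", object$transform,
                             " space)"),
                  title = sprintf("SA iterates, pair (%s, %s)",
                                  object$pair[1], object$pair[2])) +
    ggplot2::theme_minimal()
}

# Probe the regression sign at two marginal quantiles.  Returns the working
# sign plus a no-crossing indicator; determine_sign() is the documented
# wrapper with the spec'd return convention.
sign_probe <- function(model, j, d1, d2, probe_quantiles = c(0.05, 0.95),
                       m_pilot = 2000) {
  stopifnot(probe_quantiles[1] < probe_quantiles[2])
  j <- var_index(model, j)
  spec <- model$variables[[j]]
  inv <- inv_transform_fun(spec$transform)
  smp <- conditional_sampler(model, j)
  est <- function(q) {
    nat <- clamp_support(spec, inv(transformed_quantile(spec, q)))
    th <- smp(rep(nat, m_pilot))
    x <- model$utility(d1, th, model$constants) -
      model$utility(d2, th, model$constants)
    c(mean = mean(x), se = sd(x) / sqrt(m_pilot))
  }
  lo <- est(probe_quantiles[1]); hi <- est(probe_quantiles[2])
  lo_neg <- lo["mean"] < -3 * lo["se"]; lo_pos <- lo["mean"] > 3 * lo["se"]
  hi_neg <- hi["mean"] < -3 * hi["se"]; hi_pos <- hi["mean"] > 3 * hi["se"]
  slope_sign <- if (hi["mean"] >= lo["mean"]) 1 else -1
  if (lo_neg && hi_pos) list(sign = 1, no_crossing = FALSE)
  else if (lo_pos && hi_neg) list(sign = -1, no_crossing = FALSE)
  else if ((lo_neg && hi_neg) || (lo_pos && hi_pos))
    list(sign = slope_sign, no_crossing = TRUE)
  else list(sign = slope_sign, no_crossing = FALSE)
}

#' Determine the direction of the regression function through its root
#'
#' Estimates the pairwise conditional difference at two marginal quantiles
#' (with `m_pilot` conditional samples each) and classifies the crossing:
#' `+1` if the difference is confidently negative at the low probe and
#' positive at the high probe (at 3 pilot standard errors), `-1` for the
#' mirrored pattern, the string `"no-crossing"` if both probes confidently
#' agree in sign, and otherwise the sign of the difference between the two
#' estimates as a fallback.
#'
#' @inheritParams pairwise_diff_estimate
#' @param probe_quantiles Strictly ordered pair of marginal probabilities at
#'   which to probe.
#' @param m_pilot Pilot sample size per probe.
#' @return `+1`, `-1`, or the character string `"no-crossing"`.
#' @export
determine_sign <- function(model, j, d1, d2, probe_quantiles = c(0.05, 0.95),
                           m_pilot = 2000, seed = NULL) {
  if (identical(d1, d2)) stop("d1 and d2 must differ", call. = FALSE)
  pr <- with_seed(seed,
                  sign_probe(model, j, d1, d2, probe_quantiles, m_pilot))
  if (pr$no_crossing) "no-crossing" else pr$sign
}

#' Judge whether a collection of SA runs indicates an empty pairwise root set
#'
#' The pairwise root set is judged empty when *either* any run overflowed,
#' *or* the across-run standard error of the averaged iterates fails to
#' shrink between `t = T/10` and `t = T` by at least `shrink_factor` while
#' the majority of individual runs are still moving (a non-shrinking spread
#' over *settled* runs indicates multiple roots reached from different
#' initialisation basins, not emptiness), *or*
#' the across-run mean drifts monotonically away from the marginal mean,
#' ends beyond `guard_sd` marginal standard deviations from it (transform
#' space), *and* is still drifting over the last half of the iterations
#' (the increment over `[T/2, T]` exceeds a quarter of the increment over
#' `[T/10, T/2]`).  The last condition separates genuinely unbounded drift
#' (whose Polyak-Ruppert average keeps moving like `sqrt(t)`) from a root
#' that merely lies far outside the marginal's bulk, where the averaged path
#' travels beyond the guard but then settles.  A converged collection shows
#' the standard error decaying at roughly `1/sqrt(t)` instead.
#'
#' @param traces List of at least two `sa_trace` objects from independent
#'   runs with a common iteration count.
#' @param shrink_factor Required decay factor of the across-run standard
#'   error between `T/10` and `T` (default 1.5).
#' @param guard_sd Support guard in marginal standard deviations (default 8).
#' @return `TRUE` if the pairwise set is judged empty, else `FALSE`.
#' @export
detect_divergence <- function(traces, shrink_factor = 1.5, guard_sd = 8) {
  stopifnot(length(traces) >= 2,
            all(vapply(traces, inherits, TRUE, "sa_trace")))
  n_iter <- unique(vapply(traces, function(x) length(x$raw), 1L))
  if (length(n_iter) != 1)
    stop("traces must share a common iteration count", call. = FALSE)
  if (any(vapply(traces, function(x) x$diverged, TRUE))) return(TRUE)
  avg <- vapply(traces, function(x) x$averaged, numeric(n_iter))
  t0 <- max(2L, floor(n_iter / 10))
  t_half <- max(t0 + 1L, floor(n_iter / 2))
  se_at <- function(t) sd(avg[t, ]) / sqrt(ncol(avg))
  se0 <- se_at(t0); seT <- se_at(n_iter)
  # per-run settledness: a run that found a root stops moving over the last
  # half; a drifting run's Polyak average keeps moving like sqrt(t)
  inc_e <- abs(avg[t_half, ] - avg[t0, ])
  inc_l <- abs(avg[n_iter, ] - avg[t_half, ])
  settled <- ifelse(inc_e > 0, inc_l <= 0.25 * inc_e, inc_l == 0)
  if (seT > 0 && se0 / seT < shrink_factor && mean(settled) <= 0.5)
    return(TRUE)
  mu <- traces[[1]]$marginal_mean; sg <- traces[[1]]$marginal_sd
  cps <- unique(pmax(1L, floor(n_iter * c(0.1, 0.25, 0.5, 1))))
  path <- rowMeans(avg)[cps]
  dist <- abs(path - mu)
  monotone_away <- all(diff(dist) > 0)
  # the mean path is still drifting when its movement over the last half is
  # a substantial fraction of the earlier movement AND clearly exceeds the
  # Monte Carlo jitter of the across-run mean (late increments of a
  # converged far root are pure noise; genuine drift is coherent)
  inc_early <- abs(path[3] - path[1])
  late_r <- avg[n_iter, ] - avg[t_half, ]
  inc_late <- abs(mean(late_r))
  late_noise <- 3 * sd(late_r) / sqrt(length(late_r))
  still_drifting <- inc_late > late_noise &&
    (if (inc_early > 0) inc_late > 0.25 * inc_early else TRUE)
  if (monotone_away && still_drifting && sg > 0 &&
      dist[length(dist)] > guard_sd * sg)
    return(TRUE)
  FALSE
}
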