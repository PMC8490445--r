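# Decision-theoretic sensitivity measures: prior optimal option, EVPI,
# EVPPI (nested Monte Carlo with optional plug-in means), decision switching
# probability from an assembled threshold set, and reference
# conditional-expectation curves with common random numbers.

#' Prior optimal option
#'
#' Estimates each option's expected utility with common random numbers and
#' returns the argmax.  A warning is emitted when the top two options overlap
#' within 3 standard errors of their paired difference.
#'
#' @inheritParams sample_prior
#' @return An object of class `prior_optimal` with the chosen `optimal`
#'   option and a `means` tibble (`option`, `mean`, `se`).
#' @export
prior_optimal <- function(model, n = 2^16, seed = NULL) {
  stopifnot(inherits(model, "decision_model"), n >= 1)
  fu <- with_seed(seed, utility_matrix(model,
                                       sample_prior_cols(model, n)))
  mu <- colMeans(fu)
  se <- apply(fu, 2, sd) / sqrt(n)
  o <- order(mu, decreasing = TRUE)
  if (length(mu) > 1) {
    gap <- mu[o[1]] - mu[o[2]]
    gap_se <- sd(fu[, o[1]] - fu[, o[2]]) / sqrt(n)
    if (gap < 3 * gap_se)
      warning("top two options overlap within 3 SE; prior optimum unstable",
              call. = FALSE)
  }
  structure(list(optimal = model$options[o[1]],
                 means = tibble::tibble(option = model$options, mean = mu,
                                        se = se),
                 n = n, seed = seed),
            class = "prior_optimal")
}

#' @method print prior_optimal
#' @export
print.prior_optimal <- function(x, ...) {
  cat(sprintf("<prior_optimal> %s (n = %d)\n", x$optimal, x$n))
  print(as.data.frame(x$means), row.names = FALSE)
  invisible(x)
}

#' @describeIn prior_optimal Per-option mean utilities as a tibble.
#' @param x A `prior_optimal` object.
#' @param ... Unused.
#' @method tidy prior_optimal
#' @export
tidy.prior_optimal <- function(x, ...) {
  dplyr::mutate(x$means, optimal = .data$option == x$optimal)
}

#' Expected value of perfect information
#'
#' `EVPI = E[max_d f_d(theta)] - max_d E[f_d(theta)]`, estimated with the
#' paired estimator on common samples: the mean over samples of
#' `max_d f_d(theta) - f_{d*}(theta)` with `d*` the prior optimum estimated
#' on the same samples.  Pairing leaves the estimand untouched but shrinks
#' the Monte Carlo error by orders of magnitude when per-option utilities
#' share most of their variance, as they do for net-benefit models.
#'
#' @inheritParams sample_prior
#' @return A one-row tibble: `quantity`, `estimate`, `se`, `n`, `optimal`.
#' @export
evpi <- function(model, n = 2^18, seed = NULL) {
  stopifnot(inherits(model, "decision_model"), n >= 2)
  fu <- with_seed(seed, utility_matrix(model, sample_prior_cols(model, n)))
  dstar <- which.max(colMeans(fu))
  d <- do.call(pmax, lapply(seq_len(ncol(fu)), function(i) fu[, i])) -
    fu[, dstar]
  tibble::tibble(quantity = "EVPI", estimate = mean(d),
                 se = sd(d) / sqrt(n), n = n,
                 optimal = model$options[dstar])
}

#' Expected value of partial perfect information (nested Monte Carlo)
#'
#' Standard nested estimator of
#' `EVPPI_j = E[max_d E[f_d | theta_j]] - max_d E[f_d]`: `n_outer` marginal
#' samples of variable `j`, `n_inner` conditional samples each.  With
#' `plug_in = TRUE`, inner sampling substitutes the exact means of
#' linearly entering variables (the model's `plugin_means` registry), a
#' Rao-Blackwellisation that removes their sampling noise without changing
#' the estimand.  Both terms of the difference are computed from the same
#' inner means (pairing against the prior-optimum inner means), and the
#' standard error is taken over the paired per-outer differences.
#'
#' Finite `n_inner` makes the estimator upward biased (the inner max ends up
#' partly fitting inner noise); the bias is documented, not corrected, and
#' shrinks as `n_inner` grows.
#'
#' @inheritParams sample_prior
#' @param j Variable name or index.
#' @param n_outer,n_inner Outer and inner sample counts.
#' @param plug_in Substitute exact means for plug-in-eligible variables
#'   (default `TRUE`).
#' @param chunk Outer samples per vectorised block (memory knob).
#' @return A one-row tibble: `quantity`, `variable`, `estimate`, `se`,
#'   `n_outer`, `n_inner`, `plug_in`.
#' @export
evppi_nested <- function(model, j, n_outer = 2^18, n_inner = 2^10,
                         plug_in = TRUE, seed = NULL, chunk = 2048L) {
  stopifnot(inherits(model, "decision_model"), n_outer >= 1, n_inner >= 1)
  j <- var_index(model, j)
  spec <- model$variables[[j]]
  smp <- conditional_sampler(model, j, plug_in = plug_in)
  nd <- length(model$options)
  gbar <- matrix(NA_real_, n_outer, nd)
  with_seed(seed, {
    outer <- draw_marginal(spec, n_outer)
    for (s in seq(1L, n_outer, by = chunk)) {
      idx <- s:min(s + chunk - 1L, n_outer)
      vals <- rep(outer[idx], each = n_inner)
      fu <- utility_matrix(model, smp(vals))
      for (col in seq_len(nd))
        gbar[idx, col] <- colMeans(matrix(fu[, col], nrow = n_inner))
    }
  })
  dstar <- which.max(colMeans(gbar))
  d <- do.call(pmax, lapply(seq_len(nd), function(i) gbar[, i])) -
    gbar[, dstar]
  tibble::tibble(quantity = "EVPPI", variable = spec$name,
                 estimate = mean(d), se = sd(d) / sqrt(n_outer),
                 n_outer = n_outer, n_inner = n_inner, plug_in = plug_in)
}

#' Decision switching probability from an assembled threshold set
#'
#' The probability, under the marginal distribution of variable `j`, that
#' learning `theta_j` exactly changes the optimal option away from the prior
#' optimum: the marginal probability mass of every interval of the threshold
#' set whose optimal option differs from `d_opt`.  The mass is computed from
#' the closed-form marginal CDF in transform space (normal for
#' log-/logit-normal families, beta CDF for beta marginals) - no resampling.
#' An empty threshold set yields 0: when the conditionally optimal option
#' never switches it must coincide with the prior optimum everywhere.
#'
#' @inheritParams sample_prior
#' @param j Variable name or index.
#' @param thresholds A [assemble_threshold_set()] result for variable `j`.
#' @param d_opt The prior optimal option; when `NULL` it is estimated with
#'   [prior_optimal()] at `n_prior` samples.
#' @param n_prior Sample size for the prior-optimum estimate.
#' @return A single probability in `[0, 1]`.
#' @export
decision_switching_probability <- function(model, j, thresholds,
                                           d_opt = NULL, n_prior = 2^16,
                                           seed = NULL) {
  stopifnot(inherits(model, "decision_model"),
            inherits(thresholds, "threshold_set"))
  j <- var_index(model, j)
  spec <- model$variables[[j]]
  if (!identical(spec$name, thresholds$variable))
    stop("threshold set was assembled for variable '", thresholds$variable,
         "', not '", spec$name, "'", call. = FALSE)
  if (anyNA(thresholds$labels) || !length(thresholds$labels))
    stop("threshold set has unlabelled intervals", call. = FALSE)
  if (is.null(d_opt))
    d_opt <- prior_optimal(model, n_prior,
                           seed = if (is.null(seed)) NULL
                                  else derive_seed(seed, "prior"))$optimal
  bounds <- c(-Inf, thresholds$elements, Inf)
  mass <- diff(transformed_cdf(spec, bounds))
  sum(mass[thresholds$labels != d_opt])
}

#' Conditional-expectation reference curves
#'
#' Estimates `E[f_d(theta) | theta_j]` for every option on a grid of
#' `theta_j` values with `n` conditional samples per point, sharing common
#' random numbers across options and grid points (only the conditional law
#' of a correlated block partner depends on `theta_j`; its standard-normal
#' innovations are reused across the grid).  With `plug_in = TRUE`,
#' linearly entering variables are replaced by their exact means.
#'
#' @inheritParams sample_prior
#' @param j Variable name or index.
#' @param grid Numeric grid of conditioning values in *natural* space (all
#'   within the support of variable `j`).
#' @param n Conditional samples per grid point.
#' @param plug_in Substitute exact means for plug-in-eligible variables.
#' @return A tibble of class `ce_curve`: `variable`, `theta`,
#'   `theta_transformed`, `option`, `mean`, `se`.
#' @export
conditional_expectation_curve <- function(model, j, grid, n = 2^14,
                                          plug_in = TRUE, seed = NULL) {
  stopifnot(inherits(model, "decision_model"), n >= 2)
  j <- var_index(model, j)
  spec <- model$variables[[j]]
  if (!all(in_support(spec, grid)))
    stop("grid values outside the support of '", spec$name, "'",
         call. = FALSE)
  base <- with_seed(seed, crn_conditional_base(model, j, n, plug_in))
  tf <- transform_fun(spec$transform)
  out <- purrr::map_dfr(grid, function(g) {
    fu <- utility_matrix(model, base$build(g))
    tibble::tibble(variable = spec$name, theta = g,
                   theta_transformed = tf(g),
                   option = model$options, mean = colMeans(fu),
                   se = apply(fu, 2, sd) / sqrt(n))
  })
  class(out) <- c("ce_curve", class(out))
  out
}

# Common-random-number base for conditional sampling: draws every non-j
# component once (plug-in respected) and keeps the block partner's standard
# normal innovations so the same noise can be re-conditioned at any theta_j.
crn_conditional_base <- function(model, j, n, plug_in = FALSE) {
  j <- var_index(model, j)
  specs <- model$variables
  jname <- names(specs)[j]
  jspec <- specs[[jname]]
  jblock <- block_of(model, jname)
  plug <- if (plug_in) model$plugin_means else numeric()
  plug <- plug[setdiff(names(plug), jname)]
  cond <- if (!is.null(jblock)) block_conditional(jblock, jname)
  partner_plugged <- !is.null(cond) && cond$partner %in% names(plug)
  cols <- vector("list", length(specs))
  names(cols) <- names(specs)
  done <- jname
  z_partner <- NULL
  if (!is.null(cond)) {
    if (partner_plugged) cols[[cond$partner]] <- unname(plug[cond$partner])
    else z_partner <- rnorm(n)
    done <- c(done, cond$partner)
  }
  for (nm in names(specs)) {
    if (nm %in% done) next
    if (nm %in% names(plug)) {
      cols[[nm]] <- unname(plug[nm]); done <- c(done, nm); next
    }
    b <- block_of(model, nm)
    if (is.null(b) || any(b$members %in% done) ||
        any(b$members %in% names(plug))) {
      cols[[nm]] <- draw_marginal(specs[[nm]], n)
      done <- c(done, nm)
    } else {
      drawn <- draw_block(b, specs, n)
      cols[b$members] <- drawn[b$members]
      done <- c(done, b$members)
    }
  }
  jtrans <- transform_fun(jspec$transform)
  build <- function(theta_j) {
    out <- cols
    out[[jname]] <- theta_j
    if (!is.null(cond) && !partner_plugged) {
      x <- cond$mean_fun(jtrans(theta_j)) + sqrt(cond$var) * z_partner
      out[[cond$partner]] <-
        inv_transform_fun(specs[[cond$partner]]$transform)(x)
    }
    out
  }
  list(build = build)
}

#' @describeIn conditional_expectation_curve Plot the per-option curves.
#' @param object A `ce_curve` tibble.
#' @param ... Unused.
#' @method autoplot ce_curve
#' @export
autoplot.ce_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theta, y = .data$mean,
                                       colour = .data$option)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se,
                                      fill = .data$option),
                         alpha = 0.2, colour = NA) +
    ggplot2::labs(x = unique(object$variable),
                  y = "conditional expected net benefit") +
    ggplot2::theme_minimal()
}

#' Brute-force grid oracle for a pairwise root
#'
#' Independent cross-check of the stochastic-approximation estimates:
#' evaluates the pairwise conditional difference `E[(f_{d1} - f_{d2}) |
#' theta_j]` on an equispaced transform-space grid with `m` common-random-
#' number samples per point, brackets sign changes and linearly interpolates
#' the root.  The root's standard error is propagated from the Monte Carlo
#' error of the bracketing estimates through the local slope.
#'
#' @inheritParams pairwise_diff_estimate
#' @param lower,upper Grid range in transform space.
#' @param n_grid Number of grid points.
#' @param m Samples per grid point.
#' @param plug_in Substitute exact means for plug-in-eligible variables.
#' @return A tibble with one row per bracketed root: `root`, `se`, and the
#'   bracketing grid values; zero rows if no sign change occurs.  The full
#'   difference curve is attached as attribute `"curve"`.
#' @export
grid_root_oracle <- function(model, j, d1, d2, lower, upper, n_grid = 41,
                             m = 2^15, plug_in = TRUE, seed = NULL) {
  stopifnot(inherits(model, "decision_model"), lower < upper, n_grid >= 3)
  if (identical(d1, d2)) stop("d1 and d2 must differ", call. = FALSE)
  j <- var_index(model, j)
  spec <- model$variables[[j]]
  inv <- inv_transform_fun(spec$transform)
  grid <- seq(lower, upper, length.out = n_grid)
  base <- with_seed(seed, crn_conditional_base(model, j, m, plug_in))
  g <- se <- numeric(n_grid)
  for (i in seq_len(n_grid)) {
    th <- base$build(clamp_support(spec, inv(grid[i])))
    x <- model$utility(d1, th, model$constants) -
      model$utility(d2, th, model$constants)
    g[i] <- mean(x); se[i] <- sd(x) / sqrt(m)
  }
  sw <- which(sign(g[-1]) * sign(g[-n_grid]) < 0)
  roots <- purrr::map_dfr(sw, function(i) {
    slope <- (g[i + 1] - g[i]) / (grid[i + 1] - grid[i])
    root <- grid[i] - g[i] / slope
    root_se <- sqrt(se[i]^2 + se[i + 1]^2) / 2 / abs(slope)
    tibble::tibble(root = root, se = root_se, lower = grid[i],
                   upper = grid[i + 1])
  })
  attr(roots, "curve") <- tibble::tibble(theta_transformed = grid,
                                         diff = g, se = se)
  roots
}
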