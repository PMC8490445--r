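# Nested (double-loop) Monte Carlo threshold baseline: the outer loop draws
# marginal samples of theta_j, the inner loop estimates each option's
# conditional mean utility; a switch of the estimated argmax between
# consecutive sorted outer samples marks a threshold at their midpoint.

#' Nested Monte Carlo threshold estimation (baseline)
#'
#' Draws `n_outer` marginal samples of variable `j`, sorts them ascending,
#' estimates the conditionally optimal option at each by `m_inner`-sample
#' conditional means (common random numbers across options within a draw),
#' and records the midpoint of every consecutive pair of outer samples whose
#' estimated optimum differs.  The total number of model evaluations is
#' exactly `|D| * m_inner * n_outer`, which is the cost yardstick against
#' the stochastic-approximation search.
#'
#' Ties in the inner argmax are broken by option order and flagged with a
#' warning: near thresholds the Monte Carlo winner can be wrong, which is a
#' known instability of the double-loop estimator and is deliberately left
#' visible.
#'
#' @inheritParams sample_prior
#' @param j Variable name or index.
#' @param m_inner Inner (conditional) sample count per outer sample.
#' @param n_outer Outer (marginal) sample count.
#' @param chunk Outer samples processed per vectorised block.
#' @return An object of class `nested_mc_result`: sorted outer samples with
#'   their estimated optimal options (natural space), detected `switches`
#'   (midpoints), counts and the evaluation tally.  [tidy()] returns the
#'   per-outer-sample table.
#' @export
nested_mc_thresholds <- function(model, j, m_inner, n_outer, seed = NULL,
                                 chunk = 256L) {
  stopifnot(inherits(model, "decision_model"), m_inner >= 1, n_outer >= 1)
  j <- var_index(model, j)
  spec <- model$variables[[j]]
  smp <- conditional_sampler(model, j)
  n_eval <- 0L
  res <- with_seed(seed, {
    outer <- sort(draw_marginal(spec, n_outer))
    opt <- character(n_outer)
    tie <- logical(n_outer)
    for (s in seq(1L, n_outer, by = chunk)) {
      idx <- s:min(s + chunk - 1L, n_outer)
      vals <- rep(outer[idx], each = m_inner)
      th <- smp(vals)
      fu <- utility_matrix(model, th)
      n_eval <- n_eval + length(vals) * length(model$options)
      for (col in seq_len(ncol(fu))) {
        mts <- matrix(fu[, col], nrow = m_inner)
        if (col == 1) means <- matrix(NA_real_, length(idx), ncol(fu))
        means[, col] <- colMeans(mts)
      }
      for (r in seq_along(idx)) {
        mu <- means[r, ]
        w <- which(mu == max(mu))
        tie[idx[r]] <- length(w) > 1
        opt[idx[r]] <- model$options[w[1]]
      }
    }
    list(outer = outer, opt = opt, tie = tie)
  })
  if (any(res$tie))
    warning(sum(res$tie), " inner argmax tie(s) broken by option order",
            call. = FALSE)
  sw <- which(res$opt[-1] != res$opt[-n_outer])
  switches <- (res$outer[sw] + res$outer[sw + 1]) / 2
  structure(list(variable = spec$name, outer = res$outer, optimal = res$opt,
                 ties = res$tie, switches = switches,
                 switch_from = res$opt[sw], switch_to = res$opt[sw + 1],
                 m_inner = m_inner, n_outer = n_outer, n_eval = n_eval,
                 seed = seed),
            class = "nested_mc_result")
}

#' @method print nested_mc_result
#' @export
print.nested_mc_result <- function(x, ...) {
  cat(sprintf(
    "<nested_mc_result> %s: %d outer x %d inner samples (%d evaluations)\n",
    x$variable, x$n_outer, x$m_inner, x$n_eval))
  if (length(x$switches))
    cat(sprintf("  switch %s -> %s at %.6g\n", x$switch_from, x$switch_to,
                x$switches))
  else cat("  no switches detected\n")
  invisible(x)
}

#' @describeIn nested_mc_thresholds Per-outer-sample table (`theta_j`,
#'   estimated optimal option, tie flag).
#' @param x A `nested_mc_result`.
#' @param ... Unused.
#' @method tidy nested_mc_result
#' @export
tidy.nested_mc_result <- function(x, ...) {
  tibble::tibble(variable = x$variable, theta_j = x$outer,
                 optimal = x$optimal, tie = x$ties)
}

#' @describeIn nested_mc_thresholds One-row summary with the switch count
#'   and evaluation tally.
#' @method glance nested_mc_result
#' @export
glance.nested_mc_result <- function(x, ...) {
  tibble::tibble(variable = x$variable, n_outer = x$n_outer,
                 m_inner = x$m_inner, n_switches = length(x$switches),
                 n_eval = x$n_eval)
}

#' @describeIn nested_mc_thresholds Plot the estimated optimal option along
#'   the sorted outer samples, with detected switch midpoints.
#' @param object A `nested_mc_result`.
#' @method autoplot nested_mc_result
#' @export
autoplot.nested_mc_result <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$theta_j,
                                        y = .data$optimal)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = object$variable, y = "estimated optimal option",
                  title = "Nested Monte Carlo threshold scan") +
    ggplot2::theme_minimal()
  if (length(object$switches))
    p <- p + ggplot2::geom_vline(xintercept = object$switches,
                                 linetype = "dashed")
  p
}
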