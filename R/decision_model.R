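#' Construct a decision model
#'
#' A decision model bundles a finite set of options, a vectorised utility
#' function on the net (monetary) benefit scale, per-input marginal
#' distributions and optional correlated bivariate blocks.  All estimators in
#' the package operate on this object.
#'
#' The utility contract is `utility(option, theta, constants)` where `theta`
#' is a named list/data frame of equal-length numeric vectors (one element
#' per input variable, natural space) and the return value is the numeric
#' vector of utilities, one per sample.  The function must be vectorised over
#' samples: nested Monte Carlo evaluates it on millions of parameter vectors
#' per call.
#'
#' @param options Character vector of option identifiers (at least 2 for a
#'   decision problem; a single option is allowed for degenerate checks).
#' @param variables List of [marginal_spec()]s, in the canonical input order.
#' @param utility Vectorised utility function, see Details.
#' @param blocks Optional list of [correlated_block()]s; each variable may
#'   appear in at most one block, and block members must have
#'   normal-underlying families.
#' @param constants Named list of model constants passed to `utility`.
#' @param plugin_means Named numeric vector of exact means for variables that
#'   enter the utility linearly; used by plug-in (Rao-Blackwellised)
#'   conditional-expectation estimates.  Only list variables whose utility
#'   dependence is truly linear.
#' @param utility_name Optional registry name used when serialising the model
#'   to a config file (see [write_model_config()]).
#' @return An object of class `decision_model`.
#' @seealso [three_treatment_model()] for the built-in example.
#' @export
decision_model <- function(options, variables, utility, blocks = list(),
                           constants = list(), plugin_means = numeric(),
                           utility_name = NULL) {
  options <- as.character(options)
  stopifnot(length(options) >= 1, !anyDuplicated(options))
  if (!all(vapply(variables, inherits, TRUE, "marginal_spec")))
    stop("variables must be a list of marginal_spec objects", call. = FALSE)
  nms <- vapply(variables, function(v) v$name, "")
  if (anyDuplicated(nms)) stop("duplicate variable names", call. = FALSE)
  names(variables) <- nms
  if (!all(vapply(blocks, inherits, TRUE, "correlated_block")))
    stop("blocks must be a list of correlated_block objects", call. = FALSE)
  in_block <- unlist(lapply(blocks, function(b) b$members))
  if (anyDuplicated(in_block))
    stop("a variable appears in more than one block", call. = FALSE)
  if (!all(in_block %in% nms))
    stop("block member not among model variables", call. = FALSE)
  # block marginals must agree with the stated bivariate parameters
  for (b in blocks) {
    for (k in 1:2) {
      sp <- variables[[b$members[k]]]
      if (!sp$family %in% c("normal", "lognormal", "logitnormal"))
        stop("block member '", sp$name, "' must be normal-underlying",
             call. = FALSE)
      if (abs(sp$params$mean - b$mu[k]) > 1e-9 ||
          abs(sp$params$var - b$sigma[k, k]) > 1e-9)
        stop("marginal of '", sp$name,
             "' does not match its block's (mu, sigma)", call. = FALSE)
    }
  }
  stopifnot(is.function(utility))
  if (length(plugin_means) && !all(names(plugin_means) %in% nms))
    stop("plugin_means names must be model variables", call. = FALSE)
  structure(list(options = options, variables = variables, blocks = blocks,
                 constants = constants, utility = utility,
                 plugin_means = plugin_means, utility_name = utility_name),
            class = "decision_model")
}

#' @method print decision_model
#' @export
print.decision_model <- function(x, ...) {
  cat(sprintf("<decision_model> %d options (%s), %d variables, %d block(s)\n",
              length(x$options), paste(x$options, collapse = ", "),
              length(x$variables), length(x$blocks)))
  for (v in x$variables) {
    p <- paste(names(v$params), signif(unlist(v$params), 6),
               sep = "=", collapse = ", ")
    cat(sprintf("  %-10s %s(%s)%s\n", v$name, v$family, p,
                if (v$transform != "identity")
                  paste0("  [", v$transform, "]") else ""))
  }
  if (length(x$constants))
    cat("  constants:", paste(names(x$constants), unlist(x$constants),
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

var_index <- function(model, j) {
  nms <- names(model$variables)
  if (is.character(j)) {
    i <- match(j, nms)
    if (is.na(i)) stop("unknown variable '", j, "'", call. = FALSE)
    return(i)
  }
  j <- as.integer(j)
  if (j < 1 || j > length(nms)) stop("variable index out of range", call. = FALSE)
  j
}

block_of <- function(model, name) {
  for (b in model$blocks) if (name %in% b$members) return(b)
  NULL
}

# ---- sampling ---------------------------------------------------------------

# Internal column-list prior sampler (fast path; tibble wrapper below).
sample_prior_cols <- function(model, n) {
  specs <- model$variables
  out <- vector("list", length(specs))
  names(out) <- names(specs)
  done <- character()
  for (nm in names(specs)) {
    if (nm %in% done) next
    b <- block_of(model, nm)
    if (is.null(b)) {
      out[[nm]] <- draw_marginal(specs[[nm]], n)
      done <- c(done, nm)
    } else {
      # jointly draw the whole block the first time one member is reached
      cols <- draw_block(b, specs, n)
      out[b$members] <- cols[b$members]
      done <- c(done, b$members)
    }
  }
  out
}

#' Draw prior samples of the model inputs
#'
#' Components of independent specifications are mutually independent; members
#' of a [correlated_block()] are drawn jointly from the underlying bivariate
#' normal and then mapped through `exp` / inverse-logit as their family
#' dictates.
#'
#' @param model A [decision_model()].
#' @param n Number of samples (>= 1).
#' @param seed Optional integer seed; when supplied the caller's RNG state is
#'   left untouched.
#' @return A tibble with `n` rows and one column per input variable, in
#'   natural (untransformed) space.
#' @examples
#' m <- three_treatment_model()
#' sample_prior(m, 5, seed = 1)
#' @export
sample_prior <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "decision_model"), n >= 1)
  tibble::as_tibble(with_seed(seed, sample_prior_cols(model, n)))
}

# Build a fast conditional sampler for variable j: a function taking a
# natural-space vector of conditioning values (length n) and returning the
# full column list (length-n components; plug-in variables as scalars).
conditional_sampler <- function(model, j, plug_in = FALSE) {
  j <- var_index(model, j)
  specs <- model$variables
  jname <- names(specs)[j]
  jspec <- specs[[jname]]
  if (jspec$family == "constant")
    stop("cannot condition on a constant input", call. = FALSE)
  jblock <- block_of(model, jname)
  jtrans <- transform_fun(jspec$transform)
  plug <- if (plug_in) model$plugin_means else numeric()
  plug <- plug[setdiff(names(plug), jname)]
  cond <- if (!is.null(jblock)) block_conditional(jblock, jname)

  function(theta_j) {
    n <- length(theta_j)
    if (!all(in_support(jspec, theta_j)))
      stop("conditioning value outside the support of '", jname, "'",
           call. = FALSE)
    out <- vector("list", length(specs))
    names(out) <- names(specs)
    out[[jname]] <- theta_j
    done <- jname
    if (!is.null(cond)) {
      pn <- cond$partner
      if (pn %in% names(plug)) {
        out[[pn]] <- unname(plug[pn])
      } else {
        z <- jtrans(theta_j)
        x <- rnorm(n, cond$mean_fun(z), sqrt(cond$var))
        out[[pn]] <- inv_transform_fun(specs[[pn]]$transform)(x)
      }
      done <- c(done, pn)
    }
    for (nm in names(specs)) {
      if (nm %in% done) next
      if (nm %in% names(plug)) {
        out[[nm]] <- unname(plug[nm]); done <- c(done, nm); next
      }
      b <- block_of(model, nm)
      if (is.null(b) || any(b$members %in% done) ||
          any(b$members %in% names(plug))) {
        # independent draw (or partner handled separately / plugged in)
        out[[nm]] <- draw_marginal(specs[[nm]], n)
        done <- c(done, nm)
      } else {
        cols <- draw_block(b, specs, n)
        out[b$members] <- cols[b$members]
        done <- c(done, b$members)
      }
    }
    out
  }
}

#' Draw samples of the inputs conditional on one fixed component
#'
#' Component `j` is fixed at `theta_j` in every returned sample.  If `j`
#' belongs to a [correlated_block()], its partner is drawn from the exact
#' conditional univariate normal of the underlying bivariate normal given the
#' transformed fixed value, then mapped back to natural space; all other
#' components are drawn as in [sample_prior()].
#'
#' @inheritParams sample_prior
#' @param j Variable name or index.
#' @param theta_j Conditioning value in natural space (must lie in the
#'   support of variable `j`).
#' @return A tibble with `n` rows, column `j` constant at `theta_j`.
#' @export
sample_conditional <- function(model, j, theta_j, n, seed = NULL) {
  stopifnot(inherits(model, "decision_model"), n >= 1, length(theta_j) == 1)
  smp <- conditional_sampler(model, j)
  cols <- with_seed(seed, smp(rep(theta_j, n)))
  tibble::as_tibble(cols)
}

# ---- utilities --------------------------------------------------------------

#' Convert a baseline probability and odds ratio to a probability
#'
#' Returns `OR * q / (1 + OR * q)` with `q = p / (1 - p)`: the event
#' probability under a treatment whose odds ratio relative to baseline is
#' `odds_ratio`.
#'
#' @param p_base Baseline probability, strictly inside (0, 1).  Vectorised.
#' @param odds_ratio Positive odds ratio.  Vectorised.
#' @return Probability in (0, 1).
#' @examples
#' odds_to_prob(0.15, 1)       # = 0.15
#' odds_to_prob(0.15, 0.2231)  # ~ 0.0379
#' @export
odds_to_prob <- function(p_base, odds_ratio) {
  if (any(p_base <= 0 | p_base >= 1, na.rm = TRUE))
    stop("p_base must lie strictly in (0, 1)", call. = FALSE)
  if (any(odds_ratio <= 0, na.rm = TRUE))
    stop("odds_ratio must be positive", call. = FALSE)
  q <- odds_ratio * p_base / (1 - p_base)
  q / (1 + q)
}

#' Evaluate the utility (net benefit) of one option
#'
#' @param model A [decision_model()].
#' @param option Option identifier (must be one of `model$options`).
#' @param theta Data frame / named list of input columns in natural space
#'   (e.g. from [sample_prior()]), or a single named numeric vector.
#' @return Numeric vector of utilities, one per sample row.
#' @export
net_benefit <- function(model, option, theta) {
  stopifnot(inherits(model, "decision_model"))
  if (!option %in% model$options)
    stop("unknown option '", option, "'", call. = FALSE)
  if (is.numeric(theta) && !is.null(names(theta))) theta <- as.list(theta)
  model$utility(option, theta, model$constants)
}

# Utility of every option on common samples: n x |D| matrix (common random
# numbers across options by construction).  Column lengths may differ when
# plug-in means replace some components by scalars; n is the longest.
utility_matrix <- function(model, theta) {
  n <- max(lengths(theta))
  vapply(model$options,
         function(d) rep_len(as.numeric(
           model$utility(d, theta, model$constants)), n),
         numeric(n))
}

# Exact/quadrature means of all variables (used by plug-in registries and
# reference curves): closed form where available, adaptive quadrature for
# logit-normal.
marginal_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
         normal = p$mean,
         lognormal = exp(p$mean + p$var / 2),
         logitnormal = {
           s <- sqrt(p$var)
           integrate(function(z) plogis(p$mean + s * z) * dnorm(z),
                     -Inf, Inf, rel.tol = 1e-10)$value
         },
         beta = p$shape1 / (p$shape1 + p$shape2),
         constant = p$value)
}
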