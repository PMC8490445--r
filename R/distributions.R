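#' Marginal distribution specification for one model input
#'
#' Each uncertain input of a [decision_model()] carries a marginal
#' specification.  Log-normal and logit-normal inputs are parameterised by
#' the mean and variance of the *underlying normal* (not by moment
#' matching); the `transform` tag names the space in which stochastic
#' approximation iterates and in which thresholds are reported, and defaults
#' to `log` for log-normal, `logit` for logit-normal and `identity`
#' otherwise.
#'
#' @param name Variable name (unique within a model).
#' @param family One of `"normal"`, `"lognormal"`, `"logitnormal"`,
#'   `"beta"`, `"constant"`.
#' @param params Named numeric parameters: `mean`/`var` for `normal` and for
#'   the underlying normal of `lognormal`/`logitnormal`; `shape1`/`shape2`
#'   for `beta`; `value` for `constant`.
#' @param transform Iteration/reporting space: `"identity"`, `"log"` or
#'   `"logit"`; `NULL` picks the family default.
#' @return An object of class `marginal_spec`.
#' @examples
#' marginal_spec("L", "normal", c(mean = 30, var = 25))
#' marginal_spec("P_SE_d3", "logitnormal", c(mean = -1.1, var = 0.25))
#' @export
marginal_spec <- function(name,
                          family = c("normal", "lognormal", "logitnormal",
                                     "beta", "constant"),
                          params,
                          transform = NULL) {
  family <- match.arg(family)
  params <- as.list(params)
  need <- switch(family,
                 normal = , lognormal = , logitnormal = c("mean", "var"),
                 beta = c("shape1", "shape2"),
                 constant = "value")
  if (!all(need %in% names(params)))
    stop("marginal_spec('", name, "'): family '", family,
         "' needs parameters ", paste(need, collapse = ", "), call. = FALSE)
  params <- lapply(params[need], as.numeric)
  if (family %in% c("normal", "lognormal", "logitnormal") && params$var <= 0)
    stop("marginal_spec('", name, "'): variance must be > 0", call. = FALSE)
  if (family == "beta" && (params$shape1 <= 0 || params$shape2 <= 0))
    stop("marginal_spec('", name, "'): beta shapes must be > 0", call. = FALSE)
  if (is.null(transform))
    transform <- switch(family, lognormal = "log", logitnormal = "logit",
                        "identity")
  transform <- match.arg(transform, c("identity", "log", "logit"))
  structure(list(name = name, family = family, params = params,
                 transform = transform),
            class = "marginal_spec")
}

#' @method print marginal_spec
#' @export
print.marginal_spec <- function(x, ...) {
  p <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<marginal_spec> %s ~ %s(%s)  [%s space]\n",
              x$name, x$family, p, x$transform))
  invisible(x)
}

#' Correlated bivariate block of model inputs
#'
#' Pairs of inputs (e.g. the treatment costs of two new treatments) may be
#' correlated through a bivariate normal on the underlying-normal scale; the
#' members' own [marginal_spec()]s must equal the corresponding marginals of
#' `(mu, sigma)`.
#'
#' @param members Character vector of the two member variable names, in order.
#' @param mu Length-2 mean vector of the underlying normal pair.
#' @param sigma 2x2 symmetric positive-definite covariance matrix of the
#'   underlying normal pair.
#' @return An object of class `correlated_block`.
#' @export
correlated_block <- function(members, mu, sigma) {
  sigma <- matrix(as.numeric(sigma), 2, 2)
  stopifnot(length(members) == 2, length(mu) == 2)
  if (abs(sigma[1, 2] - sigma[2, 1]) > 1e-12 * max(abs(sigma)))
    stop("correlated_block: sigma must be symmetric", call. = FALSE)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("correlated_block: sigma must be positive definite", call. = FALSE)
  structure(list(members = as.character(members), mu = as.numeric(mu),
                 sigma = sigma),
            class = "correlated_block")
}

# ---- transforms -------------------------------------------------------------

transform_fun <- function(transform) {
  switch(transform, identity = identity, log = log, logit = qlogis,
         stop("unknown transform '", transform, "'", call. = FALSE))
}

inv_transform_fun <- function(transform) {
  switch(transform, identity = identity, log = exp, logit = plogis,
         stop("unknown transform '", transform, "'", call. = FALSE))
}

# Support check in natural space.
in_support <- function(spec, x) {
  switch(spec$family,
         normal = is.finite(x),
         lognormal = is.finite(x) & x > 0,
         logitnormal = , beta = is.finite(x) & x > 0 & x < 1,
         constant = x == spec$params$value)
}

# Mean and sd of the marginal in its transform space.  For normal-underlying
# families the transformed marginal is exactly normal; for beta (identity
# transform) the exact beta moments are used.
transformed_moments <- function(spec) {
  switch(spec$family,
         normal = , lognormal = , logitnormal =
           c(mean = spec$params$mean, sd = sqrt(spec$params$var)),
         beta = {
           a <- spec$params$shape1; b <- spec$params$shape2
           c(mean = a / (a + b),
             sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
         },
         constant = c(mean = spec$params$value, sd = 0))
}

# Marginal quantile in transform space.
transformed_quantile <- function(spec, p) {
  switch(spec$family,
         normal = , lognormal = , logitnormal =
           qnorm(p, spec$params$mean, sqrt(spec$params$var)),
         beta = qbeta(p, spec$params$shape1, spec$params$shape2),
         constant = rep(spec$params$value, length(p)))
}

# Marginal CDF evaluated at a transform-space point.
transformed_cdf <- function(spec, q) {
  switch(spec$family,
         normal = , lognormal = , logitnormal =
           pnorm(q, spec$params$mean, sqrt(spec$params$var)),
         beta = pbeta(q, spec$params$shape1, spec$params$shape2),
         constant = as.numeric(q >= spec$params$value))
}

# n draws from the marginal, natural space.
draw_marginal <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
         normal = rnorm(n, p$mean, sqrt(p$var)),
         lognormal = exp(rnorm(n, p$mean, sqrt(p$var))),
         logitnormal = plogis(rnorm(n, p$mean, sqrt(p$var))),
         beta = rbeta(n, p$shape1, p$shape2),
         constant = rep(p$value, n))
}

# Joint draw of a correlated block on the natural scale; returns a list of
# two vectors named after the members.  Sampling happens in the underlying
# normal space via the Cholesky factor.
draw_block <- function(block, specs, n) {
  s1 <- sqrt(block$sigma[1, 1]); s2 <- sqrt(block$sigma[2, 2])
  rho <- block$sigma[1, 2] / (s1 * s2)
  z1 <- rnorm(n); z2 <- rnorm(n)
  x1 <- block$mu[1] + s1 * z1
  x2 <- block$mu[2] + s2 * (rho * z1 + sqrt(1 - rho^2) * z2)
  out <- list(x1, x2)
  names(out) <- block$members
  for (k in 1:2) {
    fam <- specs[[block$members[k]]]$family
    out[[k]] <- switch(fam, normal = out[[k]], lognormal = exp(out[[k]]),
                       logitnormal = plogis(out[[k]]),
                       stop("block member '", block$members[k],
                            "' must have a normal-underlying family",
                            call. = FALSE))
  }
  out
}

# Conditional distribution of the partner's underlying normal given the
# block member `fixed_name` at transformed value z: N(mean_fun(z), var).
block_conditional <- function(block, fixed_name) {
  i <- match(fixed_name, block$members)
  stopifnot(!is.na(i))
  jp <- 3 - i
  b <- block$sigma[i, jp] / block$sigma[i, i]
  list(partner = block$members[jp],
       mean_fun = function(z) block$mu[jp] + b * (z - block$mu[i]),
       var = block$sigma[jp, jp] - block$sigma[i, jp]^2 / block$sigma[i, i])
}
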