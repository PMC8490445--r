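# Orchestration of the pairwise threshold search: multi-run SA campaigns,
# clustering of per-run finals, hypothesis-test membership post-processing
# and assembly of the threshold set with interval-wise optimal options.

#' Estimate the roots of one pairwise conditional difference
#'
#' Runs `n_runs` independent stochastic-approximation searches (marginal-drawn
#' initialisations) for the roots of
#' `E[(f_{d1} - f_{d2})(theta) | theta_j]`, judges emptiness of the pairwise
#' root set with [detect_divergence()], and otherwise clusters the per-run
#' final estimates by gap clustering with tolerance
#' `max(cluster_se_factor * pooled SE, cluster_sd_floor * sigma_j)`.
#' Multiple clusters indicate multiple roots reached from different
#' initialisation basins; emptiness and multi-root outcomes are data, not
#' errors.
#'
#' @inheritParams pairwise_diff_estimate
#' @param n_runs Number of independent runs `R` (>= 2; default 20).
#' @param config An [sa_config()] shared by all runs.
#' @param shrink_factor,guard_sd Passed to [detect_divergence()].
#' @param cluster_se_factor,cluster_sd_floor Gap-clustering tolerance knobs.
#' @param keep_traces Keep the full iterate history of every run (default
#'   `TRUE`; set `FALSE` to save memory in large campaigns).
#' @return An object of class `pairwise_roots`: per-run finals, the empty
#'   flag, a `clusters` tibble (`estimate`, `se`, `n_runs`), traces, the
#'   resolved sign, and seeds.  [tidy()] returns per-run finals; [glance()]
#'   the cluster summary.
#' @export
estimate_pairwise_roots <- function(model, j, d1, d2, n_runs = 20,
                                    config = sa_config(), seed = NULL,
                                    shrink_factor = 1.5, guard_sd = 8,
                                    cluster_se_factor = 5,
                                    cluster_sd_floor = 0.05,
                                    keep_traces = TRUE) {
  stopifnot(inherits(model, "decision_model"), n_runs >= 2)
  if (identical(d1, d2)) stop("d1 and d2 must differ", call. = FALSE)
  j <- var_index(model, j)
  spec <- model$variables[[j]]
  res <- with_seed(seed, {
    pr <- if (identical(config$sign, "auto"))
      sign_probe(model, j, d1, d2) else
        list(sign = config$sign, no_crossing = FALSE)
    ch <- sa_chains(model, j, d1, d2, config, n_runs, pr$sign)
    list(pr = pr, ch = ch)
  })
  traces <- lapply(seq_len(n_runs), function(r)
    new_sa_trace(res$ch$raw[, r], res$ch$diverged[r], model, j, d1, d2,
                 config, res$pr$sign, res$ch$schedule, seed))
  empty <- detect_divergence(traces, shrink_factor, guard_sd)
  finals <- vapply(traces, function(x) x$final, 1)
  sigma_j <- transformed_moments(spec)[["sd"]]
  clusters <- if (empty) {
    tibble::tibble(cluster = integer(), estimate = numeric(),
                   se = numeric(), n_runs = integer())
  } else {
    tol <- max(cluster_se_factor * sd(finals) / sqrt(n_runs),
               cluster_sd_floor * sigma_j)
    cluster_finals(finals, tol)
  }
  structure(list(variable = spec$name, transform = spec$transform,
                 pair = c(d1, d2), finals = finals, empty = empty,
                 clusters = clusters, sign = res$pr$sign,
                 no_crossing = res$pr$no_crossing,
                 traces = if (keep_traces) traces,
                 config = config, seed = seed),
            class = "pairwise_roots")
}

# Single-linkage gap clustering of sorted finals; returns the cluster table.
cluster_finals <- function(finals, tol) {
  o <- order(finals)
  x <- finals[o]
  id <- cumsum(c(1, diff(x) > tol))
  tibble::tibble(value = x, cluster = id) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(estimate = mean(.data$value),
                     se = if (dplyr::n() > 1)
                       sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
                     n_runs = dplyr::n(), .groups = "drop") |>
    dplyr::select("cluster", "estimate", "se", "n_runs")
}

#' @method print pairwise_roots
#' @export
print.pairwise_roots <- function(x, ...) {
  cat(sprintf("<pairwise_roots> %s, pair (%s, %s), %d runs: ",
              x$variable, x$pair[1], x$pair[2], length(x$finals)))
  if (x$empty) cat("EMPTY (divergence detected)\n")
  else {
    cat(sprintf("%d cluster(s)\n", nrow(x$clusters)))
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  estimate %.6g (se %.3g, %d runs)\n",
                  x$clusters$estimate[i], x$clusters$se[i],
                  x$clusters$n_runs[i]))
  }
  invisible(x)
}

#' @describeIn estimate_pairwise_roots Per-run final estimates as a tibble.
#' @param x A `pairwise_roots` object.
#' @param ... Unused.
#' @method tidy pairwise_roots
#' @export
tidy.pairwise_roots <- function(x, ...) {
  tibble::tibble(variable = x$variable, d1 = x$pair[1], d2 = x$pair[2],
                 run = seq_along(x$finals), final = x$finals,
                 empty = x$empty)
}

#' @describeIn estimate_pairwise_roots Cluster-level summary (one row per
#'   estimated root; zero rows when the set is judged empty).
#' @method glance pairwise_roots
#' @export
glance.pairwise_roots <- function(x, ...) {
  if (x$empty)
    return(tibble::tibble(variable = x$variable, d1 = x$pair[1],
                          d2 = x$pair[2], cluster = NA_integer_,
                          estimate = NA_real_, se = NA_real_,
                          n_runs = NA_integer_, empty = TRUE))
  dplyr::mutate(x$clusters, variable = x$variable, d1 = x$pair[1],
                d2 = x$pair[2], empty = FALSE, .before = 1)
}

#' @describeIn estimate_pairwise_roots Plot the averaged iterates of all
#'   runs.
#' @param object A `pairwise_roots` object.
#' @method autoplot pairwise_roots
#' @export
autoplot.pairwise_roots <- function(object, ...) {
  if (is.null(object$traces))
    stop("traces were not kept; rerun with keep_traces = TRUE",
         call. = FALSE)
  df <- purrr::imap_dfr(object$traces, function(tr, r)
    dplyr::mutate(tidy(tr), run = factor(r)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$averaged,
                                   group = .data$run)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "iteration t",
                  y = paste0(object$variable, " (", object$transform,
                             " space), averaged iterate"),
                  title = sprintf("Pairwise SA runs (%s, %s)%s",
                                  object$pair[1], object$pair[2],
                                  if (object$empty) " - judged empty" else
                                    "")) +
    ggplot2::theme_minimal()
}

#' Test whether a candidate pairwise root belongs to the threshold set
#'
#' At a candidate root of the `(d1, d2)` conditional difference, the null
#' hypothesis "the candidate belongs to the threshold set" is equivalent to
#' every competing option `d` satisfying both
#' `E[(f_d - f_{d1}) | theta_j = candidate] <= 0` and
#' `E[(f_d - f_{d2}) | theta_j = candidate] <= 0`.  Each inequality is
#' tested with a one-sided test (t by default, Wilcoxon signed-rank as a
#' robustness alternative) on `n` conditional samples; the candidate is
#' retained iff no p-value falls below `level`.  With only two options the
#' candidate is trivially retained with an empty p-value table.
#'
#' @inheritParams pairwise_diff_estimate
#' @param candidate Candidate root in the variable's transform space.
#' @param n Conditional sample size per test (>= 30; the t-test leans on
#'   approximate normality of the Monte Carlo means).
#' @param level Significance level (default 0.05).
#' @param family `"t"` (default) or `"wilcoxon"`.
#' @return An object of class `membership_test` with a `p_values` tibble
#'   (`competitor`, `versus`, `p`) and logical `retained`.
#' @export
test_membership <- function(model, j, candidate, d1, d2, n = 1e4,
                            level = 0.05, family = c("t", "wilcoxon"),
                            seed = NULL) {
  stopifnot(inherits(model, "decision_model"), is.finite(candidate), n >= 30)
  family <- match.arg(family)
  j <- var_index(model, j)
  spec <- model$variables[[j]]
  competitors <- setdiff(model$options, c(d1, d2))
  if (!length(competitors)) {
    return(structure(list(candidate = candidate, pair = c(d1, d2),
                          variable = spec$name,
                          p_values = tibble::tibble(competitor = character(),
                                                    versus = character(),
                                                    p = numeric()),
                          retained = TRUE, level = level, family = family,
                          n = n, seed = seed),
                     class = "membership_test"))
  }
  nat <- clamp_support(spec, inv_transform_fun(spec$transform)(candidate))
  smp <- conditional_sampler(model, j)
  pv <- with_seed(seed, {
    th <- smp(rep(nat, n))
    fu <- utility_matrix(model, th)
    purrr::map_dfr(competitors, function(d) {
      purrr::map_dfr(c(d1, d2), function(side) {
        x <- fu[, d] - fu[, side]
        p <- if (family == "t")
          t.test(x, alternative = "greater")$p.value
        else wilcox.test(x, alternative = "greater", exact = FALSE)$p.value
        tibble::tibble(competitor = d, versus = side, p = p)
      })
    })
  })
  structure(list(candidate = candidate, pair = c(d1, d2),
                 variable = spec$name, p_values = pv,
                 retained = all(pv$p >= level), level = level,
                 family = family, n = n, seed = seed),
            class = "membership_test")
}

#' @method print membership_test
#' @export
print.membership_test <- function(x, ...) {
  cat(sprintf("<membership_test> %s = %.6g, pair (%s, %s): %s\n",
              x$variable, x$candidate, x$pair[1], x$pair[2],
              if (x$retained) "RETAINED" else "rejected"))
  if (nrow(x$p_values))
    print(as.data.frame(x$p_values), row.names = FALSE)
  invisible(x)
}

#' @describeIn test_membership Per-(competitor, side) p-values as a tibble.
#' @param x A `membership_test`.
#' @param ... Unused.
#' @method tidy membership_test
#' @export
tidy.membership_test <- function(x, ...) {
  dplyr::mutate(x$p_values, candidate = x$candidate, retained = x$retained,
                .before = 1)
}

# Run the membership test at each per-run final of a cluster and aggregate
# by the maximum p-value per (competitor, side): the candidate is rejected
# only when every run rejects.  Returns aggregated table + per-run details.
test_membership_runs <- function(model, j, finals, d1, d2, n = 1e4,
                                 level = 0.05, family = "t", seed = NULL) {
  tests <- lapply(seq_along(finals), function(r)
    test_membership(model, j, finals[r], d1, d2, n = n, level = level,
                    family = family,
                    seed = if (is.null(seed)) NULL
                           else derive_seed(seed, "membership", r)))
  per_run <- purrr::imap_dfr(tests, function(tt, r)
    dplyr::mutate(tidy(tt), run = r))
  agg <- if (nrow(per_run)) {
    per_run |>
      dplyr::group_by(.data$competitor, .data$versus) |>
      dplyr::summarise(p = max(.data$p), .groups = "drop")
  } else tibble::tibble(competitor = character(), versus = character(),
                        p = numeric())
  list(aggregated = agg, retained = all(agg$p >= level), per_run = per_run,
       tests = tests)
}

#' Assemble the threshold set for one variable
#'
#' Collects the retained candidate roots over all option pairs, sorts them,
#' and labels every open interval between consecutive elements (plus the two
#' unbounded tails) with its optimal option, decided by conditional-mean
#' dominance at a representative point: interval midpoints, and
#' `3 * sigma_j` beyond the extreme elements for the tails.  Dominance uses
#' `n_label`-sample conditional means with a 2-standard-error margin; ties
#' are flagged.  If two adjacent intervals receive the same label, the
#' separating element is collapsed out of the set with a warning.
#'
#' @inheritParams pairwise_diff_estimate
#' @param roots List of [estimate_pairwise_roots()] results for variable `j`
#'   (one per option pair), or a single such object.
#' @param membership Optional list of results from the membership post-
#'   processing, parallel to the candidate clusters: a data frame with
#'   columns `value` and `retained`.  When `NULL` and the model has more
#'   than two options, each cluster mean is tested with [test_membership()]
#'   at `n_test` samples; with two options all candidates are retained.
#' @param n_test,level,family Membership-test settings used when
#'   `membership` is `NULL`.
#' @param n_label Conditional sample size for interval labelling.
#' @return An object of class `threshold_set`: sorted retained `elements`
#'   (transform space), `elements_natural`, interval `labels` (length
#'   `length(elements) + 1`) and tie flags.  [tidy()] returns one row per
#'   interval.
#' @export
assemble_threshold_set <- function(model, j, roots, membership = NULL,
                                   n_test = 1e4, level = 0.05, family = "t",
                                   n_label = 1e4, seed = NULL) {
  stopifnot(inherits(model, "decision_model"))
  j <- var_index(model, j)
  spec <- model$variables[[j]]
  if (inherits(roots, "pairwise_roots")) roots <- list(roots)
  stopifnot(all(vapply(roots, inherits, TRUE, "pairwise_roots")))
  empty_cand <- tibble::tibble(value = numeric(), d1 = character(),
                               d2 = character())
  cand <- purrr::map_dfr(roots, function(r) {
    if (r$empty || !nrow(r$clusters)) return(empty_cand)
    tibble::tibble(value = r$clusters$estimate, d1 = r$pair[1],
                   d2 = r$pair[2])
  })
  if (!nrow(cand)) cand <- empty_cand
  if (is.null(membership)) {
    if (nrow(cand) == 0) {
      cand$retained <- logical()
    } else if (length(model$options) == 2) {
      cand$retained <- TRUE
    } else {
      cand$retained <- vapply(seq_len(nrow(cand)), function(i) {
        test_membership(model, j, cand$value[i], cand$d1[i], cand$d2[i],
                        n = n_test, level = level, family = family,
                        seed = if (is.null(seed)) NULL
                               else derive_seed(seed, "assemble", i)
        )$retained
      }, TRUE)
    }
  } else {
    membership <- as.data.frame(membership)
    stopifnot(all(c("value", "retained") %in% names(membership)))
    idx <- match(round(cand$value, 12), round(membership$value, 12))
    if (anyNA(idx))
      stop("membership table does not cover all candidates", call. = FALSE)
    cand$retained <- membership$retained[idx]
  }
  elements <- sort(cand$value[cand$retained])
  lab <- label_intervals(model, j, elements, n_label = n_label,
                         seed = if (is.null(seed)) NULL
                                else derive_seed(seed, "label"))
  labels <- lab$labels; ties <- lab$ties
  # collapse elements separating identically labelled intervals
  repeat {
    dup <- which(labels[-length(labels)] == labels[-1])
    if (!length(dup) || !length(elements)) break
    warning("adjacent intervals share optimal option '", labels[dup[1]],
            "'; collapsing separating element ", signif(elements[dup[1]], 6),
            call. = FALSE)
    elements <- elements[-dup[1]]
    labels <- labels[-dup[1]]
    ties <- ties[-dup[1]]
  }
  inv <- inv_transform_fun(spec$transform)
  structure(list(variable = spec$name, transform = spec$transform,
                 elements = elements, elements_natural = inv(elements),
                 labels = labels, ties = ties, candidates = cand,
                 seed = seed),
            class = "threshold_set")
}

#' Construct a threshold set directly
#'
#' Builds a `threshold_set` from known elements and interval labels, e.g.
#' thresholds taken from an external analysis, for use with
#' [decision_switching_probability()].  [assemble_threshold_set()] builds the
#' same structure from estimated pairwise roots.
#'
#' @param variable Variable name the set refers to.
#' @param elements Strictly increasing threshold elements in the variable's
#'   transform space (may be empty).
#' @param labels Optimal option on each of the `length(elements) + 1` open
#'   intervals, left to right.
#' @param transform `"identity"`, `"log"` or `"logit"`.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(variable, elements, labels,
                          transform = "identity") {
  elements <- as.numeric(elements)
  if (is.unsorted(elements, strictly = TRUE))
    stop("elements must be strictly increasing", call. = FALSE)
  if (length(labels) != length(elements) + 1)
    stop("need one label per interval (elements + 1)", call. = FALSE)
  if (length(elements) && any(labels[-1] == labels[-length(labels)]))
    warning("adjacent intervals share the same optimal option", call. = FALSE)
  inv <- inv_transform_fun(transform)
  structure(list(variable = variable, transform = transform,
                 elements = elements, elements_natural = inv(elements),
                 labels = as.character(labels),
                 ties = rep(FALSE, length(labels)),
                 candidates = NULL, seed = NULL),
            class = "threshold_set")
}

# Label the intervals delimited by `elements` (transform space) with the
# dominant option at a representative point each.
label_intervals <- function(model, j, elements, n_label = 1e4, seed = NULL,
                            margin_se = 2) {
  j <- var_index(model, j)
  spec <- model$variables[[j]]
  tm <- transformed_moments(spec)
  reps <- if (!length(elements)) tm[["mean"]] else {
    lo <- elements[1] - 3 * tm[["sd"]]
    hi <- elements[length(elements)] + 3 * tm[["sd"]]
    mids <- if (length(elements) > 1)
      (elements[-1] + elements[-length(elements)]) / 2 else numeric()
    c(lo, mids, hi)
  }
  smp <- conditional_sampler(model, j)
  inv <- inv_transform_fun(spec$transform)
  with_seed(seed, {
    labs <- character(length(reps)); ties <- logical(length(reps))
    for (i in seq_along(reps)) {
      th <- smp(rep(clamp_support(spec, inv(reps[i])), n_label))
      fu <- utility_matrix(model, th)
      mu <- colMeans(fu)
      top <- order(mu, decreasing = TRUE)[1:2]
      se_gap <- sd(fu[, top[1]] - fu[, top[2]]) / sqrt(n_label)
      labs[i] <- model$options[top[1]]
      ties[i] <- (mu[top[1]] - mu[top[2]]) < margin_se * se_gap
      if (ties[i])
        warning("near-tie when labelling interval ", i, " of variable '",
                spec$name, "'", call. = FALSE)
    }
    list(labels = labs, ties = ties)
  })
}

#' @method print threshold_set
#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> %s (%s space): %d element(s)\n",
              x$variable, x$transform, length(x$elements)))
  print(as.data.frame(tidy(x)), row.names = FALSE)
  invisible(x)
}

#' @describeIn assemble_threshold_set One row per interval: bounds in
#'   transform and natural space and the optimal option.
#' @param x A `threshold_set`.
#' @param ... Unused.
#' @method tidy threshold_set
#' @export
tidy.threshold_set <- function(x, ...) {
  k <- length(x$elements)
  lower <- c(-Inf, x$elements)
  upper <- c(x$elements, Inf)
  inv <- inv_transform_fun(x$transform)
  tibble::tibble(variable = x$variable, lower = lower, upper = upper,
                 lower_natural = inv(lower), upper_natural = inv(upper),
                 optimal = x$labels, tie = x$ties)
}

#' @describeIn assemble_threshold_set One-row summary.
#' @method glance threshold_set
#' @export
glance.threshold_set <- function(x, ...) {
  tibble::tibble(variable = x$variable, transform = x$transform,
                 n_elements = length(x$elements),
                 elements = paste(signif(x$elements, 6), collapse = ", "),
                 labels = paste(x$labels, collapse = " | "))
}

# Canonical unordered option pairs of a model.
option_pairs <- function(model) {
  d <- model$options
  if (length(d) < 2) return(list())
  out <- list()
  for (i in seq_along(d)) for (k in seq_along(d))
    if (i < k) out[[length(out) + 1]] <- c(d[i], d[k])
  out
}
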