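# Campaign driver: run the full pairwise-SA threshold pipeline over a set of
# variables, with reproducible per-pair sub-seeding and optional on-disk
# serialisation.  This is the programmatic surface behind the command-line
# front-end shipped in inst/cli/.

#' Run a full threshold-analysis campaign
#'
#' For every requested variable and every (canonical, unordered) option pair:
#' run `n_runs` independent stochastic-approximation searches
#' ([estimate_pairwise_roots()]), post-process each non-empty cluster with
#' per-run membership tests aggregated by the maximum p-value
#' ([test_membership()]), assemble the threshold set
#' ([assemble_threshold_set()]), and compute the decision switching
#' probability ([decision_switching_probability()]).  Each (variable, pair)
#' stream is seeded by [derive_seed()] from the master seed, so any single
#' run is reproducible in isolation; per-variable failures are caught and
#' reported, not fatal.
#'
#' @inheritParams sample_prior
#' @param variables Character vector of variable names to analyse (empty is
#'   allowed and yields an empty campaign).
#' @param n_runs Independent SA runs per option pair (default 20).
#' @param n_iter SA iterations per run (default 10^4).
#' @param m_inner Conditional samples per SA iteration (default 1).
#' @param n_test Conditional sample size per membership test (default 10^4).
#' @param level Significance level of the membership tests.
#' @param family Membership test family, `"t"` or `"wilcoxon"`.
#' @param step_multipliers Optional named numeric vector of per-variable
#'   step-scale multipliers (see [sa_config()]); variables not named get 1.
#' @param seed Master seed (integer).
#' @param keep_traces Keep full iterate histories (memory heavy).
#' @return An object of class `threshold_campaign`.  [tidy()] returns the
#'   per-pair root summary (one row per cluster, with aggregated membership
#'   p-values); [glance()] the per-variable threshold sets with DSP.
#' @export
threshold_campaign <- function(model, variables, n_runs = 20, n_iter = 1e4,
                               m_inner = 1, n_test = 1e4, level = 0.05,
                               family = "t", step_multipliers = NULL,
                               seed = 1, keep_traces = FALSE) {
  stopifnot(inherits(model, "decision_model"))
  variables <- as.character(variables)
  bad <- setdiff(variables, names(model$variables))
  if (length(bad))
    stop("unknown variable(s): ", paste(bad, collapse = ", "), call. = FALSE)
  prior <- prior_optimal(model, n = 2^16, seed = derive_seed(seed, "prior"))
  pairs <- option_pairs(model)
  per_var <- list()
  for (v in variables) {
    per_var[[v]] <- tryCatch({
      mult <- 1
      if (!is.null(step_multipliers) && v %in% names(step_multipliers))
        mult <- step_multipliers[[v]]
      cfg <- sa_config(n_iter = n_iter, m_inner = m_inner,
                      step_multiplier = mult)
      roots <- list(); memb <- list()
      for (p in pairs) {
        key <- paste(p, collapse = ",")
        pr <- estimate_pairwise_roots(
          model, v, p[1], p[2], n_runs = n_runs, config = cfg,
          seed = derive_seed(seed, v, p[1], p[2]),
          keep_traces = keep_traces)
        roots[[key]] <- pr
        if (!pr$empty && length(model$options) > 2) {
          memb[[key]] <- lapply(seq_len(nrow(pr$clusters)), function(ci) {
            finals <- cluster_members(pr, ci)
            test_membership_runs(model, v, finals, p[1], p[2], n = n_test,
                                 level = level, family = family,
                                 seed = derive_seed(seed, v, key,
                                                    "membership", ci))
          })
        }
      }
      # candidate retention table for assembly
      cand <- purrr::imap_dfr(roots, function(r, key) {
        if (r$empty || !nrow(r$clusters)) return(tibble::tibble())
        retained <- if (length(model$options) == 2)
          rep(TRUE, nrow(r$clusters))
        else vapply(seq_len(nrow(r$clusters)),
                    function(ci) memb[[key]][[ci]]$retained, TRUE)
        tibble::tibble(value = r$clusters$estimate, retained = retained)
      })
      ts <- assemble_threshold_set(model, v, roots,
                                   membership = cand,
                                   n_label = n_test,
                                   seed = derive_seed(seed, v, "assemble"))
      dsp <- decision_switching_probability(model, v, ts,
                                            d_opt = prior$optimal)
      list(roots = roots, membership = memb, thresholds = ts, dsp = dsp,
           error = NULL)
    }, error = function(e) list(roots = NULL, membership = NULL,
                                thresholds = NULL, dsp = NA_real_,
                                error = conditionMessage(e)))
  }
  cfg_rec <- list(variables = variables, n_runs = n_runs, n_iter = n_iter,
                  m_inner = m_inner, n_test = n_test, level = level,
                  family = family,
                  step_multipliers = as.list(step_multipliers %||% list()),
                  seed = seed)
  structure(list(model_options = model$options, prior = prior,
                 results = per_var, config = cfg_rec,
                 config_hash = config_hash(cfg_rec), seed = seed),
            class = "threshold_campaign")
}

# Per-run finals assigned to cluster ci by nearest cluster estimate.
cluster_members <- function(pr, ci) {
  if (nrow(pr$clusters) == 1) return(pr$finals)
  assign <- apply(abs(outer(pr$finals, pr$clusters$estimate, "-")), 1,
                  which.min)
  pr$finals[assign == ci]
}

#' @method print threshold_campaign
#' @export
print.threshold_campaign <- function(x, ...) {
  cat(sprintf(
    "<threshold_campaign> %d variable(s), prior optimum %s, seed %d [%s]\n",
    length(x$results), x$prior$optimal, x$seed, x$config_hash))
  g <- glance(x)
  if (nrow(g)) print(as.data.frame(g), row.names = FALSE)
  invisible(x)
}

#' @describeIn threshold_campaign Per-pair cluster summary: estimate, spread,
#'   empty flag, aggregated membership p-values and retention.
#' @param x A `threshold_campaign`.
#' @param ... Unused.
#' @method tidy threshold_campaign
#' @export
tidy.threshold_campaign <- function(x, ...) {
  purrr::imap_dfr(x$results, function(res, v) {
    if (!is.null(res$error))
      return(tibble::tibble(variable = v, error = res$error))
    purrr::imap_dfr(res$roots, function(r, key) {
      base <- glance(r)
      if (r$empty) return(dplyr::mutate(base, p_aggregated = NA_character_,
                                        retained = FALSE))
      pstr <- vapply(seq_len(nrow(r$clusters)), function(ci) {
        mm <- res$membership[[key]]
        if (is.null(mm)) return("")
        format_pvals(mm[[ci]]$aggregated)
      }, "")
      ret <- vapply(seq_len(nrow(r$clusters)), function(ci) {
        mm <- res$membership[[key]]
        if (is.null(mm)) TRUE else mm[[ci]]$retained
      }, TRUE)
      dplyr::mutate(base, p_aggregated = pstr, retained = ret)
    })
  })
}

format_pvals <- function(agg) {
  if (!nrow(agg)) return("")
  paste(vapply(split(agg, agg$competitor), function(d)
    sprintf("%s: (%.3g, %.3g)", d$competitor[1], d$p[1], d$p[2]), ""),
    collapse = "; ")
}

#' @describeIn threshold_campaign Per-variable threshold summary with DSP.
#' @method glance threshold_campaign
#' @export
glance.threshold_campaign <- function(x, ...) {
  purrr::imap_dfr(x$results, function(res, v) {
    if (!is.null(res$error))
      return(tibble::tibble(variable = v, n_elements = NA_integer_,
                            elements = NA_character_, labels = NA_character_,
                            dsp = NA_real_, error = res$error))
    dplyr::mutate(glance(res$thresholds), dsp = res$dsp,
                  error = NA_character_)
  })
}

#' Run a campaign from a configuration object or file
#'
#' Thin wrapper used by the command-line front-end: reads a configuration
#' (an R list or a YAML file) with fields `model` (`"builtin"` or a model
#' config path), `variables`, and optional campaign parameters (`n_runs`,
#' `n_iter`, `m_inner`, `n_test`, `level`, `family`, `step_multipliers`,
#' `seed`, `out_dir`), validates it before any computation, runs
#' [threshold_campaign()], and serialises results with [write_campaign()]
#' when `out_dir` is set.  Rerunning the same configuration reproduces all
#' outputs byte-identically.
#'
#' @param config Named list or path to a YAML file.
#' @return The `threshold_campaign`, invisibly when written to disk.
#' @export
run_campaign <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("model", "variables", "n_runs", "n_iter", "m_inner", "n_test",
             "level", "family", "step_multipliers", "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$model)) stop("config needs a 'model'", call. = FALSE)
  model <- if (identical(config$model, "builtin")) three_treatment_model()
           else read_model_config(config$model)
  camp <- threshold_campaign(
    model,
    variables = unlist(config$variables %||% character()),
    n_runs = config$n_runs %||% 20, n_iter = config$n_iter %||% 1e4,
    m_inner = config$m_inner %||% 1, n_test = config$n_test %||% 1e4,
    level = config$level %||% 0.05, family = config$family %||% "t",
    step_multipliers = unlist(config$step_multipliers %||% NULL),
    seed = config$seed %||% 1)
  if (!is.null(config$out_dir)) {
    write_campaign(camp, config$out_dir)
    return(invisible(camp))
  }
  camp
}

#' Serialise a campaign to disk
#'
#' Writes `summary.json` (config, seed, config hash, per-pair roots,
#' per-variable thresholds and DSP), `pairwise.csv` and `thresholds.csv`
#' (the [tidy()]/[glance()] tables) and a human-readable `report.txt` into
#' `dir`.  No timestamps are embedded: identical campaigns serialise to
#' byte-identical files.
#'
#' @param campaign A [threshold_campaign()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "threshold_campaign"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  td <- tidy(campaign); gl <- glance(campaign)
  summary <- list(
    schema_version = 1L,
    config = campaign$config,
    config_hash = campaign$config_hash,
    prior_optimal = campaign$prior$optimal,
    pairwise = td,
    thresholds = purrr::imap(campaign$results, function(res, v) {
      if (!is.null(res$error)) return(list(error = res$error))
      ts <- res$thresholds
      list(elements_transformed = ts$elements,
           elements_natural = ts$elements_natural,
           labels = ts$labels, dsp = res$dsp)
    }))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(as.data.frame(td), file.path(dir, "pairwise.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(gl), file.path(dir, "thresholds.csv"),
            row.names = FALSE)
  lines <- c(sprintf("threshold campaign (seed %d, config %s)",
                     campaign$seed, campaign$config_hash),
             sprintf("prior optimal option: %s", campaign$prior$optimal),
             "", utils::capture.output(print(as.data.frame(gl),
                                             row.names = FALSE)))
  writeLines(lines, file.path(dir, "report.txt"))
  # per-run trace files when histories were kept
  for (v in names(campaign$results)) {
    res <- campaign$results[[v]]
    if (is.null(res$roots)) next
    for (key in names(res$roots)) {
      r <- res$roots[[key]]
      if (is.null(r$traces)) next
      for (i in seq_along(r$traces)) {
        f <- file.path(dir, sprintf("trace_%s_%s_run%02d.csv", v,
                                    gsub(",", "-", key), i))
        write.csv(as.data.frame(tidy(r$traces[[i]])), f, row.names = FALSE)
      }
    }
  }
  invisible(dir)
}
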