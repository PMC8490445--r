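# Config-file round trip for decision models.  The document has sections
# options / variables / blocks / constants / plugin_means / utility; the
# utility is referenced by registry name (shipped models) or supplied as an
# R function when reading a user config.

#' Write a decision model to a YAML config file
#'
#' All distributional information round-trips exactly; the utility function
#' itself is stored by registry name (for shipped utilities such as the
#' built-in model's) and must otherwise be re-supplied when reading.
#'
#' @param model A [decision_model()].
#' @param path Output file path (YAML).
#' @return `path`, invisibly.
#' @seealso [read_model_config()]
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "decision_model"))
  # numeric leaves are written as 17-significant-digit strings so doubles
  # survive the round trip bit-exactly (YAML emitters round earlier)
  num <- function(x) vapply(x, function(e) format(e, digits = 17), "")
  doc <- list(
    options = as.list(model$options),
    variables = lapply(model$variables, function(v)
      list(name = v$name, family = v$family,
           params = lapply(v$params, num), transform = v$transform)),
    blocks = lapply(model$blocks, function(b)
      list(members = as.list(b$members), mu = as.list(num(b$mu)),
           sigma = lapply(seq_len(2),
                          function(i) as.list(num(b$sigma[i, ]))))),
    constants = lapply(model$constants,
                       function(x) if (is.numeric(x)) num(x) else x),
    plugin_means = as.list(num(model$plugin_means)),
    utility = if (!is.null(model$utility_name)) model$utility_name else "user"
  )
  names(doc$variables) <- NULL
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a decision model from a YAML config file
#'
#' @param path Config file path written by [write_model_config()] or by hand.
#' @param utility Optional utility function satisfying the
#'   [decision_model()] contract; required unless the config references a
#'   shipped utility by name.
#' @return A [decision_model()].
#' @export
read_model_config <- function(path, utility = NULL) {
  doc <- yaml::read_yaml(path)
  for (f in c("options", "variables"))
    if (is.null(doc[[f]])) stop("config is missing section '", f, "'",
                                call. = FALSE)
  vars <- lapply(doc$variables, function(v)
    marginal_spec(v$name, v$family,
                  vapply(unlist(v$params), as.numeric, 1), v$transform))
  blocks <- lapply(doc$blocks %||% list(), function(b)
    correlated_block(unlist(b$members), as.numeric(unlist(b$mu)),
                     matrix(as.numeric(unlist(b$sigma)), 2, 2,
                            byrow = TRUE)))
  if (is.null(utility)) {
    if (is.null(doc$utility) || identical(doc$utility, "user"))
      stop("config does not name a shipped utility; pass `utility=`",
           call. = FALSE)
    uname <- doc$utility
    utility <- utility_registry(uname)
  } else {
    uname <- if (is.character(doc$utility) && doc$utility != "user")
      doc$utility else NULL
  }
  maybe_num <- function(x) {
    if (is.character(x) && !is.na(suppressWarnings(as.numeric(x))))
      as.numeric(x) else x
  }
  plug <- unlist(doc$plugin_means %||% list())
  plug <- if (is.null(plug)) numeric()
          else setNames(as.numeric(plug), names(plug))
  decision_model(options = unlist(doc$options), variables = vars,
                 utility = utility, blocks = blocks,
                 constants = lapply(doc$constants %||% list(), maybe_num),
                 plugin_means = plug,
                 utility_name = if (is.character(doc$utility) &&
                                    doc$utility != "user") doc$utility)
}

#' Export parameter samples to CSV
#'
#' One column per input variable (header = variable names), natural space.
#'
#' @param samples Tibble from [sample_prior()] / [sample_conditional()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(samples, path) {
  write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
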