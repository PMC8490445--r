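#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Campaigns fan out into many independent random streams (one per variable,
#' option pair and run block).  `derive_seed()` maps a master seed plus an
#' arbitrary sequence of labels to a stable 31-bit integer seed, so that any
#' single piece of a campaign can be reproduced in isolation from the records
#' in its output files.
#'
#' The derivation is a plain polynomial rolling hash over the UTF-8 bytes of
#' the label string, modulo a prime below `2^31`; it is platform independent
#' and has no dependence on R's RNG state.
#'
#' @param master Integer master seed.
#' @param ... Further labels (coerced to character) identifying the stream,
#'   e.g. variable name, option pair, run index.
#' @return A single integer in `[0, 2^31)` usable with [set.seed()].
#' @examples
#' derive_seed(1, "Q_SE", "d1", "d2")
#' @export
derive_seed <- function(master, ...) {
  stopifnot(length(master) == 1, is.finite(master))
  lab <- paste(c(format(as.integer(master)), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Run `code` under a temporary RNG state seeded with `seed` (if non-NULL),
# restoring the caller's state afterwards.  NULL means: use the current
# global stream (and advance it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Stable short hash of an R object (used to stamp configs into outputs).
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "niceNames")), collapse = "")
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 2147483629
  sprintf("%08x", h)
}
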