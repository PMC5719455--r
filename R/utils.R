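# Internal helpers shared across modules.

#' Derive a named RNG substream seed from a master seed
#'
#' Each stochastic stage of the pipeline (ancestral frequencies, ancestry
#' fractions, genotypes, missingness, catalog decoys, resampling) seeds its
#' own substream from the master seed and a stage name, so changing the
#' parameters of one stage never perturbs the draws of another.
#'
#' @param seed master integer seed.
#' @param name character stage name.
#' @return an integer seed in [0, 2^31 - 2], deterministic in (seed, name).
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483629 # largest prime < 2^31
  h <- as.double(seed) %% m
  for (code in utf8ToInt(name)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a substream seed without disturbing the caller's RNG.
with_substream <- function(seed, name, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(substream_seed(seed, name))
  expr
}

# Consistent stderr logging for dropped records and stage progress.
log_note <- function(...) {
  inform(paste0(...), class = "admixrisk_note")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_prob <- function(x, what, open_upper = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
    if (open_upper) all(x < 1) else all(x <= 1)
  if (!ok) abort(paste0(what, " must lie in [0, 1", if (open_upper) ")" else "]"))
  invisible(x)
}
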