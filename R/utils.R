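#' Derive a stage seed from a master seed
#'
#' All stochastic stages draw their seed deterministically from one master
#' seed, so that a single integer reproduces an entire run. The derived
#' seed stays below 2^31 - 1.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage label (hashed into an offset) or an integer
#'   offset.
#' @return An integer seed.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  if (is.character(stage)) {
    offset <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    offset <- as.integer(stage)
  }
  as.integer((abs(master_seed) %% 1000003L) * 1009L + offset %% 100000L)
}

# run `expr` under a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
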