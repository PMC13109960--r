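# small internal helpers

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a stage seed from a global seed
#'
#' Deterministically maps a (global seed, stage tag) pair to a 32-bit integer
#' seed, so that every random stage of an experiment consumes its own
#' reproducible stream.
#'
#' @param seed Integer global seed.
#' @param tag Character stage tag.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
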