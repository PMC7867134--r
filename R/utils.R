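# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so stochastic stages never
#' perturb each other's streams.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' Deterministic and stable: adding a new stage tag never changes the
#' sub-seed of an existing one. Result is a positive 32-bit integer.
#' @param seed master integer seed
#' @param tag character stage label
#' @keywords internal
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629L + 1)
}

#' @keywords internal
sigmoid <- function(x) {
  # numerically stable logistic
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' @keywords internal
msg <- function(...) message("[ilc2gate] ", sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a
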