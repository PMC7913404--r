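#' Inverse logit
#'
#' @param x numeric vector on the logit scale.
#' @return probabilities in (0, 1).
#' @export
expit <- function(x) 1 / (1 + exp(-x))

#' Logit
#'
#' @param p probabilities in (0, 1).
#' @return numeric vector on the logit scale.
#' @export
logit <- function(p) log(p) - log1p(-p)

## Run `code` under set.seed(seed), restoring the caller's RNG state.
## seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

## Deterministic per-task seed stream: base seed -> n child seeds < 2^31.
derive_seeds <- function(base_seed, n) {
  with_seed(base_seed, sample.int(.Machine$integer.max, n))
}

stop_if_not <- function(cond, ...) {
  if (!cond) stop(sprintf(...), call. = FALSE)
}
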