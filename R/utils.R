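#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Clip probabilities away from 0 and 1
#' @noRd
clip_prob <- function(p, eps = 1e-15) pmin(pmax(p, eps), 1 - eps)

#' Mean binary log loss with clipped probabilities
#'
#' @param labels 0/1 vector.
#' @param probs predicted probabilities of class 1.
#' @param eps clipping bound applied to `probs` before taking logs.
#' @return Mean of `-[y log p + (1-y) log(1-p)]`.
#' @export
log_loss <- function(labels, probs, eps = 1e-15) {
  stopifnot(length(labels) == length(probs), all(labels %in% c(0, 1)))
  p <- clip_prob(probs, eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Run code under a temporary RNG seed
#'
#' Evaluates `code` with the RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards, so seeded helpers do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
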