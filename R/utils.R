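#' Highest-density interval of a sample
#'
#' Shortest interval containing `prob` of the draws (assumes a unimodal
#' posterior, as is standard for reporting HDIs from MCMC output).
#'
#' @param x numeric vector of draws.
#' @param prob probability mass to cover (default 0.95).
#' @return named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.95) {
  stopifnot(is.numeric(x), length(x) > 0, prob > 0, prob <= 1)
  x <- sort(x[is.finite(x)])
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  w <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(w)
  c(lower = x[i], upper = x[i + m])
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  expr
}

# correlation matrix from SDs + covariance lower triangle helpers
sds_from_cov <- function(S) sqrt(diag(S))
cors_from_cov <- function(S) stats::cov2cor(S)[lower.tri(S)]
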