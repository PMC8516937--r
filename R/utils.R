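# Internal helpers shared across modules.

## Matrix exponential of a rate matrix.
## Eigendecomposition route; falls back to scaling-and-squaring with a Taylor
## series when Q is defective or the eigenbasis is ill-conditioned.
expm_q <- function(Q, t) {
  k <- nrow(Q)
  if (t == 0) return(diag(k))
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(eg)) {
    V <- eg$vectors
    rc <- tryCatch(rcond(V), error = function(e) 0)
    if (is.finite(rc) && rc > 1e-10) {
      Vi <- solve(V)
      P <- Re(V %*% (exp(eg$values * t) * Vi))
      P[P < 0] <- 0
      return(P / rowSums(P))
    }
  }
  expm_ss(Q * t)
}

## Scaling-and-squaring with truncated Taylor series; adequate for the small
## (k <= 4) generators used here.
expm_ss <- function(A) {
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  A <- A / 2^s
  k <- nrow(A)
  P <- diag(k)
  term <- diag(k)
  for (i in 1:16) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

## Eigen-cache for repeated P(t) on one Q: returns function(t) -> P(t).
make_pmat <- function(Q) {
  k <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(eg)) {
    rc <- tryCatch(rcond(eg$vectors), error = function(e) 0)
    ok <- is.finite(rc) && rc > 1e-10
  }
  if (ok) {
    V <- eg$vectors
    Vi <- solve(V)
    d <- eg$values
    function(t) {
      if (t == 0) return(diag(k))
      P <- Re(V %*% (exp(d * t) * Vi))
      P[P < 0] <- 0
      P / rowSums(P)
    }
  } else {
    function(t) if (t == 0) diag(k) else expm_ss(Q * t)
  }
}

## Derive a stream of child seeds from one parent seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 104729L * seq_len(n)) %% 2147483647L
}

## Run expr with a locally-set RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## log(sum(exp(x))) without overflow.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Effective sample size of an MCMC trace from its autocorrelation
## (initial-positive-sequence truncation).
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(ac))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
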