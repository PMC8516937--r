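## Binary-state speciation-extinction (BiSSE) likelihood. On an ultrametric
## extant-only tree the extinction probabilities E0(t), E1(t) depend only on
## time before present, so they are solved once on a global grid (reference
## integration by deSolve); the linear D-system is then propagated along each
## branch with a fixed-step RK4 using the interpolated E(t).

bisse_par_names <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")

validate_bisse_pars <- function(pars) {
  if (is.null(names(pars))) names(pars) <- bisse_par_names
  miss <- setdiff(bisse_par_names, names(pars))
  if (length(miss)) stopf("missing BiSSE parameter(s): %s",
                          paste(miss, collapse = ", "))
  if (any(pars[bisse_par_names] < 0)) stopf("BiSSE rates must be >= 0")
  pars[bisse_par_names]
}

## E0/E1 on a time grid from the present (t = 0) to the root age. Internal.
bisse_e_grid <- function(pars, rho, t_max, n_grid = 400, rtol = 1e-8) {
  la <- pars[c("lambda0", "lambda1")]
  mu <- pars[c("mu0", "mu1")]
  q <- c(pars["q01"], pars["q10"])
  deriv <- function(t, E, parms) {
    dE <- mu - (la + mu + q) * E + la * E^2 + q * rev(E)
    list(dE)
  }
  times <- seq(0, max(t_max, 1e-8), length.out = n_grid)
  sol <- deSolve::lsoda(y = c(1 - rho, 1 - rho), times = times, func = deriv,
                        parms = NULL, rtol = rtol, atol = 1e-10)
  E <- pmin(pmax(sol[, 2:3, drop = FALSE], 0), 1)
  list(times = times,
       E0 = stats::approxfun(times, E[, 1], rule = 2),
       E1 = stats::approxfun(times, E[, 2], rule = 2),
       E0v = E[, 1], E1v = E[, 2],
       dtE = times[2] - times[1], nE = length(times))
}

## Exact exponential of the 2x2 D-system generator frozen at the segment
## midpoint: for segments no longer than one grid cell the coefficients
## (which vary only through the slowly-changing E(t)) are effectively
## constant, giving a midpoint-exponential propagator with local error
## O(len^3). Entries of A: [a0 + l20*E0, q01; q10, a1 + l21*E1]. Internal.
bisse_segment_matrix <- function(t0, t1, cf) {
  len <- t1 - t0
  tm <- (t0 + t1) / 2
  x <- tm / cf$dtE
  i <- floor(x)
  if (i >= cf$nE - 1) i <- cf$nE - 2
  w <- x - i
  E0 <- cf$E0v[i + 1] * (1 - w) + cf$E0v[i + 2] * w
  E1 <- cf$E1v[i + 1] * (1 - w) + cf$E1v[i + 2] * w
  a11 <- cf$a0 + cf$l20 * E0
  a22 <- cf$a1 + cf$l21 * E1
  a12 <- cf$q01
  a21 <- cf$q10
  m <- (a11 + a22) / 2
  p <- (a11 - a22) / 2
  s2 <- p * p + a12 * a21
  st <- sqrt(max(s2, 0)) * len
  if (st > 1e-6) {
    ch <- cosh(st); sh_s <- sinh(st) / (st / len)   # sinh(s len)/s
  } else {
    ch <- 1 + st^2 / 2; sh_s <- len * (1 + st^2 / 6)
  }
  e <- exp(m * len)
  ## entries (m11, m21, m12, m22) as a plain vector: this sits on the
  ## innermost loop of the likelihood, where matrix allocation dominates
  c(e * (ch + sh_s * p), e * sh_s * a21,
    e * sh_s * a12, e * (ch - sh_s * p))
}

## Propagate (D0, D1) from t0 to t1: midpoint-exponential steps for the
## partial cells at the branch ends, precomputed cell propagators for the
## fully covered cells between, all unrolled as scalar arithmetic (this is
## the innermost loop of the likelihood). Internal.
bisse_propagate <- function(D, t0, t1, cf, cells) {
  if (t1 - t0 <= 1e-14) return(D)
  ch <- cells$h
  d0 <- D[1]; d1 <- D[2]
  i0 <- min(floor(t0 / ch + 1e-12), cells$n - 1)
  i1 <- min(floor(t1 / ch - 1e-12), cells$n - 1)
  if (i1 <= i0) {
    S <- bisse_segment_matrix(t0, t1, cf)
    return(c(S[1] * d0 + S[3] * d1, S[2] * d0 + S[4] * d1))
  }
  S <- bisse_segment_matrix(t0, (i0 + 1) * ch, cf)
  tmp <- S[1] * d0 + S[3] * d1; d1 <- S[2] * d0 + S[4] * d1; d0 <- tmp
  if (i1 > i0 + 1) {
    M_list <- cells$M
    for (i in (i0 + 2):i1) {
      M <- M_list[[i]]
      tmp <- M[1] * d0 + M[3] * d1; d1 <- M[2] * d0 + M[4] * d1; d0 <- tmp
    }
  }
  S <- bisse_segment_matrix(i1 * ch, t1, cf)
  c(S[1] * d0 + S[3] * d1, S[2] * d0 + S[4] * d1)
}

## Per-cell propagators of the linear D-system on a global time grid:
## M_i maps D(t_i) to D(t_{i+1}); shared by every branch. Internal.
bisse_cell_propagators <- function(cf, t_max, n_cells) {
  h <- t_max / n_cells
  M <- vector("list", n_cells)
  for (i in seq_len(n_cells))
    M[[i]] <- bisse_segment_matrix((i - 1) * h, i * h, cf)
  list(M = M, h = h, n = n_cells)
}

#' BiSSE log-likelihood
#'
#' Likelihood of a binary tip character and tree shape under the binary-state
#' speciation-extinction model: extinction probabilities are integrated once
#' on a global time grid, the D (data) system is propagated along each branch
#' and recombined at nodes with the speciation rate of the node state, and
#' the root is treated by likelihood-weighted state averaging (FitzJohn) or a
#' flat prior. Requires an ultrametric, strictly binary, extant-only tree;
#' incomplete sampling enters through `rho`.
#'
#' @param tree ultrametric binary `phylo`.
#' @param states named 0/1 vector (or binary trait frame from [binarize()]).
#' @param pars named vector `lambda0, lambda1, mu0, mu1, q01, q10` (1/My).
#' @param rho sampling fraction in (0, 1].
#' @param root `"fitzjohn"` (default) or `"flat"`.
#' @param condition `"none"` (default) or `"survival"` (divides by the
#'   probability that both root lineages survive to the present).
#' @param n_grid,h_frac integration controls: E-grid resolution and the RK4
#'   step as a fraction of tree height.
#' @return log-likelihood (scalar).
#' @export
bisse_loglik <- function(tree, states, pars, rho = 1,
                         root = c("fitzjohn", "flat"),
                         condition = c("none", "survival"),
                         n_grid = 400, h_frac = 1 / 200) {
  root <- match.arg(root)
  condition <- match.arg(condition)
  pars <- validate_bisse_pars(pars)
  if (rho <= 0 || rho > 1) stopf("rho must be in (0, 1]")
  if (!is_binary_tree(tree)) stopf("tree must be strictly binary")
  if (is.data.frame(states)) states <- stats::setNames(states$state, states$species)
  age <- node_ages(tree)
  n_tip <- length(tree$tip.label)
  if (any(age[seq_len(n_tip)] > 1e-6 * max(age)))
    stopf("tree must be ultrametric and extant-only (fossil tips found)")
  s <- states[tree$tip.label]
  if (anyNA(s)) stopf("tip(s) missing a state")
  if (!all(s %in% c(0, 1, "0", "1"))) stopf("states must be coded 0/1")
  s <- as.integer(as.character(s))

  t_max <- max(age)
  Ef <- bisse_e_grid(pars, rho, t_max, n_grid)
  la <- pars[c("lambda0", "lambda1")]
  mu <- pars[c("mu0", "mu1")]
  cf <- list(a0 = -(la[[1]] + mu[[1]] + pars[["q01"]]),
             a1 = -(la[[2]] + mu[[2]] + pars[["q10"]]),
             q01 = pars[["q01"]], q10 = pars[["q10"]],
             l20 = 2 * la[[1]], l21 = 2 * la[[2]],
             E0v = Ef$E0v, E1v = Ef$E1v, dtE = Ef$dtE, nE = Ef$nE)
  cells <- bisse_cell_propagators(cf, t_max, max(50L, round(1 / h_frac)))
  ch <- cells$h

  propagate <- function(D, t0, t1) bisse_propagate(D, t0, t1, cf, cells)

  n_node <- n_tip + tree$Nnode
  D <- matrix(0, n_node, 2)
  D[cbind(seq_len(n_tip), s + 1L)] <- rho
  logcomp <- numeric(n_node)
  prodv <- matrix(1, n_node, 2)
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    a <- po$edge[i, 1]; b <- po$edge[i, 2]
    ## node recombination: D at an internal child is la * product of its
    ## (already accumulated, postorder-complete) daughter messages
    if (b > n_tip) D[b, ] <- la * prodv[b, ]
    Db <- as.vector(propagate(D[b, ], age[b], age[a]))
    Db <- pmax(Db, 0)
    sc <- max(Db)
    if (sc <= 0 || !is.finite(sc)) return(-Inf)
    prodv[a, ] <- prodv[a, ] * (Db / sc)
    logcomp[a] <- logcomp[a] + logcomp[b] + log(sc)
  }
  rt <- n_tip + 1L
  Droot <- prodv[rt, ]   # product of the two root daughters (no extra la)
  E_root <- c(Ef$E0(t_max), Ef$E1(t_max))
  w <- switch(root,
              fitzjohn = if (sum(Droot) > 0) Droot / sum(Droot) else c(0.5, 0.5),
              flat = c(0.5, 0.5))
  Dr <- Droot
  if (condition == "survival") Dr <- Dr / (la * (1 - E_root)^2)
  val <- sum(w * Dr)
  if (val <= 0) return(-Inf)
  log(val) + logcomp[rt]
}

#' Fit the BiSSE model by maximum likelihood
#'
#' Bounded optimisation over log-rates with constraint specs tying rates
#' across states. `"full"` frees all six rates; `"null_lambda"` ties
#' `lambda0 = lambda1`; `"null_mu"` ties `mu0 = mu1`; `"null"` ties both
#' (the trait-independent null used for Akaike-weight comparison).
#'
#' @inheritParams bisse_loglik
#' @param constraint `"full"`, `"null_lambda"`, `"null_mu"`, or `"null"`.
#' @param lower,upper rate bounds (1/My).
#' @param h_frac integration resolution used during optimisation (slightly
#'   coarser than the [bisse_loglik()] default; the likelihood surface is
#'   smooth in the grid so the optimum is unaffected at this scale).
#' @return `bisse_fit`: `pars` (full named vector), `loglik`, `n_par`,
#'   `AIC`, `constraint`, `convergence`.
#' @export
fit_bisse <- function(tree, states, constraint = c("full", "null_lambda",
                                                   "null_mu", "null"),
                      rho = 1, root = "fitzjohn", condition = "none",
                      lower = 1e-6, upper = 10, h_frac = 1 / 100) {
  constraint <- match.arg(constraint)
  if (is.data.frame(states)) states <- stats::setNames(states$state, states$species)
  tie_lambda <- constraint %in% c("null_lambda", "null")
  tie_mu <- constraint %in% c("null_mu", "null")
  free <- c(if (tie_lambda) "lambda" else c("lambda0", "lambda1"),
            if (tie_mu) "mu" else c("mu0", "mu1"),
            "q01", "q10")
  expand <- function(x) {
    names(x) <- free
    c(lambda0 = unname(if (tie_lambda) x["lambda"] else x["lambda0"]),
      lambda1 = unname(if (tie_lambda) x["lambda"] else x["lambda1"]),
      mu0 = unname(if (tie_mu) x["mu"] else x["mu0"]),
      mu1 = unname(if (tie_mu) x["mu"] else x["mu1"]),
      q01 = unname(x["q01"]), q10 = unname(x["q10"]))
  }
  obj <- function(logx) {
    ll <- bisse_loglik(tree, states, expand(exp(logx)), rho, root, condition,
                       h_frac = h_frac)
    if (!is.finite(ll)) 1e10 else -ll
  }
  ## moment start: Yule rate from tip count and height, modest mu and q
  n_tip <- length(tree$tip.label)
  h <- max(node_ages(tree))
  la0 <- max(log(max(n_tip, 3) / 2) / h, 1e-3)
  start <- c(if (tie_lambda) la0 else c(la0, la0),
             if (tie_mu) la0 / 5 else c(la0 / 5, la0 / 5),
             la0 / 10, la0 / 10)
  fit <- stats::nlminb(log(start), obj, lower = log(lower), upper = log(upper),
                       control = list(iter.max = 500, eval.max = 1000,
                                      rel.tol = 1e-8))
  pars <- expand(exp(fit$par))
  np <- length(free)
  ll <- -fit$objective
  structure(list(pars = pars, loglik = ll, n_par = np,
                 AIC = 2 * np - 2 * ll, constraint = constraint,
                 convergence = fit$convergence == 0, rho = rho),
            class = "bisse_fit")
}

#' @export
print.bisse_fit <- function(x, digits = 4, ...) {
  cat(sprintf("BiSSE fit (%s): logLik %.4f, AIC %.4f, %d parameters\n",
              x$constraint, x$loglik, x$AIC, x$n_par))
  if (!x$convergence) cat("  WARNING: optimiser did not report convergence\n")
  print(signif(x$pars, digits))
  invisible(x)
}

#' @export
logLik.bisse_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, class = "logLik")
}

#' @export
coef.bisse_fit <- function(object, ...) object$pars

#' @export
AIC.bisse_fit <- function(object, ..., k = 2) object$AIC
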