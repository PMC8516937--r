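#' Rate-matrix templates for Mk models
#'
#' Builds the parameter map of a k-state continuous-time Markov generator.
#' `ER`, `SYM`, `ARD` allow all transitions with equal, symmetric, or
#' all-different rates; the `ordered_*` variants restrict transitions to
#' adjacent states on the ordinal state order (used for the custom dietary
#' hypothesis limiting transitions to carnivore-insectivore,
#' insectivore-omnivore, and omnivore-herbivore).
#'
#' @param name template name.
#' @param states character vector of state labels in ordinal order.
#' @return a `rate_template`: list with `name`, `states`, `k`, `index`
#'   (k x k integer matrix of parameter indices, 0 = structural zero or
#'   diagonal), `n_par`.
#' @examples
#' mk_template("ordered_ARD", c("1", "2", "3", "4plus"))
#' @export
mk_template <- function(name = c("ER", "SYM", "ARD",
                                 "ordered_ER", "ordered_SYM", "ordered_ARD"),
                        states) {
  name <- match.arg(name)
  k <- length(states)
  if (k < 2) stopf("need at least 2 states")
  ordered <- grepl("^ordered_", name)
  base <- sub("^ordered_", "", name)
  index <- matrix(0L, k, k, dimnames = list(states, states))
  allowed <- function(i, j) !ordered || abs(i - j) == 1L
  np <- 0L
  if (base == "ER") {
    for (i in 1:k) for (j in 1:k)
      if (i != j && allowed(i, j)) index[i, j] <- 1L
    np <- 1L
  } else if (base == "SYM") {
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      if (allowed(i, j)) {
        np <- np + 1L
        index[i, j] <- np
        index[j, i] <- np
      }
  } else {
    for (i in 1:k) for (j in 1:k)
      if (i != j && allowed(i, j)) {
        np <- np + 1L
        index[i, j] <- np
      }
  }
  structure(list(name = name, states = states, k = k,
                 index = index, n_par = np),
            class = "rate_template")
}

#' @export
print.rate_template <- function(x, ...) {
  cat(sprintf("Mk rate template '%s': %d states, %d free rate parameter(s)\n",
              x$name, x$k, x$n_par))
  print(x$index)
  invisible(x)
}

#' Build a rate matrix from a template and rate values
#'
#' @param template a `rate_template`.
#' @param rates numeric vector of length `template$n_par` (1/My).
#' @return a k x k generator `Q` with rows summing to zero.
#' @export
build_q <- function(template, rates) {
  if (length(rates) != template$n_par)
    stopf("expected %d rate(s), got %d", template$n_par, length(rates))
  if (any(rates < 0)) stopf("rates must be non-negative")
  Q <- matrix(0, template$k, template$k,
              dimnames = dimnames(template$index))
  pos <- template$index > 0
  Q[pos] <- rates[template$index[pos]]
  diag(Q) <- -rowSums(Q)
  Q
}

validate_q <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stopf("Q must be square")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stopf("off-diagonal rates must be >= 0")
  tol <- 1e-10 * max(1, max(abs(Q)))
  if (any(abs(rowSums(Q)) > tol)) stopf("rows of Q must sum to 0")
  invisible(Q)
}

## Root prior resolution. Internal.
resolve_root_prior <- function(root_prior, Q) {
  k <- nrow(Q)
  if (is.numeric(root_prior)) {
    if (length(root_prior) != k || abs(sum(root_prior) - 1) > 1e-8)
      stopf("numeric root prior must be a length-%d probability vector", k)
    return(root_prior)
  }
  switch(match.arg(root_prior, c("uniform", "stationary")),
         uniform = rep(1 / k, k),
         stationary = {
           ## left null vector of Q
           v <- Re(eigen(t(Q))$vectors[, which.min(abs(Re(eigen(t(Q))$values)))])
           v <- abs(v); v / sum(v)
         })
}

## Tip likelihood matrix (n_tip x k one-hot), states = named character vector
## over tree tip labels, state space = colnames. Internal.
tip_lik_matrix <- function(tree, states, state_levels) {
  n_tip <- length(tree$tip.label)
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) stopf("tip(s) without a state: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  s <- states[tree$tip.label]
  bad <- which(!s %in% state_levels)
  if (length(bad)) stopf("tip %s has state '%s' outside the state space",
                         tree$tip.label[bad[1]], s[bad[1]])
  L <- matrix(0, n_tip, length(state_levels),
              dimnames = list(tree$tip.label, state_levels))
  L[cbind(seq_len(n_tip), match(s, state_levels))] <- 1
  L
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' Computes the likelihood of fully-observed tip states under a k-state
#' continuous-time Markov model on a strictly binary (or multifurcating —
#' the pruning pass handles any out-degree, but fitting requires binary
#' input, see [resolve_polytomies()]) time tree.
#'
#' @param tree a `phylo` object, strictly binary.
#' @param states named character vector of tip states (names = tip labels),
#'   or a `trait_table` plus `trait`.
#' @param Q a k x k generator with state labels as dimnames.
#' @param root_prior `"uniform"` (default), `"stationary"`, or a numeric
#'   probability vector.
#' @return log-likelihood (scalar), with attribute `"partials"` used
#'   internally by the reconstruction functions.
#' @export
mk_loglik <- function(tree, states, Q, root_prior = "uniform") {
  prep <- mk_prepare(tree, states, Q, root_prior)
  res <- mk_postorder(prep)
  root <- length(prep$tree$tip.label) + 1L
  ll <- log(sum(prep$pi * res$partial[root, ])) + res$logscale[root]
  ll
}

## Shared preparation: validation, tip matrix, eigen cache. Internal.
mk_prepare <- function(tree, states, Q, root_prior) {
  if (!inherits(tree, "phylo")) stopf("tree must be a phylo object")
  if (!is_binary_tree(tree))
    stopf("tree contains polytomies; run resolve_polytomies() first")
  validate_q(Q)
  levels <- colnames(Q)
  if (is.null(levels)) stopf("Q needs state labels as dimnames")
  L <- tip_lik_matrix(tree, states, levels)
  list(tree = tree, L = L, Q = Q, pi = resolve_root_prior(root_prior, Q),
       pm = make_pmat(Q))
}

## Postorder conditional likelihoods with per-node log scaling.
## partial[v, ] = P(data below v | state at v), scaled; logscale[v] holds the
## log of the removed factor (cumulative over the subtree). Internal.
mk_postorder <- function(prep) {
  tree <- prep$tree
  n_tip <- length(tree$tip.label)
  k <- ncol(prep$L)
  n_node <- n_tip + tree$Nnode
  partial <- matrix(1, n_node, k)
  partial[seq_len(n_tip), ] <- prep$L
  logscale <- numeric(n_node)
  po <- ape::reorder.phylo(tree, "postorder")
  ## edge-wise messages child -> parent
  edge_p <- vector("list", nrow(po$edge))
  for (i in seq_len(nrow(po$edge))) {
    a <- po$edge[i, 1]; b <- po$edge[i, 2]
    P <- prep$pm(po$edge.length[i])
    edge_p[[i]] <- P
    m <- as.vector(P %*% partial[b, ])
    partial[a, ] <- partial[a, ] * m
    logscale[a] <- logscale[a] + logscale[b]
    ## scale to avoid underflow
    s <- max(partial[a, ])
    if (s > 0 && (s < 1e-100 || s > 1e100)) {
      partial[a, ] <- partial[a, ] / s
      logscale[a] <- logscale[a] + log(s)
    }
  }
  ## final rescale at root for numerical sanity
  root <- n_tip + 1L
  s <- max(partial[root, ])
  if (s > 0) {
    partial[root, ] <- partial[root, ] / s
    logscale[root] <- logscale[root] + log(s)
  }
  list(partial = partial, logscale = logscale, po = po, edge_p = edge_p)
}

#' Fit an Mk model by maximum likelihood
#'
#' Bounded multistart optimisation of [mk_loglik()] over log-rates. Starts
#' are a fixed ladder of common-rate values spanning the plausible range on a
#' My-scaled tree, so fits are deterministic.
#'
#' @inheritParams mk_loglik
#' @param template a `rate_template` from [mk_template()].
#' @param lower,upper rate bounds (1/My).
#' @param n_starts number of fixed multistart points (first values of the
#'   ladder `10^(-3:1)` scaled by tree height).
#' @return an object of class `mk_fit`: template, `rates`, `Q`, `loglik`,
#'   `n_par`, `AIC`, `convergence`, plus a data fingerprint used by
#'   [akaike_weights()].
#' @export
fit_mk <- function(tree, states, template, root_prior = "uniform",
                   lower = 1e-8, upper = 1e3, n_starts = 5) {
  stopifnot(inherits(template, "rate_template"))
  np <- template$n_par
  obj <- function(logr) {
    Q <- build_q(template, exp(logr))
    -mk_loglik(tree, states, Q, root_prior)
  }
  height <- max(node_ages(tree))
  base_rates <- 10^seq(-3, 1, length.out = n_starts) / max(height, 1e-12)
  base_rates <- pmin(pmax(base_rates, lower * 1.01), upper * 0.99)
  best <- NULL
  conv <- FALSE
  for (r0 in base_rates) {
    fit <- tryCatch(
      stats::nlminb(rep(log(r0), np), obj,
                    lower = rep(log(lower), np), upper = rep(log(upper), np),
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective - 1e-9) best <- fit
    if (fit$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) stopf("Mk optimisation failed from all starts")
  rates <- exp(best$par)
  ll <- -best$objective
  out <- list(template = template, rates = rates,
              Q = build_q(template, rates),
              loglik = ll, n_par = np, AIC = 2 * np - 2 * ll,
              convergence = conv, root_prior = root_prior,
              data_id = mk_data_id(tree, states))
  class(out) <- "mk_fit"
  out
}

mk_data_id <- function(tree, states) {
  s <- states[sort(names(states))]
  paste(length(tree$tip.label), round(sum(tree$edge.length), 6),
        paste(s, collapse = ""), sep = "|")
}

#' @export
print.mk_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Mk fit (%s, %d states)\n", x$template$name, x$template$k))
  cat(sprintf("  log-likelihood: %.4f   AIC: %.4f   parameters: %d\n",
              x$loglik, x$AIC, x$n_par))
  if (!x$convergence) cat("  WARNING: optimiser did not report convergence\n")
  cat("  rates (1/My):\n")
  print(signif(x$rates, digits))
  invisible(x)
}

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, class = "logLik")
}

#' @export
coef.mk_fit <- function(object, ...) object$rates

#' @export
AIC.mk_fit <- function(object, ..., k = 2) object$AIC

#' Akaike weights for a set of Mk fits
#'
#' @param fits list of `mk_fit` objects fitted to identical data.
#' @return numeric weights summing to 1, named by template.
#' @export
akaike_weights <- function(fits) {
  if (length(fits) < 2) stopf("need at least 2 fits")
  ids <- vapply(fits, function(f) f$data_id, "")
  if (length(unique(ids)) != 1L)
    stopf("fits were made on different datasets; weights are not comparable")
  aic <- vapply(fits, function(f) f$AIC, 0)
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w <- w / sum(w)
  names(w) <- vapply(fits, function(f) f$template$name, "")
  w
}

#' Akaike-weight average of rate matrices
#'
#' @param Qs list of generators with identical dimensions and state labels.
#' @param weights numeric weights summing to 1.
#' @return the entrywise weighted average generator.
#' @export
average_matrices <- function(Qs, weights) {
  if (length(Qs) != length(weights)) stopf("Qs and weights differ in length")
  if (abs(sum(weights) - 1) > 1e-8) stopf("weights must sum to 1")
  dims <- vapply(Qs, nrow, 0L)
  if (length(unique(dims)) != 1L) stopf("rate matrices differ in dimension")
  Q <- Reduce(`+`, Map(`*`, Qs, weights))
  validate_q(Q)
  Q
}

#' Fit, weight, and average an Mk model set
#'
#' Convenience wrapper reproducing the two model-selection protocols: for the
#' cusp character, `{ER, SYM, ARD}` are fitted and their generators averaged
#' by Akaike weight; for diet, the six templates (three default, three
#' ordered variants of the dietary-gradient hypothesis) are compared and the
#' single best-AIC model's generator returned.
#'
#' @inheritParams fit_mk
#' @param templates character vector of template names.
#' @param combine `"average"` or `"best"`.
#' @return list: `fits`, `weights`, `Q` (averaged or best), `best` (name).
#' @export
mk_model_set <- function(tree, states, state_levels,
                         templates = c("ER", "SYM", "ARD"),
                         combine = c("average", "best"),
                         root_prior = "uniform") {
  combine <- match.arg(combine)
  fits <- lapply(templates, function(nm)
    fit_mk(tree, states, mk_template(nm, state_levels), root_prior))
  names(fits) <- templates
  w <- akaike_weights(fits)
  Q <- if (combine == "average")
    average_matrices(lapply(fits, `[[`, "Q"), w)
  else fits[[which.max(w)]]$Q
  list(fits = fits, weights = w, Q = Q, best = names(which.max(w)),
       combine = combine)
}
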