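## Bayesian test of correlated evolution between two binary traits:
## the joint chain lives on {00, 01, 10, 11} (trait1 then trait2), dual
## transitions (both traits changing in one instant) are structurally zero.

pagel_states <- c("00", "01", "10", "11")

pagel_rate_names <- function(variant) {
  if (variant == "independent")
    c("gain1", "loss1", "gain2", "loss2")
  else
    c("q00.01", "q00.10", "q01.00", "q01.11",
      "q10.00", "q10.11", "q11.01", "q11.10")
}

#' Build the 4-state generator of the correlated-evolution model
#'
#' @param variant `"independent"` (4 rates: each trait's gain/loss ignores
#'   the other trait's state) or `"dependent"` (8 rates: each single-trait
#'   transition rate depends on the other trait's current state).
#' @param rates named or positional numeric vector (4 or 8 values, ordered
#'   as [pagel_rate_names()]).
#' @return 4 x 4 generator over states `00, 01, 10, 11`.
#' @export
pagel_q <- function(variant = c("independent", "dependent"), rates) {
  variant <- match.arg(variant)
  nm <- pagel_rate_names(variant)
  if (length(rates) != length(nm))
    stopf("%s model needs %d rates", variant, length(nm))
  r <- as.numeric(rates)
  names(r) <- nm
  Q <- matrix(0, 4, 4, dimnames = list(pagel_states, pagel_states))
  if (variant == "independent") {
    Q["00", "10"] <- r["gain1"]; Q["01", "11"] <- r["gain1"]
    Q["10", "00"] <- r["loss1"]; Q["11", "01"] <- r["loss1"]
    Q["00", "01"] <- r["gain2"]; Q["10", "11"] <- r["gain2"]
    Q["01", "00"] <- r["loss2"]; Q["11", "10"] <- r["loss2"]
  } else {
    Q["00", "01"] <- r["q00.01"]; Q["00", "10"] <- r["q00.10"]
    Q["01", "00"] <- r["q01.00"]; Q["01", "11"] <- r["q01.11"]
    Q["10", "00"] <- r["q10.00"]; Q["10", "11"] <- r["q10.11"]
    Q["11", "01"] <- r["q11.01"]; Q["11", "10"] <- r["q11.10"]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

## Joint tip states "00".."11" from two binary trait frames. Internal.
joint_states <- function(trait1, trait2, tree) {
  s1 <- stats::setNames(trait1$state, trait1$species)[tree$tip.label]
  s2 <- stats::setNames(trait2$state, trait2$species)[tree$tip.label]
  if (anyNA(s1) || anyNA(s2)) stopf("tip(s) missing from a binary trait table")
  stats::setNames(paste0(s1, s2), tree$tip.label)
}

#' Log-likelihood of the correlated-evolution model
#'
#' Pruning likelihood of two binary traits on the joint 4-state chain. The
#' MCMC machinery expects a tree rescaled to mean branch length 0.1 (see
#' [rescale_tree()]); a warning is issued otherwise.
#'
#' @param tree a strictly binary `phylo`, normally rescaled.
#' @param trait1,trait2 binary trait frames from [binarize()].
#' @param variant,rates see [pagel_q()].
#' @param root_prior as in [mk_loglik()].
#' @export
correlation_loglik <- function(tree, trait1, trait2,
                               variant = c("independent", "dependent"),
                               rates, root_prior = "uniform") {
  variant <- match.arg(variant)
  if (abs(mean(tree$edge.length) - 0.1) > 0.05)
    warnf("tree mean branch length is %.3g, not 0.1; rescale_tree() first",
          mean(tree$edge.length))
  mk_loglik(tree, joint_states(trait1, trait2, tree),
            pagel_q(variant, rates), root_prior)
}

## Prior spec: list(type = "uniform", max = 100) or
## list(type = "point", rates = <vector>). Internal helpers.
prior_logdensity <- function(prior, rates) {
  if (prior$type == "point") return(0)
  if (any(rates <= 0 | rates > prior$max)) return(-Inf)
  -length(rates) * log(prior$max)
}

default_rate_prior <- function() list(type = "uniform", max = 100)

#' Metropolis-Hastings sampler for the correlated-evolution model
#'
#' Single-coordinate random-walk MH on log-rates, with the proposal scale
#' adapted toward a 20-50% acceptance rate during burn-in only. The default
#' prior is uniform(0, 100) on each rate on the rescaled tree.
#'
#' @inheritParams correlation_loglik
#' @param iterations,burnin,thin chain control (proposal counts).
#' @param prior prior spec, see [default_rate_prior()]; a point-mass prior
#'   (`list(type = "point", rates = ...)`) freezes the chain at those rates.
#' @param seed RNG seed; identical seeds give identical traces.
#' @param beta power-posterior temperature (likelihood exponent); 1 for
#'   ordinary posterior sampling.
#' @param init optional starting rates.
#' @return `mcmc_chain`: `rates` (samples x parameters), `loglik`,
#'   `acceptance`, `ess` (per parameter), `variant`, settings.
#' @export
mcmc_sample <- function(tree, trait1, trait2,
                        variant = c("independent", "dependent"),
                        iterations = 20000, burnin = 2000, thin = 10,
                        prior = default_rate_prior(), seed = 1L,
                        beta = 1, init = NULL) {
  variant <- match.arg(variant)
  if (iterations <= burnin) stopf("iterations must exceed burnin")
  nm <- pagel_rate_names(variant)
  js <- joint_states(trait1, trait2, tree)
  ll_fun <- function(r) mk_loglik(tree, js, pagel_q(variant, r))
  sampled <- with_seed(seed, run_mh(ll_fun, nm, iterations, burnin, thin,
                                    prior, beta, init))
  sampled$variant <- variant
  sampled$settings <- list(iterations = iterations, burnin = burnin,
                           thin = thin, seed = seed, beta = beta)
  class(sampled) <- "mcmc_chain"
  sampled
}

## Core MH loop shared by posterior sampling and steppingstone rungs.
## Assumes RNG state is already set. Internal.
run_mh <- function(ll_fun, par_names, iterations, burnin, thin, prior,
                   beta = 1, init = NULL, step = NULL) {
  p <- length(par_names)
  if (prior$type == "point") {
    r <- prior$rates
    ll <- ll_fun(r)
    keep <- max(1L, floor((iterations - burnin) / thin))
    return(list(rates = matrix(rep(r, each = keep), keep, p,
                               dimnames = list(NULL, par_names)),
                loglik = rep(ll, keep), acceptance = 1,
                ess = rep(keep, p)))
  }
  r <- init %||% rep(1, p)
  lp <- prior_logdensity(prior, r)
  ll <- ll_fun(r)
  step <- step %||% rep(0.8, p)
  acc <- 0L; prop <- 0L
  acc_win <- integer(p); prop_win <- integer(p)
  keep_rates <- NULL; keep_ll <- NULL
  out_n <- floor((iterations - burnin) / thin)
  keep_rates <- matrix(NA_real_, out_n, p, dimnames = list(NULL, par_names))
  keep_ll <- numeric(out_n)
  ki <- 0L
  for (it in seq_len(iterations)) {
    i <- ((it - 1L) %% p) + 1L
    r2 <- r
    r2[i] <- r[i] * exp(stats::rnorm(1, 0, step[i]))
    lp2 <- prior_logdensity(prior, r2)
    if (is.finite(lp2)) {
      ll2 <- ll_fun(r2)
      ## Jacobian of the log-scale walk: + log r2[i] - log r[i]
      a <- beta * (ll2 - ll) + lp2 - lp + log(r2[i]) - log(r[i])
      if (log(stats::runif(1)) < a) {
        r <- r2; ll <- ll2; lp <- lp2
        acc <- acc + 1L; acc_win[i] <- acc_win[i] + 1L
      }
    }
    prop <- prop + 1L; prop_win[i] <- prop_win[i] + 1L
    ## adapt during burn-in only
    if (it <= burnin && prop_win[i] >= 25L) {
      rate <- acc_win[i] / prop_win[i]
      if (rate < 0.2) step[i] <- step[i] * 0.7
      if (rate > 0.5) step[i] <- step[i] * 1.4
      acc_win[i] <- 0L; prop_win[i] <- 0L
    }
    if (it > burnin && (it - burnin) %% thin == 0L) {
      ki <- ki + 1L
      if (ki <= out_n) { keep_rates[ki, ] <- r; keep_ll[ki] <- ll }
    }
  }
  list(rates = keep_rates, loglik = keep_ll, acceptance = acc / prop,
       ess = apply(keep_rates, 2, ess), step = step)
}

## Cheap ML mode of a model, used to seed the steppingstone ladder at its
## posterior end. Internal.
ml_mode <- function(ll_fun, p, lower = 1e-4, upper = 100) {
  fit <- tryCatch(
    stats::nlminb(rep(0, p), function(lr) -ll_fun(exp(lr)),
                  lower = log(lower), upper = log(upper),
                  control = list(iter.max = 200, eval.max = 400)),
    error = function(e) NULL)
  if (is.null(fit)) rep(1, p) else exp(fit$par)
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf("MCMC chain (%s model): %d samples, acceptance %.2f\n",
              x$variant, nrow(x$rates), x$acceptance))
  cat(sprintf("  min ESS: %.0f\n", min(x$ess)))
  cat("  posterior rate means:\n")
  print(signif(colMeans(x$rates), 4))
  invisible(x)
}

#' Steppingstone estimate of the log marginal likelihood
#'
#' Runs a ladder of power posteriors with temperatures at quantiles of a
#' Beta(0.4, 1) distribution (dense near the prior, where the integrand
#' changes fastest), handing the chain state from each rung to the next, and
#' combines rungs with the steppingstone estimator.
#'
#' @inheritParams mcmc_sample
#' @param stones number of ladder rungs (>= 2).
#' @param iters_per_stone MH proposals per rung (first 25% discarded as
#'   within-rung burn-in).
#' @return `marginal_likelihood`: `logZ`, `stones`, `beta` (ladder),
#'   `contributions` (per-stone log ratio estimates), `iters_per_stone`.
#' @export
steppingstone_logZ <- function(tree, trait1, trait2,
                               variant = c("independent", "dependent"),
                               stones = 100, iters_per_stone = 2000,
                               prior = default_rate_prior(), seed = 1L) {
  variant <- match.arg(variant)
  if (stones < 2) stopf("need at least 2 stones")
  nm <- pagel_rate_names(variant)
  js <- joint_states(trait1, trait2, tree)
  ll_fun <- function(r) mk_loglik(tree, js, pagel_q(variant, r))
  beta <- (seq(0, stones) / stones)^(1 / 0.4)

  if (prior$type == "point") {
    ll <- ll_fun(prior$rates)
    if (!is.finite(ll)) stopf("degenerate likelihood at the point-mass prior")
    return(structure(list(logZ = ll, stones = stones, beta = beta,
                          contributions = c((beta[-1] - beta[-length(beta)]) * ll),
                          iters_per_stone = iters_per_stone),
                     class = "marginal_likelihood"))
  }

  contributions <- numeric(stones)
  with_seed(seed, {
    ## seed the ladder at its posterior end with a cheap ML mode, then walk
    ## the rungs from beta ~ 1 down to the prior, handing over both chain
    ## state and adapted proposal scales: each rung then starts close to its
    ## own stationary distribution
    init <- ml_mode(ll_fun, length(nm),
                    upper = if (prior$type == "uniform") prior$max else 100)
    step <- rep(0.4, length(nm))
    for (s in rev(seq_len(stones))) {
      b_lo <- beta[s]; b_hi <- beta[s + 1]
      burn <- floor(iters_per_stone * 0.25)
      rung <- run_mh(ll_fun, nm, iters_per_stone, burn, 1, prior,
                     beta = b_lo, init = init, step = step)
      if (all(!is.finite(rung$loglik)))
        stopf("degenerate likelihood: all sampled log-likelihoods are -Inf")
      contributions[s] <- logsumexp((b_hi - b_lo) * rung$loglik) -
        log(length(rung$loglik))
      init <- rung$rates[nrow(rung$rates), ]
      step <- rung$step
    }
  })
  structure(list(logZ = sum(contributions), stones = stones, beta = beta,
                 contributions = contributions,
                 iters_per_stone = iters_per_stone),
            class = "marginal_likelihood")
}

#' @export
print.marginal_likelihood <- function(x, ...) {
  cat(sprintf("Steppingstone marginal likelihood: logZ = %.3f (%d stones x %d iters)\n",
              x$logZ, x$stones, x$iters_per_stone))
  invisible(x)
}

#' Log Bayes factor between two marginal likelihoods
#'
#' Uses the `2 * (logZ_complex - logZ_simple)` convention, under which values
#' above 10 are conventionally read as very strong support for the complex
#' (dependent) model.
#'
#' @param logZ_complex,logZ_simple `marginal_likelihood` objects or numbers.
#' @return scalar log Bayes factor.
#' @export
log_bayes_factor <- function(logZ_complex, logZ_simple) {
  z1 <- if (inherits(logZ_complex, "marginal_likelihood")) logZ_complex$logZ else logZ_complex
  z2 <- if (inherits(logZ_simple, "marginal_likelihood")) logZ_simple$logZ else logZ_simple
  2 * (z1 - z2)
}

#' Full correlated-evolution test
#'
#' Rescales the tree to mean branch length 0.1, runs steppingstone sampling
#' under the independent and dependent models, and reports the log Bayes
#' factor for dependence.
#'
#' @param tree a strictly binary `phylo` on the original (My) scale.
#' @inheritParams steppingstone_logZ
#' @return `correlation_test`: `log_bf`, `logZ_dependent`,
#'   `logZ_independent`, `scale_factor`.
#' @export
correlated_evolution_test <- function(tree, trait1, trait2, stones = 100,
                                      iters_per_stone = 2000,
                                      prior = default_rate_prior(),
                                      seed = 1L) {
  sc <- rescale_tree(tree, 0.1)
  seeds <- derive_seeds(seed, 2)
  z_ind <- steppingstone_logZ(sc$tree, trait1, trait2, "independent",
                              stones, iters_per_stone, prior, seeds[1])
  z_dep <- steppingstone_logZ(sc$tree, trait1, trait2, "dependent",
                              stones, iters_per_stone, prior, seeds[2])
  structure(list(log_bf = log_bayes_factor(z_dep, z_ind),
                 logZ_dependent = z_dep, logZ_independent = z_ind,
                 scale_factor = sc$scale_factor,
                 schemes = c(attr(trait1, "scheme") %||% "trait1",
                             attr(trait2, "scheme") %||% "trait2")),
            class = "correlation_test")
}

#' @export
print.correlation_test <- function(x, ...) {
  cat(sprintf("Correlated evolution test (%s x %s)\n",
              x$schemes[1], x$schemes[2]))
  cat(sprintf("  logZ dependent:   %.3f\n", x$logZ_dependent$logZ))
  cat(sprintf("  logZ independent: %.3f\n", x$logZ_independent$logZ))
  cat(sprintf("  log Bayes factor (2*dlogZ): %.2f\n", x$log_bf))
  invisible(x)
}
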