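#' Kruskal-Wallis test with epsilon-squared effect size
#'
#' Tie-corrected Kruskal-Wallis H (via [stats::kruskal.test()]) with the
#' epsilon-squared effect size `H / (n - 1)` and a seed-fixed bootstrap
#' percentile confidence interval for it (cases resampled jointly with their
#' group labels).
#'
#' @param values numeric or ordinal (ordered factor) response.
#' @param groups grouping factor.
#' @param n_boot bootstrap resamples for the CI.
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return `kw_test`: `H`, `df`, `p_value`, `epsilon_sq`, `ci` (length 2),
#'   `n`.
#' @export
kruskal_wallis <- function(values, groups, n_boot = 10000, conf = 0.95,
                           seed = 1L) {
  if (is.factor(values)) values <- as.integer(values)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  keep <- stats::complete.cases(values, groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  n <- length(values)
  if (n < 2) stopf("need at least 2 observations")
  if (stats::var(values) == 0) {
    ## all observations tied: no rank variation, H is 0 by definition
    kt <- list(statistic = 0, parameter = nlevels(groups) - 1, p.value = 1)
  } else {
    kt <- stats::kruskal.test(values, groups)
  }
  H <- unname(kt$statistic)
  eps2 <- H / (n - 1)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      g <- droplevels(groups[idx])
      if (nlevels(g) < 2) return(NA_real_)
      unname(stats::kruskal.test(values[idx], g)$statistic) / (n - 1)
    }, 0))
    ci <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
  }
  structure(list(H = H, df = unname(kt$parameter), p_value = kt$p.value,
                 epsilon_sq = eps2, ci = ci, n = n, conf = conf),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.2f, df = %d, p = %.3g, n = %d\n",
              x$H, x$df, x$p_value, x$n))
  cat(sprintf("  epsilon^2 = %.3f [%.2f, %.2f] (%.0f%% bootstrap CI)\n",
              x$epsilon_sq, x$ci[1], x$ci[2], 100 * x$conf))
  invisible(x)
}

#' Post hoc pairwise Wilcoxon-Mann-Whitney tests
#'
#' Two-sided tie-corrected tests for every group pair with a multiplicity
#' correction (Holm by default).
#'
#' @inheritParams kruskal_wallis
#' @param correction a [stats::p.adjust()] method.
#' @return data frame: `group1`, `group2`, `U`, `p_raw`, `p_adj`,
#'   `significant` (at 0.05).
#' @export
pairwise_wmw <- function(values, groups, correction = "holm") {
  if (is.factor(values)) values <- as.integer(values)
  groups <- factor(groups)
  lv <- levels(groups)
  if (any(table(groups) == 0)) stopf("empty group")
  pairs <- utils::combn(lv, 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- values[groups == pr[1]]; b <- values[groups == pr[2]]
    if (!length(a) || !length(b)) stopf("empty group '%s' or '%s'", pr[1], pr[2])
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    data.frame(group1 = pr[1], group2 = pr[2], U = unname(wt$statistic),
               p_raw = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = correction)
  out$significant <- out$p_adj < 0.05
  out
}
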