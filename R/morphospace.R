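#' Ordinary PCA morphospace of harmonic coefficients
#'
#' @param coeffs specimens x variables matrix (e.g. from
#'   [outline_coefficients()]).
#' @return `morphospace`: `scores` (centred), `var_prop` (per-axis variance
#'   proportions summing to 1), `loadings`, `center`, `method`.
#' @export
morphospace_pca <- function(coeffs) {
  if (nrow(coeffs) < 3) stopf("need at least 3 specimens")
  p <- stats::prcomp(coeffs, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  structure(list(scores = p$x, var_prop = v / sum(v),
                 loadings = p$rotation, center = p$center,
                 method = "pca"),
            class = "morphospace")
}

#' Phylogenetic PCA morphospace
#'
#' Principal components of the evolutionary covariance matrix: the
#' between-species covariance is estimated by generalised least squares
#' under the tree's phylogenetic covariance (Brownian expectation), with the
#' GLS root state as the mean. On a star phylogeny with equal tip depths
#' this reduces to ordinary PCA.
#'
#' @param coeffs specimens x variables matrix, rownames matching tree tips.
#' @param tree a `phylo` containing all specimens.
#' @return `morphospace` with `method = "ppca"`.
#' @export
morphospace_ppca <- function(coeffs, tree) {
  if (nrow(coeffs) < 3) stopf("need at least 3 specimens")
  miss <- setdiff(rownames(coeffs), tree$tip.label)
  if (length(miss)) stopf("specimen(s) missing from tree: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  tr <- ape::keep.tip(tree, rownames(coeffs))
  C <- ape::vcv(tr)[rownames(coeffs), rownames(coeffs)]
  Ci <- solve(C)
  one <- rep(1, nrow(coeffs))
  a <- as.vector(t(one) %*% Ci %*% coeffs) / as.vector(t(one) %*% Ci %*% one)
  X <- sweep(coeffs, 2, a)
  R <- t(X) %*% Ci %*% X / (nrow(coeffs) - 1)
  eg <- eigen(R, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-12)
  V <- eg$vectors[, keep, drop = FALSE]
  colnames(V) <- paste0("PC", seq_along(keep))
  rownames(V) <- colnames(coeffs)
  scores <- X %*% V
  structure(list(scores = scores, var_prop = eg$values[keep] / sum(eg$values[keep]),
                 loadings = V, center = a, method = "ppca"),
            class = "morphospace")
}

#' @export
print.morphospace <- function(x, n = 5, ...) {
  cat(sprintf("Morphospace (%s): %d specimens, %d axes\n",
              x$method, nrow(x$scores), ncol(x$scores)))
  vp <- utils::head(x$var_prop, n)
  cat("  variance proportions:",
      paste(sprintf("PC%d %.2f%%", seq_along(vp), 100 * vp), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.morphospace <- function(x, groups = NULL, axes = c(1, 2), ...) {
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(x$scores[, axes], col = col, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", axes[1], 100 * x$var_prop[axes[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", axes[2], 100 * x$var_prop[axes[2]]),
                 ...)
  invisible(x)
}

#' 95% confidence ellipses per group
#'
#' @param ms a `morphospace`.
#' @param groups factor over specimens.
#' @param axes which two axes.
#' @param level confidence level.
#' @return data frame `group`, `x`, `y` tracing each ellipse.
#' @export
group_ellipses <- function(ms, groups, axes = c(1, 2), level = 0.95) {
  sc <- ms$scores[, axes, drop = FALSE]
  th <- seq(0, 2 * pi, length.out = 100)
  circ <- cbind(cos(th), sin(th))
  out <- lapply(levels(factor(groups)), function(g) {
    m <- sc[groups == g, , drop = FALSE]
    if (nrow(m) < 3) return(NULL)
    ctr <- colMeans(m)
    S <- stats::cov(m)
    r <- sqrt(stats::qchisq(level, 2))
    e <- eigen(S, symmetric = TRUE)
    pts <- t(ctr + t(circ %*% diag(sqrt(pmax(e$values, 0)) * r) %*% t(e$vectors)))
    data.frame(group = g, x = pts[, 1], y = pts[, 2])
  })
  do.call(rbind, out)
}

## lambda-scaled phylogenetic covariance: off-diagonals * lambda. Internal.
lambda_vcv <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

## Multivariate GLS profile log-likelihood in lambda. Internal.
manova_profile_ll <- function(lambda, C, X, Y) {
  n <- nrow(Y); p <- ncol(Y)
  Cl <- lambda_vcv(C, lambda)
  L <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  Xt <- backsolve(L, X, transpose = TRUE)
  Yt <- backsolve(L, Y, transpose = TRUE)
  B <- tryCatch(qr.coef(qr(Xt), Yt), error = function(e) NULL)
  if (is.null(B)) return(-Inf)
  E <- Yt - Xt %*% B
  S <- crossprod(E) / n
  det_s <- determinant(S, logarithm = TRUE)
  if (det_s$sign <= 0) return(-Inf)
  -n / 2 * as.numeric(det_s$modulus) - p * sum(log(diag(L))) - n * p / 2 * (1 + log(2 * pi))
}

#' Permutation phylogenetic MANOVA
#'
#' Fits a multivariate linear model of score matrix on group by generalised
#' least squares under a Pagel's-lambda-scaled phylogenetic covariance
#' (lambda estimated by maximum likelihood jointly with the model), computes
#' the Pillai trace of the group effect on the phylogenetically transformed
#' data, and assesses significance by permuting the transformed residuals of
#' the null (intercept-only) model. With `lambda = 0` this reduces to an
#' ordinary (non-phylogenetic) permutation MANOVA.
#'
#' @param scores specimens x axes matrix (rownames = species).
#' @param groups factor (or coercible) over specimens.
#' @param tree a `phylo` containing the specimens.
#' @param nperm number of permutations.
#' @param seed RNG seed for the permutations.
#' @param lambda `NULL` to estimate by ML, or a fixed value in `[0, 1]`.
#' @param contrast optional contrast matrix (rows = contrasts, columns =
#'   groups in factor-level order, rows summing to 0) tested instead of the
#'   overall group effect.
#' @return `phylo_manova`: `pillai`, `p_value`, `lambda`, `df`, `nperm`,
#'   `groups`, `perm_stats`.
#' @export
phylo_manova <- function(scores, groups, tree, nperm = 1000, seed = 1L,
                         lambda = NULL, contrast = NULL) {
  groups <- factor(groups)
  g <- nlevels(groups)
  if (g < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2)) stopf("every group needs at least 2 members")
  Y <- as.matrix(scores)
  n <- nrow(Y); p <- ncol(Y)
  if (p >= n - g) stopf("singular cross-products (%d axes, %d residual df); truncate the score matrix", p, n - g)
  miss <- setdiff(rownames(Y), tree$tip.label)
  if (length(miss)) stopf("specimen(s) missing from tree: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  tr <- ape::keep.tip(tree, rownames(Y))
  C <- ape::vcv(tr)[rownames(Y), rownames(Y)]
  X <- stats::model.matrix(~groups)
  if (is.null(lambda)) {
    opt <- stats::optimise(function(l) -manova_profile_ll(l, C, X, Y),
                           c(0, 1))
    lambda <- opt$minimum
    ## snap to the boundary when it fits at least as well
    for (b in c(0, 1))
      if (manova_profile_ll(b, C, X, Y) >= -opt$objective - 1e-8) lambda <- b
  }
  Cl <- lambda_vcv(C, lambda)
  L <- chol(Cl)
  Yt <- backsolve(L, Y, transpose = TRUE)
  Xt <- backsolve(L, X, transpose = TRUE)
  X0t <- backsolve(L, matrix(1, n, 1), transpose = TRUE)

  pillai_stat <- function(Yw) {
    qrX <- qr(Xt)
    B <- qr.coef(qrX, Yw)
    E <- crossprod(Yw - Xt %*% B)
    if (is.null(contrast)) {
      B0 <- qr.coef(qr(X0t), Yw)
      E0 <- crossprod(Yw - X0t %*% B0)
      H <- E0 - E
    } else {
      ## map contrasts over group means to the treatment parameterisation
      Lc <- as.matrix(contrast)
      if (ncol(Lc) != g) stopf("contrast matrix needs %d columns", g)
      ## group means mu = M beta with M = [1 0..; 1 I]
      M <- cbind(1, rbind(0, diag(g - 1)))
      Lb <- Lc %*% M
      XtXi <- solve(crossprod(Xt))
      LB <- Lb %*% B
      H <- t(LB) %*% solve(Lb %*% XtXi %*% t(Lb)) %*% LB
    }
    sum(diag(H %*% solve(H + E)))
  }
  V <- pillai_stat(Yt)
  ## permute transformed residuals of the null model (Freedman-Lane style)
  B0 <- qr.coef(qr(X0t), Yt)
  fit0 <- X0t %*% B0
  res0 <- Yt - fit0
  perm_stats <- with_seed(seed, vapply(seq_len(nperm), function(i) {
    pillai_stat(fit0 + res0[sample.int(n), , drop = FALSE])
  }, 0))
  pval <- (1 + sum(perm_stats >= V)) / (1 + nperm)
  structure(list(pillai = V, p_value = pval, lambda = lambda,
                 df = c(groups = g - 1, residual = n - g), nperm = nperm,
                 groups = levels(groups), perm_stats = perm_stats,
                 contrast = contrast),
            class = "phylo_manova")
}

#' @export
print.phylo_manova <- function(x, ...) {
  cat("Permutation phylogenetic MANOVA\n")
  cat(sprintf("  Pillai trace V = %.4f, p = %.4g (%d permutations)\n",
              x$pillai, x$p_value, x$nperm))
  cat(sprintf("  Pagel's lambda (residuals): %.3f\n", x$lambda))
  cat(sprintf("  groups: %s\n", paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Canonical discriminant analysis with leave-one-out classification
#'
#' Eigen-analysis of the between- over within-group covariance of the score
#' matrix: at most `groups - 1` canonical axes; classification assigns each
#' specimen to the nearest group centroid in canonical space, with the
#' centroids recomputed without the focal specimen (leave-one-out).
#'
#' @param scores specimens x axes matrix.
#' @param groups factor over specimens.
#' @return `dfa_fit`: `axes` (loadings), `canonical` (specimen scores),
#'   `classification` (confusion table), `accuracy`.
#' @export
dfa <- function(scores, groups) {
  groups <- factor(groups)
  g <- nlevels(groups)
  if (g < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2)) stopf("every group needs at least 2 members")
  Y <- as.matrix(scores)
  n <- nrow(Y)
  mu <- colMeans(Y)
  W <- matrix(0, ncol(Y), ncol(Y))
  B <- matrix(0, ncol(Y), ncol(Y))
  for (lv in levels(groups)) {
    Yg <- Y[groups == lv, , drop = FALSE]
    mg <- colMeans(Yg)
    W <- W + crossprod(sweep(Yg, 2, mg))
    B <- B + nrow(Yg) * tcrossprod(mg - mu)
  }
  W <- W / (n - g)
  eg <- eigen(solve(W + diag(1e-10, ncol(W)), B))
  ord <- order(Re(eg$values), decreasing = TRUE)
  n_axes <- min(g - 1, ncol(Y))
  A <- Re(eg$vectors[, ord[seq_len(n_axes)], drop = FALSE])
  colnames(A) <- paste0("LD", seq_len(n_axes))
  rownames(A) <- colnames(Y)
  Z <- Y %*% A
  ## leave-one-out nearest-centroid classification
  pred <- character(n)
  for (i in seq_len(n)) {
    cent <- sapply(levels(groups), function(lv) {
      idx <- which(groups == lv & seq_len(n) != i)
      colMeans(Z[idx, , drop = FALSE])
    })
    d <- colSums((matrix(cent, ncol = g) - Z[i, ])^2)
    pred[i] <- levels(groups)[which.min(d)]
  }
  conf <- table(observed = groups, predicted = factor(pred, levels(groups)))
  structure(list(axes = A, canonical = Z,
                 classification = conf,
                 accuracy = mean(pred == as.character(groups))),
            class = "dfa_fit")
}

#' @export
print.dfa_fit <- function(x, ...) {
  cat(sprintf("Discriminant analysis: %d canonical axes, LOO accuracy %.1f%%\n",
              ncol(x$axes), 100 * x$accuracy))
  print(x$classification)
  invisible(x)
}
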