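make_coeff_cohort <- function(n_per = 12, effect = 1, seed = 5) {
  tab <- load_traits(data.frame(
    species = paste0("s", seq_len(3 * n_per)),
    cusp = rep("3", 3 * n_per),
    diet = rep(c("insectivore", "omnivore", "herbivore"), each = n_per)))
  cfg <- outline_config()
  cfg$protrusion_effect <- cfg$protrusion_effect * effect
  cfg$flaring_effect <- cfg$flaring_effect * effect
  os <- simulate_outlines(tab, cfg, seed = seed, multicuspid_only = TRUE)
  list(coeffs = outline_coefficients(os, 120), tab = tab)
}

test_that("pca scores are centred with diagonal covariance and full variance", {
  cc <- make_coeff_cohort()
  ms <- morphospace_pca(cc$coeffs)
  expect_equal(sum(ms$var_prop), 1, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(ms$scores))), 1e-10)
  cv <- cov(ms$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8 * max(diag(cv)))
})

test_that("ppca equals pca on a star tree and is tip-order invariant", {
  set.seed(2)
  X <- matrix(rnorm(15 * 6), 15, 6,
              dimnames = list(paste0("s", 1:15), paste0("v", 1:6)))
  star <- ape::read.tree(text = paste0(
    "(", paste0("s", 1:15, ":1", collapse = ","), ");"))
  p1 <- morphospace_pca(X)
  p2 <- morphospace_ppca(X, star)
  expect_equal(p1$var_prop, p2$var_prop, tolerance = 1e-10)
  expect_equal(abs(p1$scores[, 1:5]), abs(p2$scores[, 1:5]),
               tolerance = 1e-8, ignore_attr = TRUE)
  # tip-order invariance on a structured tree
  tr <- simulate_tree(0.4, 0, 7, fossil = FALSE, seed = 3)
  tr <- ape::keep.tip(tr, tr$tip.label[1:min(12, length(tr$tip.label))])
  Y <- matrix(rnorm(length(tr$tip.label) * 5), length(tr$tip.label), 5,
              dimnames = list(tr$tip.label, NULL))
  a <- morphospace_ppca(Y, tr)
  b <- morphospace_ppca(Y[rev(rownames(Y)), ], tr)
  expect_equal(abs(a$scores[rownames(Y), ]), abs(b$scores[rownames(Y), ]),
               tolerance = 1e-8)
  expect_error(morphospace_ppca(Y, ape::drop.tip(tr, tr$tip.label[1])),
               "missing from tree")
})

test_that("the morphometric pipeline separates diet groups", {
  cc <- make_coeff_cohort(n_per = 30, effect = 1, seed = 11)
  ms <- morphospace_pca(cc$coeffs)
  grp <- rep(c("insectivore", "omnivore", "herbivore"), each = 30)
  herb <- grp == "herbivore"
  # AUC of PC1 for herbivore vs insectivore
  pc1 <- ms$scores[, 1]
  ins <- grp == "insectivore"
  ranks <- rank(c(pc1[herb], pc1[ins]))
  auc <- (sum(ranks[seq_len(sum(herb))]) - sum(herb) * (sum(herb) + 1) / 2) /
    (sum(herb) * sum(ins))
  expect_gt(max(auc, 1 - auc), 0.8)
})

test_that("phylo MANOVA calibrates type-I error and finds true effects", {
  # null calibration under BM on a tree: rejection rate near alpha
  n_sims <- 60
  alpha <- 0.1
  rej <- 0
  tr <- simulate_tree(0.5, 0, 6, fossil = FALSE, seed = 101)
  for (s in 102:120) {
    if (length(tr$tip.label) >= 15) break
    tr <- simulate_tree(0.5, 0, 6, fossil = FALSE, seed = s)
  }
  n <- length(tr$tip.label)
  C <- ape::vcv(tr)
  L <- chol(C)
  set.seed(9)
  grp <- factor(rep_len(c("a", "b", "c"), n))
  for (i in seq_len(n_sims)) {
    Y <- t(L) %*% matrix(rnorm(n * 3), n, 3)
    rownames(Y) <- tr$tip.label
    m <- phylo_manova(Y, grp, tr, nperm = 120, seed = 1000 + i)
    if (m$p_value <= alpha) rej <- rej + 1
  }
  se <- sqrt(alpha * (1 - alpha) / n_sims)
  expect_lt(abs(rej / n_sims - alpha), 3 * se + 1e-9)

  # lambda fixed at 0 equals an ordinary permutation MANOVA Pillai trace
  Y <- t(L) %*% matrix(rnorm(n * 3), n, 3); rownames(Y) <- tr$tip.label
  m0 <- phylo_manova(Y, grp, tr, nperm = 50, seed = 3, lambda = 0)
  V_ref <- summary(manova(Y ~ grp), test = "Pillai")$stats[1, "Pillai"]
  expect_equal(m0$pillai, unname(V_ref), tolerance = 1e-8)

  # real group separation is detected
  cc <- make_coeff_cohort(n_per = 10, effect = 1.5, seed = 21)
  ms <- morphospace_pca(cc$coeffs)
  star <- ape::read.tree(text = paste0(
    "(", paste0(rownames(cc$coeffs), ":1", collapse = ","), ");"))
  grp2 <- rep(c("insectivore", "omnivore", "herbivore"), each = 10)
  m2 <- phylo_manova(ms$scores[, 1:5], grp2, star, nperm = 500, seed = 4)
  expect_lt(m2$p_value, 0.05)

  expect_error(phylo_manova(ms$scores[, 1:28], grp2, star), "singular")
})

test_that("contrast matrices isolate single group differences", {
  cc <- make_coeff_cohort(n_per = 10, effect = 1.5, seed = 33)
  ms <- morphospace_pca(cc$coeffs)
  star <- ape::read.tree(text = paste0(
    "(", paste0(rownames(cc$coeffs), ":1", collapse = ","), ");"))
  grp <- factor(rep(c("insectivore", "omnivore", "herbivore"), each = 10))
  # levels sort: herbivore, insectivore, omnivore
  herb_vs_ins <- matrix(c(1, -1, 0), 1)
  m <- phylo_manova(ms$scores[, 1:4], grp, star, nperm = 300, seed = 5,
                    contrast = herb_vs_ins)
  expect_lt(m$p_value, 0.05)
  ins_vs_omn <- matrix(c(0, 1, -1), 1)
  m2 <- phylo_manova(ms$scores[, 1:4], grp, star, nperm = 300, seed = 6,
                     contrast = ins_vs_omn)
  # herbivores sit further from insectivores than omnivores do along the
  # diet gradient, so the herb-ins contrast carries the larger effect
  expect_gt(m$pillai, m2$pillai)
})

test_that("dfa yields groups-1 axes and classifies separable clusters", {
  set.seed(8)
  X <- rbind(cbind(rnorm(20, 0), rnorm(20, 0)),
             cbind(rnorm(20, 6), rnorm(20, 0)),
             cbind(rnorm(20, 0), rnorm(20, 12)))
  grp <- rep(c("a", "b", "c"), each = 20)
  d <- dfa(X, grp)
  expect_equal(ncol(d$axes), 2)
  expect_equal(d$accuracy, 1)
  # agreement with an independent implementation on the axis count and
  # classification of well-separated data
  skip_if_not_installed("MASS")
  ld <- MASS::lda(X, grouping = grp)
  expect_equal(ncol(ld$scaling), ncol(d$axes))
  expect_error(dfa(X[c(1, 21, 41), ], c("a", "b", "c")), "at least 2")
})
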