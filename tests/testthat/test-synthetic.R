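test_that("the tree simulator matches pure-birth expectations", {
  # E[N(T)] = exp(lambda T) from one founder; 500 replicates within 3 SE
  # (fossil = TRUE output is unconditioned when death = 0)
  la <- 0.2; T <- 10
  n <- vapply(1:500, function(i)
    length(simulate_tree(la, 0, T, fossil = TRUE, seed = i)$tip.label), 0)
  m <- exp(la * T)
  se <- sqrt(exp(2 * la * T) - exp(la * T)) / sqrt(500)
  expect_lt(abs(mean(n) - m), 3 * se)

  # death = 0 -> ultrametric; determinism
  tr <- simulate_tree(0.3, 0, 8, fossil = TRUE, seed = 4)
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  expect_identical(write_phylogeny(tr),
                   write_phylogeny(simulate_tree(0.3, 0, 8, fossil = TRUE,
                                                 seed = 4)))
  # with extinction and fossil = TRUE, extinct tips appear at positive ages
  trf <- simulate_tree(0.3, 0.15, 12, fossil = TRUE, seed = 8)
  expect_gt(tree_report(trf)$n_fossil_tips, 0)
  expect_equal(tree_report(simulate_tree(0.3, 0.15, 12, fossil = FALSE,
                                         seed = 8))$n_fossil_tips, 0)
})

test_that("character simulation is exact CTMC with retained histories", {
  tr <- simulate_tree(0.3, 0, 10, fossil = FALSE, seed = 3)
  lev <- c("a", "b", "c")
  # near-zero rates: everything stays in the root state
  sim0 <- simulate_character(tr, build_q(mk_template("ER", lev), 1e-12),
                             "b", seed = 1)
  expect_true(all(sim0$node_states == "b"))
  expect_equal(sim0$n_changes, 0)

  # dwell times on each branch sum to the branch length
  Q <- build_q(mk_template("ARD", lev), c(0.2, 0.05, 0.1, 0.3, 0.15, 0.1))
  sim <- simulate_character(tr, Q, "a", seed = 9)
  el <- stats::setNames(tr$edge.length, tr$edge[, 2])
  dw <- tapply(sim$history$dwell, sim$history$branch, sum)
  expect_equal(as.numeric(dw), unname(el[names(dw)]), tolerance = 1e-9)

  # long-branch tip frequencies approach the stationary distribution
  star <- ape::read.tree(text = paste0(
    "(", paste0("s", 1:500, ":80", collapse = ","), ");"))
  star <- validate_phylogeny(star)
  Qs <- build_q(mk_template("ARD", c("x", "y")), c(0.3, 0.1))
  sims <- simulate_character(star, Qs, "x", seed = 11)
  pi_y <- 0.3 / 0.4  # stationary mass of y
  phat <- mean(sims$tip_states == "y")
  expect_lt(abs(phat - pi_y), 3 * sqrt(pi_y * (1 - pi_y) / 500))
})

test_that("dependent generation produces positive trait association", {
  dep <- c("q00.01" = 0.02, "q00.10" = 1.2, "q01.00" = 5.0, "q01.11" = 1.2,
           "q10.00" = 0.6, "q10.11" = 3.0, "q11.01" = 0.02, "q11.10" = 0.6)
  hits <- 0; tried <- 0; i <- 0
  while (tried < 12 && i < 60) {
    i <- i + 1
    tr <- simulate_tree(0.5, 0, 9, fossil = FALSE, seed = 3000 + i)
    if (length(tr$tip.label) < 60) next
    tried <- tried + 1
    trs <- rescale_tree(tr, 0.1)$tree
    pr <- simulate_binary_pair(trs, "dependent", dep, "00", seed = 3100 + i)
    tab <- table(factor(pr$trait1$state, 0:1), factor(pr$trait2$state, 0:1))
    or <- (tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
    if (or > 1) hits <- hits + 1
  }
  expect_gte(hits / tried, 0.75)
})

test_that("outline generation spans the intended cusp and diet axes", {
  # noise-free profile has exactly k interior local maxima
  count_maxima <- function(y) {
    s <- sign(diff(y))
    s <- s[s != 0]   # collapse exact-tie plateaus at symmetric apices
    sum(diff(s) == -2)
  }
  for (k in 1:4) for (h in c(0, 0.5, 1)) {
    o <- simulate_outline(k, h)
    expect_equal(count_maxima(o$coords[, 2]), k,
                 label = sprintf("k=%d, herbivory=%.1f", k, h))
  }
  # protrusion parameter strictly raises the height/width ratio
  cfg <- outline_config()
  heights <- vapply(c(0, 0.5, 1), function(h) {
    o <- simulate_outline(3, h, cfg)
    diff(range(o$coords[, 2])) / diff(range(o$coords[, 1]))
  }, 0)
  expect_true(all(diff(heights) > 0))

  # cohort separability: insectivore vs herbivore PC1 AUC > 0.8
  tab <- load_traits(data.frame(
    species = paste0("s", 1:60),
    cusp = rep("3", 60),
    diet = rep(c("insectivore", "herbivore"), each = 30)))
  os <- simulate_outlines(tab, outline_config(), seed = 6)
  ms <- morphospace_pca(outline_coefficients(os, 120))
  pc1 <- ms$scores[, 1]
  herb <- tab$diet[match(rownames(ms$scores), tab$species)] == "herbivore"
  rk <- rank(pc1)
  auc <- (sum(rk[herb]) - sum(herb) * (sum(herb) + 1) / 2) /
    (sum(herb) * sum(!herb))
  expect_gt(max(auc, 1 - auc), 0.8)
})

test_that("a full study is reproducible and internally consistent", {
  cfg <- study_config()
  cfg$tree$time <- 25
  cfg$tree$min_tips <- 30
  s1 <- simulate_study(cfg, seed = 77)
  s2 <- simulate_study(cfg, seed = 77)
  expect_identical(write_phylogeny(s1$tree), write_phylogeny(s2$tree))
  expect_identical(s1$traits, s2$traits)
  # tip table consistent with true tip states
  expect_equal(as.character(s1$traits$cusp),
               unname(s1$true_states$cusp$tip_states[s1$traits$species]))
  expect_equal(as.character(s1$traits$diet),
               unname(s1$true_states$diet$tip_states[s1$traits$species]))
  # outlines labelled by multicuspid species only
  multi <- s1$traits$species[s1$traits$cusp != "1"]
  expect_setequal(names(s1$outlines), multi)
})

test_that("state-dependent tree simulation biases tip states as expected", {
  pars <- c(lambda0 = 0.1, lambda1 = 0.45, mu0 = 0.03, mu1 = 0.03,
            q01 = 0.05, q10 = 0.05)
  sim <- simulate_bisse_tree(pars, time = 16, seed = 10, min_tips = 50)
  expect_true(ape::is.ultrametric(sim$tree, tol = 1e-6))
  expect_setequal(names(sim$states), sim$tree$tip.label)
  # the fast-speciating state should dominate the extant tips
  expect_gt(mean(sim$states), 0.5)
})
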