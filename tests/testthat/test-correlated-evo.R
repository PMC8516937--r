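test_that("the joint model factorises and respects structural zeros", {
  tr <- simulate_tree(0.4, 0, 8, fossil = FALSE, seed = 2)
  trs <- rescale_tree(tr, 0.1)$tree
  pair <- simulate_binary_pair(tr, "independent", c(2, 2, 2, 2), "00", seed = 4)
  r <- c(1.3, 0.7, 2.1, 0.4)
  # independent-model likelihood = product of the two single-trait ones
  l4 <- correlation_loglik(trs, pair$trait1, pair$trait2, "independent", r)
  q1 <- build_q(mk_template("ARD", c("0", "1")), r[1:2])
  q2 <- build_q(mk_template("ARD", c("0", "1")), r[3:4])
  s1 <- setNames(as.character(pair$trait1$state), pair$trait1$species)
  s2 <- setNames(as.character(pair$trait2$state), pair$trait2$species)
  expect_equal(l4, mk_loglik(trs, s1, q1) + mk_loglik(trs, s2, q2),
               tolerance = 1e-9)

  # dependent model with context-tied rates reproduces the independent one
  rdep <- c(r[3], r[1], r[4], r[3], r[2], r[3], r[4], r[2])
  # order: q00.01=gain2, q00.10=gain1, q01.00=loss2, q01.11=gain1(!),
  # build explicitly instead:
  rdep <- c("q00.01" = r[3], "q00.10" = r[1], "q01.00" = r[4],
            "q01.11" = r[1], "q10.00" = r[2], "q10.11" = r[3],
            "q11.01" = r[2], "q11.10" = r[4])
  expect_equal(correlation_loglik(trs, pair$trait1, pair$trait2,
                                  "dependent", rdep), l4, tolerance = 1e-9)

  # dual transitions structurally zero in both variants
  expect_equal(pagel_q("independent", r)["00", "11"], 0)
  expect_equal(pagel_q("dependent", rdep)["01", "10"], 0)

  # unscaled tree warns
  expect_warning(correlation_loglik(tr, pair$trait1, pair$trait2,
                                    "independent", r), "rescale")
})

test_that("MCMC is seed-deterministic, point-mass-exact, and tunes acceptance", {
  tr <- simulate_tree(0.4, 0, 8, fossil = FALSE, seed = 6)
  trs <- rescale_tree(tr, 0.1)$tree
  pair <- simulate_binary_pair(tr, "independent", c(2, 2, 2, 2), "00", seed = 1)
  ch1 <- mcmc_sample(trs, pair$trait1, pair$trait2, "independent",
                     iterations = 3000, burnin = 500, thin = 5, seed = 42)
  ch2 <- mcmc_sample(trs, pair$trait1, pair$trait2, "independent",
                     iterations = 3000, burnin = 500, thin = 5, seed = 42)
  expect_identical(ch1$rates, ch2$rates)
  expect_identical(ch1$loglik, ch2$loglik)
  expect_equal(nrow(ch1$rates), (3000 - 500) / 5)
  expect_gt(ch1$acceptance, 0.1)
  expect_lt(ch1$acceptance, 0.7)

  # point-mass prior: chain constant at the fixed rates
  pt <- mcmc_sample(trs, pair$trait1, pair$trait2, "independent",
                    iterations = 200, burnin = 50, thin = 5,
                    prior = list(type = "point", rates = c(1, 2, 3, 4)))
  expect_true(all(apply(pt$rates, 2, function(x) length(unique(x))) == 1))
  expect_equal(length(unique(pt$loglik)), 1)
})

test_that("steppingstone is exact under a point mass and stable under refinement", {
  tr <- simulate_tree(0.5, 0, 7, fossil = FALSE, seed = 12)
  trs <- rescale_tree(tr, 0.1)$tree
  pair <- simulate_binary_pair(tr, "independent", c(2, 2, 2, 2), "00", seed = 3)
  r <- c(1, 0.5, 1.5, 0.8)
  ll <- correlation_loglik(trs, pair$trait1, pair$trait2, "independent", r)
  for (K in c(2, 25)) {
    z <- steppingstone_logZ(trs, pair$trait1, pair$trait2, "independent",
                            stones = K, iters_per_stone = 50,
                            prior = list(type = "point", rates = r))
    expect_equal(z$logZ, ll, tolerance = 1e-12)
    expect_true(all(diff(z$beta) > 0))
    expect_equal(range(z$beta), c(0, 1))
  }
  # ladder refinement consistency on a small fixture
  z2 <- steppingstone_logZ(trs, pair$trait1, pair$trait2, "independent",
                           stones = 2, iters_per_stone = 4000, seed = 8)
  z50 <- steppingstone_logZ(trs, pair$trait1, pair$trait2, "independent",
                            stones = 50, iters_per_stone = 400, seed = 9)
  expect_lt(abs(z2$logZ - z50$logZ), 0.5)
})

test_that("log Bayes factor uses the 2*delta convention and is antisymmetric", {
  a <- structure(list(logZ = -10), class = "marginal_likelihood")
  b <- structure(list(logZ = -13.5), class = "marginal_likelihood")
  expect_equal(log_bayes_factor(a, b), 7)
  expect_equal(log_bayes_factor(b, a), -7)
  expect_equal(log_bayes_factor(a, a), 0)
})

test_that("dependence is detected and independence is not overcalled", {
  # strong context effect: the plant trait is rarely gained without the
  # complexity trait and decays quickly once complexity is lost
  dep_rates <- c("q00.01" = 0.02, "q00.10" = 1.2, "q01.00" = 5.0,
                 "q01.11" = 1.2, "q10.00" = 0.6, "q10.11" = 3.0,
                 "q11.01" = 0.02, "q11.10" = 0.6)
  big_tree <- function(seed) {
    for (s in seed + 0:30) {
      tr <- simulate_tree(0.5, 0, 9, fossil = FALSE, seed = s)
      if (length(tr$tip.label) >= 80) return(tr)
    }
    tr
  }
  n_rep <- 2
  bf_dep <- bf_ind <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    trs <- rescale_tree(big_tree(500 + 40 * i), 0.1)$tree
    pr <- simulate_binary_pair(trs, "dependent", dep_rates, "00",
                               seed = 600 + i)
    ct <- correlated_evolution_test(trs, pr$trait1, pr$trait2, stones = 12,
                                    iters_per_stone = 300, seed = 700 + i)
    bf_dep[i] <- ct$log_bf
    pri <- simulate_binary_pair(trs, "independent", c(1, 1, 1, 1), "00",
                                seed = 800 + i)
    ci <- correlated_evolution_test(trs, pri$trait1, pri$trait2, stones = 12,
                                    iters_per_stone = 300, seed = 900 + i)
    bf_ind[i] <- ci$log_bf
  }
  # dependence strongly supported on dependent data, never on independent
  expect_true(all(bf_dep > 2))
  expect_true(all(bf_ind < 2))
})
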