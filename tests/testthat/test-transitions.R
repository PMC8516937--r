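# A reconstruction object pinned by hand for toy trees.
manual_asr <- function(states, levels) {
  structure(list(prob = NULL, modal = states, method = "manual",
                 states = levels), class = "asr")
}

test_that("transitions are enumerated with signed magnitudes and flags", {
  # ((A,B),(C,D)); root 1-cusp, cherry AB reconstructed 3-cusped
  t4 <- fixture_tree4()
  lev <- c("1", "2", "3", "4plus")
  #            A    B    C    D    root n(AB) n(CD)
  modal <- c("3", "3", "1", "1", "1", "3", "1")
  tips <- c(A = "3", B = "3", C = "1", D = "1")
  ev <- enumerate_transitions(t4, manual_asr(modal, lev), tips, "cusp", lev)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$magnitude, 2)
  expect_equal(ev$direction, "increase")
  expect_true(ev$multi_step)
  expect_equal(ev$branch, 6)  # the (A,B) ancestor

  # constant reconstruction -> no events
  ev0 <- enumerate_transitions(t4, manual_asr(rep("1", 7), lev),
                               c(A = "1", B = "1", C = "1", D = "1"),
                               "cusp", lev)
  expect_equal(nrow(ev0), 0)

  # 3 -> 1 decrease flagged as multi-cusp loss
  modal2 <- c("1", "3", "1", "1", "3", "3", "1")
  tips2 <- c(A = "1", B = "3", C = "1", D = "1")
  ev2 <- enumerate_transitions(t4, manual_asr(modal2, lev), tips2, "cusp", lev)
  dec <- ev2[ev2$direction == "decrease" & ev2$branch == 1, ]
  expect_equal(dec$magnitude, -2)
  expect_true(dec$multi_step)
})

test_that("originations are classed by derived clade size and re-evolution", {
  # 10-tip balanced-ish tree, one root-adjacent gain
  tr <- simulate_tree(0.45, 0, 8, fossil = FALSE, seed = 77)
  n_tip <- length(tr$tip.label)
  lev <- c("1", "2")
  root <- n_tip + 1
  kids <- tr$edge[tr$edge[, 1] == root, 2]
  big_clade <- kids[which.max(vapply(kids, function(k)
    length(cuspevol:::clade_tips(tr, k)), 0))]
  inside <- c(big_clade, unlist(lapply(cuspevol:::clade_tips(tr, big_clade),
                                       identity)))
  modal <- rep("1", n_tip + tr$Nnode)
  desc <- cuspevol:::clade_tips(tr, big_clade)
  # derive the whole clade below big_clade
  all_nodes <- seq_len(n_tip + tr$Nnode)
  in_clade <- vapply(all_nodes, function(v)
    big_clade %in% cuspevol:::root_path(tr, v), TRUE)
  modal[in_clade] <- "2"
  tips <- setNames(modal[seq_len(n_tip)], tr$tip.label)
  ev <- enumerate_transitions(tr, manual_asr(modal, lev), tips, "cusp", lev)
  org <- count_originations(ev, tr, derived_states = "2", tip_states = tips)
  expect_equal(nrow(org), 1)
  expect_equal(org$class,
               if (length(desc) >= 3) "major_clade" else "isolated_lineage")
  expect_false(org$re_evolution)

  # gain on a terminal branch -> isolated lineage
  modal2 <- rep("1", n_tip + tr$Nnode)
  modal2[1] <- "2"
  tips2 <- setNames(modal2[seq_len(n_tip)], tr$tip.label)
  ev2 <- enumerate_transitions(tr, manual_asr(modal2, lev), tips2, "cusp", lev)
  org2 <- count_originations(ev2, tr, "2", tips2)
  expect_equal(org2$class, "isolated_lineage")

  # loss inside the derived clade followed by a regain -> re-evolution flag
  # derive clade, revert one internal subclade, regain at a tip below it
  sub_internal <- setdiff(which(in_clade), seq_len(n_tip))
  sub_internal <- setdiff(sub_internal, big_clade)
  if (length(sub_internal)) {
    v <- sub_internal[which.max(vapply(sub_internal, function(s)
      length(cuspevol:::clade_tips(tr, s)), 0))]
    below_v <- vapply(all_nodes, function(u)
      v %in% cuspevol:::root_path(tr, u), TRUE)
    modal3 <- modal
    modal3[below_v] <- "1"          # loss at v
    tip_in_v <- intersect(which(below_v), seq_len(n_tip))[1]
    modal3[tip_in_v] <- "2"          # regain at a terminal branch
    tips3 <- setNames(modal3[seq_len(n_tip)], tr$tip.label)
    ev3 <- enumerate_transitions(tr, manual_asr(modal3, lev), tips3, "cusp", lev)
    org3 <- count_originations(ev3, tr, "2", tips3)
    re <- org3[org3$branch == tip_in_v, ]
    expect_true(re$re_evolution)
  }
})

test_that("path pairing matches by direction, path, and precedence", {
  t4 <- fixture_tree4()
  lev4 <- c("1", "2", "3", "4plus")
  levd <- c("carnivore", "insectivore", "omnivore", "herbivore")
  # diet increase on internal branch 6 (A,B ancestor), cusp increase on
  # descendant terminal branch 1 (A): one pair, diet first
  cusp_modal <- c("2", "1", "1", "1", "1", "1", "1")
  cusp_tips <- c(A = "2", B = "1", C = "1", D = "1")
  diet_modal <- c("omnivore", "omnivore", "insectivore", "insectivore",
                  "insectivore", "omnivore", "insectivore")
  diet_tips <- c(A = "omnivore", B = "omnivore", C = "insectivore",
                 D = "insectivore")
  cusp_ev <- enumerate_transitions(t4, manual_asr(cusp_modal, lev4),
                                   cusp_tips, "cusp", lev4)
  diet_ev <- enumerate_transitions(t4, manual_asr(diet_modal, levd),
                                   diet_tips, "diet", levd)
  pc <- pair_changes(cusp_ev, diet_ev, t4)
  expect_equal(nrow(pc$pairs), 1)
  expect_equal(pc$pairs$initiator, "diet_first")
  expect_equal(pc$summary$n_pairs_increase, 1)
  expect_equal(pc$summary$paired_fraction_increase, 1)

  # increases in sibling subtrees do not pair
  diet_modal2 <- c("insectivore", "insectivore", "omnivore", "omnivore",
                   "insectivore", "insectivore", "omnivore")
  diet_tips2 <- c(A = "insectivore", B = "insectivore", C = "omnivore",
                  D = "omnivore")
  diet_ev2 <- enumerate_transitions(t4, manual_asr(diet_modal2, levd),
                                    diet_tips2, "diet", levd)
  pc2 <- pair_changes(cusp_ev, diet_ev2, t4)
  expect_equal(nrow(pc2$pairs), 0)

  # same branch -> same_branch initiator
  diet_modal3 <- c("insectivore", "insectivore", "insectivore", "insectivore",
                   "insectivore", "insectivore", "insectivore")
  diet_modal3[1] <- "omnivore"
  diet_tips3 <- c(A = "omnivore", B = "insectivore", C = "insectivore",
                  D = "insectivore")
  cusp_modal3 <- c("2", "1", "1", "1", "1", "1", "1")
  cusp_ev3 <- enumerate_transitions(t4, manual_asr(cusp_modal3, lev4),
                                    c(A = "2", B = "1", C = "1", D = "1"),
                                    "cusp", lev4)
  diet_ev3 <- enumerate_transitions(t4, manual_asr(diet_modal3, levd),
                                    diet_tips3, "diet", levd)
  pc3 <- pair_changes(cusp_ev3, diet_ev3, t4)
  expect_equal(pc3$pairs$initiator, "same_branch")

  # each event used at most once
  expect_lte(nrow(pc$pairs),
             min(sum(cusp_ev$direction == "increase"),
                 sum(diet_ev$direction == "increase")))
})

test_that("lineage binning conserves branch-bin overlaps", {
  # one branch spanning 25 My with width 10 -> three bins
  tr <- read_phylogeny("(A:25,B:25);")
  lev <- c("1", "2")
  modal <- c("1", "2", "1")
  tips <- c(A = "1", B = "2")
  bt <- bin_lineages(tr, manual_asr(modal, lev), tips, bin_width = 10, lev)
  expect_equal(nrow(bt), 3)
  expect_equal(unname(bt$`1`), c(1, 1, 1))
  expect_equal(unname(bt$`2`), c(1, 1, 1))

  # conservation on a simulated reconstruction
  tr2 <- simulate_tree(0.3, 0.08, 20, fossil = TRUE, seed = 55)
  Q <- build_q(mk_template("ER", lev), 0.05)
  sim <- simulate_character(tr2, Q, "1", seed = 4)
  rec <- marginal_asr(tr2, sim$tip_states, Q)
  bt2 <- bin_lineages(tr2, rec, sim$tip_states, 10, lev)
  age <- node_ages(tr2)
  for (i in seq_len(nrow(bt2))) {
    lo <- bt2$bin_end[i]; hi <- bt2$bin_start[i]
    overlap <- sum(age[tr2$edge[, 2]] < hi & age[tr2$edge[, 1]] > lo)
    expect_equal(sum(bt2[i, lev]), overlap)
  }
  # every change event lands in exactly one bin
  ev <- enumerate_transitions(tr2, rec, sim$tip_states, "x", lev)
  expect_equal(sum(bt2$n_increase) + sum(bt2$n_decrease), nrow(ev))
})
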