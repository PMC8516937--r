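# Shared fixtures, built in code.

# Small hand-checkable trees
newick_3tip <- "((A:1,B:1):1,C:2);"
newick_poly <- "(A:1,B:1,C:1);"

fixture_tree <- function() read_phylogeny(newick_3tip)

# 4-tip binary tree used by the exhaustive-enumeration oracles
fixture_tree4 <- function()
  read_phylogeny("((A:0.6,B:0.9):0.5,(C:0.4,D:1.1):0.3);")

# deterministic trait table
fixture_traits <- function() {
  load_traits(data.frame(
    species = c("A", "B", "C", "D", "E"),
    cusp = c("1", "2", "3", "4plus", "1"),
    diet = c("carnivore", "insectivore", "omnivore", "herbivore", "insectivore")))
}

# Exhaustive-enumeration Mk likelihood: sums over all internal node state
# assignments with matrix exponentials. Independent of the pruning code path.
brute_mk_loglik <- function(tree, states, Q, root_prior = NULL) {
  k <- nrow(Q)
  lev <- colnames(Q)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  internal <- (n_tip + 1):n_node
  tipidx <- match(states[tree$tip.label], lev)
  P <- lapply(seq_len(nrow(tree$edge)), function(i) {
    # series matrix exponential, independent of the package's eigen route
    A <- Q * tree$edge.length[i]
    M <- diag(k); term <- diag(k)
    for (m in 1:60) { term <- term %*% A / m; M <- M + term }
    M
  })
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    assign_state <- integer(n_node)
    assign_state[seq_len(n_tip)] <- tipidx
    assign_state[internal] <- grid[g, ]
    pr <- unname(root_prior[assign_state[n_tip + 1]])
    for (i in seq_len(nrow(tree$edge)))
      pr <- pr * P[[i]][assign_state[tree$edge[i, 1]], assign_state[tree$edge[i, 2]]]
    tot <- tot + pr
  }
  unname(log(tot))
}

# Brute-force marginal probabilities at every node by enumeration.
brute_marginals <- function(tree, states, Q, root_prior = NULL) {
  k <- nrow(Q)
  lev <- colnames(Q)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  internal <- (n_tip + 1):n_node
  tipidx <- match(states[tree$tip.label], lev)
  P <- lapply(seq_len(nrow(tree$edge)), function(i) {
    A <- Q * tree$edge.length[i]
    M <- diag(k); term <- diag(k)
    for (m in 1:60) { term <- term %*% A / m; M <- M + term }
    M
  })
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  marg <- matrix(0, n_node, k)
  for (g in seq_len(nrow(grid))) {
    assign_state <- integer(n_node)
    assign_state[seq_len(n_tip)] <- tipidx
    assign_state[internal] <- grid[g, ]
    pr <- unname(root_prior[assign_state[n_tip + 1]])
    for (i in seq_len(nrow(tree$edge)))
      pr <- pr * P[[i]][assign_state[tree$edge[i, 1]], assign_state[tree$edge[i, 2]]]
    marg[cbind(seq_len(n_node), assign_state)] <-
      marg[cbind(seq_len(n_node), assign_state)] + pr
  }
  marg / rowSums(marg)
}

# Closed-form constant-rate birth-death log-likelihood (postorder product of
# logistic-solution propagators, lambda per non-root internal node).
bd_loglik_closed <- function(tree, lambda, mu, rho = 1) {
  age <- node_ages(tree)
  r <- lambda - mu
  f <- function(t) {
    if (abs(r) < 1e-12) return(rho / (1 + lambda * rho * t))
    r * rho * exp(r * t) / (r + lambda * rho * (exp(r * t) - 1))
  }
  n_tip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  D <- numeric(n_tip + tree$Nnode)
  D[seq_len(n_tip)] <- rho
  lg <- numeric(length(D))
  prodv <- rep(1, length(D))
  for (i in seq_len(nrow(po$edge))) {
    a <- po$edge[i, 1]; b <- po$edge[i, 2]
    if (b > n_tip) D[b] <- lambda * prodv[b]
    Db <- D[b] * f(age[a])^2 / (f(age[b])^2 * exp(r * (age[a] - age[b])))
    prodv[a] <- prodv[a] * Db / max(Db)
    lg[a] <- lg[a] + lg[b] + log(max(Db))
  }
  rt <- n_tip + 1
  log(prodv[rt]) + lg[rt]
}
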