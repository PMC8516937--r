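#' Marginal ancestral state reconstruction
#'
#' Computes, for every node, the marginal posterior probability of each
#' state given all tip data, by a single up-down (outside-inside) pass over
#' the tree. For a time-reversible generator this is algebraically identical
#' to re-rooting the tree at each node and reading the root state
#' probabilities there; the up-down pass computes all nodes in one sweep.
#'
#' @inheritParams mk_loglik
#' @return an object of class `asr`: `prob` (matrix, one row per node id
#'   including tips, columns = states), `modal` (character vector of modal
#'   states, ties broken toward the lower ordinal state), `method`
#'   (`"marginal"`), `loglik`.
#' @export
marginal_asr <- function(tree, states, Q, root_prior = "uniform") {
  prep <- mk_prepare(tree, states, Q, root_prior)
  res <- mk_postorder(prep)
  tree <- prep$tree
  n_tip <- length(tree$tip.label)
  k <- ncol(prep$L)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  po <- res$po

  ## per-edge downward messages m_e(i) = sum_j P_e[i,j] partial[child,j]
  edge_msg <- matrix(0, nrow(po$edge), k)
  for (i in seq_len(nrow(po$edge)))
    edge_msg[i, ] <- as.vector(res$edge_p[[i]] %*% res$partial[po$edge[i, 2], ])

  kids_edges <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  up <- matrix(0, n_node, k)        # outside message per node
  up[root, ] <- prep$pi
  ## preorder = reverse postorder over edges
  for (i in rev(seq_len(nrow(po$edge)))) {
    a <- po$edge[i, 1]; b <- po$edge[i, 2]
    sibs <- setdiff(kids_edges[[as.character(a)]], i)
    sib_prod <- rep(1, k)
    for (e in sibs) sib_prod <- sib_prod * edge_msg[e, ]
    u <- (up[a, ] * sib_prod) %*% res$edge_p[[i]]
    u <- as.vector(u)
    s <- max(u)
    if (s > 0) u <- u / s
    up[b, ] <- u
  }
  prob <- up * res$partial
  prob <- prob / rowSums(prob)
  colnames(prob) <- colnames(prep$L)
  rownames(prob) <- as.character(seq_len(n_node))
  modal <- colnames(prob)[max.col(prob, ties.method = "first")]
  ll <- log(sum(prep$pi * res$partial[root, ])) + res$logscale[root]
  structure(list(prob = prob, modal = modal, method = "marginal",
                 states = colnames(prep$L), loglik = ll),
            class = "asr")
}

#' @export
print.asr <- function(x, ...) {
  cat(sprintf("Ancestral state reconstruction (%s), %d nodes, states: %s\n",
              x$method, nrow(x$prob), paste(x$states, collapse = ", ")))
  if (!is.null(x$loglik)) cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  cat("  modal state frequencies:\n")
  print(table(x$modal))
  invisible(x)
}

#' Write an ASR table to CSV
#' @param x an `asr` object.
#' @param path output file.
#' @export
write_asr <- function(x, path) {
  df <- data.frame(node = as.integer(rownames(x$prob)), x$prob,
                   modal = x$modal, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Stochastic character mapping
#'
#' Samples complete character histories conditional on the tip data: node
#' states are drawn from their joint conditional distribution by backward
#' sampling over the pruning partials, then each branch history is drawn
#' conditional on its endpoint states by uniformisation (rejection-free).
#' The modal node state across maps gives a `simmap_modal` reconstruction.
#'
#' @inheritParams mk_loglik
#' @param n number of maps.
#' @param seed integer seed; same seed reproduces the maps exactly.
#' @return list of class `simmap_set`: `maps` (list of per-branch segment
#'   data frames with columns `branch` (child node id), `state`, `dwell`,
#'   ordered rootward to tipward), `asr` (an `asr` with method
#'   `"simmap_modal"` whose `prob` holds across-map node state frequencies),
#'   `n`, `seed`.
#' @export
stochastic_maps <- function(tree, states, Q, n = 100, seed = 1L,
                            root_prior = "uniform") {
  stopifnot(n >= 1)
  prep <- mk_prepare(tree, states, Q, root_prior)
  res <- mk_postorder(prep)
  tree <- prep$tree
  n_tip <- length(tree$tip.label)
  k <- ncol(prep$L)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  po <- res$po
  n_edge <- nrow(po$edge)

  omega <- max(-diag(prep$Q))
  Rm <- if (omega > 0) diag(k) + prep$Q / omega else diag(k)
  rpow <- new.env()
  assign("p0", diag(k), rpow)
  rpower <- function(m) {
    key <- paste0("p", m)
    if (!exists(key, rpow)) assign(key, rpower(m - 1) %*% Rm, rpow)
    get(key, rpow)
  }

  counts <- matrix(0L, n_node, k, dimnames = list(NULL, colnames(prep$L)))
  maps <- vector("list", n)

  with_seed(seed, {
    for (m in seq_len(n)) {
      ## backward (root-to-tip) joint sampling of node states
      node_state <- integer(n_node)
      w <- prep$pi * res$partial[root, ]
      node_state[root] <- sample.int(k, 1, prob = w)
      for (i in rev(seq_len(n_edge))) {
        a <- po$edge[i, 1]; b <- po$edge[i, 2]
        w <- res$edge_p[[i]][node_state[a], ] * res$partial[b, ]
        node_state[b] <- sample.int(k, 1, prob = w)
      }
      counts[cbind(seq_len(n_node), node_state)] <-
        counts[cbind(seq_len(n_node), node_state)] + 1L
      ## branch histories conditional on endpoints
      segs <- vector("list", n_edge)
      for (i in seq_len(n_edge)) {
        a <- node_state[po$edge[i, 1]]
        b <- node_state[po$edge[i, 2]]
        t <- po$edge.length[i]
        path <- sample_endpoint_path(a, b, t, omega, Rm, rpower,
                                     res$edge_p[[i]][a, b])
        segs[[i]] <- data.frame(branch = po$edge[i, 2],
                                state = colnames(prep$L)[path$states],
                                dwell = path$dwell)
      }
      maps[[m]] <- do.call(rbind, segs)
    }
  })

  freq <- counts / n
  modal <- colnames(freq)[max.col(freq, ties.method = "first")]
  rownames(freq) <- as.character(seq_len(n_node))
  asr <- structure(list(prob = freq, modal = modal, method = "simmap_modal",
                        states = colnames(prep$L), loglik = NULL),
                   class = "asr")
  structure(list(maps = maps, asr = asr, n = n, seed = seed),
            class = "simmap_set")
}

#' @export
print.simmap_set <- function(x, ...) {
  ch <- vapply(x$maps, function(m) sum(m$state[-1] != m$state[-nrow(m)] &
                                         m$branch[-1] == m$branch[-nrow(m)]), 0)
  cat(sprintf("Stochastic map set: %d maps (seed %d); mean %.1f changes/map\n",
              x$n, x$seed, mean(ch)))
  invisible(x)
}

## Endpoint-conditioned CTMC path on one branch by uniformisation.
## Returns list(states = integer vector, dwell = numeric vector) with
## dwell summing to t. Internal.
sample_endpoint_path <- function(a, b, t, omega, Rm, rpower, pab) {
  if (t <= 0 || omega == 0) return(list(states = a, dwell = t))
  ## number of uniformised jumps: P(N = m) propto dpois(m, omega t) R^m[a,b]
  u <- stats::runif(1)
  target <- u * max(pab, .Machine$double.xmin)
  acc <- 0
  m <- -1L
  repeat {
    m <- m + 1L
    acc <- acc + stats::dpois(m, omega * t) * rpower(m)[a, b]
    if (acc >= target || m > 5000L) break
  }
  if (m == 0L) return(list(states = a, dwell = t))
  ## jump chain states given endpoints
  s <- integer(m + 1L)
  s[1] <- a; s[m + 1L] <- b
  if (m > 1L) for (j in 2:m) {
    w <- Rm[s[j - 1L], ] * rpower(m + 1L - j)[, b]
    s[j] <- sample.int(length(w), 1, prob = w)
  }
  times <- sort(stats::runif(m)) * t
  ## collapse virtual (self) jumps into dwell segments
  bounds <- c(0, times, t)
  keep_states <- s
  states <- keep_states[1]
  dwell <- numeric(0)
  seg_start <- 0
  cur <- keep_states[1]
  for (j in seq_len(m)) {
    if (keep_states[j + 1L] != cur) {
      dwell <- c(dwell, times[j] - seg_start)
      seg_start <- times[j]
      cur <- keep_states[j + 1L]
      states <- c(states, cur)
    }
  }
  dwell <- c(dwell, t - seg_start)
  list(states = states, dwell = dwell)
}

#' Serialise a stochastic map set to a segment table
#' @param x a `simmap_set`.
#' @param path output CSV.
#' @export
write_simmap <- function(x, path) {
  tab <- do.call(rbind, Map(function(m, i) cbind(map = i, m),
                            x$maps, seq_along(x$maps)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
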