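#' Read and validate a time-calibrated phylogeny
#'
#' Parses a Newick or NEXUS tree (string or file) into an [ape::ape-package]
#' `phylo` object, validates branch lengths, computes node ages, and flags
#' polytomies. Ages are measured in My before present, with the deepest
#' root-to-tip path defining time 0 (the present), so trees mixing extant and
#' fossil tips are handled naturally: extant tips sit at age 0 and extinct
#' tips at positive ages.
#'
#' @param x a Newick string, or a path to a Newick/NEXUS file.
#' @param format `"newick"` or `"nexus"`; ignored when `x` is a literal
#'   Newick string (detected by a terminal `";"`).
#' @return a `phylo` object with attributes `node_age` (named numeric vector
#'   over all node ids) and `n_polytomies`.
#' @examples
#' tr <- read_phylogeny("((A:1,B:1):1,C:2);")
#' node_ages(tr)
#' @export
read_phylogeny <- function(x, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (length(x) != 1L || !is.character(x)) stopf("x must be a single string")
  is_literal <- grepl(";\\s*$", x) && grepl("\\(", x)
  tree <- if (is_literal) {
    tryCatch(ape::read.tree(text = x), error = function(e)
      stopf("Newick parse error: %s", conditionMessage(e)))
  } else if (format == "newick") {
    ape::read.tree(x)
  } else {
    ape::read.nexus(x)
  }
  if (is.null(tree)) stopf("Newick parse error: string could not be parsed")
  validate_phylogeny(tree)
}

#' Validate a phylogeny and attach node ages
#'
#' Checks for branch lengths, rejects negative lengths, computes ages and the
#' polytomy count. All other tree functions in the package call this on input.
#'
#' @param tree a `phylo` object.
#' @param tol tolerance for the age/branch-length consistency check.
#' @return the tree with `node_age` and `n_polytomies` attributes.
#' @export
validate_phylogeny <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stopf("not a phylo object")
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stopf("validation error: negative branch length on edge(s) %s",
          paste(which(tree$edge.length < 0), collapse = ", "))
  attr(tree, "node_age") <- compute_node_ages(tree)
  attr(tree, "n_polytomies") <- count_polytomies(tree)
  tree
}

compute_node_ages <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  depth <- numeric(n_node)
  root <- n_tip + 1L
  ## preorder accumulation of root-to-node path lengths
  eo <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(eo$edge))) {
    depth[eo$edge[i, 2]] <- depth[eo$edge[i, 1]] + eo$edge.length[i]
  }
  age <- max(depth[seq_len(n_tip)]) - depth
  names(age) <- as.character(seq_len(n_node))
  age
}

count_polytomies <- function(tree) {
  sum(tabulate(tree$edge[, 1], nbins = length(tree$tip.label) + tree$Nnode) > 2)
}

#' Node ages in My before present
#'
#' @param tree a `phylo` object (validated or not).
#' @return named numeric vector of ages, indexed by node id (tips first).
#' @export
node_ages <- function(tree) {
  a <- attr(tree, "node_age")
  if (is.null(a)) a <- compute_node_ages(validate_phylogeny(tree))
  a
}

#' Is the tree strictly binary?
#' @param tree a `phylo` object.
#' @export
is_binary_tree <- function(tree) count_polytomies(tree) == 0

#' Resolve polytomies into a strictly binary tree
#'
#' Polytomies are resolved into random dichotomies (via [ape::multi2di]),
#' after which each inserted zero-length internal edge is given a small
#' positive length `epsilon`, subtracted from the edges below the inserted
#' node so that tip ages and total tree depth are preserved and node ages
#' stay strictly ordered. The same seed always yields the same topology.
#'
#' @param tree a `phylo` object.
#' @param seed integer seed controlling the random resolution.
#' @param epsilon length (My) given to inserted edges; capped at half the
#'   shortest descendant edge so no branch length becomes non-positive.
#' @return a strictly binary validated tree.
#' @examples
#' tr <- read_phylogeny("(A:1,B:1,C:1);")
#' is_binary_tree(resolve_polytomies(tr, seed = 1))
#' @export
resolve_polytomies <- function(tree, seed = 1L, epsilon = 1e-3) {
  tree <- validate_phylogeny(tree)
  if (is_binary_tree(tree)) return(tree)
  res <- with_seed(seed, ape::multi2di(tree, random = TRUE))
  ## give inserted zero-length internal edges a positive length, taken from
  ## the edges immediately below so ages above/below are untouched
  repeat {
    n_tip <- length(res$tip.label)
    kids <- res$edge[, 2]
    zero_int <- which(res$edge.length <= 0 & kids > n_tip)
    if (!length(zero_int)) break
    e <- zero_int[1]
    child <- res$edge[e, 2]
    below <- which(res$edge[, 1] == child)
    d <- min(epsilon, 0.5 * min(res$edge.length[below][res$edge.length[below] > 0],
                                epsilon * 2))
    if (!is.finite(d) || d <= 0) d <- epsilon
    res$edge.length[e] <- res$edge.length[e] + d
    res$edge.length[below] <- res$edge.length[below] - d
    res$edge.length[below][res$edge.length[below] < 0] <- 0
  }
  validate_phylogeny(res)
}

#' Rescale branch lengths to a target mean
#'
#' Multiplies every branch length by `target / mean(branch lengths)`. Used to
#' put trees on the unit scale the correlated-evolution MCMC expects (mean
#' branch length 0.1).
#'
#' @param tree a `phylo` object with at least one edge.
#' @param target_mean target mean branch length.
#' @return list with elements `tree` (rescaled, revalidated) and
#'   `scale_factor`.
#' @examples
#' tr <- read_phylogeny("((A:1,B:1):1,C:2);")
#' rescale_tree(tr, 0.1)$scale_factor
#' @export
rescale_tree <- function(tree, target_mean = 0.1) {
  tree <- validate_phylogeny(tree)
  m <- mean(tree$edge.length)
  if (m <= 0) stopf("cannot rescale: tree has zero mean branch length")
  f <- target_mean / m
  tree$edge.length <- tree$edge.length * f
  out <- validate_phylogeny(tree)
  attr(out, "rescaled_mean") <- target_mean
  list(tree = out, scale_factor = f)
}

#' Summary report for a tree
#'
#' @param tree a `phylo` object.
#' @param age_tol tips older than this count as fossil tips.
#' @return list: `n_tips`, `n_fossil_tips`, `n_polytomies`, `root_age`,
#'   `mean_branch_length`.
#' @export
tree_report <- function(tree, age_tol = 1e-8) {
  tree <- validate_phylogeny(tree)
  age <- node_ages(tree)
  n_tip <- length(tree$tip.label)
  list(
    n_tips = n_tip,
    n_fossil_tips = sum(age[seq_len(n_tip)] > age_tol),
    n_polytomies = attr(tree, "n_polytomies"),
    root_age = unname(age[n_tip + 1L]),
    mean_branch_length = mean(tree$edge.length)
  )
}

#' Write a tree report as JSON
#' @param tree a `phylo` object.
#' @param path output file.
#' @export
write_tree_report <- function(tree, path) {
  jsonlite::write_json(tree_report(tree), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a tree to Newick
#' @param tree a `phylo` object.
#' @param path output file; if `NULL` the Newick string is returned.
#' @export
write_phylogeny <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}

## Root-to-node path of node ids (root first). Internal.
root_path <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  p <- node
  out <- node
  while (p != root) {
    p <- parent[p]
    out <- c(p, out)
  }
  out
}

## Descendant tip ids of a node (the node itself if a tip). Internal.
clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v <= n_tip) out <- c(out, v) else
      stack <- c(stack, kids_of[[as.character(v)]])
  }
  out
}
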