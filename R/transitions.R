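## Branch-level transition counting from a node-state reconstruction:
## transitions, independent originations, path-paired changes between two
## characters, and per-time-bin lineage/change tables.

## Full per-node state vector (tips from observed data, internal nodes from
## the reconstruction's modal states). Internal.
node_state_vector <- function(tree, reconstruction, tip_states) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  st <- reconstruction$modal
  if (length(st) != n_node)
    stopf("reconstruction must cover all %d nodes", n_node)
  if (!is.null(tip_states)) {
    s <- tip_states[tree$tip.label]
    if (anyNA(s)) stopf("tip(s) missing an observed state")
    st[seq_len(n_tip)] <- s
  }
  st
}

#' Enumerate state transitions along branches
#'
#' Emits one event per branch whose parent and child states differ. States
#' are the reconstruction's modal states at internal nodes and the observed
#' states at tips. The signed ordinal magnitude uses the position of each
#' state in `ordering`; cusp events with |magnitude| >= 2 are multi-cusp
#' gains/losses.
#'
#' @param tree a `phylo`.
#' @param reconstruction an `asr` object covering all nodes.
#' @param tip_states named character vector of observed tip states.
#' @param trait label stored on the events (e.g. `"cusp"`, `"diet"`).
#' @param ordering character vector giving the ordinal state order; defaults
#'   to the reconstruction's state set.
#' @return data frame of class `transition_events`: `branch` (child node
#'   id), `parent_age`, `child_age`, `trait`, `from`, `to`, `magnitude`,
#'   `direction`, `multi_step`.
#' @export
enumerate_transitions <- function(tree, reconstruction, tip_states,
                                  trait = "trait", ordering = NULL) {
  tree <- validate_phylogeny(tree)
  ordering <- ordering %||% reconstruction$states
  st <- node_state_vector(tree, reconstruction, tip_states)
  age <- node_ages(tree)
  a <- tree$edge[, 1]; b <- tree$edge[, 2]
  chg <- which(st[a] != st[b])
  ord <- function(s) match(s, ordering)
  ev <- data.frame(
    branch = b[chg],
    parent_age = unname(age[a[chg]]),
    child_age = unname(age[b[chg]]),
    trait = rep(trait, length(chg)),
    from = unname(st[a[chg]]),
    to = unname(st[b[chg]]),
    stringsAsFactors = FALSE)
  ev$magnitude <- ord(ev$to) - ord(ev$from)
  ev$direction <- ifelse(ev$magnitude > 0, "increase", "decrease")
  ev$multi_step <- abs(ev$magnitude) >= 2
  ev <- ev[order(-ev$parent_age, ev$branch), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("transition_events", "data.frame")
  ev
}

#' Independent originations of a derived condition
#'
#' One record per transition into the derived condition whose parent lineage
#' is non-derived. An origination is classed `major_clade` when its branch
#' subtends an internal clade containing at least `major_min` terminal
#' species in the derived condition, `isolated_lineage` otherwise.
#' Re-evolution is flagged when an ancestral branch of the event carries an
#' earlier loss of the derived condition.
#'
#' @param events a `transition_events` frame for one trait.
#' @param tree the same tree.
#' @param derived_states character vector of states counted as derived
#'   (e.g. `c("2","3","4plus")` for multicuspidness).
#' @param tip_states named observed tip states (for counting derived
#'   terminals).
#' @param major_min minimum derived terminal species for `major_clade`.
#' @return data frame: `branch`, `parent_age`, `class`, `n_derived_tips`,
#'   `re_evolution`.
#' @export
count_originations <- function(events, tree, derived_states, tip_states,
                               major_min = 3) {
  tree <- validate_phylogeny(tree)
  n_tip <- length(tree$tip.label)
  is_derived <- function(s) s %in% derived_states
  gains <- events[!is_derived(events$from) & is_derived(events$to), ,
                  drop = FALSE]
  if (!nrow(gains))
    return(data.frame(branch = integer(0), parent_age = numeric(0),
                      class = character(0), n_derived_tips = integer(0),
                      re_evolution = logical(0)))
  tips_derived <- is_derived(tip_states[tree$tip.label])
  ## losses per branch for re-evolution scanning
  losses <- events$branch[is_derived(events$from) & !is_derived(events$to)]
  out <- lapply(seq_len(nrow(gains)), function(i) {
    b <- gains$branch[i]
    ct <- clade_tips(tree, b)
    nd <- sum(tips_derived[ct])
    cls <- if (b > n_tip && nd >= major_min) "major_clade" else "isolated_lineage"
    anc <- root_path(tree, b)
    re <- any(losses %in% anc[-length(anc)])
    data.frame(branch = b, parent_age = gains$parent_age[i], class = cls,
               n_derived_tips = nd, re_evolution = re,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pair same-direction changes of two traits on shared paths
#'
#' Pairs each change in one trait with the nearest same-direction change of
#' the other trait lying on the same root-to-descendant path, provided no
#' opposite-direction event of either trait intervenes on the path segment
#' between them; each event is pairable at most once. The initiator is the
#' temporally earlier event (`same_branch` when both sit on one branch).
#'
#' @param trait1_events,trait2_events `transition_events` frames from the
#'   same tree/reconstruction pair (e.g. cusp and diet).
#' @param tree the shared tree.
#' @return list of class `paired_changes`: `pairs` (data frame `branch1`,
#'   `branch2`, `direction`, `initiator`, `path_sep` in branch count) and
#'   `summary` (counts and paired fractions among increases and decreases).
#' @export
pair_changes <- function(trait1_events, trait2_events, tree) {
  tree <- validate_phylogeny(tree)
  paths <- lapply(seq_len(length(tree$tip.label) + tree$Nnode),
                  function(v) root_path(tree, v))
  depth <- lengths(paths)
  ## ancestry test: a on root path of b (or equal)
  on_path <- function(a, b) a == b || a %in% paths[[b]]
  tag <- function(df, w) {
    out <- df[, c("branch", "direction", "parent_age"), drop = FALSE]
    out$who <- rep(w, nrow(out))
    out
  }
  all_ev <- rbind(tag(trait1_events, 1L), tag(trait2_events, 2L))

  pairs <- NULL
  used1 <- logical(nrow(trait1_events))
  used2 <- logical(nrow(trait2_events))
  ## candidate pairs with path separation, scanned nearest-first
  cand <- NULL
  for (i in seq_len(nrow(trait1_events))) for (j in seq_len(nrow(trait2_events))) {
    if (trait1_events$direction[i] != trait2_events$direction[j]) next
    b1 <- trait1_events$branch[i]; b2 <- trait2_events$branch[j]
    if (!(on_path(b1, b2) || on_path(b2, b1))) next
    sep <- abs(depth[b1] - depth[b2])
    cand <- rbind(cand, data.frame(i = i, j = j, sep = sep))
  }
  if (!is.null(cand)) {
    cand <- cand[order(cand$sep), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used1[i] || used2[j]) next
      b1 <- trait1_events$branch[i]; b2 <- trait2_events$branch[j]
      dir <- trait1_events$direction[i]
      ## reversal blocking: no opposite-direction event of either trait
      ## strictly between the two branches on the path
      anc <- if (on_path(b1, b2)) b1 else b2
      des <- if (anc == b1) b2 else b1
      seg <- paths[[des]]
      seg <- seg[(which(seg == anc) + 1L):length(seg)]
      seg <- setdiff(seg, des)
      opp <- all_ev$branch[all_ev$direction != dir]
      if (length(seg) && any(opp %in% seg)) next
      initiator <- if (b1 == b2) "same_branch"
                   else if (anc == b1) paste0(trait1_events$trait[i], "_first")
                   else paste0(trait2_events$trait[j], "_first")
      pairs <- rbind(pairs, data.frame(branch1 = b1, branch2 = b2,
                                       direction = dir,
                                       initiator = initiator,
                                       path_sep = cand$sep[r],
                                       stringsAsFactors = FALSE))
      used1[i] <- TRUE; used2[j] <- TRUE
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(branch1 = integer(0), branch2 = integer(0),
                        direction = character(0), initiator = character(0),
                        path_sep = integer(0))
  n_inc <- sum(all_ev$direction == "increase")
  n_dec <- sum(all_ev$direction == "decrease")
  inc_paired <- 2 * sum(pairs$direction == "increase")
  dec_paired <- 2 * sum(pairs$direction == "decrease")
  structure(list(
    pairs = pairs,
    summary = list(n_increase_events = n_inc, n_decrease_events = n_dec,
                   n_pairs_increase = sum(pairs$direction == "increase"),
                   n_pairs_decrease = sum(pairs$direction == "decrease"),
                   paired_fraction_increase = if (n_inc) inc_paired / n_inc else NA,
                   paired_fraction_decrease = if (n_dec) dec_paired / n_dec else NA)),
    class = "paired_changes")
}

#' @export
print.paired_changes <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Paired changes: %d increase pairs (of %d events), %d decrease pairs (of %d events)\n",
              s$n_pairs_increase, s$n_increase_events,
              s$n_pairs_decrease, s$n_decrease_events))
  if (nrow(x$pairs)) print(table(x$pairs$initiator))
  invisible(x)
}

#' Time-binned lineage and change counts
#'
#' Counts, in half-open bins `[a, a + width)` Ma anchored at 0 Ma and
#' counting backwards in time, the number of lineages in each state (a
#' branch contributes one lineage to every bin its time interval overlaps;
#' its state in a bin is the child-node state) and the number of increase /
#' decrease events (assigned to the bin containing the branch midpoint).
#'
#' @inheritParams enumerate_transitions
#' @param bin_width bin width in My.
#' @return data frame of class `lineage_bins`: `bin_start`, `bin_end` (Ma,
#'   old to young edges), one lineage-count column per state, `n_increase`,
#'   `n_decrease`.
#' @export
bin_lineages <- function(tree, reconstruction, tip_states, bin_width = 10,
                         ordering = NULL) {
  stopifnot(bin_width > 0)
  tree <- validate_phylogeny(tree)
  ordering <- ordering %||% reconstruction$states
  st <- node_state_vector(tree, reconstruction, tip_states)
  age <- node_ages(tree)
  a_age <- age[tree$edge[, 1]]
  b_age <- age[tree$edge[, 2]]
  root_age <- max(age)
  n_bins <- ceiling(root_age / bin_width + 1e-12)
  lo <- (seq_len(n_bins) - 1) * bin_width
  hi <- lo + bin_width
  counts <- matrix(0L, n_bins, length(ordering),
                   dimnames = list(NULL, ordering))
  n_inc <- integer(n_bins); n_dec <- integer(n_bins)
  ev <- enumerate_transitions(tree, reconstruction, tip_states,
                              ordering = ordering)
  mid <- (ev$parent_age + ev$child_age) / 2
  for (bin in seq_len(n_bins)) {
    ## overlap of branch (child_age, parent_age) with [lo, hi)
    inbin <- b_age < hi[bin] & a_age > lo[bin]
    s <- st[tree$edge[inbin, 2]]
    tb <- table(factor(s, levels = ordering))
    counts[bin, ] <- as.integer(tb)
    evb <- mid >= lo[bin] & mid < hi[bin]
    n_inc[bin] <- sum(ev$direction[evb] == "increase")
    n_dec[bin] <- sum(ev$direction[evb] == "decrease")
  }
  out <- data.frame(bin_start = hi, bin_end = lo, counts,
                    n_increase = n_inc, n_decrease = n_dec,
                    check.names = FALSE)
  class(out) <- c("lineage_bins", "data.frame")
  out
}
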