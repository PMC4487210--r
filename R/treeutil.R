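# Tree helpers shared by the parsimony, likelihood and placement code.
# Trees are ape "phylo" objects; unrooted trees carry the usual basal
# trifurcation. Scoring code roots them arbitrarily (scores are
# root-invariant) and requires binary-resolved topologies.

as_rooted_binary <- function(tree) {
  if (!inherits(tree, "phylo")) stop("expected a phylo object")
  if (!ape::is.binary(tree))
    stop("binary-resolved trees required (found a multifurcation)")
  if (ape::is.rooted(tree)) return(tree)
  ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
}

# Likelihood traversal accepts the basal trifurcation of an unrooted
# tree directly (the pruning product is valid at any node under
# reversibility); only a true multifurcation elsewhere is rejected.
as_scoring_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("expected a phylo object")
  if (!ape::is.binary(tree))
    stop("binary-resolved trees required (found a multifurcation)")
  tree
}

root_node <- function(tree) setdiff(tree$edge[, 1], tree$edge[, 2])[1]

# Edge indices in an order where every edge appears after all edges in
# the subtree below it (children before parents).
postorder_edges <- function(tree) {
  E <- tree$edge
  kids <- split(seq_len(nrow(E)), E[, 1])
  res <- integer(nrow(E))
  pos <- nrow(E)
  stack <- kids[[as.character(root_node(tree))]]
  while (length(stack)) {
    e <- stack[length(stack)]
    stack <- stack[-length(stack)]
    res[pos] <- e; pos <- pos - 1L
    ch <- as.character(E[e, 2])
    if (!is.null(kids[[ch]])) stack <- c(stack, kids[[ch]])
  }
  # res holds the DFS preorder reversed (filled tail-first), which puts
  # every edge after all edges below it: a valid postorder.
  res
}

# Logical matrix (tips + internal nodes) x tips: which tips lie below
# each node (a tip lies below itself).
node_leafsets <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  below <- matrix(FALSE, nn, n)
  below[cbind(1:n, 1:n)] <- TRUE
  for (e in postorder_edges(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[p, ] <- below[p, ] | below[ch, ]
  }
  below
}

#' Canonical key for a bipartition of a taxon set
#'
#' The stored side is the one *not* containing the alphabetically first
#' taxon of the universe, so each split has exactly one key.
#' @param side character vector of taxon labels on one side.
#' @param labels the full taxon universe.
#' @return a single string key.
#' @export
split_key <- function(side, labels) {
  anchor <- sort(labels)[1]
  if (anchor %in% side) side <- setdiff(labels, side)
  paste(sort(side), collapse = ";")
}

#' Splits induced by the branches of a tree
#'
#' Every branch of the (unrooted) tree separates the taxa in two; this
#' returns the canonical key of each such split, indexed by edge.
#' @param tree a `phylo` object.
#' @param trivial include pendant-branch (single-taxon) splits.
#' @return data.frame with columns `edge`, `key`, `size` (taxa on the
#'   stored side).
#' @export
tree_splits <- function(tree, trivial = TRUE) {
  n <- length(tree$tip.label)
  below <- node_leafsets(tree)
  rows <- lapply(seq_len(nrow(tree$edge)), function(e) {
    side <- tree$tip.label[below[tree$edge[e, 2], ]]
    ns <- length(side)
    if (!trivial && (ns <= 1 || ns >= n - 1)) return(NULL)
    if (ns == 0 || ns == n) return(NULL)  # root edge of a rooted tree
    key <- split_key(side, tree$tip.label)
    data.frame(edge = e, key = key,
               size = length(strsplit(key, ";", fixed = TRUE)[[1]]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(edge = integer(0), key = character(0),
                      size = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attach a new tip along an existing branch
#'
#' Subdivides edge `edge` at a point `at` of the way from its child end
#' and hangs a new pendant branch of length `pendant` there. Used by the
#' insertion scan, evolutionary placement, and the synthetic-data
#' generators.
#'
#' @param tree a `phylo` object.
#' @param edge row index into `tree$edge`.
#' @param label new tip label.
#' @param pendant pendant branch length.
#' @param at fraction of the edge length left on the child side of the
#'   new attachment node (0 = attach at the child node).
#' @return list with the new `tree` and the indices of the `pendant_edge`,
#'   the child-side half (`lower_edge`) and parent-side half
#'   (`upper_edge`) in the new edge matrix.
#' @export
attach_tip <- function(tree, edge, label, pendant = 0.1, at = 0.5) {
  n <- length(tree$tip.label)
  stopifnot(edge >= 1, edge <= nrow(tree$edge))
  if (label %in% tree$tip.label) stop("duplicate taxon label: ", label)
  E <- tree$edge
  L <- tree$edge.length
  if (is.null(L)) L <- rep(1, nrow(E))
  E2 <- matrix(ifelse(E > n, E + 1L, E), ncol = 2)
  newtip <- n + 1L
  newnode <- n + 1L + tree$Nnode + 1L
  ch <- E2[edge, 2]; l <- L[edge]
  E2[edge, 2] <- newnode
  L[edge] <- l * (1 - at)
  E2 <- rbind(E2, c(newnode, ch), c(newnode, newtip))
  L <- c(L, l * at, pendant)
  out <- structure(list(edge = E2, edge.length = L,
                        tip.label = c(tree$tip.label, label),
                        Nnode = tree$Nnode + 1L),
                   class = "phylo")
  list(tree = out, pendant_edge = nrow(E2), lower_edge = nrow(E2) - 1L,
       upper_edge = edge)
}

# All nearest-neighbour-interchange rearrangements: for each internal
# edge (p,c), exchange one fixed neighbour subtree of p with each of c's
# two child subtrees (the two classical alternatives per edge). Branch
# lengths stay with their edge-matrix rows.
all_nni <- function(tree) {
  # a rooted root's two edges form a single unrooted branch, across which
  # child-swaps are degenerate; work on the unrooted representation
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  E <- tree$edge
  out <- list()
  for (e in which(E[, 2] > n)) {
    p <- E[e, 1]; ch <- E[e, 2]
    prows <- which(E[, 1] == p & seq_len(nrow(E)) != e)
    crows <- which(E[, 1] == ch)
    if (length(prows) == 0) next  # root edge of a rooted tree
    a <- prows[1]
    for (b in crows) {
      tr2 <- tree
      tmp <- tr2$edge[a, 2]
      tr2$edge[a, 2] <- tr2$edge[b, 2]
      tr2$edge[b, 2] <- tmp
      attr(tr2, "order") <- NULL
      out[[length(out) + 1L]] <- tr2
    }
  }
  out
}

# One random nearest-neighbour-interchange move; branch lengths stay with
# their edge-matrix rows (the proposal is symmetric). Used by the MCMC.
random_nni <- function(tree) {
  n <- length(tree$tip.label)
  E <- tree$edge
  internal <- which(E[, 2] > n)
  if (length(internal) == 0) return(tree)
  e <- internal[sample.int(length(internal), 1)]
  p <- E[e, 1]; ch <- E[e, 2]
  prows <- which(E[, 1] == p & seq_len(nrow(E)) != e)
  crows <- which(E[, 1] == ch)
  if (length(prows) == 0 || length(crows) == 0) return(tree)
  a <- prows[sample.int(length(prows), 1)]
  b <- crows[sample.int(length(crows), 1)]
  tmp <- E[a, 2]; E[a, 2] <- E[b, 2]; E[b, 2] <- tmp
  tree$edge <- E
  attr(tree, "order") <- NULL
  tree
}
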