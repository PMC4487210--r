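# Generalized Fitch parsimony over multistate characters with
# polymorphic leaf state sets (taken as-is) and missing cells (full
# state set), plus the exhaustive one-branch-at-a-time fossil insertion
# scan.

fitch_masks <- function(tree, m) {
  miss_tip <- setdiff(tree$tip.label, m$taxa)
  if (length(miss_tip))
    stop("leaf '", miss_tip[1], "' missing from matrix")
  tr <- as_rooted_binary(tree)
  n <- length(tr$tip.label)
  nn <- n + tr$Nnode
  nchr <- n_char(m)
  state <- matrix(0L, nn, nchr)
  state[1:n, ] <- m$masks[match(tr$tip.label, m$taxa), , drop = FALSE]
  list(tree = tr, state = state, n = n, nchr = nchr)
}

#' Fitch parsimony steps
#'
#' Total (optionally per-character) number of state changes required by
#' the matrix on the tree. Characters are unordered; missing cells enter
#' as the full alphabet, polymorphic cells as their state set. The count
#' is invariant to where the unrooted topology is rooted.
#'
#' @param tree a binary `phylo`; leaves must appear in `m`.
#' @param m a [data_matrix()].
#' @param weights per-character weights (default the matrix's).
#' @return list with `steps` (weighted total) and `per_character`
#'   (unweighted integer vector).
#' @export
fitch_steps <- function(tree, m, weights = NULL) {
  if (is.null(weights)) weights <- m$weights
  fm <- fitch_masks(tree, m)
  tr <- fm$tree
  state <- fm$state
  steps <- numeric(fm$nchr)
  seen <- logical(fm$n + tr$Nnode)
  seen[seq_len(fm$n)] <- TRUE
  for (e in postorder_edges(tr)) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    if (!seen[p]) {
      state[p, ] <- state[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(state[p, ], state[ch, ])
      clash <- inter == 0L
      steps[clash] <- steps[clash] + 1
      state[p, ] <- ifelse(clash, bitwOr(state[p, ], state[ch, ]), inter)
    }
  }
  list(steps = sum(weights * steps), per_character = as.integer(steps))
}

#' Minimum possible steps per character
#'
#' Number of states observed among scored, non-polymorphic cells minus
#' one (floored at zero): the denominator-free lower bound a character
#' can achieve on any tree.
#' @param m a [data_matrix()].
#' @return integer vector, one entry per character.
#' @export
min_steps <- function(m) {
  single <- matrix(bitwAnd(m$masks, m$masks - 1L) == 0L & !m$miss,
                   nrow(m$masks), ncol(m$masks))
  vapply(seq_len(n_char(m)), function(j) {
    obs <- unique(m$masks[single[, j], j])
    max(0L, length(obs) - 1L)
  }, 0L)
}

#' Per-character consistency index on a tree
#'
#' CI = minimum steps / observed steps; 1 for characters requiring no
#' homoplasy (and for invariant characters, where both are zero).
#' @inheritParams fitch_steps
#' @return numeric vector in (0, 1].
#' @export
consistency_index <- function(tree, m) {
  obs <- fitch_steps(tree, m)$per_character
  mn <- min_steps(m)
  ifelse(obs == 0, 1, pmin(1, ifelse(mn == 0, 1, mn / obs)))
}

#' Exhaustive insertion scan of a query taxon
#'
#' Attaches the query to every branch of the backbone in turn and records
#' the incremental parsimony steps added to the whole tree; ties in the
#' minimal set are reported, never broken.
#'
#' @param backbone a binary `phylo` *not* containing the query.
#' @param m a [data_matrix()] scoring the backbone taxa and the query.
#' @param query the query taxon label.
#' @param weights per-character weights.
#' @return an `insertion_scan` object: data.frame (`edge`, `split`,
#'   `steps_added`) sorted by `steps_added`, with attributes
#'   `base_steps`, `minimal_edges` and `query`.
#' @export
insertion_scan <- function(backbone, m, query, weights = NULL) {
  if (query %in% backbone$tip.label)
    stop("query '", query, "' already in the backbone")
  if (!query %in% m$taxa) stop("query '", query, "' not in the matrix")
  base <- fitch_steps(backbone, m, weights)$steps
  splits <- tree_splits(backbone, trivial = TRUE)
  sb <- vapply(seq_len(nrow(backbone$edge)), function(e) {
    ext <- attach_tip(backbone, e, query, pendant = 1)$tree
    fitch_steps(ext, m, weights)$steps - base
  }, 0)
  out <- data.frame(edge = seq_len(nrow(backbone$edge)),
                    split = splits$key[match(seq_len(nrow(backbone$edge)),
                                             splits$edge)],
                    steps_added = sb, stringsAsFactors = FALSE)
  out <- out[order(out$steps_added, out$edge), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_steps") <- base
  attr(out, "minimal_edges") <- out$edge[out$steps_added <=
                                           min(out$steps_added) + 1e-9]
  attr(out, "query") <- query
  class(out) <- c("insertion_scan", "data.frame")
  out
}

#' @export
print.insertion_scan <- function(x, ...) {
  cat(sprintf("insertion_scan of '%s': base %g steps, best +%g at %d branch(es)\n",
              attr(x, "query"), attr(x, "base_steps"), min(x$steps_added),
              length(attr(x, "minimal_edges"))))
  print.data.frame(head(x, 10))
  invisible(x)
}
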