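# Outgroup-as-query root-placement scans: each outgroup taxon is placed
# on an ingroup-only topology partition by partition, per-branch
# likelihood weights are aggregated into support for the competing root
# hypotheses, and gene jackknifing locates the partitions driving a
# contested root.

#' Classify an ingroup branch into a root hypothesis
#'
#' A root on a given ingroup branch implies a particular basal
#' arrangement. With clade definitions for the three competing
#' hypotheses (for Osmundaceae: H1 "paraphyletic Osmunda" roots between
#' Osmundastrum and the rest; H2 "monophyletic Osmunda" roots on the
#' Leptopteris+Todea stem; H3 isolates Osmunda s.str., implying an
#' Osmundastrum-Leptopteris-Todea clade), a branch maps to the
#' hypothesis whose defining taxon set it separates exactly, else to
#' `"other"`.
#'
#' @param tree the ingroup `phylo`.
#' @param edge row index into `tree$edge`.
#' @param clades named list of taxon-label vectors, e.g.
#'   `list(H1 = ..., H2 = ..., H3 = ...)`.
#' @return the matching clade name, or `"other"`.
#' @export
classify_branch <- function(tree, edge, clades) {
  below <- node_leafsets(tree)
  side <- tree$tip.label[below[tree$edge[edge, 2], ]]
  comp <- setdiff(tree$tip.label, side)
  for (h in names(clades)) {
    if (setequal(side, clades[[h]]) || setequal(comp, clades[[h]]))
      return(h)
  }
  "other"
}

count_variable_columns <- function(m) {
  sum(vapply(seq_len(n_char(m)), function(j) {
    scored <- which(!m$miss[, j])
    length(scored) >= 2 && length(unique(m$masks[scored, j])) > 1
  }, logical(1)))
}

#' Outgroup root-placement scan per partition
#'
#' For each partition, re-optimizes the ingroup branch lengths and model
#' (GTR+Gamma, empirical frequencies) on the partition's columns, places
#' every outgroup taxon as a likelihood query on every ingroup branch,
#' averages the per-branch likelihood weights over outgroups, and
#' aggregates them into per-hypothesis support via [classify_branch()].
#'
#' @param ingroup_tree binary `phylo` of the ingroup with branch lengths.
#' @param aln a nucleotide [data_matrix()] containing ingroup and
#'   outgroup taxa.
#' @param scheme a [partition_scheme()]; `NULL` treats the whole
#'   alignment as one partition.
#' @param outgroups outgroup taxon labels (in `aln`, not in the tree).
#' @param clades root-hypothesis clade definitions (see
#'   [classify_branch()]).
#' @param model optional fixed [subst_model()]; default fits GTR+Gamma4
#'   per partition.
#' @param optimize_rates also optimize exchangeabilities per partition.
#' @param min_variable partitions with fewer variable columns are
#'   flagged low-information (still reported).
#' @return a `root_support_report`: data.frame with one row per
#'   partition (support per hypothesis plus `other`, top branch and
#'   hypothesis, variable-column count); per-branch weight matrices in
#'   the `branch_weights` attribute.
#' @export
outgroup_root_scan <- function(ingroup_tree, aln, scheme = NULL, outgroups,
                               clades, model = NULL,
                               optimize_rates = TRUE, min_variable = 4) {
  stopifnot(aln$type == "nucleotide")
  if (is.null(scheme))
    scheme <- partition_scheme(list(all = seq_len(n_char(aln))))
  missing_og <- setdiff(outgroups, aln$taxa)
  if (length(missing_og)) stop("outgroup '", missing_og[1], "' not in alignment")
  if (any(outgroups %in% ingroup_tree$tip.label))
    stop("outgroups must be absent from the ingroup tree")
  outgroups <- sort(outgroups)  # scan invariant to input ordering
  hyps <- names(clades)
  ne <- nrow(ingroup_tree$edge)
  branch_class <- vapply(seq_len(ne), function(e)
    classify_branch(ingroup_tree, e, clades), "")
  rows <- list()
  bw_all <- list()
  for (part in names(scheme$cols)) {
    cols <- scheme$cols[[part]]
    sub <- aln[, cols]
    sub_in <- sub[ingroup_tree$tip.label, ]
    nv <- count_variable_columns(sub)
    if (is.null(model)) {
      fit <- optimize_model(ingroup_tree, sub_in,
                            optimize_rates = optimize_rates,
                            outer_iter = 1, brlen_sweeps = 2)
      tr <- fit$tree; mod <- fit$model
    } else {
      tr <- optimize_branch_lengths(ingroup_tree, sub_in, model,
                                    max_sweeps = 3, tol = 1e-4)$tree
      mod <- model
    }
    bw <- matrix(0, ne, length(outgroups),
                 dimnames = list(NULL, outgroups))
    for (og in outgroups) {
      tb <- place_query(tr, sub, og, scheme = "ML", model = mod)
      bw[tb$edge, og] <- tb$lweight
    }
    wmean <- rowMeans(bw)
    sup <- vapply(hyps, function(h) sum(wmean[branch_class == h]), 0)
    other <- sum(wmean[branch_class == "other"])
    top_edge <- which.max(wmean)
    rows[[part]] <- data.frame(
      subset = part, flag = unname(scheme$flags[part]),
      t(sup), other = other,
      top_edge = top_edge, top_hypothesis = branch_class[top_edge],
      n_variable = nv, low_information = nv < min_variable,
      stringsAsFactors = FALSE)
    bw_all[[part]] <- bw
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "branch_weights") <- bw_all
  attr(out, "branch_class") <- branch_class
  class(out) <- c("root_support_report", "data.frame")
  out
}

#' Gene jackknifing of the root scan
#'
#' Repeats [outgroup_root_scan()] on the concatenation, on each
#' partition alone, and on each leave-one-out concatenation (2P + 1
#' subsets for P partitions), exposing which partitions drive the root.
#'
#' @inheritParams outgroup_root_scan
#' @param mode which subsets to run.
#' @return a `root_support_report` with one row per subset (`concat`,
#'   `only:<name>`, `drop:<name>`).
#' @export
gene_jackknife <- function(ingroup_tree, aln, scheme, outgroups, clades,
                           model = NULL, optimize_rates = TRUE,
                           mode = c("all", "single", "leave-one-out",
                                    "concatenated")) {
  mode <- match.arg(mode)
  parts <- names(scheme$cols)
  subsets <- list()
  if (mode %in% c("all", "concatenated"))
    subsets[["concat"]] <- sort(unique(unlist(scheme$cols)))
  if (mode %in% c("all", "single"))
    for (p in parts) subsets[[paste0("only:", p)]] <- scheme$cols[[p]]
  if (mode %in% c("all", "leave-one-out"))
    for (p in parts) {
      rest <- sort(unique(unlist(scheme$cols[setdiff(parts, p)])))
      # with a single partition the leave-one-out subset is empty and is
      # skipped: single and concatenated runs already coincide
      if (length(rest)) subsets[[paste0("drop:", p)]] <- rest
    }
  rows <- list()
  bw <- list()
  for (nm in names(subsets)) {
    sc <- partition_scheme(setNames(list(subsets[[nm]]), nm))
    rep1 <- outgroup_root_scan(ingroup_tree, aln, sc, outgroups, clades,
                               model = model,
                               optimize_rates = optimize_rates)
    class(rep1) <- "data.frame"
    attr(rep1, "branch_weights") <- NULL
    rep1$subset <- nm
    rows[[nm]] <- rep1
    bw[[nm]] <- attr(rep1, "branch_weights")[[1]]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "branch_weights") <- bw
  class(out) <- c("root_support_report", "data.frame")
  out
}

#' Bootstrap support for focal splits across alignment subsets
#'
#' Runs the character bootstrap on each subset and reports the bootstrap
#' percentage of each named split (0 when absent from all replicates).
#'
#' @param m a [data_matrix()].
#' @param subsets named list of column-index vectors (e.g. jackknife
#'   subsets built from a [partition_scheme()]).
#' @param focal_splits named list of taxon-label vectors, each defining
#'   one side of a split of the full taxon set.
#' @param replicates,method,model,seed passed to [bootstrap_trees()].
#' @return matrix of bootstrap percentages, subsets x focal splits.
#' @export
split_support_scan <- function(m, subsets, focal_splits, replicates = 200,
                               method = "nj", model = NULL, seed = NULL) {
  stopifnot(is.list(subsets), !is.null(names(subsets)),
            is.list(focal_splits), !is.null(names(focal_splits)))
  keys <- vapply(focal_splits, function(s) split_key(s, m$taxa), "")
  out <- matrix(0, length(subsets), length(focal_splits),
                dimnames = list(names(subsets), names(focal_splits)))
  for (i in seq_along(subsets)) {
    ms <- m[, subsets[[i]]]
    bs <- bootstrap_trees(ms, replicates = replicates, method = method,
                          model = model, seed = seed)
    fr <- bipartition_frequencies(bs)
    hit <- match(keys, fr$key)
    out[i, !is.na(hit)] <- 100 * fr$freq[hit[!is.na(hit)]]
  }
  out
}
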