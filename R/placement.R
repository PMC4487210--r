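# Evolutionary-placement-style attachment of query taxa (fossils,
# outgroups) onto a fixed backbone: per-branch scores under parsimony or
# likelihood, softmax likelihood weights, character-weight calibration
# against the backbone, and cross-scheme swap reports.

#' Calibrate per-character weights against a backbone
#'
#' The three weighting schemes score how well each character fits the
#' backbone of extant taxa, and downweight ill-fitting (homoplastic)
#' characters before a query is placed:
#' * `MP`: the character's consistency index on the backbone;
#' * `ML_MK` / `ML_GTR`: `exp(l_c - max l)` from the per-character
#'   log-likelihoods on the backbone with optimized branch lengths,
#'   rescaled to mean one (`ML_MK`: uniform-frequency Mk; `ML_GTR`:
#'   frequency-augmented multistate model).
#'
#' @param backbone a binary `phylo` whose leaves are scored in `m`.
#' @param m a [data_matrix()] of the backbone (extant) taxa.
#' @param scheme `"MP"`, `"ML_MK"` or `"ML_GTR"`.
#' @return positive numeric weights, one per character.
#' @export
calibrate_character_weights <- function(backbone, m,
                                        scheme = c("MP", "ML_MK", "ML_GTR")) {
  scheme <- match.arg(scheme)
  mb <- m[backbone$tip.label, ]
  if (scheme == "MP") return(consistency_index(backbone, mb))
  model <- subst_model(if (scheme == "ML_MK") "mk" else "mk_freq")
  if (is.null(backbone$edge.length))
    backbone$edge.length <- rep(0.1, nrow(backbone$edge))
  ob <- optimize_branch_lengths(backbone, mb, model,
                                weights = rep(1, n_char(mb)),
                                max_sweeps = 5, tol = 1e-4)
  lc <- tree_loglik(ob$tree, mb, model)$per_character
  w <- exp(lc - max(lc))
  w / mean(w)
}

#' Place a query taxon on every branch of a backbone
#'
#' Attaches the query at each branch midpoint. Likelihood schemes
#' optimize the pendant branch length only and report softmax likelihood
#' weights over branches; parsimony reports weighted step increases and
#' ranks. An all-missing query yields a uniform table with a warning.
#'
#' @param backbone a binary `phylo` (branch lengths required for ML).
#' @param m a [data_matrix()] scoring backbone taxa and the query.
#' @param query query taxon label (not in the backbone).
#' @param scheme `"ML_MK"`, `"ML_GTR"`, `"MP"`, or `"ML"` with an
#'   explicit `model` (e.g. GTR for molecular outgroup placement).
#' @param model a [subst_model()]; defaults follow the scheme.
#' @param weights per-character weights (e.g. from
#'   [calibrate_character_weights()]); default 1.
#' @param pendant_bounds search interval for the pendant length.
#' @param optimize `"pendant"` (default, the standard placement
#'   economy): optimize only the new pendant branch; `"local"`: also the
#'   two halves of the subdivided attachment branch; `"two-stage"`: rank
#'   all branches with the pendant economy, then re-evaluate the
#'   `refine_top` best candidates with all branch lengths re-optimized
#'   (the usual thorough-placement heuristic); `"full"`: re-optimize all
#'   branch lengths at every attachment.
#' @param refine_top number of stage-one candidates re-evaluated under
#'   `"two-stage"`.
#' @return a `placement_table`: data.frame (`edge`, `split`, `score`,
#'   `lweight`, `pendant`, `rank`) sorted by rank, with attributes
#'   `best_edges` (tie set), `query`, `scheme`.
#' @export
place_query <- function(backbone, m, query,
                        scheme = c("ML_MK", "ML_GTR", "MP", "ML"),
                        model = NULL, weights = NULL,
                        pendant_bounds = c(1e-8, 10),
                        optimize = c("pendant", "local", "two-stage", "full"),
                        refine_top = 5) {
  scheme <- match.arg(scheme)
  optimize <- match.arg(optimize)
  if (query %in% backbone$tip.label)
    stop("query '", query, "' already in the backbone")
  if (!query %in% m$taxa) stop("query '", query, "' not in the matrix")
  if (is.null(weights)) weights <- rep(1, n_char(m))
  qi <- match(query, m$taxa)
  if (all(m$miss[qi, ])) {
    ne <- nrow(backbone$edge)
    warning("query '", query, "' has no scored characters; uniform table")
    splits <- tree_splits(backbone, trivial = TRUE)
    out <- data.frame(edge = seq_len(ne),
                      split = splits$key[match(seq_len(ne), splits$edge)],
                      score = 0, lweight = 1 / ne, pendant = NA_real_,
                      rank = 1L, stringsAsFactors = FALSE)
    attr(out, "best_edges") <- out$edge
    attr(out, "query") <- query
    attr(out, "scheme") <- scheme
    class(out) <- c("placement_table", "data.frame")
    return(out)
  }
  if (sum(!m$miss[qi, ]) < 1) stop("query must be scored for >= 1 character")
  if (scheme == "MP") {
    scan <- insertion_scan(backbone, m, query, weights = weights)
    out <- data.frame(edge = scan$edge, split = scan$split,
                      score = -scan$steps_added, lweight = NA_real_,
                      pendant = NA_real_,
                      rank = rank(scan$steps_added, ties.method = "min"),
                      stringsAsFactors = FALSE)
    best <- attr(scan, "minimal_edges")
  } else {
    if (is.null(model))
      model <- subst_model(if (scheme == "ML_GTR") "mk_freq" else "mk")
    if (is.null(backbone$edge.length))
      stop("backbone needs branch lengths for likelihood placement")
    ne <- nrow(backbone$edge)
    splits <- tree_splits(backbone, trivial = TRUE)
    score <- pend <- numeric(ne)
    m <- with_lik_cache(m)
    score_attachment <- function(e, mode) {
      att <- attach_tip(backbone, e, query, pendant = 0.05, at = 0.5)
      edges_opt <- switch(mode,
        pendant = att$pendant_edge,
        local = c(att$pendant_edge, att$lower_edge, att$upper_edge),
        full = NULL)
      ob <- optimize_branch_lengths(att$tree, m, model, weights,
                                    edges = edges_opt,
                                    max_sweeps = switch(mode, pendant = 1,
                                                        local = 3, full = 3),
                                    tol = 1e-4, bounds = pendant_bounds)
      c(ob$loglik, ob$tree$edge.length[att$pendant_edge])
    }
    stage1 <- if (optimize == "two-stage") "pendant" else optimize
    for (e in seq_len(ne)) {
      sc <- score_attachment(e, stage1)
      score[e] <- sc[1]; pend[e] <- sc[2]
    }
    if (optimize == "two-stage") {
      top <- order(-score)[seq_len(min(refine_top, ne))]
      for (e in top) {
        sc <- score_attachment(e, "full")
        if (sc[1] > score[e]) { score[e] <- sc[1]; pend[e] <- sc[2] }
      }
    }
    lw <- exp(score - max(score))
    lw <- lw / sum(lw)
    out <- data.frame(edge = seq_len(ne),
                      split = splits$key[match(seq_len(ne), splits$edge)],
                      score = score, lweight = lw, pendant = pend,
                      rank = rank(-score, ties.method = "min"),
                      stringsAsFactors = FALSE)
    best <- out$edge[out$score >= max(out$score) - 1e-9]
  }
  out <- out[order(out$rank, out$edge), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "best_edges") <- best
  attr(out, "query") <- query
  attr(out, "scheme") <- scheme
  class(out) <- c("placement_table", "data.frame")
  out
}

#' @export
print.placement_table <- function(x, ...) {
  cat(sprintf("placement of '%s' (%s): best branch %s\n",
              attr(x, "query"), attr(x, "scheme"),
              paste(attr(x, "best_edges"), collapse = ",")))
  print.data.frame(head(x, 10))
  invisible(x)
}

#' Compare a query's placements across weighting schemes
#'
#' @param tables named list of `placement_table`s for one query.
#' @return a `swap_report` row: per-scheme best branch and a `swap` flag,
#'   true iff the schemes disagree on the best branch.
#' @export
compare_schemes <- function(tables) {
  stopifnot(length(tables) >= 1, !is.null(names(tables)))
  q <- unique(vapply(tables, attr, "", "query"))
  if (length(q) != 1) stop("tables must describe a single query")
  best <- vapply(tables, function(tb) tb$edge[1], 0L)
  best_split <- vapply(tables, function(tb) tb$split[1], "")
  wt <- vapply(tables, function(tb)
    if (is.na(tb$lweight[1])) NA_real_ else tb$lweight[1], 0)
  out <- data.frame(query = q, scheme = names(tables), best_edge = best,
                    best_split = best_split, best_weight = wt,
                    stringsAsFactors = FALSE)
  attr(out, "swap") <- length(unique(best)) >= 2
  class(out) <- c("swap_report", "data.frame")
  out
}

#' Write placements as a jplace-style record
#'
#' Emits the reference tree with edge numbers in braces and one
#' placement entry per query table, in the usual
#' `[edge, score, like_weight_ratio, distal_length, pendant_length]`
#' field layout.
#' @param backbone the reference `phylo`.
#' @param tables list of `placement_table`s.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_jplace <- function(backbone, tables, file) {
  if (inherits(tables, "placement_table")) tables <- list(tables)
  txt <- jplace_newick(backbone)
  halflen <- if (is.null(backbone$edge.length))
    rep(0, nrow(backbone$edge)) else backbone$edge.length / 2
  placements <- lapply(tables, function(tb) {
    lw <- if (all(is.na(tb$lweight))) rep(NA, nrow(tb)) else tb$lweight
    list(p = lapply(seq_len(nrow(tb)), function(i)
      list(tb$edge[i] - 1L, tb$score[i],
           if (is.na(lw[i])) 0 else lw[i],
           halflen[tb$edge[i]],
           if (is.na(tb$pendant[i])) 0 else tb$pendant[i])),
      n = list(attr(tb, "query")))
  })
  obj <- list(tree = txt, placements = placements,
              fields = list("edge_num", "likelihood", "like_weight_ratio",
                            "distal_length", "pendant_length"),
              version = 3,
              metadata = list(invocation = "fossilgraft::write_jplace"))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(file)
}

# newick with {edge_index} tags after branch lengths (jplace convention)
jplace_newick <- function(tree) {
  E <- tree$edge
  L <- tree$edge.length
  if (is.null(L)) L <- rep(0, nrow(E))
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(E)), E[, 1])
  rec <- function(node, edge_in) {
    inner <- if (node <= n) quote_label(tree$tip.label[node]) else {
      sub <- vapply(kids[[as.character(node)]], function(e)
        rec(E[e, 2], e), "")
      paste0("(", paste(sub, collapse = ","), ")")
    }
    if (is.na(edge_in)) inner else
      sprintf("%s:%.12g{%d}", inner, L[edge_in], edge_in - 1L)
  }
  paste0(rec(root_node(tree), NA), ";")
}
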