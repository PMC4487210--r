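# Weighted split systems (the machinery behind splits-graph figures):
# canonical bipartitions, bootstrap/posterior bipartition frequencies,
# and support overlays onto a network.

#' Weighted system of splits over a taxon set
#'
#' @param labels taxon labels.
#' @param sides list of integer vectors: for each split, the indices (into
#'   `labels`) of the side *not* containing the first taxon.
#' @param weights non-negative split weights.
#' @param ordering optional circular ordering (labels) the splits are
#'   compatible with.
#' @return an object of class `split_system`.
#' @export
split_system <- function(labels, sides = list(), weights = numeric(0),
                         ordering = NULL) {
  stopifnot(length(sides) == length(weights), all(weights >= 0))
  sides <- lapply(sides, function(s) {
    s <- sort(as.integer(s))
    if (length(s) == 0 || length(s) >= length(labels))
      stop("a split must leave both sides non-empty")
    if (1L %in% s) s <- setdiff(seq_along(labels), s)
    s
  })
  if (!is.null(ordering)) stopifnot(setequal(ordering, labels))
  structure(list(labels = labels, sides = sides,
                 weights = as.numeric(weights), ordering = ordering,
                 annotations = NULL),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  cat(sprintf("split_system: %d taxa, %d splits%s\n", length(x$labels),
              length(x$weights),
              if (!is.null(x$ordering)) " (circular)" else ""))
  invisible(x)
}

split_system_keys <- function(ss)
  vapply(ss$sides, function(s) split_key(ss$labels[s], ss$labels), "")

#' Pairwise distances induced by a weighted split system
#'
#' d(i,j) = sum of the weights of the splits separating i and j. Used to
#' measure how faithfully a neighbour-net represents its input distances.
#' @param ss a `split_system`.
#' @return a symmetric matrix.
#' @export
split_distances <- function(ss) {
  n <- length(ss$labels)
  d <- matrix(0, n, n, dimnames = list(ss$labels, ss$labels))
  for (k in seq_along(ss$weights)) {
    inside <- seq_len(n) %in% ss$sides[[k]]
    sep <- outer(inside, inside, "!=")
    d <- d + ss$weights[k] * sep
  }
  d
}

#' Bipartition frequencies in a tree sample
#'
#' The fraction of trees (treated unrooted) containing each non-trivial
#' split. This is the bootstrap-support / posterior-probability engine.
#' @param sample a `multiPhylo` (all trees on the same taxon set).
#' @return data.frame with columns `key` and `freq`, plus a `sides`
#'   attribute (taxon-label vectors per split).
#' @export
bipartition_frequencies <- function(sample) {
  if (inherits(sample, "phylo")) sample <- structure(list(sample), class = "multiPhylo")
  taxa <- sort(sample[[1]]$tip.label)
  counts <- new.env(parent = emptyenv())
  sides <- new.env(parent = emptyenv())
  for (tr in sample) {
    if (!setequal(tr$tip.label, taxa))
      stop("trees have mismatched taxon sets")
    if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
    sp <- tree_splits(tr, trivial = FALSE)
    for (i in seq_len(nrow(sp))) {
      k <- sp$key[i]
      counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
      if (is.null(sides[[k]]))
        sides[[k]] <- strsplit(k, ";", fixed = TRUE)[[1]]
    }
  }
  keys <- ls(counts)
  out <- data.frame(key = keys,
                    freq = vapply(keys, function(k) counts[[k]], 0) / length(sample),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$freq, out$key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sides") <- lapply(out$key, function(k) sides[[k]])
  out
}

#' Annotate network splits with per-method support
#'
#' Each split of the network gains one support value per method (0 when
#' the split never occurs in that method's tree sample); sample splits
#' absent from the network are reported separately.
#' @param net a `split_system`.
#' @param freqs named list of [bipartition_frequencies()] tables, e.g.
#'   `list(BS_NJ = ..., PP = ...)`. Values on the method's own scale
#'   (bootstrap percent, posterior probability).
#' @return `net` with an `annotations` matrix (splits x methods) and an
#'   `unrepresented` attribute listing sample-only splits.
#' @export
support_overlay <- function(net, freqs) {
  stopifnot(inherits(net, "split_system"), is.list(freqs),
            !is.null(names(freqs)))
  keys <- split_system_keys(net)
  ann <- matrix(0, length(keys), length(freqs),
                dimnames = list(NULL, names(freqs)))
  extra <- list()
  for (mth in names(freqs)) {
    tab <- freqs[[mth]]
    hit <- match(keys, tab$key)
    ann[!is.na(hit), mth] <- tab$freq[hit[!is.na(hit)]]
    extra[[mth]] <- tab[!(tab$key %in% keys), , drop = FALSE]
  }
  net$annotations <- ann
  attr(net, "unrepresented") <- extra
  net
}
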