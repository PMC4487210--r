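# Neighbour-net: agglomerative construction of a circular taxon ordering
# (Bryant & Moulton's generalization of neighbor joining to split
# networks) followed by constrained least-squares estimation of the
# weights of all ordering-compatible splits.

# 3 -> 2 node reduction: nodes a - b - c on the agglomeration path are
# replaced by two nodes stored at a's and c's positions; b is retired.
nn_reduce3 <- function(d, a, b, c) {
  u <- (2 * d[a, ] + d[b, ]) / 3
  v <- (2 * d[c, ] + d[b, ]) / 3
  uv <- (d[a, b] + d[a, c] + d[b, c]) / 3
  d[a, ] <- d[, a] <- u
  d[c, ] <- d[, c] <- v
  d[b, ] <- d[, b] <- 0
  d[a, c] <- d[c, a] <- uv
  d[a, a] <- d[c, c] <- 0
  d
}

# average distance from each of the nodes `xs` to every other selected
# node and to each remaining cluster
nn_rowsums <- function(d, xs, clusters) {
  vapply(seq_along(xs), function(i) {
    s <- sum(d[xs[i], xs[-i]])
    for (cl in clusters) s <- s + mean(d[xs[i], cl$nodes])
    s
  }, 0)
}

# deterministic arg-min over the upper triangle: first (by row-major
# order) pair attaining the minimum within a small tolerance
first_min_pair <- function(Q) {
  l <- nrow(Q)
  best <- Inf; bi <- 1L; bj <- 2L
  for (i in seq_len(l - 1)) {
    for (j in (i + 1):l) {
      if (Q[i, j] < best - 1e-12) { best <- Q[i, j]; bi <- i; bj <- j }
    }
  }
  c(bi, bj)
}

# circular ordering by agglomeration over clusters holding 1-2 active
# nodes; returns taxon indices in cyclic order
nn_ordering <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), function(i) list(nodes = i, path = i))
  DM <- d
  while (length(clusters) > 1) {
    l <- length(clusters)
    if (l > 2) {
      r <- rowSums(DM) / (l - 2)
      sel <- first_min_pair(DM - outer(r, r, "+"))
    } else sel <- c(1L, 2L)
    A <- clusters[[sel[1]]]; B <- clusters[[sel[2]]]
    nA <- length(A$nodes); nB <- length(B$nodes)
    if (nA == 1 && nB == 1) {
      newc <- list(nodes = c(A$nodes, B$nodes), path = c(A$path, B$path))
    } else {
      # choose the junction endpoints x in A, y in B by the NJ criterion
      # applied to the individual endpoint nodes vs the other clusters
      endpoints <- c(A$nodes, B$nodes)
      others <- clusters[-sel]
      mh <- length(endpoints) + length(others)
      r2 <- nn_rowsums(d, endpoints, others)
      if (mh > 2) r2 <- r2 / (mh - 2)
      Q2 <- outer(seq_len(nA), seq_len(nB), function(i, j)
        d[cbind(endpoints[i], endpoints[nA + j])] - r2[i] - r2[nA + j])
      pick <- arrayInd(which.min(Q2), dim(Q2))
      xi <- pick[1]; yi <- pick[2]
      # orient A to end at x and B to start at y, then fuse the chain of
      # active nodes, reducing interior nodes pairwise
      pathA <- A$path; chainA <- A$nodes
      if (nA == 2 && xi == 1) { pathA <- rev(pathA); chainA <- rev(chainA) }
      pathB <- B$path; chainB <- B$nodes
      if (nB == 2 && yi == 2) { pathB <- rev(pathB); chainB <- rev(chainB) }
      chain <- c(chainA, chainB)
      while (length(chain) > 2) {
        d <- nn_reduce3(d, chain[1], chain[2], chain[3])
        chain <- chain[-2]
      }
      newc <- list(nodes = chain, path = c(pathA, pathB))
    }
    clusters[[sel[1]]] <- newc
    clusters <- clusters[-sel[2]]
    # refresh cluster-level average distances against the fused cluster
    l <- length(clusters)
    DM <- matrix(0, l, l)
    for (i in seq_len(l))
      for (j in seq_len(l))
        if (i != j)
          DM[i, j] <- mean(d[clusters[[i]]$nodes, clusters[[j]]$nodes])
  }
  clusters[[1]]$path
}

#' Non-negative least-squares split weights for a circular ordering
#'
#' Minimizes the squared error between the observed pairwise distances
#' and the path-sum distances of the n(n-1)/2 splits compatible with the
#' ordering, subject to non-negative weights.
#'
#' @param D a `dist_matrix` (no undefined pairs).
#' @param ordering circular ordering: taxon labels or indices.
#' @return a `split_system` carrying all compatible splits and their
#'   fitted weights (including zeros), with a `residual` attribute (the
#'   root-mean-square distance residual).
#' @export
nnls_split_weights <- function(D, ordering) {
  d <- D$d
  if (anyNA(d)) stop("undefined distances (no shared characters) present")
  n <- length(D$labels)
  ord <- if (is.character(ordering)) match(ordering, D$labels) else as.integer(ordering)
  if (anyNA(ord) || !setequal(ord, seq_len(n)))
    stop("ordering must cover all taxa exactly once")
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  dvec <- d[pairs]
  sides <- list()
  cols <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inside <- logical(n)
      inside[ord[i:(j - 1)]] <- TRUE
      sides[[length(sides) + 1L]] <- which(inside)
      cols[[length(cols) + 1L]] <- as.numeric(inside[pairs[, 1]] != inside[pairs[, 2]])
    }
  }
  A <- do.call(cbind, cols)
  fit <- pracma::lsqnonneg(A, dvec)
  w <- fit$x
  ss <- split_system(D$labels, sides, pmax(w, 0), ordering = D$labels[ord])
  attr(ss, "residual") <- sqrt(mean((A %*% w - dvec)^2))
  ss
}

#' Neighbour-net circular split system from a distance matrix
#'
#' Builds the circular taxon ordering by pairwise agglomeration (clusters
#' hold one or two active nodes; the NJ-style rate-adjusted criterion
#' selects first the cluster pair and then the junction nodes; fused
#' paths are reduced by the standard 3-to-2 node formulas), then fits
#' non-negative least-squares weights for all ordering-compatible splits
#' and keeps those above `threshold`.
#'
#' @param D a `dist_matrix` from [mean_distance_matrix()] (all pairs
#'   defined).
#' @param threshold minimum reported split weight; splits below it are
#'   treated as numerical noise.
#' @return a `split_system` with circular ordering and a `residual`
#'   attribute.
#' @export
neighbor_net <- function(D, threshold = 1e-8) {
  d <- D$d
  if (anyNA(d)) stop("undefined distances (no shared characters); cannot build a neighbour-net")
  n <- length(D$labels)
  if (n < 2) stop("need at least 2 taxa")
  ord <- if (n <= 3) seq_len(n) else nn_ordering(d)
  ss <- nnls_split_weights(D, ord)
  keep <- ss$weights > threshold
  out <- split_system(D$labels, ss$sides[keep], ss$weights[keep],
                      ordering = ss$ordering)
  attr(out, "residual") <- attr(ss, "residual")
  out
}
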