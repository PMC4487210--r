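# Felsenstein pruning likelihoods. Categorical characters use their own
# observed alphabets (k >= 2 per character) and closed-form Mk / F81-type
# transitions, vectorized across characters sharing a state count;
# nucleotide data uses GTR(+Gamma) over compressed column patterns.
# Likelihoods are invariant to root placement (all chains reversible);
# input trees are rooted arbitrarily for the traversal.

# per-character local alphabets for a categorical matrix: observed
# states, padded to at least two
char_local_info <- function(m) {
  K <- length(m$alphabet)
  lapply(seq_len(n_char(m)), function(j) {
    scored <- !m$miss[, j]
    obs_mask <- if (any(scored)) Reduce(bitwOr, m$masks[scored, j]) else 0L
    bits <- which(bitwAnd(bitwShiftR(obs_mask, 0:(K - 1)), 1L) == 1L)
    if (length(bits) < 2) bits <- sort(unique(c(bits, setdiff(seq_len(K), bits)[
      seq_len(2 - length(bits))])))
    counts <- rep(0.5, length(bits))  # pseudocount keeps frequencies positive
    for (i in which(scored)) {
      st <- which(bitwAnd(bitwShiftR(m$masks[i, j], bits - 1L), 1L) == 1L)
      if (length(st)) counts[st] <- counts[st] + 1 / length(st)
    }
    list(bits = bits, k = length(bits), pi = counts / sum(counts))
  })
}

# leaf partial-likelihood indicators for the characters in `chars`, all
# sharing state count k: array k x length(chars) per tip, flattened into
# a list over tips
leaf_partials <- function(m, tip_taxa, chars, info) {
  k <- info[[chars[1]]]$k
  lapply(tip_taxa, function(tx) {
    i <- match(tx, m$taxa)
    v <- matrix(0, k, length(chars))
    for (cc in seq_along(chars)) {
      j <- chars[cc]
      if (m$miss[i, j]) { v[, cc] <- 1; next }
      bits <- info[[j]]$bits
      v[, cc] <- as.numeric(bitwAnd(bitwShiftR(m$masks[i, j], bits - 1L), 1L) == 1L)
      if (all(v[, cc] == 0)) v[, cc] <- 1  # state outside local alphabet: treat as no information
    }
    v
  })
}

# Model-independent per-matrix scoring structures (local alphabets, leaf
# indicator partials, pattern compression). Rebuilding these dominates
# the cost of repeated likelihood evaluations on a fixed matrix, so
# looping callers (branch optimization, placement, MCMC) attach them
# once via with_lik_cache().
categorical_cache <- function(m) {
  cached <- attr(m, "cat_cache")
  if (!is.null(cached)) return(cached)
  info <- char_local_info(m)
  ks <- vapply(info, `[[`, 0L, "k")
  groups <- lapply(sort(unique(ks)), function(k) {
    chars <- which(ks == k)
    tp <- leaf_partials(m, m$taxa, chars, info)
    names(tp) <- m$taxa
    list(k = k, chars = chars, partials = tp)
  })
  names(groups) <- as.character(vapply(groups, `[[`, 0L, "k"))
  list(info = info, ks = ks, groups = groups)
}

dna_cache <- function(m) {
  cached <- attr(m, "dna_cache")
  if (!is.null(cached)) return(cached)
  cp <- compress_patterns(m)
  reps <- cp$representatives
  tp <- lapply(m$taxa, function(tx) {
    i <- match(tx, m$taxa)
    v <- matrix(0, 4, length(reps))
    for (cc in seq_along(reps)) {
      j <- reps[cc]
      v[, cc] <- if (m$miss[i, j]) 1 else
        as.numeric(bitwAnd(bitwShiftR(m$masks[i, j], 0:3), 1L) == 1L)
    }
    v
  })
  names(tp) <- m$taxa
  list(cp = cp, partials = tp)
}

#' Attach likelihood scoring caches to a matrix
#'
#' Precomputes the model-independent structures repeated likelihood
#' evaluations need (per-character observed alphabets and leaf
#' indicators; compressed patterns for nucleotide data). Purely an
#' optimization: results are identical with or without the cache.
#' @param m a [data_matrix()].
#' @return `m` with cache attributes set.
#' @export
with_lik_cache <- function(m) {
  if (m$type == "nucleotide") attr(m, "dna_cache") <- dna_cache(m)
  else attr(m, "cat_cache") <- categorical_cache(m)
  m
}

# pruning over a k-group of categorical characters; returns per-character
# log-likelihoods. pimat: k x ncg frequencies; beta: decay rate per char.
prune_categorical <- function(tree, tips_part, pimat, beta, po = NULL) {
  k <- nrow(pimat)
  ncg <- ncol(pimat)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  partial <- vector("list", nn)
  partial[seq_len(n)] <- tips_part
  logscale <- 0
  if (is.null(po)) po <- postorder_edges(tree)
  E <- tree$edge; L <- tree$edge.length
  for (e in po) {
    p <- E[e, 1]; ch <- E[e, 2]
    V <- partial[[ch]]
    efac <- exp(-beta * L[e])
    # (P %*% V)_i with P_ij = e*delta_ij + (1-e)*pi_j:
    # e*V_i + (1-e) * sum_j pi_j V_j  (same for every row i)
    cs <- colSums(pimat * V)
    W <- V * rep(efac, each = k) +
      matrix((1 - efac) * cs, k, ncg, byrow = TRUE)
    if (is.null(partial[[p]])) partial[[p]] <- W
    else {
      W <- partial[[p]] * W
      mx <- max(W)
      # rescale lazily; double range keeps per-column precision safe at
      # the tree sizes this package targets
      if (mx > 0 && mx < 1e-32) {
        W <- W / mx
        logscale <- logscale + log(mx)
      }
      partial[[p]] <- W
    }
  }
  Vr <- partial[[tree$edge[po[length(po)], 1]]]
  log(colSums(pimat * Vr)) + logscale
}

loglik_categorical <- function(tree, m, model, weights, ascertainment,
                               po = NULL) {
  tr <- as_scoring_tree(tree)
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (is.null(po)) po <- postorder_edges(tr)
  cache <- categorical_cache(m)
  info <- cache$info
  ll <- numeric(n_char(m))
  for (grp in cache$groups) {
    k <- grp$k
    chars <- grp$chars
    if (model$kind == "mk") {
      pimat <- matrix(1 / k, k, length(chars))
      beta <- rep(k / (k - 1), length(chars))
    } else {
      pimat <- vapply(chars, function(j) info[[j]]$pi, numeric(k))
      pimat <- matrix(pimat, nrow = k)
      beta <- 1 / (1 - colSums(pimat^2))
    }
    tp <- grp$partials[tr$tip.label]
    ll[chars] <- prune_categorical(tr, tp, pimat, beta, po)
    if (ascertainment == "variable") {
      # probability of a constant column, per character: k pseudo-columns
      # each fixing all leaves to one local state
      ncg <- length(chars)
      pim2 <- pimat[, rep(seq_len(ncg), each = k), drop = FALSE]
      beta2 <- rep(beta, each = k)
      const_tp <- lapply(seq_along(tp), function(i) {
        out <- matrix(0, k, ncg * k)
        for (cc in seq_len(ncg))
          for (s in seq_len(k)) out[s, (cc - 1) * k + s] <- 1
        out
      })
      lc <- prune_categorical(tr, const_tp, pim2, beta2, po)
      pconst <- vapply(seq_len(ncg), function(cc)
        sum(exp(lc[(cc - 1) * k + seq_len(k)])), 0)
      ll[chars] <- ll[chars] - log1p(-pconst)
    }
  }
  bad <- !is.finite(ll)
  if (any(bad))
    warning("zero-probability configuration for character(s) ",
            paste(head(which(bad), 5), collapse = ","),
            " (conflict across zero-length branches)")
  list(loglik = sum(weights * ll), per_character = ll)
}

prune_dna <- function(tree, tips_part, P_edges, pi, po = NULL) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  partial <- vector("list", nn)
  partial[seq_len(n)] <- tips_part
  logscale <- 0
  E <- tree$edge
  if (is.null(po)) po <- postorder_edges(tree)
  for (e in po) {
    p <- E[e, 1]; ch <- E[e, 2]
    W <- P_edges[[e]] %*% partial[[ch]]
    if (is.null(partial[[p]])) partial[[p]] <- W
    else {
      W <- partial[[p]] * W
      mx <- max(W)
      if (mx > 0 && mx < 1e-32) {
        W <- W / mx
        logscale <- logscale + log(mx)
      }
      partial[[p]] <- W
    }
  }
  log(colSums(pi * partial[[tree$edge[po[length(po)], 1]]])) + logscale
}

loglik_dna <- function(tree, m, model, weights, ascertainment, po = NULL) {
  tr <- as_scoring_tree(tree)
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (is.null(po)) po <- postorder_edges(tr)
  cache <- dna_cache(m)
  cp <- cache$cp
  tp <- cache$partials[tr$tip.label]
  rates <- gamma_rates(model$alpha, model$ncat)
  pi <- model$pi
  U <- model$eig$U; Uinv <- model$eig$Uinv; ev <- model$eig$values
  pmat <- function(t) U %*% (Uinv * exp(ev * t))
  per_cat <- lapply(rates, function(r) {
    P_edges <- lapply(tr$edge.length * r, pmat)
    prune_dna(tr, tp, P_edges, pi, po)
  })
  M <- do.call(rbind, per_cat)  # categories x patterns, log scale
  mx <- M[1, ]
  for (r in seq_len(nrow(M))[-1]) mx <- pmax(mx, M[r, ])
  llpat <- mx + log(colMeans(exp(sweep(M, 2, mx))))
  if (ascertainment == "variable") {
    const_tp <- lapply(seq_along(tp), function(i) diag(4))
    lc_cat <- lapply(rates, function(r) {
      P_edges <- lapply(tr$edge.length * r, pmat)
      prune_dna(tr, const_tp, P_edges, pi, po)
    })
    Mc <- do.call(rbind, lc_cat)
    mxc <- Mc[1, ]
    for (r in seq_len(nrow(Mc))[-1]) mxc <- pmax(mxc, Mc[r, ])
    pconst <- sum(exp(mxc + log(colMeans(exp(sweep(Mc, 2, mxc))))))
    llpat <- llpat - log1p(-pconst)
  }
  ll <- llpat[cp$index]
  list(loglik = sum(weights * ll), per_character = ll)
}

#' Tree log-likelihood by Felsenstein pruning
#'
#' @param tree a binary `phylo` with branch lengths; may be unrooted (it
#'   is rooted arbitrarily; reversibility makes the result
#'   root-invariant).
#' @param m a [data_matrix()].
#' @param model a [subst_model()]. Categorical matrices use `"mk"` or
#'   `"mk_freq"` with per-character observed alphabets; nucleotide
#'   matrices use `"gtr"` over compressed column patterns.
#' @param weights per-character weights (default the matrix's).
#' @param ascertainment `"none"`, or `"variable"` for the
#'   variable-characters-only conditioning of Lewis' Mkv: each
#'   character's likelihood is divided by one minus the probability of a
#'   constant column on the same tree.
#' @return list with `loglik` (weighted total) and `per_character`
#'   (unweighted log-likelihood per column).
#' @export
tree_loglik <- function(tree, m, model, weights = NULL,
                        ascertainment = c("none", "variable"),
                        .po = NULL) {
  ascertainment <- match.arg(ascertainment)
  if (is.null(weights)) weights <- m$weights
  miss_tip <- setdiff(tree$tip.label, m$taxa)
  if (length(miss_tip)) stop("leaf '", miss_tip[1], "' missing from matrix")
  if (model$kind == "gtr") {
    stopifnot(m$type == "nucleotide")
    loglik_dna(tree, m, model, weights, ascertainment, po = .po)
  } else {
    loglik_categorical(tree, m, model, weights, ascertainment, po = .po)
  }
}

# Robust bounded 1-D maximization: bracket the maximum on a log-spaced
# grid first (the likelihood is flat over long branch lengths, which
# defeats plain golden-section search on a wide interval), then refine
# with optimize() between the bracketing neighbours.
line_max <- function(f, lower, upper, t0 = NULL, tol = 1e-8, local = FALSE) {
  grid <- if (local && !is.null(t0) && t0 > lower) {
    # refinement pass: bracket around the current value only
    c(lower, t0 / 8, t0 / 2, t0, t0 * 2, t0 * 8, min(t0 * 64, upper))
  } else {
    c(lower, 10^seq(-4, log10(upper), by = 0.8), t0, upper)
  }
  grid <- sort(unique(pmin(pmax(grid, lower), upper)))
  vals <- vapply(grid, f, 0)
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  if (lo >= hi) return(list(maximum = grid[i], objective = vals[i]))
  opt <- optimize(f, interval = c(lo, hi), maximum = TRUE, tol = tol)
  if (opt$objective >= vals[i]) opt else
    list(maximum = grid[i], objective = vals[i])
}

#' Optimize branch lengths by coordinate-wise scalar search
#'
#' Sweeps over branches, optimizing each in turn with bounded scalar
#' optimization; the log-likelihood never decreases across sweeps.
#' @inheritParams tree_loglik
#' @param edges indices of the edges to optimize (default all).
#' @param max_sweeps,tol sweep limit and convergence tolerance on the
#'   log-likelihood.
#' @param bounds branch-length search interval.
#' @return list with `tree` (optimized lengths), `loglik`, `sweeps`.
#' @export
optimize_branch_lengths <- function(tree, m, model, weights = NULL,
                                    edges = NULL, max_sweeps = 20,
                                    tol = 1e-6, bounds = c(1e-8, 100),
                                    ascertainment = "none") {
  if (is.null(edges)) edges <- seq_len(nrow(tree$edge))
  stopifnot(!is.null(tree$edge.length), all(tree$edge.length >= 0))
  m <- with_lik_cache(m)
  po <- postorder_edges(as_scoring_tree(tree))  # topology fixed throughout
  score <- function(tr) tree_loglik(tr, m, model, weights,
                                    ascertainment = ascertainment,
                                    .po = po)$loglik
  cur <- score(tree)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    prev <- cur
    for (e in edges) {
      f <- function(t) {
        tr2 <- tree
        tr2$edge.length[e] <- t
        score(tr2)
      }
      opt <- line_max(f, bounds[1], bounds[2], tree$edge.length[e],
                      tol = max(tol, 1e-8), local = sweeps > 1)
      if (opt$objective > cur) {  # never accept a decrease
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - prev < tol || sweeps >= max_sweeps) break
  }
  list(tree = tree, loglik = cur, sweeps = sweeps)
}

#' Fit a GTR(+Gamma) model and branch lengths on a fixed topology
#'
#' Empirical base frequencies; coordinate descent alternating
#' branch-length sweeps with scalar optimization of the Gamma shape and
#' (optionally) the exchangeabilities.
#' @inheritParams tree_loglik
#' @param optimize_alpha,optimize_rates toggle shape / exchangeability
#'   estimation.
#' @param outer_iter alternations of the coordinate blocks.
#' @param brlen_sweeps branch-length sweeps per alternation.
#' @return list with `tree`, `model`, `loglik`.
#' @export
optimize_model <- function(tree, m, model = NULL, weights = NULL,
                           optimize_alpha = TRUE, optimize_rates = FALSE,
                           outer_iter = 2, brlen_sweeps = 2) {
  stopifnot(m$type == "nucleotide")
  if (is.null(model)) {
    model <- subst_model("gtr", pi = empirical_frequencies(m), alpha = 1)
  } else if (model$kind == "gtr" && is.null(model$pi)) {
    model <- subst_model("gtr", pi = empirical_frequencies(m),
                         rates = model$rates, alpha = model$alpha,
                         ncat = model$ncat)
  }
  ll <- -Inf
  for (it in seq_len(outer_iter)) {
    ob <- optimize_branch_lengths(tree, m, model, weights,
                                  max_sweeps = brlen_sweeps, tol = 1e-4)
    tree <- ob$tree; ll <- ob$loglik
    if (optimize_alpha && !is.null(model$alpha)) {
      f <- function(la) {
        mod2 <- subst_model("gtr", pi = model$pi, rates = model$rates,
                            alpha = exp(la), ncat = model$ncat)
        tree_loglik(tree, m, mod2, weights)$loglik
      }
      opt <- optimize(f, interval = log(c(0.02, 50)), maximum = TRUE,
                      tol = 1e-3)
      if (opt$objective > ll) {
        model <- subst_model("gtr", pi = model$pi, rates = model$rates,
                             alpha = exp(opt$maximum), ncat = model$ncat)
        ll <- opt$objective
      }
    }
    if (optimize_rates) {
      for (ri in 1:5) {  # GT exchangeability fixed at 1
        f <- function(lr) {
          rr <- model$rates; rr[ri] <- exp(lr)
          mod2 <- subst_model("gtr", pi = model$pi, rates = rr,
                              alpha = model$alpha, ncat = model$ncat)
          tree_loglik(tree, m, mod2, weights)$loglik
        }
        opt <- optimize(f, interval = log(c(1e-3, 1e3)), maximum = TRUE,
                        tol = 1e-3)
        if (opt$objective > ll) {
          model$rates[ri] <- exp(opt$maximum)
          model <- subst_model("gtr", pi = model$pi, rates = model$rates,
                               alpha = model$alpha, ncat = model$ncat)
          ll <- opt$objective
        }
      }
    }
  }
  list(tree = tree, model = model, loglik = ll)
}

#' Empirical state frequencies of a nucleotide matrix
#'
#' Ambiguous cells contribute fractionally to each member state.
#' @param m a [data_matrix()] of type nucleotide.
#' @return a length-4 frequency vector (A, C, G, T).
#' @export
empirical_frequencies <- function(m) {
  counts <- rep(0.5, 4)
  scored <- !m$miss
  for (b in 1:4) {
    has <- bitwAnd(bitwShiftR(m$masks, b - 1L), 1L) == 1L & scored
    nst <- matrix(0, nrow(m$masks), ncol(m$masks))
    for (b2 in 1:4)
      nst <- nst + (bitwAnd(bitwShiftR(m$masks, b2 - 1L), 1L) == 1L)
    counts[b] <- counts[b] + sum(1 / nst[has])
  }
  counts / sum(counts)
}
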