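# Tree estimation and resampling: BioNJ distance trees, NNI hill
# climbing under parsimony or likelihood, nonparametric bootstrap over
# characters, and a single-chain Metropolis-Hastings sampler under the
# Mk model for posterior bipartition frequencies.

#' BioNJ tree from a distance matrix
#'
#' Variance-weighted neighbor joining; negative branch lengths are
#' clamped to zero.
#' @param D a `dist_matrix` (all pairs defined).
#' @return an unrooted `phylo`.
#' @export
bionj_tree <- function(D) {
  if (anyNA(D$d)) stop("undefined distances; cannot build a BioNJ tree")
  tr <- ape::bionj(stats::as.dist(D$d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

score_tree <- function(tree, m, objective, model, weights, brlen_sweeps = 2) {
  if (objective == "MP") {
    list(score = -fitch_steps(tree, m, weights)$steps, tree = tree)
  } else {
    ob <- optimize_branch_lengths(tree, m, model, weights,
                                  max_sweeps = brlen_sweeps, tol = 1e-4)
    list(score = ob$loglik, tree = ob$tree)
  }
}

#' NNI hill climbing under parsimony or likelihood
#'
#' Repeatedly evaluates all nearest-neighbour-interchange rearrangements
#' and accepts the best strict improvement until none remains (steepest
#' ascent). Likelihood candidates get a short branch-length sweep; the
#' accepted tree a full optimization.
#'
#' @param start a binary `phylo` (with branch lengths for ML).
#' @param m a [data_matrix()].
#' @param objective `"MP"` or `"ML"`.
#' @param model a [subst_model()] (ML only).
#' @param weights per-character weights.
#' @param max_rounds cap on accepted rearrangements.
#' @return list with `tree`, `score` (negative steps for MP,
#'   log-likelihood for ML), and `rounds`.
#' @export
nni_search <- function(start, m, objective = c("MP", "ML"), model = NULL,
                       weights = NULL, max_rounds = 50) {
  objective <- match.arg(objective)
  if (objective == "ML" && is.null(model))
    stop("ML search needs a model")
  if (objective == "ML") m <- with_lik_cache(m)
  if (objective == "ML" && is.null(start$edge.length))
    start$edge.length <- rep(0.1, nrow(start$edge))
  cur <- score_tree(start, m, objective, model, weights)
  tree <- cur$tree
  rounds <- 0L
  repeat {
    nbrs <- all_nni(tree)
    best <- NULL
    for (nb in nbrs) {
      if (objective == "ML" && is.null(nb$edge.length))
        nb$edge.length <- rep(0.1, nrow(nb$edge))
      sc <- score_tree(nb, m, objective, model, weights)
      if (is.null(best) || sc$score > best$score) best <- sc
    }
    if (!is.null(best) && best$score > cur$score + 1e-9) {
      cur <- best
      tree <- cur$tree
      rounds <- rounds + 1L
      if (rounds >= max_rounds) break
    } else break
  }
  if (objective == "ML") {
    ob <- optimize_branch_lengths(tree, m, model, weights, max_sweeps = 10,
                                  tol = 1e-5)
    tree <- ob$tree
    cur$score <- ob$loglik
  }
  list(tree = tree, score = cur$score, rounds = rounds)
}

#' Nonparametric bootstrap over characters
#'
#' Resamples columns with replacement (per-character weights act as
#' sampling multiplicities), re-infers a tree per replicate, and returns
#' the sample. Reproducible under a fixed seed.
#'
#' @param m a [data_matrix()].
#' @param replicates number of replicates (the original study used
#'   10,000; desk-scale analyses use fewer).
#' @param method `"nj"` (BioNJ on recomputed distances), `"mp"` or
#'   `"ml"` (NNI search started from the replicate's BioNJ tree).
#' @param model a [subst_model()] for `"ml"`.
#' @param seed integer seed.
#' @return a `multiPhylo` with a `provenance` attribute.
#' @export
bootstrap_trees <- function(m, replicates = 1000,
                            method = c("nj", "mp", "ml"), model = NULL,
                            seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  nc <- n_char(m)
  prob <- m$weights / sum(m$weights)
  trees <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample.int(nc, nc, replace = TRUE, prob = prob)
    mb <- m[, cols]
    mb$weights <- rep(1, nc)
    D <- mean_distance_matrix(mb)
    tr <- bionj_tree(D)
    if (method != "nj") {
      tr <- nni_search(tr, mb, objective = toupper(method),
                       model = model)$tree
    }
    trees[[r]] <- tr
  }
  out <- structure(trees, class = "multiPhylo")
  attr(out, "provenance") <- list(method = paste0("bootstrap-", method),
                                  replicates = replicates, seed = seed)
  out
}

#' Posterior tree sample under the Mk model (Metropolis-Hastings)
#'
#' Single-chain sampler over (topology, branch lengths): NNI topology
#' moves and single-branch log-uniform multiplier moves (probability 1/2
#' each), uniform topology prior, iid exponential branch-length prior.
#' Split posterior probabilities are post-burn-in frequencies. With
#' `m = NULL` the chain samples the prior alone (the standard
#' sampler-correctness check).
#'
#' @param m a [data_matrix()] or `NULL` for a prior-only run.
#' @param taxa taxon labels (required when `m` is `NULL`).
#' @param model a [subst_model()] (default Mk).
#' @param chain_length iterations.
#' @param burnin_frac fraction discarded.
#' @param thin keep every `thin`-th state; `chain_length` must be at
#'   least `10 * thin`.
#' @param prior_mean_brlen mean of the exponential branch-length prior.
#' @param seed integer seed.
#' @return a `multiPhylo` of sampled trees with a `provenance` attribute
#'   (including the realized acceptance rate).
#' @export
mcmc_mk <- function(m, taxa = NULL, model = subst_model("mk"),
                    chain_length = 20000, burnin_frac = 0.25, thin = 20,
                    prior_mean_brlen = 0.1, seed = NULL) {
  if (chain_length < 10 * thin)
    stop("chain_length must be at least 10 * thin")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(taxa)) {
    if (is.null(m)) stop("need either data or taxa")
    taxa <- m$taxa
  }
  if (length(taxa) < 4) stop("need at least 4 taxa")
  if (!is.null(m)) m <- with_lik_cache(m)
  tree <- ape::unroot(ape::rtree(length(taxa), tip.label = sample(taxa)))
  tree$edge.length <- rexp(nrow(tree$edge), rate = 1 / prior_mean_brlen)
  loglik <- function(tr) if (is.null(m)) 0 else
    tree_loglik(tr, m, model)$loglik
  logprior <- function(tr) sum(stats::dexp(tr$edge.length,
                                           rate = 1 / prior_mean_brlen,
                                           log = TRUE))
  cur_ll <- loglik(tree); cur_lp <- logprior(tree)
  keep <- list()
  burn <- floor(chain_length * burnin_frac)
  accepted <- 0L
  for (it in seq_len(chain_length)) {
    if (runif(1) < 0.5) {
      prop <- random_nni(tree)
      log_hastings <- 0
    } else {
      prop <- tree
      e <- sample.int(nrow(prop$edge), 1)
      u <- runif(1, -0.5, 0.5)
      prop$edge.length[e] <- prop$edge.length[e] * exp(u)
      log_hastings <- u  # multiplier proposal
    }
    p_ll <- loglik(prop); p_lp <- logprior(prop)
    if (log(runif(1)) < (p_ll + p_lp) - (cur_ll + cur_lp) + log_hastings) {
      tree <- prop; cur_ll <- p_ll; cur_lp <- p_lp
      accepted <- accepted + 1L
    }
    if (it > burn && (it - burn) %% thin == 0)
      keep[[length(keep) + 1L]] <- tree
  }
  out <- structure(keep, class = "multiPhylo")
  attr(out, "provenance") <- list(method = "mcmc-mk",
                                  chain_length = chain_length,
                                  burnin_frac = burnin_frac, thin = thin,
                                  seed = seed,
                                  acceptance_rate = accepted / chain_length)
  out
}
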