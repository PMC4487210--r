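# Seed-deterministic generators emulating the study conditions: a
# ~30-taxon x 23-character multistate morphological matrix with missing
# data and a morphologically intermediate query lineage, and a
# partitioned plastid-like alignment whose coding partitions support one
# outgroup root placement and whose spacer partitions support another.

#' Simulate a Yule tree
#'
#' Pure-birth tree rescaled so the root-to-tip depth equals `depth`.
#' @param ntaxa number of tips.
#' @param depth root-to-tip depth (expected substitutions per character
#'   at rate 1).
#' @param seed integer seed.
#' @return a rooted binary `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(ntaxa, depth = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(ntaxa, birth = 1, death = 0)
  dep <- max(ape::node.depth.edgelength(tr)[seq_len(ntaxa)])
  tr$edge.length <- tr$edge.length * depth / dep
  tr$tip.label <- paste0("t", seq_len(ntaxa))
  tr
}

# evolve one k-state Mk character down the tree; returns states at every
# node (uniform root state, closed-form transition sampling per edge)
evolve_mk_states <- function(tree, k, rate = 1) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  st <- integer(nn)
  st[root_node(tree)] <- sample.int(k, 1)
  po <- rev(postorder_edges(tree))  # preorder: parents before children
  for (e in po) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t <- tree$edge.length[e] * rate
    p_same <- 1 / k + (k - 1) / k * exp(-k * t / (k - 1))
    if (runif(1) < p_same) st[ch] <- st[p]
    else {
      others <- setdiff(seq_len(k), st[p])
      st[ch] <- others[sample.int(length(others), 1)]
    }
  }
  st
}

#' Simulate a multistate morphological matrix under the Mk model
#'
#' Defaults mirror the rhizome-anatomy study scale: 23 characters with
#' 2-4 states and ~15% missing cells.
#' @param tree a `phylo` with branch lengths.
#' @param n_characters number of characters.
#' @param state_counts pool of per-character state counts, sampled
#'   uniformly.
#' @param rate substitution-rate multiplier applied to all characters.
#' @param missing_fraction independent per-cell missingness probability.
#' @param seed integer seed.
#' @return a categorical [data_matrix()] over symbols `0,1,2,3`.
#' @export
simulate_mk_matrix <- function(tree, n_characters = 23, state_counts = 2:4,
                               rate = 1, missing_fraction = 0.15,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  symbols <- as.character(0:(max(state_counts) - 1))
  cells <- matrix("0", n, n_characters, dimnames = list(tree$tip.label, NULL))
  for (j in seq_len(n_characters)) {
    k <- if (length(state_counts) == 1) state_counts else
      sample(state_counts, 1)
    st <- evolve_mk_states(tree, k, rate)
    cells[, j] <- as.character(st[seq_len(n)] - 1L)
  }
  if (missing_fraction > 0)
    cells[matrix(runif(length(cells)) < missing_fraction, n)] <- "?"
  data_matrix(cells, type = "categorical", symbols = symbols)
}

# simulate one nucleotide column set under GTR(+Gamma); among-site rates
# drawn from the same discrete Gamma categories the pruning code uses
simulate_gtr_columns <- function(tree, ncols, model, rate = 1) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  cat_rates <- gamma_rates(model$alpha, model$ncat)
  site_rates <- sample(cat_rates, ncols, replace = TRUE)
  st <- matrix(0L, nn, ncols)
  st[root_node(tree), ] <- sample.int(4, ncols, replace = TRUE,
                                      prob = model$pi)
  po <- rev(postorder_edges(tree))  # preorder: parents before children
  for (e in po) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t <- tree$edge.length[e] * rate
    for (r in unique(site_rates)) {
      grp <- which(site_rates == r)
      P <- transition_matrix(model, t, rate = r)
      cum <- t(apply(P, 1, cumsum))
      u <- runif(length(grp))
      from <- st[p, grp]
      st[ch, grp] <- max.col(cum[from, , drop = FALSE] >= u, "first")
    }
  }
  matrix(DNA_ALPHABET[st[seq_len(n), ]], n,
         dimnames = list(tree$tip.label, NULL))
}

#' Simulate a nucleotide alignment under GTR(+Gamma)
#'
#' @param tree a `phylo` with branch lengths.
#' @param ncols number of columns.
#' @param model a `"gtr"` [subst_model()].
#' @param rate rate multiplier.
#' @param seed integer seed.
#' @return a nucleotide [data_matrix()].
#' @export
simulate_dna_alignment <- function(tree, ncols, model = subst_model("gtr"),
                                   rate = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- simulate_gtr_columns(tree, ncols, model, rate)
  data_matrix(cells, type = "nucleotide")
}

#' Fixed Osmundaceae-like demonstration ingroup
#'
#' An eight-taxon unrooted ingroup topology emulating the modern
#' royal-fern genera, with the three competing root hypotheses
#' addressable as branches: H1 (Osmundastrum pendant), H2
#' (Leptopteris+Todea stem), H3 (Osmunda s.str. stem).
#' @return list with `tree` (unrooted `phylo`) and `clades` (H1/H2/H3
#'   taxon sets for [classify_branch()]).
#' @export
osmundaceae_demo <- function() {
  nwk <- paste0(
    "(Osmundastrum_cinnamomeum:0.045,",
    "(Todea_barbara:0.030,Leptopteris_hymenophylloides:0.035):0.025,",
    "(Claytosmunda_claytoniana:0.022,((Osmunda_regalis:0.015,",
    "Osmunda_japonica:0.014):0.016,(Plenasium_banksiifolium:0.018,",
    "Plenasium_javanicum:0.019):0.017):0.012):0.020);")
  tree <- ape::read.tree(text = nwk)
  osstr <- c("Claytosmunda_claytoniana", "Osmunda_regalis",
             "Osmunda_japonica", "Plenasium_banksiifolium",
             "Plenasium_javanicum")
  clades <- list(H1 = "Osmundastrum_cinnamomeum",
                 H2 = c("Todea_barbara", "Leptopteris_hymenophylloides"),
                 H3 = osstr)
  list(tree = tree, clades = clades)
}

# attach a (1- or 2-taxon) outgroup at the midpoint of the edge whose
# split matches `hypothesis` under `clades`
attach_outgroup <- function(tree, clades, hypothesis, outgroups,
                            stem = 0.2, tip_len = 0.05) {
  cls <- vapply(seq_len(nrow(tree$edge)), function(e)
    classify_branch(tree, e, clades), "")
  edge <- which(cls == hypothesis)
  if (length(edge) == 0) stop("no branch maps to hypothesis ", hypothesis)
  att <- attach_tip(tree, edge[1], outgroups[1],
                    pendant = stem + tip_len, at = 0.5)
  tr <- att$tree
  if (length(outgroups) > 1) {
    at2 <- tip_len / (stem + tip_len)
    for (og in outgroups[-1])
      tr <- attach_tip(tr, att$pendant_edge, og, pendant = tip_len,
                       at = at2)$tree
  }
  tr
}

#' Engineered coding-vs-spacer root-signal conflict
#'
#' Simulates a partitioned plastid-like alignment on a fixed ingroup
#' topology. "Coding" partitions evolve with the outgroup attached at
#' the branch of one root hypothesis, "spacer" partitions at another, so
#' the partition-wise root scan faces a genuine conflict. The long
#' outgroup stem emulates outgroup long-branch attraction pressure.
#'
#' @param partitions data.frame with columns `name`, `length`, `flag`
#'   (`coding`/`spacer`), `hypothesis` (attachment branch label), `rate`;
#'   the default mirrors the informative plastid regions of the study
#'   (two coding genes rooting at H1, three spacers at H2).
#' @param demo ingroup and clade definitions, as from
#'   [osmundaceae_demo()].
#' @param outgroups outgroup taxon labels.
#' @param stem outgroup stem length (substitutions per site).
#' @param alpha Gamma shape of among-site rate variation.
#' @param seed integer seed.
#' @return list with `alignment` (ingroup + outgroups), `scheme`
#'   (flags set), `truth` (per-partition generating hypothesis),
#'   `ingroup_tree`, `clades`, `outgroups`.
#' @export
simulate_dna_conflict <- function(partitions = NULL,
                                  demo = osmundaceae_demo(),
                                  outgroups = c("Outgroup_fern_A",
                                                "Outgroup_fern_B"),
                                  stem = 0.2, alpha = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(partitions)) {
    partitions <- data.frame(
      name = c("atpA", "rbcL", "atpB_rbcL", "rbcL_accD", "trnL_trnF"),
      length = c(900L, 1200L, 350L, 350L, 400L),
      flag = c("coding", "coding", "spacer", "spacer", "spacer"),
      hypothesis = c("H1", "H1", "H2", "H2", "H2"),
      rate = c(0.8, 0.8, 1.2, 1.2, 1.2),
      stringsAsFactors = FALSE)
  }
  model <- subst_model("gtr", pi = c(0.31, 0.19, 0.22, 0.28),
                       rates = c(1.2, 3.6, 0.8, 1.1, 4.2, 1), alpha = alpha)
  tree <- demo$tree
  blocks <- list()
  cols <- list()
  at <- 0L
  for (i in seq_len(nrow(partitions))) {
    tr_full <- attach_outgroup(tree, demo$clades,
                               partitions$hypothesis[i], outgroups,
                               stem = stem)
    cells <- simulate_gtr_columns(tr_full, partitions$length[i], model,
                                  rate = partitions$rate[i])
    blocks[[i]] <- cells
    cols[[partitions$name[i]]] <- at + seq_len(partitions$length[i])
    at <- at + partitions$length[i]
  }
  taxa <- rownames(blocks[[1]])
  cells <- do.call(cbind, lapply(blocks, function(b) b[taxa, , drop = FALSE]))
  aln <- data_matrix(cells, type = "nucleotide")
  scheme <- partition_scheme(cols, flags = setNames(partitions$flag,
                                                    partitions$name))
  list(alignment = aln, scheme = scheme,
       truth = setNames(partitions$hypothesis, partitions$name),
       ingroup_tree = tree, clades = demo$clades, outgroups = outgroups)
}

#' Generate a fossil-like query with known true attachment
#'
#' `mode = "evolve"` grows the query from a point on a chosen branch of
#' the tree (short pendant), simulating all characters jointly on the
#' extended tree so the query is genuinely correlated with its
#' neighbours; the true branch is recorded. `mode = "mosaic"` instead
#' mixes the consensus states of two clades at a given ratio, emulating
#' a morphologically intermediate lineage.
#'
#' @param tree backbone `phylo` with branch lengths.
#' @param edge attachment branch (row of `tree$edge`); default the
#'   longest internal branch.
#' @param pendant query pendant length (`evolve` mode).
#' @param at fraction of the attachment branch left on the child side.
#' @param n_characters,state_counts,rate,missing_fraction as in
#'   [simulate_mk_matrix()]; `missing_fraction` applies to the query row
#'   too.
#' @param mode `"evolve"` or `"mosaic"`.
#' @param mosaic_clades list of two taxon-label vectors (`mosaic` mode).
#' @param mosaic_ratio probability of drawing each character from the
#'   first clade's consensus.
#' @param query query label.
#' @param seed integer seed.
#' @return list with `matrix` (backbone + query rows), `query`,
#'   `true_edge` (NA for mosaic), `tree`.
#' @export
make_fossil_query <- function(tree, edge = NULL, pendant = 0.1, at = 0.5,
                              n_characters = 23, state_counts = 2:4,
                              rate = 1, missing_fraction = 0,
                              mode = c("evolve", "mosaic"),
                              mosaic_clades = NULL, mosaic_ratio = 0.5,
                              query = "fossil_query", seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "evolve") {
    if (is.null(edge)) {
      n <- length(tree$tip.label)
      internal <- which(tree$edge[, 2] > n)
      edge <- if (length(internal)) internal[which.max(
        tree$edge.length[internal])] else which.max(tree$edge.length)
    }
    ext <- attach_tip(tree, edge, query, pendant = pendant, at = at)$tree
    mm <- simulate_mk_matrix(ext, n_characters = n_characters,
                             state_counts = state_counts, rate = rate,
                             missing_fraction = missing_fraction)
    list(matrix = mm, query = query, true_edge = edge, tree = tree)
  } else {
    stopifnot(length(mosaic_clades) == 2)
    mm <- simulate_mk_matrix(tree, n_characters = n_characters,
                             state_counts = state_counts, rate = rate,
                             missing_fraction = missing_fraction)
    cons <- function(taxa) vapply(seq_len(n_char(mm)), function(j) {
      idx <- match(taxa, mm$taxa)
      sc <- idx[!mm$miss[idx, j]]
      if (length(sc) == 0) return("?")
      tab <- table(unlist(lapply(mm$masks[sc, j], states_from_mask,
                                 alphabet = mm$alphabet)))
      names(tab)[which.max(tab)]
    }, "")
    c1 <- cons(mosaic_clades[[1]]); c2 <- cons(mosaic_clades[[2]])
    pick <- runif(n_char(mm)) < mosaic_ratio
    qrow <- ifelse(pick, c1, c2)
    qmat <- data_matrix(matrix(qrow, 1, dimnames = list(query, NULL)),
                        type = "categorical", symbols = mm$alphabet)
    list(matrix = bind_taxa(mm, qmat), query = query, true_edge = NA,
         tree = tree)
  }
}
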