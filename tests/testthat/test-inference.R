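test_that("BioNJ recovers additive trees and handles three taxa", {
  tr <- ape::read.tree(text = "((A:1,B:2):1.5,(C:1,D:0.5):0);")
  d <- ape::cophenetic.phylo(tr)
  bt <- bionj_tree(dm_fix(d))
  expect_setequal(tree_splits(bt, FALSE)$key,
                  tree_splits(ape::unroot(tr), FALSE)$key)
  d3 <- matrix(c(0, .3, .5, .3, 0, .4, .5, .4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- bionj_tree(dm_fix(d3))
  expect_equal(ape::Ntip(t3), 3)
  # three-point branch lengths
  lenA <- t3$edge.length[t3$edge[, 2] == which(t3$tip.label == "A")]
  expect_equal(lenA, (.3 + .5 - .4) / 2, tolerance = 1e-6)
  # permutation equivariance
  perm <- c(3, 1, 2)
  t3p <- bionj_tree(dm_fix(d3[perm, perm]))
  expect_equal(unname(ape::cophenetic.phylo(t3p)[c("A", "B", "C"),
                                                 c("A", "B", "C")]),
               unname(ape::cophenetic.phylo(t3)[c("A", "B", "C"),
                                                c("A", "B", "C")]))
})

test_that("NNI hill climbing is monotone and stalls only at local optima", {
  m <- data_matrix(c(a = "000", b = "001", c = "011", d = "111", e = "111"),
                   symbols = c("0", "1"))
  opt <- ape::read.tree(text = "((a,b),c,(d,e));")
  best <- fitch_steps(opt, m)$steps
  # the optimum is a fixed point
  expect_equal(-nni_search(opt, m, "MP")$score, best)
  set.seed(3)
  for (i in 1:4) {
    start <- ape::unroot(ape::rtree(5, tip.label = sample(letters[1:5])))
    res <- nni_search(start, m, "MP")
    expect_lte(-res$score, fitch_steps(start, m)$steps)  # monotone
    if (-res$score > best) {
      # every endpoint above the optimum is a genuine NNI local optimum
      nb <- vapply(fossilgraft:::all_nni(res$tree),
                   function(x) fitch_steps(x, m)$steps, 0)
      expect_true(all(nb >= -res$score))
    }
  }
})

test_that("ML NNI search improves the likelihood from a wrong start", {
  tr <- quartet_tree()
  mm <- simulate_mk_matrix(tr, 40, state_counts = 2, missing_fraction = 0,
                           seed = 8)
  wrong <- ape::read.tree(text = "((A:0.2,C:0.2):0.2,(B:0.2,D:0.2):0.2);")
  res <- nni_search(wrong, mm, "ML", model = subst_model("mk"))
  key <- split_key(c("A", "B"), mm$taxa)
  expect_true(key %in% tree_splits(res$tree, FALSE)$key)
})

test_that("bootstrap is seed-reproducible and finds strong splits", {
  tr <- quartet_tree()
  m4 <- simulate_mk_matrix(tr, 20, missing_fraction = 0, seed = 8)
  bs <- bootstrap_trees(m4, 200, method = "nj", seed = 42)
  expect_length(bs, 200)
  fr <- bipartition_frequencies(bs)
  key <- split_key(c("A", "B"), m4$taxa)
  expect_gte(fr$freq[fr$key == key], 0.95)
  bs2 <- bootstrap_trees(m4, 200, method = "nj", seed = 42)
  expect_identical(write_trees(bs), write_trees(bs2))
  expect_identical(attr(bs, "provenance")$replicates, 200)
})

test_that("resampling a one-character matrix returns the original data", {
  m1 <- data_matrix(c(a = "0", b = "0", c = "1", d = "1"),
                    symbols = c("0", "1"))
  bs <- bootstrap_trees(m1, 10, method = "nj", seed = 1)
  expect_length(unique(vapply(bs, ape::write.tree, "")), 1L)
})

test_that("bootstrap frequencies are stable under replicate doubling", {
  tr <- ape::rtree(6)
  mm <- simulate_mk_matrix(tr, 25, missing_fraction = 0, seed = 10)
  f1 <- bipartition_frequencies(bootstrap_trees(mm, 150, "nj", seed = 1))
  f2 <- bipartition_frequencies(bootstrap_trees(mm, 300, "nj", seed = 2))
  # the best-supported splits must keep their frequencies when the
  # replicate count doubles
  top <- head(f1$key, 3)
  for (k in top) {
    v2 <- if (k %in% f2$key) f2$freq[f2$key == k] else 0
    expect_lt(abs(f1$freq[f1$key == k] - v2), 0.12)
  }
})

test_that("MCMC validates its arguments and mixes", {
  m <- data_matrix(c(a = "01", b = "01", c = "10", d = "10"),
                   symbols = c("0", "1"))
  expect_error(mcmc_mk(m, chain_length = 100, thin = 20), "at least 10")
  ps <- mcmc_mk(m, chain_length = 3000, thin = 10, seed = 2)
  acc <- attr(ps, "provenance")$acceptance_rate
  expect_gt(acc, 0)
  expect_lt(acc, 1)
})

test_that("a strong quartet signal yields posterior support near one", {
  tr <- quartet_tree()
  m <- simulate_mk_matrix(tr, 60, state_counts = 2:4, missing_fraction = 0,
                          seed = 8)
  ps <- mcmc_mk(m, chain_length = 12000, thin = 15, seed = 5)
  fr <- bipartition_frequencies(ps)
  key <- split_key(c("A", "B"), m$taxa)
  expect_gte(fr$freq[fr$key == key], 0.99)
})
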