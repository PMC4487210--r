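test_that("three-taxon split weights follow the three-point closed form", {
  d <- matrix(c(0, .3, .5, .3, 0, .4, .5, .4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ss <- nnls_split_weights(dm_fix(d), 1:3)
  keys <- ss_keys(ss)
  wA <- ss$weights[keys == split_key("A", c("A", "B", "C"))]
  expect_equal(wA, (.3 + .5 - .4) / 2, tolerance = 1e-9)
})

test_that("additive quartet distances give the five tree splits exactly", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):0);")
  d <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  net <- neighbor_net(dm_fix(d))
  expect_length(net$weights, 5)
  expect_lt(attr(net, "residual"), 1e-8)
  keys <- ss_keys(net)
  ab <- split_key(c("A", "B"), LETTERS[1:4])
  expect_equal(net$weights[keys == ab], 1, tolerance = 1e-8)
})

test_that("all-zero distances give no splits above threshold", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_length(neighbor_net(dm_fix(d))$weights, 0)
})

test_that("weighted circular split systems are represented exactly", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    labels <- paste0("x", 1:n)
    perm <- sample(n)
    sides <- list(); weights <- numeric(0)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.4) next
      s <- perm[i:(j - 1)]
      sides <- c(sides, list(s)); weights <- c(weights, runif(1, 0.05, 1))
    }
    ss0 <- split_system(labels, sides, weights)
    M <- split_distances(ss0)
    net <- neighbor_net(dm_fix(M, labels))
    expect_lt(max(abs(M - split_distances(net)[labels, labels])), 1e-6)
  }
})

test_that("tree-additive distances recover the tree's splits and lengths", {
  set.seed(9)
  tr <- ape::unroot(ape::rtree(10))
  d <- ape::cophenetic.phylo(tr)
  net <- neighbor_net(dm_fix(d), threshold = 1e-7)
  keys <- ss_keys(net)
  tsp <- tree_splits(tr, trivial = TRUE)
  expect_setequal(keys, unique(tsp$key))
  for (i in seq_along(keys)) {
    bl <- sum(tr$edge.length[tsp$edge[tsp$key == keys[i]]])
    expect_equal(net$weights[i], bl, tolerance = 1e-6)
  }
})

test_that("neighbour-net splits are arcs of its ordering; equivariance", {
  tr <- ape::rtree(8)
  mm <- simulate_mk_matrix(tr, 40, missing_fraction = 0, seed = 2)
  D <- mean_distance_matrix(mm)
  net <- neighbor_net(D)
  ordv <- match(net$ordering, net$labels)
  pos <- match(seq_along(net$labels), ordv)  # taxon -> position on circle
  for (s in net$sides) {
    p <- sort(pos[s])
    q <- sort(pos[setdiff(seq_along(net$labels), s)])
    # one of the two sides must occupy consecutive circle positions
    expect_true(all(diff(p) == 1) || all(diff(q) == 1))
  }
  expect_true(all(net$weights >= 0))
  set.seed(77)
  perm <- sample(8)
  Dp <- structure(list(labels = D$labels[perm], d = D$d[perm, perm]),
                  class = "dist_matrix")
  expect_setequal(ss_keys(neighbor_net(Dp)), ss_keys(net))
})

test_that("bipartition frequencies count unrooted splits", {
  tr <- quartet_tree()
  sample100 <- structure(rep(list(tr), 100), class = "multiPhylo")
  fr <- bipartition_frequencies(sample100)
  expect_true(all(fr$freq == 1))
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  mix <- structure(c(rep(list(t1), 70), rep(list(t2), 30)),
                   class = "multiPhylo")
  fr2 <- bipartition_frequencies(mix)
  key <- split_key(c("A", "B"), LETTERS[1:4])
  expect_equal(fr2$freq[fr2$key == key], 0.70)
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(bipartition_frequencies(
    structure(list(t1, t3), class = "multiPhylo")), "mismatch")
})

test_that("bipartition frequencies match an independent clade-count oracle", {
  set.seed(13)
  trees <- structure(replicate(50, ape::rtree(6), simplify = FALSE),
                     class = "multiPhylo")
  fr <- bipartition_frequencies(trees)
  # oracle: per tree, ape::prop.part clades mapped to canonical unrooted
  # keys and deduplicated (both clades flanking the root give one split)
  counts <- new.env()
  labs <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    pp <- ape::prop.part(tr)
    plabs <- attr(pp, "labels")
    keys <- unique(unlist(lapply(pp, function(cl) {
      side <- plabs[cl]
      if (length(side) %in% c(1, 5, 6)) return(NULL)
      split_key(side, plabs)
    })))
    for (k in keys)
      counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
  }
  for (k in ls(counts))
    expect_equal(fr$freq[fr$key == k], counts[[k]] / 50)
  expect_setequal(fr$key, ls(counts))
})

test_that("support overlay annotates network splits and reports strays", {
  tr <- quartet_tree()
  mm <- simulate_mk_matrix(tr, 25, missing_fraction = 0, seed = 4)
  net <- neighbor_net(mean_distance_matrix(mm))
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  mix <- structure(c(rep(list(t1), 70), rep(list(t2), 30)),
                   class = "multiPhylo")
  fr <- bipartition_frequencies(mix)
  out <- support_overlay(net, list(PP = fr))
  expect_equal(ncol(out$annotations), 1)
  keys <- ss_keys(out)
  ab <- split_key(c("A", "B"), LETTERS[1:4])
  if (ab %in% keys)
    expect_equal(unname(out$annotations[keys == ab, "PP"]), 0.70)
  expect_true(all(out$annotations >= 0 & out$annotations <= 1))
  # a split in the sample but absent from the network is reported aside
  stray <- attr(out, "unrepresented")$PP
  expect_true(all(!(stray$key %in% keys)))
})
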