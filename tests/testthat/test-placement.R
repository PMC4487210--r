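leafrow_as <- function(m, taxon, label) {
  q <- m[taxon, ]
  q$taxa <- label
  rownames(q$masks) <- rownames(q$miss) <- label
  q
}

test_that("a query identical to a leaf places on that leaf's branch", {
  set.seed(2)
  tr <- ape::unroot(simulate_tree(8, depth = 1))
  mm <- simulate_mk_matrix(tr, 20, missing_fraction = 0, seed = 3)
  mq <- bind_taxa(mm, leafrow_as(mm, "t3", "Q"))
  tb <- place_query(tr, mq, "Q", scheme = "ML_MK")
  pend <- which(tr$edge[, 2] == which(tr$tip.label == "t3"))
  expect_true(pend %in% attr(tb, "best_edges"))
  expect_equal(sum(tb$lweight), 1, tolerance = 1e-9)
  expect_true(all(tb$lweight >= 0))
})

test_that("MP placement scores equal the insertion scan at unit weights", {
  tr <- ape::unroot(ape::rtree(6))
  mm0 <- simulate_mk_matrix(attach_tip(tr, 2, "Q", 0.5)$tree, 15,
                            missing_fraction = 0.1, seed = 7)
  tb <- place_query(tr, mm0, "Q", scheme = "MP")
  sc <- insertion_scan(tr, mm0, "Q")
  expect_equal(-tb$score[order(tb$edge)], sc$steps_added[order(sc$edge)])
  expect_setequal(attr(tb, "best_edges"), attr(sc, "minimal_edges"))
})

test_that("an unscored query yields a uniform table with a warning", {
  tr <- ape::unroot(ape::rtree(5))
  mm <- simulate_mk_matrix(tr, 10, missing_fraction = 0, seed = 1)
  qna <- data_matrix(matrix("?", 1, 10, dimnames = list("QNA", NULL)),
                     symbols = mm$alphabet)
  expect_warning(tb <- place_query(tr, bind_taxa(mm, qna), "QNA",
                                   scheme = "ML_MK"), "no scored")
  expect_true(all(abs(tb$lweight - 1 / nrow(tr$edge)) < 1e-12))
})

test_that("character-weight calibration behaves per scheme", {
  mhf <- data_matrix(c(a = "00", b = "00", c = "01", d = "11"),
                     symbols = c("0", "1"))
  trhf <- ape::unroot(ape::read.tree(text = "((a:.1,b:.1):.1,(c:.1,d:.1):.1);"))
  expect_equal(calibrate_character_weights(trhf, mhf, "MP"), c(1, 1))
  mci <- data_matrix(c(a = "00", b = "01", c = "10", d = "11"),
                     symbols = c("0", "1"))
  expect_equal(calibrate_character_weights(
    ape::read.tree(text = "((a,b),(c,d));"), mci, "MP"), c(1, 0.5))
  # ML weights: a duplicated character receives the same weight
  tr <- ape::unroot(ape::rtree(6))
  mm <- simulate_mk_matrix(tr, 12, missing_fraction = 0, seed = 5)
  w <- calibrate_character_weights(tr, mm[, c(1:12, 1)], "ML_MK")
  expect_equal(w[13], w[1], tolerance = 1e-6)
  expect_true(all(w > 0))
  expect_equal(mean(w), 1, tolerance = 1e-9)
})

test_that("adding uninformative characters never changes the best branch", {
  set.seed(9)
  tr <- ape::unroot(simulate_tree(7, depth = 1.5))
  fq <- make_fossil_query(tr, pendant = 0.1, n_characters = 20, seed = 11)
  tb0 <- place_query(tr, fq$matrix, fq$query, scheme = "ML_MK")
  # append constant and all-missing characters
  n <- n_taxa(fq$matrix)
  extra <- data_matrix(
    matrix(c(rep("0", n), rep("?", n)), n, 2,
           dimnames = list(fq$matrix$taxa, NULL)),
    symbols = fq$matrix$alphabet)
  maug <- fq$matrix
  maug$masks <- cbind(maug$masks, extra$masks)
  maug$miss <- cbind(maug$miss, extra$miss)
  maug$weights <- c(maug$weights, extra$weights)
  tb1 <- place_query(tr, maug, fq$query, scheme = "ML_MK")
  expect_equal(tb1$edge[1], tb0$edge[1])
})

test_that("compare_schemes flags swaps exactly when best branches differ", {
  tr <- ape::unroot(ape::rtree(6))
  mm0 <- simulate_mk_matrix(attach_tip(tr, 3, "Q", 0.3)$tree, 18,
                            missing_fraction = 0, seed = 21)
  tabs <- list(MP = place_query(tr, mm0, "Q", scheme = "MP"),
               ML_MK = place_query(tr, mm0, "Q", scheme = "ML_MK"))
  rep1 <- compare_schemes(tabs)
  expect_identical(attr(rep1, "swap"),
                   length(unique(rep1$best_edge)) >= 2)
  # identical tables never swap
  rep2 <- compare_schemes(list(a = tabs$ML_MK, b = tabs$ML_MK))
  expect_false(attr(rep2, "swap"))
})

test_that("a mosaic query places on the path between its donor clades", {
  demo <- osmundaceae_demo()
  cl1 <- "Osmundastrum_cinnamomeum"
  cl2 <- demo$clades$H3
  hit <- 0
  for (s in 1:10) {
    fq <- make_fossil_query(demo$tree, mode = "mosaic",
                            mosaic_clades = list(cl1, cl2),
                            n_characters = 23, rate = 6, seed = 30 + s)
    tb <- place_query(demo$tree, fq$matrix, fq$query, scheme = "MP")
    # the path between the donor clades = the Osmundastrum pendant (H1)
    # plus the Osmunda s.str. stem (H3); ties are a set, any member counts
    cls <- vapply(attr(tb, "best_edges"), function(e)
      classify_branch(demo$tree, e, demo$clades), "")
    hit <- hit + any(cls %in% c("H1", "H3"))
  }
  expect_gte(hit, 8)
})

test_that("jplace export carries the edge numbering and placements", {
  tr <- ape::unroot(ape::rtree(5))
  mm0 <- simulate_mk_matrix(attach_tip(tr, 1, "Q", 0.3)$tree, 12,
                            missing_fraction = 0, seed = 2)
  tb <- place_query(tr, mm0, "Q", scheme = "ML_MK")
  f <- withr::local_tempfile(fileext = ".jplace")
  write_jplace(tr, list(tb), f)
  js <- jsonlite::read_json(f)
  expect_equal(js$version, 3)
  expect_equal(length(js$placements[[1]]$p), nrow(tr$edge))
  expect_equal(js$fields[[1]], "edge_num")
  expect_match(js$tree, "\\{0\\}")
})
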