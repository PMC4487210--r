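# Scaled-down engineered-conflict configuration used across these tests:
# two coding genes rooting at H1, three spacers at H2, zero-length
# outgroup stem (the condition under which per-partition recovery is
# assessed).
conflict_parts <- function() {
  data.frame(
    name = c("atpA", "rbcL", "atpB_rbcL", "rbcL_accD", "trnL_trnF"),
    length = c(450L, 600L, 300L, 300L, 300L),
    flag = c("coding", "coding", "spacer", "spacer", "spacer"),
    hypothesis = c("H1", "H1", "H2", "H2", "H2"),
    rate = c(0.8, 0.8, 1.2, 1.2, 1.2), stringsAsFactors = FALSE)
}

test_that("branches classify into the three root hypotheses by their split", {
  demo <- osmundaceae_demo()
  cls <- vapply(seq_len(nrow(demo$tree$edge)), function(e)
    classify_branch(demo$tree, e, demo$clades), "")
  expect_equal(sum(cls == "H1"), 1)  # Osmundastrum pendant
  expect_equal(sum(cls == "H2"), 1)  # Leptopteris+Todea stem
  expect_equal(sum(cls == "H3"), 1)  # Osmunda s.str. stem
  h1_edge <- which(cls == "H1")
  expect_equal(demo$tree$edge[h1_edge, 2],
               which(demo$tree$tip.label == "Osmundastrum_cinnamomeum"))
  # a branch inside the Plenasium subtree is "other"
  plen <- which(demo$tree$tip.label == "Plenasium_javanicum")
  expect_equal(cls[which(demo$tree$edge[, 2] == plen)], "other")
})

test_that("per-partition scans recover the engineered root assignments", {
  sim <- simulate_dna_conflict(partitions = conflict_parts(), stem = 0,
                               seed = 11)
  rep1 <- outgroup_root_scan(sim$ingroup_tree, sim$alignment, sim$scheme,
                             sim$outgroups, sim$clades)
  expect_identical(unname(rep1$top_hypothesis), unname(sim$truth[rep1$subset]))
  expect_equal(rep1$H1 + rep1$H2 + rep1$H3 + rep1$other,
               rep(1, nrow(rep1)), tolerance = 1e-9)
  expect_false(any(rep1$low_information))
  # flags carried through from the scheme
  expect_identical(unname(rep1$flag),
                   unname(sim$scheme$flags[rep1$subset]))
})

test_that("the scan is invariant to outgroup ordering and validates inputs", {
  sim <- simulate_dna_conflict(partitions = conflict_parts()[2, ], stem = 0,
                               seed = 12)
  r1 <- outgroup_root_scan(sim$ingroup_tree, sim$alignment, sim$scheme,
                           sim$outgroups, sim$clades)
  r2 <- outgroup_root_scan(sim$ingroup_tree, sim$alignment, sim$scheme,
                           rev(sim$outgroups), sim$clades)
  expect_equal(r1$H1, r2$H1, tolerance = 1e-12)
  expect_error(outgroup_root_scan(sim$ingroup_tree, sim$alignment,
                                  sim$scheme, c("nope"), sim$clades),
               "not in alignment")
})

test_that("an invariant alignment spreads weight, 'other' dominating", {
  demo <- osmundaceae_demo()
  taxa <- c(demo$tree$tip.label, "Out_A")
  aln <- data_matrix(setNames(rep(strrep("ACGT", 10), length(taxa)), taxa),
                     type = "nucleotide")
  rep1 <- outgroup_root_scan(demo$tree, aln, NULL, "Out_A", demo$clades,
                             model = subst_model("gtr", alpha = 1))
  expect_true(rep1$low_information)
  expect_gt(rep1$other, rep1$H1)
  expect_gt(rep1$other, rep1$H2)
  expect_gt(rep1$other, rep1$H3)
})

test_that("gene jackknifing runs 2P+1 subsets; single partition collapses", {
  sim <- simulate_dna_conflict(partitions = conflict_parts()[c(2, 5), ],
                               stem = 0, seed = 13)
  jk <- gene_jackknife(sim$ingroup_tree, sim$alignment, sim$scheme,
                       sim$outgroups, sim$clades)
  expect_equal(nrow(jk), 1 + 2 * 2)
  # with one partition, the concatenated and single runs coincide and the
  # empty leave-one-out subset is skipped
  one <- partition_scheme(sim$scheme$cols["rbcL"])
  jk1 <- gene_jackknife(sim$ingroup_tree, sim$alignment, one,
                        sim$outgroups, sim$clades)
  expect_equal(nrow(jk1), 2)
  expect_equal(jk1$H1[1], jk1$H1[2], tolerance = 1e-9)
})

test_that("split support scans report bootstrap percentages per subset", {
  # a homoplasy-free matrix: every replicate supports AB|CD, so the focal
  # AB split is at 100 and the incompatible AC split is absent everywhere
  rows <- c(A = strrep("01", 6), B = strrep("01", 6),
            C = strrep("10", 6), D = strrep("10", 6))
  mm <- data_matrix(rows, symbols = c("0", "1"))
  subsets <- list(first_half = 1:6, all = 1:12)
  focal <- list(AB = c("A", "B"), AC = c("A", "C"))
  out <- split_support_scan(mm, subsets, focal, replicates = 100,
                            method = "nj", seed = 3)
  expect_equal(dim(out), c(2L, 2L))
  expect_true(all(out >= 0 & out <= 100))
  expect_gte(out["all", "AB"], 95)
  expect_equal(out["all", "AC"], 0)  # split absent from all replicates
})
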