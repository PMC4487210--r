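test_that("Mk transition probabilities follow the closed form", {
  mod <- subst_model("mk", k = 2)
  expect_equal(transition_matrix(mod, 0.5)[1, 1], 0.5 * (1 + exp(-1)),
               tolerance = 1e-12)
  for (k in 2:5) {
    mk <- subst_model("mk", k = k)
    expect_equal(transition_matrix(mk, 0), diag(k), tolerance = 1e-12)
    P <- transition_matrix(mk, 0.37)
    expect_equal(P[1, 1], 1 / k + (k - 1) / k * exp(-k * 0.37 / (k - 1)),
                 tolerance = 1e-12)
    expect_equal(rowSums(P), rep(1, k), tolerance = 1e-12)
    expect_equal(transition_matrix(mk, 500),
                 matrix(1 / k, k, k), tolerance = 1e-9)  # stationarity
  }
})

test_that("GTR transitions match an independent series expansion", {
  mg <- subst_model("gtr", pi = c(.1, .2, .3, .4),
                    rates = c(1.5, 3, .5, .8, 2.5, 1))
  Q <- mg$eig$Q
  expect_equal(rowSums(Q), rep(0, 4), tolerance = 1e-12)
  expect_equal(mg$pi %*% Q, t(rep(0, 4)), tolerance = 1e-12)
  # detailed balance
  expect_equal(mg$pi * Q, t(mg$pi * Q), tolerance = 1e-12)
  Pser <- diag(4); term <- diag(4)
  for (i in 1:60) { term <- term %*% (Q * 0.3) / i; Pser <- Pser + term }
  expect_equal(transition_matrix(mg, 0.3), Pser, tolerance = 1e-10)
})

test_that("two-taxon likelihood matches the binary closed form", {
  t <- 0.7
  m <- data_matrix(c(a = "0", b = "1"), symbols = c("0", "1"))
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t / 2, t / 2))
  expect_equal(tree_loglik(tr, m, subst_model("mk"))$loglik,
               log(0.25 * (1 - exp(-2 * t))), tolerance = 1e-9)
})

test_that("pruning matches brute-force summation over internal states", {
  set.seed(7)
  tr <- ape::rtree(5)
  m <- data_matrix(c(t1 = "0", t2 = "1", t3 = "2", t4 = "0", t5 = "{12}"),
                   symbols = c("0", "1", "2"))
  mod <- subst_model("mk")
  k <- 3
  tipstate <- list(t1 = 1, t2 = 2, t3 = 3, t4 = 1, t5 = c(2, 3))[tr$tip.label]
  Pm <- lapply(tr$edge.length, function(t) transition_matrix(mod, t, k = k))
  total <- 0
  grid <- expand.grid(rep(list(1:k), tr$Nnode))
  for (g in seq_len(nrow(grid))) {
    asg <- as.integer(grid[g, ])
    pr <- 1 / k
    for (e in seq_len(nrow(tr$edge))) {
      p <- asg[tr$edge[e, 1] - 5]; ch <- tr$edge[e, 2]
      pr <- pr * if (ch <= 5) sum(Pm[[e]][p, tipstate[[ch]]]) else
        Pm[[e]][p, asg[ch - 5]]
    }
    total <- total + pr
  }
  expect_equal(tree_loglik(tr, m, mod)$loglik, log(total), tolerance = 1e-9)
})

test_that("likelihood agrees with phangorn under Mk and GTR+Gamma", {
  set.seed(11)
  tr <- ape::unroot(ape::rtree(6))
  mod <- subst_model("gtr", pi = c(.28, .22, .24, .26),
                     rates = c(1.2, 3.5, .6, .9, 3.1, 1), alpha = 0.7)
  aln <- simulate_dna_alignment(tr, 150, mod, seed = 3)
  seqs <- t(vapply(seq_len(6), function(i)
    strsplit(fossilgraft:::row_string(aln, i), "")[[1]], character(150)))
  rownames(seqs) <- aln$taxa
  fitp <- phangorn::pml(tr, phangorn::phyDat(seqs, type = "DNA"),
                        bf = mod$pi, Q = mod$rates, shape = mod$alpha, k = 4)
  expect_equal(tree_loglik(tr, aln, mod)$loglik, fitp$logLik,
               tolerance = 1e-6)
  mm <- simulate_mk_matrix(tr, 15, state_counts = 2, missing_fraction = 0,
                           seed = 4)
  states <- matrix(vapply(matrix_states(mm), `[`, "", 1), 6)
  rownames(states) <- mm$taxa
  fit2 <- phangorn::pml(tr, phangorn::phyDat(states, type = "USER",
                                             levels = c("0", "1")))
  expect_equal(tree_loglik(tr, mm, subst_model("mk"))$loglik, fit2$logLik,
               tolerance = 1e-6)
})

test_that("likelihood is invariant to rerooting (reversibility)", {
  set.seed(19)
  tr <- ape::unroot(ape::rtree(7))
  mod <- subst_model("gtr", pi = c(.3, .2, .2, .3), alpha = 0.9)
  aln <- simulate_dna_alignment(tr, 100, mod, seed = 6)
  mm <- simulate_mk_matrix(tr, 12, missing_fraction = 0.1, seed = 6)
  ll_dna <- tree_loglik(tr, aln, mod)$loglik
  ll_cat <- tree_loglik(tr, mm, subst_model("mk_freq"))$loglik
  for (tip in tr$tip.label[1:4]) {
    rt <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(tree_loglik(rt, aln, mod)$loglik, ll_dna, tolerance = 1e-9)
    expect_equal(tree_loglik(rt, mm, subst_model("mk_freq"))$loglik, ll_cat,
                 tolerance = 1e-9)
  }
})

test_that("pattern compression does not change the likelihood", {
  tr <- ape::rtree(5)
  mod <- subst_model("gtr", alpha = 1)
  aln <- simulate_dna_alignment(tr, 60, mod, seed = 2)
  full <- tree_loglik(tr, aln, mod)
  # per-column scoring (no shared patterns) must sum to the same value
  percol <- sum(vapply(seq_len(60), function(j)
    tree_loglik(tr, aln[, j], mod)$loglik, 0))
  expect_equal(full$loglik, percol, tolerance = 1e-8)
})

test_that("long branches decouple tips (stationary limit)", {
  # the character's alphabet is its observed states (k = 2 here), so the
  # independence limit is (1/2)^2
  m <- data_matrix(c(a = "0", b = "2"), symbols = c("0", "1", "2"))
  tr <- ape::read.tree(text = "(a:25,b:25);")
  expect_equal(tree_loglik(tr, m, subst_model("mk"))$loglik, log(1 / 4),
               tolerance = 1e-6)
  # with all three states observed the limit is (1/3)^3
  m3 <- data_matrix(c(a = "0", b = "1", c = "2"), symbols = c("0", "1", "2"))
  tr3 <- ape::read.tree(text = "(a:25,b:25,c:25);")
  expect_equal(tree_loglik(tr3, m3, subst_model("mk"))$loglik, 3 * log(1 / 3),
               tolerance = 1e-6)
})

test_that("branch-length optimization hits the closed-form two-taxon MLE", {
  nsite <- 100; x <- 13
  m <- data_matrix(c(a = paste(c(rep("0", nsite - x), rep("1", x)),
                               collapse = ""),
                     b = strrep("0", nsite)), symbols = c("0", "1"))
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  ob <- optimize_branch_lengths(tr, m, subst_model("mk"), max_sweeps = 40,
                                tol = 1e-12)
  expect_equal(sum(ob$tree$edge.length), -0.5 * log(1 - 2 * x / nsite),
               tolerance = 1e-3)
  # never decreases; already-optimal tree stays put
  expect_gte(ob$loglik, tree_loglik(tr, m, subst_model("mk"))$loglik)
  ob2 <- optimize_branch_lengths(ob$tree, m, subst_model("mk"),
                                 max_sweeps = 5, tol = 1e-8)
  expect_equal(ob2$loglik, ob$loglik, tolerance = 1e-4)
})

test_that("variable-only ascertainment matches the two-taxon closed form", {
  tt <- 0.4
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", tt / 2, tt / 2))
  m <- data_matrix(c(a = "0", b = "1"), symbols = c("0", "1"))
  raw <- tree_loglik(tr, m, subst_model("mk"))$loglik
  cor <- tree_loglik(tr, m, subst_model("mk"),
                     ascertainment = "variable")$loglik
  psame <- 0.5 * (1 + exp(-2 * tt))
  expect_equal(cor, raw - log(1 - psame), tolerance = 1e-9)
  expect_lt(raw, cor)  # conditioning on variability raises each variable column
  # mode "none" is the identity
  expect_identical(raw, tree_loglik(tr, m, subst_model("mk"),
                                    ascertainment = "none")$loglik)
})
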