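test_that("three-taxon NJ solves the three-point formulas", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = rep(list(c("A", "B", "C")), 2))
  tr <- nj_tree(dm)
  bl <- stats::setNames(tr$edge.length,
                        tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
})

test_that("NJ exactly recovers a known additive four-taxon tree", {
  dm <- matrix(0, 4, 4, dimnames = rep(list(c("A", "B", "C", "D")), 2))
  dm["A", "B"] <- 3; dm["A", "C"] <- 5; dm["A", "D"] <- 6
  dm["B", "C"] <- 6; dm["B", "D"] <- 7; dm["C", "D"] <- 7
  dm <- dm + t(dm)
  tr <- nj_tree(dm)
  # additivity: path lengths reproduce the matrix exactly
  cc <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(cc, dm, tolerance = 1e-10)
  # topology AB|CD
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::read.tree(
    text = "((A:1,B:2):1,C:3,D:4);")), structure(0, names = "PH85"),
    ignore_attr = TRUE)
})

test_that("NJ recovers random additive trees of 4-8 taxa exactly", {
  for (seed in 1:10) {
    n <- 4 + (seed %% 5)
    fix <- random_additive_tree(n, seed)
    tr <- nj_tree(fix$dm)
    cc <- ape::cophenetic.phylo(tr)
    cc <- cc[rownames(fix$dm), colnames(fix$dm)]
    expect_equal(cc, fix$dm, tolerance = 1e-8, info = seed)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(fix$tree))), 0,
                 info = seed)
  }
})

test_that("NJ agrees with the reference implementation on noisy matrices", {
  for (seed in c(4, 9)) {
    dm <- withr::with_seed(seed, {
      n <- 6
      m <- matrix(stats::runif(n * n, 0.1, 1), n, n)
      m <- (m + t(m)) / 2
      diag(m) <- 0
      dimnames(m) <- rep(list(letters[1:n]), 2)
      m
    })
    ours <- nj_tree(dm)
    ref <- ape::nj(stats::as.dist(dm))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ours),
                                           ape::unroot(ref))), 0,
                 info = seed)
  }
})

test_that("degenerate matrices give a flagged zero-length star", {
  dm <- matrix(0, 4, 4, dimnames = rep(list(letters[1:4]), 2))
  tr <- nj_tree(dm)
  expect_true(all(tr$edge.length == 0))
  expect_true(attr(tr, "zero_matrix"))
  expect_error(nj_tree(matrix(c(0, 1, 1, 0), 2, 2)), ">= 3 taxa")
  bad <- matrix(c(0, 1, 2, 3, 0, 4, 2, 4, 0), 3, 3)
  expect_error(nj_tree(bad), "symmetric")
})

test_that("Newick serialization round-trips topology, lengths and supports", {
  fix <- random_additive_tree(6, 77)
  tr <- nj_tree(fix$dm)
  tr$node.label <- c(NA, 95, 80, 100)[seq_len(tr$Nnode)]
  td <- withr::local_tempdir()
  p <- file.path(td, "t.nwk")
  ape::write.tree(tr, p)
  back <- ape::read.tree(p)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(back),
                                         ape::unroot(tr))), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-8)
  expect_setequal(
    suppressWarnings(stats::na.omit(as.numeric(back$node.label))),
    stats::na.omit(as.numeric(tr$node.label)))
})

test_that("bootstrap saturates on clean signal and is seed-deterministic", {
  seqs <- withr::with_seed(9, {
    anc <- syntevol:::random_dna_int(2000)
    inner <- syntevol:::evolve_k2p_int(anc, 0.15, 2)
    vapply(list(A = syntevol:::evolve_k2p_int(anc, 0.02, 2),
                B = syntevol:::evolve_k2p_int(anc, 0.02, 2),
                C = syntevol:::evolve_k2p_int(inner, 0.02, 2),
                D = syntevol:::evolve_k2p_int(inner, 0.02, 2)),
           syntevol:::int_to_seq, "")
  })
  tr <- bootstrap_support(seqs, n_reps = 100, seed = 4)
  expect_equal(stats::na.omit(as.numeric(tr$node.label)),
               100, ignore_attr = TRUE)
  tr2 <- bootstrap_support(seqs, n_reps = 100, seed = 4)
  expect_identical(tr$node.label, tr2$node.label)
  tr1 <- bootstrap_support(seqs, n_reps = 1, seed = 4)
  expect_true(all(stats::na.omit(as.numeric(tr1$node.label)) %in% c(0, 100)))
  expect_error(bootstrap_support(seqs, n_reps = 0), "n_reps")
})
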