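test_that("global alignment reproduces expected optima", {
  al <- global_align("ACGT", "ACGT")
  expect_equal(al$score, 4)
  expect_equal(al$a_aln, "ACGT")
  al2 <- global_align("ACGT", "AGT")
  expect_equal(al2$a_aln, "ACGT")
  expect_equal(al2$b_aln, "A-GT")
  s <- rand_seq(10000, 61)
  al3 <- global_align(s, s)
  expect_equal(al3$a_aln, al3$b_aln)
  expect_error(global_align("", "ACGT"), "empty")
})

test_that("K2P distance matches the closed form", {
  a <- strrep("A", 1000)
  y <- strsplit(a, "")[[1]]
  y[1:100] <- "G"   # 100 transitions
  y[101:150] <- "C" # 50 transversions
  d <- k2p_distance(pairwise_alignment(a, paste(y, collapse = "")))
  expect_equal(d$P, 0.10)
  expect_equal(d$Q, 0.05)
  expect_equal(d$K, -0.5 * log(0.75) - 0.25 * log(0.90), tolerance = 1e-12)
  expect_equal(round(d$K, 4), 0.1702)

  ident <- k2p_distance(pairwise_alignment(a, a))
  expect_equal(c(ident$P, ident$Q, ident$K), c(0, 0, 0))

  # saturation: P = 0.5, Q = 0
  y2 <- strsplit(a, "")[[1]]
  y2[1:500] <- "G"
  expect_error(k2p_distance(pairwise_alignment(a, paste(y2, collapse = ""))),
               "saturation")
})

test_that("gap and N columns are excluded from distance estimation", {
  d <- k2p_distance(pairwise_alignment("ACGTNN--AC", "ACGTAANNAC"))
  expect_equal(d$n_sites, 6L)
  expect_equal(d$K, 0)
  # K2P >= p-distance on mutated alignments (correction inflates)
  for (seed in 1:5) {
    x <- rand_seq(2000, seed)
    y <- withr::with_seed(seed + 10, {
      ch <- strsplit(x, "")[[1]]
      idx <- sample(2000, 150)
      ch[idx] <- vapply(ch[idx], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      paste(ch, collapse = "")
    })
    d <- k2p_distance(pairwise_alignment(x, y))
    p_dist <- mean(charToRaw(x) != charToRaw(y))
    expect_gte(d$K, p_dist)
  }
})

test_that("codon alignments are protein-guided and stop-checked", {
  cds <- paste(rep("GCT", 100), collapse = "")
  ca <- build_codon_alignment(cds, cds)
  expect_equal(ca$n_codons, 100L)
  # in-frame deletion: 99 columns retained
  cds_b <- paste(rep("GCT", 99), collapse = "")
  ca2 <- build_codon_alignment(cds, cds_b)
  expect_equal(ca2$n_codons, 99L)
  # terminal stop stripped, internal stop rejected with its index
  expect_equal(build_codon_alignment(paste0(cds, "TAA"), cds)$n_codons, 100L)
  bad <- paste0(substr(cds, 1, 30), "TAA", substr(cds, 34, 300))
  expect_error(build_codon_alignment(bad, bad), "codon 11")
})

test_that("NG86 reproduces hand-counted sites and JC correction", {
  ca <- build_codon_alignment("TTTGCTAAA", "TTCGCTAAA")
  kk <- suppressWarnings(ng86_kaks(ca))
  expect_equal(kk$S, 5 / 3, tolerance = 1e-12)
  expect_equal(kk$N, 22 / 3, tolerance = 1e-12)
  expect_equal(kk$Sd, 1)
  expect_equal(kk$Nd, 0)
  expect_equal(kk$ps, 0.6, tolerance = 1e-12)
  expect_equal(kk$Ks, -0.75 * log(0.2), tolerance = 1e-12)
  expect_equal(round(kk$Ks, 4), 1.2071)
  expect_equal(kk$Ka, 0)

  ident <- suppressWarnings(ng86_kaks(build_codon_alignment("ATGGCT",
                                                            "ATGGCT")))
  expect_equal(ident$Ks, 0)
  expect_true(ident$omega_undefined)
})

test_that("NG86 site counts always sum to 3 codons and scale-invariantly", {
  for (seed in 1:4) {
    cp <- simulate_cds_pair(80, 0.3, 0.2, seed = seed)
    ca <- build_codon_alignment(cp$cds_a, cp$cds_b)
    kk <- ng86_kaks(ca)
    expect_equal(kk$S + kk$N, 3 * ca$n_codons, tolerance = 1e-9)
    # duplication invariance: concatenating the alignment with itself
    ca2 <- build_codon_alignment(paste0(cp$cds_a, cp$cds_a),
                                 paste0(cp$cds_b, cp$cds_b))
    kk2 <- ng86_kaks(ca2)
    expect_equal(kk2$ps, kk$ps, tolerance = 1e-9)
    expect_equal(kk2$pn, kk$pn, tolerance = 1e-9)
    expect_equal(kk2$Ks, kk$Ks, tolerance = 1e-9)
    expect_equal(kk2$Ka, kk$Ka, tolerance = 1e-9)
  }
})

test_that("NG86 pathway averaging equals brute-force enumeration", {
  pairs <- list(c("TTT", "TTC"), c("ATG", "TAC"), c("GGG", "CCC"),
                c("AAA", "ACC"), c("TGG", "TAC"), c("CGA", "CGA"),
                c("TTA", "CAT"))
  for (p in pairs) {
    got <- syntevol:::ng86_codon_diffs(p[1], p[2])
    oracle <- brute_force_codon_paths(p[1], p[2])
    expect_equal(unname(got), unname(oracle), info = paste(p, collapse = "-"))
  }
  # random codon pairs
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  withr::with_seed(71, {
    for (i in 1:25) {
      p <- sample(sense, 2)
      got <- syntevol:::ng86_codon_diffs(p[1], p[2])
      oracle <- brute_force_codon_paths(p[1], p[2])
      expect_equal(unname(got), unname(oracle),
                   info = paste(p, collapse = "-"))
    }
  })
})

test_that("simulated noncoding pairs recover the configured rate", {
  n_rep <- 100
  ks <- vapply(seq_len(n_rep), function(i) {
    seqs <- withr::with_seed(3000 + i, {
      anc <- syntevol:::random_dna_int(2000)
      list(a = syntevol:::evolve_k2p_int(anc, 0.03, 2),
           b = syntevol:::evolve_k2p_int(anc, 0.03, 2))
    })
    noncoding_rate(pairwise_alignment(syntevol:::int_to_seq(seqs$a),
                                      syntevol:::int_to_seq(seqs$b)))
  }, numeric(1))
  se <- stats::sd(ks) / sqrt(n_rep)
  expect_lt(abs(mean(ks) - 0.06), 3 * se)
})
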