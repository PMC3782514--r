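test_that("CNS detection recovers implanted tri-shared segments", {
  cfg <- sim_config(seed = 11)
  trio <- simulate_trio_with_cns(cfg, n_cns = 3, cns_identity = 0.85)
  cns <- find_cns(trio$regions)
  expect_setequal(unique(cns$label), c("CNS1", "CNS2", "CNS3"))
  w <- cns_params()$window
  for (i in seq_len(nrow(cns))) {
    truth <- trio$truth[trio$truth$label == cns$label[i] &
                        trio$truth$region == cns$region[i], ]
    expect_lte(abs(cns$start[i] - truth$start), w)
    expect_lte(abs(cns$end[i] - truth$end), w)
  }
  expect_true(all(cns$identity >= 0.80))
})

test_that("no CNS is reported when none was implanted", {
  cfg <- sim_config(seed = 12)
  trio <- simulate_trio_with_cns(cfg, n_cns = 0)
  cns <- find_cns(trio$regions)
  expect_equal(nrow(cns), 0L)
})

test_that("fully identical shared segments are detected at identity 1", {
  cfg <- sim_config(seed = 13)
  trio <- simulate_trio_with_cns(cfg, n_cns = 2, cns_identity = 1.0)
  cns <- find_cns(trio$regions)
  expect_setequal(unique(cns$label), c("CNS1", "CNS2"))
  expect_true(all(cns$identity > 0.97))  # only window-edge effects
})

test_that("conserved sequence inside genic features is masked", {
  withr::with_seed(19, {
    gene1 <- rand_seq(600)
    gene2 <- rand_seq(600)
    shared <- rand_seq(600)
  })
  # the shared segment is annotated as an exon of a middle gene in region 1
  mk <- function(id, masked) {
    left <- rand_seq(300)
    right <- rand_seq(300)
    res <- paste0(left, gene1, rand_seq(200), shared, rand_seq(200), gene2,
                  right)
    feats <- feature_table(
      start = c(300L, 300L, 1700L, 1700L),
      end = c(900L, 900L, 2300L, 2300L),
      strand = "+", kind = c("gene", "CDS", "gene", "CDS"),
      name = c("anchor1", "anchor1", "anchor2", "anchor2"))
    if (masked) {
      feats <- rbind(feats, feature_table(1100L, 1700L, "+", "exon", "mid"))
    }
    genomic_region(id, res, feats)
  }
  masked_trio <- list(mk("r1", TRUE), mk("r2", FALSE), mk("r3", FALSE))
  expect_equal(nrow(find_cns(masked_trio)), 0L)
  open_trio <- list(mk("r1", FALSE), mk("r2", FALSE), mk("r3", FALSE))
  cns <- find_cns(open_trio)
  expect_gt(nrow(cns), 0L)
  # invariant: no CNS interval overlaps any genic feature
  for (i in seq_len(nrow(cns))) {
    reg <- open_trio[[match(cns$region[i], c("r1", "r2", "r3"))]]
    gf <- reg$features[reg$features$kind %in%
                       c("gene", "exon", "CDS"), , drop = FALSE]
    expect_false(any(gf$start < cns$end[i] & gf$end > cns$start[i]))
  }
})

test_that("identical regions give the full intergenic stretch as CNS", {
  withr::with_seed(23, {
    res <- rand_seq(3000)
  })
  feats <- feature_table(c(200L, 2400L), c(700L, 2900L), "+",
                         c("gene", "gene"), c("anchor1", "anchor2"))
  regs <- lapply(c("r1", "r2", "r3"), genomic_region, residues = res,
                 features = feats)
  cns <- find_cns(regs)
  expect_equal(nrow(cns), 3L)  # one CNS, present in all three regions
  p <- cns_params()
  intergenic <- 2400 - 700
  expect_true(all(abs((cns$end - cns$start) - intergenic) <= 2 * p$window))
})

test_that("regions without shared anchors are rejected with guidance", {
  r1 <- genomic_region("r1", rand_seq(500, 1),
                       feature_table(0L, 100L, "+", "gene", "gA"))
  r2 <- genomic_region("r2", rand_seq(500, 2),
                       feature_table(0L, 100L, "+", "gene", "gB"))
  expect_error(find_cns(list(r1, r2)), "anchor")
})

test_that("cis-element scanning matches IUPAC consensi on both strands", {
  s <- paste0(rand_seq(10, 31), "CACGTG", rand_seq(10, 32))
  hits <- scan_cis_elements(s)
  gbox <- hits[hits$name == "G-box", ]
  expect_equal(gbox$position, 10L)
  expect_equal(gbox$strand, "+")
  # palindromic consensus: exactly one hit per site, not two
  expect_equal(nrow(gbox), 1L)
  # brute-force both-strand scan agrees there is exactly one CACGTG site
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  n_sites <- length(gregexpr("CACGTG", s)[[1]][gregexpr("CACGTG", s)[[1]] > 0])
  expect_equal(nrow(gbox), n_sites)

  # reverse-strand hit of a non-palindromic motif
  s2 <- paste0("AAAAAA", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("CCTTTTG"))), "AAAAAA")
  h2 <- scan_cis_elements(s2)
  pbox <- h2[h2$name == "P-box", ]
  expect_equal(pbox$strand, "-")
  expect_equal(pbox$position, 6L)

  # composition-checked motif-free sequence: no P-box on either strand
  s3 <- strrep("AC", 200)
  h3 <- scan_cis_elements(s3)
  expect_false("P-box" %in% h3$name)

  expect_error(scan_cis_elements("ACGT", data.frame(name = "bad",
                                                    consensus = "AXGT")),
               "IUPAC")
})

test_that("SSR detection honors thresholds, rotations and nesting rules", {
  s <- paste0(rand_seq(50, 41), strrep("CT", 23), rand_seq(50, 42))
  ssr <- find_ssrs(s)
  ct <- ssr[ssr$unit == "CT", ]
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$copies, 23L)
  expect_equal(ct$end - ct$start, 46L)

  gaa <- find_ssrs(paste0("CCCC", strrep("GAA", 8), "CCCC"))
  expect_equal(gaa$unit, "AAG")  # smallest rotation
  expect_equal(gaa$copies[1], 8L)

  canonical <- min(c("CGGT", "GGTC", "GTCG", "TCGG"))
  hit <- find_ssrs(paste0(rand_seq(30, 43), strrep("CGGT", 5),
                          rand_seq(30, 44)))
  expect_true(any(hit$unit == canonical))
  miss <- find_ssrs(paste0(rand_seq(30, 45), strrep("CGGT", 4),
                           rand_seq(30, 46)))
  expect_false(any(miss$copies == 4 & nchar(miss$unit) == 4))

  # a (CTCT)n run reports as (CT)2n, not as a 4-mer
  tet <- find_ssrs(strrep("CTCT", 8))
  expect_equal(tet$unit, "CT")
  expect_equal(tet$copies, 16L)
})

test_that("SSR detection equals the brute-force tandem scan", {
  for (seed in c(51, 52, 53)) {
    s <- withr::with_seed(seed, paste0(
      rand_seq(300), strrep("AT", 7), rand_seq(100), strrep("A", 12),
      rand_seq(100), strrep("GGC", 6), rand_seq(300)))
    got <- find_ssrs(s)
    oracle <- brute_force_ssrs(s)
    got <- got[order(got$start), ]
    oracle <- oracle[order(oracle$start), ]
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle, info = seed)
  }
})
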