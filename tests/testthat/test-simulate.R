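test_that("null process yields identical regions with zero-divergence truth", {
  cfg <- sim_config(seed = 3, ancestor_length = 5000, target_K = 0,
                    indel_rate = 0, te_insertions_per_lineage = 0L,
                    gene_models = list())
  sp <- simulate_pair(cfg)
  expect_identical(sp$a$residues, sp$b$residues)
  expect_equal(sp$truth$true_K, 0)
  expect_equal(nrow(sp$truth$conserved), 1L)
  expect_equal(sp$truth$conserved$a_end - sp$truth$conserved$a_start, 5000L)
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 7, ancestor_length = 8000)
  s1 <- simulate_pair(cfg)
  s2 <- simulate_pair(cfg)
  expect_identical(s1$a$residues, s2$a$residues)
  expect_identical(s1$b, s2$b)
  expect_identical(s1$truth, s2$truth)
  td <- withr::local_tempdir()
  write_simulation(s1, file.path(td, "d1"))
  write_simulation(s2, file.path(td, "d2"))
  for (f in list.files(file.path(td, "d1"))) {
    expect_identical(readLines(file.path(td, "d1", f)),
                     readLines(file.path(td, "d2", f)), info = f)
  }
})

test_that("truth conserved intervals are disjoint, sorted and length-consistent", {
  cfg <- sim_config(seed = 21, ancestor_length = 20000, indel_rate = 2e-4,
                    te_insertions_per_lineage = 2L)
  sp <- simulate_pair(cfg)
  tr <- sp$truth$conserved
  expect_true(all(diff(tr$anc_start) > 0))
  expect_true(all(tr$anc_end[-nrow(tr)] <= tr$anc_start[-1]))
  expect_equal(tr$a_end - tr$a_start, tr$anc_end - tr$anc_start)
  expect_equal(tr$b_end - tr$b_start, tr$anc_end - tr$anc_start)
  # mapped intervals carry genuinely homologous sequence (identity >> chance)
  for (i in seq_len(nrow(tr))) {
    sa <- substr(sp$a$residues, tr$a_start[i] + 1, tr$a_end[i])
    sb <- substr(sp$b$residues, tr$b_start[i] + 1, tr$b_end[i])
    expect_gt(mean(charToRaw(sa) == charToRaw(sb)), 0.85)
  }
  # TE truth intervals carry LTR5/LTR3 annotations nested in the TE
  f <- sp$a$features
  for (te in sp$truth$te$a) {
    expect_true(any(f$kind == "TE" & f$start == te$start & f$end == te$end))
    expect_true(any(f$kind == "LTR5" & f$name == te$name))
  }
})

test_that("K2P estimate on simulated pairs recovers the configured divergence", {
  n_rep <- 60
  ks <- vapply(seq_len(n_rep), function(i) {
    cfg <- sim_config(seed = 1000 + i, ancestor_length = 10000,
                      target_K = 0.05, indel_rate = 0,
                      te_insertions_per_lineage = 0L, gene_models = list())
    sp <- simulate_pair(cfg)
    k2p_distance(pairwise_alignment(sp$a$residues, sp$b$residues))$K
  }, numeric(1))
  se <- stats::sd(ks) / sqrt(n_rep)
  expect_lt(abs(mean(ks) - 0.05), 3 * se)
})

test_that("zero-age and zero-rate LTR elements have identical LTRs", {
  el0 <- simulate_ltr_element(500, age_years = 0, r = 1.3e-8, seed = 2)
  expect_identical(el0$ltr5, el0$ltr3)
  elr <- simulate_ltr_element(500, age_years = 2e6, r = 0, seed = 2)
  expect_identical(elr$ltr5, elr$ltr3)
  expect_equal(ltr_insertion_age(elr$ltr5, elr$ltr3)$T_years, 0)
})

test_that("simulated CDS pairs are frame-intact, stop-free and identical at Ks = 0", {
  cp0 <- simulate_cds_pair(60, 0, 0.5, seed = 4)
  expect_identical(cp0$cds_a, cp0$cds_b)
  cp <- simulate_cds_pair(200, 0.4, 0.1, seed = 5)
  for (s in c(cp$cds_a, cp$cds_b)) {
    expect_equal(nchar(s) %% 3, 0)
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- vapply(codons, function(cd)
      as.character(Biostrings::GENETIC_CODE[[cd]]), "")
    expect_false(any(aa == "*"))
  }
})

test_that("trio generator places tri-shared segments at the stated identity", {
  cfg <- sim_config(seed = 11)
  trio <- simulate_trio_with_cns(cfg, n_cns = 3, cns_identity = 0.85)
  expect_length(trio$regions, 3)
  expect_equal(nrow(trio$truth), 9L)  # 3 CNS x 3 regions
  expect_setequal(unique(trio$truth$label), c("CNS1", "CNS2", "CNS3"))
  # pairwise identities: a-b and a-c at the target, b-c identical
  tr <- trio$truth
  seg <- function(reg, row) substr(trio$regions[[row$region]]$residues,
                                   row$start + 1, row$end)
  for (lab in unique(tr$label)) {
    rows <- tr[tr$label == lab, ]
    sa <- seg(trio$regions, rows[rows$region == "region_a", ])
    sb <- seg(trio$regions, rows[rows$region == "region_b", ])
    sc <- seg(trio$regions, rows[rows$region == "region_c", ])
    expect_identical(sb, sc)
    idn <- mean(charToRaw(sa) == charToRaw(sb))
    expect_equal(idn, 0.85, tolerance = 0.005)
  }
  # degenerate settings
  t0 <- simulate_trio_with_cns(cfg, n_cns = 0)
  expect_equal(nrow(t0$truth), 0L)
  t1 <- simulate_trio_with_cns(cfg, n_cns = 1, cns_identity = 1.0)
  rows <- t1$truth
  s <- vapply(seq_len(nrow(rows)), function(i)
    substr(t1$regions[[rows$region[i]]]$residues, rows$start[i] + 1,
           rows$end[i]), "")
  expect_length(unique(s), 1L)
})

test_that("saturating divergence targets are refused", {
  expect_error(sim_config(target_K = 3.5), "saturated")
})
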