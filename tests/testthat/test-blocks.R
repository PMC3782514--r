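test_that("self-comparison yields one full-coverage block at identity 1", {
  s <- rand_seq(10000, 42)
  bl <- find_conserved_blocks(s, s)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$a_start, 0L)
  expect_equal(bl$a_end, 10000L)
  expect_equal(bl$identity, 1.0)
  st <- conservation_stats(bl)
  expect_equal(st$csr, 100.0)
})

test_that("independent random sequences share almost nothing", {
  a <- rand_seq(10000, 1)
  b <- rand_seq(10000, 2)
  bl <- find_conserved_blocks(a, b)
  st <- conservation_stats(bl, overlap_length = 10000)
  expect_lt(st$conserved_total, 0.02 * 10000)
})

test_that("an implanted identical segment is recovered to within word_size", {
  withr::with_seed(5, {
    a <- rand_seq(20000)
    insert <- rand_seq(3000)
    b <- paste0(rand_seq(4000), insert, rand_seq(13000))
  })
  a <- paste0(substr(a, 1, 9000), insert, substr(a, 12001, 20000))
  bl <- find_conserved_blocks(a, b)
  expect_equal(nrow(bl), 1L)
  w <- block_params()$word_size
  expect_lt(abs(bl$a_start - 9000), w)
  expect_lt(abs(bl$a_end - 12000), w)
  expect_lt(abs(bl$b_start - 4000), w)
  expect_lt(abs(bl$b_end - 7000), w)
})

test_that("block coverage agrees with an exhaustive window-pair scan", {
  # small sequences so the O(n*m) oracle is feasible
  withr::with_seed(8, {
    core <- rand_seq(800)
    a <- paste0(rand_seq(400), core, rand_seq(300))
    mut <- strsplit(core, "")[[1]]
    idx <- sample(800, 120)  # 15% divergence
    mut[idx] <- vapply(mut[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    b <- paste0(rand_seq(250), paste(mut, collapse = ""), rand_seq(450))
  })
  params <- block_params(min_block_length = 100L)
  bl <- find_conserved_blocks(a, b, params)
  oracle_cov <- brute_force_window_scan(a, b)
  blk_cov <- logical(nchar(a))
  for (i in seq_len(nrow(bl))) blk_cov[(bl$a_start[i] + 1):bl$a_end[i]] <- TRUE
  # boundary agreement within one word_size at each end
  disagree <- sum(xor(blk_cov, oracle_cov))
  expect_lt(disagree, 2 * params$word_size * max(1, nrow(bl)))
})

test_that("conserved totals are symmetric in the input order", {
  cfg <- sim_config(seed = 33, ancestor_length = 15000,
                    te_insertions_per_lineage = 1L)
  sp <- simulate_pair(cfg)
  ab <- find_conserved_blocks(sp$a, sp$b)
  ba <- find_conserved_blocks(sp$b, sp$a)
  expect_equal(sum(ab$length), sum(ba$length))
  expect_equal(ab$a_start, ba$b_start)
  expect_equal(ab$b_end, ba$a_end)
})

test_that("CSR and CFS reproduce the published conservation arithmetic", {
  # block counts are implied by conserved_total / CFS
  tab <- reference_table("conservation")
  n_blocks <- round(tab$conserved_bp / tab$cfs_printed)
  for (i in seq_len(nrow(tab))) {
    st <- conservation_summary(tab$conserved_bp[i], n_blocks[i],
                               tab$overlap_bp[i])
    expect_equal(st$cfs, tab$cfs_printed[i], info = tab$pair[i])
    expect_lt(abs(st$csr_raw - tab$csr_printed[i]), 0.11)
  }
  # the two flagship rows, at printed precision
  st1 <- conservation_summary(82563, 9, 123270)
  expect_equal(st1$csr, 67.0)
  expect_equal(st1$cfs, 9173L)
  st2 <- conservation_summary(95924, 2, 96932)
  expect_equal(st2$cfs, 47962L)
  expect_lt(abs(st2$csr_raw - 98.9), 0.11)
})

test_that("the empty block set is flagged", {
  st <- conservation_stats(find_conserved_blocks(rand_seq(1000, 3),
                                                 rand_seq(1000, 4)),
                           overlap_length = 1000)
  expect_true(st$no_blocks)
  expect_equal(st$csr, 0.0)
  expect_equal(st$cfs, 0L)
})

test_that("CFS * n_blocks brackets the conserved total", {
  for (seed in 1:5) {
    tot <- withr::with_seed(seed, sample(1000:100000, 1))
    n <- withr::with_seed(seed + 100, sample(1:12, 1))
    st <- conservation_summary(tot, n, tot * 2)
    expect_lte(st$cfs * st$n_blocks, st$conserved_total)
    expect_lt(st$conserved_total, st$cfs * st$n_blocks + st$n_blocks)
  }
})

test_that("gaps are classified as TE insertion, deletion or unknown", {
  withr::with_seed(14, {
    base <- rand_seq(12000)
    te_seq <- rand_seq(5000)
    extra <- rand_seq(1000)
  })
  a <- genomic_region("a", base)
  # b = a with an annotated LTR TE inserted at 6000
  b_res <- paste0(substr(base, 1, 6000), te_seq, substr(base, 6001, 12000))
  b <- genomic_region("b", b_res, feature_table(
    c(6000L, 6000L, 10200L), c(11000L, 6800L, 11000L), "+",
    c("TE", "LTR5", "LTR3"), "wis_like"))
  bl <- find_conserved_blocks(a, b)
  ev <- classify_gaps(bl, a, b)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$side, "b")
  expect_equal(ev$cause, "TE_insertion")
  expect_match(ev$evidence, "wis_like")

  # unannotated extra segment, no outgroup -> unknown indel
  b2 <- genomic_region("b2", paste0(substr(base, 1, 6000), extra,
                                    substr(base, 6001, 12000)))
  ev2 <- classify_gaps(find_conserved_blocks(a, b2), a, b2)
  expect_equal(ev2$cause, "unknown_indel")

  # segment in a that aligns to an outgroup -> deletion (lost on the b side)
  a3 <- genomic_region("a3", paste0(substr(base, 1, 6000), extra,
                                    substr(base, 6001, 12000)))
  outg <- genomic_region("outgroup", paste0(rand_seq(500, 77), extra,
                                            rand_seq(500, 78)))
  ev3 <- classify_gaps(find_conserved_blocks(a3, a), a3, a, outgroup = outg)
  expect_equal(ev3$side, "a")
  expect_equal(ev3$cause, "deletion")
})
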