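# Pairwise conserved-block detection between homologous regions: an explicit
# seed-chain-extend-merge algorithm whose window (40 bp) and identity (60%)
# defaults match the dot-plot criteria classically used for this comparison.

#' Parameters for conserved-block detection
#'
#' @param word_size Window size in bp for identity evaluation (default 40).
#' @param min_identity Minimum window identity for conserved sequence
#'   (default 0.60).
#' @param merge_distance Chains/blocks closer than this (bp, on both
#'   sequences) are merged (default 200).
#' @param min_block_length Blocks shorter than this (bp, mean of the two
#'   spans) are dropped (default 200).
#' @param max_kmer_hits Seeds from k-mers occurring more often than this in
#'   either sequence are skipped (simple repeat masking).
#' @param include_reverse Also seed against the reverse complement of `b`
#'   (off by default; forward-strand comparison is the primary use).
#' @return List of class `block_params`.
#' @export
block_params <- function(word_size = 40L, min_identity = 0.60,
                         merge_distance = 200L, min_block_length = 200L,
                         max_kmer_hits = 10L, include_reverse = FALSE) {
  stopifnot(word_size >= 8, min_identity > 0, min_identity <= 1,
            merge_distance >= 0, min_block_length >= 0)
  structure(list(word_size = as.integer(word_size),
                 min_identity = min_identity,
                 merge_distance = as.integer(merge_distance),
                 min_block_length = as.integer(min_block_length),
                 max_kmer_hits = as.integer(max_kmer_hits),
                 include_reverse = include_reverse),
            class = "block_params")
}

# All shared k-mer seed positions between two sequences (1-based starts).
kmer_seeds <- function(sa, sb, k, max_hits) {
  na <- nchar(sa); nb <- nchar(sb)
  if (na < k || nb < k) return(data.table::data.table(i = integer(),
                                                      j = integer()))
  ka <- substring(sa, 1:(na - k + 1), k:na)
  kb <- substring(sb, 1:(nb - k + 1), k:nb)
  dta <- data.table::data.table(kmer = ka, i = seq_along(ka))
  dtb <- data.table::data.table(kmer = kb, j = seq_along(kb))
  # mask high-copy k-mers (repeats) and anything containing N
  cnt_a <- dta[, .N, by = "kmer"]
  cnt_b <- dtb[, .N, by = "kmer"]
  ok <- intersect(cnt_a[cnt_a$N <= max_hits]$kmer,
                  cnt_b[cnt_b$N <= max_hits]$kmer)
  ok <- ok[!grepl("N", ok, fixed = TRUE)]
  dta <- dta[dta$kmer %in% ok]
  dtb <- dtb[dtb$kmer %in% ok]
  merge(dta, dtb, by = "kmer", allow.cartesian = TRUE)[, c("i", "j")]
}

# Extend a chained segment along its diagonal: positions covered by any
# word-sized window with identity >= min_identity, taking the maximal covered
# run intersecting the seed chain. raw_a/raw_b are charToRaw of the sequences.
extend_segment <- function(raw_a, raw_b, a1, a2, diag, params, ext = 5000L) {
  w <- params$word_size
  na <- length(raw_a); nb <- length(raw_b)
  lo <- max(1L, a1 - ext, diag + 1L)          # b index = a index - diag >= 1
  hi <- min(na, a2 + ext, nb + diag)
  if (hi - lo + 1L < w) return(NULL)
  mv <- raw_a[lo:hi] == raw_b[(lo - diag):(hi - diag)]
  win <- rolling_mean(mv, w)
  cov <- covered_positions(win >= params$min_identity, w)
  runs <- true_runs(cov)
  if (nrow(runs) == 0) return(NULL)
  runs$start <- runs$start + lo - 1L
  runs$end <- runs$end + lo - 1L
  hit <- runs[runs$start <= a2 & runs$end >= a1, , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  hit <- hit[which.max(hit$end - hit$start), ]
  idn <- mean(mv[(hit$start - lo + 1L):(hit$end - lo + 1L)])
  data.frame(a_start = hit$start, a_end = hit$end, diag = diag,
             identity = idn)
}

#' Find conserved blocks between two homologous regions
#'
#' Seeds are shared exact k-mers (k = `word_size / 2`); seeds on the same
#' diagonal within `merge_distance` are chained; chains are extended to the
#' maximal run of `word_size`-bp windows with identity >= `min_identity`;
#' chains within `merge_distance` (on both sequences) are merged; blocks
#' shorter than `min_block_length` are dropped. Coordinates in the result are
#' 0-based half-open; `length` is the mean of the two spans.
#'
#' @param a,b [genomic_region()] objects (or plain sequence strings).
#' @param params A [block_params()].
#' @return data.frame of class `conserved_blocks` with columns `a_start`,
#'   `a_end`, `b_start`, `b_end`, `strand`, `identity`, `length`, sorted by
#'   `a_start`. Empty data.frame when nothing is conserved.
#' @export
find_conserved_blocks <- function(a, b, params = block_params()) {
  sa <- if (inherits(a, "genomic_region")) a$residues else toupper(a)
  sb <- if (inherits(b, "genomic_region")) b$residues else toupper(b)
  stopifnot(nchar(sa) > 0, nchar(sb) > 0)
  out <- find_blocks_one_strand(sa, sb, params, strand = "+")
  if (isTRUE(params$include_reverse)) {
    rb <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sb)))
    rev <- find_blocks_one_strand(sa, rb, params, strand = "-")
    if (nrow(rev) > 0) {
      nb <- nchar(sb)
      bs <- nb - rev$b_end
      be <- nb - rev$b_start
      rev$b_start <- bs
      rev$b_end <- be
      out <- rbind(out, rev)
    }
  }
  out <- out[order(out$a_start, out$b_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("conserved_blocks", "data.frame")
  out
}

find_blocks_one_strand <- function(sa, sb, params, strand) {
  empty <- data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      strand = character(), identity = numeric(),
                      length = numeric())
  k <- max(8L, params$word_size %/% 2L)
  seeds <- kmer_seeds(sa, sb, k, params$max_kmer_hits)
  if (nrow(seeds) == 0) return(empty)
  seeds$diag <- seeds$i - seeds$j
  data.table::setorderv(seeds, c("diag", "i"))
  raw_a <- charToRaw(sa)
  raw_b <- charToRaw(sb)
  segs <- list()
  for (sd in split(seeds, seeds$diag)) {
    brk <- c(0L, which(diff(sd$i) > params$merge_distance), nrow(sd))
    for (ci in seq_len(length(brk) - 1L)) {
      idx <- (brk[ci] + 1L):brk[ci + 1L]
      a1 <- sd$i[idx[1]]
      a2 <- sd$i[idx[length(idx)]] + k - 1L
      seg <- extend_segment(raw_a, raw_b, a1, a2, sd$diag[1], params)
      if (!is.null(seg)) segs[[length(segs) + 1L]] <- seg
    }
  }
  if (length(segs) == 0) return(empty)
  segs <- unique(do.call(rbind, segs))
  # 1-based inclusive -> block table (still 1-based here)
  blk <- data.frame(a_start = segs$a_start, a_end = segs$a_end,
                    b_start = segs$a_start - segs$diag,
                    b_end = segs$a_end - segs$diag,
                    identity = segs$identity)
  blk <- blk[order(blk$a_start, blk$b_start), , drop = FALSE]
  # merge blocks within merge_distance on both axes
  merged <- blk[1, , drop = FALSE]
  if (nrow(blk) > 1) {
    for (i in 2:nrow(blk)) {
      last <- nrow(merged)
      ga <- blk$a_start[i] - merged$a_end[last]
      gb <- blk$b_start[i] - merged$b_end[last]
      if (ga <= params$merge_distance && gb <= params$merge_distance &&
          blk$b_end[i] > merged$b_start[last]) {
        w1 <- merged$a_end[last] - merged$a_start[last] + 1L
        w2 <- blk$a_end[i] - blk$a_start[i] + 1L
        merged$identity[last] <-
          (merged$identity[last] * w1 + blk$identity[i] * w2) / (w1 + w2)
        merged$a_end[last] <- max(merged$a_end[last], blk$a_end[i])
        merged$b_end[last] <- max(merged$b_end[last], blk$b_end[i])
        merged$b_start[last] <- min(merged$b_start[last], blk$b_start[i])
      } else {
        merged <- rbind(merged, blk[i, ])
      }
    }
  }
  # enforce non-overlap on each axis (trim the later block)
  if (nrow(merged) > 1) {
    for (i in 2:nrow(merged)) {
      ov_a <- merged$a_end[i - 1L] - merged$a_start[i] + 1L
      if (ov_a > 0) {
        merged$a_start[i] <- merged$a_start[i] + ov_a
        merged$b_start[i] <- merged$b_start[i] + ov_a
      }
      ov_b <- merged$b_end[i - 1L] - merged$b_start[i] + 1L
      if (ov_b > 0) {
        merged$a_start[i] <- merged$a_start[i] + ov_b
        merged$b_start[i] <- merged$b_start[i] + ov_b
      }
    }
    merged <- merged[merged$a_start <= merged$a_end &
                     merged$b_start <= merged$b_end, , drop = FALSE]
  }
  merged$length <- ((merged$a_end - merged$a_start + 1L) +
                    (merged$b_end - merged$b_start + 1L)) / 2
  merged <- merged[merged$length >= params$min_block_length, , drop = FALSE]
  if (nrow(merged) == 0) return(empty)
  data.frame(a_start = merged$a_start - 1L, a_end = merged$a_end,
             b_start = merged$b_start - 1L, b_end = merged$b_end,
             strand = strand, identity = merged$identity,
             length = merged$length)
}

#' Conservation statistics (CSR and CFS) from a block set
#'
#' CSR (conserved sequence ratio) is the percentage of the homologous overlap
#' covered by conserved blocks; CFS (average conserved fragment size) is the
#' total conserved length divided by the number of blocks, truncated to
#' integer bp. CSR is computed at full precision and rounded once to one
#' decimal for display.
#'
#' @param blocks A `conserved_blocks` data.frame from
#'   [find_conserved_blocks()].
#' @param overlap_length Length (bp) of the mutually alignable interval. If
#'   `NULL`, it is taken as the mean of the first-to-last block anchor spans
#'   on the two sequences.
#' @return List of class `conservation_stats`: `overlap_length`,
#'   `conserved_total`, `n_blocks`, `csr` (rounded percent), `csr_raw`,
#'   `cfs` (floored bp) and `no_blocks` flag.
#' @export
conservation_stats <- function(blocks, overlap_length = NULL) {
  n <- nrow(blocks)
  if (n == 0) {
    if (is.null(overlap_length)) overlap_length <- NA_real_
    return(structure(list(overlap_length = overlap_length,
                          conserved_total = 0, n_blocks = 0L,
                          csr = 0.0, csr_raw = 0.0, cfs = 0L,
                          no_blocks = TRUE),
                     class = "conservation_stats"))
  }
  total <- sum(blocks$length)
  if (is.null(overlap_length)) {
    overlap_length <- ((max(blocks$a_end) - min(blocks$a_start)) +
                       (max(blocks$b_end) - min(blocks$b_start))) / 2
  }
  stopifnot(overlap_length > 0)
  conservation_summary(total, n, overlap_length)
}

#' Conservation statistics from totals
#'
#' Same statistic as [conservation_stats()] computed directly from a conserved
#' total, block count and overlap length (e.g. when reproducing published
#' summary tables whose block sets are not available).
#'
#' @param conserved_total Total conserved length in bp.
#' @param n_blocks Number of conserved blocks.
#' @param overlap_length Homologous overlap length in bp.
#' @return See [conservation_stats()].
#' @export
conservation_summary <- function(conserved_total, n_blocks, overlap_length) {
  stopifnot(overlap_length > 0, n_blocks >= 0)
  if (n_blocks == 0) return(conservation_stats(
    data.frame(a_start = integer(), a_end = integer(), b_start = integer(),
               b_end = integer(), strand = character(), identity = numeric(),
               length = numeric()), overlap_length))
  csr_raw <- 100 * conserved_total / overlap_length
  structure(list(overlap_length = overlap_length,
                 conserved_total = conserved_total,
                 n_blocks = as.integer(n_blocks),
                 csr = round(csr_raw, 1), csr_raw = csr_raw,
                 cfs = as.integer(floor(conserved_total / n_blocks)),
                 no_blocks = FALSE),
            class = "conservation_stats")
}

#' @export
print.conservation_stats <- function(x, ...) {
  cat(sprintf(paste0("<conservation_stats> overlap %s bp, conserved %s bp ",
                     "in %d block(s): CSR %.1f%%, CFS %s bp%s\n"),
              format(x$overlap_length, big.mark = ","),
              format(round(x$conserved_total), big.mark = ","),
              x$n_blocks, x$csr, format(x$cfs, big.mark = ","),
              if (x$no_blocks) " [no blocks]" else ""))
  invisible(x)
}

# fraction of [start,end) covered by feature rows of the given kinds
feature_coverage <- function(features, start, end, kinds) {
  f <- features[features$kind %in% kinds, , drop = FALSE]
  if (nrow(f) == 0) return(0)
  s <- pmax(f$start, start)
  e <- pmin(f$end, end)
  ov <- pmax(0L, e - s)
  # merge overlaps crudely via coverage on a small vector
  if (sum(ov) == 0) return(0)
  cov <- logical(end - start)
  for (i in which(ov > 0)) cov[(s[i] - start + 1L):(e[i] - start)] <- TRUE
  mean(cov)
}

#' Classify inter-block gaps
#'
#' For each interval between adjacent conserved blocks that is present on
#' exactly one sequence: if at least half of it is covered by an annotated TE
#' feature it is a `TE_insertion` on that side; else if it is mostly simple
#' sequence it is `low_complexity`; else if an outgroup region is supplied and
#' the interval aligns to the outgroup it is a `deletion` (the material is
#' ancestral and was lost on the other side); otherwise `unknown_indel`.
#'
#' @param blocks Sorted non-overlapping `conserved_blocks`.
#' @param a,b The two [genomic_region()]s (with TE annotations if available).
#' @param outgroup Optional [genomic_region()] used as deletion evidence.
#' @param params [block_params()] used for the outgroup alignment check.
#' @param tol Spans up to this size (bp) on the other side are ignored
#'   (default `word_size`).
#' @return data.frame with columns `side`, `start`, `end`, `cause`,
#'   `evidence`.
#' @export
classify_gaps <- function(blocks, a, b, outgroup = NULL,
                          params = block_params(), tol = params$word_size) {
  out <- data.frame(side = character(), start = integer(), end = integer(),
                    cause = character(), evidence = character())
  if (nrow(blocks) < 2) return(out)
  for (i in seq_len(nrow(blocks) - 1L)) {
    ga <- c(blocks$a_end[i], blocks$a_start[i + 1L])
    gb <- c(blocks$b_end[i], blocks$b_start[i + 1L])
    la <- ga[2] - ga[1]
    lb <- gb[2] - gb[1]
    side <- if (la > tol && lb <= tol) "a"
            else if (lb > tol && la <= tol) "b"
            else next
    reg <- if (side == "a") a else b
    gap <- if (side == "a") ga else gb
    te_cov <- feature_coverage(reg$features, gap[1], gap[2],
                               c("TE", "LTR5", "LTR3"))
    seg <- region_subseq(reg, gap[1], gap[2])
    if (te_cov >= 0.5) {
      f <- reg$features
      hit <- f$kind %in% c("TE", "LTR5", "LTR3") &
        f$start < gap[2] & f$end > gap[1]
      out <- rbind(out, data.frame(
        side = side, start = gap[1], end = gap[2], cause = "TE_insertion",
        evidence = paste(unique(f$name[hit]), collapse = ",")))
      next
    }
    ssr <- find_ssrs(seg)
    ssr_cov <- if (nrow(ssr) == 0) 0 else
      sum(ssr$end - ssr$start) / nchar(seg)
    if (ssr_cov >= 0.5) {
      out <- rbind(out, data.frame(
        side = side, start = gap[1], end = gap[2], cause = "low_complexity",
        evidence = paste(unique(ssr$unit), collapse = ",")))
      next
    }
    if (!is.null(outgroup)) {
      og_blocks <- find_conserved_blocks(seg, outgroup, params)
      og_cov <- if (nrow(og_blocks) == 0) 0 else
        sum(og_blocks$a_end - og_blocks$a_start) / nchar(seg)
      if (og_cov >= 0.5) {
        out <- rbind(out, data.frame(
          side = side, start = gap[1], end = gap[2], cause = "deletion",
          evidence = sprintf("aligns to outgroup %s", outgroup$id)))
        next
      }
    }
    out <- rbind(out, data.frame(side = side, start = gap[1], end = gap[2],
                                 cause = "unknown_indel", evidence = ""))
  }
  out
}
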