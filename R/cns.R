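# Conserved non-coding sequence (CNS) detection across homologous regions.
# Intergenic stretches between shared anchor genes are globally aligned per
# region pair; a sliding window (default 100 bp at >= 80% identity, the
# VISTA-style criterion) defines conserved columns, whose maximal runs are
# intersected across all pairs and mapped back to each region.

#' Parameters for CNS detection
#'
#' @param window Sliding window size in alignment columns (default 100).
#' @param min_identity Minimum window identity (default 0.80); gap columns
#'   count as mismatches.
#' @param min_length Minimum CNS length in bp (default 100).
#' @param genic_mask_padding Extra bp around genic features that a CNS must
#'   avoid (default 0).
#' @param identity_mode How the per-CNS identity is summarized across region
#'   pairs: `"min"` (pairwise minimum, default) or `"mean"`.
#' @return List of class `cns_params`.
#' @export
cns_params <- function(window = 100L, min_identity = 0.80, min_length = 100L,
                       genic_mask_padding = 0L,
                       identity_mode = c("min", "mean")) {
  stopifnot(window >= 20, min_identity > 0, min_identity <= 1,
            min_length >= 1, genic_mask_padding >= 0)
  structure(list(window = as.integer(window), min_identity = min_identity,
                 min_length = as.integer(min_length),
                 genic_mask_padding = as.integer(genic_mask_padding),
                 identity_mode = match.arg(identity_mode)),
            class = "cns_params")
}

GENIC_KINDS <- c("gene", "exon", "CDS", "five_prime_UTR", "three_prime_UTR")

# Conserved runs of alignment columns for one aligned pair.
# Returns data.frame(col_start, col_end) (1-based inclusive columns).
conserved_column_runs <- function(a_aln, b_aln, params) {
  x <- charToRaw(a_aln)
  y <- charToRaw(b_aln)
  acgt <- charToRaw("ACGT")
  mv <- (x == y) & (x %in% acgt)   # gaps and N count as mismatch
  if (length(mv) < params$window) return(data.frame(col_start = integer(),
                                                    col_end = integer()))
  win <- rolling_mean(mv, params$window)
  cov <- covered_positions(win >= params$min_identity, params$window)
  runs <- true_runs(cov)
  runs <- runs[runs$end - runs$start + 1L >= params$min_length, , drop = FALSE]
  data.frame(col_start = runs$start, col_end = runs$end)
}

# Coordinate maps between alignment columns and ungapped sequence positions.
# pos_of_col[i]: 1-based ungapped position at column i (last position at or
# before i); col_of_pos[p]: alignment column of ungapped position p.
aln_maps <- function(aln_str) {
  nongap <- strsplit(aln_str, "")[[1]] != "-"
  pos_of_col <- cumsum(nongap)
  col_of_pos <- which(nongap)
  list(pos_of_col = pos_of_col, col_of_pos = col_of_pos)
}

#' Detect conserved non-coding sequences shared by homologous regions
#'
#' Regions must share at least one anchor gene (a `gene` feature with the same
#' name in every region). For each stretch between consecutive shared anchors,
#' every region pair is globally aligned; runs of sliding-window identity >=
#' `min_identity` and length >= `min_length` are intersected across all pairs
#' and mapped back to each region's coordinates. CNS overlapping any genic
#' feature are discarded.
#'
#' @param regions List of >= 2 [genomic_region()]s with gene features.
#' @param params A [cns_params()].
#' @param anchors Optional character vector of anchor gene names (default:
#'   all gene names shared by every region, ordered along the first region).
#' @return data.frame with one row per CNS per region: `label`, `region`,
#'   `start`, `end` (0-based half-open), `identity` (pairwise summary per
#'   `identity_mode`) and `length` (mean span across regions).
#' @export
find_cns <- function(regions, params = cns_params(), anchors = NULL) {
  stopifnot(length(regions) >= 2)
  ids <- vapply(regions, `[[`, "", "id")
  names(regions) <- ids
  if (is.null(anchors)) {
    gene_names <- lapply(regions, function(r) {
      f <- r$features
      f$name[f$kind == "gene"]
    })
    anchors <- Reduce(intersect, gene_names)
    f1 <- regions[[1]]$features
    ord <- f1[f1$kind == "gene" & f1$name %in% anchors, , drop = FALSE]
    anchors <- ord$name[order(ord$start)]
  }
  if (length(anchors) == 0) {
    stopf(paste0("regions share no anchor genes; supply anchor names ",
                 "explicitly via `anchors`"))
  }
  gene_span <- function(region, name) {
    f <- region$features
    g <- f[f$kind == "gene" & f$name == name, , drop = FALSE]
    if (nrow(g) == 0) stopf("region '%s' lacks anchor gene '%s'",
                            region$id, name)
    c(g$start[1], g$end[1])
  }
  # stretches: between consecutive anchors (>= 2 anchors), or the full
  # intergenic space around a single anchor is not used -- CNS are searched
  # strictly between anchors.
  if (length(anchors) < 2) {
    stopf("need >= 2 shared anchor genes to delimit intergenic stretches")
  }
  records <- list()
  for (g in seq_len(length(anchors) - 1L)) {
    offs <- lapply(regions, function(r) {
      s <- gene_span(r, anchors[g])[2]
      e <- gene_span(r, anchors[g + 1])[1]
      if (e <= s) c(s, s) else c(s, e)
    })
    stretches <- lapply(ids, function(id) {
      region_subseq(regions[[id]], offs[[id]][1], offs[[id]][2])
    })
    names(stretches) <- ids
    if (any(nchar(stretches) < params$window)) next
    k <- length(ids)
    pairs <- utils::combn(k, 2)
    alns <- list()
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      alns[[paste(i, j)]] <- global_align(stretches[[i]], stretches[[j]])
    }
    # conserved intervals per pair, expressed in region-1 stretch positions
    ref_sets <- list()
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      aln <- alns[[paste(i, j)]]
      runs <- conserved_column_runs(aln$a_aln, aln$b_aln, params)
      if (nrow(runs) == 0) {
        ref_sets[[p]] <- IRanges::IRanges()
        next
      }
      mi <- aln_maps(aln$a_aln)
      # interval in sequence-i stretch coordinates (1-based inclusive)
      si <- pmax(1L, mi$pos_of_col[runs$col_start])
      ei <- mi$pos_of_col[runs$col_end]
      if (i == 1) {
        ref_sets[[p]] <- IRanges::IRanges(start = si, end = ei)
      } else {
        # map sequence-i positions to region-1 stretch positions through the
        # (1, i) alignment
        a1i <- alns[[paste(1, i)]]
        m1 <- aln_maps(a1i$a_aln)
        mi2 <- aln_maps(a1i$b_aln)
        map_pos <- function(p_i) {
          p_i <- pmin(p_i, length(mi2$col_of_pos))
          cols <- mi2$col_of_pos[p_i]
          pmax(1L, m1$pos_of_col[cols])
        }
        ref_sets[[p]] <- IRanges::IRanges(start = map_pos(si),
                                          end = map_pos(ei))
      }
    }
    final <- Reduce(IRanges::intersect, ref_sets)
    final <- final[IRanges::width(final) >= params$min_length]
    if (length(final) == 0) next
    # trim interval ends to columns that match in every alignment with the
    # reference region, so a CNS starts and ends on conserved sequence rather
    # than on window-edge overhang
    all_match <- rep(TRUE, nchar(stretches[[1]]))
    for (j in 2:k) {
      a1j <- alns[[paste(1, j)]]
      x <- charToRaw(a1j$a_aln)
      y <- charToRaw(a1j$b_aln)
      m <- (x == y) & (x %in% charToRaw("ACGT"))
      m1 <- aln_maps(a1j$a_aln)
      pos_match <- m[m1$col_of_pos]
      all_match <- all_match & pos_match
    }
    edge <- 10L  # edge mini-window for boundary refinement
    trim <- function(s, e) {
      repeat {
        moved <- FALSE
        while (s < e && !all_match[s]) { s <- s + 1L; moved <- TRUE }
        while (e > s && !all_match[e]) { e <- e - 1L; moved <- TRUE }
        if (e - s + 1L > edge &&
            mean(all_match[s:(s + edge - 1L)]) < params$min_identity) {
          s <- s + edge
          moved <- TRUE
        }
        if (e - s + 1L > edge &&
            mean(all_match[(e - edge + 1L):e]) < params$min_identity) {
          e <- e - edge
          moved <- TRUE
        }
        if (!moved || e - s + 1L <= edge) break
      }
      c(s, e)
    }
    tr <- t(mapply(trim, IRanges::start(final), IRanges::end(final)))
    final <- IRanges::IRanges(start = tr[, 1], end = tr[, 2])
    final <- final[IRanges::width(final) >= params$min_length]
    if (length(final) == 0) next
    for (ci in seq_along(final)) {
      s1 <- IRanges::start(final)[ci]
      e1 <- IRanges::end(final)[ci]
      # per-region coordinates through the (1, j) alignments
      coords <- matrix(NA_integer_, nrow = k, ncol = 2)
      coords[1, ] <- c(s1, e1)
      for (j in 2:k) {
        a1j <- alns[[paste(1, j)]]
        m1 <- aln_maps(a1j$a_aln)
        mj <- aln_maps(a1j$b_aln)
        cs <- m1$col_of_pos[s1]
        ce <- m1$col_of_pos[e1]
        coords[j, ] <- pmax(1L, c(mj$pos_of_col[cs], mj$pos_of_col[ce]))
      }
      # pairwise identities over the interval
      idns <- numeric(ncol(pairs))
      for (p in seq_len(ncol(pairs))) {
        i <- pairs[1, p]; j <- pairs[2, p]
        aln <- alns[[paste(i, j)]]
        mi <- aln_maps(aln$a_aln)
        pi_s <- if (i == 1) s1 else coords[i, 1]
        pi_e <- if (i == 1) e1 else coords[i, 2]
        cs <- mi$col_of_pos[min(pi_s, length(mi$col_of_pos))]
        ce <- mi$col_of_pos[min(pi_e, length(mi$col_of_pos))]
        x <- charToRaw(substr(aln$a_aln, cs, ce))
        y <- charToRaw(substr(aln$b_aln, cs, ce))
        idns[p] <- mean((x == y) & (x %in% charToRaw("ACGT")))
      }
      identity <- if (params$identity_mode == "min") min(idns) else mean(idns)
      # absolute region coordinates (0-based half-open)
      rows <- lapply(seq_len(k), function(j) {
        data.frame(region = ids[j],
                   start = offs[[ids[j]]][1] + coords[j, 1] - 1L,
                   end = offs[[ids[j]]][1] + coords[j, 2],
                   identity = identity)
      })
      rec <- do.call(rbind, rows)
      # genic masking: discard if any region's interval touches a genic
      # feature (with padding)
      pad <- params$genic_mask_padding
      masked <- any(vapply(seq_len(k), function(j) {
        f <- regions[[j]]$features
        gf <- f[f$kind %in% GENIC_KINDS, , drop = FALSE]
        any(gf$start - pad < rec$end[j] & gf$end + pad > rec$start[j])
      }, logical(1)))
      if (!masked) records[[length(records) + 1L]] <- rec
    }
  }
  if (length(records) == 0) {
    return(data.frame(label = character(), region = character(),
                      start = integer(), end = integer(),
                      identity = numeric(), length = numeric()))
  }
  # order by region-1 start, label CNS1..n
  ord <- order(vapply(records, function(r) r$start[1], numeric(1)))
  out <- do.call(rbind, lapply(seq_along(ord), function(i) {
    r <- records[[ord[i]]]
    r$label <- sprintf("CNS%d", i)
    r$length <- mean(r$end - r$start)
    r
  }))
  rownames(out) <- NULL
  out[, c("label", "region", "start", "end", "identity", "length")]
}

#' Write CNS records as BED files (one per region) plus a cross-reference TSV
#'
#' @param cns Output of [find_cns()].
#' @param dir Output directory.
#' @return Invisible character vector of written paths.
#' @export
write_cns <- function(cns, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (id in unique(cns$region)) {
    sub <- cns[cns$region == id, , drop = FALSE]
    feats <- feature_table(sub$start, sub$end, ".", "CNS", sub$label)
    p <- file.path(dir, sprintf("cns_%s.bed", id))
    write_features(feats, p, "bed", region_id = id)
    paths <- c(paths, p)
  }
  xref <- file.path(dir, "cns_crossref.tsv")
  utils::write.table(cns, xref, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, xref))
}
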