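# End-to-end orchestration: simulate (or load) homologous regions, detect
# conserved blocks and CNS, estimate substitution rates and Ka/Ks on shared
# genes, date LTR elements and calibrated divergences, and build an NJ tree.
# Configuration is a YAML file (or list) validated against a strict schema;
# every analysis threshold is surfaced there.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "syntevol_out",
    simulate = NULL,
    regions = NULL,
    params = list(
      blocks = list(word_size = 40L, min_identity = 0.6,
                    merge_distance = 200L, min_block_length = 200L),
      cns = list(window = 100L, min_identity = 0.8, min_length = 100L),
      dating = list(rate = "ltr",
                    cal_gene1_K = 1.6802, cal_gene2_K = 0.8707,
                    cal_T_years = 60e6),
      tree = list(bootstrap = 100L)))
}

merge_defaults <- function(user, defaults, path = "") {
  for (key in names(user)) {
    if (!key %in% names(defaults)) {
      stopf("unknown config key: %s%s", path, key)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      defaults[[key]] <- merge_defaults(user[[key]], defaults[[key]],
                                        paste0(path, key, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML path or a list. Unknown keys are rejected; defaults (block
#' word size 40 at 60% identity, CNS window 100 at 80% identity, LTR clock)
#' are filled in; referenced input files must exist; region ids must be
#' unique; thresholds are range-checked.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return Normalized list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  # `simulate` and `regions` have free-form sub-schemas; validate separately
  sim <- config$simulate
  regions <- config$regions
  config$simulate <- NULL
  config$regions <- NULL
  defaults$simulate <- NULL
  defaults$regions <- NULL
  cfg <- merge_defaults(config, defaults)
  cfg$simulate <- sim
  cfg$regions <- regions
  with(cfg$params$blocks, {
    if (min_identity <= 0 || min_identity > 1)
      stopf("blocks.min_identity must be in (0, 1], got %g", min_identity)
  })
  with(cfg$params$cns, {
    if (min_identity <= 0 || min_identity > 1)
      stopf("cns.min_identity must be in (0, 1], got %g", min_identity)
  })
  if (is.null(cfg$simulate) && is.null(cfg$regions)) {
    stopf("config must provide either `simulate` or `regions`")
  }
  if (!is.null(cfg$regions)) {
    ids <- vapply(cfg$regions, function(r) r$id %||% "", "")
    if (any(ids == "")) stopf("every region entry needs an `id`")
    if (anyDuplicated(ids)) {
      stopf("duplicate region id: %s", ids[duplicated(ids)][1])
    }
    for (r in cfg$regions) {
      if (is.null(r$fasta) || !file.exists(r$fasta)) {
        stopf("region '%s': FASTA not found: %s", r$id,
              r$fasta %||% "<missing>")
      }
      if (!is.null(r$features) && !file.exists(r$features)) {
        stopf("region '%s': feature file not found: %s", r$id, r$features)
      }
    }
  }
  if (!is.null(cfg$simulate)) {
    allowed <- c(names(formals(sim_config)), "n_cns", "cns_identity",
                 "cns_length", "spacer_length", "with_te")
    bad <- setdiff(names(cfg$simulate), allowed)
    if (length(bad) > 0) stopf("unknown simulate key(s): %s",
                               paste(bad, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

pipeline_regions <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim_keys <- intersect(names(cfg$simulate), names(formals(sim_config)))
    sc_args <- cfg$simulate[sim_keys]
    sc_args$seed <- cfg$seed
    sc <- do.call(sim_config, sc_args)
    trio <- simulate_trio_with_cns(
      sc,
      n_cns = cfg$simulate$n_cns %||% 3,
      cns_identity = cfg$simulate$cns_identity %||% 0.85,
      cns_length = cfg$simulate$cns_length %||% 600L,
      spacer_length = cfg$simulate$spacer_length %||% 400L,
      with_te = cfg$simulate$with_te %||% TRUE)
    return(trio$regions)
  }
  regions <- list()
  for (r in cfg$regions) {
    reg <- read_fasta(r$fasta)[[1]]
    reg$id <- r$id
    if (!is.null(r$features)) {
      dialect <- if (grepl("\\.bed$", r$features)) "bed" else "gff3"
      feats <- read_features(r$features, dialect,
                             stats::setNames(reg$length, r$id))
      reg <- genomic_region(r$id, reg$residues, feats[[r$id]])
    }
    regions[[r$id]] <- reg
  }
  regions
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparative pipeline
#'
#' Stages: obtain regions (simulated trio or user inputs) -> pairwise
#' conserved blocks with CSR/CFS (`table2_conservation.tsv`) -> shared-gene
#' Ka/Ks and intron rates (`table3_rates.tsv`) -> calibrated two-gene
#' divergence times (`table4_clock.tsv`) -> LTR element insertion ages
#' (`table5_ltr_ages.tsv`) -> CNS BED per region + cross-reference ->
#' bootstrapped NJ tree (`tree.nwk`) -> run manifest with parameter and
#' output checksums (`manifest.json`). Deterministic given the seed.
#'
#' @param config A [validate_config()] result, YAML path, or config list.
#' @return Invisible list with `out_dir`, the written `paths`, and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  regions <- stage("regions", pipeline_regions(cfg))
  if (length(regions) < 2) stopf("pipeline needs >= 2 regions")
  ids <- names(regions)
  paths <- character()

  # --- conserved blocks / CSR / CFS ---------------------------------------
  bp <- do.call(block_params, cfg$params$blocks)
  pair_idx <- utils::combn(length(regions), 2)
  t2 <- list()
  blocks_by_pair <- list()
  t2 <- stage("blocks", {
    lapply(seq_len(ncol(pair_idx)), function(p) {
      i <- pair_idx[1, p]; j <- pair_idx[2, p]
      blocks <- find_conserved_blocks(regions[[i]], regions[[j]], bp)
      blocks_by_pair[[paste(ids[i], ids[j], sep = " : ")]] <<- blocks
      st <- conservation_stats(blocks)
      data.frame(pair = paste(ids[i], ids[j], sep = " : "),
                 overlap_bp = st$overlap_length,
                 conserved_bp = round(st$conserved_total),
                 n_blocks = st$n_blocks,
                 csr_pct = st$csr, cfs_bp = st$cfs)
    })
  })
  paths["table2"] <- write_tsv(do.call(rbind, t2),
                               file.path(out, "table2_conservation.tsv"))

  # --- shared-gene rates (Ks, Ka, omega, intron K) ------------------------
  shared_genes <- Reduce(intersect, lapply(regions, function(r) {
    r$features$name[r$features$kind == "gene"]
  }))
  t3 <- stage("rates", {
    rows <- list()
    for (g in shared_genes) {
      for (p in seq_len(ncol(pair_idx))) {
        i <- pair_idx[1, p]; j <- pair_idx[2, p]
        cds_i <- feature_sequence(regions[[i]], g, "CDS")
        cds_j <- feature_sequence(regions[[j]], g, "CDS")
        ca <- build_codon_alignment(cds_i, cds_j)
        kk <- ng86_kaks(ca)
        int_i <- intron_sequence(regions[[i]], g)
        int_j <- intron_sequence(regions[[j]], g)
        intron_K <- if (nzchar(int_i) && nzchar(int_j)) {
          k2p_distance(global_align(int_i, int_j))$K
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          pair = paste(ids[i], ids[j], sep = " : "), gene = g,
          cds_len = 3L * ca$n_codons,
          Ks = kk$Ks, Ka = kk$Ka, omega = kk$omega,
          intron_K = intron_K,
          Ks_display = round(kk$Ks, 4), Ka_display = round(kk$Ka, 4))
      }
    }
    do.call(rbind, rows)
  })
  paths["table3"] <- write_tsv(t3, file.path(out, "table3_rates.tsv"))

  # --- calibrated divergence times ----------------------------------------
  dcfg <- cfg$params$dating
  cal1 <- calibrate(dcfg$cal_gene1_K, dcfg$cal_T_years)
  cal2 <- calibrate(dcfg$cal_gene2_K, dcfg$cal_T_years)
  t4 <- stage("clock", {
    g1 <- shared_genes[1]
    g2 <- if (length(shared_genes) > 1) shared_genes[2] else shared_genes[1]
    rows <- lapply(unique(t3$pair), function(pr) {
      r1 <- t3[t3$pair == pr & t3$gene == g1, ]
      r2 <- t3[t3$pair == pr & t3$gene == g2, ]
      locus_dating_row(pr, r1$Ks[1], r1$intron_K[1], r2$Ks[1], cal1, cal2)
    })
    do.call(rbind, rows)
  })
  paths["table4"] <- write_tsv(t4, file.path(out, "table4_clock.tsv"))

  # --- LTR element ages ----------------------------------------------------
  rate <- clock_rate(dcfg$rate)
  t5 <- stage("ltr_ages", {
    rows <- list()
    for (id in ids) {
      f <- regions[[id]]$features
      tes <- f[f$kind == "TE", , drop = FALSE]
      for (t in seq_len(nrow(tes))) {
        nm <- tes$name[t]
        l5 <- f[f$kind == "LTR5" & f$name == nm, , drop = FALSE]
        l3 <- f[f$kind == "LTR3" & f$name == nm, , drop = FALSE]
        if (nrow(l5) != 1 || nrow(l3) != 1) next
        age <- ltr_insertion_age(
          region_subseq(regions[[id]], l5$start, l5$end),
          region_subseq(regions[[id]], l3$start, l3$end), rate)
        rows[[length(rows) + 1L]] <- data.frame(
          region = id, element = nm, K = age$K,
          age_mya = age$T_mya, age_display = round(age$T_mya, 2))
      }
    }
    if (length(rows) == 0) {
      data.frame(region = character(), element = character(), K = numeric(),
                 age_mya = numeric(), age_display = numeric())
    } else do.call(rbind, rows)
  })
  paths["table5"] <- write_tsv(t5, file.path(out, "table5_ltr_ages.tsv"))

  # --- CNS ------------------------------------------------------------------
  cns <- stage("cns", {
    if (length(regions) >= 2 && length(shared_genes) >= 2) {
      find_cns(regions, do.call(cns_params, cfg$params$cns))
    } else {
      data.frame(label = character(), region = character(),
                 start = integer(), end = integer(), identity = numeric(),
                 length = numeric())
    }
  })
  cns_paths <- write_cns(cns, out)
  paths <- c(paths, stats::setNames(cns_paths, basename(cns_paths)))

  # --- NJ tree --------------------------------------------------------------
  tree <- NULL
  if (length(regions) >= 3 && length(shared_genes) >= 1) {
    tree <- stage("tree", {
      cds <- vapply(ids, function(id) {
        feature_sequence(regions[[id]], shared_genes[1], "CDS")
      }, "")
      if (length(unique(nchar(cds))) == 1) {
        bootstrap_support(cds, n_reps = cfg$params$tree$bootstrap,
                          seed = cfg$seed + 1L)
      } else {
        nj_tree(k2p_dist_matrix_unaligned(cds))
      }
    })
    ape::write.tree(tree, file.path(out, "tree.nwk"))
    paths["tree"] <- file.path(out, "tree.nwk")
  }

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    package = "syntevol",
    version = as.character(utils::packageVersion("syntevol")),
    seed = cfg$seed,
    params = cfg$params,
    regions = stats::setNames(
      lapply(regions, function(r) list(length = r$length,
                                       n_features = nrow(r$features))), ids),
    checksums = as.list(tools::md5sum(sort(unname(paths)))))
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths["manifest"] <- manifest_path
  invisible(list(out_dir = out, paths = paths, regions = regions,
                 blocks = blocks_by_pair, conservation = do.call(rbind, t2),
                 rates = t3, clock = t4, ltr_ages = t5, cns = cns,
                 tree = tree))
}

# intron sequence of a gene: gene interval minus its exons, concatenated
intron_sequence <- function(region, gene_name) {
  f <- region$features
  g <- f[f$kind == "gene" & f$name == gene_name, , drop = FALSE]
  ex <- f[f$kind == "exon" & f$name == gene_name, , drop = FALSE]
  if (nrow(g) == 0 || nrow(ex) == 0) return("")
  ex <- ex[order(ex$start), , drop = FALSE]
  pieces <- character()
  pos <- g$start[1]
  for (i in seq_len(nrow(ex))) {
    if (ex$start[i] > pos) {
      pieces <- c(pieces, region_subseq(region, pos, ex$start[i]))
    }
    pos <- max(pos, ex$end[i])
  }
  if (g$end[1] > pos) pieces <- c(pieces, region_subseq(region, pos, g$end[1]))
  paste(pieces, collapse = "")
}

# K2P matrix from unaligned sequences via pairwise global alignment
k2p_dist_matrix_unaligned <- function(seqs) {
  n <- length(seqs)
  dm <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dm[i, j] <- dm[j, i] <- k2p_distance(global_align(seqs[[i]],
                                                        seqs[[j]]))$K
    }
  }
  dm
}
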