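# Synthetic homologous regions with known ground truth.
#
# The generator emulates a pair (or trio) of genomic regions descended from a
# common ancestor: substitutions follow a Kimura two-parameter (K2P) process
# split equally between lineages, indels are Poisson events with geometric
# lengths, transposable-element insertions are lineage-specific annotated
# intervals (LTR retroelements whose twin LTRs start identical and diverge at
# 2*r*age), and embedded multi-exon genes evolve under purifying selection
# (nonsynonymous changes accepted with probability omega).

#' Simulation configuration
#'
#' Defaults describe a wheat-like homologous-region scenario: a 50-kb
#' ancestral region, pairwise divergence K = 0.05 substitutions/site (between
#' the observed diploid--tetraploid and inter-subgenome divergences),
#' transition/transversion ratio kappa = 2, sparse indels, two
#' lineage-specific LTR retroelement insertions per lineage with 1.5-kb LTRs
#' inserted 1 million years ago under an LTR clock of 1.3e-8
#' substitutions/site/year, and two embedded two-exon genes evolving at
#' omega = 0.05.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param ancestor_length Ancestral region length in bp.
#' @param target_K Total pairwise divergence (substitutions/site) between the
#'   two lineages.
#' @param ts_tv_ratio kappa, the transition/transversion rate ratio of the
#'   K2P process (alpha/beta).
#' @param indel_rate Indel events per ancestral site per lineage.
#' @param indel_length_geometric_p Geometric length parameter; mean indel
#'   length is `1/p`.
#' @param te_insertions_per_lineage Number of lineage-specific LTR
#'   retroelement insertions per lineage.
#' @param ltr_length LTR length (bp) of simulated retroelements.
#' @param te_body_length Internal (between-LTR) length of simulated elements.
#' @param ltr_age_years Age of simulated insertions in years.
#' @param clock_rate_r Substitution rate (per site per year) applied to LTRs.
#' @param gene_models List of gene models, each `list(exons = c(...),
#'   introns = c(...))` with exon lengths summing to a multiple of 3.
#' @param omega_target Ka/Ks imposed on embedded coding sequence, in (0, 1].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       ancestor_length = 50000L,
                       target_K = 0.05,
                       ts_tv_ratio = 2,
                       indel_rate = 2e-5,
                       indel_length_geometric_p = 0.1,
                       te_insertions_per_lineage = 2L,
                       ltr_length = 1500L,
                       te_body_length = 3000L,
                       ltr_age_years = 1e6,
                       clock_rate_r = 1.3e-8,
                       gene_models = list(
                         list(exons = c(300L, 450L), introns = 400L),
                         list(exons = c(450L, 300L), introns = 600L)),
                       omega_target = 0.05) {
  stopifnot(is_count(seed), is_count(ancestor_length), ancestor_length > 0,
            target_K >= 0, ts_tv_ratio > 0,
            indel_rate >= 0, indel_length_geometric_p > 0,
            indel_length_geometric_p <= 1,
            is_count(te_insertions_per_lineage),
            omega_target > 0, omega_target <= 1)
  if (target_K > 3) {
    stopf("target_K = %g is saturated (expected identity approaches 25%%)",
          target_K)
  }
  for (gm in gene_models) {
    if (sum(gm$exons) %% 3 != 0) stopf("gene model exon lengths must sum to a multiple of 3")
    if (length(gm$introns) != length(gm$exons) - 1)
      stopf("gene model needs one intron fewer than exons")
  }
  structure(as.list(environment()), class = "sim_config")
}

# K2P per-site substitution probabilities after branch length d (expected
# substitutions/site) with kappa = alpha/beta. Returns c(same, ts, tv_each).
k2p_site_probs <- function(d, kappa) {
  e1 <- exp(-4 * d / (kappa + 2))
  e2 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
  same <- 0.25 + 0.25 * e1 + 0.5 * e2
  ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  tv_each <- (1 - same - ts) / 2
  c(same = same, ts = ts, tv_each = tv_each)
}

# Evolve an integer-encoded sequence along one branch of length d under K2P.
# Vectorized per-site sampling from the exact marginal distribution.
evolve_k2p_int <- function(x, d, kappa) {
  if (d <= 0 || length(x) == 0) return(x)
  p <- k2p_site_probs(d, kappa)
  u <- stats::runif(length(x))
  ts <- u >= p["same"] & u < p["same"] + p["ts"]
  tv1 <- u >= p["same"] + p["ts"] & u < p["same"] + p["ts"] + p["tv_each"]
  tv2 <- u >= p["same"] + p["ts"] + p["tv_each"]
  out <- x
  out[ts] <- TS_PARTNER[x[ts]]
  out[tv1] <- TV_OPTIONS[x[tv1], 1]
  out[tv2] <- TV_OPTIONS[x[tv2], 2]
  out
}

# --- genetic code tables (standard code) -----------------------------------

codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- stats::setNames(as.character(gc), names(gc))
    }
    tab
  }
})

translate_codon <- function(codon) codon_table()[[codon]]
is_stop_codon <- function(codon) codon_table()[[codon]] == "*"

# Evolve a coding sequence (string, length %% 3 == 0) along branch length d
# with purifying selection: substitution proposals arrive at rate d per site;
# synonymous proposals are always accepted, nonsynonymous with probability
# omega, proposals creating stop codons never. `proposal` picks the proposal
# kernel: "k2p" (kappa-weighted) or "jc" (uniform over the 3 alternatives).
evolve_cds <- function(cds, d, kappa, omega, proposal = c("k2p", "jc")) {
  proposal <- match.arg(proposal)
  x <- seq_to_int(cds)
  L <- length(x)
  if (d <= 0 || L == 0) return(cds)
  n_events <- stats::rpois(1, L * d)
  if (n_events == 0) return(int_to_seq(x))
  gc <- codon_table()
  pos <- sample.int(L, n_events, replace = TRUE)
  u_kind <- stats::runif(n_events)
  u_acc <- stats::runif(n_events)
  p_ts <- if (proposal == "k2p") kappa / (kappa + 2) else 1 / 3
  for (e in seq_len(n_events)) {
    i <- pos[e]
    old <- x[i]
    new <- if (u_kind[e] < p_ts) {
      TS_PARTNER[old]
    } else if (u_kind[e] < p_ts + (1 - p_ts) / 2) {
      TV_OPTIONS[old, 1]
    } else {
      TV_OPTIONS[old, 2]
    }
    ci <- (i - 1L) %/% 3L
    cod <- x[(ci * 3L + 1L):(ci * 3L + 3L)]
    new_cod <- cod
    new_cod[(i - 1L) %% 3L + 1L] <- new
    aa_old <- gc[[int_to_seq(cod)]]
    aa_new <- gc[[int_to_seq(new_cod)]]
    if (aa_new == "*") next
    if (aa_old != aa_new && u_acc[e] > omega) next
    x[i] <- new
  }
  int_to_seq(x)
}

# Random coding sequence of n_codons sense codons starting ATG, no stops.
random_cds_int <- function(n_codons) {
  gc <- codon_table()
  sense <- names(gc)[gc != "*"]
  codons <- c("ATG", sample(sense, n_codons - 1L, replace = TRUE))
  unlist(lapply(codons, seq_to_int), use.names = FALSE)
}

#' Simulate an LTR retrotransposon of known age
#'
#' The element's two LTRs are identical at insertion time and each then
#' accumulates substitutions for `age_years` at rate `r`, so their expected
#' pairwise divergence is `2 * r * age_years`.
#'
#' @param ltr_length LTR length in bp.
#' @param age_years Insertion age in years (>= 0).
#' @param r Substitution rate per site per year.
#' @param seed Integer seed.
#' @param body_length Internal sequence length between the LTRs.
#' @param kappa Transition/transversion ratio of the substitution process.
#' @return A list with `sequence` (full element), `features` (TE/LTR5/LTR3
#'   intervals relative to the element, 0-based half-open), `ltr5`, `ltr3`
#'   (the two LTR sequences) and `true_divergence` (= 2*r*age).
#' @export
simulate_ltr_element <- function(ltr_length = 1500L, age_years = 1e6,
                                 r = 1.3e-8, seed = 1L, body_length = 3000L,
                                 kappa = 2) {
  stopifnot(age_years >= 0, r >= 0, ltr_length >= 1)
  withr::with_seed(seed, {
    sim_ltr_element_impl(ltr_length, age_years, r, body_length, kappa)
  })
}

# RNG-stream version used inside larger simulations (no seed handling).
sim_ltr_element_impl <- function(ltr_length, age_years, r, body_length, kappa) {
  anc <- random_dna_int(ltr_length)
  d <- r * age_years
  ltr5 <- evolve_k2p_int(anc, d, kappa)
  ltr3 <- evolve_k2p_int(anc, d, kappa)
  body <- random_dna_int(body_length)
  total <- 2L * ltr_length + body_length
  feats <- feature_table(
    start = c(0L, 0L, ltr_length + body_length),
    end = c(total, ltr_length, total),
    strand = rep("+", 3),
    kind = c("TE", "LTR5", "LTR3"),
    name = rep("LTR_element", 3))
  list(sequence = int_to_seq(c(ltr5, body, ltr3)),
       features = feats,
       ltr5 = int_to_seq(ltr5), ltr3 = int_to_seq(ltr3),
       true_divergence = 2 * r * age_years)
}

#' Simulate a codon alignment pair with target Ks and omega
#'
#' Substitution proposals arrive uniformly over sites (Jukes--Cantor kernel)
#' at intensity `Ks_target` per site split between the two lineages;
#' synonymous proposals are always accepted, nonsynonymous ones with
#' probability `omega_target`, and proposals creating internal stop codons are
#' rejected. In expectation the Nei--Gojobori estimator recovers
#' `Ks = Ks_target` and `omega = omega_target`.
#'
#' @param n_codons Number of codons (>= 50).
#' @param Ks_target Target synonymous divergence (substitutions per
#'   synonymous site).
#' @param omega_target Target Ka/Ks in (0, 1].
#' @param seed Integer seed.
#' @return List with `cds_a`, `cds_b`: gap-free coding sequences of equal
#'   length `3 * n_codons`, no internal stops.
#' @export
simulate_cds_pair <- function(n_codons, Ks_target, omega_target, seed = 1L) {
  stopifnot(n_codons >= 50, Ks_target >= 0, omega_target > 0,
            omega_target <= 1)
  withr::with_seed(seed, {
    anc <- int_to_seq(random_cds_int(n_codons))
    a <- evolve_cds(anc, Ks_target / 2, kappa = 1, omega = omega_target,
                    proposal = "jc")
    b <- evolve_cds(anc, Ks_target / 2, kappa = 1, omega = omega_target,
                    proposal = "jc")
    list(cds_a = a, cds_b = b)
  })
}

# Sample interval start positions of given widths uniformly, avoiding a set of
# blocked intervals (data.frame start/end, 0-based half-open) on [0, L).
sample_positions_avoiding <- function(n, widths, L, blocked, max_tries = 1000) {
  out <- integer(0)
  taken <- blocked
  for (i in seq_len(n)) {
    w <- widths[i]
    for (t in seq_len(max_tries)) {
      p <- sample.int(max(1L, L - w), 1L) - 1L
      clash <- nrow(taken) > 0 &&
        any(p < taken$end & (p + w) > taken$start)
      if (!clash) break
      if (t == max_tries) stopf("could not place interval of width %d", w)
    }
    out <- c(out, p)
    taken <- rbind(taken, data.frame(start = p, end = p + w))
  }
  out
}

# Build gene features + sequence for a gene model at ancestral offset `at`.
# Returns list(seq_int, features) where features are ancestral coordinates.
build_gene <- function(gm, at, name) {
  n_codons <- sum(gm$exons) / 3L
  cds <- random_cds_int(n_codons)
  pieces <- list()
  feats <- feature_table()
  pos <- at
  cds_off <- 0L
  for (i in seq_along(gm$exons)) {
    ex_len <- gm$exons[i]
    pieces[[length(pieces) + 1L]] <- cds[(cds_off + 1L):(cds_off + ex_len)]
    feats <- rbind(feats,
                   feature_table(pos, pos + ex_len, "+", "exon", name),
                   feature_table(pos, pos + ex_len, "+", "CDS", name))
    pos <- pos + ex_len
    cds_off <- cds_off + ex_len
    if (i < length(gm$exons)) {
      in_len <- gm$introns[i]
      pieces[[length(pieces) + 1L]] <- random_dna_int(in_len)
      pos <- pos + in_len
    }
  }
  feats <- rbind(feature_table(at, pos, "+", "gene", name), feats)
  list(seq_int = unlist(pieces, use.names = FALSE), features = feats,
       length = pos - at)
}

# Map ancestral coordinates to lineage coordinates given a keep mask and a
# table of insertions (insertion with `after = p` is spliced between ancestral
# prefix [0, p) and position p). Returns two maps over 0-based ancestral
# boundaries 0..L: `left(p)` excludes an insertion sitting exactly at p (the
# coordinate where that insertion itself starts), `right(p)` includes it (the
# coordinate of ancestral base p in the lineage).
make_coord_map <- function(keep, insertions) {
  L <- length(keep)
  kept_before <- c(0L, cumsum(keep))           # kept ancestral bases before pos
  ins_lt <- integer(L + 2L)                    # widths with after <  p, at p+1
  if (nrow(insertions) > 0) {
    agg <- tapply(insertions$width, insertions$after, sum)
    at <- as.integer(names(agg))
    for (i in seq_along(at)) {
      idx <- (at[i] + 2L):(L + 2L)             # boundaries p > after
      ins_lt[idx] <- ins_lt[idx] + agg[i]
    }
  }
  ins_le <- c(ins_lt[-1L], ins_lt[L + 2L])     # widths with after <= p
  list(left = function(pos0) kept_before[pos0 + 1L] + ins_lt[pos0 + 1L],
       right = function(pos0) kept_before[pos0 + 1L] + ins_le[pos0 + 1L])
}

# Evolve one lineage from an integer ancestor. Returns region pieces:
# sequence, features (mapped), coord map, TE truth, keep mask.
evolve_lineage <- function(anc, anc_features, cfg, lineage_id) {
  L <- length(anc)
  kappa <- cfg$ts_tv_ratio
  d <- cfg$target_K / 2
  # substitutions: neutral everywhere except CDS (purifying selection)
  cds_feats <- anc_features[anc_features$kind == "CDS", , drop = FALSE]
  in_cds <- logical(L)
  for (i in seq_len(nrow(cds_feats))) {
    in_cds[(cds_feats$start[i] + 1L):cds_feats$end[i]] <- TRUE
  }
  mut <- anc
  mut[!in_cds] <- evolve_k2p_int(anc[!in_cds], d, kappa)
  if (any(in_cds)) {
    cds_feats <- cds_feats[order(cds_feats$start), , drop = FALSE]
    for (nm in unique(cds_feats$name)) {
      f <- cds_feats[cds_feats$name == nm, , drop = FALSE]
      idx <- unlist(lapply(seq_len(nrow(f)), function(i)
        (f$start[i] + 1L):f$end[i]), use.names = FALSE)
      new_cds <- evolve_cds(int_to_seq(anc[idx]), d, kappa, cfg$omega_target)
      mut[idx] <- seq_to_int(new_cds)
    }
  }
  # protected intervals: no indels/TEs inside annotated ancestral features
  protected <- anc_features[, c("start", "end")]
  # deletions
  keep <- rep(TRUE, L)
  n_indel <- stats::rpois(1, cfg$indel_rate * L)
  ins_tab <- data.frame(after = integer(), width = integer())
  ins_seq <- list()
  if (n_indel > 0) {
    lens <- stats::rgeom(n_indel, cfg$indel_length_geometric_p) + 1L
    is_del <- stats::runif(n_indel) < 0.5
    for (e in seq_len(n_indel)) {
      w <- lens[e]
      if (is_del[e]) {
        p <- sample_positions_avoiding(1L, w, L, protected)
        keep[(p + 1L):(p + w)] <- FALSE
        protected <- rbind(protected, data.frame(start = p, end = p + w))
      } else {
        p <- sample_positions_avoiding(1L, 1L, L, protected)
        ins_tab <- rbind(ins_tab, data.frame(after = p, width = w))
        ins_seq[[nrow(ins_tab)]] <- random_dna_int(w)
        protected <- rbind(protected, data.frame(start = p, end = p + 1L))
      }
    }
  }
  # TE insertions (LTR retroelements)
  te_truth <- list()
  te_elements <- list()
  n_te <- cfg$te_insertions_per_lineage
  if (n_te > 0) {
    for (t in seq_len(n_te)) {
      el <- sim_ltr_element_impl(cfg$ltr_length, cfg$ltr_age_years,
                                 cfg$clock_rate_r, cfg$te_body_length, kappa)
      w <- nchar(el$sequence)
      p <- sample_positions_avoiding(1L, 1L, L, protected)
      ins_tab <- rbind(ins_tab, data.frame(after = p, width = w))
      ins_seq[[nrow(ins_tab)]] <- seq_to_int(el$sequence)
      te_elements[[t]] <- list(after = p, element = el,
                               name = sprintf("%s_TE%d", lineage_id, t))
      protected <- rbind(protected, data.frame(start = p, end = p + 1L))
    }
  }
  cmap <- make_coord_map(keep, ins_tab)
  # assemble sequence: kept mutated bases with insertions spliced in
  ord <- order(ins_tab$after)
  pieces <- list()
  prev <- 0L
  for (i in ord) {
    p <- ins_tab$after[i]
    if (p > prev) pieces[[length(pieces) + 1L]] <- mut[(prev + 1L):p][keep[(prev + 1L):p]]
    pieces[[length(pieces) + 1L]] <- ins_seq[[i]]
    prev <- p
  }
  if (prev < L) pieces[[length(pieces) + 1L]] <- mut[(prev + 1L):L][keep[(prev + 1L):L]]
  out_seq <- unlist(pieces, use.names = FALSE)
  # map ancestral features (protected from indels, so fully kept)
  feats <- anc_features
  if (nrow(feats) > 0) {
    feats$start <- vapply(feats$start, cmap$right, integer(1))
    feats$end <- vapply(feats$end, cmap$left, integer(1))
  }
  # TE features at lineage coordinates
  te_rows <- feature_table()
  for (t in seq_along(te_elements)) {
    te <- te_elements[[t]]
    # insertion boundaries are unique (each is protected once used), so the
    # element's lineage start is exactly the mapped ancestral boundary
    base <- cmap$left(te$after)
    f <- te$element$features
    f$start <- f$start + base
    f$end <- f$end + base
    f$name <- te$name
    te_rows <- rbind(te_rows, f)
    te_truth[[t]] <- list(name = te$name, start = base,
                          end = base + nchar(te$element$sequence),
                          true_divergence = te$element$true_divergence,
                          age_years = cfg$ltr_age_years)
  }
  feats <- rbind(feats, te_rows)
  feats <- feats[order(feats$start, feats$end), , drop = FALSE]
  rownames(feats) <- NULL
  list(seq_int = out_seq, features = feats, cmap = cmap, keep = keep,
       te_truth = te_truth, ins_after = ins_tab$after)
}

#' Simulate a pair of homologous regions with known truth
#'
#' Two regions descend from one random ancestor. Substitutions follow the K2P
#' process at total divergence `target_K` split equally between lineages
#' (purifying selection with `omega_target` inside embedded CDS); indels and
#' LTR retroelement insertions are lineage-specific. The returned truth
#' records everything a downstream estimator should recover.
#'
#' @param config A [sim_config()].
#' @return List with `a`, `b` ([genomic_region()]s) and `truth`: a list with
#'   `true_K`, `conserved` (data.frame of ancestral segments surviving in both
#'   lineages, with coordinates in each), `te` (per-lineage insertion truth)
#'   and `genes` (embedded gene names).
#' @export
simulate_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    L <- config$ancestor_length
    anc <- random_dna_int(L)
    anc_features <- feature_table()
    # place gene models evenly through the ancestor
    n_genes <- length(config$gene_models)
    if (n_genes > 0) {
      slots <- floor(L * (seq_len(n_genes)) / (n_genes + 1))
      for (g in seq_len(n_genes)) {
        gm <- config$gene_models[[g]]
        gene <- build_gene(gm, slots[g], sprintf("gene%d", g))
        anc[(slots[g] + 1L):(slots[g] + gene$length)] <- gene$seq_int
        anc_features <- rbind(anc_features, gene$features)
        # promoter motifs upstream of each gene (TATA box + G-box)
        if (slots[g] >= 60) {
          pstart <- slots[g] - 50L
          anc[(pstart + 1L):(pstart + 6L)] <- seq_to_int("TATAAA")
          anc[(pstart + 21L):(pstart + 26L)] <- seq_to_int("CACGTG")
          anc_features <- rbind(anc_features,
            feature_table(c(pstart, pstart + 20L), c(pstart + 6L, pstart + 26L),
                          "+", "other", c("TATA-box", "G-box")))
        }
      }
    }
    # one embedded SSR in intergenic space
    ssr <- strrep("CT", 23)
    sp <- sample_positions_avoiding(1L, nchar(ssr), L,
                                    anc_features[, c("start", "end")])
    anc[(sp + 1L):(sp + nchar(ssr))] <- seq_to_int(ssr)
    anc_features <- rbind(anc_features,
                          feature_table(sp, sp + nchar(ssr), "+", "SSR",
                                        "(CT)23"))
    anc_features <- anc_features[order(anc_features$start), , drop = FALSE]

    lin_a <- evolve_lineage(anc, anc_features, config, "a")
    lin_b <- evolve_lineage(anc, anc_features, config, "b")

    both <- lin_a$keep & lin_b$keep
    runs <- true_runs(both)
    # split runs at insertion boundaries of either lineage so each truth
    # interval is contiguous ancestral material in both output regions
    bnd <- sort(unique(c(lin_a$ins_after, lin_b$ins_after)))
    if (length(bnd) > 0 && nrow(runs) > 0) {
      pieces <- list()
      for (i in seq_len(nrow(runs))) {
        cuts <- bnd[bnd > runs$start[i] - 1L & bnd < runs$end[i]]
        edges <- c(runs$start[i] - 1L, cuts, runs$end[i])  # 0-based half-open
        pieces[[i]] <- data.frame(start = edges[-length(edges)] + 1L,
                                  end = edges[-1])
      }
      runs <- do.call(rbind, pieces)
    }
    conserved <- if (nrow(runs) == 0) {
      data.frame(anc_start = integer(), anc_end = integer(),
                 a_start = integer(), a_end = integer(),
                 b_start = integer(), b_end = integer())
    } else {
      data.frame(
        anc_start = runs$start - 1L, anc_end = runs$end,
        a_start = vapply(runs$start - 1L, lin_a$cmap$right, integer(1)),
        a_end = vapply(runs$end, lin_a$cmap$left, integer(1)),
        b_start = vapply(runs$start - 1L, lin_b$cmap$right, integer(1)),
        b_end = vapply(runs$end, lin_b$cmap$left, integer(1)))
    }
    a <- genomic_region("lineage_a", int_to_seq(lin_a$seq_int),
                        lin_a$features)
    b <- genomic_region("lineage_b", int_to_seq(lin_b$seq_int),
                        lin_b$features)
    list(a = a, b = b,
         truth = list(true_K = config$target_K,
                      conserved = conserved,
                      te = list(a = lin_a$te_truth, b = lin_b$te_truth),
                      ltr_divergence = 2 * config$clock_rate_r *
                        config$ltr_age_years,
                      genes = sprintf("gene%d", seq_along(config$gene_models))))
  })
}

#' Simulate a trio of homologous regions sharing conserved non-coding segments
#'
#' Three regions share two anchor genes (evolved from common ancestors at
#' `config$target_K` with purifying selection) separated by intergenic space.
#' `n_cns` ancestral segments are shared by all three regions: regions 2 and 3
#' carry the ancestral state while region 1's copy is mutated at a fraction
#' `1 - cns_identity` of its sites, so the minimum pairwise identity across
#' the trio equals `cns_identity`. All remaining intergenic sequence is
#' independent random sequence (diverged beyond any detection threshold).
#' Optionally each region also receives one lineage-specific LTR retroelement.
#'
#' @param config A [sim_config()]; uses `seed`, `target_K`, `ts_tv_ratio`,
#'   `omega_target`, `gene_models` (first two models), and the TE fields when
#'   `with_te = TRUE`.
#' @param n_cns Number of tri-shared conserved non-coding segments.
#' @param cns_identity Identity of the shared segments, >= 0.80 (or exactly
#'   1 for identical copies).
#' @param cns_length Length of each shared segment (bp).
#' @param spacer_length Length of the divergent spacer between elements (bp).
#' @param with_te If `TRUE`, insert one dated LTR retroelement per region into
#'   the intergenic space.
#' @return List with `regions` (list of 3 [genomic_region()]s) and `truth`
#'   (data.frame: one row per CNS per region with coordinates and identity).
#' @export
simulate_trio_with_cns <- function(config = sim_config(), n_cns = 3,
                                   cns_identity = 0.85, cns_length = 600L,
                                   spacer_length = 400L, with_te = FALSE) {
  stopifnot(inherits(config, "sim_config"),
            is_count(n_cns), cns_identity >= 0.80, cns_identity <= 1)
  withr::with_seed(config$seed, {
    kappa <- config$ts_tv_ratio
    d <- config$target_K / 2
    gm1 <- config$gene_models[[1]]
    gm2 <- config$gene_models[[2]] %||% config$gene_models[[1]]
    g1 <- build_gene(gm1, 0L, "anchor1")
    g2 <- build_gene(gm2, 0L, "anchor2")
    cns_anc <- lapply(seq_len(n_cns), function(i) random_dna_int(cns_length))
    te_el <- if (with_te) {
      lapply(1:3, function(i)
        sim_ltr_element_impl(config$ltr_length, config$ltr_age_years,
                             config$clock_rate_r, config$te_body_length,
                             kappa))
    } else NULL

    n_mut <- round((1 - cns_identity) * cns_length)
    truth_rows <- list()
    regions <- vector("list", 3)
    ids <- c("region_a", "region_b", "region_c")
    for (r in 1:3) {
      pieces <- list()
      feats <- feature_table()
      pos <- 0L
      add <- function(x) {
        pieces[[length(pieces) + 1L]] <<- x
        pos <<- pos + length(x)
      }
      add(random_dna_int(spacer_length))  # leading flank, independent
      # anchor gene 1 (evolved copy)
      gstart <- pos
      gseq <- evolve_gene_copy(g1, d, kappa, config$omega_target)
      f <- g1$features
      f$start <- f$start + gstart
      f$end <- f$end + gstart
      feats <- rbind(feats, f)
      add(gseq)
      for (i in seq_len(n_cns)) {
        add(random_dna_int(spacer_length))
        cstart <- pos
        copy <- cns_anc[[i]]
        if (r == 1 && n_mut > 0) {
          at <- sample.int(cns_length, n_mut)
          shift <- sample.int(3L, n_mut, replace = TRUE)
          copy[at] <- ((copy[at] - 1L + shift) %% 4L) + 1L
        }
        add(copy)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          label = sprintf("CNS%d", i), region = ids[r],
          start = cstart, end = cstart + cns_length,
          identity = cns_identity)
      }
      add(random_dna_int(spacer_length))
      if (with_te) {
        el <- te_el[[r]]
        tstart <- pos
        f <- el$features
        f$start <- f$start + tstart
        f$end <- f$end + tstart
        f$name <- sprintf("%s_TE1", ids[r])
        feats <- rbind(feats, f)
        add(seq_to_int(el$sequence))
        add(random_dna_int(spacer_length))
      }
      # anchor gene 2
      gstart <- pos
      gseq <- evolve_gene_copy(g2, d, kappa, config$omega_target)
      f <- g2$features
      f$start <- f$start + gstart
      f$end <- f$end + gstart
      feats <- rbind(feats, f)
      add(gseq)
      add(random_dna_int(spacer_length))  # trailing flank
      seq_int <- unlist(pieces, use.names = FALSE)
      feats <- feats[order(feats$start, feats$end), , drop = FALSE]
      rownames(feats) <- NULL
      regions[[r]] <- genomic_region(ids[r], int_to_seq(seq_int), feats)
    }
    truth <- if (length(truth_rows) > 0) do.call(rbind, truth_rows) else
      data.frame(label = character(), region = character(),
                 start = integer(), end = integer(), identity = numeric())
    list(regions = stats::setNames(regions, ids), truth = truth)
  })
}

# Evolve a built gene's sequence (exons under selection, introns neutral).
evolve_gene_copy <- function(gene, d, kappa, omega) {
  x <- gene$seq_int
  f <- gene$features
  cds <- f[f$kind == "CDS", , drop = FALSE]
  in_cds <- logical(length(x))
  for (i in seq_len(nrow(cds))) in_cds[(cds$start[i] + 1L):cds$end[i]] <- TRUE
  x[!in_cds] <- evolve_k2p_int(x[!in_cds], d, kappa)
  idx <- which(in_cds)
  if (length(idx) > 0) {
    x[idx] <- seq_to_int(evolve_cds(int_to_seq(x[idx]), d, kappa, omega))
  }
  x
}

#' Write a simulated pair or trio to disk
#'
#' Writes FASTA, GFF3 and a tab-separated truth file so simulations can be
#' consumed as ordinary inputs.
#'
#' @param sim Output of [simulate_pair()] or [simulate_trio_with_cns()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  regions <- if (!is.null(sim$regions)) sim$regions else
    list(sim$a, sim$b)
  write_fasta(regions, file.path(dir, "regions.fa"))
  feats <- lapply(regions, `[[`, "features")
  names(feats) <- vapply(regions, `[[`, "", "id")
  write_features(feats, file.path(dir, "regions.gff3"), "gff3")
  truth <- sim$truth
  if (is.data.frame(truth)) {
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(truth$conserved, file.path(dir, "truth_conserved.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
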