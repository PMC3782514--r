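# Pairwise alignment utilities and substitution-rate estimators: Kimura
# two-parameter (K2P) nucleotide distance and Nei-Gojobori (NG86) Ka/Ks.

#' Global pairwise alignment with affine gaps
#'
#' Needleman--Wunsch global alignment (via \pkg{Biostrings}) with the scoring
#' scheme match = +1, mismatch = -1 and affine gaps scoring
#' `gap_open + (k - 1) * gap_extend` for a gap of length k, so a single-base
#' gap scores `-5` with the defaults.
#'
#' @param a,b Nucleotide strings (or `genomic_region`s), each <= 100 kb.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (signs as
#'   conventionally written: positive match, negative penalties).
#' @return List of class `pairwise_alignment` with `a_aln`, `b_aln` (gapped
#'   strings of equal length), `score`, `a_id`, `b_id`.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap_open = -5,
                         gap_extend = -1) {
  a_id <- if (inherits(a, "genomic_region")) a$id else "a"
  b_id <- if (inherits(b, "genomic_region")) b$id else "b"
  sa <- if (inherits(a, "genomic_region")) a$residues else toupper(a)
  sb <- if (inherits(b, "genomic_region")) b$residues else toupper(b)
  if (nchar(sa) == 0 || nchar(sb) == 0) stopf("cannot align empty sequences")
  if (nchar(sa) > 1e5 || nchar(sb) > 1e5) {
    stopf("global_align is limited to sequences <= 100 kb (got %d, %d)",
          nchar(sa), nchar(sb))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sa), Biostrings::DNAString(sb),
    type = "global", substitutionMatrix = mat,
    gapOpening = -(gap_open - gap_extend), gapExtension = -gap_extend)
  structure(list(a_aln = as.character(Biostrings::alignedPattern(pa)),
                 b_aln = as.character(Biostrings::alignedSubject(pa)),
                 score = Biostrings::score(pa),
                 a_id = a_id, b_id = b_id),
            class = "pairwise_alignment")
}

#' Construct a pairwise alignment from pre-aligned strings
#'
#' @param a_aln,b_aln Gapped sequences of equal length.
#' @param a_id,b_id Labels.
#' @return A `pairwise_alignment`.
#' @export
pairwise_alignment <- function(a_aln, b_aln, a_id = "a", b_id = "b") {
  a_aln <- toupper(a_aln); b_aln <- toupper(b_aln)
  if (nchar(a_aln) != nchar(b_aln)) {
    stopf("aligned sequences differ in length (%d vs %d)",
          nchar(a_aln), nchar(b_aln))
  }
  structure(list(a_aln = a_aln, b_aln = b_aln, score = NA_real_,
                 a_id = a_id, b_id = b_id), class = "pairwise_alignment")
}

#' Kimura two-parameter distance
#'
#' Columns containing gaps or `N` are excluded. With `P` the transition and
#' `Q` the transversion proportion over usable columns, the distance is
#' `K = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#'
#' @param aln A `pairwise_alignment` (from [global_align()] or
#'   [pairwise_alignment()]).
#' @return List of class `distance_estimate`: `P`, `Q`, `K`, `n_sites`.
#' @export
k2p_distance <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  x <- charToRaw(aln$a_aln)
  y <- charToRaw(aln$b_aln)
  acgt <- charToRaw("ACGT")
  use <- (x %in% acgt) & (y %in% acgt)
  n <- sum(use)
  if (n == 0) stopf("no usable (ungapped, non-N) columns in alignment")
  x <- x[use]; y <- y[use]
  diff <- x != y
  # transitions: A<->G (0x41,0x47), C<->T (0x43,0x54)
  pur <- x %in% charToRaw("AG")
  pur_y <- y %in% charToRaw("AG")
  ts <- diff & (pur == pur_y)
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    stopf("K2P saturation: P = %.4f, Q = %.4f", P, Q)
  }
  K <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  structure(list(P = P, Q = Q, K = K, n_sites = n),
            class = "distance_estimate")
}

#' @export
print.distance_estimate <- function(x, ...) {
  cat(sprintf("<distance_estimate> K = %.4f (P = %.4f, Q = %.4f, %d sites)\n",
              x$K, x$P, x$Q, x$n_sites))
  invisible(x)
}

#' Substitution rate of a non-coding alignment
#'
#' K2P distance of a UTR or intron alignment (thin wrapper over
#' [k2p_distance()]).
#'
#' @param aln A `pairwise_alignment`.
#' @return The K2P distance `K` (scalar).
#' @export
noncoding_rate <- function(aln) k2p_distance(aln)$K

#' Build a codon alignment from two coding sequences
#'
#' Protein-guided: both CDS are translated, the proteins globally aligned, and
#' the alignment mapped back to codons; codon columns containing a gap are
#' dropped. A terminal stop codon is stripped; an internal stop is an error
#' reporting the codon index.
#'
#' @param cds_a,cds_b Coding sequences, lengths divisible by 3, standard
#'   genetic code.
#' @return List of class `codon_alignment`: `codons_a`, `codons_b` (character
#'   vectors of paired codons) and `n_codons`.
#' @export
build_codon_alignment <- function(cds_a, cds_b) {
  prep <- function(cds, label) {
    cds <- toupper(cds)
    if (nchar(cds) %% 3 != 0) {
      stopf("%s length %d is not divisible by 3", label, nchar(cds))
    }
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aa <- vapply(codons, translate_codon, "")
    if (length(aa) > 0 && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    if (any(aa == "*")) {
      stopf("%s has an internal stop codon at codon %d", label,
            which(aa == "*")[1])
    }
    list(codons = codons, aa = paste(aa, collapse = ""))
  }
  pa <- prep(cds_a, "cds_a")
  pb <- prep(cds_b, "cds_b")
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa$aa), Biostrings::AAString(pb$aa),
    type = "global", substitutionMatrix = get("BLOSUM62"),
    gapOpening = 10, gapExtension = 0.5)
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(sa != "-")
  ib <- cumsum(sb != "-")
  keep <- sa != "-" & sb != "-"
  structure(list(codons_a = pa$codons[ia[keep]],
                 codons_b = pb$codons[ib[keep]],
                 n_codons = sum(keep)),
            class = "codon_alignment")
}

# --- NG86 machinery ---------------------------------------------------------

# Fraction of the 3 alternatives at each codon position that are synonymous;
# alternatives creating a stop codon count as nonsynonymous. Returns the
# total synonymous site count of a codon (0..3).
ng86_syn_sites <- function(codon) {
  gc <- codon_table()
  aa <- gc[[codon]]
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    for (alt in setdiff(BASES, chars[p])) {
      mut <- chars
      mut[p] <- alt
      if (gc[[paste(mut, collapse = "")]] == aa) s <- s + 1 / 3
    }
  }
  s
}

ng86_sites_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- codon_table()
      sense <- names(gc)[gc != "*"]
      tab <<- vapply(sense, ng86_syn_sites, numeric(1))
    }
    tab
  }
})

# Synonymous/nonsynonymous differences between two codons, averaging over all
# substitution pathways with equal weights; pathways passing through a stop
# codon are excluded (all pathways are used if every one is blocked).
ng86_codon_diffs <- function(ca, cb) {
  if (ca == cb) return(c(sd = 0, nd = 0))
  gc <- codon_table()
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  perms <- if (length(pos) == 1) list(pos) else
    if (length(pos) == 2) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) pos[o])
  paths <- list()
  for (perm in perms) {
    cur <- a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in perm) {
      nxt <- cur
      nxt[p] <- b[p]
      aa_cur <- gc[[paste(cur, collapse = "")]]
      aa_nxt <- gc[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*" || aa_cur == "*") blocked <- TRUE
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- c(sd = sd, nd = nd, blocked = blocked)
  }
  m <- do.call(rbind, paths)
  ok <- m[, "blocked"] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, "sd"]), nd = mean(m[ok, "nd"]))
}

#' Nei--Gojobori (1986) Ka/Ks estimation
#'
#' Synonymous site counts come from the standard genetic code (changes to stop
#' codons count as nonsynonymous); differences in multi-substitution codons
#' are averaged over all substitution pathways with equal weights (pathways
#' through stop codons excluded); proportions are Jukes--Cantor corrected:
#' `Ks = -3/4 log(1 - 4 ps / 3)` and likewise for `Ka`.
#'
#' @param ca A `codon_alignment` from [build_codon_alignment()].
#' @return List of class `kaks_result`: `S`, `N`, `Sd`, `Nd`, `ps`, `pn`,
#'   `Ks`, `Ka`, `omega` (`NA` with `omega_undefined = TRUE` when `Ks = 0`)
#'   and `n_codons`.
#' @export
ng86_kaks <- function(ca) {
  stopifnot(inherits(ca, "codon_alignment"))
  n <- ca$n_codons
  if (n == 0) stopf("codon alignment is empty")
  if (n < 10) warnf("only %d codon columns; Ka/Ks will be unstable", n)
  st <- ng86_sites_table()
  s_a <- sum(st[ca$codons_a])
  s_b <- sum(st[ca$codons_b])
  if (anyNA(c(s_a, s_b))) stopf("alignment contains stop or ambiguous codons")
  S <- (s_a + s_b) / 2
  N <- 3 * n - S
  dd <- vapply(seq_len(n), function(i) {
    ng86_codon_diffs(ca$codons_a[i], ca$codons_b[i])
  }, numeric(2))
  Sd <- sum(dd["sd", ])
  Nd <- sum(dd["nd", ])
  ps <- Sd / S
  pn <- Nd / N
  if (ps >= 0.75 || pn >= 0.75) {
    stopf("NG86 saturation: ps = %.4f, pn = %.4f", ps, pn)
  }
  Ks <- -0.75 * log(1 - 4 * ps / 3) + 0  # + 0 normalizes IEEE -0
  Ka <- -0.75 * log(1 - 4 * pn / 3) + 0
  omega_undefined <- Ks == 0
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 Ks = Ks, Ka = Ka,
                 omega = if (omega_undefined) NA_real_ else Ka / Ks,
                 omega_undefined = omega_undefined, n_codons = n),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(paste0("<kaks_result> %d codons: Ks = %.4f, Ka = %.4f, ",
                     "omega = %s (S = %.2f, N = %.2f, Sd = %.2f, Nd = %.2f)\n"),
              x$n_codons, x$Ks, x$Ka,
              if (x$omega_undefined) "undefined" else sprintf("%.4f", x$omega),
              x$S, x$N, x$Sd, x$Nd))
  invisible(x)
}
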