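# Cis-regulatory motif scanning (IUPAC consensus matching on both strands)
# and perfect microsatellite (SSR) detection.

#' Default cis-regulatory motif table
#'
#' Core plant promoter elements: TATA-box, CAAT-box, GC-box, G-box (CACGTG),
#' P-box (CCTTTTG), 5' UTR Py-rich stretch (TTTCTTCTCT), SP1 and the MYB
#' binding site (MBS). Consensi are IUPAC strings and can be replaced or
#' extended by the caller.
#'
#' @return data.frame with columns `name`, `consensus`.
#' @export
default_motif_table <- function() {
  data.frame(
    name = c("TATA-box", "CAAT-box", "GC-box", "G-box", "P-box",
             "Py-rich", "SP1", "MBS"),
    consensus = c("TATAAA", "CCAAT", "GGGCGG", "CACGTG", "CCTTTTG",
                  "TTTCTTCTCT", "CCRCCC", "CAACTG"),
    stringsAsFactors = FALSE)
}

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

iupac_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Scan a sequence for cis-regulatory elements
#'
#' Reports all exact IUPAC-consensus matches on both strands, sorted by
#' position. Palindromic consensi (equal to their reverse complement) are
#' reported once per site on the `+` strand.
#'
#' @param seq Nucleotide string or [genomic_region()].
#' @param motif_table data.frame with columns `name` and `consensus` (IUPAC);
#'   defaults to [default_motif_table()].
#' @return data.frame with columns `name`, `consensus`, `position` (0-based
#'   start on the forward strand), `strand`.
#' @export
scan_cis_elements <- function(seq, motif_table = default_motif_table()) {
  s <- if (inherits(seq, "genomic_region")) seq$residues else toupper(seq)
  stopifnot(is.data.frame(motif_table),
            all(c("name", "consensus") %in% names(motif_table)))
  bad <- vapply(motif_table$consensus, function(m) {
    any(!strsplit(toupper(m), "")[[1]] %in% IUPAC_CHARS)
  }, logical(1))
  if (any(bad)) {
    stopf("invalid IUPAC character in motif consensus: %s",
          paste(motif_table$consensus[bad], collapse = ", "))
  }
  subject <- Biostrings::DNAString(s)
  rows <- list()
  for (i in seq_len(nrow(motif_table))) {
    cons <- toupper(motif_table$consensus[i])
    fwd <- Biostrings::matchPattern(cons, subject, fixed = FALSE)
    if (length(fwd) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = motif_table$name[i], consensus = cons,
        position = Biostrings::start(fwd) - 1L, strand = "+")
    }
    rc <- iupac_revcomp(cons)
    if (rc != cons) {  # palindromes: one hit per site, strand +
      rev <- Biostrings::matchPattern(rc, subject, fixed = FALSE)
      if (length(rev) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = motif_table$name[i], consensus = cons,
          position = Biostrings::start(rev) - 1L, strand = "-")
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(name = character(), consensus = character(),
                      position = integer(), strand = character()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# lexicographically smallest rotation of a repeat unit
canonical_rotation <- function(unit) {
  n <- nchar(unit)
  rots <- vapply(seq_len(n), function(i) {
    paste0(substr(unit, i, n), substr(unit, 1, i - 1))
  }, "")
  min(rots)
}

# TRUE if the unit is itself a tandem repetition of a shorter unit
is_primitive_unit <- function(unit) {
  n <- nchar(unit)
  for (d in seq_len(n - 1)) {
    if (n %% d == 0 &&
        strrep(substr(unit, 1, d), n / d) == unit) return(FALSE)
  }
  TRUE
}

#' Find perfect microsatellites (SSRs)
#'
#' Maximal perfect tandem runs of 1--6 bp units meeting a per-unit-length
#' minimum copy number. Runs are reported under the lexicographically smallest
#' rotation of their unit; runs whose unit is itself a repetition of a shorter
#' unit are reported at the shorter unit only.
#'
#' @param seq Nucleotide string or [genomic_region()].
#' @param min_copies Named numeric vector mapping unit length (as `"1"` ..
#'   `"6"`) to the minimum copy number.
#' @return data.frame with columns `unit` (canonical rotation), `copies`,
#'   `start`, `end` (0-based half-open; `end - start = copies * unit length`).
#' @export
find_ssrs <- function(seq, min_copies = c(`1` = 10, `2` = 6, `3` = 5,
                                          `4` = 5, `5` = 5, `6` = 5)) {
  s <- if (inherits(seq, "genomic_region")) seq$residues else toupper(seq)
  n <- nchar(s)
  raw <- charToRaw(s)
  rows <- list()
  for (u in 1:6) {
    if (n < 2 * u || is.na(min_copies[as.character(u)])) next
    eq <- raw[seq_len(n - u)] == raw[(u + 1):n]
    runs <- true_runs(eq)
    if (nrow(runs) == 0) next
    total <- runs$end - runs$start + 1L + u     # matched stretch length
    copies <- total %/% u
    keep <- copies >= min_copies[as.character(u)]
    for (i in which(keep)) {
      st <- runs$start[i]                        # 1-based start in sequence
      unit <- substr(s, st, st + u - 1L)
      if (!is_primitive_unit(unit)) next         # reported at the shorter unit
      if (grepl("N", unit, fixed = TRUE)) next
      rows[[length(rows) + 1L]] <- data.frame(
        unit = canonical_rotation(unit), copies = copies[i],
        start = st - 1L, end = st - 1L + copies[i] * u)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(unit = character(), copies = integer(),
                      start = integer(), end = integer()))
  }
  out <- do.call(rbind, rows)
  # suppress runs fully contained in a longer reported run (e.g. the
  # homopolymer stretches inside a long dinucleotide run never qualify, but a
  # short-unit run inside a longer-unit run can; keep the longest span)
  out <- out[order(out$start, -(out$end - out$start)), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    inside <- out$start >= out$start[i] & out$end <= out$end[i] &
      seq_len(nrow(out)) != i
    keep[inside & (out$end - out$start) < (out$end[i] - out$start[i])] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
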