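#' Construct a genomic region
#'
#' A `genomic_region` bundles a named nucleotide sequence with its typed
#' feature intervals. All feature coordinates are 0-based half-open and must
#' lie within `[0, length)`.
#'
#' @param id Region identifier (single string).
#' @param residues Nucleotide string. Lowercase is uppercased; characters
#'   outside `A,C,G,T,N` are mapped to `N` with a warning giving the count.
#' @param features A feature data.frame as returned by [feature_table()], or
#'   `NULL` for no features.
#' @return An object of class `genomic_region`: a list with elements `id`,
#'   `residues`, `length` and `features`.
#' @export
genomic_region <- function(id, residues, features = NULL) {
  stopifnot(is.character(id), length(id) == 1, nchar(id) > 0)
  residues <- toupper(residues)
  bad <- gregexpr("[^ACGTN]", residues)[[1]]
  n_bad <- if (bad[1] == -1L) 0L else length(bad)
  if (n_bad > 0) {
    residues <- gsub("[^ACGTN]", "N", residues)
    warnf("region '%s': %d non-ACGTN characters mapped to N", id, n_bad)
  }
  len <- nchar(residues)
  features <- validate_features(features %||% feature_table(), len, id)
  structure(list(id = id, residues = residues, length = len,
                 features = features),
            class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<genomic_region> %s: %s bp, %d features\n",
              x$id, format(x$length, big.mark = ","), nrow(x$features)))
  if (nrow(x$features) > 0) print(utils::head(x$features, 10))
  invisible(x)
}

FEATURE_KINDS <- c("gene", "exon", "CDS", "five_prime_UTR", "three_prime_UTR",
                   "TE", "LTR5", "LTR3", "SSR", "CNS", "other")

#' Build a feature interval table
#'
#' Feature intervals are 0-based half-open with `0 <= start < end`. `LTR5` and
#' `LTR3` intervals must be nested inside a `TE` interval when attached to a
#' region.
#'
#' @param start,end Integer vectors, 0-based half-open.
#' @param strand Character vector over `+`, `-`, `.`.
#' @param kind Character vector over the supported kinds (see
#'   `syntevol:::FEATURE_KINDS`).
#' @param name Feature names.
#' @return A data.frame with columns `start`, `end`, `strand`, `kind`, `name`.
#' @export
feature_table <- function(start = integer(), end = integer(),
                          strand = character(), kind = character(),
                          name = character()) {
  n <- length(start)
  if (length(strand) == 0 && n > 0) strand <- rep(".", n)
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), kind = as.character(kind),
                   name = as.character(name), stringsAsFactors = FALSE)
  df
}

validate_features <- function(df, region_length, region_id = "<region>") {
  stopifnot(is.data.frame(df))
  need <- c("start", "end", "strand", "kind", "name")
  if (!all(need %in% names(df))) {
    stopf("feature table must have columns %s", paste(need, collapse = ", "))
  }
  df <- df[need]
  if (nrow(df) == 0) return(df)
  if (any(df$start < 0) || any(df$start >= df$end) ||
      any(df$end > region_length)) {
    bad <- which(df$start < 0 | df$start >= df$end | df$end > region_length)[1]
    stopf("region '%s': feature %d ('%s') interval [%d,%d) outside [0,%d)",
          region_id, bad, df$name[bad], df$start[bad], df$end[bad],
          region_length)
  }
  if (!all(df$kind %in% FEATURE_KINDS)) {
    stopf("unknown feature kind(s): %s",
          paste(setdiff(df$kind, FEATURE_KINDS), collapse = ", "))
  }
  ltr <- df$kind %in% c("LTR5", "LTR3")
  if (any(ltr)) {
    te <- df[df$kind == "TE", , drop = FALSE]
    for (i in which(ltr)) {
      nested <- any(te$start <= df$start[i] & te$end >= df$end[i])
      if (!nested) {
        stopf("region '%s': %s interval [%d,%d) is not nested in a TE interval",
              region_id, df$kind[i], df$start[i], df$end[i])
      }
    }
  }
  df
}

#' Read a multi-record FASTA file into genomic regions
#'
#' Lowercase residues are uppercased and characters outside `A,C,G,T,N` are
#' mapped to `N` (one warning per region gives the count). Duplicate record
#' ids and empty files are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named list of [genomic_region()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stopf("FASTA file is empty: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stopf("duplicate FASTA id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  widths <- Biostrings::width(set)
  if (any(widths == 0)) stopf("FASTA record with empty sequence: %s",
                              ids[which(widths == 0)[1]])
  regions <- lapply(seq_along(set), function(i) {
    genomic_region(ids[i], as.character(set[[i]]))
  })
  stats::setNames(regions, ids)
}

#' Write genomic regions to FASTA
#'
#' @param regions A `genomic_region` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(regions, path) {
  if (inherits(regions, "genomic_region")) regions <- list(regions)
  set <- Biostrings::DNAStringSet(vapply(regions, `[[`, "", "residues"))
  names(set) <- vapply(regions, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# BED has no type column; the package encodes `kind|name` in the BED name
# field so that interval sets round-trip through both dialects.
bed_name_encode <- function(kind, name) paste(kind, name, sep = "|")
bed_name_decode <- function(x) {
  has <- grepl("|", x, fixed = TRUE)
  kind <- ifelse(has, sub("\\|.*$", "", x), "other")
  name <- ifelse(has, sub("^[^|]*\\|", "", x), x)
  list(kind = kind, name = name)
}

#' Read feature annotations (GFF3 or BED)
#'
#' Coordinates are normalized to the package's internal 0-based half-open
#' convention (GFF3 is 1-based closed on disk; BED is already 0-based
#' half-open). Parsing is delegated to \pkg{rtracklayer}.
#'
#' @param path Path to a GFF3 or BED6 file.
#' @param dialect `"gff3"` or `"bed"`.
#' @param region_lengths Optional named integer vector of region lengths used
#'   to reject out-of-bounds intervals.
#' @return Named list of feature data.frames, one per region id present in the
#'   file.
#' @export
read_features <- function(path, dialect = c("gff3", "bed"),
                          region_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("feature file not found: %s", path)
  if (file.size(path) == 0 ||
      all(grepl("^(#|\\s*$)", readLines(path, warn = FALSE)))) {
    return(stats::setNames(list(), character()))
  }
  gr <- rtracklayer::import(path, format = dialect)
  ids <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L  # 1-based closed -> 0-based half-open
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  if (dialect == "gff3") {
    kind <- as.character(gr$type)
    name <- as.character(gr$Name %||% gr$ID %||% rep(NA_character_, length(gr)))
    name[is.na(name)] <- ""
  } else {
    dec <- bed_name_decode(as.character(gr$name))
    kind <- dec$kind
    name <- dec$name
  }
  if (!is.null(region_lengths)) {
    known <- ids %in% names(region_lengths)
    oob <- known & (end0 > region_lengths[ids] | start0 < 0)
    if (any(oob)) {
      i <- which(oob)[1]
      stopf("%s record %d: interval [%d,%d) on '%s' exceeds region length %d",
            dialect, i, start0[i], end0[i], ids[i], region_lengths[ids[i]])
    }
  }
  out <- lapply(split(seq_along(gr), ids), function(idx) {
    feature_table(start0[idx], end0[idx], strand[idx], kind[idx], name[idx])
  })
  out[order(names(out))]
}

#' Write feature annotations (GFF3 or BED)
#'
#' The inverse of [read_features()]: internal 0-based half-open intervals are
#' converted to the dialect's convention at the boundary, so that
#' `read_features(write_features(x))` round-trips exactly.
#'
#' @param features Named list of feature data.frames (names are region ids),
#'   or a single feature data.frame together with `region_id`.
#' @param path Output path.
#' @param dialect `"gff3"` or `"bed"`.
#' @param region_id Region id when `features` is a single data.frame.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, dialect = c("gff3", "bed"),
                           region_id = NULL) {
  dialect <- match.arg(dialect)
  if (is.data.frame(features)) {
    stopifnot(!is.null(region_id))
    features <- stats::setNames(list(features), region_id)
  }
  rows <- do.call(rbind, lapply(names(features), function(id) {
    df <- features[[id]]
    if (nrow(df) == 0) return(NULL)
    cbind(seqid = id, df)
  }))
  if (is.null(rows) || nrow(rows) == 0) {
    # valid empty file: header only for GFF3, empty file for BED
    writeLines(if (dialect == "gff3") "##gff-version 3" else character(), path)
    return(invisible(path))
  }
  strand <- rows$strand
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = rows$seqid,
    ranges = IRanges::IRanges(start = rows$start + 1L, end = rows$end),
    strand = strand)
  if (dialect == "gff3") {
    gr$source <- "syntevol"
    gr$type <- rows$kind
    gr$ID <- sprintf("%s_%05d", rows$kind, seq_len(nrow(rows)))
    gr$Name <- rows$name
    # GFF3 phase for CDS segments: offset to the next codon boundary,
    # accumulated over the gene's CDS parts in genomic order
    phase <- rep(NA_integer_, nrow(rows))
    is_cds <- rows$kind == "CDS"
    if (any(is_cds)) {
      for (key in unique(paste(rows$seqid, rows$name)[is_cds])) {
        idx <- which(is_cds & paste(rows$seqid, rows$name) == key)
        idx <- idx[order(rows$start[idx])]
        lens <- rows$end[idx] - rows$start[idx]
        phase[idx] <- c(0L, cumsum(lens)[-length(lens)]) %% 3L
        phase[idx] <- (3L - phase[idx]) %% 3L
      }
    }
    gr$phase <- phase
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    gr$name <- bed_name_encode(rows$kind, rows$name)
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

# Extract the residues of a 0-based half-open interval.
region_subseq <- function(region, start, end) {
  substr(region$residues, start + 1L, end)
}

# Spliced feature sequence: concatenation of intervals of the given kind and
# name, in genomic order, reverse-complemented for '-' strand features.
feature_sequence <- function(region, name, kind = "CDS") {
  f <- region$features
  f <- f[f$name == name & f$kind == kind, , drop = FALSE]
  if (nrow(f) == 0) stopf("region '%s': no %s feature named '%s'",
                          region$id, kind, name)
  f <- f[order(f$start), , drop = FALSE]
  s <- paste(vapply(seq_len(nrow(f)), function(i) {
    region_subseq(region, f$start[i], f$end[i])
  }, ""), collapse = "")
  if (all(f$strand == "-")) {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}
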