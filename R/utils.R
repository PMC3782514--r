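# Internal helpers shared across modules. All coordinates in this package are
# 0-based half-open unless a function converts at an I/O boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.table is used with its native [ semantics inside this package
.datatable.aware <- TRUE

BASES <- c("A", "C", "G", "T")

# Integer encoding A=1 C=2 G=3 T=4 used by the simulator (N never simulated).
seq_to_int <- function(s) {
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], BASES)
  if (anyNA(v)) stop("sequence contains non-ACGT characters")
  v
}

int_to_seq <- function(v) paste(BASES[v], collapse = "")

random_dna_int <- function(n) sample.int(4L, n, replace = TRUE)

random_dna <- function(n) int_to_seq(random_dna_int(n))

# Transition partner (A<->G, C<->T) in integer encoding.
TS_PARTNER <- c(3L, 4L, 1L, 2L)
# Transversion alternatives per base, integer encoding.
TV_OPTIONS <- matrix(c(2L, 4L,   # A -> C/T
                       1L, 3L,   # C -> A/G
                       2L, 4L,   # G -> C/T
                       1L, 3L),  # T -> A/G
                     nrow = 4, byrow = TRUE)

is_transition <- function(x, y) TS_PARTNER[x] == y

# Rolling mean of a 0/1 vector over windows of width w; returns one value per
# window start (length(x) - w + 1 values). cumsum-based, exact.
rolling_mean <- function(x, w) {
  cs <- cumsum(x)
  n <- length(x)
  if (n < w) return(numeric(0))
  (cs[w:n] - c(0, cs[seq_len(n - w)])) / w
}

# Maximal runs of TRUE in a logical vector -> data.frame(start, end) with
# 1-based inclusive indices.
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Positions (1-based) covered by at least one passing window of width w whose
# start index is TRUE in `ok`.
covered_positions <- function(ok, w) {
  n <- length(ok) + w - 1L
  idx <- which(ok)
  if (length(idx) == 0L) return(logical(n))
  delta <- tabulate(idx, n + 1L) - tabulate(idx + w, n + 1L)
  cumsum(delta[seq_len(n)]) > 0L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
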