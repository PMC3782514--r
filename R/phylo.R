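# Neighbor-joining trees from distance matrices, with column-resampling
# bootstrap. The NJ implementation is the package's own (deterministic
# lexicographic tie-breaking, negative branch lengths clamped and flagged);
# trees are returned as ape "phylo" objects and serialize to Newick via ape.

validate_dist_matrix <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  }
  if (!all(is.finite(dm))) stopf("distance matrix has non-finite entries")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stopf("distance matrix is not symmetric")
  }
  if (any(diag(dm) != 0)) stopf("distance matrix diagonal must be zero")
  if (any(dm < 0)) stopf("distance matrix has negative entries")
  dm
}

#' Neighbor-joining tree
#'
#' Saitou--Nei neighbor joining with deterministic tie-breaking (among equal
#' Q values, the join with the lexicographically lowest label pair is taken;
#' a cluster's label is the smallest leaf label it contains). Negative branch
#' lengths are clamped to zero; the number clamped is recorded in
#' `attr(tree, "clamped")`.
#'
#' @param dm Symmetric distance matrix with taxon labels as dimnames,
#'   >= 3 taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- validate_dist_matrix(dm)
  n <- nrow(dm)
  if (n < 3) stopf("neighbor joining needs >= 3 taxa (got %d)", n)
  labels <- rownames(dm)
  clamped <- 0L
  fmt_len <- function(v) {
    if (v < 0) {
      clamped <<- clamped + 1L
      v <- 0
    }
    format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }
  # active nodes: newick fragment + representative label (smallest leaf)
  frag <- as.list(labels)
  rep_lab <- labels
  D <- dm
  while (length(frag) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- NULL
    best_q <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        key <- sort(c(rep_lab[i], rep_lab[j]))
        if (Q[i, j] < best_q - 1e-12 ||
            (abs(Q[i, j] - best_q) <= 1e-12 && !is.null(best) &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, key = key)
          best_q <- min(best_q, Q[i, j])
        }
      }
    }
    i <- best$i; j <- best$j
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[[i]], fmt_len(li),
                        frag[[j]], fmt_len(lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    D <- D2
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], min(best$key))
  }
  # final three-point resolution
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[[1]], fmt_len(l1), frag[[2]], fmt_len(l2),
                 frag[[3]], fmt_len(l3))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  attr(tree, "zero_matrix") <- all(dm == 0)
  tree
}

#' Pairwise K2P distance matrix from aligned sequences
#'
#' Distances are computed per pair over the columns ungapped and non-N in
#' that pair (pairwise deletion).
#'
#' @param seqs Named character vector of aligned (equal-length) sequences.
#' @return Symmetric distance matrix with taxon labels.
#' @export
k2p_dist_matrix <- function(seqs) {
  stopifnot(!is.null(names(seqs)), length(seqs) >= 2,
            length(unique(nchar(seqs))) == 1)
  n <- length(seqs)
  dm <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- k2p_distance(pairwise_alignment(seqs[[i]], seqs[[j]]))
      dm[i, j] <- dm[j, i] <- d$K
    }
  }
  dm
}

#' Neighbor-joining tree with column-resampling bootstrap support
#'
#' Builds a K2P neighbor-joining tree from aligned sequences, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds the tree per
#' replicate, and records for each internal edge the percentage of replicates
#' containing the same bipartition (stored in `tree$node.label`).
#'
#' @param seqs Named character vector of aligned (equal-length) sequences,
#'   >= 3 taxa.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return An `ape::phylo` tree with `node.label` support values in
#'   `[0, 100]` (the root label is `NA`).
#' @export
bootstrap_support <- function(seqs, n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1)
  cols <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(cols) <- names(seqs)
  L <- ncol(cols)
  tree <- nj_tree(k2p_dist_matrix(apply(cols, 1, paste, collapse = "")))
  boots <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(b) {
      idx <- sample.int(L, L, replace = TRUE)
      resampled <- apply(cols[, idx, drop = FALSE], 1, paste, collapse = "")
      nj_tree(k2p_dist_matrix(resampled))
    })
  })
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_reps)
  support[1] <- NA  # root of an unrooted tree carries no support
  tree$node.label <- support
  tree
}
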