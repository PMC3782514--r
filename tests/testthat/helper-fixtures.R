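# Shared fixtures and independent brute-force oracles.

rand_seq <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Brute-force oracle: does any word-sized window pair on a shared diagonal
# reach the identity threshold? Returns per-diagonal coverage of passing
# windows (positions on sequence a). O(n*m); keep sequences small.
brute_force_window_scan <- function(sa, sb, word = 40L, min_id = 0.6) {
  ra <- charToRaw(sa); rb <- charToRaw(sb)
  na <- length(ra); nb <- length(rb)
  covered <- logical(na)
  for (d in (-(nb - word)):(na - word)) {
    lo <- max(1L, d + 1L)
    hi <- min(na, nb + d)
    if (hi - lo + 1L < word) next
    mv <- ra[lo:hi] == rb[(lo - d):(hi - d)]
    cs <- cumsum(mv)
    nwin <- (hi - lo + 1L) - word + 1L
    ids <- (cs[word:(hi - lo + 1L)] - c(0, cs[seq_len(nwin - 1L)])) / word
    for (s in which(ids >= min_id)) {
      covered[(lo + s - 1L):(lo + s - 2L + word)] <- TRUE
    }
  }
  covered
}

# Brute-force SSR oracle: for every start and unit length, extend the maximal
# perfect tandem run; report canonical units meeting the copy minimum.
brute_force_ssrs <- function(s, min_copies = c(`1` = 10, `2` = 6, `3` = 5,
                                               `4` = 5, `5` = 5, `6` = 5)) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  canon <- function(u) {
    k <- nchar(u)
    min(vapply(seq_len(k), function(i)
      paste0(substr(u, i, k), substr(u, 1, i - 1)), ""))
  }
  prim <- function(u) {
    k <- nchar(u)
    for (d in seq_len(k - 1)) {
      if (k %% d == 0 && strrep(substr(u, 1, d), k / d) == u) return(FALSE)
    }
    TRUE
  }
  found <- list()
  for (u in 1:6) {
    for (st in seq_len(n - 2 * u + 1)) {
      # maximality on the left: the tandem lag-match must not extend by even
      # one base
      if (st > 1 && st + u - 1 <= n && ch[st - 1] == ch[st - 1 + u]) next
      cp <- 1L
      while (st + (cp + 1L) * u - 1L <= n &&
             all(ch[st:(st + u - 1)] == ch[(st + cp * u):(st + (cp + 1L) * u - 1L)])) {
        cp <- cp + 1L
      }
      unit <- substr(s, st, st + u - 1)
      if (cp >= min_copies[as.character(u)] && prim(unit) &&
          !grepl("N", unit, fixed = TRUE)) {
        found[[length(found) + 1L]] <- data.frame(
          unit = canon(unit), copies = cp, start = st - 1L,
          end = st - 1L + cp * u)
      }
    }
  }
  if (length(found) == 0) {
    return(data.frame(unit = character(), copies = integer(),
                      start = integer(), end = integer()))
  }
  out <- unique(do.call(rbind, found))
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

# Brute-force NG86 pathway enumeration for a single codon pair, written
# independently of the package implementation.
brute_force_codon_paths <- function(ca, cb) {
  gc <- Biostrings::GENETIC_CODE
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  perm_list <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_list(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  res <- list()
  for (ord in perm_list(pos)) {
    cur <- a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b[p]
      if (gc[[paste(nxt, collapse = "")]] == "*") blocked <- TRUE
      if (gc[[paste(cur, collapse = "")]] == gc[[paste(nxt, collapse = "")]])
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[[length(res) + 1L]] <- c(sd, nd, blocked)
  }
  m <- do.call(rbind, res)
  ok <- m[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, 1]), nd = mean(m[ok, 2]))
}

# Random additive tree distances: returns list(tree, dm) for n taxa.
random_additive_tree <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.05, 1))
    tr$tip.label <- sort(tr$tip.label)
    dm <- ape::cophenetic.phylo(tr)
    dm <- dm[order(rownames(dm)), order(colnames(dm))]
    list(tree = tr, dm = dm)
  })
}
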