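# Independent brute-force oracles used to cross-check package results.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n, alphabet = AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# transitive closure of a thresholded identity graph by plain union-find,
# independent of the igraph-based implementation
closure_clusters <- function(idm, threshold) {
  n <- nrow(idm)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && idm[i, j] >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# all maximal segments with exactly two residue types, by direct enumeration
# of every window
ac2_windows_oracle <- function(sequence, min_length) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  segs <- list()
  for (s in seq_len(n)) for (e in s:n) {
    w <- ch[s:e]
    if ("X" %in% w) next
    if (length(unique(w)) != 2L) next
    left_ok <- s == 1L || ch[s - 1L] == "X" || !(ch[s - 1L] %in% w)
    right_ok <- e == n || ch[e + 1L] == "X" || !(ch[e + 1L] %in% w)
    if (left_ok && right_ok && e - s + 1L >= min_length)
      segs[[length(segs) + 1L]] <- c(s, e)
  }
  if (!length(segs)) return(matrix(integer(0), ncol = 2))
  unique(do.call(rbind, segs))
}

# exhaustive enumeration of P(sequence of length L uses exactly two types)
prob_ac2_enumeration <- function(L, p) {
  grid <- do.call(expand.grid, rep(list(seq_along(p)), L))
  probs <- apply(grid, 1, function(idx) prod(p[idx]))
  two <- apply(grid, 1, function(idx) length(unique(idx)) == 2L)
  sum(probs[two])
}

# naive per-chain disorder counts for a pattern: no clustering, no weights
naive_pattern_counts <- function(pattern, sequence, mask) {
  starts <- idrlib::match_pattern(pattern, sequence)
  cov <- logical(nchar(sequence))
  for (s in starts) cov[s:(s + nchar(pattern) - 1L)] <- TRUE
  m <- strsplit(mask, "")[[1]]
  c(u = sum(cov & m == "U"), s = sum(cov & m == "S"))
}
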