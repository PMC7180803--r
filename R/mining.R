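# Pattern mining: candidates from majority-disordered stretches of C100
# clusters, X-masking of homologue divergences, the C1-C3 conditions and the
# iterative greedy selection scored by D = N_u - N_f.

#' Effective (non-X) length of a pattern
#'
#' @param pattern pattern string over the 20 amino acids plus the wildcard X.
#' @return number of non-X positions.
#' @export
effective_length <- function(pattern) {
  vapply(pattern, function(p) sum(seq_chars(p) != "X"), integer(1),
         USE.NAMES = FALSE)
}

#' Match a pattern (with X wildcards) against a sequence
#'
#' A pattern matches at a position when every non-X pattern letter equals
#' the corresponding sequence letter; X matches any residue.  Overlapping
#' matches are all reported.
#'
#' @param pattern pattern string (letters + X).
#' @param sequence amino-acid string.
#' @return integer vector of 1-based start positions (possibly empty).
#' @examples
#' match_pattern("ASXTGGQQMGR", "ASNTGGQQMGR")  # 1
#' match_pattern("SSPAK", "GGSSPAKGG")          # 3
#' @export
match_pattern <- function(pattern, sequence) {
  stopifnot_scalar_string(pattern, "pattern")
  stopifnot_scalar_string(sequence, "sequence")
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(sequence))
    return(integer(0))
  rx <- paste0("(?=", gsub("X", ".", pattern, fixed = TRUE), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Extract candidate pattern fragments from identical-sequence clusters
#'
#' Within each 100 percent-identity cluster (all member chains share one
#' sequence), the per-position disorder fraction is the share of member
#' chains in which that residue is U.  Maximal stretches where the fraction
#' is at least `min_fraction` ("disordered in half the cases", inclusive)
#' and at least `min_length` residues long become candidate fragments;
#' duplicate fragment strings are dropped, keeping the first occurrence.
#'
#' @param records chain-record `data.frame`.
#' @param forest a [cluster_forest()] with a 100 level covering `records`.
#' @param min_fraction minimum disorder fraction (default 0.5, inclusive).
#' @param min_length minimum fragment length (default 3).
#' @return character vector of candidate fragments, in discovery order.
#' @export
extract_candidates <- function(records, forest, min_fraction = 0.5,
                               min_length = 3L) {
  validate_chain_records(records)
  if (!"C100" %in% names(forest$assignment))
    stop("cluster forest must include level 100", call. = FALSE)
  keys <- chain_key(records)
  idx <- match(keys, forest$assignment$chain)
  if (anyNA(idx))
    stop("cluster forest does not cover all chains", call. = FALSE)
  c100 <- forest$assignment$C100[idx]
  out <- character(0)
  for (cl in split(seq_along(keys), c100)[as.character(
         unique(c100))]) {
    seqs <- unique(records$sequence[cl])
    if (length(seqs) != 1L)
      stop("chains of one C100 cluster must share an identical sequence",
           call. = FALSE)
    masks <- do.call(rbind, lapply(records$mask[cl],
                                   function(m) seq_chars(m) == "U"))
    frac <- colMeans(masks)
    ok <- frac >= min_fraction
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_length)) {
      out <- c(out, substr(seqs, starts[k], ends[k]))
    }
  }
  unique(out)
}

#' Allowed substitutions for homologue search
#'
#' Homologues of a candidate must stay above 80 percent identity: candidates
#' of 3-5 residues admit no substitution (no homologue search), 6-10 residues
#' one, 11-15 two, and so on — i.e. `ceiling(L / 5) - 1`.
#'
#' @param L candidate length in residues.
#' @return allowed number of substitutions.
#' @export
allowed_substitutions <- function(L) {
  if (any(L < 1)) stop("L must be >= 1", call. = FALSE)
  as.integer(ceiling(L / 5) - 1)
}

#' Find homologues of a candidate among equal-length fragments
#'
#' A homologue is a distinct fragment of the same length within
#' [allowed_substitutions()] mismatches (Hamming distance) of the candidate.
#'
#' @param candidate candidate fragment (no X).
#' @param pool character vector of fragments to search.
#' @return character vector of homologues, in pool order.
#' @export
find_homologs <- function(candidate, pool) {
  stopifnot_scalar_string(candidate, "candidate")
  L <- nchar(candidate)
  k <- allowed_substitutions(L)
  if (k == 0L) return(character(0))
  pool <- pool[nchar(pool) == L & pool != candidate]
  if (!length(pool)) return(character(0))
  cc <- seq_chars(candidate)
  d <- vapply(pool, function(p) sum(seq_chars(p) != cc), integer(1),
              USE.NAMES = FALSE)
  pool[d >= 1L & d <= k]
}

#' Synthesise X-masked patterns from a candidate and its homologues
#'
#' For each homologue, the positions diverging from the candidate are
#' replaced by the wildcard X.  X-patterns are then combined pairwise —
#' taking the union of their X position sets — and the combination is closed
#' to a fixed point, so homologues diverging in different positions also
#' yield the joint template.  The candidate itself is retained; duplicates
#' are removed and the output order is deterministic (candidate first, then
#' by increasing X count, then lexicographically).
#'
#' @param candidate candidate fragment.
#' @param homologs character vector of equal-length fragments, each within
#'   [allowed_substitutions()] mismatches of `candidate`.
#' @return character vector of patterns, starting with the candidate.
#' @export
synthesize_xpatterns <- function(candidate, homologs) {
  stopifnot_scalar_string(candidate, "candidate")
  L <- nchar(candidate)
  if (any(nchar(homologs) != L))
    stop("homologs must have the same length as the candidate",
         call. = FALSE)
  cc <- seq_chars(candidate)
  kmax <- allowed_substitutions(L)
  sets <- lapply(sort(unique(homologs)), function(h) {
    d <- which(seq_chars(h) != cc)
    if (length(d) > kmax)
      stop("homolog ", h, " exceeds the allowed ", kmax, " substitution(s)",
           call. = FALSE)
    d
  })
  sets <- unique(sets[lengths(sets) > 0L])
  # closure under pairwise union
  key <- function(s) paste(s, collapse = ",")
  seen <- new.env(parent = emptyenv())
  for (s in sets) assign(key(s), TRUE, envir = seen)
  frontier <- sets
  all_sets <- sets
  while (length(frontier)) {
    new_sets <- list()
    for (f in frontier) {
      for (s in all_sets) {
        u <- sort(union(f, s))
        k <- key(u)
        if (!exists(k, envir = seen)) {
          assign(k, TRUE, envir = seen)
          new_sets[[length(new_sets) + 1L]] <- u
        }
      }
    }
    all_sets <- c(all_sets, new_sets)
    frontier <- new_sets
  }
  pats <- vapply(all_sets, function(s) {
    p <- cc
    p[s] <- "X"
    paste(p, collapse = "")
  }, character(1))
  pats <- unique(pats)
  pats <- pats[order(nchar(gsub("[^X]", "", pats)), pats)]
  c(candidate, pats)
}

#' Pattern disorder statistics over 75 percent-identity clusters
#'
#' For one pattern, counts the disordered (U) and ordered (S) residues it
#' covers, weighted the two-level way: within each C75 cluster, per-chain
#' (u, s) counts over all residues covered by the pattern's matches (minus
#' any already-consumed residues) are averaged within C100 sub-clusters and
#' then across sub-clusters.  Summing the per-cluster means over all C75
#' clusters containing at least one match gives `n_u` and `n_f`;
#' `c_u`/`c_f` count the matched clusters whose mean is majority-disordered
#' (`u > s`) / not; `d = n_u - n_f` is the greedy selection score.
#'
#' @param pattern pattern string (letters + X).
#' @param records chain-record `data.frame`.
#' @param forest a [cluster_forest()] with levels 100 and `level`.
#' @param consumed optional named list (chain key -> logical vector) of
#'   residues already claimed by previously selected patterns; such residues
#'   are not counted.
#' @param level cluster level for the outer averaging (default 75).
#' @return list of class `pattern_stats`: `n_u`, `n_f`, `c_u`, `c_f`, `d`.
#' @export
pattern_stats <- function(pattern, records, forest, consumed = NULL,
                          level = 75) {
  validate_chain_records(records)
  groups <- forest_groups(records, forest, level)
  keys <- chain_key(records)
  cover <- lapply(seq_along(keys), function(i)
    match_coverage(pattern, records$sequence[i]))
  pattern_stats_from_coverage(cover, records, groups, keys, consumed)
}

# logical coverage vector of all matched positions of `pattern` in `sequence`
match_coverage <- function(pattern, sequence) {
  starts <- match_pattern(pattern, sequence)
  v <- logical(nchar(sequence))
  L <- nchar(pattern)
  for (s in starts) v[s:(s + L - 1L)] <- TRUE
  v
}

pattern_stats_from_coverage <- function(cover, records, groups, keys,
                                        consumed = NULL) {
  n_u <- 0; n_f <- 0; c_u <- 0L; c_f <- 0L
  for (cl in groups) {
    matched <- FALSE
    sub_means <- matrix(numeric(0), ncol = 2)
    for (sub in cl) {
      us <- t(vapply(sub, function(i) {
        cv <- cover[[i]]
        if (!any(cv)) return(c(0, 0))
        matched <<- TRUE
        if (!is.null(consumed)) {
          cs <- consumed[[keys[i]]]
          if (!is.null(cs)) cv <- cv & !cs
        }
        m <- seq_chars(records$mask[i])
        c(sum(cv & m == "U"), sum(cv & m == "S"))
      }, numeric(2)))
      sub_means <- rbind(sub_means, colMeans(us))
    }
    if (!matched) next
    cl_mean <- colMeans(sub_means)
    n_u <- n_u + cl_mean[1L]
    n_f <- n_f + cl_mean[2L]
    if (cl_mean[1L] > cl_mean[2L]) c_u <- c_u + 1L else c_f <- c_f + 1L
  }
  structure(list(n_u = unname(n_u), n_f = unname(n_f),
                 c_u = c_u, c_f = c_f, d = unname(n_u - n_f)),
            class = "pattern_stats")
}

#' @export
print.pattern_stats <- function(x, ...) {
  cat(sprintf("pattern stats: N_u = %.3f, N_f = %.3f, C_u = %d, C_f = %d, D = %.3f\n",
              x$n_u, x$n_f, x$c_u, x$c_f, x$d))
  invisible(x)
}

#' Greedy selection of a disordered pattern library
#'
#' Iteratively builds a non-redundant library from a candidate list.  Each
#' round, candidates are scored with [pattern_stats()] against the residues
#' not yet claimed and filtered by the three conditions
#' C1: `c_u >= c1_min`; C2: `c_u > c_f`; C3: `n_u > n_f`.
#' The surviving candidate with maximal `d = n_u - n_f` is selected (ties:
#' greater effective length, then lexicographically smaller pattern), all
#' residues covered by its matches are marked consumed, and scores are
#' recomputed.  The procedure stops when no candidate passes C1-C3; finally
#' only selections with `d >= d_min` are returned.
#'
#' Candidates that are themselves low-complexity — homo-repeats (one residue
#' type) or AC2-like (two non-X residue types) — are removed up front; they
#' belong to the separate homo-repeat and AC2 sets of the library.
#'
#' @param candidates character vector of patterns (letters + X).
#' @param records chain-record `data.frame`.
#' @param forest a [cluster_forest()] with levels 100 and `level`.
#' @param c1_min minimum number of majority-disordered clusters (C1).
#' @param d_min minimum final score `d` for the returned library; the
#'   default 25 equals five fully disordered five-residue occurrences in
#'   five clusters.
#' @param level outer cluster level (default 75).
#' @param drop_low_complexity drop homo-repeat/AC2-like candidates first.
#' @return `data.frame` of the selected library in selection order:
#'   `pattern`, `effective_length`, `n_u`, `n_f`, `c_u`, `c_f`, `d`.
#' @export
greedy_select <- function(candidates, records, forest, c1_min = 5L,
                          d_min = 25, level = 75,
                          drop_low_complexity = TRUE) {
  validate_chain_records(records)
  candidates <- unique(candidates)
  if (drop_low_complexity && length(candidates)) {
    ntypes <- vapply(candidates, function(p) {
      length(unique(setdiff(seq_chars(p), "X")))
    }, integer(1), USE.NAMES = FALSE)
    candidates <- candidates[ntypes > 2L]
  }
  empty <- data.frame(pattern = character(0), effective_length = integer(0),
                      n_u = numeric(0), n_f = numeric(0), c_u = integer(0),
                      c_f = integer(0), d = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(candidates)) return(empty)

  groups <- forest_groups(records, forest, level)
  keys <- chain_key(records)
  # match coverage never changes across iterations; cache it per candidate
  coverage <- lapply(candidates, function(p)
    lapply(seq_along(keys), function(i)
      match_coverage(p, records$sequence[i])))
  names(coverage) <- candidates

  consumed <- setNames(lapply(nchar(records$sequence), logical), keys)
  selected <- list()
  pool <- candidates
  while (length(pool)) {
    stats <- lapply(pool, function(p)
      pattern_stats_from_coverage(coverage[[p]], records, groups, keys,
                                  consumed))
    ok <- vapply(stats, function(s)
      s$c_u >= c1_min && s$c_u > s$c_f && s$n_u > s$n_f, logical(1))
    if (!any(ok)) break
    d <- vapply(stats, `[[`, numeric(1), "d")
    el <- effective_length(pool)
    cand_order <- order(-d, -el, pool)
    best <- cand_order[ok[cand_order]][1L]
    p <- pool[best]
    selected[[length(selected) + 1L]] <-
      data.frame(pattern = p, effective_length = el[best],
                 n_u = stats[[best]]$n_u, n_f = stats[[best]]$n_f,
                 c_u = stats[[best]]$c_u, c_f = stats[[best]]$c_f,
                 d = stats[[best]]$d, stringsAsFactors = FALSE)
    for (i in seq_along(keys))
      consumed[[keys[i]]] <- consumed[[keys[i]]] | coverage[[p]][[i]]
    pool <- pool[-best]
  }
  if (!length(selected)) return(empty)
  out <- do.call(rbind, selected)
  rownames(out) <- NULL
  out[out$d >= d_min, , drop = FALSE]
}

#' Proximity of pattern occurrences to histidine tags
#'
#' Artificial purification tags (His runs) are usually unresolved in crystal
#' structures and can masquerade as natural disordered patterns.  For each
#' occurrence of `pattern` in `records`, this checks whether a histidine run
#' of length at least `tag_min_run` lies within `window` residues
#' (fewer than `window` residues between occurrence and run).  `pc` is the
#' percentage of near-tag occurrences, binned as in the library summary:
#' PC = 0 (far), 0-33, 33-67, 67-100, PC = 100 (near).
#'
#' @param pattern pattern string (letters + X).
#' @param records chain-record `data.frame`.
#' @param tag_min_run minimum His-run length counting as a tag (default 4).
#' @param window maximum separation in residues (default 40, exclusive).
#' @return list with `pc` (percent, NA when the pattern never occurs),
#'   `n_occurrences`, and `bin` (label).
#' @export
histag_proximity <- function(pattern, records, tag_min_run = 4L,
                             window = 40L) {
  validate_chain_records(records)
  total <- 0L
  near <- 0L
  L <- nchar(pattern)
  for (i in seq_len(nrow(records))) {
    starts <- match_pattern(pattern, records$sequence[i])
    if (!length(starts)) next
    hr <- find_homorepeats(records$sequence[i], tag_min_run)
    hr <- hr[hr$aa == "H", , drop = FALSE]
    for (s in starts) {
      total <- total + 1L
      if (!nrow(hr)) next
      e <- s + L - 1L
      gap <- pmax(0L, pmax(hr$start - e, s - hr$end) - 1L)
      if (any(gap < window)) near <- near + 1L
    }
  }
  if (total == 0L)
    return(list(pc = NA_real_, n_occurrences = 0L, bin = "not_applicable"))
  pc <- 100 * near / total
  bin <- if (pc == 0) "PC = 0%"
  else if (pc < 33) "0% < PC < 33%"
  else if (pc <= 67) "33% <= PC <= 67%"
  else if (pc < 100) "67% < PC < 100%"
  else "PC = 100%"
  list(pc = pc, n_occurrences = total, bin = bin)
}
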