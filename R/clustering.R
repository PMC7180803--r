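# Nested identity clustering: C100 (byte-identical sequences) coarsened by
# single linkage at 75/50/25/5 percent identity.

#' Pairwise sequence identity
#'
#' Identity between two chains is defined over the optimal local alignment as
#' \deqn{Id = I / (L_1 + L_2 - I) \times 100}
#' where `I` is the number of identical aligned residue pairs and `L1`, `L2`
#' the full chain lengths.  The alignment is Smith-Waterman with BLOSUM62,
#' gap open 11 and gap extension 1 (the defaults of the standard protein
#' local-alignment search), so the measure is symmetric, deterministic, and
#' equals 100 exactly when the sequences are identical.
#'
#' @param seq_a,seq_b non-empty amino-acid strings.
#' @return identity in percent (0..100).
#' @examples
#' pairwise_identity(strrep("A", 10), strrep("A", 5))  # 50
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  stopifnot_scalar_string(seq_a, "seq_a")
  stopifnot_scalar_string(seq_b, "seq_b")
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("sequences must be non-empty", call. = FALSE)
  if (seq_a == seq_b) return(100)
  # co-optimal tracebacks can carry different identity counts; fixing the
  # argument order makes the measure symmetric and deterministic
  if (seq_a > seq_b) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  i <- alignment_identities(seq_a, seq_b)
  l1 <- nchar(seq_a)
  l2 <- nchar(seq_b)
  i / (l1 + l2 - i) * 100
}

# number of identical aligned pairs in the optimal local alignment of
# each element of `a` against the single subject `b`
alignment_identities <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  Biostrings::nmatch(aln)
}

# full pairwise identity matrix for a set of (distinct) sequences; each
# pair is aligned in canonical order, vectorising the alignments per subject
identity_matrix <- function(seqs) {
  n <- length(seqs)
  m <- diag(100, n)
  if (n < 2L) return(m)
  lens <- nchar(seqs)
  ord <- order(seqs)  # align smaller-ranked sequence as pattern
  for (jj in 2:n) {
    j <- ord[jj]
    prev <- ord[seq_len(jj - 1L)]
    i <- alignment_identities(seqs[prev], seqs[j])
    id <- i / (lens[prev] + lens[j] - i) * 100
    m[prev, j] <- id
    m[j, prev] <- id
  }
  m
}

#' Construct a cluster forest from explicit assignments
#'
#' A cluster forest is a nested partition of chains: one partition per
#' identity threshold, where every cluster at a stricter threshold lies
#' wholly inside one cluster at any looser threshold.
#'
#' @param assignment `data.frame` with a `chain` column (chain keys,
#'   `entry_chain`) and one integer column `C<level>` per level.
#' @param levels identity thresholds in percent, strictly decreasing.
#' @return an object of class `cluster_forest`.
#' @export
cluster_forest <- function(assignment, levels) {
  levels <- as.numeric(levels)
  if (any(diff(levels) >= 0))
    stop("levels must be strictly decreasing", call. = FALSE)
  cols <- paste0("C", levels)
  miss <- setdiff(c("chain", cols), names(assignment))
  if (length(miss))
    stop("assignment is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(assignment$chain))
    stop("duplicate chain keys in assignment", call. = FALSE)
  fo <- structure(list(levels = levels,
                       assignment = assignment[, c("chain", cols)]),
                  class = "cluster_forest")
  check_nesting(fo)
  fo
}

check_nesting <- function(forest) {
  lv <- forest$levels
  a <- forest$assignment
  if (length(lv) < 2L) return(invisible(TRUE))
  for (k in seq_len(length(lv) - 1L)) {
    fine <- a[[paste0("C", lv[k])]]
    coarse <- a[[paste0("C", lv[k + 1L])]]
    per <- tapply(coarse, fine, function(x) length(unique(x)))
    if (any(per > 1L))
      stop("nesting violated between levels ", lv[k], " and ", lv[k + 1L],
           call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.cluster_forest <- function(x, ...) {
  cat("cluster forest:", nrow(x$assignment), "chains at levels",
      paste(x$levels, collapse = "/"), "\n")
  print(cluster_summary(x))
  invisible(x)
}

#' Build the nested cluster hierarchy
#'
#' Chains with byte-identical sequences form the 100 percent clusters; each
#' coarser level merges clusters of the previous level by single linkage —
#' any cross-cluster pair of chains whose [pairwise_identity()] reaches the
#' threshold joins their clusters, applied transitively to a fixed point
#' (equivalently, connected components of the thresholded identity graph).
#'
#' @param records chain-record `data.frame`.
#' @param thresholds identity levels in percent, strictly decreasing, with
#'   100 first.
#' @return a [cluster_forest()] covering all chains in `records`.
#' @export
build_clusters <- function(records, thresholds = c(100, 75, 50, 25, 5)) {
  validate_chain_records(records)
  thresholds <- as.numeric(thresholds)
  if (thresholds[1L] != 100 || any(diff(thresholds) >= 0))
    stop("thresholds must start at 100 and be strictly decreasing",
         call. = FALSE)
  keys <- chain_key(records)
  useq <- unique(records$sequence)
  c100_of_chain <- match(records$sequence, useq)

  assignment <- data.frame(chain = keys, stringsAsFactors = FALSE)
  assignment$C100 <- relabel_first_occurrence(c100_of_chain)

  if (length(thresholds) > 1L) {
    idm <- identity_matrix(useq)
    for (t in thresholds[-1L]) {
      adj <- idm >= t
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                               diag = FALSE)
      comp <- igraph::components(g)$membership
      assignment[[paste0("C", t)]] <-
        relabel_first_occurrence(comp[c100_of_chain])
    }
  }
  cluster_forest(assignment, thresholds)
}

# renumber cluster ids 1,2,... in order of first occurrence (deterministic)
relabel_first_occurrence <- function(ids) {
  match(ids, unique(ids))
}

#' Cluster counts per identity level
#'
#' @param forest a [cluster_forest()].
#' @return `data.frame` with one row per level: `level`, `n_clusters`,
#'   `mean_size` (mean number of chains per cluster).
#' @export
cluster_summary <- function(forest) {
  stopifnot(inherits(forest, "cluster_forest"))
  a <- forest$assignment
  do.call(rbind, lapply(forest$levels, function(lv) {
    ids <- a[[paste0("C", lv)]]
    data.frame(level = lv,
               n_clusters = length(unique(ids)),
               mean_size = nrow(a) / length(unique(ids)))
  }))
}

#' Write a cluster forest as TSV
#'
#' @param forest a [cluster_forest()].
#' @param file output path or `NULL` for the text.
#' @return TSV text, invisibly if written to file.
#' @export
write_cluster_table <- function(forest, file = NULL) {
  stopifnot(inherits(forest, "cluster_forest"))
  con <- textConnection("txt", "w", local = TRUE)
  write.table(forest$assignment, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  text <- paste0(paste(txt, collapse = "\n"), "\n")
  if (is.null(file)) return(text)
  writeLines(txt, file)
  invisible(text)
}
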