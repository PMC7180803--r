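# Two-level cluster-weighted disorder statistics.
#
# Redundancy in a structure database is extreme: the same protein may be
# deposited dozens of times.  To keep statistics from being dominated by
# popular proteins, counts are first averaged within groups of identical
# sequences (C100) and then averaged across those groups within each 75
# percent-identity cluster, so each C75 cluster contributes one weight.

#' Two-level weighted average of (unstructured, structured) counts
#'
#' `groups` holds the per-chain counts of one C75 cluster, split by C100
#' sub-cluster: each element is one sub-cluster, a two-column matrix (or
#' data.frame, or list of length-2 vectors) of per-chain (u, s) counts.
#' The result is the unweighted mean over sub-clusters of the per-sub-cluster
#' unweighted means.
#'
#' @param groups non-empty list of per-sub-cluster (u, s) count sets.
#' @return named numeric vector `c(u = ..., s = ...)`; values may be
#'   fractional.
#' @examples
#' two_level_average(list(rbind(c(23, 8), c(24, 7), c(31, 0), c(31, 0)),
#'                        rbind(c(8, 0), c(6, 2))))   # u = 17.125, s = 2.375
#' @export
two_level_average <- function(groups) {
  if (!is.list(groups) || length(groups) == 0L)
    stop("groups must be a non-empty list of (u, s) count sets",
         call. = FALSE)
  group_means <- vapply(groups, function(g) {
    m <- as_us_matrix(g)
    if (nrow(m) == 0L)
      stop("each group must contain at least one chain", call. = FALSE)
    colMeans(m)
  }, numeric(2))
  out <- rowMeans(group_means)
  names(out) <- c("u", "s")
  out
}

as_us_matrix <- function(g) {
  if (is.data.frame(g)) g <- as.matrix(g)
  if (is.list(g)) g <- do.call(rbind, g)
  if (is.numeric(g) && is.null(dim(g))) g <- matrix(g, ncol = 2, byrow = TRUE)
  if (!is.matrix(g) || ncol(g) != 2L)
    stop("each group must reduce to a two-column (u, s) matrix",
         call. = FALSE)
  storage.mode(g) <- "double"
  if (any(g < 0)) stop("counts must be non-negative", call. = FALSE)
  g
}

#' Label residues as N-terminal, middle or C-terminal
#'
#' A maximal disordered run (consecutive U) that touches the first residue
#' defines the N-terminal region; a maximal U-run touching the last residue
#' defines the C-terminal region; every other residue — including all
#' structured residues — is middle.  A fully disordered chain is assigned
#' N-terminal as a whole (deterministic tie-break).
#'
#' @param mask U/S mask string.
#' @return character vector (one label per residue) over
#'   `"nterm"`, `"middle"`, `"cterm"`.
#' @export
classify_regions <- function(mask) {
  stopifnot_scalar_string(mask, "mask")
  ch <- seq_chars(mask)
  n <- length(ch)
  out <- rep("middle", n)
  if (ch[1L] == "U") {
    r <- rle(ch)
    k <- r$lengths[1L]
    out[seq_len(k)] <- "nterm"
    if (k == n) return(out)  # fully disordered: all N-terminal
  }
  if (ch[n] == "U") {
    r <- rle(rev(ch))
    k <- r$lengths[1L]
    out[(n - k + 1L):n] <- "cterm"
  }
  out
}

#' Positional disorder frequencies per amino acid
#'
#' For each of the 20 amino acids and each region (N-terminal, middle,
#' C-terminal, per [classify_regions()]), computes the cluster-weighted
#' disorder frequency at the given identity level: counts of disordered
#' residues and of all residues of that type/region are averaged within C100
#' sub-clusters, then within each level-`level` cluster, summed over
#' clusters, and the frequency is their ratio.
#'
#' @param records chain-record `data.frame`.
#' @param forest a [cluster_forest()] covering all chains of `records`.
#' @param level identity level (percent) to weight at; must be present in
#'   `forest` along with level 100.
#' @return `data.frame` with columns `aa`, `region`, `weighted_u`,
#'   `weighted_total`, `frequency` (NA where no residue of that type/region
#'   occurs).
#' @export
positional_disorder_frequencies <- function(records, forest, level = 75) {
  validate_chain_records(records)
  groups <- forest_groups(records, forest, level)
  regions <- c("nterm", "middle", "cterm")
  dims <- c(length(AA20), length(regions))
  tot_u <- array(0, dims)
  tot_n <- array(0, dims)

  per_chain <- function(i) {
    s <- factor(seq_chars(records$sequence[i]), levels = AA20)
    m <- seq_chars(records$mask[i])
    r <- factor(classify_regions(records$mask[i]), levels = regions)
    list(u = table(s[m == "U"], r[m == "U"]), n = table(s, r))
  }

  for (cl in groups) {
    cl_u <- array(0, dims); cl_n <- array(0, dims)
    for (sub in cl) {
      sub_u <- array(0, dims); sub_n <- array(0, dims)
      for (i in sub) {
        counts <- per_chain(i)
        sub_u <- sub_u + unclass(counts$u)
        sub_n <- sub_n + unclass(counts$n)
      }
      cl_u <- cl_u + sub_u / length(sub)
      cl_n <- cl_n + sub_n / length(sub)
    }
    tot_u <- tot_u + cl_u / length(cl)
    tot_n <- tot_n + cl_n / length(cl)
  }

  out <- data.frame(aa = rep(AA20, times = length(regions)),
                    region = rep(regions, each = length(AA20)),
                    weighted_u = as.vector(tot_u),
                    weighted_total = as.vector(tot_n),
                    stringsAsFactors = FALSE)
  out$frequency <- ifelse(out$weighted_total > 0,
                          out$weighted_u / out$weighted_total, NA_real_)
  out
}

# nested grouping of record row indices: level cluster -> C100 sub-cluster
forest_groups <- function(records, forest, level) {
  col <- paste0("C", level)
  if (!col %in% names(forest$assignment))
    stop("level ", level, " is not present in the cluster forest",
         call. = FALSE)
  if (!"C100" %in% names(forest$assignment))
    stop("cluster forest must include level 100", call. = FALSE)
  keys <- chain_key(records)
  idx <- match(keys, forest$assignment$chain)
  if (anyNA(idx))
    stop("cluster forest does not cover chain(s): ",
         paste(head(keys[is.na(idx)], 5L), collapse = ", "), call. = FALSE)
  lv <- forest$assignment[[col]][idx]
  c100 <- forest$assignment$C100[idx]
  lapply(split(seq_along(keys), lv),
         function(rows) unname(split(rows, c100[rows])))
}
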