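# Synthetic fixtures: toy PDB entries with controlled missing residues,
# mutated chain families with known pairwise identity, and planted
# disordered motifs with ground truth, so every pipeline stage can be
# tested without external data.

#' Build a synthetic PDB-format entry
#'
#' Emits SEQRES records for the full sequence, CA-only ATOM records for
#' resolved residues, and REMARK 465 lines for the missing intervals, plus
#' HEADER/EXPDTA/REMARK 2 so [parse_entry()] recovers entry id, method and
#' resolution.  Parsing the output yields exactly the intended U/S mask.
#'
#' @param sequence amino-acid string (one-letter codes, no X).
#' @param missing_intervals list of `c(start, end)` 1-based inclusive
#'   intervals of residues without coordinates.
#' @param entry_id 4-character entry id.
#' @param chain_id chain label.
#' @param resolution reported resolution in Angstrom.
#' @param method EXPDTA method string.
#' @param extra_chains optional list of further chain specs, each a list
#'   with elements `sequence` (or `codes`, explicit three-letter codes),
#'   `chain_id`, and optional `missing_intervals` — used e.g. to add a
#'   nucleic-acid chain.
#' @return the PDB-format text as a single string.
#' @export
make_pdb_fixture <- function(sequence, missing_intervals = list(),
                             entry_id = "SYN1", chain_id = "A",
                             resolution = 2.0,
                             method = "X-RAY DIFFRACTION",
                             extra_chains = list()) {
  chains <- c(list(list(sequence = sequence, chain_id = chain_id,
                        missing_intervals = missing_intervals)),
              extra_chains)
  lines <- c(
    sprintf("%-62s%4s", "HEADER    SYNTHETIC FIXTURE          01-JAN-20",
            entry_id),
    sprintf("EXPDTA    %s", method),
    sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution),
    "REMARK 465 MISSING RESIDUES",
    "REMARK 465   M RES C SSSEQI")

  seqres_lines <- character(0)
  remark465 <- character(0)
  atoms <- character(0)
  serial <- 0L
  for (cs in chains) {
    codes <- if (!is.null(cs$codes)) cs$codes else {
      one <- seq_chars(toupper(cs$sequence))
      unknown <- setdiff(one, names(AA_ONE_TO_THREE))
      if (length(unknown))
        stop("no three-letter code for: ", paste(unknown, collapse = ", "),
             call. = FALSE)
      unname(AA_ONE_TO_THREE[one])
    }
    n <- length(codes)
    miss <- logical(n)
    for (iv in (cs$missing_intervals %||% list())) {
      if (iv[1L] < 1L || iv[2L] > n || iv[1L] > iv[2L])
        stop("invalid missing interval for chain ", cs$chain_id,
             call. = FALSE)
      miss[iv[1L]:iv[2L]] <- TRUE
    }
    for (k in seq_len(ceiling(n / 13))) {
      sel <- ((k - 1L) * 13L + 1L):min(k * 13L, n)
      seqres_lines <- c(seqres_lines,
                        sprintf("SEQRES %3d %s %4d  %s", k, cs$chain_id, n,
                                paste(codes[sel], collapse = " ")))
    }
    for (i in which(miss))
      remark465 <- c(remark465,
                     sprintf("REMARK 465     %3s %s %5d", codes[i],
                             cs$chain_id, i))
    for (i in which(!miss)) {
      serial <- serial + 1L
      atoms <- c(atoms, sprintf(
        "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, codes[i], cs$chain_id, i, i * 3.8, 0, 0, 1.0, 20.0))
    }
  }
  paste(c(lines, remark465, seqres_lines, atoms, "END"), collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a family of mutated sequences at a target identity
#'
#' Produces `n` copies of `base_sequence`, each carrying point substitutions
#' at its own disjoint set of interior positions, sized so that every pair
#' of members has [pairwise_identity()] within about 3 percentage points of
#' `target_identity`.  With disjoint mutation sets of size `k`, two members
#' share `L - 2k` identical positions, giving
#' `Id = (L - 2k) / (L + 2k) x 100`; `k` is chosen accordingly.
#' Deterministic under `seed`.
#'
#' @param base_sequence amino-acid string.
#' @param n number of family members (>= 1).
#' @param target_identity target pairwise identity in percent (0..100].
#' @param seed integer seed.
#' @return character vector of `n` sequences.
#' @export
make_family <- function(base_sequence, n, target_identity, seed = 1L) {
  stopifnot_scalar_string(base_sequence, "base_sequence")
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (target_identity <= 0 || target_identity > 100)
    stop("target_identity must be in (0, 100]", call. = FALSE)
  if (target_identity == 100) return(rep(base_sequence, n))
  L <- nchar(base_sequence)
  t <- target_identity
  k <- max(1L, round(L * (100 - t) / (2 * (100 + t))))
  interior <- 3:(L - 2L)
  if (n * k > length(interior))
    stop("base sequence too short for ", n, " members at identity ", t,
         call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pos <- sample(interior, n * k)
  base <- seq_chars(base_sequence)
  out <- character(n)
  for (m in seq_len(n)) {
    p <- pos[((m - 1L) * k + 1L):(m * k)]
    s <- base
    for (i in p) s[i] <- sample(setdiff(AA20, s[i]), 1L)
    out[m] <- paste(s, collapse = "")
  }
  out
}

#' Plant disordered motifs into synthetic clusters
#'
#' Builds a synthetic chain set with known ground truth for testing the
#' mining stage: each motif is inserted into the chains of `n_clusters`
#' distinct 75 percent-identity clusters (each cluster one C100 group of
#' `chains_per_cluster` identical chains on its own random background).
#' Background residues are structured (S); planted motif residues are
#' disordered (U) when the motif is flagged `disordered`.
#'
#' @param motifs list of motif specs, each a list with `letters` (the motif
#'   string), `n_clusters` (number of clusters to plant it in), and
#'   optionally `disordered` (default `TRUE`).
#' @param chains_per_cluster identical chains per cluster (default 1).
#' @param background_length background chain length before insertion.
#' @param seed integer seed; fixtures are byte-reproducible under it.
#' @return list: `records` (chain table), `forest` ([cluster_forest()] with
#'   levels 100 and 75, one cluster per planted group), and `truth`
#'   (`data.frame` of planted placements: `pattern`, `entry`, `chain`,
#'   `start`, `end`, `disordered`).
#' @export
plant_motifs <- function(motifs, chains_per_cluster = 1L,
                         background_length = 60L, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  entry <- character(0); chain <- character(0)
  sequence <- character(0); mask <- character(0)
  c100 <- integer(0); c75 <- integer(0)
  truth <- list()
  cluster_id <- 0L
  ent <- 0L
  for (mo in motifs) {
    m <- toupper(mo$letters)
    Lm <- nchar(m)
    dis <- mo$disordered %||% TRUE
    for (cl in seq_len(mo$n_clusters)) {
      cluster_id <- cluster_id + 1L
      bg <- paste(sample(AA20, background_length, replace = TRUE),
                  collapse = "")
      at <- sample(10:(background_length - 10L), 1L)
      seqs <- paste0(substr(bg, 1L, at - 1L), m,
                     substr(bg, at, background_length))
      msk <- paste0(strrep("S", at - 1L),
                    strrep(if (dis) "U" else "S", Lm),
                    strrep("S", background_length - at + 1L))
      for (ch_i in seq_len(chains_per_cluster)) {
        ent <- ent + 1L
        eid <- sprintf("S%03d", ent)
        entry <- c(entry, eid); chain <- c(chain, "A")
        sequence <- c(sequence, seqs); mask <- c(mask, msk)
        c100 <- c(c100, cluster_id); c75 <- c(c75, cluster_id)
        truth[[length(truth) + 1L]] <-
          data.frame(pattern = m, entry = eid, chain = "A", start = at,
                     end = at + Lm - 1L, disordered = dis,
                     stringsAsFactors = FALSE)
      }
    }
  }
  records <- chain_records(entry, chain, sequence, mask,
                           method = "x-ray", resolution = 2.0)
  forest <- cluster_forest(
    data.frame(chain = chain_key(records), C100 = c100, C75 = c75,
               stringsAsFactors = FALSE),
    levels = c(100, 75))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(pattern = character(0), entry = character(0),
               chain = character(0), start = integer(0), end = integer(0),
               disordered = logical(0), stringsAsFactors = FALSE)
  list(records = records, forest = forest, truth = truth)
}
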