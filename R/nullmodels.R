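# Null models: expected pattern occurrence counts in large sequence sets
# and the random-proteome generator.

#' Summarise a proteome sequence set
#'
#' @param sequences character vector of amino-acid sequences (a proteome).
#' @return list of class `proteome_summary`: `n_res` (total residues),
#'   `n_prot` (number of proteins), `freqs` (amino-acid frequencies over the
#'   20 canonical letters, renormalised to exclude X), `lengths`
#'   (per-protein lengths).
#' @export
proteome_summary <- function(sequences) {
  if (!length(sequences)) stop("empty proteome", call. = FALSE)
  lengths <- nchar(sequences)
  counts <- table(factor(unlist(strsplit(sequences, "", fixed = TRUE)),
                         levels = AA20))
  freqs <- as.numeric(counts) / sum(counts)
  structure(list(n_res = sum(lengths), n_prot = length(sequences),
                 freqs = setNames(freqs, AA20), lengths = lengths),
            class = "proteome_summary")
}

#' Expected number of pattern occurrences in a residue corpus
#'
#' Under a null model of independently drawn residues, a pattern with
#' effective (non-X) length `L` is expected at
#' \deqn{N_o \approx n_{res} \cdot (1/20)^L}
#' positions under uniform frequencies, or, accounting for the real
#' amino-acid frequencies, `n_res` times the product of the frequencies of
#' its non-X letters.
#'
#' @param pattern pattern string (letters + X).
#' @param summary a [proteome_summary()], or a single number taken as
#'   `n_res` (only valid with `uniform = TRUE`).
#' @param uniform if `TRUE`, use the uniform 1/20 frequency for every
#'   position; otherwise use `summary$freqs`.
#' @return expected occurrence count `N_o`.
#' @examples
#' expected_count("QQQQQ", 6.3e8)  # about 200 for effective length 5
#' @export
expected_count <- function(pattern, summary, uniform = TRUE) {
  stopifnot_scalar_string(pattern, "pattern")
  letters <- seq_chars(pattern)
  letters <- letters[letters != "X"]
  if (is.numeric(summary) && length(summary) == 1L) {
    if (!uniform)
      stop("frequency mode needs a proteome_summary, not a residue count",
           call. = FALSE)
    n_res <- summary
  } else {
    stopifnot(inherits(summary, "proteome_summary"))
    n_res <- summary$n_res
  }
  if (uniform) return(n_res * (1 / 20)^length(letters))
  n_res * prod(summary$freqs[letters])
}

#' Count pattern occurrences in a proteome
#'
#' @param pattern pattern string (letters + X).
#' @param sequences character vector of sequences.
#' @return list: `occurrences` (total match positions, overlapping matches
#'   counted) and `n_p` (number of sequences with at least one match).
#' @export
count_in_proteome <- function(pattern, sequences) {
  hits <- vapply(sequences, function(s) length(match_pattern(pattern, s)),
                 integer(1), USE.NAMES = FALSE)
  list(occurrences = sum(hits), n_p = sum(hits > 0L))
}

#' Generate a random proteome
#'
#' One random sequence per requested length, residues drawn independently
#' from `freqs` (uniform over the 20 amino acids by default) with R's
#' Mersenne-Twister generator under the given seed, so output is
#' reproducible byte-for-byte.
#'
#' @param lengths integer vector of sequence lengths (the real proteome's
#'   length list, typically).
#' @param freqs named amino-acid frequency vector, or `NULL` for uniform.
#' @param seed integer seed.
#' @return character vector of sequences.
#' @export
random_proteome <- function(lengths, freqs = NULL, seed = 1L) {
  lengths <- as.integer(lengths)
  if (any(is.na(lengths) | lengths < 0L))
    stop("lengths must be non-negative", call. = FALSE)
  if (is.null(freqs)) freqs <- setNames(rep(1 / 20, 20), AA20)
  p <- as.numeric(freqs[AA20])
  if (anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("freqs must cover the 20 amino acids and sum to 1", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draw <- sample(AA20, sum(lengths), replace = TRUE, prob = p)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  big <- paste(draw, collapse = "")
  substring(big, starts, ends)
}
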