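# Low-complexity analysis: AC2 segments (exactly two amino-acid types),
# homo-repeats, binary-template classification, and closed-form null
# probabilities for random sequences.

#' Find maximal AC2 segments
#'
#' An AC2 segment is a stretch whose residue set is exactly two amino-acid
#' types (e.g. `GSGSGSGSGSSG`).  All maximal such segments of length at least
#' `min_length` are reported; maximality means the segment cannot be extended
#' by one residue on either side without introducing a third type.  Segments
#' built from different pairs may overlap and are all reported.  Unknown
#' residues (X) break segments.
#'
#' Each segment carries its binary template — residues re-encoded over
#' \{0, 1\} with the first-seen type mapped to 0 — and the template's group
#' per [classify_ac2()].
#'
#' @param sequence amino-acid string.
#' @param min_length minimum segment length (>= 2); the library default is 8,
#'   the length at which such segments switch to being mostly disordered.
#' @return `data.frame` with columns `start`, `end` (1-based inclusive),
#'   `pair` (the two letters, sorted, pasted), `template`, `group`.
#' @examples
#' find_ac2_runs("GSGSGSGSGSSG")  # one {G,S} run covering the whole string
#' @export
find_ac2_runs <- function(sequence, min_length = 8L) {
  stopifnot_scalar_string(sequence, "sequence")
  if (min_length < 2L) stop("min_length must be >= 2", call. = FALSE)
  ch <- seq_chars(sequence)
  runs <- list()
  # process each X-free stretch independently
  breaks <- c(0L, which(ch == "X"), length(ch) + 1L)
  for (b in seq_len(length(breaks) - 1L)) {
    lo <- breaks[b] + 1L
    hi <- breaks[b + 1L] - 1L
    if (hi - lo + 1L < min_length) next
    runs <- c(runs, ac2_in_segment(ch, lo, hi, min_length))
  }
  if (!length(runs))
    return(data.frame(start = integer(0), end = integer(0),
                      pair = character(0), template = character(0),
                      group = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  out
}

# maximal exactly-two-type runs inside ch[lo..hi] (no X inside).
# works on the run-length encoding: adjacent rle values always differ, so a
# window of rle runs has exactly two types iff it spans >= 2 runs and its
# value set is {a, b}; two-pointer gives the maximal right extension.
ac2_in_segment <- function(ch, lo, hi, min_length) {
  r <- rle(ch[lo:hi])
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(v)
  out <- list()
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    if (j == i && j < n) j <- i + 1L       # need two runs for two types
    if (j <= i) break                       # single run only
    a <- v[i]; b <- v[i + 1L]
    # re-derive the pair for this window start, then extend
    while (j + 1L <= n && (v[j + 1L] == a || v[j + 1L] == b)) j <- j + 1L
    # left-maximal? (previous run's letter would have to be a third type)
    left_ok <- i == 1L || !(v[i - 1L] %in% c(a, b))
    len <- ends[j] - starts[i] + 1L
    if (left_ok && len >= min_length) {
      s0 <- lo + starts[i] - 1L
      e0 <- lo + ends[j] - 1L
      seg <- ch[s0:e0]
      out[[length(out) + 1L]] <- data.frame(
        start = s0, end = e0,
        pair = paste(sort(c(a, b)), collapse = ""),
        template = paste(ifelse(seg == seg[1L], "0", "1"), collapse = ""),
        group = classify_ac2(paste(ifelse(seg == seg[1L], "0", "1"),
                                   collapse = "")),
        stringsAsFactors = FALSE)
    }
  }
  out
}

#' Find homo-repeats
#'
#' Maximal runs of a single repeated amino acid of length at least
#' `min_length`.  X runs are not reported.
#'
#' @param sequence amino-acid string.
#' @param min_length minimum run length.
#' @return `data.frame` with columns `start`, `end` (1-based inclusive),
#'   `aa`, `length`.
#' @export
find_homorepeats <- function(sequence, min_length = 4L) {
  stopifnot_scalar_string(sequence, "sequence")
  ch <- seq_chars(sequence)
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_length & r$values != "X"
  data.frame(start = starts[keep], end = ends[keep],
             aa = r$values[keep], length = r$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Classify an AC2 binary template
#'
#' Templates (segments re-encoded over \{0, 1\}) fall into three groups:
#'
#' * `homo_adjacent` — a homo-repeat with one adjacent single residue of the
#'   other type: one symbol occurs exactly once, at either terminus
#'   (`01111111`, `10000000`).
#' * `internal_repeat` — a whole or truncated repetition of a word of period
#'   2 or 4 (`01010101`, `00010001`, `00110011`, ...): the template satisfies
#'   `t[i] == t[i + p]` for `p` in \{2, 4\} at every position.  Period-3
#'   templates such as `00100100` deliberately fall through to `other`.
#' * `other` — everything else.
#'
#' `homo_adjacent` takes precedence over `internal_repeat`.
#'
#' @param template binary string over \{0, 1\} containing both symbols.
#' @return one of `"homo_adjacent"`, `"internal_repeat"`, `"other"`.
#' @export
classify_ac2 <- function(template) {
  stopifnot_scalar_string(template, "template")
  t <- seq_chars(template)
  n <- length(t)
  if (!all(t %in% c("0", "1")) || length(unique(t)) != 2L)
    stop("template must be a binary string containing both 0 and 1",
         call. = FALSE)
  n0 <- sum(t == "0")
  minority <- if (n0 <= n - n0) "0" else "1"
  if (sum(t == minority) == 1L) {
    pos <- which(t == minority)
    if (pos == 1L || pos == n) return("homo_adjacent")
  }
  for (p in c(2L, 4L)) {
    if (n > p && all(t[seq_len(n - p)] == t[seq_len(n - p) + p]))
      return("internal_repeat")
  }
  "other"
}

#' Probability that a random sequence uses exactly two amino-acid types
#'
#' For a random sequence of length `L` with residues drawn independently
#' with frequencies `p`, the probability of consisting of exactly two types
#' is, by inclusion-exclusion over unordered pairs,
#' \deqn{P_{AC2}(L) = \sum_{i<j} ((p_i + p_j)^L - p_i^L - p_j^L).}
#'
#' @param L sequence length (>= 1).
#' @param freqs named numeric vector of amino-acid frequencies (non-negative,
#'   summing to 1 within 1e-9).
#' @return the probability.
#' @seealso [prob_ac2_uniform()] for the equal-frequency closed form.
#' @export
prob_ac2 <- function(L, freqs) {
  if (!is.numeric(L) || length(L) != 1L || L < 1)
    stop("L must be a single length >= 1", call. = FALSE)
  p <- as.numeric(freqs)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("freqs must be non-negative and sum to 1", call. = FALSE)
  if (length(p) < 2L) return(0)
  pairs <- combn(length(p), 2L)
  pi <- p[pairs[1L, ]]
  pj <- p[pairs[2L, ]]
  sum((pi + pj)^L - pi^L - pj^L)
}

#' Uniform-frequency AC2 probability
#'
#' With all 20 amino acids at frequency 0.05 the pair sum collapses to
#' \deqn{\tilde P_{AC2}(L) = 190 (0.1^L - 2 \cdot 0.05^L).}
#'
#' @param L sequence length (>= 1).
#' @return the probability; 0 at `L = 1`, about 2e-6 at `L = 8`.
#' @export
prob_ac2_uniform <- function(L) {
  if (!is.numeric(L) || any(L < 1))
    stop("L must be >= 1", call. = FALSE)
  190 * (0.1^L - 2 * 0.05^L)
}
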