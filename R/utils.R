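# Shared constants and small helpers.

#' The 20 canonical amino acids (one-letter codes)
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# three-letter <-> one-letter residue code tables
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA_ONE_TO_THREE <- setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

#' Round half away from zero
#'
#' Fixed-point rounding in which ties go up (2.375 -> 2.38 at two decimals),
#' matching how the summary tables round reported means.  Base `round()` uses
#' round-half-to-even and would give 2.37 surprises in printed output.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(17.125, 2)  # 17.13
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# chain key used to join chain tables with cluster assignments
chain_key <- function(records) paste(records$entry, records$chain, sep = "_")

# split a sequence string into single characters
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
}
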