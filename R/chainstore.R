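# Chain store: disorder annotation from PDB-format text and the chain table.
#
# A "chain record" is one row of a data.frame with columns
#   entry      4-character structure accession
#   chain      chain label
#   sequence   uppercase amino acids (20 letters + X for unknown residues)
#   mask       same length as sequence, over {U, S}: U = unstructured
#              (no resolved coordinates), S = structured
#   method     experimental method label ("x-ray", "nmr", ...)
#   resolution resolution in Angstrom (NA for non-diffraction methods)

#' Construct a validated chain-record table
#'
#' @param entry,chain,sequence,mask,method,resolution parallel vectors, one
#'   element per chain.  `mask` must have the same length as `sequence`
#'   row-wise and use only the letters U and S.
#' @return a `data.frame` with one row per chain.
#' @export
chain_records <- function(entry, chain, sequence, mask,
                          method = "x-ray", resolution = NA_real_) {
  n <- length(entry)
  df <- data.frame(entry = as.character(entry),
                   chain = as.character(chain),
                   sequence = toupper(as.character(sequence)),
                   mask = toupper(as.character(mask)),
                   method = rep_len(as.character(method), n),
                   resolution = rep_len(as.numeric(resolution), n),
                   stringsAsFactors = FALSE)
  validate_chain_records(df)
  df
}

validate_chain_records <- function(df) {
  need <- c("entry", "chain", "sequence", "mask", "method", "resolution")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("chain table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_len <- which(nchar(df$sequence) != nchar(df$mask))
  if (length(bad_len))
    stop("sequence/mask length mismatch in row(s) ",
         paste(bad_len, collapse = ", "), call. = FALSE)
  if (any(nchar(df$sequence) == 0L))
    stop("empty sequence in row(s) ",
         paste(which(nchar(df$sequence) == 0L), collapse = ", "),
         call. = FALSE)
  bad_seq <- grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), df$sequence)
  if (any(bad_seq))
    stop("sequence contains letters outside the 20 amino acids + X in row(s) ",
         paste(which(bad_seq), collapse = ", "), call. = FALSE)
  bad_mask <- grepl("[^US]", df$mask)
  if (any(bad_mask))
    stop("mask contains letters other than U/S in row(s) ",
         paste(which(bad_mask), collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Parse a PDB-format entry into chain records with disorder masks
#'
#' The full sequence of each chain is taken from its SEQRES records; a residue
#' is labelled U (unstructured) when it appears in the full sequence but has
#' no resolved coordinates — i.e. it is listed under REMARK 465 (missing
#' residues) or is absent from the ATOM records — and S otherwise.  Modified
#' residues are mapped to their parent amino acid through MODRES records when
#' present, else to X.  Chains whose SEQRES residues are not mostly amino
#' acids (nucleic-acid chains) are skipped.
#'
#' When a chain has coordinates but no SEQRES records, the sequence is
#' reconstructed from the ATOM records (all residues S) with a warning.  If
#' the residue numbering of ATOM + REMARK 465 does not add up to the SEQRES
#' length, the mask falls back to assuming numbering 1..L and a warning
#' reports the mismatch.
#'
#' @param structure_text PDB-format text: a single string or a character
#'   vector of lines.  SEQRES, ATOM/HETATM, REMARK 465, MODRES, EXPDTA and
#'   REMARK 2 RESOLUTION records are honoured.
#' @return a chain-record `data.frame` (see [chain_records()]), one row per
#'   protein chain.
#' @seealso [make_pdb_fixture()] for generating synthetic entries.
#' @export
parse_entry <- function(structure_text) {
  lines <- if (length(structure_text) == 1L && grepl("\n", structure_text))
    strsplit(structure_text, "\n", fixed = TRUE)[[1]] else structure_text
  rec <- substr(lines, 1L, 6L)

  entry_id <- "XXXX"
  hdr <- which(rec == "HEADER")
  if (length(hdr)) {
    id <- trimws(substr(lines[hdr[1L]], 63L, 66L))
    if (nzchar(id)) entry_id <- id
  }

  method <- NA_character_
  exp <- which(rec == "EXPDTA")
  if (length(exp)) {
    lab <- toupper(lines[exp[1L]])
    method <- if (grepl("X-RAY", lab)) "x-ray"
    else if (grepl("NMR", lab)) "nmr"
    else if (grepl("ELECTRON MICROSCOPY", lab)) "em"
    else tolower(trimws(substr(lines[exp[1L]], 11L, 79L)))
  }

  resolution <- NA_real_
  rem2 <- lines[rec == "REMARK" & grepl("^REMARK   2 RESOLUTION", lines)]
  if (length(rem2)) {
    m <- regmatches(rem2[1L],
                    regexec("RESOLUTION\\.\\s+([0-9]+\\.?[0-9]*)\\s+ANGSTROM",
                            rem2[1L]))[[1L]]
    if (length(m) == 2L) resolution <- as.numeric(m[2L])
  }

  # MODRES: modified residue name -> standard three-letter parent
  modres_map <- character(0)
  for (ln in lines[rec == "MODRES"]) {
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    # MODRES idCode resName chain seqNum stdRes ...
    if (length(toks) >= 6L) modres_map[toks[3L]] <- toks[6L]
  }

  translate3 <- function(codes) {
    mapped <- ifelse(codes %in% names(modres_map), modres_map[codes], codes)
    out <- unname(AA_THREE_TO_ONE[mapped])
    known <- !is.na(out)
    out[!known] <- "X"
    list(one = out, known = known)
  }

  # SEQRES: per-chain three-letter code lists
  seqres <- list()
  for (i in which(rec == "SEQRES")) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(toks) < 5L)
      stop("malformed SEQRES record at line ", i, call. = FALSE)
    ch <- toks[3L]
    seqres[[ch]] <- c(seqres[[ch]], toks[-(1:4)])
  }

  # ATOM/HETATM: resolved residue numbers per chain (any atom counts)
  resolved <- list()   # chain -> named character: names = resSeq, values = resName
  for (i in which(rec == "ATOM  " | rec == "HETATM")) {
    ln <- lines[i]
    if (nchar(ln) < 26L)
      stop("malformed coordinate record at line ", i, call. = FALSE)
    res3 <- trimws(substr(ln, 18L, 20L))
    ch <- substr(ln, 22L, 22L)
    num <- suppressWarnings(as.integer(trimws(substr(ln, 23L, 26L))))
    if (is.na(num))
      stop("malformed residue number in coordinate record at line ", i,
           call. = FALSE)
    if (rec[i] == "HETATM" && !(res3 %in% names(modres_map)) &&
        !(res3 %in% names(AA_THREE_TO_ONE)))
      next  # ligand/solvent
    key <- as.character(num)
    if (is.null(resolved[[ch]])) resolved[[ch]] <- character(0)
    if (!key %in% names(resolved[[ch]])) resolved[[ch]][key] <- res3
  }

  # REMARK 465: missing residues (resName chain seqNum)
  missing <- list()    # chain -> integer residue numbers
  for (ln in lines[grepl("^REMARK 465", lines)]) {
    body <- trimws(substr(ln, 11L, nchar(ln)))
    m <- regmatches(body,
                    regexec("^([A-Z]{3})\\s+([0-9A-Za-z])\\s+(-?[0-9]+)$",
                            body))[[1L]]
    if (length(m) == 4L) {
      ch <- m[3L]
      missing[[ch]] <- c(missing[[ch]], as.integer(m[4L]))
    }
  }

  out <- list()
  chains <- union(names(seqres), names(resolved))
  for (ch in chains) {
    if (is.null(seqres[[ch]])) {
      # coordinates but no declared full sequence
      warning("chain ", ch, " has coordinates but no SEQRES records; ",
              "sequence reconstructed from coordinates (all residues S)")
      nums <- sort(as.integer(names(resolved[[ch]])))
      codes <- resolved[[ch]][as.character(nums)]
      tr <- translate3(codes)
      out[[ch]] <- data.frame(entry = entry_id, chain = ch,
                              sequence = paste(tr$one, collapse = ""),
                              mask = strrep("S", length(tr$one)),
                              method = method, resolution = resolution,
                              stringsAsFactors = FALSE)
      next
    }
    codes <- seqres[[ch]]
    tr <- translate3(codes)
    if (mean(tr$known) < 0.5) next  # not a protein chain
    n <- length(tr$one)
    res_num <- sort(as.integer(names(resolved[[ch]])))
    mis_num <- sort(unique(setdiff(missing[[ch]], res_num)))
    if (length(res_num) + length(mis_num) == n) {
      ord <- order(c(res_num, mis_num))
      labels <- c(rep("S", length(res_num)), rep("U", length(mis_num)))[ord]
    } else {
      warning("chain ", ch, " of entry ", entry_id,
              ": SEQRES length (", n, ") does not match ATOM + REMARK 465 ",
              "residue count (", length(res_num) + length(mis_num),
              "); assuming residue numbering 1..", n)
      labels <- ifelse(seq_len(n) %in% res_num, "S", "U")
    }
    out[[ch]] <- data.frame(entry = entry_id, chain = ch,
                            sequence = paste(tr$one, collapse = ""),
                            mask = paste(labels, collapse = ""),
                            method = method, resolution = resolution,
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(chain_records(character(0), character(0), character(0),
                         character(0), character(0), numeric(0)))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  validate_chain_records(df)
  df
}

#' Filter chains by method, resolution and length
#'
#' Keeps x-ray chains determined at a resolution of at most `max_resolution`
#' Angstrom ("resolution better than 3 A") with at least `min_length`
#' residues.  Both thresholds are inclusive.
#'
#' @param records chain-record `data.frame`.
#' @param max_resolution maximum (i.e. worst) allowed resolution in Angstrom.
#' @param min_length minimum chain length in residues.
#' @param method experimental method label that must match exactly.
#' @return the filtered chain-record `data.frame`.
#' @export
filter_chains <- function(records, max_resolution = 3.0, min_length = 40L,
                          method = "x-ray") {
  validate_chain_records(records)
  keep <- !is.na(records$method) & records$method == method &
    !is.na(records$resolution) & records$resolution <= max_resolution &
    nchar(records$sequence) >= min_length
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read the chain table as TSV
#'
#' Lossless round-trip of all chain-record fields.  Columns: entry, chain,
#' sequence, mask, method, resolution.
#'
#' @param records chain-record `data.frame`.
#' @param file path to write to, or `NULL` to return the TSV text.
#' @return `write_chain_table()`: the TSV text, invisibly if written to file.
#'   `read_chain_table()`: the chain-record `data.frame`.
#' @export
write_chain_table <- function(records, file = NULL) {
  validate_chain_records(records)
  con <- textConnection("txt", "w", local = TRUE)
  write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  text <- paste0(paste(txt, collapse = "\n"), "\n")
  if (is.null(file)) return(text)
  writeLines(txt, file)
  invisible(text)
}

#' @param x a file path or TSV text (anything containing a newline or not
#'   naming an existing file is treated as literal text).
#' @rdname write_chain_table
#' @export
read_chain_table <- function(x) {
  df <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    read.delim(x, stringsAsFactors = FALSE, colClasses = "character")
  else read.delim(text = x, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (!nrow(df)) {
    df$resolution <- numeric(0)
    return(validate_chain_records(df))
  }
  df$resolution <- suppressWarnings(as.numeric(df$resolution))
  bad <- which(nchar(df$sequence) != nchar(df$mask))
  if (length(bad))
    stop("sequence/mask length mismatch in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  validate_chain_records(df)
  df
}

#' Export chain sequences (and masks) as FASTA
#'
#' Writes the amino-acid sequences as FASTA; with `what = "mask"`, writes the
#' parallel U/S disorder masks under the same identifiers.
#'
#' @param records chain-record `data.frame`.
#' @param file output path.
#' @param what `"sequence"` or `"mask"`.
#' @return the output path, invisibly.
#' @export
write_chain_fasta <- function(records, file, what = c("sequence", "mask")) {
  validate_chain_records(records)
  what <- match.arg(what)
  x <- Biostrings::BStringSet(setNames(records[[what]], chain_key(records)))
  Biostrings::writeXStringSet(x, filepath = file)
  invisible(file)
}
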