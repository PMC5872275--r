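# -- IUPAC alphabet ----------------------------------------------------------

#' IUPAC nucleotide expansion table
#'
#' Returns the standard IUPAC ambiguity alphabet as a named list mapping each
#' single-letter code to the set of concrete bases it denotes (e.g. `M` ->
#' `A`,`C`). The table is taken from [Biostrings::IUPAC_CODE_MAP].
#'
#' @return Named list of character vectors over `A`,`C`,`G`,`T`.
#' @export
iupac_table <- function() {
  lapply(as.list(Biostrings::IUPAC_CODE_MAP), function(x) strsplit(x, "")[[1]])
}

# 15 codes x 4 bases compatibility lookup, built once at load time
.iupac_compat <- local({
  tab <- lapply(as.list(Biostrings::IUPAC_CODE_MAP), function(x) strsplit(x, "")[[1]])
  m <- matrix(FALSE, nrow = length(tab), ncol = 4,
              dimnames = list(names(tab), c("A", "C", "G", "T")))
  for (code in names(tab)) m[code, tab[[code]]] <- TRUE
  m
})

.iupac_codes <- rownames(.iupac_compat)
.dna_concrete <- c("A", "C", "G", "T")

.check_dna <- function(seq, what = "sequence", allow_gap = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  ok <- chars %in% .iupac_codes
  if (allow_gap) ok <- ok | chars == "-"
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("invalid character '%s' at position %d of %s (IUPAC DNA only)",
                 chars[bad], bad, what), call. = FALSE)
  }
  chars
}

#' Does a concrete template base match an IUPAC code?
#'
#' @param template_base Single concrete base (`A`, `C`, `G` or `T`).
#' @param code Single IUPAC nucleotide code (possibly degenerate).
#' @return `TRUE` iff `template_base` lies in the expansion of `code`.
#' @examples
#' iupac_match("A", "M")  # TRUE: M = A/C
#' iupac_match("G", "M")  # FALSE
#' @export
iupac_match <- function(template_base, code) {
  template_base <- toupper(template_base)
  code <- toupper(code)
  if (!template_base %in% .dna_concrete)
    stop("template base must be concrete (A/C/G/T), got '", template_base, "'",
         call. = FALSE)
  if (!code %in% .iupac_codes)
    stop("'", code, "' is not an IUPAC DNA code", call. = FALSE)
  .iupac_compat[code, template_base]
}

#' Reverse complement of an IUPAC DNA string
#'
#' Complements degenerate codes through the standard IUPAC complement table
#' (M <-> K, R <-> Y, ...) and reverses the sequence, so that applying the
#' function twice returns the input.
#'
#' @param seq DNA string, 5'->3', possibly containing IUPAC ambiguity codes.
#' @return The reverse complement, uppercase, 5'->3'.
#' @examples
#' reverse_complement("CAM")  # "KTG"
#' @export
reverse_complement <- function(seq) {
  .check_dna(seq, "input")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

# -- sequence records --------------------------------------------------------

#' Create a sequence record
#'
#' A lightweight record holding an identifier, an optional description and an
#' uppercase IUPAC DNA sequence. Lowercase input is normalised; `U` and other
#' non-DNA characters are rejected.
#'
#' @param id Non-empty record identifier.
#' @param seq DNA string; `-` alignment gaps are allowed.
#' @param desc Optional free-text description.
#' @return An object of class `seq_record` with fields `id`, `desc`, `seq`.
#' @export
seq_record <- function(id, seq, desc = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  chars <- .check_dna(seq, sprintf("record '%s'", id), allow_gap = TRUE)
  structure(list(id = id, desc = desc, seq = paste(chars, collapse = "")),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  s <- x$seq
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(sprintf("<seq_record %s [%d bp]> %s\n", x$id, nchar(x$seq), s))
  invisible(x)
}

.seq_of <- function(x) {
  if (inherits(x, "seq_record")) x$seq else x
}

.id_of <- function(x, default = "seq") {
  if (inherits(x, "seq_record")) x$id else default
}

# -- FASTA I/O ---------------------------------------------------------------

#' Read a multi-record FASTA file
#'
#' @param path Path to a FASTA file.
#' @return List of [seq_record] objects, in file order. An empty file yields
#'   an empty list with a warning; duplicate identifiers are an error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    warning("no records in ", path)
    return(list())
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- seq_record(ids[i], as.character(set[[i]]), descs[i])
  }
  names(out) <- ids
  out
}

#' Write sequence records to FASTA
#'
#' Sequences are wrapped at 70 columns. Round-tripping through [read_fasta]
#' preserves ids, descriptions and sequences.
#'
#' @param records List of [seq_record] objects (or named character vector).
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    stopifnot(!is.null(names(records)))
    records <- Map(seq_record, names(records), unname(records))
  }
  seqs <- vapply(records, function(r) r$seq, character(1))
  hdrs <- vapply(records, function(r) {
    if (nzchar(r$desc)) paste(r$id, r$desc) else r$id
  }, character(1))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- hdrs
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

# -- translation QC ----------------------------------------------------------

#' Translate a barcode sequence and flag stops and gaps
#'
#' Conceptual quality control for COX1 barcode reads: the sequence is
#' translated with the invertebrate mitochondrial genetic code (NCBI table 5)
#' and checked for internal stop codons and alignment gaps, either of which
#' indicates a pseudogene, frameshift or miscalled read. If `frame` is `NULL`
#' the frame with the fewest internal stops is chosen and flagged as a
#' heuristic.
#'
#' @param seq DNA string or [seq_record]; `-` gap characters are tolerated
#'   and reported.
#' @param frame Reading-frame offset 0, 1 or 2, or `NULL` for best-frame.
#' @param code_table NCBI genetic code id (default `"5"`, invertebrate
#'   mitochondrial).
#' @return List with `protein`, `has_stop` (internal stops only), `has_gap`,
#'   `frame` and `frame_heuristic`.
#' @export
translation_qc <- function(seq, frame = NULL, code_table = "5") {
  s <- toupper(.seq_of(seq))
  chars <- .check_dna(s, "input", allow_gap = TRUE)
  has_gap <- any(chars == "-")
  code <- Biostrings::getGeneticCode(code_table)

  translate_frame <- function(fr) {
    sub <- chars[chars != "-"]
    if (fr > 0) sub <- sub[-seq_len(fr)]
    n_cod <- length(sub) %/% 3L
    if (n_cod == 0L) stop("sequence too short to translate in frame ", fr,
                          call. = FALSE)
    sub <- sub[seq_len(n_cod * 3L)]
    codons <- vapply(seq_len(n_cod), function(i)
      paste(sub[(3L * i - 2L):(3L * i)], collapse = ""), character(1))
    aa <- vapply(codons, function(cd) {
      if (cd %in% names(code)) unname(code[cd]) else "X"
    }, character(1))
    prot <- paste(aa, collapse = "")
    internal <- if (n_cod > 1L) any(aa[-n_cod] == "*") else FALSE
    list(protein = prot, has_stop = internal,
         n_internal_stops = sum(aa[-length(aa)] == "*"))
  }

  heuristic <- is.null(frame)
  if (heuristic) {
    cand <- lapply(0:2, translate_frame)
    frame <- which.min(vapply(cand, `[[`, integer(1), "n_internal_stops")) - 1L
    res <- cand[[frame + 1L]]
  } else {
    stopifnot(frame %in% 0:2)
    res <- translate_frame(frame)
  }
  list(protein = res$protein, has_stop = res$has_stop, has_gap = has_gap,
       frame = as.integer(frame), frame_heuristic = heuristic)
}
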