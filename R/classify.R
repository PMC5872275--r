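# SNP calling in the Folmer frame, haplogroup assignment from sequence, and
# the RFLP decision matrix turning gel patterns into subspecies calls.

.transition_pairs <- list(c("A", "G"), c("C", "T"))

.classify_substitution <- function(bases) {
  bases <- sort(unique(bases))
  if (length(bases) != 2L) return("multiallelic")
  if (any(vapply(.transition_pairs, function(p) identical(bases, p),
                 logical(1)))) "transition" else "transversion"
}

#' Call SNPs across an aligned set of Folmer sequences
#'
#' Reports every alignment column holding at least two distinct concrete
#' bases, classified as transition (purine-purine or pyrimidine-pyrimidine)
#' or transversion. Positions are reported in the Folmer coordinate frame:
#' `frame_offset` gives the Folmer position of alignment column 1 (default 1
#' for sequences already trimmed to the 658-bp region).
#'
#' @param records List of equal-length [seq_record]s (pre-aligned), >= 2.
#' @param frame_offset Folmer position of the first alignment column.
#' @return `data.frame` with columns `position` (Folmer frame), `alleles`
#'   (e.g. `"C/T"`), `class` (`transition`/`transversion`/`multiallelic`)
#'   and `flagged` (`TRUE` when the column also contains gaps, `N` or other
#'   ambiguity codes). Zero rows when the records are identical.
#' @export
call_snps <- function(records, frame_offset = 1L) {
  stopifnot(length(records) >= 2L)
  seqs <- vapply(records, function(r) toupper(.seq_of(r)), character(1))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("records differ in length (", paste(unique(lens), collapse = ", "),
         "); align them before calling SNPs", call. = FALSE)
  mat <- do.call(rbind, strsplit(seqs, ""))
  out <- list()
  for (col in seq_len(ncol(mat))) {
    column <- mat[, col]
    concrete <- unique(column[column %in% .dna_concrete])
    if (length(concrete) < 2L) next
    out[[length(out) + 1L]] <- data.frame(
      position = col + frame_offset - 1L,
      alleles = paste(sort(concrete), collapse = "/"),
      class = .classify_substitution(concrete),
      flagged = any(!column %in% .dna_concrete),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(position = integer(), alleles = character(),
                      class = character(), flagged = logical()))
  do.call(rbind, out)
}

#' The packaged diagnostic SNP key
#'
#' Three positions of the 658-bp Folmer frame carry the subspecies signal:
#' 99 (A reference / G in carnica and carpatica), 421 (C reference / T in
#' mellifera haplogroup 1 / A in haplogroup 2) and 448 (A reference / G in
#' carnica). Alleles are stored as reference-vs-variant pairs relative to
#' the caucasica-type background.
#'
#' @return List of `diagnostic_snp` entries with fields `folmer_pos`, `ref`
#'   and `variants` (named base -> label map).
#' @export
snp_key <- function() {
  list(
    pos99  = list(folmer_pos = 99L,  ref = "A",
                  variants = c(G = "carnica_carpatica")),
    pos421 = list(folmer_pos = 421L, ref = "C",
                  variants = c(T = "mellifera_H1", A = "mellifera_H2")),
    pos448 = list(folmer_pos = 448L, ref = "A",
                  variants = c(G = "carnica"))
  )
}

#' Assign a haplogroup label from a Folmer-frame sequence
#'
#' Applies the diagnostic key: a variant at 99 opens the carnica/carpatica
#' branch, within which a variant at 448 means carnica; otherwise a T-type
#' variant at 421 means mellifera haplogroup 1 and an A-type variant
#' haplogroup 2; a sequence with reference bases at all key positions is
#' caucasica-consistent (identification by exclusion). A base incompatible
#' with every key allele (including `N`) yields `"unknown"` rather than a
#' forced call.
#'
#' @param folmer_seq [seq_record] or DNA string mapped to the 658-bp frame.
#' @param key Diagnostic key as produced by [snp_key].
#' @return Label string: `"carnica"`, `"carpatica"`, `"mellifera_H1"`,
#'   `"mellifera_H2"`, `"caucasica_consistent"` or `"unknown"`.
#' @export
assign_haplogroup <- function(folmer_seq, key = snp_key()) {
  chars <- strsplit(toupper(.seq_of(folmer_seq)), "")[[1]]
  base_at <- function(entry) {
    if (entry$folmer_pos > length(chars)) return(NA_character_)
    chars[entry$folmer_pos]
  }
  state <- function(entry) {
    b <- base_at(entry)
    if (is.na(b)) return("unknown")
    if (b == entry$ref) return("ref")
    if (b %in% names(entry$variants)) return(unname(entry$variants[b]))
    "unknown"
  }
  s99 <- state(key$pos99); s421 <- state(key$pos421); s448 <- state(key$pos448)
  if ("unknown" %in% c(s99, s421, s448)) return("unknown")
  if (s99 == "carnica_carpatica")
    return(if (s448 == "carnica") "carnica" else "carpatica")
  if (s421 == "mellifera_H1") return("mellifera_H1")
  if (s421 == "mellifera_H2") return("mellifera_H2")
  "caucasica_consistent"
}

#' The packaged RFLP decision matrix
#'
#' One row per haplotype, one column per assay (named by enzyme), each cell
#' `"cut"` or `"uncut"`. The caucasica row is all-uncut: that subspecies is
#' identified by exclusion, running all four assays.
#'
#' @param path TSV override; `NULL` for the packaged matrix.
#' @return `data.frame` with rownames = haplotype labels, columns = assay
#'   enzyme names.
#' @export
decision_matrix <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "decision_matrix.tsv", package = "beeRFLP",
                        mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  rownames(df) <- df$haplotype
  df$haplotype <- NULL
  stopifnot(all(unlist(df) %in% c("cut", "uncut")))
  df
}

#' Classify an observed cut/uncut pattern into a subspecies call
#'
#' Looks the observed pattern up in the decision matrix. The biologically
#' important special cases are handled explicitly: the HspAI-cut/MspI-uncut
#' pattern is called carpatica but flagged, because a fraction of carnica
#' specimens lack the position-448 SNP and produce the identical pattern;
#' the all-uncut pattern is a caucasica call by exclusion only. Patterns
#' matching no matrix row are reported as inconsistent, never coerced to the
#' nearest row.
#'
#' @param observed Named character vector, assay enzyme name -> `"cut"` or
#'   `"uncut"`. May cover a subset of the assays, in which case the call is
#'   flagged partial and made only if a single row remains compatible.
#' @param matrix Decision matrix from [decision_matrix].
#' @return List with `call` (label or `NA`), `confidence_note` (one of
#'   `"unique"`, `"carnica_carpatica_ambiguous"`, `"caucasica_by_exclusion"`,
#'   `"inconsistent"`) and `partial` (logical).
#' @export
rflp_classify <- function(observed, matrix = decision_matrix()) {
  stopifnot(is.character(observed), !is.null(names(observed)))
  unknown <- setdiff(names(observed), colnames(matrix))
  if (length(unknown))
    stop("unknown assay name(s): ", paste(unknown, collapse = ", "),
         "; expected ", paste(colnames(matrix), collapse = ", "),
         call. = FALSE)
  if (!all(observed %in% c("cut", "uncut")))
    stop("observed values must be 'cut' or 'uncut'", call. = FALSE)
  partial <- length(observed) < ncol(matrix)

  compatible <- rownames(matrix)[apply(
    matrix[, names(observed), drop = FALSE], 1,
    function(row) all(row == observed))]

  if (length(compatible) == 0L)
    return(list(call = NA_character_, confidence_note = "inconsistent",
                partial = partial))
  if (length(compatible) > 1L)  # underdetermined partial pattern
    return(list(call = NA_character_, confidence_note = "inconsistent",
                partial = partial))

  call <- compatible
  note <- "unique"
  hspa <- if ("HspAI" %in% names(observed)) observed[["HspAI"]] else NA
  mspi <- if ("MspI" %in% names(observed)) observed[["MspI"]] else NA
  if (identical(call, "carpatica") && identical(hspa, "cut") &&
      identical(mspi, "uncut"))
    note <- "carnica_carpatica_ambiguous"
  if (all(observed == "uncut") && identical(call, "caucasica"))
    note <- "caucasica_by_exclusion"
  list(call = call, confidence_note = note, partial = partial)
}

#' Classify many samples from a pattern table
#'
#' @param patterns `data.frame` with a `sample` column plus one cut/uncut
#'   column per assay enzyme.
#' @param matrix Decision matrix from [decision_matrix].
#' @return `data.frame` with `sample`, `call`, `confidence_note`, `partial`.
#' @export
classify_samples <- function(patterns, matrix = decision_matrix()) {
  stopifnot("sample" %in% colnames(patterns))
  assay_cols <- setdiff(colnames(patterns), "sample")
  out <- lapply(seq_len(nrow(patterns)), function(i) {
    obs <- vapply(assay_cols, function(cn) as.character(patterns[[cn]][i]),
                  character(1))
    names(obs) <- assay_cols
    obs <- obs[!is.na(obs) & nzchar(obs)]
    res <- rflp_classify(obs, matrix)
    data.frame(sample = patterns$sample[i],
               call = ifelse(is.na(res$call), "inconsistent", res$call),
               confidence_note = res$confidence_note,
               partial = res$partial, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
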