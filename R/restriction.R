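# Restriction-enzyme model and digestion simulator.
#
# Recognition sites may contain IUPAC degeneracy (HinfI = GANTC). Scanning
# covers both strands; for the palindromic/self-complementary sites used
# here the two scans coincide. Only top-strand cut positions define
# fragments: a gel reads double-stranded lengths, so overhang geometry is
# irrelevant. Complete digestion is assumed (every site is cut).

#' Create a restriction enzyme definition
#'
#' @param name Canonical enzyme name.
#' @param site Recognition sequence, IUPAC codes allowed, length >= 4.
#' @param cut_offset Number of site bases 5' of the top-strand cut (AluI
#'   AG^CT has offset 2; HinfI G^ANTC offset 1).
#' @param isoschizomers Character vector of alternative enzyme names sharing
#'   the recognition site.
#' @return Object of class `enzyme`.
#' @export
enzyme <- function(name, site, cut_offset, isoschizomers = character()) {
  chars <- .check_dna(site, sprintf("site of '%s'", name))
  if (length(chars) < 4L) stop("recognition site of '", name,
                               "' shorter than 4 bp", call. = FALSE)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > length(chars))
    stop("cut offset of '", name, "' outside the site", call. = FALSE)
  structure(list(name = name, site = paste(chars, collapse = ""),
                 cut_offset = cut_offset,
                 isoschizomers = as.character(isoschizomers)),
            class = "enzyme")
}

#' @export
print.enzyme <- function(x, ...) {
  s <- strsplit(x$site, "")[[1]]
  cat(sprintf("<enzyme %s %s^%s>\n", x$name,
              paste(s[seq_len(x$cut_offset)], collapse = ""),
              paste(s[-seq_len(x$cut_offset)], collapse = "")))
  invisible(x)
}

#' Load the enzyme table
#'
#' The packaged table holds the five enzymes used for honey-bee subspecies
#' typing (AluI, HinfI, HspAI, MspI and DraI) together with their commercial
#' isoschizomers.
#'
#' @param path TSV with columns `name`, `site`, `cut_offset`,
#'   `isoschizomers` (comma-separated); `NULL` for the packaged table.
#' @return Named list of [enzyme] objects.
#' @export
load_enzymes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "enzymes.tsv", package = "beeRFLP",
                        mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  out <- lapply(seq_len(nrow(df)), function(i) {
    iso <- df$isoschizomers[i]
    iso <- if (is.na(iso) || !nzchar(iso)) character() else
      strsplit(iso, ",")[[1]]
    enzyme(df$name[i], df$site[i], as.integer(df$cut_offset[i]), iso)
  })
  names(out) <- df$name
  out
}

#' Resolve an enzyme name, following isoschizomers
#'
#' `"HpaII"` resolves to the canonical MspI record (site CCGG), `"AluBI"` to
#' AluI, and so on. GlaI resolves to HspAI but triggers a warning because its
#' activity requires methylated substrates, which this model ignores.
#'
#' @param name Canonical or isoschizomer enzyme name (case-insensitive).
#' @param enzymes Enzyme table from [load_enzymes].
#' @return The canonical [enzyme] record.
#' @export
resolve_enzyme <- function(name, enzymes = load_enzymes()) {
  stopifnot(is.character(name), length(name) == 1L)
  for (e in enzymes) {
    if (tolower(name) == tolower(e$name)) return(e)
    if (tolower(name) %in% tolower(e$isoschizomers)) {
      if (tolower(name) == "glai")
        warning("GlaI cleaves only methylated ", e$site,
                "; methylation sensitivity is not modelled", call. = FALSE)
      return(e)
    }
  }
  known <- unlist(lapply(enzymes, function(e) c(e$name, e$isoschizomers)))
  stop("unknown enzyme '", name, "'; known names: ",
       paste(sort(known), collapse = ", "), call. = FALSE)
}

#' Find restriction-site positions in a concrete sequence
#'
#' Scans the top strand for IUPAC-compatible occurrences of the recognition
#' site and of its reverse complement; duplicate positions from palindromic
#' sites are collapsed.
#'
#' @param seq Concrete DNA string or [seq_record].
#' @param enzyme [enzyme] object.
#' @return Sorted integer vector of 1-based site start positions (possibly
#'   empty).
#' @export
find_sites <- function(seq, enzyme) {
  stopifnot(inherits(enzyme, "enzyme"))
  chars <- .check_dna(.seq_of(seq), "input")
  if (!all(chars %in% .dna_concrete))
    stop("digestion input must be concrete (A/C/G/T only)", call. = FALSE)
  site <- strsplit(enzyme$site, "")[[1]]
  rc <- strsplit(reverse_complement(enzyme$site), "")[[1]]
  hits <- which(.scan_mismatches(chars, site) == 0L)
  if (!identical(site, rc))
    hits <- union(hits, which(.scan_mismatches(chars, rc) == 0L))
  sort(hits)
}

#' Digest a linear sequence with a restriction enzyme
#'
#' Cut positions are `site_start + cut_offset - 1` ("cut after this base",
#' top strand) for every site found by [find_sites]; fragments are the
#' maximal uncut intervals, and their lengths always sum to the input
#' length.
#'
#' @inheritParams find_sites
#' @return Object of class `digest_result`: list with `enzyme`,
#'   `cut_positions` (sorted ascending) and `fragment_lengths` (sorted
#'   descending, as printed on a gel report).
#' @export
digest <- function(seq, enzyme) {
  s <- .seq_of(seq)
  n <- nchar(s)
  starts <- find_sites(s, enzyme)
  cuts <- sort(unique(starts + enzyme$cut_offset - 1L))
  cuts <- cuts[cuts >= 1L & cuts < n]  # terminal "cuts" release nothing
  frag <- diff(c(0L, cuts, n))
  structure(list(enzyme = enzyme$name,
                 cut_positions = cuts,
                 fragment_lengths = sort(frag, decreasing = TRUE)),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest %s: %s bp>\n", x$enzyme,
              paste(x$fragment_lengths, collapse = ", ")))
  invisible(x)
}

#' Can a fragment set be resolved on an agarose gel?
#'
#' A pattern is callable when every fragment is long enough to be visible
#' and every pair of distinct fragment lengths differs by enough to separate
#' as two bands. Defaults are set for a 3% agarose gel, on which cleaved
#' fragments of ~30 bp are readily visualised; both thresholds are
#' configurable.
#'
#' @param fragments Integer vector of fragment lengths (bp), non-empty.
#' @param min_fragment Smallest visible fragment (default 20 bp).
#' @param min_delta Smallest resolvable length difference between distinct
#'   fragments (default 15 bp).
#' @return List with `ok` (logical) and `violations` (character vector
#'   describing each failure, empty when resolvable).
#' @export
gel_resolvable <- function(fragments, min_fragment = 20L, min_delta = 15L) {
  stopifnot(length(fragments) >= 1L, all(fragments > 0))
  viol <- character()
  small <- fragments[fragments < min_fragment]
  if (length(small))
    viol <- c(viol, sprintf("fragment %d bp below visibility threshold %d bp",
                            small, min_fragment))
  lens <- sort(unique(fragments))
  if (length(lens) > 1L) {
    d <- diff(lens)
    bad <- which(d > 0 & d < min_delta)
    if (length(bad))
      viol <- c(viol, sprintf("fragments %d and %d bp differ by %d < %d bp",
                              lens[bad], lens[bad + 1L], d[bad], min_delta))
  }
  list(ok = length(viol) == 0L, violations = viol)
}
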