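# In-silico PCR with degenerate and mutagenic primers.
#
# The central modelling decision: in a PCR product the primer sequences
# replace the template at both ends (the polymerase extends the primer, so
# the oligo itself is incorporated). Mutagenic (dCAPS) primers exploit this:
# deliberate mismatches near the 3' end create, together with a template SNP
# just beyond the primer, a restriction site that exists only in products of
# the targeted allele.

#' Create a primer definition
#'
#' @param name Primer name.
#' @param seq Oligo sequence, 5'->3', IUPAC codes allowed. Minimum 15 nt.
#' @param direction `"forward"` or `"reverse"` (annotation of intended role).
#' @param mutagenic Does the primer carry deliberate template mismatches?
#' @param mutated_positions 1-based positions (within the primer) of the
#'   deliberate substitutions; at most two, and all must lie in the
#'   3'-terminal half of the oligo.
#' @return Object of class `primer`.
#' @export
primer <- function(name, seq, direction = c("forward", "reverse"),
                   mutagenic = FALSE, mutated_positions = integer()) {
  direction <- match.arg(direction)
  chars <- .check_dna(seq, sprintf("primer '%s'", name))
  len <- length(chars)
  if (len < 15L) stop("primer '", name, "' shorter than 15 nt", call. = FALSE)
  mutated_positions <- as.integer(mutated_positions)
  if (mutagenic) {
    if (!length(mutated_positions) %in% 1:2)
      stop("mutagenic primer '", name, "' must declare 1 or 2 substitutions",
           call. = FALSE)
    if (any(mutated_positions < 1L | mutated_positions > len))
      stop("mutated positions outside primer '", name, "'", call. = FALSE)
    if (any(mutated_positions <= len / 2))
      stop("mutagenic substitutions of '", name,
           "' must lie in the 3'-terminal half", call. = FALSE)
  } else if (length(mutated_positions)) {
    stop("non-mutagenic primer '", name, "' cannot declare substitutions",
         call. = FALSE)
  }
  structure(list(name = name, seq = paste(chars, collapse = ""),
                 direction = direction, mutagenic = mutagenic,
                 mutated_positions = sort(mutated_positions)),
            class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer %s (%s%s) %d nt> %s\n", x$name, x$direction,
              if (x$mutagenic) ", mutagenic" else "", nchar(x$seq), x$seq))
  invisible(x)
}

#' Load primer definitions from a tab-separated file
#'
#' The packaged default table carries the barcoding primers (LepF1/LepR1,
#' CYTB pair, AmCarp-f/AmCar-r) and the four subspecies-diagnostic pairs
#' with their mutagenic annotations.
#'
#' @param path TSV with columns `name`, `seq`, `direction`, `mutagenic`,
#'   `mutated_positions` (comma-separated, may be empty). `NULL` for the
#'   packaged table.
#' @return Named list of [primer] objects.
#' @export
load_primers <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "primers.tsv", package = "beeRFLP",
                        mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  out <- lapply(seq_len(nrow(df)), function(i) {
    mp <- df$mutated_positions[i]
    mp <- if (is.na(mp) || !nzchar(mp)) integer() else
      as.integer(strsplit(mp, ",")[[1]])
    primer(df$name[i], df$seq[i], df$direction[i],
           mutagenic = tolower(df$mutagenic[i]) %in% c("true", "yes", "1"),
           mutated_positions = mp)
  })
  names(out) <- df$name
  out
}

# -- annealing ---------------------------------------------------------------

# Count, for every offset of `pattern` (IUPAC chars) along `subject`
# (concrete chars), the positions where the subject base is not in the
# pattern code's expansion. Returns integer vector over offsets 1..n-m+1.
.scan_mismatches <- function(subject_chars, pattern_chars) {
  n <- length(subject_chars)
  m <- length(pattern_chars)
  if (m > n) return(integer(0))
  n_off <- n - m + 1L
  mm <- integer(n_off)
  for (j in seq_len(m)) {
    ok <- .iupac_compat[pattern_chars[j], subject_chars[j:(j + n_off - 1L)]]
    mm <- mm + !ok
  }
  unname(mm)
}

.mismatch_positions <- function(subject_chars, pattern_chars, start) {
  idx <- seq_along(pattern_chars)
  ok <- .iupac_compat[cbind(pattern_chars, subject_chars[start + idx - 1L])]
  idx[!ok]
}

#' Find primer annealing sites on a template
#'
#' Scans both strands of a concrete template for footprints where at most
#' `max_mismatch` primer positions fail to match (degenerate primer codes
#' match any base in their expansion). No 3'-clamp rule is applied: mutagenic
#' primers anneal despite 3'-terminal non-complementarity, so terminal
#' mismatches are counted like any other.
#'
#' @param template [seq_record] or concrete DNA string.
#' @param primer [primer] object.
#' @param max_mismatch Maximum tolerated mismatches (default 3).
#' @return `data.frame` with columns `template_id`, `start`, `end` (1-based
#'   inclusive footprint on the top strand), `strand` (`+` if the primer
#'   reads along the top strand, `-` if it anneals to it), `mismatches`, and
#'   a list-column `mismatch_positions` (1-based within the primer, 5'->3').
#'   Sorted by (mismatches, start). A primer longer than the template yields
#'   zero rows.
#' @export
find_primer_sites <- function(template, primer, max_mismatch = 3L) {
  stopifnot(inherits(primer, "primer"), max_mismatch >= 0L)
  tid <- .id_of(template)
  tchars <- .check_dna(.seq_of(template), sprintf("template '%s'", tid))
  if (!all(tchars %in% .dna_concrete))
    stop("template '", tid, "' must be concrete (A/C/G/T only)", call. = FALSE)
  pchars <- strsplit(primer$seq, "")[[1]]
  m <- length(pchars)
  rc_chars <- strsplit(reverse_complement(primer$seq), "")[[1]]

  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") pchars else rc_chars
    mm <- .scan_mismatches(tchars, pat)
    sel <- which(mm <= max_mismatch)
    if (!length(sel)) next
    mp <- lapply(sel, function(s) {
      pos <- .mismatch_positions(tchars, pat, s)
      # map back to primer coordinates (5'->3' on the oligo)
      if (strand == "-") sort(m - pos + 1L) else pos
    })
    hits[[strand]] <- data.frame(
      template_id = tid, start = sel, end = sel + m - 1L, strand = strand,
      mismatches = mm[sel], stringsAsFactors = FALSE)
    hits[[strand]]$mismatch_positions <- mp
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(template_id = character(), start = integer(), end = integer(),
               strand = character(), mismatches = integer(),
               mismatch_positions = I(list()))
  out <- out[order(out$mismatches, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Resolve an IUPAC pattern against a concrete template window: the template
# base is kept where the pattern code admits it (the polymerase copies the
# template), otherwise the lexicographically smallest base of the expansion
# is substituted (deterministic choice; for concrete pattern chars this is
# the primer base itself, i.e. the overwrite).
.resolve_pattern <- local({
  tab <- NULL
  function(pattern_chars, template_chars) {
    if (is.null(tab)) tab <<- iupac_table()
    out <- character(length(pattern_chars))
    for (j in seq_along(pattern_chars)) {
      exp <- tab[[pattern_chars[j]]]
      out[j] <- if (template_chars[j] %in% exp) template_chars[j] else exp[1L]
    }
    out
  }
})

#' Virtual amplification with primer overwrite
#'
#' Pairs every forward-orientation hit of `fwd` with every downstream
#' reverse-orientation hit of `rev` and emits the products whose length falls
#' in `size_range`. The product sequence is the resolved forward primer, the
#' template interior verbatim, and the reverse complement of the resolved
#' reverse primer: template bases under the footprints are overwritten by the
#' primers, which is how mutagenic primers introduce restriction sites.
#' Degenerate primer positions resolve to the template base where compatible.
#'
#' @inheritParams find_primer_sites
#' @param fwd,rev [primer] objects.
#' @param size_range Two-element numeric `[min, max]` product length filter.
#' @return List of `amplicon` objects (fields `template_id`, `fwd_hit`,
#'   `rev_hit`, `start`, `end`, `length`, `product_seq`), ordered by product
#'   start then length. Empty list when either primer finds no site.
#' @export
amplify <- function(template, fwd, rev, max_mismatch = 3L,
                    size_range = c(100L, 1000L)) {
  stopifnot(length(size_range) == 2L, size_range[1] <= size_range[2])
  tid <- .id_of(template)
  tseq <- toupper(.seq_of(template))
  tchars <- strsplit(tseq, "")[[1]]

  fhits <- find_primer_sites(template, fwd, max_mismatch)
  fhits <- fhits[fhits$strand == "+", , drop = FALSE]
  rhits <- find_primer_sites(template, rev, max_mismatch)
  rhits <- rhits[rhits$strand == "-", , drop = FALSE]
  if (nrow(fhits) == 0L || nrow(rhits) == 0L) return(list())

  fchars <- strsplit(fwd$seq, "")[[1]]
  rc_rev <- strsplit(reverse_complement(rev$seq), "")[[1]]

  out <- list()
  for (i in seq_len(nrow(fhits))) {
    for (j in seq_len(nrow(rhits))) {
      fs <- fhits$start[i]; fe <- fhits$end[i]
      rs <- rhits$start[j]; re <- rhits$end[j]
      if (rs <= fe) next  # overlapping or upstream footprints: no product
      len <- re - fs + 1L
      if (len < size_range[1] || len > size_range[2]) next
      head <- .resolve_pattern(fchars, tchars[fs:fe])
      tail <- .resolve_pattern(rc_rev, tchars[rs:re])
      interior <- if (rs - fe > 1L) tchars[(fe + 1L):(rs - 1L)] else character()
      out[[length(out) + 1L]] <- structure(
        list(template_id = tid,
             fwd_hit = fhits[i, , drop = FALSE],
             rev_hit = rhits[j, , drop = FALSE],
             start = fs, end = re, length = len,
             product_seq = paste(c(head, interior, tail), collapse = "")),
        class = "amplicon")
    }
  }
  ord <- order(vapply(out, `[[`, integer(1), "start"),
               vapply(out, `[[`, integer(1), "length"))
  out[ord]
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon %s:%d-%d [%d bp]>\n", x$template_id, x$start, x$end,
              x$length))
  invisible(x)
}

#' Two-step (nested) amplification
#'
#' Rescue strategy for degraded templates: a first round with a highly
#' specific outer pair produces a long product that then serves as the
#' template for the inner, assay-specific pair.
#'
#' @inheritParams amplify
#' @param outer_pair,inner_pair Lists of two [primer]s (forward, reverse).
#' @param outer_size_range Size filter for the outer round (default wide).
#' @param outer_max_mismatch Mismatch tolerance for the outer round; by
#'   default the same as `max_mismatch`, but the outer pair is typically
#'   long and highly specific and may be run more permissively.
#' @return List of inner amplicons. If the outer round yields nothing the
#'   result is an empty list with attribute `outer_failed = TRUE`.
#' @export
nested_amplify <- function(template, outer_pair, inner_pair,
                           max_mismatch = 3L, size_range = c(100L, 1000L),
                           outer_size_range = c(100L, 5000L),
                           outer_max_mismatch = max_mismatch) {
  outer <- amplify(template, outer_pair[[1]], outer_pair[[2]],
                   max_mismatch = outer_max_mismatch,
                   size_range = outer_size_range)
  if (length(outer) == 0L) {
    return(structure(list(), outer_failed = TRUE))
  }
  inner <- list()
  for (k in seq_along(outer)) {
    tmpl <- seq_record(paste0(.id_of(template), "|outer", k),
                       outer[[k]]$product_seq)
    inner <- c(inner, amplify(tmpl, inner_pair[[1]], inner_pair[[2]],
                              max_mismatch = max_mismatch,
                              size_range = size_range))
  }
  inner
}
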