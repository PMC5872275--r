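# PCR-RFLP assay objects, re-simulation of packaged assays, and the design
# search that generalises how the diagnostic mutagenic-primer assays were
# constructed: find a (mutagenic primer, enzyme) combination whose PCR
# product is cleaved in exactly the haplotypes carrying the target allele.

#' Create an assay definition
#'
#' @param name Assay name.
#' @param fwd,rev [primer] objects.
#' @param enzyme [enzyme] object.
#' @param size_range Product-length window (default `c(120, 160)`, the
#'   window used for the packaged diagnostic assays so products separate
#'   cleanly on 3% agarose).
#' @param max_mismatch Annealing mismatch tolerance.
#' @return Object of class `rflp_assay`.
#' @export
rflp_assay <- function(name, fwd, rev, enzyme, size_range = c(120L, 160L),
                       max_mismatch = 3L) {
  stopifnot(inherits(fwd, "primer"), inherits(rev, "primer"),
            inherits(enzyme, "enzyme"))
  structure(list(name = name, fwd = fwd, rev = rev, enzyme = enzyme,
                 size_range = size_range, max_mismatch = max_mismatch),
            class = "rflp_assay")
}

#' @export
print.rflp_assay <- function(x, ...) {
  cat(sprintf("<assay %s: %s/%s + %s, %d-%d bp>\n", x$name, x$fwd$name,
              x$rev$name, x$enzyme$name, x$size_range[1], x$size_range[2]))
  invisible(x)
}

#' Load the packaged diagnostic assays
#'
#' Four assays, one per informative enzyme: AmEu1/AluI (mellifera
#' haplogroup 1), AmEu2/HinfI (haplogroup 2), AmCarp/HspAI (carpatica and
#' carnica) and AmCar/MspI (carnica).
#'
#' @param path TSV override (`name`, `fwd`, `rev`, `enzyme`, `size_min`,
#'   `size_max`, `max_mismatch`); `NULL` for the packaged table.
#' @param primers,enzymes Lookup tables for primer and enzyme names.
#' @return Named list of [rflp_assay] objects.
#' @export
load_assays <- function(path = NULL, primers = load_primers(),
                        enzymes = load_enzymes()) {
  if (is.null(path))
    path <- system.file("extdata", "assays.tsv", package = "beeRFLP",
                        mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    rflp_assay(df$name[i],
               fwd = primers[[df$fwd[i]]],
               rev = primers[[df$rev[i]]],
               enzyme = resolve_enzyme(df$enzyme[i], enzymes),
               size_range = c(df$size_min[i], df$size_max[i]),
               max_mismatch = df$max_mismatch[i])
  })
  names(out) <- df$name
  out
}

#' Expected fragment patterns for the packaged assays
#'
#' The machine-readable analogue of the published digestion table: one row
#' per assay, one column per haplotype, each cell the expected fragment
#' lengths (descending, comma-separated).
#'
#' @param path TSV override; `NULL` for the packaged table.
#' @return `data.frame` with rownames = assay names.
#' @export
expected_patterns <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "expected_patterns.tsv",
                        package = "beeRFLP", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  rownames(df) <- df$assay
  df$assay <- NULL
  df
}

#' Re-simulate an assay across a set of haplotypes
#'
#' Runs [amplify] and [digest] for each haplotype and tabulates product
#' length, fragment pattern and cut status: the in-silico analogue of
#' running the PCR-RFLP panel on a gel.
#'
#' @param assay [rflp_assay] object.
#' @param haplotypes List of [seq_record] templates.
#' @return `data.frame` with columns `haplotype`, `n_products`,
#'   `product_len`, `fragments` (comma-separated, descending), `cut`.
#'   Haplotypes on which a primer fails to anneal get `n_products = 0` and
#'   `fragments = "no product"`.
#' @export
validate_assay <- function(assay, haplotypes) {
  stopifnot(inherits(assay, "rflp_assay"))
  rows <- lapply(haplotypes, function(h) {
    amps <- amplify(h, assay$fwd, assay$rev,
                    max_mismatch = assay$max_mismatch,
                    size_range = assay$size_range)
    if (length(amps) == 0L)
      return(data.frame(haplotype = .id_of(h), n_products = 0L,
                        product_len = NA_integer_, fragments = "no product",
                        cut = NA, stringsAsFactors = FALSE))
    dg <- digest(amps[[1]]$product_seq, assay$enzyme)
    data.frame(haplotype = .id_of(h), n_products = length(amps),
               product_len = amps[[1]]$length,
               fragments = paste(dg$fragment_lengths, collapse = ","),
               cut = length(dg$fragment_lengths) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Declare a diagnostic SNP
#'
#' @param folmer_pos 1-based position in the 658-bp Folmer frame.
#' @param alleles Named character vector, haplotype label -> concrete base;
#'   at least two distinct bases.
#' @return Object of class `diagnostic_snp`.
#' @export
diagnostic_snp <- function(folmer_pos, alleles) {
  folmer_pos <- as.integer(folmer_pos)
  stopifnot(folmer_pos >= 1L, !is.null(names(alleles)),
            all(alleles %in% .dna_concrete))
  if (length(unique(alleles)) < 2L)
    stop("not polymorphic: all haplotypes share base '", alleles[[1]],
         "' at position ", folmer_pos, call. = FALSE)
  structure(list(folmer_pos = folmer_pos, alleles = alleles),
            class = "diagnostic_snp")
}

# -- design search -----------------------------------------------------------

# Consensus of haplotypes outside the SNP (they are assumed identical there;
# at the SNP the completing allele's base is used for primer extraction).
.design_one_strand <- function(seqs, snp_pos, alleles, enz, size_range,
                               max_subs, mut_len, opp_len, max_mismatch,
                               strand, records) {
  site <- strsplit(enz$site, "")[[1]]
  L <- length(site)
  tab <- iupac_table()
  n <- nchar(seqs[[1]])
  results <- list()

  for (k in 0:(L - 1L)) {                 # SNP sits at site index k+1
    s <- snp_pos - k
    if (s < 1L || s + L - 1L > n) next
    site_char <- site[k + 1L]
    compat <- vapply(alleles, function(b) b %in% tab[[site_char]], logical(1))
    targets <- names(alleles)[compat]
    if (length(targets) == 0L || length(targets) == length(alleles)) next

    tgt_seq <- strsplit(seqs[[targets[1L]]], "")[[1]]
    # primer 3' end e: template must supply the SNP, primer the bases <= e
    for (e in (s - 1L):(snp_pos - 1L)) {
      if (e < 1L) next
      p_start <- e - mut_len + 1L
      if (p_start < 1L) next
      # template part of the site must be compatible in every target
      tpl_idx <- (e + 1L):(s + L - 1L)
      ok_targets <- all(vapply(targets, function(h) {
        hc <- strsplit(seqs[[h]], "")[[1]]
        all(.iupac_compat[cbind(site[tpl_idx - s + 1L], hc[tpl_idx])])
      }, logical(1)))
      if (!ok_targets) next

      # build the mutagenic primer: template bases, site-overlap resolved
      pchars <- tgt_seq[p_start:e]
      n_subs <- 0L; sub_pos <- integer()
      if (e >= s) {
        for (pos in s:e) {
          want <- site[pos - s + 1L]
          j <- pos - p_start + 1L
          if (!pchars[j] %in% tab[[want]]) {
            pchars[j] <- tab[[want]][1L]
            n_subs <- n_subs + 1L
            sub_pos <- c(sub_pos, j)
          }
        }
      }
      if (n_subs > max_subs) next
      if (length(sub_pos) && any(sub_pos <= mut_len / 2)) next

      # opposite (downstream) primer: smallest product inside the window
      found <- FALSE
      for (plen in size_range[1]:size_range[2]) {
        q_end <- p_start + plen - 1L
        if (q_end > n) break
        q_start <- q_end - opp_len + 1L
        if (q_start <= e) next
        fwd_p <- primer(sprintf("dsn-%s-f", enz$name),
                        paste(pchars, collapse = ""), "forward",
                        mutagenic = n_subs > 0L, mutated_positions = sub_pos)
        rev_p <- primer(sprintf("dsn-%s-r", enz$name),
                        reverse_complement(paste(tgt_seq[q_start:q_end],
                                                 collapse = "")), "reverse")
        if (strand == "-") {              # map back to original orientation
          cand <- list(
            fwd = primer(rev_p$name, rev_p$seq, "forward"),
            rev = primer(fwd_p$name, fwd_p$seq, "reverse",
                         mutagenic = fwd_p$mutagenic,
                         mutated_positions = fwd_p$mutated_positions))
        } else {
          cand <- list(fwd = fwd_p, rev = rev_p)
        }
        val <- validate_assay(
          rflp_assay("candidate", cand$fwd, cand$rev, enz,
                     size_range = size_range, max_mismatch = max_mismatch),
          records)
        ok <- all(val$n_products == 1L) &&
          all(val$cut[val$haplotype %in% targets]) &&
          !any(val$cut[!val$haplotype %in% targets])
        if (ok) {
          patterns <- stats::setNames(val$fragments, val$haplotype)
          results[[length(results) + 1L]] <- structure(
            list(fwd = cand$fwd, rev = cand$rev, enzyme = enz,
                 target_haplotypes = targets,
                 predicted_patterns = patterns,
                 n_substitutions = n_subs, product_len = plen),
            class = "assay_design")
          found <- TRUE
        }
        if (found) break                  # one opposite primer per anchor
      }
    }
  }
  results
}

#' Search primer-by-enzyme space for an allele-specific cleavage assay
#'
#' For each enzyme, orientation and placement of the recognition site over
#' the SNP, the search constructs the mutagenic primer whose 3'-adjacent
#' template allele completes the site in the target haplotypes only,
#' applying at most `max_subs` substitutions (all in the 3'-terminal half,
#' never on the SNP-complementary position itself). Each candidate is
#' validated by full re-simulation ([amplify] + [digest]) on every
#' haplotype, so every returned design is sound: the product is cut in
#' exactly the declared target haplotypes and nowhere else in any
#' non-target product.
#'
#' @param haplotypes List of equal-length [seq_record]s.
#' @param snp [diagnostic_snp] whose `alleles` names match the haplotype
#'   ids.
#' @param enzymes List of [enzyme] candidates.
#' @param size_range Product-length window.
#' @param max_subs Maximum mutagenic substitutions (default 2).
#' @param mut_len Length of generated mutagenic primers (default 30 nt: the
#'   cleaved-off fragment is about as long as the mutagenic primer, sized
#'   for 3% agarose).
#' @param opp_len Length of the opposite, non-mutagenic primer (default
#'   19 nt).
#' @param max_mismatch Annealing tolerance used during validation.
#' @return List of `assay_design` objects ranked by (substitution count,
#'   product length, enzyme name), deterministically. When empty, the
#'   attribute `failure_reasons` names each enzyme's obstruction.
#' @export
design_assay <- function(haplotypes, snp, enzymes = load_enzymes(),
                         size_range = c(120L, 160L), max_subs = 2L,
                         mut_len = 30L, opp_len = 19L, max_mismatch = 3L) {
  stopifnot(inherits(snp, "diagnostic_snp"))
  ids <- vapply(haplotypes, .id_of, character(1))
  names(haplotypes) <- ids
  if (!all(names(snp$alleles) %in% ids))
    stop("snp alleles name haplotypes absent from the input", call. = FALSE)
  seqs <- lapply(haplotypes, function(h) toupper(.seq_of(h)))
  lens <- vapply(seqs, nchar, integer(1))
  if (length(unique(lens)) != 1L)
    stop("haplotypes must be aligned to equal length", call. = FALSE)
  observed <- vapply(names(snp$alleles), function(h)
    substr(seqs[[h]], snp$folmer_pos, snp$folmer_pos), character(1))
  if (length(unique(observed)) < 2L)
    stop("not polymorphic: haplotypes are identical at position ",
         snp$folmer_pos, call. = FALSE)
  if (!identical(unname(observed), unname(snp$alleles[names(observed)])))
    stop("declared alleles disagree with the sequences at position ",
         snp$folmer_pos, call. = FALSE)

  n <- lens[[1]]
  results <- list()
  reasons <- character()
  for (enz in enzymes) {
    found <- list()
    for (strand in c("+", "-")) {
      if (strand == "+") {
        work_seqs <- seqs
        work_pos <- snp$folmer_pos
        work_alleles <- snp$alleles
      } else {
        work_seqs <- lapply(seqs, reverse_complement)
        work_pos <- n - snp$folmer_pos + 1L
        work_alleles <- vapply(snp$alleles, function(b)
          reverse_complement(b), character(1))
      }
      found <- c(found, .design_one_strand(
        work_seqs, work_pos, work_alleles, enz, size_range, max_subs,
        mut_len, opp_len, max_mismatch, strand, haplotypes))
    }
    if (length(found) == 0L)
      reasons[enz$name] <- paste0(
        "no placement of ", enz$site, " over position ", snp$folmer_pos,
        " admits allele-specific completion within ", max_subs,
        " substitution(s)")
    results <- c(results, found)
  }

  if (length(results)) {
    key <- vapply(results, function(r)
      paste(r$fwd$seq, r$rev$seq, r$enzyme$name), character(1))
    results <- results[!duplicated(key)]
    ord <- order(vapply(results, `[[`, integer(1), "n_substitutions"),
                 vapply(results, `[[`, integer(1), "product_len"),
                 vapply(results, function(r) r$enzyme$name, character(1)))
    results <- results[ord]
  }
  structure(results, failure_reasons = reasons)
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf(
    "<design %s: %d bp product, %d substitution(s), cuts %s>\n  fwd %s\n  rev %s\n",
    x$enzyme$name, x$product_len, x$n_substitutions,
    paste(x$target_haplotypes, collapse = "+"), x$fwd$seq, x$rev$seq))
  invisible(x)
}
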