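# Kimura 2-parameter distances, neighbor-joining trees and bootstrap
# supports for barcode alignments. The distance counting and the closed-form
# K2P evaluation are implemented here; tree agglomeration, Newick I/O and
# bipartition counting go through ape.

.purines <- c("A", "G")

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Counts the transition proportion P and transversion proportion Q over the
#' usable sites and evaluates
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#' Sites where either sequence carries a gap, `N` or any other ambiguity
#' code are dropped (pairwise deletion).
#'
#' @param seq1,seq2 Aligned equal-length DNA strings or [seq_record]s.
#' @return List with `d`, `P`, `Q`, `n_sites`, `transitions`,
#'   `transversions`.
#' @section Saturation: when `1 - 2P - Q <= 0` or `1 - 2Q <= 0` the model
#'   distance is undefined and an error of class `beeRFLP_saturation` is
#'   thrown rather than returning an arbitrary large value.
#' @export
k2p_distance <- function(seq1, seq2) {
  c1 <- strsplit(toupper(.seq_of(seq1)), "")[[1]]
  c2 <- strsplit(toupper(.seq_of(seq2)), "")[[1]]
  if (length(c1) != length(c2))
    stop("sequences must be aligned to equal length", call. = FALSE)
  use <- c1 %in% .dna_concrete & c2 %in% .dna_concrete
  n <- sum(use)
  if (n == 0L) stop("no usable sites after deletion", call. = FALSE)
  a <- c1[use]; b <- c2[use]
  diff <- a != b
  ts <- sum(diff & ((a %in% .purines) == (b %in% .purines)))
  tv <- sum(diff) - ts
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop(structure(class = c("beeRFLP_saturation", "error", "condition"),
                   list(message = sprintf(
                     "substitution saturation (P = %.3f, Q = %.3f): K2P distance undefined",
                     P, Q), call = NULL)))
  list(d = -0.5 * log(w1) - 0.25 * log(w2), P = P, Q = Q, n_sites = n,
       transitions = ts, transversions = tv)
}

#' Pairwise K2P distance matrix
#'
#' @param records List of aligned [seq_record]s (>= 2).
#' @param deletion `"pairwise"` (default: drop unusable sites per pair) or
#'   `"complete"` (drop every column containing a gap or ambiguity in any
#'   record before computing all pairs).
#' @return Symmetric numeric matrix with zero diagonal, labelled by record
#'   id. Saturated pairs are `NA` with a warning; the attribute
#'   `n_saturated` counts them.
#' @export
k2p_matrix <- function(records, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(length(records) >= 2L)
  ids <- vapply(records, .id_of, character(1))
  seqs <- vapply(records, function(r) toupper(.seq_of(r)), character(1))
  if (length(unique(nchar(seqs))) != 1L)
    stop("records must be aligned to equal length", call. = FALSE)
  if (deletion == "complete") {
    mat <- do.call(rbind, strsplit(seqs, ""))
    keep <- apply(mat, 2, function(col) all(col %in% .dna_concrete))
    if (!any(keep)) stop("no usable columns after complete deletion",
                         call. = FALSE)
    seqs <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  }
  k <- length(seqs)
  d <- matrix(0, k, k, dimnames = list(ids, ids))
  n_sat <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      val <- tryCatch(k2p_distance(seqs[i], seqs[j])$d,
                      beeRFLP_saturation = function(e) NA_real_)
      if (is.na(val)) n_sat <- n_sat + 1L
      d[i, j] <- d[j, i] <- val
    }
  }
  if (n_sat > 0L)
    warning(n_sat, " saturated pair(s) set to NA", call. = FALSE)
  attr(d, "n_saturated") <- n_sat
  d
}

#' Mean pairwise K2P distance within groups
#'
#' The package's measure of intra-group barcode variability: the average
#' K2P distance over unordered pairs inside each group, plus the overall
#' average over all pairs. Groups with fewer than two members are `NA`.
#' Saturated pairs are excluded with a warning and counted.
#'
#' @param records List of aligned [seq_record]s.
#' @param groups Named character vector, record id -> group label.
#' @inheritParams k2p_matrix
#' @return `data.frame` with columns `group`, `n_members`, `n_pairs`,
#'   `mean_d`; the last row (`group == "overall"`) averages all pairs.
#' @export
mean_group_distance <- function(records, groups,
                                deletion = c("pairwise", "complete")) {
  d <- k2p_matrix(records, deletion = match.arg(deletion))
  ids <- rownames(d)
  stopifnot(all(ids %in% names(groups)))
  pair_mean <- function(members) {
    if (length(members) < 2L) return(c(n = length(members), pairs = 0, m = NA))
    sub <- d[members, members]
    vals <- sub[upper.tri(sub)]
    c(n = length(members), pairs = sum(!is.na(vals)),
      m = mean(vals, na.rm = TRUE))
  }
  labs <- unique(groups[ids])
  rows <- lapply(labs, function(g) {
    st <- pair_mean(ids[groups[ids] == g])
    data.frame(group = g, n_members = st[["n"]], n_pairs = st[["pairs"]],
               mean_d = st[["m"]], stringsAsFactors = FALSE)
  })
  st <- pair_mean(ids)
  rows[[length(rows) + 1L]] <- data.frame(
    group = "overall", n_members = st[["n"]], n_pairs = st[["pairs"]],
    mean_d = st[["m"]], stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj]). Negative
#' branch-length estimates, which NJ can produce on non-additive matrices,
#' are clamped to zero and flagged through the attribute
#' `negative_clamped`.
#'
#' @param dm Symmetric labelled distance matrix (e.g. from [k2p_matrix]).
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("neighbor joining requires >= 3 taxa", call. = FALSE)
  if (any(!is.finite(dm)))
    stop("distance matrix contains non-finite entries ",
         "(saturated pairs?); cannot build a tree", call. = FALSE)
  tr <- ape::nj(dm)
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "negative_clamped") <- clamped
  tr
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P/NJ tree
#' per replicate, and reports for every internal edge of the original tree
#' the percentage of replicates containing the same bipartition
#' (unrooted). Replicates in which some pair saturates are skipped and
#' counted. Reproducible for a fixed `seed`.
#'
#' @param records List of aligned [seq_record]s (>= 3).
#' @param n_reps Number of replicates (>= 1; 500 is conventional for
#'   barcode trees).
#' @param seed Integer seed for the column resampling.
#' @inheritParams k2p_matrix
#' @return The original NJ tree with integer percentage supports in
#'   `node.label` (root node blank) and attributes `n_reps_used` and
#'   `n_skipped`.
#' @export
bootstrap_support <- function(records, n_reps = 500L, seed = NULL,
                              deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(length(records) >= 3L, n_reps >= 1L)
  ids <- vapply(records, .id_of, character(1))
  seqs <- vapply(records, function(r) toupper(.seq_of(r)), character(1))
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- ids
  ref <- nj_tree(k2p_matrix(records, deletion = deletion))

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  draws <- matrix(sample.int(ncol(mat), ncol(mat) * n_reps, replace = TRUE),
                  nrow = n_reps)
  trees <- list()
  n_skipped <- 0L
  for (r in seq_len(n_reps)) {
    sub <- mat[, draws[r, ], drop = FALSE]
    reps <- lapply(seq_len(nrow(sub)), function(i)
      seq_record(ids[i], paste(sub[i, ], collapse = "")))
    tr <- tryCatch({
      dm <- suppressWarnings(k2p_matrix(reps, deletion = "pairwise"))
      if (any(!is.finite(dm))) NULL else nj_tree(dm)
    }, error = function(e) NULL)
    if (is.null(tr)) n_skipped <- n_skipped + 1L else
      trees[[length(trees) + 1L]] <- tr
  }
  n_used <- length(trees)
  if (n_used == 0L) stop("all bootstrap replicates failed", call. = FALSE)
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- as.integer(round(100 * counts / n_used))
  ref$node.label <- as.character(support)
  ref$node.label[1L] <- ""  # root of the unrooted display carries no support
  attr(ref, "n_reps_used") <- n_used
  attr(ref, "n_skipped") <- n_skipped
  ref
}

#' Write / read trees in Newick format
#'
#' Thin wrappers around [ape::write.tree] and [ape::read.tree] so that trees
#' round-trip with topology, branch lengths and node-label supports intact.
#'
#' @param tree An [ape::phylo] object.
#' @param path File path.
#' @return `read_newick` returns an [ape::phylo]; malformed input is an
#'   error naming the file.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed Newick in '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  if (is.null(tr)) stop("malformed Newick in '", path, "'", call. = FALSE)
  tr
}
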