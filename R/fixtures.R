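# Seeded generator of 658-bp Folmer-like haplotype fixtures.
#
# The five haplotypes (mellifera_H1, mellifera_H2, carpatica, carnica,
# caucasica) share a random AT-rich background into which the generator
# implants (i) the footprints of the four packaged primer pairs at offsets
# chosen so every uncut product has its published length, (ii) one
# recognition-site context per assay placed so the diagnostic allele
# completes the site in the target haplotypes only, and (iii) the
# diagnostic alleles themselves. Each assay's fragment split then equals
# the published digestion table exactly, and non-target products contain no
# recognition site at all (enforced by a deterministic scrub of the random
# background followed by full re-simulation).
#
# Site placements are solved in template coordinates rather than across the
# primer junction: the printed fragment pairs are reproduced exactly by an
# in-template site whose completing base is the diagnostic allele (the
# HinfI assay keyed on position 421, HspAI on 99, MspI on 448) or, for the
# AluI assay, one of haplogroup 1's C->T transitions at a fixture-defined
# position. See the methods vignette for why the AluI and HinfI sites
# cannot both contain position 421.

.FOLMER_LEN <- 658L

# Folmer-frame layout: amplicon spans, footprint implants, site contexts.
.fixture_layout <- function() {
  primers <- load_primers()
  rc <- reverse_complement
  implants <- list(
    list(start = 70L,  seq = primers$`AmCarp-f`$seq),            # 70..87
    list(start = 178L, seq = rc(primers$`AmCarp-r`$seq)),        # 178..210
    list(start = 299L, seq = primers$`AmEu2-f`$seq),             # 299..329
    # AmCar-f resolved (M->A, Y->T); base 1 yields to AmEu2-f's 3' T at 329
    list(start = 330L, seq = substring(
      gsub("Y", "T", gsub("M", "A", primers$`AmCar-f`$seq)), 2L)),  # 330..360
    list(start = 431L, seq = rc(primers$`AmEu2-r`$seq)),         # 431..448
    list(start = 458L, seq = rc(primers$`AmCar-r`$seq)),         # 458..476
    list(start = 500L, seq = primers$`AmEu1-f`$seq),             # 500..519
    list(start = 607L, seq = rc(primers$`AmEu1-r`$seq))          # 607..638
  )
  # fixed context bases: recognition-site completions and junction guards
  context <- c(
    `100` = "C", `101` = "G", `102` = "C",   # HspAI GCGC completed by G@99
    `177` = "T",                             # guard: no GCGC at footprint edge
    `361` = "A",                             # guard: no CCGG at AmCar junction
    `420` = "G", `423` = "T", `424` = "C",   # HinfI GANTC completed by A@421
    `447` = "C", `449` = "G",                # MspI CCGG completed by G@448
    `530` = "A", `531` = "G", `532` = "C",   # AluI AGCT completed by T@533
    `606` = "T"                              # guard: no AGCT at footprint edge
  )
  snps <- list(pos99 = 99L, pos421 = 421L, pos448 = 448L, h1_alu = 533L)
  amplicons <- list(AmCarp = c(70L, 210L), AmEu2 = c(299L, 448L),
                    AmCar = c(329L, 476L), AmEu1 = c(500L, 638L))
  # designed recognition-site start, Folmer coordinates, per assay
  site_starts <- c(AmCarp = 99L, AmEu2 = 420L, AmCar = 446L, AmEu1 = 530L)
  background_alleles <- c(`99` = "A", `421` = "C", `448` = "A", `533` = "C")
  list(implants = implants, context = context, snps = snps,
       amplicons = amplicons, site_starts = site_starts,
       background_alleles = background_alleles)
}

.constrained_positions <- function(layout) {
  pos <- integer()
  for (im in layout$implants)
    pos <- c(pos, im$start:(im$start + nchar(im$seq) - 1L))
  pos <- c(pos, as.integer(names(layout$context)),
           unlist(layout$snps, use.names = FALSE))
  sort(unique(pos))
}

.free_zones <- function(layout) {
  spans <- do.call(rbind, layout$amplicons)
  covered <- unlist(apply(spans, 1, function(x) x[1]:x[2]))
  setdiff(seq_len(.FOLMER_LEN), covered)
}

.build_haplotypes <- function(bg, layout, h1_extra_pos) {
  set_base <- function(chars, pos, base) { chars[pos] <- base; chars }
  mk <- function(chars, id) seq_record(id, paste(chars, collapse = ""))
  cauc <- bg
  carp <- set_base(bg, 99L, "G")
  carn <- set_base(carp, 448L, "G")
  h2 <- set_base(bg, 421L, "A")
  h1 <- set_base(set_base(bg, 421L, "T"), 533L, "T")
  for (i in seq_along(h1_extra_pos$pos))
    h1[h1_extra_pos$pos[i]] <- h1_extra_pos$base[i]
  list(mellifera_H1 = mk(h1, "mellifera_H1"),
       mellifera_H2 = mk(h2, "mellifera_H2"),
       carpatica = mk(carp, "carpatica"),
       carnica = mk(carn, "carnica"),
       caucasica = mk(cauc, "caucasica"))
}

# Draw haplogroup-1's additional background divergence in the regions
# outside every assay amplicon, so intra-subspecies variation can never
# perturb an assay product: n_ct C<->T transitions, one A->G transition and
# one T->A transversion.
.draw_h1_extra <- function(bg, layout, n_ct) {
  zones <- .free_zones(layout)
  ct_pool <- zones[bg[zones] %in% c("C", "T")]
  a_pool <- zones[bg[zones] == "A"]
  t_pool <- zones[bg[zones] == "T"]
  if (length(ct_pool) < n_ct + 1L || length(a_pool) < 1L)
    stop("background too constrained to place haplogroup-1 divergence",
         call. = FALSE)
  ct <- sample(ct_pool, n_ct)
  a1 <- sample(a_pool, 1L)
  t1 <- sample(setdiff(t_pool, ct), 1L)
  pos <- c(ct, a1, t1)
  base <- c(ifelse(bg[ct] == "C", "T", "C"), "G", "A")
  list(pos = pos, base = base)
}

# One scrub pass: re-simulate all assay x haplotype cells; destroy every
# unexpected recognition site by flipping a free background base inside it.
# Returns list(bg = possibly-modified background, clean = logical,
# stuck = logical).
.scrub_pass <- function(bg, layout, haps, assays, expected, free_ok) {
  tab <- iupac_table()
  for (an in names(assays)) {
    asy <- assays[[an]]
    exp_row <- expected[an, ]
    for (hn in names(haps)) {
      amps <- amplify(haps[[hn]], asy$fwd, asy$rev,
                      max_mismatch = asy$max_mismatch,
                      size_range = asy$size_range)
      if (length(amps) != 1L) return(list(bg = bg, clean = FALSE,
                                          stuck = TRUE))
      prod <- amps[[1]]$product_seq
      dg <- digest(prod, asy$enzyme)
      want <- as.integer(strsplit(exp_row[[hn]], ",")[[1]])
      if (identical(sort(dg$fragment_lengths, decreasing = TRUE),
                    sort(want, decreasing = TRUE))) next
      # locate unexpected site occurrences and flip a free base inside one
      sites <- find_sites(prod, asy$enzyme)
      expected_cut <- length(want) > 1L
      site_len <- nchar(asy$enzyme$site)
      keep <- if (expected_cut) {
        designed <- layout$site_starts[[an]] - amps[[1]]$start + 1L
        sites[sites != designed]
      } else sites
      if (!length(keep)) return(list(bg = bg, clean = FALSE, stuck = TRUE))
      fixed <- FALSE
      for (sp in keep) {
        tpos <- (amps[[1]]$start + sp - 1L):(amps[[1]]$start + sp + site_len - 2L)
        cand <- tpos[free_ok[tpos]]
        if (!length(cand)) next
        p <- cand[1L]
        offset <- p - (amps[[1]]$start + sp - 1L) + 1L
        want_char <- strsplit(asy$enzyme$site, "")[[1]][offset]
        bad <- tab[[want_char]]
        # also avoid the reverse-complement site's requirement at p
        repl <- setdiff(c("T", "A", "C", "G"), bad)[1L]
        bg[p] <- repl
        fixed <- TRUE
        break
      }
      if (!fixed) return(list(bg = bg, clean = FALSE, stuck = TRUE))
      return(list(bg = bg, clean = FALSE, stuck = FALSE))
    }
  }
  list(bg = bg, clean = TRUE, stuck = FALSE)
}

#' Generate the five Folmer-region haplotype fixtures
#'
#' Builds a seeded random AT-rich 658-bp background, implants the packaged
#' primer footprints, recognition-site contexts and diagnostic alleles, and
#' iterates a deterministic scrub until every one of the twenty assay-by-
#' haplotype cells re-simulates to its published fragment pattern. The
#' generator exercises the amplification and digestion engines themselves:
#' fixtures are accepted only after full re-simulation.
#'
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param gc Background GC content (default 0.30; the honey-bee COX1 region
#'   is AT-rich).
#' @param n_h1_ct Additional C<->T transitions private to mellifera
#'   haplogroup 1, beyond the two it carries inside assay amplicons
#'   (positions 421 and the AluI-site position), for a default total of 8.
#' @param max_tries Background resamples before giving up.
#' @return Object of class `bee_fixtures`: list with `haplotypes` (named
#'   list of five [seq_record]s), `assays`, `expected` (fragment table),
#'   `validation` (the 20-cell re-simulation table), `layout` and `seed`.
#' @export
generate_fixtures <- function(seed = 1L, gc = 0.30, n_h1_ct = 6L,
                              max_tries = 25L) {
  layout <- .fixture_layout()
  assays <- load_assays()
  expected <- expected_patterns()
  constrained <- .constrained_positions(layout)
  free_ok <- rep(TRUE, .FOLMER_LEN)
  free_ok[constrained] <- FALSE

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)

  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  for (try in seq_len(max_tries)) {
    bg <- sample(names(probs), .FOLMER_LEN, replace = TRUE, prob = probs)
    for (im in layout$implants) {
      chars <- strsplit(im$seq, "")[[1]]
      bg[im$start:(im$start + length(chars) - 1L)] <- chars
    }
    for (nm in names(layout$context)) bg[as.integer(nm)] <- layout$context[[nm]]
    for (nm in names(layout$background_alleles))
      bg[as.integer(nm)] <- layout$background_alleles[[nm]]

    h1_extra <- .draw_h1_extra(bg, layout, n_h1_ct)

    stuck <- FALSE
    for (pass in seq_len(60L)) {
      haps <- .build_haplotypes(bg, layout, h1_extra)
      res <- .scrub_pass(bg, layout, haps, assays, expected, free_ok)
      bg <- res$bg
      if (res$clean) break
      if (res$stuck) { stuck <- TRUE; break }
    }
    if (stuck || !res$clean) next

    haps <- .build_haplotypes(bg, layout, h1_extra)
    validation <- do.call(rbind, lapply(names(assays), function(an) {
      v <- validate_assay(assays[[an]], haps)
      cbind(assay = an, v, stringsAsFactors = FALSE)
    }))
    ok <- all(vapply(seq_len(nrow(validation)), function(i)
      identical(validation$fragments[i],
                expected[validation$assay[i], validation$haplotype[i]]),
      logical(1)))
    if (!ok) next

    return(structure(list(haplotypes = haps, assays = assays,
                          expected = expected, validation = validation,
                          layout = layout, seed = seed),
                     class = "bee_fixtures"))
  }
  stop("could not satisfy all fixture constraints after ", max_tries,
       " background resamples", call. = FALSE)
}

#' @export
print.bee_fixtures <- function(x, ...) {
  cat(sprintf("<bee_fixtures seed=%d: %d haplotypes x %d assays, all cells validated>\n",
              x$seed, length(x$haplotypes), length(x$assays)))
  invisible(x)
}

#' Write fixtures to a directory
#'
#' Emits `haplotypes.fasta`, the expected fragment table
#' (`expected_patterns.tsv`), the re-simulated validation table
#' (`validation.tsv`) and the observed per-assay cut/uncut pattern table
#' (`observed_patterns.tsv`, one row per haplotype, suitable for
#' [classify_samples]).
#'
#' @param fx `bee_fixtures` object.
#' @param dir Output directory (created if missing).
#' @export
write_fixtures <- function(fx, dir) {
  stopifnot(inherits(fx, "bee_fixtures"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fx$haplotypes, file.path(dir, "haplotypes.fasta"))
  exp_out <- cbind(assay = rownames(fx$expected), fx$expected)
  utils::write.table(exp_out, file.path(dir, "expected_patterns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fx$validation, file.path(dir, "validation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  obs <- fixture_patterns(fx)
  utils::write.table(obs, file.path(dir, "observed_patterns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Observed cut/uncut pattern table for a fixture set
#'
#' @param fx `bee_fixtures` object.
#' @return `data.frame` with a `sample` column and one cut/uncut column per
#'   assay enzyme, as consumed by [classify_samples].
#' @export
fixture_patterns <- function(fx) {
  stopifnot(inherits(fx, "bee_fixtures"))
  enz_of <- vapply(fx$assays, function(a) a$enzyme$name, character(1))
  samples <- names(fx$haplotypes)
  out <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (an in names(fx$assays)) {
    v <- fx$validation[fx$validation$assay == an, ]
    out[[enz_of[[an]]]] <- ifelse(v$cut[match(samples, v$haplotype)],
                                  "cut", "uncut")
  }
  out
}

#' Introduce controlled substitutions into a record
#'
#' Adds exactly `n_transitions` transitions (A<->G, C<->T) and
#' `n_transversions` transversions at uniformly drawn positions outside
#' `protected`, reproducibly for a fixed seed. Used to emulate intra-breed
#' variability around a fixture haplotype.
#'
#' @param record [seq_record].
#' @param n_transitions,n_transversions Substitution counts (>= 0).
#' @param seed Integer seed.
#' @param protected Integer vector of 1-based positions that must not be
#'   touched (primer footprints, diagnostic sites).
#' @return A new [seq_record] with id suffixed `"_mut"`.
#' @export
mutate_record <- function(record, n_transitions, n_transversions, seed,
                          protected = integer()) {
  stopifnot(n_transitions >= 0L, n_transversions >= 0L)
  chars <- strsplit(toupper(.seq_of(record)), "")[[1]]
  pool <- setdiff(which(chars %in% .dna_concrete), protected)
  n <- n_transitions + n_transversions
  if (length(pool) < n)
    stop("only ", length(pool), " unprotected positions for ", n,
         " substitutions", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pos <- sample(pool, n)
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partner <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))
  if (n_transitions > 0L) {
    p <- pos[seq_len(n_transitions)]
    chars[p] <- ts_partner[chars[p]]
  }
  if (n_transversions > 0L) {
    p <- pos[n_transitions + seq_len(n_transversions)]
    chars[p] <- vapply(chars[p], function(b) sample(tv_partner[[b]], 1L),
                       character(1))
  }
  seq_record(paste0(.id_of(record), "_mut"), paste(chars, collapse = ""),
             desc = sprintf("%d ts + %d tv from %s", n_transitions,
                            n_transversions, .id_of(record)))
}
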