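# Independent brute-force oracles and random-sequence helpers. These are
# deliberately naive re-derivations (nested loops, regex scans) so that the
# vectorised implementations in the package are checked against a different
# computational path.

# IUPAC expansions taken directly from Biostrings, not from the package
ORACLE_IUPAC <- lapply(as.list(Biostrings::IUPAC_CODE_MAP),
                       function(x) strsplit(x, "")[[1]])

rand_dna <- function(n, gc = 0.35) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y", W = "W",
            S = "S", Y = "R", K = "M", V = "B", H = "D", D = "H", B = "V",
            N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# all offsets at which `pattern` (IUPAC) matches `subject` (concrete) with
# at most max_mm mismatching positions; plain nested loops
oracle_scan <- function(subject, pattern, max_mm = 0L) {
  sc <- strsplit(subject, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  n <- length(sc); m <- length(pc)
  if (m > n) return(integer())
  hits <- integer()
  for (s in 1:(n - m + 1L)) {
    mm <- 0L
    for (j in 1:m) {
      if (!sc[s + j - 1L] %in% ORACLE_IUPAC[[pc[j]]]) mm <- mm + 1L
      if (mm > max_mm) break
    }
    if (mm <= max_mm) hits <- c(hits, s)
  }
  hits
}

# both-strand restriction-site scan via the naive scanner
oracle_sites <- function(seq, site) {
  sort(union(oracle_scan(seq, site, 0L),
             oracle_scan(seq, oracle_revcomp(site), 0L)))
}

# overlapping site count through lookahead regex: a third, independent path
regex_site_count <- function(seq, site) {
  to_re <- function(p) {
    chars <- strsplit(p, "")[[1]]
    paste(vapply(chars, function(ch) {
      exp <- ORACLE_IUPAC[[ch]]
      if (length(exp) == 1L) exp else paste0("[", paste(exp, collapse = ""), "]")
    }, character(1)), collapse = "")
  }
  at <- function(pat) {
    m <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1L) integer() else as.integer(m)
  }
  rc <- oracle_revcomp(site)
  length(union(at(to_re(site)), at(to_re(rc))))
}

# Build a template that contains the given primer footprints verbatim:
# [left flank][fwd][interior][revcomp(rev)][right flank]
template_with_footprints <- function(fwd_seq, rev_seq, interior,
                                     left = "", right = "") {
  paste0(left, fwd_seq, interior, oracle_revcomp(rev_seq), right)
}

# Exhaustive design-existence oracle at toy scale: is there any enzyme /
# strand / site placement / primer-template split that yields an
# allele-specific cut, validating products by direct string construction
# and the regex site counter? Mirrors the problem definition, not the
# package's search implementation.
oracle_design_exists <- function(seqs, snp_pos, enzymes, size_range,
                                 max_subs = 2L, mut_len = 30L,
                                 opp_len = 19L) {
  n <- nchar(seqs[[1]])
  for (enz in enzymes) {
    site <- enz$site
    L <- nchar(site)
    for (strand in c("+", "-")) {
      ws <- if (strand == "+") seqs else lapply(seqs, oracle_revcomp)
      wp <- if (strand == "+") snp_pos else n - snp_pos + 1L
      alle <- vapply(ws, function(s) substr(s, wp, wp), character(1))
      for (k in 0:(L - 1L)) {
        s0 <- wp - k
        if (s0 < 1L || s0 + L - 1L > n) next
        sc <- substr(site, k + 1L, k + 1L)
        targets <- names(alle)[vapply(alle, function(b)
          b %in% ORACLE_IUPAC[[sc]], logical(1))]
        if (!length(targets) || length(targets) == length(alle)) next
        for (e in (s0 - 1L):(wp - 1L)) {
          ps <- e - mut_len + 1L
          if (ps < 1L || e < 1L) next
          tpl_rng <- (e + 1L):(s0 + L - 1L)
          tmpl_ok <- all(vapply(targets, function(h) {
            all(mapply(function(pos, j)
              substr(ws[[h]], pos, pos) %in%
                ORACLE_IUPAC[[substr(site, j, j)]],
              tpl_rng, tpl_rng - s0 + 1L))
          }, logical(1)))
          if (!tmpl_ok) next
          pr <- strsplit(substr(ws[[targets[1]]], ps, e), "")[[1]]
          nsub <- 0L; subs_ok <- TRUE
          if (e >= s0) for (pos in s0:e) {
            j <- pos - ps + 1L
            want <- ORACLE_IUPAC[[substr(site, pos - s0 + 1L, pos - s0 + 1L)]]
            if (!pr[j] %in% want) {
              pr[j] <- want[1L]
              nsub <- nsub + 1L
              if (j <= mut_len / 2) subs_ok <- FALSE
            }
          }
          if (!subs_ok || nsub > max_subs) next
          for (plen in size_range[1]:size_range[2]) {
            qe <- ps + plen - 1L
            if (qe > n) break
            qs <- qe - opp_len + 1L
            if (qs <= e) next
            ok <- TRUE
            for (h in names(ws)) {
              prod <- paste0(paste(pr, collapse = ""),
                             substr(ws[[h]], e + 1L, qe))
              cut <- regex_site_count(prod, site) > 0L
              if (cut != (h %in% targets)) { ok <- FALSE; break }
            }
            if (ok) return(TRUE)
          }
        }
      }
    }
  }
  FALSE
}
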