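primers <- load_primers()

test_that("find_primer_sites locates exact and degenerate footprints", {
  set.seed(21)
  lep_r1 <- primers$LepR1
  tmpl <- seq_record("t1", paste0(rand_dna(40), oracle_revcomp(lep_r1$seq),
                                  rand_dna(40)))
  hits <- find_primer_sites(tmpl, lep_r1, max_mismatch = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 41L)
  expect_equal(hits$mismatches, 0L)

  # AmCar-f carries M and Y; a footprint reading A and T at those positions
  # anneals without mismatch
  amcar_f <- primers$`AmCar-f`
  resolved <- gsub("Y", "T", gsub("M", "A", amcar_f$seq))
  tmpl2 <- seq_record("t2", paste0(rand_dna(25), resolved, rand_dna(25)))
  hits2 <- find_primer_sites(tmpl2, amcar_f, max_mismatch = 0)
  expect_true(any(hits2$strand == "+" & hits2$start == 26L &
                    hits2$mismatches == 0L))
})

test_that("a 20-nt primer absent from a random 100-bp template yields no hit", {
  set.seed(33)
  tmpl <- seq_record("t", rand_dna(100, gc = 0.5))
  p <- primer("probe", "GGGGCCCCGGGGCCCCGGGG", "forward")
  expect_equal(nrow(find_primer_sites(tmpl, p, max_mismatch = 0)), 0L)
})

test_that("mismatch accounting agrees with the brute-force scanner", {
  set.seed(55)
  for (rep in 1:40) {
    n <- sample(60:200, 1)
    tmpl <- rand_dna(n)
    m <- sample(15:24, 1)
    pseq <- if (rep %% 3 == 0) {
      # embed a (possibly degenerate) footprint to guarantee hits
      start <- sample(n - m, 1)
      foot <- substr(tmpl, start, start + m - 1L)
      pieces <- strsplit(foot, "")[[1]]
      j <- sample(m, 1)
      pieces[j] <- c(A = "M", C = "Y", G = "R", T = "W")[pieces[j]]
      paste(pieces, collapse = "")
    } else rand_dna(m)
    mm_budget <- sample(0:3, 1)
    p <- primer("p", pseq, "forward")
    hits <- find_primer_sites(tmpl, p, max_mismatch = mm_budget)

    exp_plus <- oracle_scan(tmpl, pseq, mm_budget)
    exp_minus <- oracle_scan(tmpl, oracle_revcomp(pseq), mm_budget)
    got_plus <- sort(hits$start[hits$strand == "+"])
    got_minus <- sort(hits$start[hits$strand == "-"])
    expect_identical(got_plus, exp_plus)
    expect_identical(got_minus, exp_minus)
    # footprint width is always the primer length
    expect_true(all(hits$end - hits$start + 1L == nchar(pseq)))
    expect_true(all(hits$mismatches ==
                      lengths(hits$mismatch_positions)))
  }
})

test_that("amplify reproduces exact product lengths from planted footprints", {
  set.seed(77)
  fwd <- primers$`AmEu1-f`; rev <- primers$`AmEu1-r`
  interior <- rand_dna(87)
  tmpl <- seq_record("hap", template_with_footprints(
    fwd$seq, rev$seq, interior, left = rand_dna(30), right = rand_dna(30)))
  amps <- amplify(tmpl, fwd, rev, max_mismatch = 0, size_range = c(120, 160))
  expect_length(amps, 1L)
  expect_equal(amps[[1]]$length, 20L + 87L + 32L)
  expect_equal(amps[[1]]$product_seq,
               paste0(fwd$seq, interior, oracle_revcomp(rev$seq)))
})

test_that("amplify enforces orientation and the size window", {
  set.seed(78)
  fwd <- primer("f", "ATTGACCTAGGATCAGT", "forward")
  rev <- primer("r", "CCATGGTTAGGACTTAC", "reverse")
  # reverse footprint upstream of the forward footprint: no product
  tmpl_bad <- seq_record("bad", paste0(
    rand_dna(20), oracle_revcomp(rev$seq), rand_dna(40), fwd$seq,
    rand_dna(20)))
  expect_length(amplify(tmpl_bad, fwd, rev, max_mismatch = 0), 0L)

  # 200-bp product excluded by the assay window [120, 160]
  tmpl_long <- seq_record("long", paste0(
    rand_dna(10), fwd$seq, rand_dna(200 - 17 - 17),
    oracle_revcomp(rev$seq), rand_dna(10)))
  expect_length(amplify(tmpl_long, fwd, rev, max_mismatch = 0,
                        size_range = c(120, 160)), 0L)
  expect_length(amplify(tmpl_long, fwd, rev, max_mismatch = 0,
                        size_range = c(120, 250)), 1L)
})

test_that("primer overwrite confines product/template differences to footprints", {
  set.seed(99)
  for (rep in 1:25) {
    n <- 220L
    tmpl_seq <- rand_dna(n)
    fs <- 21L; fe <- fs + 19L
    rs <- 181L; re <- rs + 19L
    fwd_chars <- strsplit(substr(tmpl_seq, fs, fe), "")[[1]]
    # mutagenic: force 1-2 substitutions in the 3'-terminal half
    nsub <- sample(1:2, 1)
    pos <- sample(11:20, nsub)
    for (p in pos) fwd_chars[p] <- setdiff(c("A", "C", "G", "T"),
                                           fwd_chars[p])[sample(3, 1)]
    fwd <- primer("mut-f", paste(fwd_chars, collapse = ""), "forward",
                  mutagenic = TRUE, mutated_positions = pos)
    rev <- primer("r", oracle_revcomp(substr(tmpl_seq, rs, re)), "reverse")
    amps <- amplify(seq_record("t", tmpl_seq), fwd, rev,
                    max_mismatch = 3, size_range = c(100, 250))
    amp <- Filter(function(a) a$start == fs && a$end == re, amps)
    expect_length(amp, 1L)
    prod <- strsplit(amp[[1]]$product_seq, "")[[1]]
    tpl <- strsplit(substr(tmpl_seq, fs, re), "")[[1]]
    diffs <- which(prod != tpl)
    # every difference lies inside a primer footprint, at the mutated spots
    expect_true(all(diffs %in% pos))
  }
})

test_that("nested amplification rescues primers that only match the overwritten product", {
  set.seed(101)
  tmpl_seq <- rand_dna(240)
  os <- 31L; oe <- os + 21L
  outer_chars <- strsplit(substr(tmpl_seq, os, oe), "")[[1]]
  outer_chars[c(15L, 20L)] <- vapply(outer_chars[c(15L, 20L)], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  outer_f <- primer("outer-f", paste(outer_chars, collapse = ""), "forward")
  outer_r <- primer("outer-r", oracle_revcomp(substr(tmpl_seq, 191, 210)),
                    "reverse")
  inner_f <- primer("inner-f", outer_f$seq, "forward")  # exact only on product
  inner_r <- primer("inner-r", oracle_revcomp(substr(tmpl_seq, 141, 160)),
                    "reverse")
  tmpl <- seq_record("degraded", tmpl_seq)

  direct <- amplify(tmpl, inner_f, inner_r, max_mismatch = 0,
                    size_range = c(100, 250))
  expect_length(direct, 0L)

  nested <- nested_amplify(tmpl, list(outer_f, outer_r),
                           list(inner_f, inner_r), max_mismatch = 0,
                           size_range = c(100, 250),
                           outer_max_mismatch = 2)
  expect_length(nested, 1L)
  expect_equal(nested[[1]]$length, 130L)
})

test_that("nested amplification flags outer failure and is idempotent", {
  set.seed(103)
  tmpl <- seq_record("t", rand_dna(200))
  absent_f <- primer("af", "GGGGCCCCGGGGCCCC", "forward")
  absent_r <- primer("ar", "CCCCGGGGCCCCGGGG", "reverse")
  inner_f <- primer("if", substr(tmpl$seq, 11, 28), "forward")
  inner_r <- primer("ir", oracle_revcomp(substr(tmpl$seq, 151, 168)),
                    "reverse")
  res <- nested_amplify(tmpl, list(absent_f, absent_r),
                        list(inner_f, inner_r))
  expect_length(res, 0L)
  expect_true(attr(res, "outer_failed"))

  # inner pair == outer pair: the two-step product equals the one-step one
  one <- amplify(tmpl, inner_f, inner_r, max_mismatch = 0)
  two <- nested_amplify(tmpl, list(inner_f, inner_r), list(inner_f, inner_r),
                        max_mismatch = 0)
  expect_equal(vapply(two, `[[`, "", "product_seq"),
               vapply(one, `[[`, "", "product_seq"))
})

test_that("primer constructor enforces the mutagenic contract", {
  expect_error(primer("p", "ACGTACGTAC", "forward"), "15")
  expect_error(primer("p", "ACGTACGTACGTACGTACGT", "forward",
                      mutagenic = TRUE, mutated_positions = c(1, 2, 3)),
               "1 or 2")
  expect_error(primer("p", "ACGTACGTACGTACGTACGT", "forward",
                      mutagenic = TRUE, mutated_positions = 2),
               "3'-terminal half")
  p <- primer("p", "ACGTACGTACGTACGTACGT", "forward",
              mutagenic = TRUE, mutated_positions = c(19, 20))
  expect_true(p$mutagenic)
})
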