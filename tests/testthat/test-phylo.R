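test_that("K2P matches its closed form and handles saturation", {
  a <- paste(rep("A", 20), collapse = "")
  expect_equal(k2p_distance(a, a)$d, 0)

  # one transition in 20 bp: P = 0.05, d = -0.5 ln(0.9)
  b <- paste(c(rep("A", 19), "G"), collapse = "")
  res <- k2p_distance(a, b)
  expect_equal(res$P, 0.05)
  expect_equal(res$Q, 0)
  expect_equal(res$d, -0.5 * log(1 - 2 * 0.05), tolerance = 1e-12)
  expect_equal(res$d, 0.05268, tolerance = 1e-4)

  # P = 0.5, Q = 0 saturates the transition term
  half <- paste(c(rep("G", 10), rep("A", 10)), collapse = "")
  expect_error(k2p_distance(a, half), class = "beeRFLP_saturation")
})

test_that("K2P counts transitions and transversions separately", {
  s1 <- "AAAACCCCGGGGTTTT"
  s2 <- "GAAATCCCAGGGATTT"  # A>G ts, C>T ts, G>A ts, T>A tv
  res <- k2p_distance(s1, s2)
  expect_equal(res$transitions, 3L)
  expect_equal(res$transversions, 1L)
  expect_equal(res$d,
               -0.5 * log(1 - 2 * 3 / 16 - 1 / 16) - 0.25 * log(1 - 2 / 16),
               tolerance = 1e-12)
})

test_that("pairwise deletion drops gap/N sites; K2P agrees with ape", {
  a <- seq_record("a", "ACGTACGTACGTACGTACG-")
  b <- seq_record("b", "ACGTACGTNCGTACGAACGT")
  res <- k2p_distance(a, b)
  expect_equal(res$n_sites, 18L)  # one gap site + one N site dropped

  set.seed(17)
  base <- strsplit(rand_dna(400), "")[[1]]
  recs <- lapply(1:5, function(i) {
    s <- base
    idx <- sample(400, 12)
    s[idx] <- vapply(s[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    seq_record(paste0("s", i), paste(s, collapse = ""))
  })
  mine <- k2p_matrix(recs)
  chmat <- do.call(rbind, lapply(recs, function(r)
    strsplit(tolower(r$seq), "")[[1]]))
  rownames(chmat) <- vapply(recs, `[[`, "", "id")
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(chmat), model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("for small P with Q = 0 the K2P distance approaches P", {
  for (k in c(2L, 5L)) {          # P = 0.002, 0.005 over 1000 sites
    a <- paste(rep("A", 1000), collapse = "")
    b <- paste(c(rep("G", k), rep("A", 1000 - k)), collapse = "")
    res <- k2p_distance(a, b)
    expect_equal(res$d, res$P, tolerance = 0.01)
  }
})

test_that("group variability is the mean pairwise distance, NA for singletons", {
  a <- seq_record("a", paste(rep("ACGT", 50), collapse = ""))
  b <- mutate_record(a, 2, 0, seed = 9)
  b$id <- "b"
  c_ <- seq_record("c", paste(rep("ACGT", 50), collapse = ""))
  groups <- c(a = "g1", b = "g1", c = "g2")
  tab <- mean_group_distance(list(a, b, c_), groups)
  expect_equal(tab$mean_d[tab$group == "g1"],
               k2p_distance(a, b)$d, tolerance = 1e-12)
  expect_true(is.na(tab$mean_d[tab$group == "g2"]))
  d_ab <- k2p_distance(a, b)$d
  d_ac <- 0
  d_bc <- k2p_distance(b, c_)$d
  expect_equal(tab$mean_d[tab$group == "overall"],
               mean(c(d_ab, d_ac, d_bc)), tolerance = 1e-12)
})

test_that("identical groups have zero variability", {
  a <- seq_record("a", paste(rep("ACGT", 30), collapse = ""))
  b <- seq_record("b", a$seq)
  tab <- mean_group_distance(list(a, b), c(a = "g", b = "g"))
  expect_equal(tab$mean_d[tab$group == "g"], 0)
})

test_that("NJ reproduces the three-point closed form", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d)
  # v_x = (d_xy + d_xz - d_yz)/2 = 1, v_y = 2, v_z = 3
  lens <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(unname(lens[c("x", "y", "z")]), c(1, 2, 3))
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3 taxa")
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    true <- ape::rtree(n, rooted = FALSE,
                       br = function(k) stats::runif(k, 0.05, 1))
    dm <- ape::cophenetic.phylo(true)
    rec <- nj_tree(dm[order(rownames(dm)), order(colnames(dm))])
    expect_equal(ape::dist.topo(ape::unroot(true), rec), 0,
                 ignore_attr = TRUE)
    # additivity: path lengths are restored, not just the topology
    expect_equal(ape::cophenetic.phylo(rec)[rownames(dm), colnames(dm)],
                 dm, tolerance = 1e-8)
  }
})

test_that("degenerate matrices with identical rows do not crash NJ", {
  d <- matrix(c(0, 0, 1, 2,
                0, 0, 1, 2,
                1, 1, 0, 2,
                2, 2, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  expect_true(all(tr$edge.length >= 0))
})

test_that("saturated pairs abort tree building with a clear error", {
  a <- paste(rep("A", 30), collapse = "")
  g <- paste(rep("G", 30), collapse = "")
  t_ <- paste(c(rep("A", 15), rep("G", 15)), collapse = "")
  recs <- list(seq_record("a", a), seq_record("g", g), seq_record("t", t_))
  expect_warning(dm <- k2p_matrix(recs), "saturated")
  expect_error(nj_tree(dm), "non-finite")
})

test_that("bootstrap is reproducible and finds overwhelming signal", {
  set.seed(29)
  # two clades separated by 30 diagnostic columns in a 300-bp alignment
  base <- strsplit(rand_dna(300), "")[[1]]
  variant <- base
  idx <- sample(300, 30)
  variant[idx] <- vapply(base[idx], function(x)
    c(A = "G", G = "A", C = "T", T = "C")[x], character(1))
  jitter1 <- function(chars, pos) {
    chars[pos] <- c(A = "G", G = "A", C = "T", T = "C")[chars[pos]]
    chars
  }
  recs <- list(
    seq_record("a1", paste(base, collapse = "")),
    seq_record("a2", paste(jitter1(base, 3L), collapse = "")),
    seq_record("b1", paste(variant, collapse = "")),
    seq_record("b2", paste(jitter1(variant, 7L), collapse = "")))

  tr1 <- bootstrap_support(recs, n_reps = 100, seed = 42)
  tr2 <- bootstrap_support(recs, n_reps = 100, seed = 42)
  expect_identical(tr1$node.label, tr2$node.label)
  sup <- as.integer(tr1$node.label[tr1$node.label != ""])
  expect_equal(sup, 100L)  # the a|b split is in every replicate

  # order invariance of the supported bipartition
  tr3 <- bootstrap_support(recs[c(3, 1, 4, 2)], n_reps = 100, seed = 42)
  sup3 <- as.integer(tr3$node.label[tr3$node.label != ""])
  expect_equal(sup3, 100L)

  # a single replicate can only give 0 or 100
  tr4 <- bootstrap_support(recs, n_reps = 1, seed = 7)
  sup4 <- as.integer(tr4$node.label[tr4$node.label != ""])
  expect_true(all(sup4 %in% c(0L, 100L)))
})

test_that("Newick round-trip preserves topology, lengths and supports", {
  set.seed(31)
  path <- withr::local_tempfile(fileext = ".nwk")
  for (rep in 1:10) {
    tr <- ape::rtree(sample(4:10, 1))
    write_newick(tr, path)
    back <- read_newick(path)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-8)
  }
  txt <- readLines({write_newick(ape::rtree(3), path); path})
  expect_match(txt, ";$")

  tr <- nj_tree(matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3, 3,
                       dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
  tr$node.label <- "87"
  write_newick(tr, path)
  expect_match(readLines(path), "87")

  writeLines("((a,b,(c,d));", path)
  expect_error(read_newick(path), "[Mm]alformed|error")
})
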