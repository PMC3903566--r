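test_that("FASTA + population map round-trips into a validated set", {
  fa <- writeToyFasta(list(a = "ACGT", b = "ACGA", c = "ACGT"))
  pm <- writeToyPopmap(c("a", "b", "c"), c("p1", "p2", "p2"))
  x <- suppressMessages(readFastaWithPopulations(fa, pm))
  expect_s4_class(x, "AlignedSeqSet")
  expect_equal(length(x), 3L)
  expect_equal(seqLength(x), 4L)
  expect_setequal(unique(populations(x)), c("p1", "p2"))
})

test_that("read errors name the offending records", {
  fa <- writeToyFasta(list(a = "ACGT", b = "ACGA"))
  pm <- writeToyPopmap("a", "p1")
  expect_error(suppressMessages(readFastaWithPopulations(fa, pm)), "b")

  fa2 <- writeToyFasta(list(a = "ACGT", b = "ACG"))
  pm2 <- writeToyPopmap(c("a", "b"), c("p1", "p1"))
  expect_error(suppressMessages(readFastaWithPopulations(fa2, pm2)),
               "length")

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(suppressMessages(readFastaWithPopulations(empty, pm2)))
})

test_that("haplotype collapsing partitions individuals as expected", {
  x <- alignedSeqSet(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"),
                     c("p1", "p1", "p2", "p2"))
  h <- collapseHaplotypes(x)
  expect_equal(unname(haplotypeCounts(h)), matrix(c(2L, 2L), ncol = 1))

  y <- alignedSeqSet(c(a = "AAAA", b = "AAAA", c = "AAAT"), rep("p", 3))
  hy <- collapseHaplotypes(y)
  expect_equal(unname(colSums(haplotypeCounts(hy))), c(2L, 1L))
})

test_that("strict collapsing is invariant to input order and conserves n", {
  set.seed(11)
  for (rep in 1:5) {
    x <- randomSeqSet(12, 40, popLabels = rep(c("p1", "p2"), 6),
                      mutRate = 0.05)
    h1 <- collapseHaplotypes(x)
    perm <- sample(length(x))
    x2 <- alignedSeqSet(sequences(x)[perm], populations(x)[perm])
    h2 <- collapseHaplotypes(x2)
    expect_setequal(unname(haplotypeSequences(h1)),
                    unname(haplotypeSequences(h2)))
    expect_equal(sum(haplotypeCounts(h1)), length(x))
    expect_equal(sum(haplotypeCounts(h2)), length(x))
    # identical partitions up to haplotype and population relabelling
    m1 <- haplotypeCounts(h1)[, order(haplotypeSequences(h1))]
    m2 <- haplotypeCounts(h2)[, order(haplotypeSequences(h2))]
    expect_equal(m1[sort(rownames(m1)), ], m2[sort(rownames(m2)), ],
                 ignore_attr = TRUE)
  }
})

test_that("N handling follows the ambiguity policy", {
  x <- alignedSeqSet(c(a = "ACGT", b = "ACGN", c = "ACGA"), rep("p", 3))
  expect_equal(length(haplotypeSequences(collapseHaplotypes(x, "strict"))),
               3L)
  hm <- collapseHaplotypes(x, "match_N")
  expect_equal(length(haplotypeSequences(hm)), 2L)
  # the N individual joined the first compatible haplotype in input order
  expect_equal(unname(colSums(haplotypeCounts(hm))), c(2L, 1L))
})

test_that("K2P distance matches the closed form and its domain", {
  expect_equal(k2pDistance(strrep("A", 700), strrep("A", 700)), 0)
  # one transition among 700 sites, no transversions
  a <- strrep("A", 700)
  b <- paste0(strrep("A", 699), "G")
  P <- 1 / 700
  expect_equal(k2pDistance(a, b), -0.5 * log(1 - 2 * P) - 0.25 * log(1))
  # P = 0.5, Q = 0.25 drives the first log argument below zero
  expect_error(k2pDistance("AAAA", "GGCA"), "saturated")
  expect_error(k2pDistance("NNNN", "ACGT"), "comparable")
  expect_error(k2pDistance("AC", "ACG"), "length")
})

test_that("K2P is symmetric, exceeds the p-distance, and matches ape", {
  skip_if_not_installed("ape")
  set.seed(7)
  for (rep in 1:10) {
    x <- randomSeqSet(6, 120, rep("p", 6), mutRate = 0.04)
    s <- as.character(sequences(x))
    d <- divergenceValues(pairwiseK2PMatrix(x))
    expect_equal(d, t(d))
    # correction never shrinks the raw mismatch proportion
    for (i in 1:5) for (j in (i + 1):6) {
      ai <- strsplit(s[i], "")[[1]]; bj <- strsplit(s[j], "")[[1]]
      pdist <- mean(ai != bj)
      expect_gte(d[i, j] + 1e-12, pdist)
    }
    bin <- ape::as.DNAbin(t(sapply(s, function(z) strsplit(z, "")[[1]])))
    dape <- as.matrix(ape::dist.dna(bin, model = "K80",
                                    pairwise.deletion = TRUE))
    expect_equal(unname(d), unname(dape), tolerance = 1e-10)
  }
})

test_that("pairwise matrix equals a brute-force loop over the formula", {
  x <- alignedSeqSet(c(a = "AAGGTTCC", b = "AAGGTTCA", c = "CAGGTTCC"),
                     rep("p", 3))
  d <- divergenceValues(pairwiseK2PMatrix(x))
  s <- as.character(sequences(x))
  for (i in 1:3) for (j in 1:3) {
    if (i == j) expect_equal(d[i, j], 0)
    else expect_equal(d[i, j], oracleK2P(s[i], s[j]))
  }
  xid <- alignedSeqSet(c(a = "ACGT", b = "ACGT", c = "ACGT"), rep("p", 3))
  expect_true(all(divergenceValues(pairwiseK2PMatrix(xid)) == 0))
})

test_that("planted synthetic haplotypes stay far below K2P saturation", {
  gen <- generateSequences(simulationConfig(seed = 3L))
  haps <- alignedSeqSet(gen$truth$haplotypes,
                        rep("h", length(gen$truth$haplotypes)))
  d <- divergenceValues(pairwiseK2PMatrix(haps))
  expect_lt(max(d), 0.01)
})
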