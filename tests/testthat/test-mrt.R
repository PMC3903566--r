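makeXY <- function(n = 6L, seed = 1L) {
  set.seed(seed)
  X <- data.frame(g1 = rnorm(n), g2 = rnorm(n), g3 = rnorm(n),
                  row.names = as.character(seq_len(n)))
  Y <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(rownames(X), c("hsp70_mean", "mav_a", "mav_b")))
  list(X = X, Y = Y)
}

test_that("constant responses give a root-only tree with zero reductions", {
  d <- makeXY(6)
  Yc <- matrix(2, 6, 3, dimnames = dimnames(d$Y))
  tree <- fitMrt(d$X, Yc)
  expect_true(all(tree@frame$isLeaf))
  expect_equal(suppressWarnings(firstSplitR2(tree)), 0)
  expect_warning(firstSplitR2(tree), "root-only")
})

test_that("a planted two-cluster signal is found at the exact midpoint", {
  X <- data.frame(g1 = c(1, 2, 3, 10, 11, 12), g2 = rep(1, 6),
                  row.names = as.character(1:6))
  Y <- matrix(c(rep(0, 3), rep(5, 3)), 6, 2,
              dimnames = list(rownames(X), c("hsp70_mean", "mav_a")))
  tree <- fitMrt(X, Y, standardize = FALSE)
  fr <- tree@frame
  first <- fr[!fr$isLeaf & fr$splitOrder == 1L, ]
  expect_equal(first$splitVar, "g1")
  expect_equal(first$splitValue, 6.5)
  kids <- fr$id[!is.na(fr$parent) & fr$parent == 1L]
  expect_equal(sort(tree@members[[kids[1L]]]), c("1", "2", "3"))
  expect_equal(firstSplitR2(tree), 1)
  oracle <- oracleFirstSplit(X, Y)
  expect_equal(first$splitValue, oracle$value)
  expect_equal(sort(tree@members[[kids[1L]]]), oracle$left)
})

test_that("the greedy first split equals exhaustive search on random data", {
  for (sd in 1:10) {
    d <- makeXY(n = sample(4:8, 1), seed = sd + 100)
    tree <- fitMrt(d$X, d$Y, standardize = FALSE)
    fr <- tree@frame
    if (all(fr$isLeaf)) next
    first <- fr[!fr$isLeaf & fr$splitOrder == 1L, ]
    oracle <- oracleFirstSplit(d$X, d$Y)
    expect_equal(first$splitVar, oracle$var)
    expect_equal(first$splitValue, oracle$value)
    expect_equal(first$improve, oracle$reduction, tolerance = 1e-10)
  }
})

test_that("total SS decomposes into leaf SS plus split reductions", {
  for (sd in 1:5) {
    d <- makeXY(7, seed = sd)
    tree <- fitMrt(d$X, d$Y, standardize = FALSE)
    fr <- tree@frame
    expect_equal(fr$ss[fr$id == 1L],
                 sum(fr$ss[fr$isLeaf]) + sum(fr$improve[!fr$isLeaf]),
                 tolerance = 1e-10)
  }
})

test_that("fits are invariant to row order and explanatory rescaling", {
  d <- makeXY(7, seed = 42)
  tree <- fitMrt(d$X, d$Y)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  tree2 <- fitMrt(d$X[perm, ], d$Y[perm, ])
  expect_equal(newickPartition(newickTopology(tree)),
               newickPartition(newickTopology(tree2)))
  # affine rescaling of one variable moves the cut but not the partition
  X3 <- d$X
  X3$g2 <- 100 * X3$g2 + 7
  tree3 <- fitMrt(X3, d$Y)
  expect_equal(newickPartition(newickTopology(tree)),
               newickPartition(newickTopology(tree3)))
  expect_equal(firstSplitR2(tree), firstSplitR2(tree3))
})

test_that("Newick rendering follows the pinned conventions", {
  X <- data.frame(g1 = rep(1, 7), row.names = as.character(1:7))
  Y <- matrix(1, 7, 2, dimnames = list(rownames(X), c("a", "b")))
  root <- fitMrt(X, Y)
  expect_equal(newickTopology(root), "(1,2,3,4,5,6,7);")

  X2 <- data.frame(g1 = c(0, 5, 0, 5, 5, 5, 5), row.names = as.character(1:7))
  Y2 <- matrix(c(0, 9, 0, 9, 9, 9, 9), 7, 2,
               dimnames = list(rownames(X2), c("a", "b")))
  one <- fitMrt(X2, Y2, maxDepth = 1L)
  expect_equal(newickTopology(one), "((1,3),(2,4,5,6,7));")
  expect_equal(newickTopology(one, style = "paper"), "(1,3),(2,4,5,6,7)")
  # round-trip: the string re-parses to the same leaf partition
  expect_setequal(newickPartition(newickTopology(one)),
                  list(c("1", "3"), c("2", "4", "5", "6", "7")))
})

test_that("primary split correlations report planted signs", {
  X <- data.frame(g1 = c(1, 2, 3, 4, 10, 11, 12),
                  row.names = as.character(1:7))
  hits <- 0L
  for (sd in 1:100) {
    set.seed(sd)
    Y <- cbind(hsp70_mean = X$g1 + rnorm(7, 0, 0.3),
               mav_tubule = -X$g1 + rnorm(7, 0, 0.3))
    rownames(Y) <- rownames(X)
    tree <- fitMrt(X, Y, standardize = FALSE)
    sig <- primarySplitCorrelations(tree)
    ok <- sig$sign[sig$response == "hsp70_mean"] == "+" &&
      sig$sign[sig$response == "mav_tubule"] == "i"
    hits <- hits + ok
  }
  expect_gte(hits, 95L)

  # zero-variance response flags undefined
  Yz <- cbind(hsp70_mean = X$g1, mav_tubule = rep(2, 7))
  rownames(Yz) <- rownames(X)
  treez <- fitMrt(X, Yz, standardize = FALSE)
  sigz <- primarySplitCorrelations(treez)
  expect_equal(sigz$sign[sigz$response == "mav_tubule"], "undefined")
  expect_equal(sigz$sign[sigz$response == "hsp70_mean"], "+")
})

test_that("leave-one-out cross-validation is deterministic in the seed", {
  d <- makeXY(7, seed = 3)
  cv1 <- suppressMessages(crossValidate(d$X, d$Y, folds = 10, reps = 1000,
                                        seed = 1))
  cv2 <- suppressMessages(crossValidate(d$X, d$Y, folds = 10, reps = 1000,
                                        seed = 999))
  expect_identical(cv1$cvError, cv2$cvError)
  expect_identical(cv1$selectedSize, cv2$selectedSize)
  expect_message(crossValidate(d$X, d$Y, folds = 10, reps = 5, seed = 1),
                 "leave-one-out")
})

test_that("cross-validation separates planted signal from noise", {
  signalHits <- 0L
  nullHits <- 0L
  for (sd in 1:20) {
    set.seed(sd)
    X <- data.frame(g1 = c(rnorm(4, 0), rnorm(3, 8)), g2 = rnorm(7),
                    row.names = as.character(1:7))
    Ysig <- cbind(a = c(rnorm(4, 0, 0.3), rnorm(3, 6, 0.3)),
                  b = c(rnorm(4, 0, 0.3), rnorm(3, 6, 0.3)))
    rownames(Ysig) <- rownames(X)
    cvs <- suppressMessages(crossValidate(X, Ysig, seed = sd))
    signalHits <- signalHits + (cvs$selectedSize >= 2L)
    # pure noise on explanatory variables without planted structure
    Xn <- data.frame(g1 = rnorm(7), g2 = rnorm(7),
                     row.names = as.character(1:7))
    Ynull <- matrix(rnorm(14), 7, 2,
                    dimnames = list(rownames(Xn), c("a", "b")))
    cvn <- suppressMessages(crossValidate(Xn, Ynull, seed = sd))
    nullHits <- nullHits + (cvn$selectedSize == 1L)
  }
  expect_gte(signalHits, 19L)
  expect_gte(nullHits, 16L)
})

test_that("explanatory table assembly aligns populations and axes", {
  gen <- generateSequences(simulationConfig(seed = 5L))
  tab <- indexTable(collapseHaplotypes(gen$seqs), gen$seqs)
  oh <- suppressWarnings(pcoa(tab$morisitaHorn, 3L))
  of <- suppressWarnings(pcoa(tab$fst, 2L))
  X <- buildExplanatoryTable(tab$diversity, oh, of)
  expect_equal(names(X), c("pi", "H_MH1", "H_MH2", "H_MH3", "F_ST1", "F_ST2"))
  expect_equal(rownames(X), tab$diversity$population)
  expect_equal(X["4", "F_ST1"], ordinationCoordinates(of)["4", 1L])
})
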