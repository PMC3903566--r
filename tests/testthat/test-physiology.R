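test_that("mean assessment values match direct mean/SD computation", {
  rec <- rbind(physRows("1", 25, tubule = rep(1, 8)),
               physRows("1", 48, tubule = c(4, 5, 5, 5, 5, 5, 5, 5)))
  ctrl <- meanAssessmentValue(rec, "1", 25, "tubule")
  expect_equal(ctrl$mean, 1)
  expect_equal(ctrl$sd, 0)
  hot <- meanAssessmentValue(rec, "1", 48, "tubule")
  expect_equal(hot$mean, 4.875)
  expect_equal(hot$sd, sd(c(4, 5, 5, 5, 5, 5, 5, 5)))
  expect_error(meanAssessmentValue(rec, "1", 40, "tubule"), "40")
  set.seed(2)
  for (rep in 1:10) {
    v <- sample(seq(1, 5, 0.5), 8, replace = TRUE)
    r <- physRows("z", 33, digestive = v)
    m <- meanAssessmentValue(r, "z", 33, "digestive")$mean
    expect_true(m >= 1 && m <= 5)
  }
})

test_that("percent-of-control reproduces the induction arithmetic", {
  rec <- rbind(physRows("6", 25, hsp = rep(1, 10)),
               physRows("6", 38, hsp = rep(1.042, 10)),
               physRows("6", 40, hsp = rep(1.939, 10)))
  pct <- hsp70PercentOfControl(rec, "6")
  expect_equal(unname(pct[["25"]]), 100)
  expect_equal(unname(pct[["40"]]), 193.9)
  expect_equal(unname(pct[["38"]]), 104.2)
  mi <- maxInduction(rec, "6")
  expect_equal(mi$temperature, 40)
  expect_equal(mi$percent, 193.9)
  noCtrl <- physRows("9", 40, hsp = rep(1, 5))
  expect_error(hsp70PercentOfControl(noCtrl, "9"), "control")
})

test_that("a flat induction profile ties to the lowest temperature", {
  rec <- do.call(rbind, lapply(c(25, 33, 40), function(tt)
    physRows("2", tt, hsp = rep(2, 6))))
  mi <- suppressMessages(maxInduction(rec, "2"))
  expect_equal(mi$temperature, 33)
  expect_equal(mi$percent, 100)
})

test_that("integrity ratio compares digestive to calcium condition", {
  rec <- physRows("1", 40, digestive = rep(2, 8), calcium = rep(4, 8))
  expect_equal(integrityRatio(rec, "1", 40), 0.5)
  eq <- physRows("1", 33, digestive = rep(3, 8), calcium = rep(3, 8))
  expect_equal(integrityRatio(eq, "1", 33), 1)
})

test_that("rank-sum p-values follow the exact permutation null", {
  # perfectly separated tied groups: 2 of the 70 assignments are as extreme
  expect_equal(rankSumTest(rep(1, 4), rep(5, 4)), 2 / choose(8, 4))
  expect_warning(p1 <- rankSumTest(rep(3, 5), rep(3, 4)), "identical")
  expect_equal(p1, 1)
  rec <- rbind(physRows("1", 25, tubule = rep(1, 4)),
               physRows("1", 48, tubule = rep(5, 4)))
  expect_equal(wilcoxonVsControl(rec, "1", "tubule_score", 48),
               2 / choose(8, 4))
})

test_that("the normal approximation tracks exhaustive permutation", {
  # continuous (untied) samples: the approximation is tight
  set.seed(9)
  untied <- replicate(20, {
    x <- rnorm(7); y <- rnorm(7)
    abs(rankSumTest(x, y, method = "approx") - oraclePermRankSum(x, y))
  })
  expect_lt(mean(untied), 0.01)
  expect_lt(max(untied), 0.03)
  # heavily tied 1-5 scores: still close on average, and both are valid
  # p-values of the same ordering
  set.seed(9)
  tied <- replicate(20, {
    x <- sample(1:5, 7, replace = TRUE)
    y <- sample(1:5, 7, replace = TRUE)
    if (length(unique(c(x, y))) == 1L) return(0)
    abs(rankSumTest(x, y, method = "approx") - oraclePermRankSum(x, y))
  })
  expect_lt(mean(tied), 0.03)
})

test_that("Bonferroni tiers reproduce both printed threshold sets", {
  expect_equal(unname(bonferroniThresholds(4)),
               c(0.0125, 0.0025, 0.00025))
  expect_equal(unname(bonferroniThresholds(6)),
               c(0.0083, 0.0017, 0.00017))
  expect_equal(bonferroniTier(0.01, 4), "*")
  expect_equal(bonferroniTier(0.0017, 6), "**")  # inclusive boundary
  expect_equal(bonferroniTier(0.5, 4), "ns")
  expect_equal(bonferroniTier(0.0002, 4), "***")
  # monotone: smaller p never gives a weaker tier
  tiers <- c(ns = 0L, `*` = 1L, `**` = 2L, `***` = 3L)
  for (m in c(1, 4, 6, 10)) {
    ps <- sort(runif(50))
    lv <- tiers[vapply(ps, bonferroniTier, "", m = m)]
    expect_true(all(diff(lv) <= 0))
  }
})

test_that("ANOVA with Tukey-Kramer letters behaves on planted groups", {
  # equal group means -> F exactly 0
  rec0 <- rbind(physRows("a", 40, hsp = c(1, 2, 3)),
                physRows("b", 40, hsp = c(2, 3, 1)))
  expect_equal(anovaTukey(rec0, 40, "hsp70_rel")$F, 0)

  # two groups: F equals the square of the pooled-variance t statistic
  set.seed(14)
  recT <- rbind(physRows("a", 40, hsp = rnorm(8, 1)),
                physRows("b", 40, hsp = rnorm(9, 1.5)))
  out <- anovaTukey(recT, 40, "hsp70_rel")
  tt <- t.test(recT$hsp70_rel[recT$population_id == "a"],
               recT$hsp70_rel[recT$population_id == "b"],
               var.equal = TRUE)
  expect_equal(out$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$p, tt$p.value, tolerance = 1e-10)

  # a clearly shifted group earns its own letter; equivalent groups share
  set.seed(16)
  recL <- rbind(physRows("low", 40, hsp = rnorm(10, 0.5, 0.2)),
                physRows("midA", 40, hsp = rnorm(10, 1.8, 0.2)),
                physRows("midB", 40, hsp = rnorm(10, 1.8, 0.2)))
  out2 <- anovaTukey(recL, 40, "hsp70_rel")
  # the letter display must mirror the pairwise decisions exactly
  share <- function(a, b) any(strsplit(out2$letters[[a]], "")[[1]] %in%
                                strsplit(out2$letters[[b]], "")[[1]])
  for (a in rownames(out2$pairwise)) for (b in colnames(out2$pairwise)) {
    if (a == b) next
    expect_equal(share(a, b), out2$pairwise[a, b] > 0.05,
                 label = paste("letters for", a, "vs", b))
  }
  expect_false(share("low", "midA"))
  expect_true(share("midA", "midB"))
  expect_error(anovaTukey(physRows("a", 40, hsp = 1:5), 40, "hsp70_rel"),
               "2 groups")
})

test_that("population summary assembles consistent cells", {
  cfg <- simulationConfig(seed = 8L)
  rec <- generatePhysiology(cfg)$records
  sm <- populationSummary(rec)
  expect_equal(nrow(sm), 7L * 7L)
  expect_true(all(sm$mav_tubule >= 1 & sm$mav_tubule <= 5))
  expect_true(all(abs(sm$hsp70_percent_of_control[sm$temperature == 25] -
                        100) < 1e-9))
  expect_true(all(sm$integrity_ratio >= 0.2 & sm$integrity_ratio <= 5))
  Y <- buildResponseMatrix(rec, 40)
  expect_equal(dim(Y), c(7L, 4L))
  expect_equal(Y["3", "mav_digestive"],
               meanAssessmentValue(rec, "3", 40, "digestive")$mean)
})
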