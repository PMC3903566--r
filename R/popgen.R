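#' Within-population nucleotide diversity under K2P
#'
#' Nucleotide diversity is the mean, over all pairs of individuals in a
#' population, of the Kimura 2-parameter per-site distance. The reported
#' standard deviation is, by default, the square root of the Nei (1987)
#' total variance of the estimate
#' \deqn{V(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2,}
#' which combines sampling and stochastic terms (the form used by standard
#' population-genetics estimation software); `sdEstimator = "sample"` gives
#' the plain sample SD of the pairwise distances instead.
#'
#' @param seqs an [AlignedSeqSet-class] containing the individuals of a
#'   single population (the population labels are not consulted).
#' @param sdEstimator `"nei"` (default) or `"sample"`.
#' @return list with elements `pi`, `sd`, `n`.
#' @examples
#' x <- alignedSeqSet(c(a = "AAAA", b = "AAAA", c = "AAAG"), rep("p", 3))
#' nucleotideDiversity(x)$pi
#' @export
nucleotideDiversity <- function(seqs, sdEstimator = c("nei", "sample")) {
  sdEstimator <- match.arg(sdEstimator)
  stopifnot(is(seqs, "AlignedSeqSet"))
  n <- length(seqs)
  if (n < 2L)
    stop("nucleotide diversity undefined for fewer than 2 individuals")
  d <- divergenceValues(pairwiseK2PMatrix(seqs))
  pairs <- d[upper.tri(d)]
  pi <- mean(pairs)
  L <- seqLength(seqs)
  if (pi == 0) {
    sd <- 0
  } else if (sdEstimator == "nei") {
    v <- (n + 1) / (3 * (n - 1) * L) * pi +
      2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
    sd <- sqrt(v)
  } else {
    sd <- stats::sd(pairs)
  }
  list(pi = pi, sd = sd, n = n)
}

#' Nei pairwise fixation index from haplotype counts
#'
#' G_ST-type pooled-frequency estimator: with relative haplotype frequencies
#' p and q and pooled frequencies (p+q)/2,
#' F_ST = (H_T - H_S)/H_T where H_S = 1 - (sum p^2 + sum q^2)/2 and
#' H_T = 1 - sum((p+q)/2)^2. Defined as 0 when H_T = 0 (both populations
#' fixed for the same haplotype). No sample-size bias correction is applied.
#'
#' @param countsA,countsB non-negative haplotype count (or frequency)
#'   vectors over the same haplotype index.
#' @return F_ST in [0, 1].
#' @examples
#' neiPairwiseFst(c(10, 0), c(0, 10))  # fixed differences -> 1
#' @export
neiPairwiseFst <- function(countsA, countsB) {
  if (length(countsA) != length(countsB))
    stop("haplotype count vectors of unequal length")
  if (sum(countsA) <= 0 || sum(countsB) <= 0)
    stop("each population needs at least one individual")
  p <- countsA / sum(countsA)
  q <- countsB / sum(countsB)
  hs <- 1 - (sum(p^2) + sum(q^2)) / 2
  ht <- 1 - sum(((p + q) / 2)^2)
  if (ht == 0) return(0)
  (ht - hs) / ht
}

#' Morisita-Horn haplotype divergence
#'
#' Treats haplotypes as species and computes 1 - C_MH where
#' C_MH = 2 sum(x_i y_i) / ((d_x + d_y) X Y), d_x = sum(x_i^2)/X^2,
#' d_y = sum(y_i^2)/Y^2, X and Y the totals. 0 for proportional
#' compositions, 1 for disjoint supports.
#'
#' @param countsX,countsY non-negative haplotype count vectors over the same
#'   haplotype index, totals >= 1.
#' @return divergence in [0, 1].
#' @examples
#' morisitaHornDivergence(c(2, 2), c(5, 5))  # proportional -> 0
#' @export
morisitaHornDivergence <- function(countsX, countsY) {
  if (length(countsX) != length(countsY))
    stop("haplotype count vectors of unequal length")
  X <- sum(countsX); Y <- sum(countsY)
  if (X <= 0 || Y <= 0)
    stop("each population needs at least one individual")
  dx <- sum(countsX^2) / X^2
  dy <- sum(countsY^2) / Y^2
  overlap <- 2 * sum(countsX * countsY) / ((dx + dy) * X * Y)
  1 - overlap
}

#' Population-level diversity and divergence table
#'
#' Computes nucleotide diversity per population plus both between-population
#' divergence matrices, and assembles the combined square report table:
#' pi +/- SD on the diagonal, Morisita-Horn divergence above it and the Nei
#' pairwise fixation index below it.
#'
#' @param haps a [HaplotypeTable-class].
#' @param seqs the matching [AlignedSeqSet-class] (same populations).
#' @param sdEstimator passed to [nucleotideDiversity()].
#' @return list with elements `diversity` (data.frame `population, pi, sd,
#'   n`), `fst` and `morisitaHorn` ([DivergenceMatrix-class]), and
#'   `combined` (character matrix in the report layout; pi rounded to 4
#'   decimals, F_ST to 3, H_MH to 2).
#' @export
indexTable <- function(haps, seqs, sdEstimator = "nei") {
  stopifnot(is(haps, "HaplotypeTable"), is(seqs, "AlignedSeqSet"))
  counts <- haplotypeCounts(haps)
  pops <- rownames(counts)
  if (!setequal(pops, unique(populations(seqs))))
    stop("populations of the haplotype table and sequence set differ")
  k <- length(pops)

  div <- data.frame(population = pops, pi = NA_real_, sd = NA_real_,
                    n = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    sel <- populations(seqs) == pops[i]
    sub <- alignedSeqSet(sequences(seqs)[sel], populations(seqs)[sel])
    est <- nucleotideDiversity(sub, sdEstimator = sdEstimator)
    div$pi[i] <- est$pi; div$sd[i] <- est$sd; div$n[i] <- est$n
  }

  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  mh <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      fst[i, j] <- fst[j, i] <- neiPairwiseFst(counts[i, ], counts[j, ])
      mh[i, j] <- mh[j, i] <- morisitaHornDivergence(counts[i, ], counts[j, ])
    }
  }

  combined <- matrix("", k, k, dimnames = list(pops, pops))
  for (i in seq_len(k)) {
    combined[i, i] <- sprintf("%.4f±%.4f", div$pi[i], div$sd[i])
    for (j in seq_len(k)) {
      if (j > i) combined[i, j] <- sprintf("%.2f", mh[i, j])
      if (j < i) combined[i, j] <- sprintf("%.3f", fst[i, j])
    }
  }

  list(diversity = div,
       fst = divergenceMatrix(fst, "FST"),
       morisitaHorn = divergenceMatrix(mh, "MorisitaHorn"),
       combined = combined)
}

#' Write the combined index table and its tidy long form
#'
#' @param tab result of [indexTable()].
#' @param prefix output prefix; writes `<prefix>_combined.csv` (report
#'   layout) and `<prefix>_long.csv` (`pop_a,pop_b,index,value`).
#' @export
writeIndexTable <- function(tab, prefix) {
  utils::write.csv(as.data.frame(tab$combined), paste0(prefix, "_combined.csv"))
  fst <- divergenceValues(tab$fst)
  mh <- divergenceValues(tab$morisitaHorn)
  pops <- rownames(fst)
  rows <- list()
  for (i in seq_along(pops)) {
    rows[[length(rows) + 1L]] <- data.frame(
      pop_a = pops[i], pop_b = pops[i], index = "pi",
      value = tab$diversity$pi[i])
    for (j in seq_along(pops)) {
      if (j <= i) next
      rows[[length(rows) + 1L]] <- data.frame(
        pop_a = pops[i], pop_b = pops[j], index = "FST", value = fst[i, j])
      rows[[length(rows) + 1L]] <- data.frame(
        pop_a = pops[i], pop_b = pops[j], index = "H_MH", value = mh[i, j])
    }
  }
  utils::write.csv(do.call(rbind, rows), paste0(prefix, "_long.csv"),
                   row.names = FALSE)
  invisible(prefix)
}
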