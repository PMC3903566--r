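# Independent brute-force oracles used to cross-check the package's
# statistics. These deliberately re-derive each quantity from its defining
# formula with plain loops, sharing no code with the implementation.

oracleK2P <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  bases <- c("A", "C", "G", "T")
  purine <- c("A", "G")
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(av)) {
    if (!(av[i] %in% bases) || !(bv[i] %in% bases)) next
    n <- n + 1L
    if (av[i] == bv[i]) next
    if ((av[i] %in% purine) == (bv[i] %in% purine)) ts <- ts + 1L
    else tv <- tv + 1L
  }
  P <- ts / n; Q <- tv / n
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

oraclePi <- function(seqStrings) {
  n <- length(seqStrings)
  tot <- 0; cnt <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + oracleK2P(seqStrings[i], seqStrings[j])
      cnt <- cnt + 1L
    }
  }
  tot / cnt
}

oracleFst <- function(a, b) {
  p <- a / sum(a); q <- b / sum(b)
  hs <- 1 - (sum(p * p) + sum(q * q)) / 2
  pbar <- (p + q) / 2
  ht <- 1 - sum(pbar * pbar)
  if (ht == 0) 0 else (ht - hs) / ht
}

# exhaustive search over every (variable, midpoint) candidate split
oracleFirstSplit <- function(X, Y) {
  Y <- as.matrix(Y)
  ssOf <- function(rows) {
    if (length(rows) <= 1L) return(0)
    sub <- Y[rows, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  parent <- ssOf(seq_len(nrow(Y)))
  best <- list(reduction = -Inf)
  for (v in seq_along(X)) {
    u <- sort(unique(X[[v]]))
    if (length(u) < 2L) next
    for (cut in (u[-length(u)] + u[-1L]) / 2) {
      left <- which(X[[v]] <= cut)
      right <- which(X[[v]] > cut)
      red <- parent - ssOf(left) - ssOf(right)
      if (red > best$reduction + 1e-12)
        best <- list(var = names(X)[v], value = cut, reduction = red,
                     left = sort(rownames(X)[left]))
    }
  }
  best
}

# independent scalar transcription of the pinned probability-of-parsimony
# recursion (the package version is vectorised)
oracleParsimonyProb <- function(j, m) {
  p <- j / m
  if (p >= 0.75) return(0)
  lambda <- m * (-0.75 * log(1 - 4 * p / 3))
  kmax <- max(j + 20, ceiling(lambda + 12 * sqrt(lambda) + 20))
  dmax <- min(m, kmax)
  f <- numeric(dmax + 1)
  f[1] <- 1
  num <- 0; den <- 0
  for (k in 0:kmax) {
    w <- dpois(k, lambda)
    if (k >= j) {
      den <- den + w * f[j + 1]
      if (k == j) num <- w * f[j + 1]
    }
    fn <- numeric(dmax + 1)
    for (d in 0:dmax) {
      val <- 0
      if (d >= 1) val <- val + f[d] * (m - (d - 1)) / m
      val <- val + f[d + 1] * (d / m) * (2 / 3)
      if (d + 1 <= dmax) val <- val + f[d + 2] * ((d + 1) / m) * (1 / 3)
      fn[d + 1] <- val
    }
    f <- fn
  }
  num / den
}

# exhaustive two-sided permutation p-value of the rank-sum statistic
oraclePermRankSum <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x); N <- length(pooled)
  mu <- n1 * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  hits <- 0L; tot <- 0L
  idx <- utils::combn(N, n1)
  for (c in seq_len(ncol(idx))) {
    tot <- tot + 1L
    if (abs(sum(r[idx[, c]]) - mu) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / tot
}

# random aligned sequences with modest divergence (stays in the K2P domain)
randomSeqSet <- function(n, len, popLabels = rep("p", n), mutRate = 0.03) {
  ref <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- ref
    k <- rbinom(1, len, mutRate)
    if (k > 0) {
      at <- sample.int(len, k)
      s[at] <- vapply(s[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    paste(s, collapse = "")
  }, "")
  names(seqs) <- sprintf("s%02d", seq_len(n))
  alignedSeqSet(seqs, popLabels)
}

writeToyFasta <- function(seqs) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(id)
    c(paste0(">", id), seqs[[id]]))), fa)
  fa
}

writeToyPopmap <- function(ids, pops) {
  pm <- tempfile(fileext = ".csv")
  writeLines(c("sequence_id,population_id",
               paste(ids, pops, sep = ",")), pm)
  pm
}

# leaf partition of a newick-style topology string: set of top-level groups
newickPartition <- function(s) {
  s <- sub(";$", "", s)
  s <- sub("^\\((.*)\\)$", "\\1", s)
  depth <- 0L
  cuts <- integer()
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  groups <- vapply(seq_along(starts), function(g)
    paste(chars[starts[g]:ends[g]], collapse = ""), "")
  lapply(groups, function(g) sort(strsplit(gsub("[()]", "", g), ",")[[1]]))
}

# quick builder of tidy physiology records
physRows <- function(pop, temp, hsp = NULL, tubule = NULL, digestive = NULL,
                     calcium = NULL) {
  n <- max(length(hsp), length(tubule), length(digestive), length(calcium))
  pad <- function(v) if (is.null(v)) rep(NA_real_, n) else v
  data.frame(individual_id = sprintf("%s_%g_%02d", pop, temp, seq_len(n)),
             population_id = pop, temperature = temp,
             hsp70_rel = pad(hsp), tubule_score = pad(tubule),
             digestive_score = pad(digestive), calcium_score = pad(calcium))
}
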