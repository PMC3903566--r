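#' Assemble the genetic explanatory table
#'
#' Combines per-population nucleotide diversity with the PCoA coordinates of
#' the two divergence matrices into the explanatory variables of the
#' regression-tree analysis: `pi`, `H_MH1..H_MH3` (3 axes of the
#' Morisita-Horn divergence ordination) and `F_ST1, F_ST2` (2 axes of the
#' fixation-index ordination).
#'
#' @param diversity data.frame with columns `population` and `pi` (as from
#'   [indexTable()]).
#' @param ordHmh [OrdinationResult-class] of the Morisita-Horn matrix with
#'   >= 3 axes.
#' @param ordFst [OrdinationResult-class] of the F_ST matrix with >= 2 axes.
#' @return data.frame, populations x c(pi, H_MH1, H_MH2, H_MH3, F_ST1,
#'   F_ST2).
#' @export
buildExplanatoryTable <- function(diversity, ordHmh, ordFst) {
  ch <- ordinationCoordinates(ordHmh)
  cf <- ordinationCoordinates(ordFst)
  stopifnot(ncol(ch) >= 3L, ncol(cf) >= 2L)
  pops <- diversity$population
  stopifnot(identical(sort(pops), sort(rownames(ch))),
            identical(sort(pops), sort(rownames(cf))))
  out <- data.frame(pi = diversity$pi,
                    H_MH1 = ch[pops, 1L], H_MH2 = ch[pops, 2L],
                    H_MH3 = ch[pops, 3L],
                    F_ST1 = cf[pops, 1L], F_ST2 = cf[pops, 2L],
                    row.names = pops)
  out
}

# within-node sum of squared Euclidean distances to the node centroid
.nodeSS <- function(Y, rows) {
  if (length(rows) <= 1L) return(0)
  sub <- Y[rows, , drop = FALSE]
  sum(sweep(sub, 2L, colMeans(sub))^2)
}

# best (variable, midpoint) split of a node; ties resolved by lowest
# variable index, then lowest split value. minNodeSize is a minimum size
# for the node being split (CART minsplit); children may be singletons.
.bestSplit <- function(X, Y, rows, minNodeSize) {
  if (length(rows) < minNodeSize) return(NULL)
  parent <- .nodeSS(Y, rows)
  best <- NULL
  for (v in seq_along(X)) {
    xs <- X[rows, v]
    u <- sort(unique(xs))
    if (length(u) < 2L) next
    cuts <- (u[-length(u)] + u[-1L]) / 2
    for (cv in cuts) {
      left <- rows[xs <= cv]
      right <- rows[xs > cv]
      if (length(left) < 1L || length(right) < 1L) next
      red <- parent - .nodeSS(Y, left) - .nodeSS(Y, right)
      if (is.null(best) || red > best$reduction + 1e-12) {
        best <- list(var = v, value = cv, reduction = red,
                     left = left, right = right)
      }
    }
  }
  if (!is.null(best) && best$reduction <= 1e-12) best <- NULL
  best
}

#' Fit a multivariate regression tree
#'
#' Greedy recursive binary partitioning of a multivariate response by
#' thresholds on the explanatory variables. Candidate splits are midpoints
#' between consecutive sorted unique values of each explanatory variable;
#' the chosen split maximises the reduction in total within-node sum of
#' squared Euclidean distances of the response. Growth is best-first (the
#' leaf offering the largest reduction is split next), which makes the
#' nested sequence of tree sizes explicit for cross-validation. Recursion
#' stops at `minNodeSize`, `maxDepth`, `maxLeaves`, or when no split
#' achieves a positive reduction.
#'
#' @param X explanatory data.frame (rows = populations, named).
#' @param Y response matrix (same rows; e.g. from [buildResponseMatrix()]).
#' @param minNodeSize minimum members a node must have for a split to be
#'   attempted (default 2); child nodes may hold a single population, so a
#'   lone divergent population can be isolated by the primary split.
#' @param maxDepth maximum split depth (default 3).
#' @param maxLeaves optional cap on the number of leaves.
#' @param standardize scale response columns to zero mean and unit variance
#'   before fitting (default TRUE: Hsp70 percentages and 1-5 scores are on
#'   incommensurate scales). Constant columns are left unscaled.
#' @return an [MRTree-class].
#' @export
fitMrt <- function(X, Y, minNodeSize = 2L, maxDepth = 3L, maxLeaves = Inf,
                   standardize = TRUE) {
  stopifnot(is.data.frame(X), nrow(X) == nrow(Y))
  if (is.null(rownames(X)) || is.null(rownames(Y)) ||
      !identical(rownames(X), rownames(Y)))
    stop("X and Y must carry identical population row names")
  n <- nrow(X)
  if (n < 2L * minNodeSize)
    stop("need at least 2 * minNodeSize populations")
  Y <- as.matrix(Y)
  if (standardize) Y <- .standardizeResponse(Y)

  frame <- data.frame(id = 1L, parent = NA_integer_, depth = 0L,
                      isLeaf = TRUE, splitVar = NA_character_,
                      splitValue = NA_real_, n = n,
                      ss = .nodeSS(Y, seq_len(n)), improve = NA_real_,
                      splitOrder = NA_integer_, stringsAsFactors = FALSE)
  members <- list(rownames(X))
  rowsOf <- list(seq_len(n))
  pending <- list()  # candidate split per leaf id
  pending[["1"]] <- .bestSplit(X, Y, seq_len(n), minNodeSize)
  splitOrder <- 0L

  repeat {
    leaves <- frame$id[frame$isLeaf]
    if (sum(frame$isLeaf) >= maxLeaves) break
    elig <- leaves[frame$depth[match(leaves, frame$id)] < maxDepth]
    elig <- elig[!vapply(pending[as.character(elig)], is.null, TRUE)]
    if (!length(elig)) break
    reds <- vapply(pending[as.character(elig)], `[[`, numeric(1), "reduction")
    pick <- elig[which.max(reds)]  # unique ids; first max = lowest id
    sp <- pending[[as.character(pick)]]
    splitOrder <- splitOrder + 1L
    i <- match(pick, frame$id)
    frame$isLeaf[i] <- FALSE
    frame$splitVar[i] <- names(X)[sp$var]
    frame$splitValue[i] <- sp$value
    frame$improve[i] <- sp$reduction
    frame$splitOrder[i] <- splitOrder
    for (side in c("left", "right")) {
      rows <- sp[[side]]
      nid <- max(frame$id) + 1L
      frame <- rbind(frame, data.frame(
        id = nid, parent = pick, depth = frame$depth[i] + 1L, isLeaf = TRUE,
        splitVar = NA_character_, splitValue = NA_real_, n = length(rows),
        ss = .nodeSS(Y, rows), improve = NA_real_,
        splitOrder = NA_integer_))
      members[[nid]] <- rownames(X)[rows]
      rowsOf[[nid]] <- rows
      pending[[as.character(nid)]] <- .bestSplit(X, Y, rows, minNodeSize)
    }
  }

  if (nrow(frame) == 1L && .nodeSS(Y, seq_len(n)) > 0 &&
      all(vapply(X, function(v) length(unique(v)), 1L) == 1L))
    warning("constant explanatory variables; returning a root-only tree")

  new("MRTree", frame = frame, members = members, response = Y,
      explanatory = X, standardized = isTRUE(standardize))
}

.standardizeResponse <- function(Y) {
  mu <- colMeans(Y)
  sdev <- apply(Y, 2L, stats::sd)
  sdev[sdev == 0] <- 1  # constant columns stay constant
  sweep(sweep(Y, 2L, mu), 2L, sdev, "/")
}

# route rows of newX down a fitted tree; returns leaf node id per row
.routeRows <- function(tree, newX) {
  fr <- tree@frame
  out <- integer(nrow(newX))
  for (r in seq_len(nrow(newX))) {
    node <- 1L
    repeat {
      i <- match(node, fr$id)
      if (fr$isLeaf[i]) break
      kids <- fr$id[!is.na(fr$parent) & fr$parent == node]
      node <- if (newX[r, fr$splitVar[i]] <= fr$splitValue[i])
        kids[1L] else kids[2L]
    }
    out[r] <- node
  }
  out
}

#' Cross-validated tree-size selection
#'
#' Repeated k-fold cross-validation of the best-first tree-growing sequence:
#' per candidate size s (1 = root only), the tree grown to s leaves on each
#' training set predicts its held-out populations by the training leaf
#' centroid, and the CV relative error is the total held-out squared error
#' divided by the total response sum of squares. `folds` is clamped to the
#' number of populations; when it equals it, the scheme is leave-one-out,
#' which is deterministic, so the repetitions collapse to one (a message is
#' emitted). Size is selected by the minimum-CV rule (default) or the
#' 1-SE rule.
#'
#' @inheritParams fitMrt
#' @param folds requested number of folds (default 10).
#' @param reps random fold-assignment repetitions (default 1000; ignored
#'   under leave-one-out).
#' @param seed integer seed for fold assignment.
#' @param sizeRule `"min"` or `"1se"`.
#' @return list with `cvError` (named by size), `se` (approximate standard
#'   errors), `selectedSize`, and `tree` (the full-data fit pruned to the
#'   selected size).
#' @export
crossValidate <- function(X, Y, folds = 10L, reps = 1000L, seed = 1L,
                          minNodeSize = 2L, maxDepth = 3L,
                          standardize = TRUE, sizeRule = c("min", "1se")) {
  sizeRule <- match.arg(sizeRule)
  n <- nrow(X)
  Y <- as.matrix(Y)
  if (standardize) Y <- .standardizeResponse(Y)
  folds <- min(folds, n)
  if (folds < 2L) stop("need at least 2 folds")
  loo <- folds == n
  if (loo && reps > 1L) {
    message("leave-one-out cross-validation is deterministic; ",
            "collapsing ", reps, " repetitions to 1")
    reps <- 1L
  }
  full <- fitMrt(X, Y, minNodeSize = minNodeSize, maxDepth = maxDepth,
                 standardize = FALSE)
  sizes <- seq_len(sum(full@frame$isLeaf))
  ssTot <- .nodeSS(Y, seq_len(n))
  if (ssTot == 0) stop("constant response; cross-validation undefined")

  perObs <- matrix(0, n, length(sizes))  # held-out SE per population x size
  set.seed(seed)
  for (rep in seq_len(reps)) {
    assign <- if (loo) seq_len(n) else sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      hold <- which(assign == f)
      train <- setdiff(seq_len(n), hold)
      for (s in sizes) {
        fit <- fitMrt(X[train, , drop = FALSE], Y[train, , drop = FALSE],
                      minNodeSize = minNodeSize, maxDepth = maxDepth,
                      maxLeaves = s, standardize = FALSE)
        leafId <- .routeRows(fit, X[hold, , drop = FALSE])
        for (h in seq_along(hold)) {
          tr <- match(fit@members[[leafId[h]]], rownames(X))
          pred <- colMeans(Y[tr, , drop = FALSE])
          perObs[hold[h], s] <- perObs[hold[h], s] +
            sum((Y[hold[h], ] - pred)^2) / reps
        }
      }
    }
  }
  cv <- colSums(perObs) / ssTot
  se <- apply(perObs, 2L, function(col) sqrt(stats::var(col) * n)) / ssTot
  names(cv) <- names(se) <- sizes
  selected <- if (sizeRule == "min") {
    sizes[which.min(cv)]
  } else {
    thr <- min(cv) + se[which.min(cv)]
    sizes[which(cv <= thr)[1L]]
  }
  pruned <- fitMrt(X, Y, minNodeSize = minNodeSize, maxDepth = maxDepth,
                   maxLeaves = selected, standardize = FALSE)
  list(cvError = cv, se = se, selectedSize = selected, tree = pruned)
}

#' Proportion of variance explained by the first split
#'
#' (SS_root - SS_left - SS_right) / SS_root for the primary grouping of the
#' tree; 0 with a warning for a root-only tree.
#'
#' @param tree an [MRTree-class].
#' @return proportion in [0, 1].
#' @export
firstSplitR2 <- function(tree) {
  stopifnot(is(tree, "MRTree"))
  fr <- tree@frame
  if (all(fr$isLeaf)) {
    warning("root-only tree; first-split R^2 is 0")
    return(0)
  }
  root <- fr[fr$id == 1L, ]
  kids <- fr[!is.na(fr$parent) & fr$parent == 1L, ]
  (root$ss - sum(kids$ss)) / root$ss
}

#' Newick rendering of the leaf-group topology
#'
#' Leaves are population ids; a leaf holding several populations is rendered
#' as a comma list in parentheses; sibling order is (low side of the split,
#' high side). `style = "newick"` (default) emits well-formed Newick with
#' outer parentheses and a terminal semicolon; `style = "paper"` drops the
#' outermost parentheses and semicolon, matching the compact display style
#' of summary tables.
#'
#' @param tree an [MRTree-class].
#' @param style `"newick"` or `"paper"`.
#' @return character string.
#' @export
newickTopology <- function(tree, style = c("newick", "paper")) {
  style <- match.arg(style)
  fr <- tree@frame
  render <- function(node) {
    i <- match(node, fr$id)
    if (fr$isLeaf[i]) {
      mem <- tree@members[[node]]
      if (length(mem) == 1L) mem else
        paste0("(", paste(mem, collapse = ","), ")")
    } else {
      kids <- fr$id[!is.na(fr$parent) & fr$parent == node]
      paste0("(", render(kids[1L]), ",", render(kids[2L]), ")")
    }
  }
  body <- render(1L)
  if (style == "newick") {
    if (!startsWith(body, "(")) body <- paste0("(", body, ")")
    paste0(body, ";")
  } else {
    sub("^\\((.*)\\)$", "\\1", body)
  }
}

#' Correlation signs of the primary split variable with each response
#'
#' Pearson correlation, across populations, between the primary split
#' variable and each response column. The Hsp70 response is reported as
#' `+`/`-`; each histopathology MAV is mapped to `i` (improved: negative
#' correlation, higher divergence associated with lower damage scores) or
#' `d` (deteriorated: positive correlation). Zero-variance inputs yield an
#' `undefined` flag.
#'
#' @param tree a fitted [MRTree-class] with at least one split.
#' @return data.frame with columns `response`, `correlation`, `sign`.
#' @export
primarySplitCorrelations <- function(tree) {
  stopifnot(is(tree, "MRTree"))
  fr <- tree@frame
  if (all(fr$isLeaf)) stop("tree has no split")
  var <- fr$splitVar[!fr$isLeaf & fr$splitOrder == 1L]
  x <- tree@explanatory[[var]]
  Y <- tree@response
  out <- data.frame(response = colnames(Y), correlation = NA_real_,
                    sign = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      out$sign[j] <- "undefined"
      next
    }
    r <- stats::cor(x, y)
    out$correlation[j] <- r
    isMav <- startsWith(colnames(Y)[j], "mav")
    out$sign[j] <- if (isMav) {
      if (r < 0) "i" else "d"
    } else {
      if (r >= 0) "+" else "-"
    }
  }
  attr(out, "splitVariable") <- var
  out
}
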