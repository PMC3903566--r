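#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps j such that the probability that j
#' observed differences between two aligned sequences arose without any
#' superimposed (homoplastic) change is at least `confidence`.
#'
#' The probability of parsimony is computed by a pinned recursion in the
#' Hudson/Templeton tradition: mutations hit sites uniformly at random and a
#' mutation at an already-differing site reverts it with probability 1/3
#' (Jukes-Cantor-style); the number of mutations separating a pair showing j
#' differences over `seqLength` sites is given a Poisson prior whose mean is
#' the Jukes-Cantor-corrected expected mutation count. The probability of
#' parsimony for j differences is then the posterior probability that the
#' true mutation count equals j. The exact variant is pinned here for
#' reproducibility; pass an explicit limit downstream to mimic another
#' implementation.
#'
#' @param seqLength number of aligned sites (>= 1).
#' @param confidence probability in (0,1); default 0.95, the conventional
#'   cladogram-estimation cutoff.
#' @return integer number of steps, at least 1.
#' @examples
#' parsimonyConnectionLimit(700)
#' @export
parsimonyConnectionLimit <- function(seqLength, confidence = 0.95) {
  stopifnot(seqLength >= 1, confidence > 0, confidence < 1)
  j <- 1L
  while (j < seqLength &&
         parsimonyProbability(j + 1L, seqLength) >= confidence) {
    j <- j + 1L
  }
  if (parsimonyProbability(1L, seqLength) < confidence) {
    # even one step falls below the requested confidence; floor at 1
    return(1L)
  }
  j
}

#' Probability of parsimony for j observed differences
#'
#' @param j observed number of differing sites (>= 1).
#' @param m number of aligned sites.
#' @return probability that the j differences reflect exactly j mutations.
#' @seealso [parsimonyConnectionLimit()] for the model.
#' @export
parsimonyProbability <- function(j, m) {
  stopifnot(j >= 1, j <= m)
  p <- j / m
  if (p >= 0.75) return(0)
  lambda <- m * (-0.75 * log(1 - 4 * p / 3))
  kmax <- max(j + 20, ceiling(lambda + 12 * sqrt(lambda) + 20))
  dmax <- min(m, kmax)
  f <- numeric(dmax + 1L)   # f[d+1] = P(d observed differences | k mutations)
  f[1L] <- 1
  num <- 0; den <- 0
  for (k in 0:kmax) {
    w <- stats::dpois(k, lambda)
    if (k >= j) {
      den <- den + w * f[j + 1L]
      if (k == j) num <- w * f[j + 1L]
    }
    d <- 0:dmax
    fNew <- numeric(dmax + 1L)
    # new difference at an identical site
    fNew[-1L] <- f[-length(f)] * (m - d[-1L] + 1) / m
    # mutation at a differing site that does not revert it
    fNew <- fNew + f * (d / m) * (2 / 3)
    # reversion of a differing site
    fNew[-length(fNew)] <- fNew[-length(fNew)] +
      f[-1L] * (d[-1L] / m) * (1 / 3)
    f <- fNew
  }
  num / den
}

# Hamming distance between two haplotype strings over unambiguous sites
.mutationalDistance <- function(a, b) {
  ai <- match(strsplit(a, "")[[1]], c("A", "C", "G", "T"))
  bi <- match(strsplit(b, "")[[1]], c("A", "C", "G", "T"))
  ok <- !is.na(ai) & !is.na(bi)
  sum(ai[ok] != bi[ok])
}

#' Build a statistical-parsimony haplotype network
#'
#' Agglomerative connection of haplotypes: pairs of clusters are joined in
#' order of increasing mutational distance d = 1, 2, ..., `limit`; a join at
#' distance d inserts d-1 inferred intermediate nodes on one shortest
#' mutational path (sites mutated left-to-right along the alignment, an
#' arbitrary but pinned choice among equally parsimonious paths). Clusters
#' are never joined at d > `limit`; remaining clusters are reported as
#' separate components. Ties in join order are resolved by haplotype id.
#'
#' @param haps a [HaplotypeTable-class].
#' @param limit integer connection limit in mutational steps, e.g. from
#'   [parsimonyConnectionLimit()].
#' @return a [ParsimonyNetwork-class].
#' @examples
#' x <- alignedSeqSet(c(a = "AAAA", b = "AAAT", c = "AATT"),
#'                    c("p1", "p1", "p2"))
#' net <- buildNetwork(collapseHaplotypes(x), limit = 2L)
#' length(networkComponents(net))
#' @export
buildNetwork <- function(haps, limit) {
  stopifnot(is(haps, "HaplotypeTable"), limit >= 1)
  limit <- as.integer(limit)
  hapSeqs <- haplotypeSequences(haps)
  ids <- names(hapSeqs)
  k <- length(ids)
  totals <- colSums(haplotypeCounts(haps))

  nodes <- data.frame(id = ids, kind = "observed",
                      count = as.integer(totals),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = character(), to = character())
  cluster <- seq_len(k)   # cluster membership of observed haplotypes
  nInferred <- 0L

  if (k > 1L) {
    dm <- matrix(0L, k, k)
    for (i in seq_len(k - 1L))
      for (j in (i + 1L):k)
        dm[i, j] <- dm[j, i] <- .mutationalDistance(hapSeqs[i], hapSeqs[j])
    for (d in seq_len(limit)) {
      # candidate pairs at exactly this distance, in id order for determinism
      cand <- which(upper.tri(dm) & dm == d, arr.ind = TRUE)
      if (nrow(cand)) cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1L]; j <- cand[r, 2L]
        if (cluster[i] == cluster[j]) next
        path <- .mutationPath(hapSeqs[i], hapSeqs[j])
        prev <- ids[i]
        if (d > 1L) {
          for (s in seq_len(d - 1L)) {
            nInferred <- nInferred + 1L
            mid <- paste0("i", nInferred)
            nodes <- rbind(nodes, data.frame(id = mid, kind = "inferred",
                                             count = 0L))
            edges <- rbind(edges, data.frame(from = prev, to = mid))
            prev <- mid
          }
        }
        edges <- rbind(edges, data.frame(from = prev, to = ids[j]))
        cluster[cluster == cluster[j]] <- cluster[i]
      }
    }
  }

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  comps <- split(ids, cluster)
  comps <- comps[order(vapply(comps, function(x) match(x[1L], ids), 1L))]
  names(comps) <- NULL
  new("ParsimonyNetwork", graph = g, components = comps,
      connectionLimit = limit)
}

# intermediate haplotype sequences on the left-to-right shortest path a -> b
.mutationPath <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  ok <- !is.na(match(av, c("A", "C", "G", "T"))) &
        !is.na(match(bv, c("A", "C", "G", "T")))
  sites <- which(av != bv & ok)
  path <- character()
  cur <- av
  for (s in sites) {
    cur[s] <- bv[s]
    path <- c(path, paste(cur, collapse = ""))
  }
  path
}

#' Export a parsimony network
#'
#' Writes the edge list and node table as CSV and the graph as GraphML.
#'
#' @param net a [ParsimonyNetwork-class].
#' @param prefix output path prefix; files `<prefix>_edges.csv`,
#'   `<prefix>_nodes.csv`, `<prefix>.graphml` are written.
#' @export
writeNetwork <- function(net, prefix) {
  stopifnot(is(net, "ParsimonyNetwork"))
  g <- networkGraph(net)
  el <- igraph::as_data_frame(g, what = "edges")
  names(el) <- c("node_a", "node_b")
  nd <- igraph::as_data_frame(g, what = "vertices")
  names(nd) <- c("node_id", "kind", "total_count")
  utils::write.csv(el, paste0(prefix, "_edges.csv"), row.names = FALSE)
  utils::write.csv(nd, paste0(prefix, "_nodes.csv"), row.names = FALSE)
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  invisible(prefix)
}
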