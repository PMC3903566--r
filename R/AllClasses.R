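#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
NULL

#' AlignedSeqSet: aligned sequences with population labels
#'
#' Container for an alignment of equal-length DNA sequences, each assigned to
#' a sampling population. This is the entry point of the genetic side of the
#' pipeline: haplotype collapsing, distance computation and network building
#' all start from an \code{AlignedSeqSet}.
#'
#' @slot sequences a \code{\link[Biostrings]{DNAStringSet}} of identical
#'   widths; names are individual sequence ids (unique).
#' @slot populations character vector parallel to \code{sequences}, the
#'   population id of each individual.
#'
#' @seealso [alignedSeqSet()], [collapseHaplotypes()], [pairwiseK2PMatrix()]
#' @export
setClass("AlignedSeqSet",
  representation(sequences = "DNAStringSet", populations = "character"))

setValidity("AlignedSeqSet", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (n == 0L)
    msg <- c(msg, "empty sequence set")
  if (length(object@populations) != n)
    msg <- c(msg, "populations must be parallel to sequences")
  if (n > 0L) {
    w <- Biostrings::width(object@sequences)
    if (length(unique(w)) > 1L) {
      bad <- names(object@sequences)[w != w[1L]]
      msg <- c(msg, paste0("sequences not all the same length; offending ids: ",
                           paste(utils::head(bad, 5L), collapse = ", ")))
    }
    ids <- names(object@sequences)
    if (is.null(ids) || anyDuplicated(ids))
      msg <- c(msg, "sequence ids must be present and unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AlignedSeqSet
#'
#' @param sequences named character vector or \code{DNAStringSet} of aligned,
#'   equal-length DNA sequences (alphabet \code{A,C,G,T,N,-}).
#' @param populations character vector of population ids, one per sequence.
#' @return a validated [AlignedSeqSet-class] object.
#' @examples
#' x <- alignedSeqSet(c(s1 = "ACGT", s2 = "ACGA"), c("p1", "p2"))
#' seqLength(x)
#' @export
alignedSeqSet <- function(sequences, populations) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  obj <- new("AlignedSeqSet", sequences = sequences,
             populations = as.character(populations))
  obj
}

#' @describeIn alignedSeqSet number of aligned sites
#' @param x an \code{AlignedSeqSet}
#' @export
seqLength <- function(x) {
  stopifnot(is(x, "AlignedSeqSet"))
  if (length(x@sequences) == 0L) 0L else Biostrings::width(x@sequences)[1L]
}

#' @describeIn alignedSeqSet population label accessor
#' @export
populations <- function(x) x@populations

#' @describeIn alignedSeqSet sequence accessor (DNAStringSet)
#' @export
sequences <- function(x) x@sequences

setMethod("show", "AlignedSeqSet", function(object) {
  tab <- table(object@populations)
  cat("AlignedSeqSet:", length(object@sequences), "sequences x",
      seqLength(object), "sites\n")
  cat("populations:",
      paste(sprintf("%s(%d)", names(tab), as.integer(tab)), collapse = " "),
      "\n")
})

setMethod("length", "AlignedSeqSet", function(x) length(x@sequences))

#' HaplotypeTable: distinct haplotypes and their per-population counts
#'
#' The substrate of all haplotype-frequency statistics: the distinct sequences
#' observed in an alignment plus a populations x haplotypes count matrix.
#'
#' @slot haplotypeSeqs character vector of distinct haplotype sequences,
#'   named \code{H1, H2, ...} in order of first appearance.
#' @slot counts integer matrix, rows = populations, columns = haplotypes.
#' @export
setClass("HaplotypeTable",
  representation(haplotypeSeqs = "character", counts = "matrix"))

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  if (ncol(object@counts) != length(object@haplotypeSeqs))
    msg <- c(msg, "count matrix columns must match haplotype sequences")
  if (any(object@counts < 0))
    msg <- c(msg, "negative haplotype counts")
  if (length(object@haplotypeSeqs) &&
      any(colSums(object@counts) < 1))
    msg <- c(msg, "every haplotype must be observed at least once")
  if (is.null(rownames(object@counts)))
    msg <- c(msg, "count matrix must have population row names")
  if (length(msg)) msg else TRUE
})

#' @describeIn collapseHaplotypes haplotype count matrix (populations x haplotypes)
#' @export
haplotypeCounts <- function(x) {
  stopifnot(is(x, "HaplotypeTable"))
  x@counts
}

#' @describeIn collapseHaplotypes distinct haplotype sequences
#' @export
haplotypeSequences <- function(x) {
  stopifnot(is(x, "HaplotypeTable"))
  x@haplotypeSeqs
}

#' @describeIn collapseHaplotypes overall haplotype relative frequencies
#' @export
haplotypeFrequencies <- function(x) {
  stopifnot(is(x, "HaplotypeTable"))
  tot <- colSums(x@counts)
  tot / sum(tot)
}

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable:", length(object@haplotypeSeqs), "haplotypes,",
      nrow(object@counts), "populations,", sum(object@counts),
      "individuals\n")
  print(object@counts)
})

#' DivergenceMatrix: symmetric between-population dissimilarities
#'
#' A labelled symmetric matrix with zero diagonal holding one between-
#' population index (Nei pairwise fixation index or Morisita-Horn haplotype
#' divergence), or a K2P distance matrix between sequences.
#'
#' @slot values symmetric numeric matrix, zero diagonal, row/col names set.
#' @slot indexKind one of \code{"FST"}, \code{"MorisitaHorn"}, \code{"K2P"}.
#' @export
setClass("DivergenceMatrix",
  representation(values = "matrix", indexKind = "character"))

setValidity("DivergenceMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  else {
    if (any(abs(v - t(v)) > 1e-12)) msg <- c(msg, "matrix must be symmetric")
    if (any(abs(diag(v)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
    if (any(v < -1e-12)) msg <- c(msg, "negative dissimilarities")
  }
  if (!object@indexKind %in% c("FST", "MorisitaHorn", "K2P"))
    msg <- c(msg, "unknown indexKind")
  if (length(msg)) msg else TRUE
})

divergenceMatrix <- function(values, indexKind) {
  new("DivergenceMatrix", values = values, indexKind = indexKind)
}

#' @describeIn pcoa extract the plain numeric matrix of a DivergenceMatrix
#' @export
divergenceValues <- function(x) {
  stopifnot(is(x, "DivergenceMatrix"))
  x@values
}

setMethod("show", "DivergenceMatrix", function(object) {
  cat("DivergenceMatrix (", object@indexKind, "): ",
      nrow(object@values), " x ", ncol(object@values), "\n", sep = "")
  print(round(object@values, 4))
})

#' ParsimonyNetwork: statistical parsimony haplotype network
#'
#' Graph of observed haplotypes plus inferred single-step intermediates.
#' Every edge is exactly one mutational step. The number of connected
#' components is the cryptic-lineage screen: a single component means all
#' haplotypes can be joined within the parsimony limit.
#'
#' @slot graph an \code{igraph} object; vertex attributes \code{kind}
#'   (\code{"observed"}/\code{"inferred"}) and \code{count} (total
#'   individuals, 0 for inferred nodes).
#' @slot components list of character vectors partitioning the observed
#'   haplotype ids.
#' @slot connectionLimit integer, maximum mutational steps allowed per join.
#' @export
setClass("ParsimonyNetwork",
  representation(graph = "ANY", components = "list",
                 connectionLimit = "integer"))

setValidity("ParsimonyNetwork", function(object) {
  msg <- character()
  obs <- unlist(object@components)
  if (anyDuplicated(obs))
    msg <- c(msg, "observed haplotype assigned to more than one component")
  if (object@connectionLimit < 1L)
    msg <- c(msg, "connection limit must be at least 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn buildNetwork number of connected components over observed haplotypes
#' @export
networkComponents <- function(x) {
  stopifnot(is(x, "ParsimonyNetwork"))
  x@components
}

#' @describeIn buildNetwork underlying igraph object
#' @export
networkGraph <- function(x) {
  stopifnot(is(x, "ParsimonyNetwork"))
  x@graph
}

setMethod("show", "ParsimonyNetwork", function(object) {
  nv <- igraph::vcount(object@graph)
  kinds <- igraph::V(object@graph)$kind
  cat("ParsimonyNetwork: ", sum(kinds == "observed"), " observed + ",
      sum(kinds == "inferred"), " inferred nodes, ",
      igraph::ecount(object@graph), " edges, ",
      length(object@components), " component(s), limit ",
      object@connectionLimit, " step(s)\n", sep = "")
})

#' OrdinationResult: principal coordinates of a divergence matrix
#'
#' @slot coordinates numeric matrix, populations x kept axes; axis j is the
#'   unit eigenvector scaled by sqrt(eigenvalue j).
#' @slot eigenvalues numeric vector of all eigenvalues, descending.
#' @slot axesKept integer, number of axes retained.
#' @export
setClass("OrdinationResult",
  representation(coordinates = "matrix", eigenvalues = "numeric",
                 axesKept = "integer"))

setValidity("OrdinationResult", function(object) {
  msg <- character()
  if (is.unsorted(rev(object@eigenvalues), strict = FALSE))
    msg <- c(msg, "eigenvalues must be sorted descending")
  if (ncol(object@coordinates) != object@axesKept)
    msg <- c(msg, "coordinate columns must equal axesKept")
  if (length(msg)) msg else TRUE
})

#' @describeIn pcoa coordinate matrix accessor
#' @export
ordinationCoordinates <- function(x) {
  stopifnot(is(x, "OrdinationResult"))
  x@coordinates
}

#' @describeIn pcoa eigenvalue accessor
#' @export
ordinationEigenvalues <- function(x) {
  stopifnot(is(x, "OrdinationResult"))
  x@eigenvalues
}

setMethod("show", "OrdinationResult", function(object) {
  cat("OrdinationResult:", nrow(object@coordinates), "points,",
      object@axesKept, "axes kept\n")
  cat("eigenvalues:", paste(signif(object@eigenvalues, 4), collapse = " "),
      "\n")
})

#' MRTree: fitted multivariate regression tree
#'
#' Result of [fitMrt()]: a greedy binary partition of populations by genetic
#' explanatory variables minimising within-node sums of squared distances of
#' the multivariate physiological response.
#'
#' @slot frame data.frame with one row per node: \code{id, parent, depth,
#'   isLeaf, splitVar, splitValue, n, ss, improve, splitOrder}.
#' @slot members list of character vectors: population ids per node.
#' @slot response the (possibly standardized) response matrix used in the fit.
#' @slot explanatory the explanatory table used in the fit.
#' @slot standardized logical flag.
#' @export
setClass("MRTree",
  representation(frame = "data.frame", members = "list", response = "matrix",
                 explanatory = "data.frame", standardized = "logical"))

setValidity("MRTree", function(object) {
  msg <- character()
  fr <- object@frame
  for (i in seq_len(nrow(fr))) {
    if (!fr$isLeaf[i]) {
      kids <- which(fr$parent == fr$id[i])
      if (length(kids) != 2L) {
        msg <- c(msg, "internal node without two children")
        next
      }
      got <- sort(unlist(object@members[kids]))
      if (!identical(got, sort(object@members[[i]])))
        msg <- c(msg, "children do not partition the parent")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MRTree", function(object) {
  fr <- object@frame
  cat("MRTree:", sum(fr$isLeaf), "leaves,",
      sum(!fr$isLeaf), "split(s)",
      if (object@standardized) "(standardized response)" else "(raw response)",
      "\n")
  if (any(!fr$isLeaf)) {
    first <- fr[!fr$isLeaf & fr$splitOrder == 1L, ]
    cat("primary split:", first$splitVar, "at",
        signif(first$splitValue, 4), "\n")
  }
  cat("topology:", newickTopology(object), "\n")
})
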