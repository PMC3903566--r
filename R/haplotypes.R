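#' Read an aligned FASTA with a population map
#'
#' Reads a multi-record FASTA of aligned, equal-length sequences and joins it
#' with a two-column population map (`sequence_id,population_id`, with
#' header). Sequences are expected pre-aligned and indel-free; unequal
#' lengths are an error unless a trim window is given.
#'
#' @param fastaPath path to a FASTA file.
#' @param popmapPath path to a CSV/TSV population map with columns
#'   `sequence_id` and `population_id` (separator auto-detected).
#' @param trimWindow optional integer c(start, end): keep only this 1-based
#'   column window before length validation.
#' @return an [AlignedSeqSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), fa)
#' pm <- tempfile(fileext = ".csv")
#' writeLines(c("sequence_id,population_id", "a,p1", "b,p2"), pm)
#' readFastaWithPopulations(fa, pm)
#' @export
readFastaWithPopulations <- function(fastaPath, popmapPath, trimWindow = NULL) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  if (length(seqs) == 0L)
    stop("empty FASTA file: ", fastaPath)
  # FASTA headers may carry descriptions after whitespace; ids are the first token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  sep <- if (grepl("\t", readLines(popmapPath, n = 1L))) "\t" else ","
  popmap <- utils::read.table(popmapPath, header = TRUE, sep = sep,
                              colClasses = "character")
  if (!all(c("sequence_id", "population_id") %in% names(popmap)))
    stop("population map must have columns sequence_id,population_id")
  missing <- setdiff(names(seqs), popmap$sequence_id)
  if (length(missing))
    stop("sequence ids absent from population map: ",
         paste(missing, collapse = ", "))
  if (!is.null(trimWindow)) {
    stopifnot(length(trimWindow) == 2L, trimWindow[1L] >= 1L)
    seqs <- Biostrings::subseq(seqs, trimWindow[1L], trimWindow[2L])
  }
  pops <- popmap$population_id[match(names(seqs), popmap$sequence_id)]
  out <- alignedSeqSet(seqs, pops)
  tab <- table(pops)
  message("read ", length(seqs), " sequences x ", seqLength(out), " sites; ",
          paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                collapse = ", "))
  out
}

#' Collapse aligned sequences to haplotypes
#'
#' Partitions individuals into haplotypes (distinct sequence variants) and
#' tabulates per-population counts. Under the default `strict` policy two
#' sequences share a haplotype only if they are identical strings, so `N`
#' behaves as a fifth symbol; under `match_N` an `N` matches any base and an
#' individual joins the first compatible haplotype in input order.
#'
#' @param seqs an [AlignedSeqSet-class].
#' @param ambiguityPolicy `"strict"` (default) or `"match_N"`.
#' @return a [HaplotypeTable-class]; haplotypes are numbered in order of
#'   first appearance.
#' @examples
#' x <- alignedSeqSet(c(a = "AAAA", b = "AAAA", c = "AAAT"),
#'                    c("p1", "p2", "p2"))
#' haplotypeCounts(collapseHaplotypes(x))
#' @export
collapseHaplotypes <- function(seqs, ambiguityPolicy = c("strict", "match_N")) {
  ambiguityPolicy <- match.arg(ambiguityPolicy)
  stopifnot(is(seqs, "AlignedSeqSet"))
  chars <- as.character(sequences(seqs))
  pops <- populations(seqs)
  if (ambiguityPolicy == "strict") {
    hapSeqs <- unique(chars)
    assign <- match(chars, hapSeqs)
  } else {
    hapSeqs <- character()
    assign <- integer(length(chars))
    for (i in seq_along(chars)) {
      hit <- 0L
      for (h in seq_along(hapSeqs)) {
        if (.compatibleN(chars[i], hapSeqs[h])) { hit <- h; break }
      }
      if (hit == 0L) {
        hapSeqs <- c(hapSeqs, chars[i])
        hit <- length(hapSeqs)
      } else if (grepl("N", hapSeqs[hit], fixed = TRUE) &&
                 !grepl("N", chars[i], fixed = TRUE)) {
        # prefer the fully resolved representative for the class
        hapSeqs[hit] <- chars[i]
      }
      assign[i] <- hit
    }
  }
  popLevels <- unique(pops)
  counts <- table(factor(pops, levels = popLevels),
                  factor(assign, levels = seq_along(hapSeqs)))
  counts <- matrix(as.integer(counts), nrow = length(popLevels),
                   dimnames = list(popLevels,
                                   paste0("H", seq_along(hapSeqs))))
  names(hapSeqs) <- colnames(counts)
  new("HaplotypeTable", haplotypeSeqs = hapSeqs, counts = counts)
}

# do two equal-length sequences agree at every site, letting N match anything?
.compatibleN <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  all(av == bv | av == "N" | bv == "N")
}

# encode a character matrix of bases as integers; non-ACGT -> NA
.encodeBases <- function(charMat) {
  m <- matrix(match(charMat, c("A", "C", "G", "T")), nrow = nrow(charMat))
  rownames(m) <- rownames(charMat)
  m
}

.seqMatrix <- function(seqs) {
  m <- as.matrix(sequences(seqs))
  rownames(m) <- names(sequences(seqs))
  m
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computes the K2P distance d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q),
#' where P and Q are the transition and transversion proportions over the
#' sites at which both sequences carry an unambiguous base (pairwise
#' deletion; `N` and `-` are excluded).
#'
#' @param a,b equal-length DNA strings.
#' @return distance in substitutions/site.
#' @examples
#' k2pDistance(strrep("A", 700), paste0(strrep("A", 699), "G"))
#' @export
k2pDistance <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  if (length(av) != length(bv))
    stop("sequences of unequal length")
  .k2pFromCodes(match(av, c("A", "C", "G", "T")),
                match(bv, c("A", "C", "G", "T")))
}

# K2P from integer-coded sequences (A=1 C=2 G=3 T=4, NA = ambiguous/gap)
.k2pFromCodes <- function(ai, bi) {
  ok <- !is.na(ai) & !is.na(bi)
  n <- sum(ok)
  if (n == 0L)
    stop("no comparable sites (all ambiguous or gapped)")
  ai <- ai[ok]; bi <- bi[ok]
  diff <- ai != bi
  # purines code 1,3; pyrimidines 2,4: a transition keeps parity
  ts <- diff & ((ai %% 2L) == (bi %% 2L))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance undefined/saturated (P=", signif(P, 3),
         ", Q=", signif(Q, 3), ")")
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix of an aligned set
#'
#' @param seqs an [AlignedSeqSet-class] with at least 2 sequences.
#' @return a [DivergenceMatrix-class] with `indexKind = "K2P"`, labelled by
#'   sequence id.
#' @export
pairwiseK2PMatrix <- function(seqs) {
  stopifnot(is(seqs, "AlignedSeqSet"))
  m <- .encodeBases(.seqMatrix(seqs))
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- tryCatch(
        .k2pFromCodes(m[i, ], m[j, ]),
        error = function(e) stop("pair (", rownames(m)[i], ", ",
                                 rownames(m)[j], "): ", conditionMessage(e)))
    }
  }
  divergenceMatrix(d, "K2P")
}

#' Write a labelled square distance matrix as CSV
#'
#' @param d a [DivergenceMatrix-class].
#' @param path output file.
#' @export
writeDistanceMatrix <- function(d, path) {
  stopifnot(is(d, "DivergenceMatrix"))
  utils::write.csv(as.data.frame(divergenceValues(d)), path)
  invisible(path)
}
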