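#' Simulation configuration with planted ground truth
#'
#' Builds the configuration of the synthetic-data generator. The defaults
#' emulate the statistical structure the pipeline expects from a seven-
#' population land-snail heat-stress study: ~6 COI haplotypes over <1%
#' variable positions with two dominant haplotypes (66%/19% of sequences),
#' one monomorphic population, one genetically divergent population, and
#' per-population heat-response "strategies" (moderate, high or flat Hsp70
#' induction with matching histopathology trajectories) over exposure
#' temperatures 25-48 degC.
#'
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @param nPopulations,nSeqPerPop,seqLength,nHaplotypes genetic design
#'   (defaults 7, 20, 700, 6).
#' @param globalHaplotypeFreqs global haplotype frequencies; default
#'   c(0.66, 0.19) with the remainder split equally.
#' @param maxVariableSites maximum distinct mutated alignment columns
#'   (default 7, keeping > 99\% of sites shared).
#' @param dirichletConcentration Dirichlet concentration for per-population
#'   frequency jitter (larger = closer to the profile; default 60).
#' @param monomorphicPopulations,divergentPopulations population ids
#'   (defaults "7" and "4").
#' @param strategyMap named character vector population -> strategy in
#'   c("moderate", "high", "flat").
#' @param hsp70NoiseSd SD of individual Hsp70 levels around the group mean
#'   (relative units; control mean is 1).
#' @param scoreNoiseSd SD of the latent damage score before discretisation.
#' @param nHsp70,nHistology individuals per population x temperature cell
#'   (defaults 10 and 8).
#' @param temperatures exposure temperatures in degC.
#' @return a `SimulationConfig` list (classed).
#' @export
simulationConfig <- function(seed = 1L,
                             nPopulations = 7L,
                             nSeqPerPop = 20L,
                             seqLength = 700L,
                             nHaplotypes = 6L,
                             globalHaplotypeFreqs = NULL,
                             maxVariableSites = 7L,
                             dirichletConcentration = 60,
                             monomorphicPopulations = "7",
                             divergentPopulations = "4",
                             strategyMap = NULL,
                             hsp70NoiseSd = 0.12,
                             scoreNoiseSd = 0.7,
                             nHsp70 = 10L,
                             nHistology = 8L,
                             temperatures = c(25, 33, 38, 40, 43, 45, 48)) {
  pops <- as.character(seq_len(nPopulations))
  if (is.null(globalHaplotypeFreqs)) {
    rest <- (1 - 0.66 - 0.19) / max(nHaplotypes - 2L, 1L)
    globalHaplotypeFreqs <- c(0.66, 0.19, rep(rest, nHaplotypes - 2L))
  }
  stopifnot(abs(sum(globalHaplotypeFreqs) - 1) < 1e-8,
            length(globalHaplotypeFreqs) == nHaplotypes,
            maxVariableSites / seqLength <= 0.01,
            nHaplotypes - 1L <= maxVariableSites)
  if (is.null(strategyMap)) {
    strategyMap <- stats::setNames(rep("moderate", nPopulations), pops)
    strategyMap[intersect(c("3", "6", "7"), pops)] <- "high"
    strategyMap[intersect(divergentPopulations, pops)] <- "flat"
  }
  stopifnot(setequal(names(strategyMap), pops),
            all(strategyMap %in% c("moderate", "high", "flat")))
  cfg <- list(seed = as.integer(seed), nPopulations = nPopulations,
              nSeqPerPop = nSeqPerPop, seqLength = seqLength,
              nHaplotypes = nHaplotypes,
              globalHaplotypeFreqs = globalHaplotypeFreqs,
              maxVariableSites = maxVariableSites,
              dirichletConcentration = dirichletConcentration,
              monomorphicPopulations = monomorphicPopulations,
              divergentPopulations = divergentPopulations,
              strategyMap = strategyMap,
              hsp70NoiseSd = hsp70NoiseSd, scoreNoiseSd = scoreNoiseSd,
              nHsp70 = nHsp70, nHistology = nHistology,
              temperatures = temperatures,
              # mean Hsp70 percent-of-control profiles per strategy
              hsp70Profiles = list(
                moderate = c(`25` = 100, `33` = 108, `38` = 122, `40` = 135,
                             `43` = 112, `45` = 88, `48` = 72),
                high = c(`25` = 100, `33` = 112, `38` = 150, `40` = 175,
                         `43` = 130, `45` = 95, `48` = 75),
                flat = c(`25` = 100, `33` = 100, `38` = 104, `40` = 102,
                         `43` = 92, `45` = 80, `48` = 65)),
              # latent histopathology damage: 1 + 4 * plogis((T - t50)/width)
              # anchored so controls sit near category 1, most populations
              # reach the "status of reaction" (~2.5-3.5) at 40 degC and
              # "destruction" (~4-5) at 48 degC, while the flat strategy
              # holds good condition to 40 degC and collapses sharply above
              histologyCurves = list(
                moderate = c(t50 = 41, width = 4),
                high = c(t50 = 40.5, width = 4),
                flat = c(t50 = 43, width = 1.2)),
              # tissue-specific shift of t50: digestive cells are the most
              # heat sensitive, calcium cells the most resistant
              tissueShift = c(tubule = 0, digestive = -2, calcium = 2))
  class(cfg) <- "SimulationConfig"
  cfg
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Generate a synthetic aligned sequence set with planted haplotype truth
#'
#' Builds a random reference sequence and derives the haplotypes as single
#' mutational steps away from a hub haplotype at distinct alignment columns
#' (so the statistical-parsimony network is connected by construction);
#' samples per-population haplotype counts from a Dirichlet-multinomial
#' around the global frequencies. Divergent populations receive a shifted
#' frequency profile (mass moved onto an otherwise-rare haplotype, giving
#' them elevated divergence against every other population); monomorphic
#' populations carry only the hub haplotype.
#'
#' @param config a [simulationConfig()].
#' @return list with `seqs` (an [AlignedSeqSet-class]) and `truth` (planted
#'   haplotype sequences, per-population frequency profiles and realized
#'   counts).
#' @export
generateSequences <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  k <- config$nHaplotypes
  if (k - 1L > config$maxVariableSites)
    stop("more haplotypes than available variable sites")
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, config$seqLength, replace = TRUE)
  varSites <- sort(sample.int(config$seqLength, k - 1L))
  haps <- character(k)
  haps[1L] <- paste(ref, collapse = "")          # hub haplotype
  for (h in seq_len(k - 1L)) {
    mut <- ref
    mut[varSites[h]] <- sample(setdiff(bases, ref[varSites[h]]), 1L)
    haps[h + 1L] <- paste(mut, collapse = "")
  }
  names(haps) <- paste0("H", seq_len(k))

  pops <- as.character(seq_len(config$nPopulations))
  # divergent populations: most global mass moved onto haplotype 3
  divergentProfile <- c(0.15, 0.05, 0.66, rep(0.14 / max(k - 3L, 1L),
                                              k - 3L))
  profiles <- matrix(NA_real_, config$nPopulations, k,
                     dimnames = list(pops, names(haps)))
  counts <- matrix(0L, config$nPopulations, k,
                   dimnames = list(pops, names(haps)))
  seqsOut <- character(0)
  popsOut <- character(0)
  for (p in pops) {
    if (p %in% config$monomorphicPopulations) {
      profiles[p, ] <- c(1, rep(0, k - 1L))
      cnt <- c(config$nSeqPerPop, rep(0L, k - 1L))
    } else {
      base <- if (p %in% config$divergentPopulations) divergentProfile
      else config$globalHaplotypeFreqs
      prob <- .rdirichlet1(config$dirichletConcentration * base)
      profiles[p, ] <- prob
      cnt <- as.integer(stats::rmultinom(1L, config$nSeqPerPop, prob))
    }
    counts[p, ] <- cnt
  }
  # the planted truth contains every haplotype: re-seat one copy of any
  # haplotype that multinomial sampling dropped, taking it from the most
  # common haplotype of the population where its profile frequency is top
  for (h in seq_len(k)) {
    if (sum(counts[, h]) > 0L) next
    free <- setdiff(pops, config$monomorphicPopulations)
    target <- free[which.max(profiles[free, h])]
    donor <- which.max(counts[target, ])
    counts[target, donor] <- counts[target, donor] - 1L
    counts[target, h] <- 1L
  }
  for (p in pops) {
    idx <- rep(seq_len(k), counts[p, ])
    ids <- sprintf("pop%s_%02d", p, seq_along(idx))
    seqsOut <- c(seqsOut, stats::setNames(haps[idx], ids))
    popsOut <- c(popsOut, rep(p, length(idx)))
  }
  list(seqs = alignedSeqSet(seqsOut, popsOut),
       truth = list(haplotypes = haps, variableSites = varSites,
                    frequencyProfiles = profiles, counts = counts,
                    strategyMap = config$strategyMap))
}

#' Generate a synthetic physiology table with planted strategy truth
#'
#' Per population x temperature cell: individual Hsp70 levels are drawn from
#' a truncated-at-zero Gaussian around the strategy-specific unimodal
#' temperature profile (flat strategy peaking near 104\% of control,
#' moderate near 135\%, high near 175\%, all declining at >= 43 degC);
#' histopathology scores discretise a latent damage curve rising with
#' temperature into the 1-5 categories, with digestive cells more heat
#' sensitive than calcium cells and the flat-strategy population collapsing
#' sharply above 40 degC.
#'
#' @param config a [simulationConfig()].
#' @return list with `records` (tidy data.frame as in [readPhysiology()])
#'   and `truth` (per-cell true Hsp70 means and latent MAVs).
#' @export
generatePhysiology <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  pops <- as.character(seq_len(config$nPopulations))
  tissues <- c("tubule", "digestive", "calcium")
  rows <- list()
  truthHsp <- list(); truthMav <- list()
  for (p in pops) {
    strat <- config$strategyMap[[p]]
    prof <- config$hsp70Profiles[[strat]]
    curve <- config$histologyCurves[[strat]]
    for (tt in config$temperatures) {
      key <- paste0("p", p, "_t", tt)
      hspMean <- prof[[as.character(tt)]] / 100
      truthHsp[[key]] <- hspMean
      # Hsp70 individuals (truncated at zero by redraw)
      v <- stats::rnorm(config$nHsp70, hspMean, config$hsp70NoiseSd)
      while (any(v <= 0))
        v[v <= 0] <- stats::rnorm(sum(v <= 0), hspMean, config$hsp70NoiseSd)
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = sprintf("p%s_t%g_h%02d", p, tt,
                                seq_len(config$nHsp70)),
        population_id = p, temperature = tt, hsp70_rel = v,
        tubule_score = NA_real_, digestive_score = NA_real_,
        calcium_score = NA_real_)
      # histology individuals: all three tissues scored on the same snail
      latent <- vapply(tissues, function(ts)
        1 + 4 * stats::plogis((tt - (curve[["t50"]] +
                                       config$tissueShift[[ts]])) /
                                curve[["width"]]), numeric(1))
      truthMav[[key]] <- latent
      sc <- lapply(tissues, function(ts) {
        s <- round(latent[[ts]] + stats::rnorm(config$nHistology, 0,
                                               config$scoreNoiseSd))
        pmin(pmax(s, 1), 5)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = sprintf("p%s_t%g_s%02d", p, tt,
                                seq_len(config$nHistology)),
        population_id = p, temperature = tt, hsp70_rel = NA_real_,
        tubule_score = sc[[1L]], digestive_score = sc[[2L]],
        calcium_score = sc[[3L]])
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  list(records = validatePhysiology(records),
       truth = list(hsp70Means = truthHsp, latentMavs = truthMav,
                    strategyMap = config$strategyMap))
}
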