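#' Write a synthetic study to disk
#'
#' Materialises the synthetic datasets in the exact input formats of the
#' pipeline: an aligned FASTA, a `sequence_id,population_id` population map,
#' a tidy physiology CSV, and the planted truth as JSON.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if missing).
#' @return named list of file paths (`fasta`, `popmap`, `physiology`,
#'   `truth`).
#' @export
simulateStudy <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- generateSequences(config)
  phys <- generatePhysiology(config)
  fasta <- file.path(dir, "sequences.fasta")
  Biostrings::writeXStringSet(sequences(gen$seqs), fasta)
  popmap <- file.path(dir, "popmap.csv")
  utils::write.csv(data.frame(sequence_id = names(sequences(gen$seqs)),
                              population_id = populations(gen$seqs)),
                   popmap, row.names = FALSE, quote = FALSE)
  physPath <- file.path(dir, "physiology.csv")
  utils::write.csv(phys$records, physPath, row.names = FALSE, quote = FALSE)
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(list(sequences = gen$truth, physiology = phys$truth),
                       truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(fasta = fasta, popmap = popmap, physiology = physPath, truth = truth)
}

#' Pipeline configuration
#'
#' @param fasta,popmap,physiology input file paths (see
#'   [readFastaWithPopulations()] and [readPhysiology()]).
#' @param outDir output directory for the report bundle.
#' @param confidence statistical-parsimony confidence (default 0.95).
#' @param connectionLimit optional integer override of the parsimony
#'   connection limit in steps.
#' @param axesHmh,axesFst PCoA axes kept per divergence index (defaults 3
#'   and 2 — exactly the explanatory variables of the tree analysis).
#' @param folds,reps,seed cross-validation settings (defaults 10, 1000, 1).
#' @param standardize standardize the response columns in the tree fits.
#' @param mrtTemperatures temperatures with a full response matrix, each
#'   getting its own regression tree (default c(25, 33, 40, 48)).
#' @return classed configuration list.
#' @export
pipelineConfig <- function(fasta, popmap, physiology, outDir,
                           confidence = 0.95, connectionLimit = NULL,
                           axesHmh = 3L, axesFst = 2L, folds = 10L,
                           reps = 1000L, seed = 1L, standardize = TRUE,
                           mrtTemperatures = c(25, 33, 40, 48)) {
  for (f in c(fasta, popmap, physiology))
    if (!file.exists(f)) stop("input file does not exist: ", f)
  cfg <- list(fasta = fasta, popmap = popmap, physiology = physiology,
              outDir = outDir, confidence = confidence,
              connectionLimit = connectionLimit, axesHmh = axesHmh,
              axesFst = axesFst, folds = folds, reps = reps,
              seed = as.integer(seed), standardize = standardize,
              mrtTemperatures = mrtTemperatures)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes haplotype collapsing, parsimony network construction,
#' population indices, PCoA ordination, physiology summaries and the
#' per-temperature multivariate regression trees, and writes the report
#' bundle: the combined diversity/divergence table, the Hsp70 maximum-
#' induction table, a tree-summary table (one row per temperature with the
#' first-split R^2, CV error, Newick topology, primary variable and
#' correlation signs), network exports, and a JSON manifest recording seed
#' and parameters.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) list with all intermediate objects and the manifest.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  seqs <- stage("read", readFastaWithPopulations(config$fasta, config$popmap))
  haps <- stage("haplotypes", collapseHaplotypes(seqs))
  limit <- if (!is.null(config$connectionLimit))
    as.integer(config$connectionLimit)
  else stage("limit", parsimonyConnectionLimit(seqLength(seqs),
                                               config$confidence))
  net <- stage("network", buildNetwork(haps, limit))
  writeNetwork(net, file.path(config$outDir, "network"))

  idx <- stage("indices", indexTable(haps, seqs))
  writeIndexTable(idx, file.path(config$outDir, "indices"))

  ordHmh <- stage("ordination", pcoa(idx$morisitaHorn, config$axesHmh))
  ordFst <- stage("ordination", pcoa(idx$fst, config$axesFst))
  writeOrdination(ordHmh, file.path(config$outDir, "pcoa_hmh"))
  writeOrdination(ordFst, file.path(config$outDir, "pcoa_fst"))
  expl <- stage("ordination", buildExplanatoryTable(idx$diversity, ordHmh,
                                                    ordFst))

  rec <- stage("physiology", readPhysiology(config$physiology))
  summ <- stage("physiology", populationSummary(rec))
  utils::write.csv(summ, file.path(config$outDir, "physiology_summary.csv"),
                   row.names = FALSE)
  pops <- sort(unique(rec$population_id))
  induction <- do.call(rbind, lapply(pops, function(p) {
    mi <- maxInduction(rec, p)
    data.frame(population = p, temperature = mi$temperature,
               max_induction_percent = mi$percent)
  }))
  utils::write.csv(induction, file.path(config$outDir, "induction.csv"),
                   row.names = FALSE)

  mrtRows <- list()
  mrtFits <- list()
  for (tt in config$mrtTemperatures) {
    Y <- stage("mrt", buildResponseMatrix(rec, tt))
    Xt <- expl[rownames(Y), , drop = FALSE]
    cv <- stage("mrt", crossValidate(Xt, Y, folds = config$folds,
                                     reps = config$reps, seed = config$seed,
                                     standardize = config$standardize))
    tree <- stage("mrt", fitMrt(Xt, Y, standardize = config$standardize))
    sig <- if (any(!tree@frame$isLeaf)) primarySplitCorrelations(tree)
    else NULL
    hspSign <- if (!is.null(sig)) sig$sign[sig$response == "hsp70_mean"]
    else NA_character_
    mavSigns <- if (!is.null(sig))
      paste(sig$sign[startsWith(sig$response, "mav")], collapse = "")
    else NA_character_
    mrtRows[[length(mrtRows) + 1L]] <- data.frame(
      temperature = tt,
      r2_first_split = firstSplitR2(tree),
      cv_error = unname(cv$cvError[as.character(cv$selectedSize)]),
      selected_size = cv$selectedSize,
      newick = newickTopology(tree),
      paper_style = newickTopology(tree, style = "paper"),
      primary_variable = if (!is.null(sig)) attr(sig, "splitVariable")
      else NA_character_,
      hsp70_sign = hspSign, histology_signs = mavSigns)
    mrtFits[[as.character(tt)]] <- list(tree = tree, cv = cv)
  }
  mrtTable <- do.call(rbind, mrtRows)
  utils::write.csv(mrtTable, file.path(config$outDir, "mrt_summary.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "thermopop",
    version = as.character(utils::packageVersion("thermopop")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "outDir")],
    connection_limit = limit,
    n_haplotypes = length(haplotypeSequences(haps)),
    n_components = length(networkComponents(net)))
  manifest$config_checksum <- sum(utf8ToInt(jsonlite::toJSON(
    manifest$parameters, auto_unbox = TRUE)))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(seqs = seqs, haplotypes = haps, network = net,
                 indices = idx, ordinationHmh = ordHmh,
                 ordinationFst = ordFst, explanatory = expl,
                 physiology = rec, summary = summ, induction = induction,
                 mrt = mrtFits, mrtTable = mrtTable, manifest = manifest))
}
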