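#' Read a tidy physiology table
#'
#' Expects a CSV with columns `individual_id, population_id, temperature,
#' hsp70_rel, tubule_score, digestive_score, calcium_score`; empty cells are
#' allowed (an individual contributes either the Hsp70 assay or the
#' histology scores). Scores must lie in [1, 5].
#'
#' @param path CSV file path.
#' @return validated data.frame of individual records.
#' @export
readPhysiology <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  validatePhysiology(rec)
}

#' Validate a physiology record table
#'
#' @param rec data.frame of individual records (see [readPhysiology()]).
#' @return the validated data.frame, invisibly unchanged.
#' @export
validatePhysiology <- function(rec) {
  need <- c("individual_id", "population_id", "temperature", "hsp70_rel",
            "tubule_score", "digestive_score", "calcium_score")
  if (!all(need %in% names(rec)))
    stop("physiology table must have columns: ", paste(need, collapse = ", "))
  scores <- c("tubule_score", "digestive_score", "calcium_score")
  for (s in scores) {
    v <- rec[[s]]
    if (any(!is.na(v) & (v < 1 | v > 5)))
      stop(s, " outside the 1-5 assessment scale")
  }
  if (any(!is.na(rec$hsp70_rel) & rec$hsp70_rel < 0))
    stop("negative hsp70_rel values")
  empty <- is.na(rec$hsp70_rel) & is.na(rec$tubule_score) &
    is.na(rec$digestive_score) & is.na(rec$calcium_score)
  if (any(empty))
    stop("records with no measurement at all: ",
         paste(utils::head(rec$individual_id[empty], 5L), collapse = ", "))
  rec
}

.tissueColumn <- function(tissue) {
  col <- c(tubule = "tubule_score", digestive = "digestive_score",
           calcium = "calcium_score")[tissue]
  if (is.na(col)) stop("unknown tissue: ", tissue)
  col
}

#' Mean assessment value (MAV) for one population/temperature/tissue cell
#'
#' Arithmetic mean and sample SD of the 1-5 semi-quantitative histopathology
#' scores (1 = control status, 3 = status of reaction, 5 = destruction).
#'
#' @param rec physiology record data.frame.
#' @param population,temperature cell selectors.
#' @param tissue one of `"tubule"`, `"digestive"`, `"calcium"`.
#' @return list with `mean`, `sd`, `n`.
#' @export
meanAssessmentValue <- function(rec, population, temperature, tissue) {
  col <- .tissueColumn(tissue)
  v <- rec[[col]][rec$population_id == population &
                    rec$temperature == temperature]
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop("no ", tissue, " scores for population ", population, " at ",
         temperature, " degrees C")
  list(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
       n = length(v))
}

#' Hsp70 level as percent of the 25 degC control
#'
#' Per exposure temperature, 100 x mean(hsp70) / mean(hsp70 at 25 degC) for
#' one population; the control group is 100% by construction.
#'
#' @param rec physiology record data.frame.
#' @param population population id.
#' @return named numeric vector, one entry per temperature present.
#' @export
hsp70PercentOfControl <- function(rec, population) {
  sub <- rec[rec$population_id == population & !is.na(rec$hsp70_rel), ]
  if (!any(sub$temperature == 25))
    stop("no 25 degC control group for population ", population)
  ctrl <- mean(sub$hsp70_rel[sub$temperature == 25])
  if (ctrl <= 0)
    stop("zero-mean control group for population ", population)
  temps <- sort(unique(sub$temperature))
  out <- vapply(temps, function(tt)
    100 * mean(sub$hsp70_rel[sub$temperature == tt]) / ctrl, numeric(1))
  names(out) <- temps
  out
}

#' Maximum Hsp70 induction of a population
#'
#' The non-control temperature with the highest percent-of-control Hsp70
#' level; ties are broken towards the lower temperature (reported via a
#' message).
#'
#' @inheritParams hsp70PercentOfControl
#' @return list with `temperature` and `percent`.
#' @export
maxInduction <- function(rec, population) {
  pct <- hsp70PercentOfControl(rec, population)
  pct <- pct[names(pct) != "25"]
  if (length(pct) < 1L)
    stop("need at least one non-control temperature group")
  best <- max(pct)
  at <- as.numeric(names(pct)[pct == best])
  if (length(at) > 1L)
    message("induction maximum tied at ", paste(at, collapse = "/"),
            " degC; reporting the lower temperature")
  list(temperature = min(at), percent = best)
}

#' Digestive/calcium cell integrity ratio
#'
#' Ratio of the digestive-cell MAV to the calcium-cell MAV for one
#' population and temperature; values below 1 indicate digestive cells in
#' better (lower-score) condition than calcium cells.
#'
#' @inheritParams meanAssessmentValue
#' @return numeric ratio.
#' @export
integrityRatio <- function(rec, population, temperature) {
  dig <- meanAssessmentValue(rec, population, temperature, "digestive")$mean
  cal <- meanAssessmentValue(rec, population, temperature, "calcium")$mean
  dig / cal
}

#' Two-sample rank-sum test of a treatment group against the control
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum comparison of one exposure group
#' against the 25 degC control of the same population. Uses exact
#' enumeration when both groups have at most 10 observations and there are
#' no ties, and the tie-corrected normal approximation (with continuity
#' correction) otherwise — histopathology scores tie heavily. If the pooled
#' data are all identical the p-value is 1 with a warning.
#'
#' @param rec physiology record data.frame.
#' @param population population id.
#' @param variable one of `"hsp70_rel"`, `"tubule_score"`,
#'   `"digestive_score"`, `"calcium_score"`.
#' @param temperature treatment temperature to compare against 25 degC.
#' @return two-sided p-value.
#' @export
wilcoxonVsControl <- function(rec, population, variable, temperature) {
  stopifnot(variable %in% c("hsp70_rel", "tubule_score", "digestive_score",
                            "calcium_score"))
  sub <- rec[rec$population_id == population, ]
  x <- sub[[variable]][sub$temperature == temperature]
  y <- sub[[variable]][sub$temperature == 25]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("empty group in rank-sum comparison")
  rankSumTest(x, y)
}

#' Rank-sum test on two raw samples
#'
#' `method = "auto"` (default) enumerates the exact permutation null of the
#' midrank statistic when both samples have at most 10 observations (ties
#' are handled correctly by the enumeration), and otherwise uses the
#' tie-corrected normal approximation with continuity correction;
#' `"exact"`/`"approx"` force one path.
#'
#' @param x,y numeric samples.
#' @param method `"auto"`, `"exact"` or `"approx"`.
#' @return two-sided p-value (see [wilcoxonVsControl()] for the policy).
#' @export
rankSumTest <- function(x, y, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all pooled observations identical; p = 1")
    return(1)
  }
  if (method == "auto")
    method <- if (length(x) <= 10L && length(y) <= 10L) "exact" else "approx"
  if (method == "exact") {
    r <- rank(pooled)
    n1 <- length(x); N <- length(pooled)
    mu <- n1 * (N + 1) / 2
    obs <- abs(sum(r[seq_len(n1)]) - mu)
    sums <- utils::combn(N, n1, function(i) sum(r[i]))
    mean(abs(sums - mu) >= obs - 1e-9)
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
}

#' Bonferroni-corrected significance tier
#'
#' Maps a p-value to star tiers under a Bonferroni correction for `m`
#' comparisons, using half-open intervals: `ns` for p above the 0.05/m
#' cutoff; `*` down to the 0.01/m cutoff; `**` down to the 0.001/m cutoff;
#' `***` at or below it. Cutoffs are reported the way such tiers are
#' conventionally printed: the exact quotient where the division terminates
#' within five decimals (m = 4: 0.0125/0.0025/0.00025), otherwise rounded
#' to two significant digits (m = 6: 0.0083/0.0017/0.00017), and the
#' comparison is inclusive against the printed cutoff.
#'
#' @param p p-value in [0, 1].
#' @param m number of comparisons (>= 1).
#' @return one of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @examples
#' bonferroniTier(0.01, 4)  # "*"
#' @export
bonferroniTier <- function(p, m) {
  stopifnot(p >= 0, p <= 1, m >= 1)
  thr <- bonferroniThresholds(m)
  if (p <= thr[["***"]]) "***"
  else if (p <= thr[["**"]]) "**"
  else if (p <= thr[["*"]]) "*"
  else "ns"
}

#' @describeIn bonferroniTier the printed tier cutoffs for m comparisons
#' @export
bonferroniThresholds <- function(m) {
  q <- c(`*` = 0.05, `**` = 0.01, `***` = 0.001) / m
  vapply(q, function(v) {
    if (abs(v - round(v, 5)) < 1e-12) round(v, 5) else signif(v, 2)
  }, numeric(1))
}

#' One-way ANOVA with Tukey-Kramer letters across populations
#'
#' For one variable at a single exposure temperature: one-way ANOVA across
#' populations, Tukey-Kramer HSD pairwise comparisons (studentized-range
#' based, with the unequal-n correction), and a compact letter display in
#' which groups sharing a letter are not significantly different at `alpha`.
#' Letters are assigned by the insert-and-absorb algorithm over the
#' significant pairs, with groups ordered by decreasing mean.
#'
#' @param rec physiology record data.frame.
#' @param temperature exposure temperature selecting the records.
#' @param variable response column name.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list with `F`, `df` (c(between, within)), `p`, `pairwise`
#'   (symmetric matrix of Tukey-Kramer p-values) and `letters` (named
#'   character vector).
#' @export
anovaTukey <- function(rec, temperature, variable, alpha = 0.05) {
  sub <- rec[rec$temperature == temperature & !is.na(rec[[variable]]), ]
  groups <- split(sub[[variable]], sub$population_id)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) < 2L)
    stop("need at least 2 groups with at least 2 observations")
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(names(groups), lengths(groups))))
  fit <- stats::aov(y ~ g, data = df)
  at <- stats::anova(fit)
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  k <- length(groups)
  pm <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  for (r in rownames(tuk)) {
    ab <- strsplit(r, "-", fixed = TRUE)[[1]]
    pm[ab[1L], ab[2L]] <- pm[ab[2L], ab[1L]] <- tuk[r, "p adj"]
  }
  letters <- .letterDisplay(pm, vapply(groups, mean, numeric(1)), alpha)
  list(F = at$`F value`[1L], df = at$Df, p = at$`Pr(>F)`[1L],
       pairwise = pm, letters = letters)
}

# insert-and-absorb compact letter display
.letterDisplay <- function(pm, means, alpha) {
  ids <- names(means)[order(-means)]
  sets <- list(ids)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      if (pm[ids[i], ids[j]] > alpha) next
      newSets <- list()
      for (s in sets) {
        if (all(c(ids[i], ids[j]) %in% s)) {
          newSets <- c(newSets, list(setdiff(s, ids[i])),
                       list(setdiff(s, ids[j])))
        } else {
          newSets <- c(newSets, list(s))
        }
      }
      # absorb sets contained in another set
      keep <- rep(TRUE, length(newSets))
      for (a in seq_along(newSets)) {
        for (b in seq_along(newSets)) {
          if (a == b || !keep[a]) next
          if (all(newSets[[a]] %in% newSets[[b]]) &&
              (length(newSets[[a]]) < length(newSets[[b]]) || a > b))
            keep[a] <- FALSE
        }
      }
      sets <- unique(newSets[keep])
    }
  }
  out <- stats::setNames(rep("", length(ids)), ids)
  for (s in seq_along(sets))
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  out[names(means)]
}

#' Per-population, per-temperature physiology summary
#'
#' @param rec physiology record data.frame.
#' @return data.frame with one row per population x temperature: MAV mean
#'   +/- SD per tissue, Hsp70 mean +/- SD, percent of control and the
#'   digestive/calcium integrity ratio (NA where a cell has no data).
#' @export
populationSummary <- function(rec) {
  cells <- unique(rec[, c("population_id", "temperature")])
  cells <- cells[order(cells$population_id, cells$temperature), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    p <- cells$population_id[i]; tt <- cells$temperature[i]
    sub <- rec[rec$population_id == p & rec$temperature == tt, ]
    mav <- lapply(c("tubule", "digestive", "calcium"), function(ts) {
      tryCatch(meanAssessmentValue(rec, p, tt, ts),
               error = function(e) list(mean = NA_real_, sd = NA_real_, n = 0L))
    })
    hs <- sub$hsp70_rel[!is.na(sub$hsp70_rel)]
    pct <- tryCatch(hsp70PercentOfControl(rec, p)[as.character(tt)],
                    error = function(e) NA_real_)
    data.frame(population_id = p, temperature = tt,
               mav_tubule = mav[[1L]]$mean, mav_tubule_sd = mav[[1L]]$sd,
               mav_digestive = mav[[2L]]$mean, mav_digestive_sd = mav[[2L]]$sd,
               mav_calcium = mav[[3L]]$mean, mav_calcium_sd = mav[[3L]]$sd,
               hsp70_mean = if (length(hs)) mean(hs) else NA_real_,
               hsp70_sd = if (length(hs) > 1L) stats::sd(hs) else NA_real_,
               hsp70_percent_of_control = unname(pct),
               integrity_ratio = if (!is.na(mav[[2L]]$mean) &&
                                     !is.na(mav[[3L]]$mean))
                 mav[[2L]]$mean / mav[[3L]]$mean else NA_real_)
  })
  do.call(rbind, rows)
}

#' Per-population response matrix at one temperature
#'
#' Assembles the multivariate physiological response used by [fitMrt()]:
#' mean Hsp70 level and the three tissue MAVs per population at a single
#' exposure temperature.
#'
#' @param rec physiology record data.frame.
#' @param temperature exposure temperature.
#' @return numeric matrix, populations x c(hsp70_mean, mav_tubule,
#'   mav_digestive, mav_calcium).
#' @export
buildResponseMatrix <- function(rec, temperature) {
  sm <- populationSummary(rec)
  sm <- sm[sm$temperature == temperature, ]
  if (nrow(sm) == 0L)
    stop("no records at ", temperature, " degrees C")
  out <- as.matrix(sm[, c("hsp70_mean", "mav_tubule", "mav_digestive",
                          "mav_calcium")])
  rownames(out) <- sm$population_id
  if (any(is.na(out)))
    stop("missing response cells at ", temperature, " degrees C")
  out
}
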