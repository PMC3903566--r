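---
title: "Methods: linking haplotype structure to heat-stress physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking haplotype structure to heat-stress physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermopop)
```

## The question and the data model

Mediterranean land snails such as *Xeropicta derbentina* survive hot, dry
habitats through a mix of behavioural, cellular and biochemical defences.
`thermopop` implements an analysis that asks whether the *population
genetic structure* of such snails — summarised from an alignment of
mitochondrial COI sequences — explains between-population differences in
two heat-stress biomarkers measured after controlled exposure to elevated
temperatures:

* the relative Hsp70 level (optical volume against an internal standard,
  expressed as percent of the 25 °C control group), and
* semi-quantitative histopathology scores of the hepatopancreas on a 1–5
  scale (1 = control status, 3 = status of reaction, 5 = destruction) for
  three tissues: tubules, digestive cells and calcium cells.

The genetic side consumes an `AlignedSeqSet` (equal-length, pre-aligned
sequences with population labels); the physiological side consumes a tidy
table of individual records (population, exposure temperature, Hsp70
level, three tissue scores). Everything downstream is derived from these
two inputs.

## Genetic summaries

**Haplotypes.** Individuals sharing an identical sequence share a
haplotype. The default `strict` policy treats `N` as a fifth symbol, so
collapsing is a deterministic partition into exact equivalence classes;
the opt-in `match_N` policy lets an `N` match any base and assigns each
individual to the first compatible haplotype in input order. We default to
determinism because chromatogram-consensus `N`s are rare and the
permissive rule is order-dependent by construction.

**K2P distances.** Pairwise distances use the Kimura 2-parameter model,
\[
d = -\tfrac12\,\log(1 - 2P - Q) - \tfrac14\,\log(1 - 2Q),
\]
with transition proportion \(P\) and transversion proportion \(Q\)
computed over the sites where both sequences carry an unambiguous base
(*pairwise* deletion; gaps are treated like `N`). Pairwise deletion keeps
the maximum number of comparable sites per pair at this data scale; the
choice is stated here because published tables rarely say which deletion
rule produced them. If \(1-2P-Q \le 0\) or \(1-2Q \le 0\) the distance is
undefined and the package raises an error naming the offending pair rather
than clamping — intraspecific COI data sit far from that boundary.

**Nucleotide diversity.** \(\pi\) is the mean K2P distance over all
\(n(n-1)/2\) pairs within a population. The reported SD is, by default,
the square root of the Nei (1987) total variance
\[
V(\pi) = \frac{n+1}{3(n-1)L}\,\pi + \frac{2(n^2+n+3)}{9n(n-1)}\,\pi^2,
\]
the estimator used by the standard population-genetics packages that print
"π ± SD"; a plain sample SD of the pairwise distances is available via
`sdEstimator = "sample"`. The point estimate is the quantity the rest of
the pipeline consumes; the SD is descriptive only.

**Between-population divergence.** Two indices are computed from the
populations × haplotypes count matrix:

* Nei's pairwise fixation index in its pooled-frequency \(G_{ST}\) form,
  \(F_{ST} = (H_T - H_S)/H_T\) with \(H_S\) the mean within-population
  heterozygosity and \(H_T\) the heterozygosity of the pooled (averaged)
  frequencies, defined as 0 when \(H_T = 0\). No sample-size bias
  correction is applied; the estimator is non-negative by concavity, so no
  clamping is needed.
* Morisita–Horn divergence, \(1 - C_{MH}\), treating haplotypes as
  species. It is abundance-weighted, equals 0 for proportional
  compositions and 1 for disjoint ones, and is invariant to scaling either
  count vector.

Report tables print π to 4 decimals, \(F_{ST}\) to 3 and \(H_{MH}\) to 2,
in the conventional combined layout (π on the diagonal, \(H_{MH}\) above,
\(F_{ST}\) below).

## The statistical parsimony network

The cryptic-lineage screen connects haplotypes by single mutational steps
up to a *connection limit*: the largest number of steps \(j\) whose
probability of being homoplasy-free is at least the confidence level
(default 0.95). Because the classical software for this analysis does not
document every numerical detail, the probability model is pinned
explicitly here: mutations hit sites uniformly at random, a mutation at an
already-differing site reverts it with probability 1/3 (a Jukes–Cantor
single-parameter alphabet), the number of mutations separating a pair with
\(j\) observed differences over \(m\) sites carries a Poisson prior whose
mean is the Jukes–Cantor-corrected expected mutation count, and the
probability of parsimony is the posterior probability that the mutation
count equals \(j\). `parsimonyProbability()` exposes the recursion;
`parsimonyConnectionLimit(700)` evaluates to `r parsimonyConnectionLimit(700)`
steps at 95%. An integer override is available wherever the limit is
consumed, so results from other implementations can be mimicked exactly.
Two consequences of the pinned model are worth knowing: the probability is
strictly decreasing in \(j\), and the divergence correction saturates at
75% observed differences, so even a vanishing confidence cannot admit
connections beyond that boundary.

Network construction is agglomerative: candidate pairs are processed in
order of increasing mutational distance \(d = 1, 2, \ldots\), ties broken
by haplotype id; a join at distance \(d\) inserts \(d-1\) inferred
intermediate nodes along one shortest mutational path, with sites mutated
left-to-right along the alignment — an arbitrary but fixed choice among
equally parsimonious paths. Clusters are never joined beyond the limit,
and the connected components over observed haplotypes are the screen's
answer: one component means no evidence of cryptic lineages.

## Ordination of divergence matrices

Between-population indices cannot explain within-population responses
directly, so each divergence matrix is converted to per-population
coordinates by classical scaling (PCoA): Gower double-centering of the
squared dissimilarities, eigendecomposition, and scaling of eigenvectors
by the square roots of their eigenvalues. Three axes are kept for
\(H_{MH}\) and two for \(F_{ST}\) — exactly the explanatory variables the
tree analysis uses — both configurable. Divergence matrices of this kind
are generally non-Euclidean; negative eigenvalues are dropped with a
warning (no Cailliez-type correction is applied, and missing positive
axes are zero-padded). Axis signs are fixed by forcing each axis's
largest-magnitude loading positive so that runs are bit-reproducible.

## Physiology summaries and tests

Per population × temperature cell the package reports the mean assessment
value (MAV, mean ± sample SD of the 1–5 scores), the Hsp70 mean and its
percent of the 25 °C control, the maximum induction (argmax over
non-control temperatures, ties resolved to the lower temperature), and
the digestive/calcium integrity ratio (values below 1 mean digestive
cells in better condition).

Treatment-vs-control comparisons use the two-sample rank-sum test. The 1–5
scores tie heavily, so for small groups (both \(n \le 10\)) the package
enumerates the exact permutation distribution of the midrank statistic;
beyond that it uses the tie-corrected normal approximation with continuity
correction. The exact path is the default in the regime this study
operates in (\(n\) of 8–10 per cell) because the normal approximation on
such coarse lattices can deviate from the permutation p-value by a few
hundredths. Significance tiers follow a Bonferroni correction with
half-open intervals against the conventionally printed cutoffs: exact
quotients where the division terminates (m = 4: 0.0125/0.0025/0.00025),
two significant digits where it repeats (m = 6: 0.0083/0.0017/0.00017),
inclusive at the boundary. m = 4 corresponds to the four
histologically-scored treatment temperatures, m = 6 to the six Hsp70
treatment temperatures.

Between-population comparisons at one temperature use one-way ANOVA with
Tukey–Kramer HSD (studentized-range based, unequal-n correction) and a
compact letter display assigned by insert-and-absorb: groups sharing a
letter are not significantly different at 0.05.

## Multivariate regression trees

The central analysis fits, separately for each exposure temperature with
full histology (default 25, 33, 40, 48 °C), a multivariate regression
tree: the response matrix holds the per-population mean Hsp70 level and
three MAVs; the explanatory table holds π and the PCoA axes
\(H_{MH}1..3\), \(F_{ST}1..2\). Response columns are standardized to zero
mean and unit variance by default because percent-scale Hsp70 and 1–5
scores are incommensurate; a raw-scale flag exists and both modes are
legitimate reads of the analysis.

Splits are thresholds at midpoints between consecutive sorted unique
values of an explanatory variable, chosen to maximise the reduction in
total within-node sum of squared Euclidean distances; ties go to the
lowest variable index, then the lowest split value. Growth is best-first
(the leaf with the largest achievable reduction splits next), which makes
the nested size sequence explicit for cross-validation. `minNodeSize`
(default 2) is the minimum size of a node *to be split* — CART's
`minsplit` — so a single divergent population can be isolated by the
primary split; `maxDepth` defaults to 3. With seven populations these are
the only sensible values.

Tree size is selected by cross-validation. The conventional prescription
of 10 folds with many repetitions collapses at \(n = 7\): folds are
clamped to \(n\), giving leave-one-out, which is deterministic, so the
repetitions reduce to one (a message says so). The CV relative error of a
size is the total held-out squared error divided by the total response sum
of squares; size is chosen by the minimum-CV rule by default, with a 1-SE
option. LOO errors at \(n = 7\) are intrinsically large (the root-only
tree already has a relative error of \((7/6)^2 \approx 1.36\)); this is a
property of the design size, not a defect of the fit.

Reported per tree: the first-split \(R^2\)
(\((SS_{root} - SS_{left} - SS_{right})/SS_{root}\)), the selected size
and its CV error, the leaf topology in Newick form (well-formed, with
outer parentheses and semicolon; a "paper-style" string without them is
also emitted for compact tables; sibling order is low-side first), and
the Pearson correlation sign of the primary split variable with each
response across populations — `+`/`-` for Hsp70 and `i`
(improved: negative correlation with damage scores) or `d` (deteriorated)
for each MAV, with an `undefined` flag for zero-variance inputs.

## The synthetic study and its planted truth

Raw individual measurements for studies of this design are typically not
deposited, so the package ships a generator that emulates the statistical
structure the analysis assumes and records the planted truth for testing:

* **Sequences.** A random 700-site reference; 6 haplotypes, each a single
  mutational step from a hub haplotype at a distinct column (so the
  parsimony network is connected by construction and > 99% of columns are
  shared); global haplotype frequencies (0.66, 0.19, rest split equally);
  per-population counts drawn Dirichlet-multinomial (concentration 60)
  around the global profile, 7 populations × 20 sequences. Population 7
  is monomorphic for the hub (π = 0 downstream); population 4 receives a
  shifted profile with most mass on an otherwise-rare haplotype, making it
  the most divergent population in both indices. Any haplotype that
  multinomial sampling drops entirely is re-seated with one copy so the
  planted count of distinct haplotypes is always observed. Frequencies are
  jittered rather than coalescent-simulated because the analysis consumes
  only haplotype counts; a frequency-level model is the minimal sufficient
  emulation.
* **Physiology.** Each population follows one of three archetypal
  strategies: *moderate* induction (populations 1, 2, 5; peak ≈ 135% of
  control at 40 °C), *high* induction (3, 6, 7; peak ≈ 175%), and *flat*
  (4; ≤ ≈ 104%, peaking at 38 °C), all declining at ≥ 43 °C. Individual
  Hsp70 levels are Gaussian around the strategy mean (SD 0.12 relative
  units, truncated at zero by redraw), n = 10 per cell. Histology scores
  discretise a latent logistic damage curve
  \(1 + 4\,\mathrm{plogis}((T - t_{50})/w)\) with Gaussian noise (SD 0.7)
  clamped to 1–5, n = 8 per cell; t50/width are anchored so controls sit
  near category 1, most populations reach the status of reaction
  (≈ 2.5–3.5) at 40 °C and destruction (≈ 4–5) at 48 °C, while the flat
  strategy holds good condition to 40 °C and collapses sharply above
  (t50 = 43, width = 1.2). Digestive cells are the most heat-sensitive
  tissue (t50 − 2) and calcium cells the most resistant (t50 + 2).

What the generator does *not* emulate: realistic sequence evolution
(recurrent/parallel mutation, rate heterogeneity), within-individual
replicates, blot-level measurement structure, and any correlation between
an individual's genotype and its physiology — strategies are assigned at
the population level. Passing tests therefore demonstrate that the
pipeline recovers population-level planted structure at realistic effect
sizes and sample sizes; they do not validate the biological claim on real
data.

## Problem sizes, tolerances and degenerate inputs

The test suite exercises oracle equivalence (closed-form loops, exhaustive
split enumeration, exact permutation, classical-scaling and K2P
references) on randomized instances of up to 8 units, and parameter
recovery on 100 synthetic seeds at the default study shape
(7 × 20 sequences, 700 sites; 7 × 7 physiology cells). Numerical
comparisons use tolerances of 1e-8–1e-12 for algebraic identities. Matrix
validity checks use 1e-12 for symmetry/diagonal; PCoA treats eigenvalues
above `1e-8 × max|eigenvalue|` as positive. Degenerate inputs are
surfaced, not silently repaired: undefined π for n < 2, saturated K2P
pairs, empty summary cells, all-identical rank-sum pools (p = 1 with a
warning), constant responses (root-only tree), and zero-variance
correlation inputs (`undefined` sign).

## Known limitations

* The parsimony-probability recursion is a pinned model in the
  Templeton–Crandall–Sing tradition, not a byte-level reimplementation of
  any particular legacy program; use the integer limit override for exact
  mimicry of other software.
* \(F_{ST}\) uses pooled-frequency \(G_{ST}\) without bias correction;
  estimators with sample-size corrections will differ, particularly at
  n = 20 haplotypes per population.
* At seven populations, cross-validated size selection is leave-one-out
  and noisy by nature; topologies beyond the primary split should be read
  qualitatively.
* The combined report's ±SD column depends on the chosen variance
  estimator; the point estimates are the comparable quantities.
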