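---
title: "Multivariate screening of pooled preclinical trials: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate screening of pooled preclinical trials: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scimint)
```

# The problem

A CNS injury such as a cervical spinal cord contusion produces a *syndrome*:
correlated deficits across behavioral assays (paw preference, grooming range
of motion, fine forelimb function) and histological measures (tissue sparing,
lesion area, white-matter sparing, motor-neuron counts). A therapy that is
genuinely effective tends to move many of these endpoints together, while any
single pre-declared endpoint may miss the effect. scimint implements a
screening workflow for this situation: map the multivariate outcome space of
a pooled, multi-arm trial collection with a topological graph; extract
syndromic axes with PCA over the outcome correlation matrix; test for
dose-structured treatment effects on those axes; and, on the transcriptomic
side, find co-expression modules and individual genes whose injury response
is *reversed* by treatment.

Everything is exercised end to end on seeded synthetic data with known
ground truth, because the analytic machinery — not any one dataset — is the
deliverable.

# Topology over subjects (Mapper with bootstrap consensus)

`build_mapper_graph()` implements the canonical Mapper construction:

1. **Standardize** the outcome battery (`standardize_outcomes()`): each
   column to mean 0, sample SD 1 over its non-missing entries; constant
   columns dropped with a warning; remaining missing entries mean-imputed
   (0 after standardization) so every subject appears in the topology.
   Mean imputation, rather than listwise deletion, was chosen so that the
   pooled cohort — where different trials measured different batteries —
   retains all subjects.
2. **Lens**: by default the projection onto the first two principal axes of
   the standardized matrix; alternatively any one or two named columns.
3. **Cover**: each lens axis's range is split into `resolution` equal base
   intervals of width $w$, each expanded symmetrically to width
   $w(1+\mathrm{gain})$; bins in two dimensions are Cartesian products. With
   gain 0 the bins partition the range; with gain $> 0$ adjacent bins share
   points, which is what creates edges.
4. **Within-bin clustering**: single linkage on pairwise distances
   (Euclidean by default), cut at the classic first-gap heuristic — the
   lower edge of the first empty bin of the pairwise-distance histogram
   (10 bins by default). Singleton bins yield singleton nodes.
5. **Nerve**: one node per within-bin cluster; an edge wherever two nodes
   share a subject. Node ids are assigned deterministically by
   (bin, cluster), so the construction is reproducible and
   permutation-invariant up to isomorphism.

`bootstrap_consensus()` stabilizes the graph by resampling subjects with
replacement, rebuilding the graph per replicate, and recording for each
subject pair the fraction of replicates — among those in which both were
drawn — where they shared a node. Pairs never jointly drawn are reported as
missing, not zero. The consensus graph keeps a full-data edge only when the
mean co-occurrence across the edge's member pairs reaches
`consensus_threshold` (default 0.5 over 30 replicates). `overlay()`
summarizes any variable per node (mean over members) or any group label as
a membership percentage in $[0, 100]$.

The commercial TDA platforms used for this style of analysis do not disclose
their lens or clustering internals; the parameters here (metric, lens,
resolution, gain) are therefore explicit configuration, and no particular
setting is claimed to reproduce any published figure.

# Syndromic PCA and dose-response contrasts

`correlation_pca()` eigendecomposes the Pearson correlation matrix of all
outcomes (pairwise-complete by default, since pooled trials have unequal
batteries; if the pairwise estimate is not positive semidefinite it falls
back to complete cases with a warning). Loadings are reported on the
correlation scale (eigenvector $\times \sqrt{\lambda}$), so a loading is the
correlation between a variable and a component, and component $c$ explains
$\lambda_c / p$ of the total variance. Each eigenvector is oriented so its
largest-magnitude loading is positive.

`retain_components()` applies three conjunctive rules, each audited per
component:

* **Kaiser**: eigenvalue $> 1$;
* **Scree**: the elbow is operationalized numerically as the maximum of the
  second difference (acceleration) of the eigenvalue sequence, restricted to
  components whose eigenvalue lies below the mean eigenvalue (the scree
  "floor"; the mean is exactly 1 for a correlation matrix). Components
  strictly before the elbow pass. The restriction to the floor keeps the
  elbow at the start of the flat tail rather than at the (always convex)
  drop after the first component, which matches what a reader of a scree
  plot actually does;
* **Over-determination**: at least 3 loadings above 0.4 in absolute value.

`score_subjects()` projects standardized (mean-imputed) outcome rows onto
the retained eigenvectors and rescales each score column to unit variance,
i.e. subject z-scores along each syndromic axis.

`test_dose_response()` runs a one-way ANOVA over ordered dose groups and
then orthogonal polynomial contrasts built on the dose values (equally
spaced codes when no numeric doses are given; coefficients from
`stats::contr.poly`, unit-normalized and mutually orthogonal). Each
contrast is tested with

$$t = \frac{\sum_k c_k \bar y_k}{\sqrt{\mathrm{MSE}\sum_k c_k^2/n_k}}$$

on the ANOVA residual degrees of freedom; with unequal group sizes the
variance uses $\sum c_k^2 / n_k$ without reweighting the coefficients
(standard GLM contrast practice). An *inverted-U* dose response — efficacy
peaking at an intermediate dose — is flagged when the quadratic estimate is
negative and its p-value is below 0.05. Whether doses are coded numerically
or ordinally is left to the caller; the package's own drivers use ordinal
level codes.

# Co-expression modules

The four-step procedure in `detect_modules()` / `merge_modules()`:

1. **bicor**: all pairwise biweight midcorrelations between genes, with
   Tukey biweight weights around medians, tuning constant 9, and unscaled
   MAD. Rows with zero MAD fall back to Pearson (mean-centered, unit
   weights) with a warning; this also makes `bicor` exactly Pearson in the
   degenerate all-weights-one case.
2. **Clustering**: complete linkage on $D = 1 - \mathrm{bicor}$ (signed by
   default; an unsigned option uses $1 - |\mathrm{bicor}|$).
3. **Static cut**: the dendrogram is cut at the height equal to the 0.10
   quantile of the off-diagonal distances, i.e. only the strongest decile
   of pairwise correlations falls below the cut. This is an interpretation:
   "the top decile of correlations" is mapped to a distance quantile, since
   correlations do not otherwise define a dendrogram height.
4. **Eigengenes and merging**: each cluster is summarized by its eigengene —
   the first right-singular vector of the gene-standardized submatrix,
   unit-variance, oriented so its mean correlation with member genes is
   positive (sign stability matters for merging; orientation is otherwise
   arbitrary). While any two eigengenes correlate (Pearson) above 0.85, the
   highest-correlated pair is merged, its eigengene recomputed, and all
   pairs re-tested; the merge log records every step. The fixed point
   guarantees no post-merge eigengene pair exceeds the threshold.

**Fragment rescue.** With few samples the static cut necessarily fragments
coherent modules: the complete-linkage height at which a module becomes one
cluster is its *diameter*, $1 - \min_{ij} \hat r_{ij}$, and with $n$ samples
the sampling noise of $\hat r$ puts that diameter far above the top-decile
cut even for strongly coherent modules. Merging is the procedure's own
mechanism for reassembling such fragments, so by default
(`network_params(rescue_fragments = TRUE)`) clusters below
`min_module_size` (12) participate in the merge iteration as provisional
fragments, and the minimum-size rule is enforced after merging; fragments
that never reach the minimum size stay unassigned. Setting the flag to
`FALSE` restricts merging to full-size modules.

Even with rescue, exact recovery of planted modules at the package's
default scale (15 samples, intra-module correlation 0.7) is only partial:
fragment eigengenes of the same module correlate near — and often just
below — the 0.85 merge threshold, because the dendrogram splits modules
along their selectively weakest links. This is a property of the procedure
at small sample sizes, not of the implementation (each step is tested
against independent brute-force oracles); users with ~15 samples should
expect conservative, high-purity modules whose recall improves with sample
size, and should read kME (computed for *all* genes against every module
eigengene) alongside the hard assignment.

`flag_outlier_samples()` screens samples before network construction:
standardized mean inter-sample correlation (connectivity) below $-2$ flags
a sample, iteratively re-checked after each removal, aborting if more than
half the samples would be removed. `module_trait_test()` runs a one-way
ANOVA of each eigengene over the ordered reference / vehicle / treated
groups with Tukey post-hocs, and flags a *reversion* when the omnibus test
is significant, vehicle differs from reference, and the treated mean lies
strictly between the vehicle and reference means.

Soft thresholding, topological overlap, and signed-network machinery are
deliberately absent: the implemented procedure uses none of them. Batch
correction is likewise out of scope — the matrix is accepted as already
corrected.

# Differential expression and reversal

`normalize_counts()` produces $\log_2(\mathrm{CPM} + 1)$.
`differential_expression()` applies a per-gene Welch t-test with
Benjamini-Hochberg adjustment; significance means adjusted $p < 0.05$. A
deliberately transparent test was chosen over a negative-binomial model so
the downstream reversal logic stays oracle-checkable; the DE table is a
plain data frame, so any other per-gene test can be substituted upstream.
For genes significantly altered in vehicle vs reference,
`classify_reversal()` assigns:

* **full** — the treated-vs-vehicle change opposes the injury change in
  sign and treated no longer differs significantly from reference;
* **partial** — the sign opposes but treated still differs from reference;
* **none** — otherwise. Genes not significantly altered by injury carry no
  reversal class.

`geneset_enrichment()` is a generic one-sided hypergeometric
over-representation test over user-supplied sets (GMT input supported),
BH-adjusted across sets — a deliberately annotation-free stand-in for
ontology enrichment.

# The synthetic study

`simulate_trial()` emulates a pooled five-arm preclinical collection
(default 159 subjects: a dose-ranging arm with five dose levels plus four
single-dose comparator arms, allocated evenly over (arm, dose) cells; the
published pooled datasets this emulates do not report per-arm sizes or dose
levels, so these defaults are explicit placeholders). Injury severity is
uniform on 50-100 (a tissue-deformation-like scale); a latent lesion factor
tracks severity, a latent recovery factor is anti-correlated with lesion
load, and the two factors drive the histological and behavioral batteries
respectively (loadings 0.8, residual SD 0.6), producing one correlated
syndromic space. The treated arm adds an inverted-U shaped mean shift
(0, 1.0, 1.8, 1.0, 0.25 SD units across the five dose levels) to the
behavioral outcomes only — a strong but realistic effect for a therapy
detected as "robust recovery". Outcome entries are masked missing completely
at random (default 5%); no informative missingness mechanism is modeled.
Behavioral outcomes are generated on continuous scales; an optional flag
discretizes two of them to ordinal ranges (0-5, 0-9), off by default so
closed-form oracles stay exact.

`simulate_expression()` emulates a 3-group x 5-sample RNA-seq comparison:
per-gene log2 baselines $\sim N(4, 1.5^2)$, 10 planted 50-gene modules
driven by shared latent factors scaled to a target intra-module correlation
of 0.7, 300 injury genes shifted by 3 log2 units (8-fold — squarely in the
range of acute inflammatory inductions; coordinated gene programs carry
correlated noise, so a materially smaller shift would leave module-member
genes at the edge of detectability at $n = 5$) in both lesioned groups, and
225 reversal genes whose treated-group shift is reduced by 80%. Two modules
are designated injury-responsive; their genes shift coherently (one up, one
down) and their residual coordination factor is halved, since response
modules cohere mainly through the response they share. Counts are Poisson
observations of the log-normal latent signal with log-normal library-size
factors (mean 2 million counts over the 2000-gene transcriptome), which
reproduces overdispersion qualitatively without committing to a particular
DE model.

What the generators do **not** emulate: longitudinal behavior curves,
informative missingness, batch structure, count-level biological
overdispersion beyond the latent log-normal, gene-length effects, and any
real annotation. Passing tests therefore demonstrate the machinery's
correctness and calibration on data with this structure — not performance
on any particular real dataset.

# Numerical choices and degenerate inputs

* Quantiles use R's default type-7 interpolation; the dendrogram cut uses
  strict inequality semantics via `cutree(h)` (a merge exactly at the cut
  height joins).
* The first-gap histogram threshold is applied with a $1 - 10^{-12}$
  relative backoff so distances exactly at the empty bin's lower edge are
  split, not joined.
* An all-identical cohort yields a single Mapper node; a single-member bin
  yields a singleton node; an all-constant matrix is an error at
  standardization.
* ANOVA on all-equal values returns $F = 0$, $p = 1$; zero within-group
  variance with distinct means returns $F = \infty$, $p = 0$; a per-gene
  test with both groups constant and equal means returns $p = 1$ by
  convention.
* Constant genes propagate `NA` kME with a warning; constant rows are
  dropped before eigengene SVD.
* Merging tie-breaks (exactly equal correlations) resolve to the
  lowest-index pair; module labels are re-assigned by decreasing size after
  merging, and the merge log keeps the pre-relabel provisional ids.

# Problem sizes used by the test suite

The packaged checks run the generators at the defaults above (159 subjects;
2000 genes x 15 samples), plus: a 2000-replicate null calibration of the
quadratic contrast (5 groups of 10), a 60-replicate power study of the
inverted-U detection through the full PCA path, 10-seed repetitions of the
topology recovery (two-blob and noisy-circle point clouds of 60-80 points)
and of the 350-gene module-recovery condition, and brute-force oracle
comparisons on instances small enough to enumerate (15-point clusterings,
universes up to 25 for the hypergeometric tail). These sizes were chosen so
the whole suite documents the pipeline's behavior at the scale of the study
design it emulates.

# Known limitations

* Module recall at 15 samples is intrinsically partial (see above); module
  *count* and *purity* are reliable, exact membership is not.
* The scree elbow is a numeric proxy for a visual judgment; on eigenvalue
  sequences without a clear floor it falls back to admitting everything
  before the last interior component, and the Kaiser and over-determination
  rules then dominate.
* Repeated-measures designs are reduced to per-subject summaries before
  entering the outcome battery; no mixed-effects machinery is provided.
* The bootstrap consensus quantifies stability of co-clustering, not
  statistical significance of topology features.
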