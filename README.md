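# scimint

Multivariate syndromic analysis of pooled preclinical injury trials.

CNS injury produces a *syndrome*: correlated deficits across behavioral and
histological endpoints. A genuinely effective therapy moves many endpoints
at once, and a single pre-declared outcome often misses it. scimint is an R
package for screening pooled, multi-arm preclinical trial collections (and
matched injured-tissue transcriptomes) for such multivariate treatment
effects. It is aimed at preclinical neurotrauma groups who have accumulated
several small trials and want one analytic pass over all of them.

The workflow has four stages, each exposed as plain functions and driven by
the numbered scripts under `analysis/`:

1. **Topology** — a Mapper graph over subjects: standardize the outcome
   battery, project onto a low-dimensional lens (first two principal axes
   by default), cover the lens space with overlapping bins
   (`resolution`, `gain`), single-linkage cluster each bin's members with a
   first-gap histogram heuristic, and link clusters that share subjects.
   Stability comes from a bootstrap consensus: subjects are resampled with
   replacement, co-occurrence of subject pairs in shared nodes is tallied,
   and edges that fail a consensus threshold are dropped. Node overlays
   (means of any variable, or group-membership percentages) make the graph
   readable.
2. **Syndromic PCA** — eigendecomposition of the outcome correlation
   matrix R = V Λ Vᵀ, loadings on the correlation scale (V √Λ), component
   retention by three conjunctive rules (Kaiser λ > 1; a scree-acceleration
   elbow; ≥ 3 loadings > |0.4|), subject z-scores along retained axes, and
   orthogonal polynomial dose–response contrasts
   t = Σcₖȳₖ / √(MSE·Σcₖ²/nₖ). An inverted-U dose response is a significant
   negative quadratic trend.
3. **Co-expression modules** — the four-step procedure: biweight
   midcorrelation (bicor) between all genes; complete-linkage clustering on
   1 − bicor; a static cut at the top decile of pairwise correlations with
   a minimum module size of 12; eigengene summarization (first singular
   vector per module) with iterative merging of any module pair whose
   eigengenes correlate above 0.85; kME (gene–eigengene correlation) for
   every gene; and per-module ANOVA + Tukey tests for treatment *reversion*
   of the injury phenotype.
4. **Differential expression and reversal** — per-gene Welch t on log-CPM
   with Benjamini–Hochberg adjustment; genes altered by injury are
   classified as fully reversed, partially reversed, or not reversed by
   treatment, by sign opposition plus treated-vs-reference significance;
   hypergeometric over-representation of user-supplied gene sets (GMT)
   among the treatment DEGs.

Seeded generators (`simulate_trial()`, `simulate_expression()`) produce a
159-subject five-arm outcome table and a planted-module 2000 × 15 count
matrix with known ground truth, so the whole pipeline is testable without
any external data. The methods vignette
(`vignettes/multivariate-preclinical-screening.Rmd`) documents the models,
parameter choices, and known limitations.

## Worked example

Simulate the pooled trial, extract the first syndromic axis, and test the
dose response within the treated arm:

```r
library(scimint)

trial <- simulate_trial(trial_sim_config(seed = 1))
model <- correlation_pca(trial$data)
model <- retain_components(model)
model <- score_subjects(model, trial$data)

treated <- trial$data$meta$arm == "sTNFR1"
test_dose_response(model$scores[treated, 1], trial$data$meta$dose[treated])
```

```
<dose_response> F(4, 85) = 9.802, p = 1.438e-06; inverted-U: TRUE
     order     estimate        se           t df            p
    linear  0.225769935 0.1968003  1.14720348 85 2.545164e-01
 quadratic -1.211198320 0.1968003 -6.15445511 85 2.391571e-08
     cubic  0.008954585 0.1968003  0.04550088 85 9.638148e-01
    order4 -0.021534423 0.1968003 -0.10942274 85 9.131251e-01
```

The first component (57.8% of total variance here, spanning both behavioral
and histological loadings) shows a highly significant *negative quadratic*
dose trend — efficacy peaks at an intermediate dose, the planted inverted-U.
`model$audit` prints the per-component retention audit behind the choice of
PC1.

The same session's expression arm, via the drivers:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/04_coexpression_modules.R
Rscript analysis/05_de_reversal.R
```

```
<module_set> 16 modules over 2000 genes (1292 unassigned)
5 of 16 modules show a treatment reversion of the injury phenotype: M1, M2, M4, M6, M15
500 genes altered by injury; 334 altered by treatment
456 injury genes reversed by treatment (401 fully, 55 partially)
sensitivity for planted reversal genes: 1.000
top enriched sets among treatment DEGs:
             set set_size overlap expected             p
 injury_response      300     221    50.10 4.832931e-138
```

Module and gene-level reversal point at the planted injury-responsive
programs, and the enrichment table ranks the planted injury set first —
the behavior expected when a treatment truly pushes the injured
transcriptome back toward the uninjured state.

`run_pipeline(pipeline_config(out_dir, seed = 7))` executes every stage and
writes all tables plus a manifest (parameters, seed, MD5 per output);
identical config and seed give byte-identical outputs.

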