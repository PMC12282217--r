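---
title: "Consensus differential abundance for shotgun metagenomic profiles: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus differential abundance: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Differential-abundance (DA) analysis of microbiome profiles is notoriously
tool-dependent: the same table analysed with different well-regarded
methods can yield largely disjoint feature lists, because each method makes
different assumptions about compositionality, zeros, and the count layer.
`condaba` implements a consensus workflow for this setting: six natively
implemented DA engine *families* sharing one interface, a majority-vote
rule across them, and the surrounding machinery — compositional transforms,
diversity analyses, depth-confound controls, and a synthetic cohort
generator with implanted ground truth so that every claim the pipeline
makes can be benchmarked against known signals.

The engines are families, not re-implementations of the packages that
inspired them (MaAsLin2, LinDA, ANCOM-BC2, ALDEx2, DESeq2, ZicoSeq). Each
one keeps the defining mechanism of its family and fixes every remaining
free choice explicitly; the fixed choices are documented here and covered
by oracle tests. Bit-compatibility with the upstream tools is a non-goal.

## Data model

A `feature_table` is a samples-by-features matrix of non-negative
abundances tagged with a unit — `relative_percent` (MetaPhlAn-style, rows
sum to 100), `proportion`, `count`, or `rpk` (HUMAnN-style reads per
kilobase) — and a feature level (kingdom … species, SGB, or pathway).
Sample metadata carries `group` (control/case), `subject_id`, `timepoint`
(early/late), optional `bmi`, and `library_size`, the post-QC read count.

Shotgun profilers report relative abundances, so count-requiring engines
receive *approximate counts*: abundance fraction × library size, rounded
half-to-even (unbiased over many cells). `to_proportions()` after
`to_approximate_counts()` recovers the original fractions to within
1/library_size per cell, and that round trip is tested.

## Shared preprocessing

* **Prevalence filter.** A feature is kept when it exceeds a tiny
  abundance floor (0 for counts, 1e-15 otherwise — the floor exists so
  numerically-zero cells never count as present) in at least
  `ceiling(0.1 × n)` samples. The filter is applied once per level before
  engine dispatch, the sample set never changes, and rows are *not*
  renormalized — filtered relative tables are open compositions, and the
  proportion/count inputs handed to engines are derived from the unfiltered
  table and then subset, so no hidden re-closure occurs.
* **CLR.** `log(x + pseudo)` centred per sample. The pseudo-count lives on
  the table's native scale: 0.0001 on percent-scale taxa and 1 on RPK
  pathways. Each CLR row sums to zero (machine tolerance) and per-sample
  scale multiples map to the same point, which is also why Aitchison
  distances (Euclidean on CLR rows) are scale-invariant.
* **AST.** `asin(sqrt(x))` for proportions, the classical
  variance-stabilizing transform.
* **Rarefaction.** Subsampling without replacement (multivariate
  hypergeometric, via `vegan::rrarefy`) to an even depth before alpha
  diversity; samples below the target depth are dropped with a warning.
  Richness is strongly depth-sensitive — the synthetic cohorts reproduce a
  Spearman depth-richness correlation above 0.5 — so unrarefied richness
  is only used for that diagnostic.

## The six engine families

All engines consume `(feature_table, metadata, design)` and return one row
per feature: `effect`, `p`, `q`, `significant` (q < 0.05), `direction`.
Subject pairing enters as subject fixed effects — the one uniform,
tractable stand-in for random effects across all six families; this
approximation is deliberate.

1. **`lm_ast` (MaAsLin2-style).** OLS per feature on AST proportions
   (method 1) or CLR counts with pseudo-count 0.5 (method 2); two-sided t
   on the group coefficient; BH.
2. **`lm_clr_bias` (LinDA-style).** CLR with a proportion-scale
   pseudo-count, or, for counts, zero cells imputed as half the feature's
   minimum non-zero proportion scaled by the sample's library size. After
   per-feature OLS the median of all raw group effects is subtracted as
   the compositional-bias estimate; the t statistic uses the corrected
   effect with the unchanged standard error; BH.
3. **`loglin_bias` (ANCOM-BC2-style).** `log(count + 1)` modelled with
   per-sample offsets, estimated by alternating per-feature regression
   with offset = mean residual across features (convergence 1e-8, max 100
   iterations). The offset/coefficient pair is only identified up to a
   design-space shift, so the across-feature mean of every coefficient is
   pinned to zero each iteration — the family's "most features are
   non-differential" assumption. The Wald statistic is referred to
   t(n − p): at cohort-scale n the normal reference is measurably
   anti-conservative. Holm–Bonferroni.
4. **`dirichlet_mc` (ALDEx2-style).** Per instance, proportions drawn from
   a Dirichlet(counts + 0.5) posterior (0.5 is the conventional
   uninformative half-count), CLR, plus per-sample log-scale noise with SD
   `gamma = 0.25` to model scale uncertainty; a two-sided Wilcoxon
   rank-sum per feature (exact by enumeration for total n ≤ 8, midrank
   normal approximation with tie correction otherwise); BH within
   instance. Reported p and q are means over instances; the effect is the
   median over instances of the between-group mean difference divided by
   the larger within-group SD. Designs with covariates fall back to
   per-instance OLS on the CLR values.
5. **`negbin_wald` (DESeq2-style).** Negative-binomial GLM per feature
   with log link. Size factors use the positive-counts variant of
   median-of-ratios, normalized to geometric mean one, and enter as
   offsets; doubling one sample's counts doubles its factor *relative to
   the others* exactly (the geometric-mean reference itself shifts by
   2^(1/n)). Dispersions come from within-group method-of-moments, floored
   at 1e-8 and shrunk half-weight toward a log-mean trend; Wald z on the
   group coefficient; BH. Under Poisson data the estimated dispersions
   collapse to the floor.
6. **`ref_perm` (ZicoSeq-style).** Count input becomes posterior-mean
   proportions under the same Dirichlet prior. Stage 1 ranks features by a
   Freedman–Lane residual-permutation F-test on sqrt-proportions and takes
   the lower half of evidence (largest p) as the reference set — the
   "least likely differential" features. Stage 2 tests
   `sqrt(feature / reference-total)` with the same permutation scheme
   (the permutation set is shared across features), and a permutation FDR:
   for each feature, the mean permuted exceedance count of its observed F
   divided by the observed exceedance count, clipped to [0, 1] and
   monotonized in F. The per-feature p is the unbiased exceedance fraction
   rather than the add-one estimate — at n_perm = 199 the add-one version
   carries a systematic +1/(2·n_perm) shift that shows up in pooled null
   checks; significance is governed by q. When n! fits in the permutation
   budget the engine enumerates the full permutation group, so small-n
   p-values are exact (and strictly positive, since the identity is
   included).

"Smith permutation" as named by the family's documentation is not defined
precisely enough to copy; reduced-model residual permutation
(Freedman–Lane) is the documented choice here.

### Input modes (method 1 / method 2)

Three engines accept proportions natively (`lm_ast`, `lm_clr_bias`,
`ref_perm`). Under `input_mode = "proportions"` (method 1) they receive
proportions while the count-only engines receive approximate counts; under
`"counts"` (method 2) all six receive approximate counts, which also
switches the three engines' internal transforms. The audit table records
the unit actually fed to every engine × level, and `compare_methods()`
reports the consensus overlap between the two modes stratified by vote
count.

## Consensus

A feature at one level is a consensus call when at least
`ceiling(threshold × n_engines)` of the engines that successfully ran call
it significant — 3 of 6 at the default 50% threshold, a simple majority.
Levels are voted independently; nothing propagates across levels.
Features called by one or two engines form a separate supplementary tier.
The majority direction is the sign of the sum of significant engines'
directions; when significant engines disagree in sign the feature carries
a `discordant` flag (and a tied direction reports 0) rather than being
suppressed — such conflicts are information, not noise. Direction
agreement is deliberately *not* required for a consensus call; the flag
makes disagreement visible instead. Engines that error on a dataset shrink
the denominator and are logged.

## Diversity and stability

Alpha diversity (Shannon in natural log, richness, Pielou's evenness —
the log base is a convention choice) is computed on rarefied counts only.
Beta diversity uses Aitchison distances; group location is tested by a
native PERMANOVA (pseudo-F from within-group squared-distance sums,
permutation p with the add-one convention so p is never zero) *gated* by a
native permdisp (distances to group centroids in principal-coordinate
space, F under label permutation): location results are reported only when
dispersions are homogeneous at alpha 0.05. Both match their vegan
counterparts (`adonis2`, `betadisper(type = "centroid")`) on the observed
statistics and match exhaustive enumeration exactly for n ≤ 8 via
`exact = TRUE`. Time-point contrasts restrict permutations within subject.

Stability across time points compares matched (same subject, early vs
late) to unmatched cross-subject distances by a two-sided rank-sum test;
all-tied degenerate inputs report p = 1. The per-group version applies a
Shapiro gate (alpha 0.05, both groups) to choose t vs rank-sum and reports
which test ran, since both appear in practice for such comparisons.

One caveat worth stating: group-level PERMANOVA on a cohort with two
samples per subject treats samples as exchangeable, which is
anti-conservative under subject correlation; the simulated null cohorts
make this visible. The time-point test avoids it via strata; the group
test at a single time point avoids it by construction.

## The synthetic cohort generator

The generator is first-class, tested code — it defines the conditions
under which the pipeline's guarantees are demonstrated.

* **Baseline.** Feature log-abundances i.i.d. normal with SD 3, closed to
  proportions: a log-normal rank-abundance curve whose top feature exceeds
  10× the median share, giving realistic dominance and sparsity once the
  multinomial count layer is applied. The profiles' sparsity is chosen for
  qualitative realism; no quantitative sparsity target exists to match.
* **Design.** Default subject structure mirrors the emulated study: 24
  paired + 3 early-only + 1 late-only controls and 9 paired + 2 early-only
  cases, so the bookkeeping (27 early / 25 late control samples) is
  reproduced exactly. The configuration expresses pairing as explicit
  per-group subject counts rather than a single fraction, which a
  symmetric fraction could not represent.
* **Signal.** Group effects are implanted on the log scale *before*
  closure, so compositional spillover onto non-differential features is
  real and intended, exactly as in relative-abundance data. Differential
  features are drawn from the 50th–85th percentile of baseline share —
  detectable but low-abundance, where such differences were observed.
  `implant_signal()` alternatively spikes an existing null table
  post-hoc (multiply counts in the target group, update library sizes).
* **Variance.** Per-subject, per-feature random intercepts (SD 1, shared
  across the subject's time points) over residual log-scale noise (SD
  0.6). A multinomial count layer (not Dirichlet-multinomial) sits on
  top: overdispersion enters through the log-normal abundance noise, which
  keeps biological and sampling variance separable for oracle checks.
* **Depth.** Library sizes are log-normal with mean 375,199 paired reads
  and log-SD 0.63 (matched to the reported post-QC IQR of buccal swabs);
  `depth_group_shift` multiplies case depths to create the depth-group
  confound studied by the depth controls, and defaults to 1 (no
  confound) — the confound is a condition to be switched on, not a
  background assumption.
* **BMI.** Group-dependent BMI distributions (control ≈ N(25.8, 4.5),
  case ≈ N(34.5, 6), truncated at 17, approximating the reported
  medians); `bmi_effect` attaches a log-scale slope to designated
  features for covariate-adjustment benchmarks.

What the generator does *not* emulate: real taxon-taxon correlation
structure, contamination, batch effects, strain-level variation, or the
read-mapping process itself. Passing tests demonstrate statistical
correctness under the stated generative model, not performance on any
particular real dataset.

## Numerical choices and degenerate inputs

* Features constant across samples get effect 0, p 1 rather than an
  error; zero-variance columns are flagged internally.
* Rank tests use exact enumeration (ties included) for total n ≤ 8 and
  midrank normal approximation with tie-corrected variance and continuity
  correction above.
* The log-linear engine refuses single-feature tables (offsets
  unidentifiable); `matched_by_group` refuses single-pair groups; the
  depth test refuses n < 2 per group.
* Permutation p-values in the diversity module use the add-one
  convention; engine permutation p-values are unbiased exceedance
  fractions (see above); exhaustive enumeration replaces sampling whenever
  n! fits the budget.
* Ties in `depth_matched_subset` break deterministically by sample id.
* All randomness flows from one root seed through named substreams
  (`derive_seed`), so any stage can be re-run in isolation and two runs
  with the same seed are byte-identical.

## Calibration properties and known limitations

On pooled null cohorts (50 seeds, 20 samples per group, 200 features,
reduced Monte-Carlo and permutation budgets of 128 and 199), the AST,
bias-corrected CLR, log-linear and reference-permutation engines produce
p-values indistinguishable from uniform by a Kolmogorov–Smirnov test at
alpha 0.01, and the consensus makes at most one call per seed. Two engines
deviate by construction:

* `dirichlet_mc` reports the *expected* p over Monte-Carlo instances.
  An expected p-value under instance noise is compressed toward the
  centre — fewer very small and very large values — so it is mildly
  conservative (pooled fraction below 0.05 ≈ 0.024) and fails a strict
  uniformity test even though its error control is sound. This is a
  property of the family's reporting convention, kept deliberately.
* `negbin_wald` is anti-conservative (pooled fraction below 0.05 ≈ 0.09)
  and makes the most calls of any engine on identical inputs. That is the
  known behaviour of the negative-binomial Wald family on microbiome
  data, and it is the reason consensus voting exists; "fixing" it by
  inflating dispersions would misrepresent the family. The consensus rule
  absorbs it: on implanted-signal cohorts (8-fold on 5 features, 50 per
  group) consensus sensitivity is ≥ 0.8 with observed FDR ≤ 0.1.

Problem sizes in the test-suite and acceptance runs (cohorts of 200–300
features, 20–50 samples per group, `mc_samples = 128`, `n_perm = 199`,
10–50 seeds per property) are the package's chosen demonstration scale;
the engine defaults (`mc_samples = 1000`, `n_perm = 999`) match the
families' conventional settings.

## Clinical summaries

`cohort_summary()` reproduces the standard clinical-table conventions:
continuous variables pass a normality gate (Shapiro–Wilk by default;
strict mode additionally requires Lilliefors, Anderson–Darling and Pearson
chi-square, all passing, mirroring the unanimous-pass convention) and are
shown as mean ± sd with a t-test or median (IQR, linear-interpolation
quartiles) with a rank-sum test; 2×2 categorical tables use the exact
hypergeometric test with an odds ratio, larger tables chi-square.
Percentages print with one decimal, rounded half away from zero, trailing
".0" dropped — so 10/28 prints as 35.7 and 14/28 as 50. The
single-omnibus default gate is a documented simplification of the
four-test unanimity rule; strict mode restores it. The IQR quartile
convention affects only display, never tests.
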