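---
title: "The three-method integration screen: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The three-method integration screen: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryomics)
```

`cryomics` prioritizes molecular candidates from paired gene and protein
abundance matrices of a small two-group design (fresh vs. cryopreserved
semen, typically three biological replicates per group). This vignette is the
package's own account of the statistics it implements, the tunable
parameters, the places where the design was genuinely open and what we chose,
and what the accompanying simulation does and does not demonstrate.

## 1. Differential calling

Both omics are handled identically. For each feature, the fold change is
computed on the raw abundance scale,

$$\mathrm{log_2FC} = \log_2 \frac{\bar{x}_{PS} + \varepsilon}{\bar{x}_{FS} + \varepsilon},$$

so a negative value means loss after freezing. The pseudocount
$\varepsilon$ (default `1e-3`, configurable) bounds the magnitude when a
feature is essentially absent in one group; note the bound depends on
$\varepsilon$ *relative to the abundance scale* — a feature at FPKM ~2500 in
one group and ~0 in the other yields $\approx \log_2(\varepsilon/2500)$,
which is how fold-change magnitudes of ±11 and beyond arise in real
transcript tables.

Significance uses the pooled-variance (Student's) two-sample t-test with
$df = n_1 + n_2 - 2$ on `log2(value + eps)` — testing on the log scale
matches the log-normal abundance model and makes the test statistic
consistent in sign with the fold change. A Welch variant sits behind
`welch = TRUE`. Degenerate rows (zero pooled variance) are flagged rather
than dropped: p = 1 when the means agree, p = 0 when they differ — the
zero-noise limit a simulation can legitimately produce. Multiplicity is
controlled with Benjamini–Hochberg (`stats::p.adjust`); the test suite
verifies it against a brute-force step-up enumeration.

Calling is strict on both gates: `|log2FC| > threshold` **and**
`fdr < alpha`, with defaults 1 (genes), 0.263 (proteins; a 1.2-fold change,
the customary TMT gate given ratio compression) and $\alpha = 0.05$.
Features exactly on a threshold are *not* called; the acceptance suite pins
this boundary behavior.

## 2. Enrichment

Over-representation uses the exact hypergeometric upper tail

$$p = \sum_{i = k}^{\min(K, n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

with the universe taken as the *quantified* features of the omics at hand,
not a full annotation — with shallow quantified spaces (a few thousand genes,
a few hundred proteins) an annotation-wide background would overstate
enrichment. Co-enrichment maps differential proteins to gene ids, takes the
union selection against the union universe, and reports which members each
omics contributed. Its significance gate is the **raw** p < 0.05 (an FDR
column is still emitted): with ten-odd pathway-scale sets the BH correction
is nearly idle, and the screen's downstream consensus step is itself the
false-positive control.

GSEA follows the classic weighted Kolmogorov–Smirnov running sum with
`|score|^weight` hit increments (weight default 1) and $1/(N-K)$ miss
decrements. The null relabels set membership (random same-size sets) rather
than permuting phenotypes: with three samples per group only 20 relabelings
exist, far too few for a permutation p-value. p-values use add-one smoothing
so they are never zero, and NES divides ES by the mean |ES| of same-sign null
draws. Ranking ties break lexicographically by feature id, making results
deterministic at a fixed seed.

## 3. Correlation network

All pathway-enriched differential genes are tested against all
pathway-enriched differential proteins ("pathway-enriched" = member of a set
significant in that omics' own enrichment). Correlation is computed across
all matched samples pooled over groups — the screen deliberately asks which
genes and proteins *travel together across samples*, group response
included, mirroring how phenotype–candidate correlations mix both groups.
Edges require $|\rho| > 0.8$ and p < 0.05 simultaneously; at $n = 6$ the
p-gate is the binding one (it corresponds to $|\rho| > 0.811$), so the null
edge rate is 5%, which the suite confirms by simulation. Edge p-values are
not multiplicity-adjusted by default (`adjust = TRUE` switches the gate to BH
values) — the raw double gate is the convention this screen reproduces.
Zero-variance features are dropped with a log entry, never treated as
$\rho = 0$. Abundances are log2-transformed before correlation, consistent
with the differential module.

## 4. O2PLS

The two blocks (samples × features, centered; unit-variance scaling behind a
flag, off by default since abundances within a block share units) are
decomposed into joint, block-orthogonal, and residual variation. The joint
loadings are the leading singular vectors of the cross-covariance
$X^\top Y$; orthogonal components per block are extracted from the residual
of the joint fit (SVD of $E^\top T$), removed by projecting out their score
subspace, and the joint part is refit on the deflated blocks. This is the
standard estimation route; with `n_orth = 0` the loadings are *exactly* the
cross-covariance SVD, which the test suite uses as an oracle.

Defaults are `n_joint = 1`, `n_orth_x = n_orth_y = 0`: with six samples a
centered block has rank five, and more components are barely identifiable;
the counts are configuration knobs recorded in the model metadata. Loading
signs are fixed deterministically (largest-magnitude element of each column
made positive) so repeated runs and oracles agree. Two numerical notes:
(i) the joint/orthogonal/residual parts are mutually orthogonal *by
construction*, so their $R^2$ sums to 1 exactly, which the suite asserts;
(ii) orthogonal-part scores are uncorrelated with the opposite block's joint
scores only as a population-model property — at $n = 6$ their sample
covariance is not numerically zero, and the suite asserts the exact
within-block orthogonalities instead.

Candidates from this screen are the top `k = 25` features per block ranked
by maximum absolute joint loading (ties lexicographic). The consensus step
keeps features present in **both** blocks' top-25 lists (via the id map) by
default: the candidate the screen is designed to find is one that
contributes to the shared variation on *both* molecular levels. A `union`
mode is available; the choice is recorded in the pipeline parameters.

## 5. Consensus

Set algebra runs in gene-symbol space after case-insensitive normalization
(the two omics often spell the same symbol differently). The Pearson set
includes both endpoints of every significant edge — the screen's candidate
list mixes genes and proteins, and a protein hub is as interesting as a gene
hub. Empty intersections are a valid outcome, reported with a warning, never
an error. Ranking uses (screens supporting, network degree, max |joint
loading|, id) in that order.

## 6. What the simulation emulates — and what it does not

`generate_paired_omics()` draws log-normal abundances: per-feature baselines
uniform on log2 ∈ [3, 10], a planted group effect applied as ±effect/2
around the baseline (down-regulation in the frozen group for the candidate
and its pathway, mixed signs elsewhere with up-fractions matching the
study-scale rates of 45/336 for genes and 30/78 for proteins), a shared
per-sample latent factor on the planted pairs, and i.i.d. Gaussian log2
noise.

Default condition choices, made once:

* **3 vs 3 samples, 500 genes / 300 proteins, 22 / 9 differential** — the
  study's differential rates (≈4.4% of 7,682 genes, ≈3% of 2,631 proteins)
  scaled to desk size.
* **Effects 2.0 / 0.6 log2** — comfortably past the 1 / 0.263 gates, the
  regime the screen targets.
* **`noise_sd_log2 = 0.05`** — chosen by a power calculation: at $n = 3$ the
  protein effect of 0.6 gives $t = 0.6/(\hat\sigma\sqrt{2/3})$, and the BH
  step-up line at $m = 300$ with nine true effects requires roughly
  $p \lesssim 1.5\times10^{-3}$; $\sigma = 0.05$ keeps that power above 99%
  accounting for the $\chi^2_4$ spread of the variance estimate. This is
  realistic for TMT reporter ratios but optimistic for low-input RNA-seq —
  see the limitations below.
* **`latent_rho = 0.95`, 8 planted pairs** — past the 0.811 effective edge
  gate. The latent factor is *centered within each group*, so it never moves
  group means: the zero-noise exactness property (realized effects equal
  planted effects to machine precision) holds by construction. For
  differential pairs the shared group response already induces correlation
  at or above the target at default noise; the extra latent loading is
  solved numerically (`uniroot`) only when the group response alone falls
  short. Consequently, with zero noise the latent term vanishes — a
  fractional target correlation is not representable in noiseless data.
* **Pathway of 20** — 1 candidate + 7 differential genes + 5 differential
  proteins' genes + 7 non-differential fillers, flanked by nine random decoy
  sets, so both single-omics enrichments and the co-enrichment find it while
  decoys behave like the null.
* **Phenotype** — viability and motility are `intercept + 22 × candidate
  log2 abundance + N(0, 1.5)`, intercepts anchoring the fresh group near
  typical fresh-semen values (≈89% viability, ≈83% motility), clamped to
  [0, 100].

Not emulated: sequencing reads or spectra, missing values, TMT ratio
compression, overdispersed count noise, correlated noise between features,
or feature-length/abundance biases. Passing the planted-recovery acceptance
check therefore demonstrates that the *screening logic* is correct and
well-calibrated under a faithful generative model of its assumptions — not
that the screen's error rates transfer to real cryopreservation data, where
noise is heavier-tailed and the latent structure is not a single factor.

## 7. Problem sizes and determinism in the test suite

The suite validates oracles at small sizes where exhaustive enumeration is
exact (hypergeometric tails for all universes up to 12; GSEA running sums on
rankings up to 10; BH on a thousand random vectors against the brute-force
step-up) and the full screen at the default 500 × 300 scale across 50
simulation seeds, where the planted candidate must be the unique triple hit
in at least 90% of runs. Monte-Carlo checks that need concentration (the
planted-pair correlation target) raise the per-group sample count to 50
instead of loosening tolerances. Every stochastic component (generator,
GSEA permutations) flows from one explicit seed, and the pipeline itself is
deterministic, which the suite asserts by exact rerun comparison.

## 8. Known limitations

* With three samples per group the t-test's variance estimate is fragile;
  the package deliberately implements the screen's historical form rather
  than a moderated (empirical-Bayes) test, which would be the modern choice.
* The co-enrichment gate at raw p < 0.05 is liberal; treat the KEGG set as a
  recall-oriented filter whose precision comes from the triple intersection.
* O2PLS component counts are not cross-validated; at $n = 6$ any such
  selection would be unstable, so the defaults are fixed and recorded.
* Pearson edges pool groups, so a strong group effect alone can create
  edges; that is intended behavior for this screen, but users wanting
  within-group co-variation should partial out the group term upstream.
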