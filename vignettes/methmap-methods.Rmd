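---
title: "Models and methods behind methmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`methmap` implements a chain of analyses for DNA methylomes: HMR
segmentation of per-CpG bisulfite calls, a multi-tissue HMR catalog,
confidence-band DMR calling on smoothed profiles, cohort-scale
hypermethylation analysis on beta matrices, and a burden-weighted
permutation test for mutual exclusivity. This vignette records the models,
the tunable parameters, and the design choices made where more than one
reasonable construction existed.

## Coordinates and input formats

Everything internal is 0-based half-open (BED convention). The Bismark
coverage dialect is 1-based inclusive and converted at the boundary; the
bedGraph-with-counts dialect is already 0-based. Neither dialect carries
strand, so CpG positions are taken exactly as given — no dyad collapsing
is attempted. Chromosome names are compared as exact strings; no "chr"
aliasing. Zero-coverage rows are dropped at read time (they carry no
level), duplicate positions are an error, and unsorted input is sorted
with a message. Interval algebra (intersection, gap-closing merge,
overlap flags, k-of-n coverage) is delegated to `IRanges` behind thin
wrappers that keep the half-open convention at the interface.

## HMR segmentation

The segmenter is a two-state first-order HMM over the ordered CpG
sequence. Emissions are beta-binomial: state $k$ has mean $\mu_k$ and
precision $s_k$, and a CpG with $m$ methylated of $n$ reads contributes
$\Pr(m \mid n, \mu_k, s_k) = \binom{n}{m} B(m + \mu_k s_k,\; n - m +
(1-\mu_k)s_k) / B(\mu_k s_k, (1-\mu_k)s_k)$. The beta-binomial absorbs
the overdispersion of real per-CpG levels, which a plain binomial
emission underestimates at low coverage. Parameters are fitted by
Baum–Welch EM (forward–backward in compiled code, chromosomes as
independent chains sharing parameters) to a relative log-likelihood
tolerance of $10^{-4}$ or 200 iterations; within each M-step the state
mean comes from the posterior-weighted counts and the precision from a
1-D profile-likelihood search. States are identified by emission mean
after fitting, so label switching cannot change the decoded set; if EM
degenerates the fit restarts once from a seeded, perturbed start.

Decoding is posterior (state probability > 0.5) by default because it
gives stabler boundaries for short HMRs than Viterbi, which is available
via `decoding = "viterbi"`. Maximal hypomethylated runs become HMRs with
three post-rules: runs split where consecutive CpGs are more than 5 kb
apart (so calls never bridge unsequenced deserts), runs with fewer than
10 CpGs are discarded, and the interval spans the first CpG to the last
CpG + 2 so the final dinucleotide is covered — the end convention used
for every region type in the package. Essentially constant inputs bypass
the HMM entirely: a uniformly methylated sample yields no HMRs and a
uniformly unmethylated one yields one HMR per chromosome.

`classify_blocks` labels an HMR a PMD-like block when it is longer than
1,500 bp *and* its mean level falls in [0.3, 0.7]; both the size cut and
the band are arguments.

## Smoothing and DMR calling

For each CpG a symmetric window starts at 1 kb half-width and grows until
it holds at least 20 CpGs. The smoothed level is the tricube-weighted
proportion $\hat p = \sum w_i m_i / \sum w_i n_i$, and the 95% band is a
Wilson score interval on effective counts. Two conventions are offered:

- `"weighted"` (default) uses $(\sum w m, \sum w n)$ directly. Because
  tricube down-weights window edges, $\sum w n$ slightly overstates the
  information only if weights were flat; in practice this band
  over-covers mildly (~96–97% empirical coverage for a smooth truth).
- `"ess"` rescales to the Kish effective sample size
  $n_{\mathrm{eff}} = (\sum w n)^2 / \sum w^2 n$, which equals the true
  sampling variance of the weighted proportion and yields bands calibrated
  at the nominal 95%.

The conservative default is deliberate: DMR calling declares a CpG
"separated" when the two samples' bands are disjoint, and a DMR is a
maximal same-sign run of at least six separated CpGs ("more than five"),
spanning first to last CpG + 2. Disjointness of two pointwise bands is a
stringent per-CpG event, but smoothing correlates neighboring CpGs over a
whole window, so a single noise excursion separates many consecutive CpGs
at once: the false-call rate therefore scales with the number of
independent smoothing windows, at roughly $10^{-3}$–$2\times10^{-3}$ per
window with calibrated 95% bands. Genome-scale screens that need a
near-zero family-wise rate should raise `conf` or `min_consecutive`; the
per-window property is inherent to the disjoint-band rule, not to the
implementation. Whether the original rule required full band
disjointness or only non-crossing point estimates is ambiguous; the
stricter disjointness reading is implemented. Positions present in only
one profile are dropped (with a message), never imputed, and runs never
span chromosome boundaries.

## The HMR catalog

c-HMRs intersect all tissues first and then merge fragments at most
100 bp apart (intersect-then-merge; the opposite order would let the
merge manufacture common bases that no tissue fully covers). The t-HMR
rule is absolute — zero shared bases with any other tissue's HMRs — and
"present in > 50% of tissues" is strict (> 0.5, so 5 of 8). Frequent
regions overlapping any c-HMR are removed whole. Both partition
invariants (t-HMRs disjoint from all other tissues; frequent disjoint
from common) are asserted on every build rather than trusted.

Promoters default to the supplied per-gene intervals; co-activation
assigns each t-HMR to its nearest promoter within 10 kb (the proximal
convention; < 50 kb is the extended distal one) and scores the fraction
whose gene is hypomethylated — treated as potentially active — in each
evaluation tissue. Composite profiles average CpG levels in 4-bp bins
over ±2 kb around HMR centers, reporting empty bins as missing rather
than zero. Interval enrichment tiles the universe at 100 bp, classifies
each tile by whether its *midpoint* lies in query/annotation (an
unambiguous rule that avoids double-counting partial tiles), and applies
Fisher's exact test; tiling avoids treating single bases as independent
trials.

## Cohort-scale hypermethylation

Probes map into an HMR when their position falls inside the half-open
interval. All thresholds follow the strict/inclusive readings stated with
the functions: confirmation needs ≥ 6 probes ("more than five") and mean
beta ≤ 0.30 in *every* normal sample; an event needs mean beta strictly
> 0.33 in at least 25% of cancer samples; candidates need promoter
overlap, ≥ 2 probes, and strictly > 1% of (optionally solid-only) cancer
samples above 0.50. Missing betas are excluded pairwise; an HMR-sample
mean requires one non-missing probe. Event frequencies are pooled across
cancer samples by default — running per type is a column subset away, and
the planted-truth tests do exactly that since planted events are
type-specific. Validation sweeps a beta threshold over (t-HMR, sample)
pairs — below-threshold matched pairs are true positives, below-threshold
unmatched pairs false positives — and integrates the ROC by trapezoid
with (0,0) and (1,1) anchors. Clustering dichotomizes mean betas at 0.33,
uses Jaccard distance between binary sample vectors and Ward linkage
(`ward.D2`); two samples with empty union get distance 0, and an
all-identical matrix is flagged rather than clustered silently.

## Mutual exclusivity

The statistic is coverage: the number of samples altered in at least one
gene of the set. The null redraws each gene's observed alteration count
without replacement with selection probability proportional to the
per-sample total burden computed over *all* genes of the matrix (not just
the tested set — using the set alone would let the tested signal distort
its own null). Zero-burden samples keep a pseudo-burden of ε = 0.01 so
coverage is not forced onto altered samples only. Sampling uses
exponential races ($\mathrm{Exp}(w_s)$ keys, keep the $k$ smallest),
vectorized across simulations in memory-bounded chunks, which is exactly
weighted sampling without replacement. The empirical p-value is
$(1 + \#\{\mathrm{cov_{sim}} \ge \mathrm{cov_{obs}}\}) / (n_{\mathrm{sims}} + 1)$
— never zero — and the Z score is computed on raw coverage. Exclusivity
is the upper tail: observed coverage above the null.

Two calibration properties are worth knowing. When the tested set makes
up a sizable share of the matrix (small panels), the set's own
alterations feed the burden weights and the test turns mildly
anti-conservative; with a large panel and a small cohort the
integer-valued coverage makes the empirical p conservative. In the
intended regime — a large gene panel and cohorts of hundreds of samples —
the type-I error sits close to nominal, which the test suite measures
over 400 null datasets at that scale.

## The synthetic-data generators

The generators exist so every stage has planted ground truth; they are
first-class, tested code. The default genome is 2 chromosomes × 5 Mb
with ~52,000 CpGs: a clustered point process of dense islands (50–200
CpGs at ~10 bp spacing) over a sparse background (~300 bp mean spacing,
chosen so the default design lands at the intended desk scale). Islands
carry the planted architecture — 30 common, 8 frequent (in a fixed
majority of 5 of 8 tissues), 12 tissue-specific per tissue, 20 never
hypomethylated — which obeys the catalog algebra by construction, and
tissue1 carries exactly 50 planted HMRs. Methylomes draw true levels from
Beta(7.5, 2.5) (mean 0.75, matching the 70–80% somatic background)
outside planted regions and Beta(1, 19) (mean 0.05) inside, read depths
from a truncated Poisson (≥ 1) at configurable mean (default 15×, within
the realistic 6–25× band), and methylated counts binomially. Cancer
series add PMD blocks at intermediate levels, focal hypermethylation on
planted HMRs and a global background loss, with the metastasis strictly
extending the primary so planted global means decrease monotonically.

Beta cohorts place 2–8 probes per island and draw per-sample HMR betas
from the planted state (hypo ~U(0.05, 0.15), methylated ~U(0.65, 0.85),
events ~U over the configured intensity range) plus truncated Gaussian
probe noise. Planted events hit an *exact* number of samples per type
(`round(frequency × n)` randomly chosen carriers) rather than a Bernoulli
draw, so the planted frequency is a design condition and exact
threshold-recovery statements are well-defined. Alteration matrices are
independent Bernoulli with per-gene rates × per-sample burden multipliers
in null mode, and draw within-set altered samples disjointly in exclusive
mode. All generators are seed-deterministic and return their truth.

What the generators do *not* emulate: sequence context and bisulfite
conversion errors, copy-number effects on coverage, spatially varying
CpG density beyond the island/background dichotomy, probe-specific array
biases, or biological replicate structure. Passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
model, not robustness to every artifact of real libraries.

## Problem sizes and numerical choices

The test suite runs at desk scale by choice: segmentation recovery on the
~52k-CpG default genome; smoother coverage over 200 replicates of a
1,000-CpG chromosome with a slowly varying sinusoidal truth; DMR power
and null calibration over 100 replicate pairs of a 100-CpG locus at 20×;
the cohort stage on 12 cancer types × 25 samples; mutual-exclusivity
calibration over 400 null matrices of 100 genes × 200 samples at 499
permutations each, with 10⁵ permutations where a single test's precision
matters. EM tolerance is 10⁻⁴ relative; Wilson intervals are clamped to
[0, 1]; geometric mean size of an empty segmentation is reported as 0;
correlation on zero-variance input is flagged `NA`, never silently 0;
ROC AUC uses trapezoids with anchored endpoints. The pipeline derives
every stage seed from the single root seed by fixed offsets, which is
what makes end-to-end runs byte-reproducible.

## Known limitations

The HMM has exactly two states: no three-way UMR/LMR/FMR distinction, and
PMD-like blocks are separated only by the post-hoc size/level rule. The
smoother is local-constant; a local-linear variant would reduce boundary
bias at sharp HMR edges at the cost of occasional overshoot. DMR calling
is two-sample without replicate shrinkage. The mutual-exclusivity null
conditions on realized marginals through weights rather than exact
conditional sampling, which is the standard, tractable reading of
burden-respecting permutation. And the catalog treats HMR sets as exact
intervals: uncertainty in HMR boundaries does not propagate into the
partition.
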