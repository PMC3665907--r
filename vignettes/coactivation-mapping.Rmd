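---
title: "Seed co-activation, resting-state correlation, and functional decoding: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed co-activation, resting-state correlation, and functional decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coactmeta)
```

# What the package computes

`coactmeta` characterizes a seed region of the brain by two complementary
measures of functional connectivity and by its functional profile:

1. **Task-dependent co-activation (MACM).** From a coordinate database of
   neuroimaging experiments, the experiments reporting at least one
   activation focus inside the seed are selected, and their brain-wide
   convergence is quantified by activation likelihood estimation (ALE).
2. **Task-independent resting-state correlation.** Per participant, the
   seed's summary time course is correlated with every brain voxel after
   nuisance regression and band-pass filtering; Fisher-z maps enter a
   random-effects group analysis.
3. **Functional decoding.** The seed's associations with task labels are
   tested in the forward direction (probability of activation given the
   label, against the database base rate) and the reverse direction
   (probability of the label given activation, via Bayes' rule).

Seed-versus-seed differences are assessed in both connectivity modalities
and in decoding; agreement across modalities is established with
minimum-statistic conjunctions.

The empirical inputs such analyses normally consume (a curated experiment
database, a resting-state cohort) are access-restricted, so the package
ships generators that synthesize both kinds of data *with planted ground
truth*. Every claim the test suite makes about recovery or calibration is
scored against those planted structures.

# The ALE model

Each reported focus is modeled as a 3D Gaussian centred on the focus,
expressing the spatial uncertainty of reported coordinates. Its standard
deviation combines a between-subject component, shrinking with the number
of scanned subjects $n$, and a between-template component that does not:

$$\sigma(n) = \sqrt{\sigma_{\mathrm{template}}^2 +
\sigma_{\mathrm{subject}}^2 / n}.$$

The defaults $\sigma_{\mathrm{subject}} = 5$ mm and
$\sigma_{\mathrm{template}} = 2.4$ mm approximate the empirical estimates
commonly used in coordinate-based meta-analysis; both are configurable in
`kernel_spec()` because the underlying estimates are themselves data-set
dependent. The kernel is evaluated at voxel centres, truncated at
3.5 $\sigma$, and normalized to unit sum over the truncated support, so
kernel values are probabilities (the mass the focus assigns to each
voxel).

Per experiment, focus kernels combine into a *modeled activation* (MA)
map by the voxel-wise **maximum**, not the sum: several nearby foci from
one experiment are one piece of evidence, not many. Across experiments
the MA maps combine by the union formula

$$\mathrm{ALE}(v) = 1 - \prod_i \bigl(1 - \mathrm{MA}_i(v)\bigr),$$

the probability that at least one experiment activates at $v$ under
independence.

## The analytic null and voxel-level inference

Significance of convergence is assessed against a null of *random spatial
association*: each experiment keeps its within-experiment distribution of
MA values over in-mask voxels, but experiments are combined at
independently drawn voxels. The null distribution of the ALE score is
tabulated by successive histogram combination with bin width $10^{-5}$:
the running ALE histogram is folded with each next MA histogram through
the union formula. Each bin carries its probability mass *and* the
mass-weighted mean of the exact values that landed in it, and folding
proceeds from those representative values; folding from bin left edges
instead would bias combination values systematically downward by up to a
bin per fold, which is visible against a Monte Carlo oracle at the
$10^{-3}$ scale. The p-value of an observed score is the closed upper
tail (mass of equal-or-higher bins); scores above the null support
receive the smallest positive tail mass rather than zero, and Z scores
are the inverse-normal transform of p.

## Cluster-level familywise error

Voxels with $p <$ the cluster-forming threshold (default 0.001) are
grouped into connected clusters (26-neighborhood by default; 6 and 18
are available). The null distribution of the maximum cluster size is
built by Monte Carlo: every experiment's foci are relocated to uniformly
random in-mask voxels, focus counts and kernels preserved, and the
largest suprathreshold cluster recorded. A cluster is retained when its
permutation-style p-value $(1 + \#\{\text{null} \ge \text{size}\}) /
(1 + n_{\mathrm{mc}})$ is at most the cluster alpha (default 0.05). With
small Monte Carlo counts the discreteness of cluster sizes makes this
mildly conservative; the calibration test accepts the familywise rate
through its binomial confidence interval rather than as a point value.

## Differences between seeds

The observed statistic is the voxel-wise ALE difference between the two
seeds' analyses. Experiments contributing to either selection are pooled
and repeatedly re-divided at random, and the difference recomputed under
each division (cached MA maps make this cheap: an experiment's MA map
depends only on the experiment, never on the seed — an efficiency
contract that is output-equivalent to naive recomputation and tested as
such). The per-voxel empirical probability
$(1 + \#\{d_{\mathrm{perm}} < d_{\mathrm{obs}}\}) / (1 + n_{\mathrm{perm}})$
avoids exact zeros and ones under ties; voxels exceeding 0.95 are
reported, inclusively masked by the corresponding seed's thresholded main
effect. Two points were genuinely open and are resolved as follows:

* **Overlapping selections.** A partition into groups of the two original
  sizes is impossible when an experiment activates both seeds. The
  permutation preserves the counts of A-only, B-only and shared
  experiments, assigning each permuted "shared" experiment to both
  groups. This reduces exactly to the plain partition (`split_pool()`)
  for disjoint selections and makes identical selections exchangeable by
  construction, so the degenerate case is empty as it must be.
* **Swap symmetry.** The permutation stream is generated in a canonical
  seed order (lexicographic by name), so calling the analysis with the
  seeds swapped reproduces the identical stream and exactly mirrors the
  directional outputs.

Whether cluster-level correction should be recomputed inside each
permutation is not settled practice; this implementation applies
voxel-level empirical thresholding plus main-effect masking, and reports
the permutation count alongside.

# Resting-state correlation

The preprocessing contract is: discard dummy volumes, smooth (5 mm FWHM
default), regress nuisance variance, band-pass, then correlate. Smoothing
is placed before nuisance regression because it belongs to spatial
preprocessing; the opposite order for the regression/filter pair changes
the output and is deliberately not offered as an option — a test asserts
the orders differ rather than silently allowing both.

* **Nuisance model.** Six motion parameters, their backward-difference
  derivatives (zero first row), three tissue means, the element-wise
  square of each (the second-order terms), and an intercept — 31 columns.
  Columns constant after construction are dropped with a warning;
  rank-deficient designs keep a maximal independent subset.
* **Band-pass.** Frequency-domain filter with unity gain in 0.01–0.08 Hz
  and cosine tapers of width 0.005 Hz; the mean (0 Hz) is removed. The
  contracts are behavioral: passband amplitudes within 5%, stopband
  (half the lower or twice the upper edge) attenuated by at least 90%.
* **Seed time course.** The first eigenvariate (dominant singular
  direction of the time-by-voxel matrix), unit variance, sign aligned
  with the seed-mean course; a plain-mean mode exists for comparison.
* **Correlation and z.** Pearson r against every in-mask voxel, clipped
  at $|r| = 1 - 10^{-7}$ before `atanh`; zero-variance voxels get r = 0
  and a flag, as do voxels inside the seed itself.
* **Group inference.** One-sample (or paired, for seed contrasts) t-tests
  on the z maps with the same cluster-forming threshold as MACM and a
  sign-flip maximum-cluster-size null. The original ANOVA machinery with
  non-sphericity correction is replaced by this simpler random-effects
  scheme with the same null-rejection contract, because the non-sphericity
  estimator is not reproducible from published descriptions; the
  replacement is calibrated by simulation in the test suite.

# Functional decoding

For a label $T$ and seed activation $A$, the counts
$(n_{\mathrm{total}}, n_T, n_A, n_{TA})$ determine everything.
Forward inference is the exact binomial tail
$P(X \ge n_{TA})$, $X \sim \mathrm{Bin}(n_T, n_A/n_{\mathrm{total}})$
(exact rather than a normal approximation because small label counts are
routine). Reverse inference tests the 2x2 association with the Pearson
chi-square without continuity correction (expected counts below 5 are
flagged) and reports the posterior
$P(T \mid A) = P(A \mid T)\,P(T)/P(A) = n_{TA}/n_A$. A label is *robust*
when both directions are significant (default $\alpha = 0.001$ each).

Contrast decoding restricts to experiments activating exactly one of the
two seeds, tests each label's differential association by 2x2 chi-square,
corrects across labels by Benjamini–Hochberg FDR (q = 0.05), and reports
a label for a seed only if it is also robust in that seed's individual
profile (the masking rule). The exact 2x2 construction used historically
for reverse contrast inference is not printed anywhere authoritative;
ours lives in one internal function (`.contrast_table`) precisely so it
can be substituted. Labels are flat strings; an optional prefix-expansion
flag lets an experiment labeled `"Cognition.Memory"` also count for
`"Cognition"`, since hierarchical taxonomies interrelate sub- and parent
categories without a defined propagation rule.

# The synthetic study and what it does (not) show

`generate_database()` plants experiment classes that co-activate
spherical regions (one focus per co-activating region, Gaussian with sd
half the region radius, truncated to the mask) over uniform background
foci, with class-specific label probabilities; subject counts are drawn
uniformly from 8–30, the typical fMRI group-size range, which exercises
the sample-size dependence of the kernel. `generate_rs_dataset()` mixes a
shared band-limited course into each network's voxels at the amplitude
$a = \sigma_{\mathrm{noise}}\sqrt{\rho/(1-\rho)}$ that yields the target
within-network correlation $\rho$ in expectation, plus motion- and
tissue-coupled nuisance signal, white noise, and a decaying saturation
offset on the initial dummy volumes. Manifests record every planted
assignment, so recovery is scored against the generator, not against the
method's own output.

The generators emulate the *structure* the pipeline relies on — seed-
linked convergence, label enrichment, low-frequency shared variance,
nuisance coupling — but not several properties of real data: spatially
correlated physiological noise, distance-dependent co-activation
gradients, realistic label marginals, nonstationary motion artifacts, or
anatomy. Passing tests therefore demonstrate that the machinery recovers
what it claims to recover and controls what it claims to control *under
its own model assumptions*; they do not validate the neurobiological
interpretation of any real-data result.

# Numerical choices and degenerate inputs

* Focus-to-voxel assignment is nearest-voxel with half-way ties broken
  toward the lower index; all voxel indices are 0-based in affine
  arithmetic and mm coordinates are MNI throughout (Talairach input is
  refused, never converted silently).
* Statistic maps hold zero outside the brain mask as a uniform missing
  marker; all thresholding operates strictly inside the mask.
* Cluster tables are sorted by size with peak-coordinate tie-breaks, so
  identical inputs give identical tables.
* Empty selections, all-zero maps, absent labels, zero-variance voxels
  and degenerate 2x2 margins all return flagged/empty results or clear
  errors rather than NaNs.
* Every stochastic stage takes an explicit RNG seed, and the workflow
  derives per-stage seeds from one master seed; identical configurations
  are bit-identical end to end.

# Problem sizes

The shipped tests and the acceptance script run the whole pipeline on
small grids (16³–32³ voxels at 2 mm, ellipsoidal masks) with databases of
tens to low hundreds of experiments, permutation counts of 100–1000
(10000 reproduces the conventional full-scale setting), Monte Carlo
cluster nulls of 100–200 iterations, and resting-state samples of 8–30
participants with 68–136 volumes. These sizes were chosen so a study
runs in seconds to minutes on one CPU while every statistic remains in
its calibrated regime; all of them scale up by configuration alone.

# Known limitations

* The histogram null treats voxels as exchangeable within the mask; edge
  voxels have slightly clipped kernels, which the null inherits from the
  observed MA maps rather than modeling explicitly.
* Cluster-level inference with small Monte Carlo counts is conservative
  under heavy size ties (small masks, very sparse databases).
* The sign-flip group model assumes symmetric errors; it replaces, not
  reimplements, ANOVA-based non-sphericity machinery.
* Seeds are binary masks; probabilistic seeds and surface-based analysis
  are out of scope, as are database querying and Talairach conversion.
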