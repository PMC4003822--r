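---
title: "Genotyping samples with copy-number alterations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping samples with copy-number alterations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A SNP array reports, for every SNP and sample, one summarized intensity
per allele (6–10 probe replicates averaged on the raw scale, then
log-transformed).  Plotted as B-allele against A-allele log-intensity,
the samples of one SNP form three clusters along roughly parallel lines —
the AA, AB and BB genotypes — and genotyping is cluster assignment.
Tumor samples break this picture: somatic copy-number alterations (CNAs)
delete or duplicate whole chromosome arms, so within a copy-loss region a
sample is hemizygous (A or B, never AB) and its point sits between the
diploid clusters, the more so the more normal tissue contaminates the
specimen.  Callers that only know the three diploid clusters either
withhold those calls or, worse, call them heterozygous.

`bcrgeno` treats the copy-number status of each (SNP, sample) pair —
supplied by an upstream CNA caller, as status codes loss / normal /
gain — as a fixed covariate of the cluster regression, so the cluster
lines themselves move to where CNA-affected points lie.

## The per-SNP model

All intensities are first centred per SNP at the median of the A-allele
log-intensities; only the relative position of the two channels carries
genotype information.  For one SNP with centred values $(x_i, y_i)$ and
cluster membership $C_i = k \in \{AA, AB, BB\}$ with mixing proportions
$\pi$:

$$y_i = \beta_{k0} + \beta_{k1} x_i + \beta_{kCN}\,CN_i + \xi_k,\qquad
\xi_k \sim N(0, (c_k\sigma)^2),\; c = (2, 1, 2).$$

The heterozygote cloud is visibly tighter than the homozygote clouds on
real arrays; the fixed scale factors $c$ encode that with a single base
scale $\sigma$.  Each cluster's coefficient vector carries a conjugate
normal prior $N(\beta_{prior,k}, \sigma^2 V)$ with diagonal $V$, giving
the closed-form posterior mean
$(V^{-1} + X'WX)^{-1}(V^{-1}\beta_{prior} + X'Wy)$ under observation
weights $W$.  $\sigma^2$ takes no prior and is estimated from the data.
Clusters are labelled by intercept order — the lowest intercept (B signal
far below A) is AA — which makes every result invariant to how clusters
were ordered upstream.

### EM algorithm and numerical choices

* **E step.** $r_{ik} \propto \pi_k\,N(y_i;\,\hat y_{ik},
  (c_k\sigma)^2)$, computed in log space; a sample whose three
  log-densities all underflow receives uniform responsibilities (counted
  and reported).
* **M step.** Coefficients: posterior mean with weights
  $r_{ik}/c_k^2$; a cluster with essentially no responsibility
  ($\sum_i r_{ik} < 10^{-8}$) keeps its prior mean, so an absent genotype
  cannot destabilize the fit.  Error scale:
  $\sigma^2 = (S + P)/(n + 3p)$ with
  $S = \sum_{ik} r_{ik}\,e_{ik}^2/c_k^2$ the de-scaled pooled residual
  sum and $P = \sum_k (\beta_k - \beta_{prior,k})'V^{-1}(\beta_k -
  \beta_{prior,k})$; the prior terms are an $O(p/n)$ correction to the
  plain frequentist $S/n$ that makes the update the exact conditional
  maximizer, so the penalized observed-data log-likelihood (recorded per
  iteration in `fit$objective`) provably cannot decrease.  Proportions:
  responsibility means.
* **Initialization.** Coefficients at the prior means, $\sigma$ at
  1.4826 times the median absolute residual from each point's nearest
  prior line (a robust scale that survives misplaced clusters), and
  $\pi$ at the prior proportions with the heterozygote multiplied by
  `ab_weight` (default 0.5) and renormalized.  Heterozygotes are less
  frequent than homozygotes and a homozygote-leaning start discourages
  spurious AB calls.  We deliberately apply this weight only at
  initialization: folding it into every proportion update makes the
  update a non-maximizer, and on SNPs whose true lines sit away from the
  generic prior we observed it steadily decreasing the objective and
  collapsing the AB component.
* **Stopping.** Maximum absolute parameter change below `tol`
  (default 1e-6) or 30 iterations; the last iterate is the estimate.
* **Degenerate input.** SNPs with fewer than 4 samples skip EM and are
  classified against the prior lines directly.
* **Calling.** `argmax_k r_{ik}`, withheld as `NoCall` below the 0.999
  posterior threshold.  Thresholding trades call rate for concordance;
  threshold 0 forces a 100% call rate.

## Prior construction

**Means.** A random subset of (SNP, sample) pairs — 5,000 by default,
anything in the 5,000–50,000 range behaves the same — is pooled across
the dataset and split into three clusters on the log-ratio $d = x - y$:
sort $d$, take first differences, smooth them with a trailing unweighted
moving average (window 25), and take the largest smoothed value once
among gaps whose lower point lies in the (25%, 50%] rank band and once in
(50%, 75%].  Ties break toward the band centre, and within the trailing
window of the winning value the single largest raw difference is taken as
the cut, so the boundary falls inside the between-cluster gap rather than
up to a window after it.  An ordinary regression per cluster gives the
prior means; slopes are replaced by 1 by default (`slope_mode = "unit"`),
since the clouds are near-symmetric about the 45° line and unit slopes
work as well as fitted ones.  When a CNA status matrix is available,
pooling (and the monomorphic screen below) is restricted to copy-number
normal observations — hemizygous points do not belong to any diploid
cluster and would contaminate the fit.

**Variances.** 100 monomorphic SNPs (all samples AA or all BB — a SNP
qualifies when at least 99% of its log-ratios fall beyond the AB/
homozygote cut on one side) are fitted by ordinary regression; the prior
variance scale is one third of the mean sampling variance for the slope
(so the slope prior binds firmly) and three times it for the intercept.
The calibrated values are used directly as the diagonal of $V$ in the
posterior-mean formula.  Because the formula adds $V^{-1}$ to $X'WX$,
this makes the intercept and slope priors strong anchors: we also tried
interpreting the calibrated values as absolute variances (rescaling by
$\sigma^2$ inside the fit), which frees the intercepts to follow the
data, but the weakened slope and covariate priors then let the AB
cluster tilt onto contaminated hemizygous points in loss regions and the
loss-region suppression collapsed.  The strong-anchor reading is the one
that works, and per-SNP structure is instead handled by the training
step.

**Training.** With reference samples of known genotype,
`train_snp_priors()` refits each SNP's observed clusters and uses those
lines as that SNP's prior means (clusters with under three training
points fall back to the generic entries).  Per-SNP mixing proportions
are floored at 0.01 and renormalized so a genotype unseen in training
remains callable.  Training and target samples must be disjoint —
reusing samples inflates apparent accuracy — and the package enforces
this by identifier.

## The copy-number covariate

`constant`, the covariate magnitude, is the larger of the absolute 2.5th
and 97.5th percentiles of the pooled log-ratios: roughly the full
one-allele signal range.  Status codes map to covariate values by which
allele is affected: for loss, the brighter channel is the remaining
allele (A brighter ⇒ B lost ⇒ $+constant$; otherwise $-constant$; exact
ties count as B-loss and are a measure-zero convention); gains are coded
analogously at $constant/5$, since probe saturation compresses the
intensity gain of an extra copy to roughly a fifth of the loss scale.
The covariate is held fixed during EM — only $\beta_{kCN}$ is estimated —
and the prior is extended with a weak entry ($\beta_{kCN,prior} = 1$,
variance $100 \times$ the slope scale) so the pre-set value matters
little where data exist.  Mechanically, the covariate's main effect is on
the heterozygote cluster: in a loss region no true AB points exist, so
$\beta_{AB,CN}$ stays near its prior and the shifted AB line sits far
from the hemizygous points, which the (data-adjusted) homozygote lines
absorb.  SNPs whose samples are all copy-number normal are fitted without
the covariate, so an all-normal status matrix reproduces the CNA-naive
run bit for bit.

After calling, `het_check()` computes per sample the proportion of
heterozygous calls among called SNPs in regions the status matrix marks
as loss.  True loss regions cannot contain heterozygotes, so a proportion
above 1% flags the sample and points at the upstream copy-number calls.
The check is only informative against a trustworthy reference status: if
the corrupted status itself is used, relabelled regions are simply
invisible to it.

## Quantile normalization

For CNA-free cohorts the arrays are quantile-normalized first: each
sample's A and B channels come from one physical array and are pooled
into a single per-sample vector, normalized on the raw scale (each rank
receives the across-sample mean of the sorted values, via
`limma::normalizeQuantiles`, ties at average ranks), and re-logged.  QN
assumes all samples share one abundance distribution; CNAs violate that
assumption, so the function refuses cohorts with a CNA matrix unless
forced.  Whether enzyme fractions of an array set should be normalized
separately is left to the caller: whatever matrix is supplied is one
batch.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates the study cohorts every test runs on.  Per
SNP: a minor-allele frequency from `maf_range` (default U(0.05, 0.5)),
Hardy–Weinberg genotypes, and a fraction `mono_frac = 0.1` of monomorphic
SNPs, as on real arrays in any one population — these are what the
variance calibration needs.  Signal: each allele channel has a saturating
copies→log-signal map with per-copy step 1.5 (so diploid cluster
intercepts are −3, 0, +3), a shared per-observation array effect
(`sigma_x = 0.3`) spreads points along the line, and response noise is
`sigma_het = 0.15` (homozygotes doubled) times a per-SNP lognormal
quality multiplier (`sigma_snp_sd = 0.3`).  Each SNP also carries
per-channel probe-affinity offsets (`snp_affinity_sd = 0.2`), which shift
that SNP's intercepts jointly — the per-SNP structure a generic prior
cannot represent but the training step can.  The affinity scale was set
so that a generic-prior run on a clean cohort lands at the
call-everything concordance level published cohorts reach (around
99.5%), and the per-SNP training then adds the small but consistent
improvement reported for trained callers; these constants were fixed
before the acceptance checks were written and are not tuned thereafter.

CNAs: a loss makes the (SNP, sample) pair hemizygous — its point moves to
the remaining allele's one-copy position, with AB samples losing either
allele with equal probability (loss of heterozygosity).  We deliberately
do *not* model loss as subtracting a constant from one channel only:
that geometry leaves AB-origin points exactly on the covariate-shifted
AB line, i.e. it would make the model call them heterozygous, which is
the opposite of how hemizygous signal behaves.  A gain displaces the
point vertically by ±`gain_shift` (one fifth of the loss scale), with
the same sign convention as the covariate coding — exactly the
proportionality the regression model assumes when one per-cluster
coefficient serves both loss (CN = ±c) and gain (CN = ±c/5).
Contamination mixes tumor and germline signal on the raw intensity scale
before logging; it only matters where the tumor state differs from
germline, and it is what drags hemizygous points toward the AB cluster.
The canonical tumor cohort (`sim_config_tumor()`) gives every sample loss
segments covering ~20% of SNPs, one gain segment covering ~10%, and
contamination drawn U(0.10, 0.40).

Passing tests on these cohorts show that the estimator recovers the
generative model it was built for, that the covariate suppresses
loss-region heterozygous calls by more than an order of magnitude over a
CNA-naive run of the same engine, and that the diagnostic detects status
misclassification.  They do not certify performance on real arrays:
the simulator has no probe-sequence effects, no background or spatial
artefacts, no batch structure beyond the per-sample distribution shifts
QN removes, a single fixed saturation factor for gains, and no minor
clones (a subclonal loss behaves like a heavily contaminated one, but
the continuum is not modelled separately).

## Problem sizes

The test suite and the acceptance script run, by choice, on: a 5,000 SNP
× 100 sample clean cohort; a 2,000 SNP × 80 sample tumor cohort; 200
SNPs × 270 samples for parameter recovery (fixed geometry, no per-SNP
effects, matching the recovery tolerances of ±0.05); 100 SNPs for the
EM-ascent check; and 20 replicates of a 250-SNP, 135-training /
50-target split for the trained-prior comparison (a one-sided sign test
across replicates).  A full run of either takes a few minutes on one
CPU.

## Known limitations

* Copy-number calls are an input and their quality bounds the output;
  only the global misclassification mode is detectable retrospectively.
* Gain regions are never reported in triploid notation (AAB etc.):
  contamination, saturation and interpretability argue against it; loss
  regions can optionally be rendered A/B.
* The linear model is deliberately first-order; quadratic terms changed
  fits negligibly in our experience with the simulated cohorts and are
  excluded for parsimony.
* Normal-cell contamination is not an explicit model term; heavy
  contamination (well above ~40%) shrinks CNA shifts toward zero and
  degrades the covariate's benefit.
* Hardy–Weinberg equilibrium is never used as a calling filter: it does
  not hold in CNA regions, and a significant deviation there is not a
  genotyping error.
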