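# bcrgeno — copy-number-aware SNP genotyping by Bayesian cluster regression

SNP-array genotype callers cluster the summarized A- and B-allele
intensities of each SNP into the three diploid genotype groups (AA, AB,
BB).  That works for germline samples, but tumor genomes carry large
somatic copy-number alterations (CNAs): in a copy-loss region only one
allele remains, so a true heterozygote is physically impossible there, yet
normal-cell contamination drags the hemizygous signal back toward the AB
cluster and conventional callers produce heterozygous calls exactly where
they cannot occur.  `bcrgeno` genotypes such samples by adding the
copy-number status — produced by any upstream CNA caller — to the
clustering model itself.

## The model

For one SNP, let `x_i` and `y_i` be sample *i*'s centred A- and B-allele
log-intensities.  Each sample belongs to an unobserved genotype cluster
`C_i = k` (k = AA, AB, BB) with probability `pi_k`, and within cluster *k*

```
y_i = beta_k0 + beta_k1 * x_i + beta_kCN * CN_i + xi_k,
xi_k ~ N(0, (c_k * sigma)^2),   c = (2, 1, 2)
```

with a conjugate normal prior `beta_k ~ N(beta_prior_k, sigma^2 V)` on
each cluster's coefficients and a frequentist error scale `sigma` (the
homozygote clouds get twice the heterozygote spread).  The EM algorithm
alternates responsibilities `E(C_ik | y)` with the closed-form posterior
mean update `(V^-1 + X'WX)^-1 (V^-1 beta_prior + X'Wy)` and stops on a
1e-6 parameter tolerance or after 30 iterations.  A sample is called
`argmax_k resp_ik` when that posterior exceeds a 99.9% threshold, else
`NoCall`.

`CN_i` is a fixed covariate built from the upstream status calls: 0 for
two-copy samples, `±constant` for copy loss (sign from which allele
remains), `±constant/5` for copy gain (probe saturation compresses gains),
where `constant` is the larger absolute 2.5th/97.5th percentile of the
pooled log-ratios `x − y`.  The covariate moves each cluster's prediction
line to where CNA-affected points actually lie — in particular it moves
the AB line *away* from hemizygous observations, which is what suppresses
the spurious heterozygous calls.

Prior means come from the data: a pooled subset of intensity pairs is
split into the three clusters by a moving-average peak search on the first
differences of the sorted log-ratios, and a per-cluster regression gives
the generic prior (slopes are taken as 1).  Prior variances are calibrated
on 100 single-genotype SNPs (slope: one third of the mean sampling
variance, so the slope prior binds; intercept: three times).  With
reference samples of known genotype, `train_snp_priors()` learns per-SNP
priors instead, which raises concordance further.

## Worked example

Simulate a tumor cohort (20% of SNPs per sample in copy-loss segments,
10% in gain segments, 10–40% normal-cell contamination), build the prior
from the copy-number-normal observations, and genotype with the covariate:

```r
library(bcrgeno)
sim   <- simulate_dataset(sim_config_tumor(n_snps = 1000, n_samples = 60, seed = 7))
ds    <- center_snps(sim$dataset)
prior <- build_prior(ds, cna = sim$cna, seed = 8)
prior
#> Cluster-regression prior
#>    intercept slope     pi
#> AA   -2.9644     1 0.3116
#> AB    0.0046     1 0.3184
#> BB    2.9777     1 0.3700
#> prior variance scales: intercept=0.008288, slope=0.01023

calls <- bcr_genotype(ds, prior, cna = sim$cna)
evaluate_concordance(calls, sim$truth)
#> call rate 0.9463 (hom 0.9897, het 0.8575)
#> concordance 0.9979 (hom 0.9999, het 0.9932)
#>  stratum     n n_called call_rate ab_prop error_rate concordance
#>     loss 12000    11046    0.9205  0.0033      3e-04      0.9900
#>   normal 42000    40210    0.9574  0.2979      0e+00      1.0000
#>     gain  6000     5519    0.9198  0.2761      0e+00      0.9987
```

The recovered prior intercepts sit at the cluster geometry (±3, 0), and in
copy-loss regions only 0.33% of called genotypes are heterozygous.
Withholding the copy-number status from the same data (a conventional,
CNA-naive run) raises that to 7.3% and brings the loss-region concordance
down to 0.93:

```r
naive <- bcr_genotype(ds, prior)
evaluate_concordance(naive, sim$truth)$strata
#>   stratum     n n_called call_rate   ab_prop  error_rate concordance
#> 1    loss 12000     7741 0.6450833 0.0728588 0.002066916   0.9271412
#> 2  normal 42000    37910 0.9026190 0.2577948 0.001266157   0.9987338
#> 3    gain  6000     5594 0.9323333 0.2895960 0.001430104   0.9985699
```

The retrospective diagnostic catches this: checking the naive calls
against the copy-number status flags essentially every sample, because
far more than 1% of their loss-region calls are heterozygous:

```r
head(het_check(naive, sim$cna), 3)
#>   sample_id n_loss_snps    prop_ab flagged
#> 1      s001         131 0.05343511    TRUE
#> 2      s002         142 0.16197183    TRUE
#> 3      s003         131 0.07633588    TRUE
```

The per-SNP model behind all of this is exposed directly:
`fit <- bcr_fit(x, y, prior, cn = cn)` returns a classed object with
`print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot` and
`simulate` methods; `call_genotypes(fit)` turns it into calls.

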