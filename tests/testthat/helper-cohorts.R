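# lazily computed shared cohorts for the expensive end-to-end checks;
# computed once per test run, whichever test asks first
.cohort_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cohort_cache))
    assign(name, force(expr), envir = .cohort_cache)
  get(name, envir = .cohort_cache)
}

clean_cohort <- function() {
  cached("clean", {
    sim <- simulate_dataset(sim_config_clean(n_snps = 5000L,
                                             n_samples = 100L, seed = 101))
    ds <- center_snps(sim$dataset)
    prior <- build_prior(ds, seed = 102)
    calls0 <- bcr_genotype(ds, prior, threshold = 0)
    calls9 <- bcr_genotype(ds, prior, threshold = 0.999)
    list(sim = sim, ds = ds, prior = prior,
         m0 = evaluate_concordance(calls0, sim$truth),
         m9 = evaluate_concordance(calls9, sim$truth),
         calls0 = calls0, calls9 = calls9)
  })
}

tumor_cohort <- function() {
  cached("tumor", {
    sim <- simulate_dataset(sim_config_tumor(n_snps = 2000L,
                                             n_samples = 80L, seed = 201))
    ds <- center_snps(sim$dataset)
    prior <- build_prior(ds, cna = sim$cna, seed = 202)
    aware <- bcr_genotype(ds, prior, cna = sim$cna)
    naive <- bcr_genotype(ds, prior)   # same data, CNA status withheld
    list(sim = sim, ds = ds, prior = prior, aware = aware, naive = naive)
  })
}

# proportion of heterozygous calls among called entries of a stratum
ab_proportion <- function(calls, mask) {
  cm <- calls$calls[mask]
  mean(cm[cm != "NoCall"] == "AB")
}
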