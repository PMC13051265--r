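# In-code fixtures shared across test files.

# Minimal canonical summary-statistic data.frame.
ss_row <- function(id, chrom = "1", pos = 1L, ea = "A", oa = "G", eaf = 0.3,
                   beta = 0.1, se = 0.02, pvalue = 1e-6, n = 1e5) {
  data.frame(variant_id = id, chrom = chrom, pos = pos, ea = ea, oa = oa,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n)
}

make_ss <- function(rows, trait = "trait", type = "quantitative") {
  SummaryStats(do.call(rbind, rows), trait = trait, traitType = type)
}

# Random harmonized set with a homogeneous true slope plus optional noise.
make_hset <- function(k, seed, slope = 0.5, sey = 0.02, sex = 0.005,
                      noise = TRUE) {
  withr::with_seed(seed, {
    bx_true <- runif(k, 0.05, 0.3) * sample(c(-1, 1), k, replace = TRUE)
    bx <- bx_true + if (noise) rnorm(k, 0, sex) else 0
    by <- slope * bx_true + if (noise) rnorm(k, 0, sey) else 0
    HarmonizedSet(sprintf("v%02d", seq_len(k)), bx, rep(sex, k), by,
                  rep(sey, k))
  })
}

# Exposure-instrument harmonized pair from the generator, restricted to
# the exposure block (mediator instruments carry no exposure effect).
sim_exposure_outcome <- function(cfg) {
  sim <- simulateMediationGwas(cfg)
  ids <- names(sim$truth@gamma)
  list(h = harmonize(subsetVariants(sim$exposure, ids), sim$outcome),
       sim = sim)
}
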