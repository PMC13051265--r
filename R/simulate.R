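# Seeded generator of three-cohort GWAS summary statistics under a known
# exposure -> mediator -> outcome structural model, plus a colocalization
# region fixture. This module defines the ground truth for every
# simulation-based property in the package.

.NONPAL_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                       c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

# GWAS standard error of a per-allele effect for a trait with unit
# variance: se = 1 / sqrt(2 n maf (1 - maf)).
.gwas_se <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

# Draw effects from N(0, scale^2) conditioned on |effect|/se > zmin
# (instrument-grade strength without modeling winner's curse).
.cond_effect <- function(scale, se, zmin = 6) {
  n <- length(se)
  out <- numeric(n)
  need <- seq_len(n)
  for (iter in seq_len(10000)) {
    if (!length(need)) return(out)
    g <- rnorm(length(need), 0, scale)
    ok <- abs(g) / se[need] > zmin
    out[need[ok]] <- g[ok]
    need <- need[!ok]
  }
  stop("effect scale too small to reach instrument-grade strength |z| > ", zmin)
}

.sim_sumstats <- function(ids, chrom, pos, ea, oa, maf, truth, n, trait,
                          traitType, shift = 0) {
  se <- .gwas_se(n, maf)
  beta <- rnorm(length(ids), truth, se) + shift * se
  SummaryStats(data.frame(
    variant_id = ids, chrom = chrom, pos = pos, ea = ea, oa = oa,
    eaf = maf, beta = beta, se = se,
    pvalue = pmax(.z_pvalue(beta, se), 1e-300), n = as.numeric(n)),
    trait = trait, traitType = traitType)
}

#' Build a simulation configuration
#'
#' Defaults are the package's reference study conditions: 14 exposure
#' instruments and 10 mediator instruments, cohort sizes 344,182 /
#' 7,821 / 218,792, and structural coefficients `beta1 = 0.5`,
#' `beta2 = 0.3`, `thetaDirect = 0.45`, giving a true total effect of
#' 0.60 and true proportion mediated of exactly 0.25.
#'
#' @param k,kM exposure / mediator instrument counts.
#' @param nX,nM,nY exposure, mediator and outcome cohort sizes.
#' @param mafRange allele-frequency interval (uniform draw).
#' @param gammaScale,deltaScale SDs of true variant effects on exposure
#'   (exposure instruments) and mediator (mediator instruments).
#' @param beta1,beta2,thetaDirect structural coefficients.
#' @param pleioMeanM,pleioSdM,pleioMeanY,pleioSdY pleiotropy distribution
#'   parameters for exposure instruments.
#' @param nOutliers,outlierShift number of exposure instruments receiving
#'   an additive outcome shift of `outlierShift` outcome-SE units.
#' @param biomarkerReplicate also generate an independent replicate of
#'   the exposure GWAS at the same sample size.
#' @param seed RNG seed (mandatory).
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(k = 14L, kM = 10L, nX = 344182L, nM = 7821L,
                      nY = 218792L, mafRange = c(0.05, 0.5),
                      gammaScale = 0.03, deltaScale = 0.15,
                      beta1 = 0.5, beta2 = 0.3, thetaDirect = 0.45,
                      pleioMeanM = 0, pleioSdM = 0,
                      pleioMeanY = 0, pleioSdY = 0,
                      nOutliers = 0L, outlierShift = 0,
                      biomarkerReplicate = FALSE, seed) {
  new("SimConfig", k = as.integer(k), kM = as.integer(kM),
      nX = as.integer(nX), nM = as.integer(nM), nY = as.integer(nY),
      mafRange = as.numeric(mafRange), gammaScale = gammaScale,
      deltaScale = deltaScale, beta1 = beta1, beta2 = beta2,
      thetaDirect = thetaDirect, pleioMeanM = pleioMeanM,
      pleioSdM = pleioSdM, pleioMeanY = pleioMeanY, pleioSdY = pleioSdY,
      nOutliers = as.integer(nOutliers), outlierShift = outlierShift,
      biomarkerReplicate = biomarkerReplicate, seed = as.integer(seed))
}

#' Simulate three-cohort summary statistics with known mediation truth
#'
#' Generates exposure, mediator and outcome GWAS summary statistics under
#' the structural model
#' `mediator = beta1 * exposure`, `outcome = thetaDirect * exposure +
#' beta2 * mediator`, observed at the per-variant level as
#' `beta_m = beta1 * gamma_j + alpha_m_j` and
#' `beta_y = thetaDirect * gamma_j + beta2 * (beta1 * gamma_j +
#' alpha_m_j) + alpha_y_j` plus sampling noise with standard errors
#' `1 / sqrt(2 n maf (1 - maf))`. Exposure instruments (chromosome 16
#' block) carry true exposure effects `gamma_j ~ N(0, gammaScale^2)`
#' conditioned on `|gamma_j| / se_x_j > 6`; mediator instruments
#' (chromosome 1 block, widely spaced) carry mediator effects
#' `delta_j` under the same strength conditioning at the mediator sample
#' size and act on the outcome only through the mediator
#' (`beta2 * delta_j`). Pleiotropy (`alpha`) and planted outcome outliers
#' apply to exposure instruments. Alleles are non-palindromic; all draws
#' come from the single seeded generator, so identical configurations
#' give bitwise-identical output.
#'
#' @param cfg A [SimConfig-class] from [simConfig()].
#' @return list with elements `exposure`, `mediator`, `outcome`
#'   ([SummaryStats-class]), `truth` ([TrueParams-class]), `ld` (identity
#'   [LDMatrix-class] over all variants: instruments are simulated
#'   mutually independent) and, when requested, `biomarker`.
#' @export
simulateMediationGwas <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  .with_seed(cfg@seed, {
    k <- cfg@k; kM <- cfg@kM
    ids_x <- sprintf("rs16_%03d", seq_len(k))
    ids_m <- if (kM > 0) sprintf("rs01_%03d", seq_len(kM)) else character(0)
    ids <- c(ids_x, ids_m)
    chrom <- c(rep("16", k), rep("1", kM))
    pos <- c(31260000L + (seq_len(k) - 1L) * 34000L,
             27400000L + (seq_len(kM) - 1L) * 1000000L)
    pair <- .NONPAL_PAIRS[sample.int(nrow(.NONPAL_PAIRS), k + kM,
                                     replace = TRUE), , drop = FALSE]
    maf <- runif(k + kM, cfg@mafRange[1], cfg@mafRange[2])

    se_x <- .gwas_se(cfg@nX, maf)
    se_m <- .gwas_se(cfg@nM, maf)
    gamma <- .cond_effect(cfg@gammaScale, se_x[seq_len(k)])
    delta <- if (kM > 0) .cond_effect(cfg@deltaScale, se_m[k + seq_len(kM)])
             else numeric(0)
    alpha_m <- rnorm(k, cfg@pleioMeanM, cfg@pleioSdM)
    alpha_y <- rnorm(k, cfg@pleioMeanY, cfg@pleioSdY)

    true_x <- c(gamma, rep(0, kM))
    true_m <- c(cfg@beta1 * gamma + alpha_m, delta)
    true_y <- c(cfg@thetaDirect * gamma +
                  cfg@beta2 * (cfg@beta1 * gamma + alpha_m) + alpha_y,
                cfg@beta2 * delta)

    exposure <- .sim_sumstats(ids, chrom, pos, pair[, 1], pair[, 2], maf,
                              true_x, cfg@nX, "exposure", "quantitative")
    mediator <- .sim_sumstats(ids, chrom, pos, pair[, 1], pair[, 2], maf,
                              true_m, cfg@nM, "mediator", "quantitative")
    outcome <- .sim_sumstats(ids, chrom, pos, pair[, 1], pair[, 2], maf,
                             true_y, cfg@nY, "outcome", "binary")
    # outliers are applied after all cohorts are drawn, so a clean run
    # with the same seed differs only at the shifted variants
    outlier_idx <- if (cfg@nOutliers > 0) sort(sample.int(k, cfg@nOutliers))
                   else integer(0)
    if (length(outlier_idx)) {
      d <- outcome@data
      d$beta[outlier_idx] <- d$beta[outlier_idx] +
        cfg@outlierShift * d$se[outlier_idx]
      d$pvalue <- pmax(.z_pvalue(d$beta, d$se), 1e-300)
      outcome <- SummaryStats(d, trait = "outcome", traitType = "binary")
    }
    out <- list(exposure = exposure, mediator = mediator, outcome = outcome,
                truth = new("TrueParams",
                            gamma = setNames(gamma, ids_x),
                            delta = setNames(delta, ids_m),
                            beta1 = cfg@beta1, beta2 = cfg@beta2,
                            thetaDirect = cfg@thetaDirect,
                            totalTrue = cfg@thetaDirect + cfg@beta1 * cfg@beta2,
                            proportionTrue = if (cfg@thetaDirect +
                                                 cfg@beta1 * cfg@beta2 != 0)
                              cfg@beta1 * cfg@beta2 /
                                (cfg@thetaDirect + cfg@beta1 * cfg@beta2)
                              else NA_real_,
                            outlierIds = ids_x[outlier_idx]),
                ld = LDMatrix(diag(k + kM), ids))
    if (cfg@biomarkerReplicate)
      out$biomarker <- .sim_sumstats(ids, chrom, pos, pair[, 1], pair[, 2],
                                     maf, true_x, cfg@nX, "biomarker",
                                     "quantitative")
    out
  })
}

#' Write a simulated dataset to disk
#'
#' Writes each cohort in the delimited summary-statistic format, the LD
#' matrix, and a JSON truth manifest, for use as pipeline input.
#'
#' @param sim output of [simulateMediationGwas()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in intersect(names(sim), c("exposure", "mediator", "outcome",
                                     "biomarker")))
    writeSumstats(sim[[nm]], file.path(dir, paste0(nm, ".tsv")))
  writeLDMatrix(sim$ld, file.path(dir, "ld.tsv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(gamma = as.list(truth@gamma), delta = as.list(truth@delta),
         beta1 = truth@beta1, beta2 = truth@beta2,
         theta_direct = truth@thetaDirect, total_true = truth@totalTrue,
         proportion_true = truth@proportionTrue,
         outlier_ids = truth@outlierIds),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a colocalization region
#'
#' Generates regional summary statistics for two traits over `mVariants`
#' variants with AR(1) linkage disequilibrium `r_ij = rho^|i-j|`. Under
#' `shared = TRUE` one causal variant drives both traits; otherwise each
#' trait gets its own causal variant, with the pair constrained to
#' `|r| < 0.05` (error if the region cannot accommodate that
#' separation). Marginal true effects are the LD row times the causal
#' effect (magnitude `effectSd`, random sign per trait); observed effects
#' add noise with GWAS standard errors at the given sample sizes,
#' correlated across variants by the LD matrix within each trait (the
#' joint sampling distribution of marginal GWAS estimates under LD) and
#' independent between the two cohorts.
#'
#' @param mVariants region size (>= 10).
#' @param n1,n2 sample sizes of the two traits.
#' @param shared single shared causal variant (`TRUE`) or two distinct
#'   ones (`FALSE`).
#' @param rho AR(1) LD decay parameter in \[0, 1).
#' @param effectSd causal effect magnitude (0 gives a null region).
#' @param seed RNG seed (mandatory).
#' @param mafRange allele-frequency interval.
#' @return list with `trait1`, `trait2` ([SummaryStats-class]),
#'   `causalIds` and `ld` ([LDMatrix-class]).
#' @export
simulateColocRegion <- function(mVariants = 200L, n1 = 100000L, n2 = 100000L,
                                shared = TRUE, rho = 0.9, effectSd = 0.1,
                                seed, mafRange = c(0.1, 0.5)) {
  stopifnot(mVariants >= 10, rho >= 0, rho < 1)
  .with_seed(seed, {
    m <- as.integer(mVariants)
    ids <- sprintf("reg_%04d", seq_len(m))
    r <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
    c1 <- sample.int(m, 1)
    if (shared) {
      c2 <- c1
    } else {
      eligible <- which(r[c1, ] < 0.05)
      if (!length(eligible)) stop("region too small for H3 scenario")
      c2 <- eligible[sample.int(length(eligible), 1)]
    }
    e1 <- effectSd * sample(c(-1, 1), 1)
    e2 <- effectSd * sample(c(-1, 1), 1)
    maf <- runif(m, mafRange[1], mafRange[2])
    pos <- 1000000L + (seq_len(m) - 1L) * 2000L
    pair <- .NONPAL_PAIRS[sample.int(nrow(.NONPAL_PAIRS), m,
                                     replace = TRUE), , drop = FALSE]
    L <- t(chol(r + diag(1e-10, m)))
    mk <- function(truth, n, trait) {
      se <- .gwas_se(n, maf)
      beta <- truth + se * drop(L %*% rnorm(m))
      SummaryStats(data.frame(
        variant_id = ids, chrom = "2", pos = pos, ea = pair[, 1],
        oa = pair[, 2], eaf = maf, beta = beta, se = se,
        pvalue = pmax(.z_pvalue(beta, se), 1e-300), n = as.numeric(n)),
        trait = trait, traitType = "quantitative")
    }
    t1 <- mk(r[, c1] * e1, n1, "trait1")
    t2 <- mk(r[, c2] * e2, n2, "trait2")
    list(trait1 = t1, trait2 = t2,
         causalIds = unique(ids[c(c1, c2)]), ld = LDMatrix(r, ids))
  })
}
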