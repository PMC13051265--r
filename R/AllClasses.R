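#' @import methods
#' @importFrom stats approx dnorm median pchisq pnorm pt qnorm quantile rnorm
#'   runif sd setNames p.adjust IQR
#' @importFrom utils read.delim write.table combn head packageVersion
NULL

.SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "ea", "oa",
                    "eaf", "beta", "se", "pvalue", "n")

#' SummaryStats: GWAS summary statistics for one trait
#'
#' Container for per-variant summary associations of a single trait: one row
#' per variant with identifier, coordinates (1-based), effect/other allele,
#' effect-allele frequency, effect estimate (log-odds for binary traits, SD
#' units for quantitative traits), its standard error, p-value and sample
#' size. Variant identifiers are unique; matching across cohorts is always
#' identifier-driven, positions are carried for window filters only.
#'
#' @slot trait trait name.
#' @slot traitType `"quantitative"` or `"binary"`.
#' @slot data `data.frame` with columns `variant_id`, `chrom`, `pos`, `ea`,
#'   `oa`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#'
#' @seealso [readSumstats()], [harmonize()]
#' @export
setClass("SummaryStats",
  slots = c(trait = "character", traitType = "character", data = "data.frame"))

setValidity("SummaryStats", function(object) {
  d <- object@data
  msg <- character()
  if (!all(.SUMSTATS_COLS %in% names(d)))
    msg <- c(msg, paste("missing columns:",
                        paste(setdiff(.SUMSTATS_COLS, names(d)), collapse = ", ")))
  else {
    if (anyDuplicated(d$variant_id)) msg <- c(msg, "duplicate variant_id")
    if (nrow(d)) {
      if (any(!is.finite(d$se) | d$se <= 0)) msg <- c(msg, "se must be > 0")
      if (any(d$pvalue <= 0 | d$pvalue > 1)) msg <- c(msg, "pvalue must be in (0,1]")
      ok_eaf <- is.na(d$eaf) | (d$eaf > 0 & d$eaf < 1)
      if (!all(ok_eaf)) msg <- c(msg, "eaf must be in (0,1) or NA")
      if (any(d$ea == d$oa)) msg <- c(msg, "effect_allele must differ from other_allele")
      if (!all(d$ea %in% c("A", "C", "G", "T")) || !all(d$oa %in% c("A", "C", "G", "T")))
        msg <- c(msg, "alleles must be single bases A/C/G/T")
    }
  }
  if (!object@traitType %in% c("quantitative", "binary"))
    msg <- c(msg, "traitType must be 'quantitative' or 'binary'")
  if (length(msg)) msg else TRUE
})

#' Construct a SummaryStats object
#'
#' @param data data.frame in canonical column layout (see
#'   [SummaryStats-class]).
#' @param trait trait name.
#' @param traitType `"quantitative"` or `"binary"`.
#' @return A [SummaryStats-class] object.
#' @examples
#' d <- data.frame(variant_id = "rs1", chrom = "1", pos = 100L,
#'                 ea = "A", oa = "G", eaf = 0.3, beta = 0.1, se = 0.02,
#'                 pvalue = 5e-7, n = 10000L)
#' SummaryStats(d, trait = "hba1c", traitType = "quantitative")
#' @export
SummaryStats <- function(data, trait = "trait", traitType = "quantitative") {
  rownames(data) <- NULL
  new("SummaryStats", trait = trait, traitType = traitType,
      data = data[, .SUMSTATS_COLS, drop = FALSE])
}

#' HarmonizedSet: allele-aligned effects across two or three traits
#'
#' Per-variant exposure/outcome (and optionally mediator) effect estimates on
#' a single common effect-allele orientation, as produced by [harmonize()].
#' Every MR estimator in the package consumes this class. Variants excluded
#' during harmonization are recorded in `dropped` with a reason, never
#' silently.
#'
#' @slot variantId variant identifiers of retained variants.
#' @slot betaX,seX exposure effects and standard errors.
#' @slot betaY,seY outcome effects and standard errors.
#' @slot betaM,seM mediator effects and standard errors (length zero when no
#'   mediator trait was supplied).
#' @slot dropped `data.frame` with columns `variant_id`, `reason`.
#' @export
setClass("HarmonizedSet",
  slots = c(variantId = "character",
            betaX = "numeric", seX = "numeric",
            betaY = "numeric", seY = "numeric",
            betaM = "numeric", seM = "numeric",
            dropped = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  k <- length(object@variantId)
  msg <- character()
  core <- list(object@betaX, object@seX, object@betaY, object@seY)
  if (!all(lengths(core) == k)) msg <- c(msg, "effect vectors must share length")
  if (length(object@betaM) && length(object@betaM) != k)
    msg <- c(msg, "mediator vectors must share length with exposure vectors")
  if (length(object@betaM) != length(object@seM))
    msg <- c(msg, "betaM and seM must share length")
  if (any(object@seX <= 0) || any(object@seY <= 0) ||
      (length(object@seM) && any(object@seM <= 0)))
    msg <- c(msg, "standard errors must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' @rdname HarmonizedSet-class
#' @param variantId,betaX,seX,betaY,seY,betaM,seM,dropped slot values; see
#'   slot documentation.
#' @return A [HarmonizedSet-class] object.
#' @export
HarmonizedSet <- function(variantId, betaX, seX, betaY, seY,
                          betaM = numeric(0), seM = numeric(0),
                          dropped = data.frame(variant_id = character(),
                                               reason = character())) {
  new("HarmonizedSet", variantId = as.character(variantId),
      betaX = as.numeric(betaX), seX = as.numeric(seX),
      betaY = as.numeric(betaY), seY = as.numeric(seY),
      betaM = as.numeric(betaM), seM = as.numeric(seM),
      dropped = dropped)
}

#' LDMatrix: labeled pairwise linkage-disequilibrium correlations
#'
#' Square symmetric matrix of signed correlations (r, not r-squared) between
#' variants, with a unit diagonal. Used by the greedy clumping routine.
#'
#' @slot variantIds variant identifiers labelling rows and columns.
#' @slot r numeric matrix of correlations in \[-1, 1\].
#' @export
setClass("LDMatrix", slots = c(variantIds = "character", r = "matrix"))

setValidity("LDMatrix", function(object) {
  r <- object@r
  msg <- character()
  if (nrow(r) != ncol(r)) msg <- c(msg, "matrix must be square")
  if (nrow(r) != length(object@variantIds))
    msg <- c(msg, "variantIds must label every row")
  if (nrow(r)) {
    if (max(abs(r - t(r))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
    if (max(abs(diag(r) - 1)) > 1e-8) msg <- c(msg, "diagonal must be 1")
    if (any(abs(r) > 1 + 1e-8)) msg <- c(msg, "entries must lie in [-1,1]")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname LDMatrix-class
#' @param r square correlation matrix.
#' @param variantIds labels; defaults to `rownames(r)`.
#' @return An [LDMatrix-class] object.
#' @export
LDMatrix <- function(r, variantIds = rownames(r)) {
  dimnames(r) <- list(variantIds, variantIds)
  new("LDMatrix", variantIds = as.character(variantIds), r = r)
}

#' MREstimate: one estimator's causal-effect estimate
#'
#' Slope-scale estimate (log-odds of outcome per unit exposure for a binary
#' outcome), its standard error and p-value, the odds-scale conversion
#' `or = exp(b)` with a 95% interval `exp(b +/- 1.96 se)`, and, where the
#' estimator provides them, Cochran's Q heterogeneity and the MR-Egger
#' intercept pleiotropy diagnostics (NA otherwise).
#'
#' @slot method estimator name as printed in result tables.
#' @slot nSnp number of instruments used.
#' @slot b,se,pvalue causal estimate, standard error, two-sided p-value.
#' @slot orval,orLo,orHi odds-scale point estimate and 95% CI.
#' @slot q,qPvalue Cochran's Q and its p-value (NA when not applicable).
#' @slot eggerIntercept,eggerInterceptSe,eggerInterceptPvalue MR-Egger
#'   intercept diagnostics (NA except for the Egger estimator).
#' @export
setClass("MREstimate",
  slots = c(method = "character", nSnp = "integer",
            b = "numeric", se = "numeric", pvalue = "numeric",
            orval = "numeric", orLo = "numeric", orHi = "numeric",
            q = "numeric", qPvalue = "numeric",
            eggerIntercept = "numeric", eggerInterceptSe = "numeric",
            eggerInterceptPvalue = "numeric"))

setValidity("MREstimate", function(object) {
  msg <- character()
  if (is.finite(object@b)) {
    if (abs(object@orval - exp(object@b)) > 1e-12 * max(1, exp(object@b)))
      msg <- c(msg, "orval must equal exp(b)")
    if (is.finite(object@se) &&
        (object@orLo > object@orval || object@orval > object@orHi))
      msg <- c(msg, "odds CI must bracket the point estimate")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname MREstimate-class
#' @param method,nSnp,b,se,pvalue,q,qPvalue,eggerIntercept,eggerInterceptSe,eggerInterceptPvalue
#'   slot values; odds-scale fields are derived from `b` and `se`.
#' @return An [MREstimate-class] object.
#' @export
MREstimate <- function(method, nSnp, b, se, pvalue,
                       q = NA_real_, qPvalue = NA_real_,
                       eggerIntercept = NA_real_, eggerInterceptSe = NA_real_,
                       eggerInterceptPvalue = NA_real_) {
  new("MREstimate", method = method, nSnp = as.integer(nSnp),
      b = b, se = se, pvalue = pvalue,
      orval = exp(b), orLo = exp(b - 1.96 * se), orHi = exp(b + 1.96 * se),
      q = q, qPvalue = qPvalue,
      eggerIntercept = eggerIntercept, eggerInterceptSe = eggerInterceptSe,
      eggerInterceptPvalue = eggerInterceptPvalue)
}

#' MRResultTable: estimator suite output in published table layout
#'
#' One row per estimator (IVW, MR-Egger, weighted median, weighted mode,
#' simple mode) with the standard columns `Method`, `nsnp`, `b`, `se`,
#' `pval`, `or`, `or_lci95`, `or_uci95`, `P-heterogeneity`, `P-pleiotropy`.
#'
#' @slot estimates list of [MREstimate-class] objects.
#' @slot table formatted `data.frame` mirror of the estimates.
#' @export
setClass("MRResultTable", slots = c(estimates = "list", table = "data.frame"))

setValidity("MRResultTable", function(object) {
  ns <- vapply(object@estimates, function(e) e@nSnp, integer(1))
  if (length(ns) && length(unique(ns)) != 1) "all rows must share nSnp" else TRUE
})

#' ColocResult: colocalization posterior probabilities
#'
#' Posterior probabilities of the five single-causal-variant hypotheses for a
#' region and two traits: H0 no association, H1/H2 association with one trait
#' only, H3 two distinct causal variants, H4 one shared causal variant.
#'
#' @slot pp named numeric vector `PP.H0` .. `PP.H4`, summing to one.
#' @slot nVariants number of variants in the region.
#' @slot priors per-variant priors `(p1, p2, p12)`.
#' @slot priorVariances prior effect variances `(W1, W2)` used in the
#'   approximate Bayes factors.
#' @export
setClass("ColocResult",
  slots = c(pp = "numeric", nVariants = "integer",
            priors = "numeric", priorVariances = "numeric"))

setValidity("ColocResult", function(object) {
  msg <- character()
  if (length(object@pp) != 5) msg <- c(msg, "pp must have 5 entries")
  if (any(object@pp < 0)) msg <- c(msg, "pp entries must be nonnegative")
  if (abs(sum(object@pp) - 1) > 1e-9) msg <- c(msg, "pp must sum to 1 within 1e-9")
  if (length(msg)) msg else TRUE
})

#' InstrumentSet: selected genetic instruments with provenance
#'
#' Instruments surviving a selection cascade, their per-variant F statistics
#' (instrument strength, `(beta/se)^2`), and an ordered log of every filter
#' applied with in/out counts.
#'
#' @slot variantIds retained variant identifiers, in selection order.
#' @slot stats [SummaryStats-class] restricted to the retained variants.
#' @slot fStats per-variant F statistics (named by variant).
#' @slot selectionLog `data.frame` with columns `step`, `n_in`, `n_out`,
#'   `note`.
#' @export
setClass("InstrumentSet",
  slots = c(variantIds = "character", stats = "SummaryStats",
            fStats = "numeric", selectionLog = "data.frame"))

setValidity("InstrumentSet", function(object) {
  if (length(object@fStats) != length(object@variantIds))
    "fStats length must equal variant count" else TRUE
})

#' PressoResult: MR-PRESSO global, outlier and distortion tests
#'
#' @slot rssObs observed weighted residual sum of squares.
#' @slot globalPvalue simulation p-value for the global heterogeneity test.
#' @slot perVariantPvalues Bonferroni-adjusted per-variant outlier p-values.
#' @slot outliers variant identifiers flagged as outliers.
#' @slot bRaw IVW estimate on all variants.
#' @slot bCorrected IVW estimate after outlier removal (`NULL` when no
#'   outlier was flagged).
#' @slot distortionPvalue simulation p-value for the change in estimate (NA
#'   when no outlier was flagged).
#' @slot nSim,seed simulation settings used.
#' @export
setClass("PressoResult",
  slots = c(rssObs = "numeric", globalPvalue = "numeric",
            perVariantPvalues = "numeric", outliers = "character",
            bRaw = "MREstimate", bCorrected = "ANY",
            distortionPvalue = "numeric", nSim = "integer", seed = "integer"))

setValidity("PressoResult", function(object) {
  msg <- character()
  if (object@globalPvalue <= 0 || object@globalPvalue > 1)
    msg <- c(msg, "globalPvalue must be in (0,1]")
  if (!all(object@outliers %in% names(object@perVariantPvalues)))
    msg <- c(msg, "outliers must be a subset of tested variants")
  if (length(object@outliers) > 0 && is.null(object@bCorrected))
    msg <- c(msg, "bCorrected required when outliers were flagged")
  if (length(object@outliers) == 0 && !is.null(object@bCorrected))
    msg <- c(msg, "bCorrected must be absent without outliers")
  if (length(msg)) msg else TRUE
})

#' BMAResult: Bayesian model averaging over risk-factor subsets
#'
#' @slot modelPosteriors posterior probability of every enumerated subset
#'   (named by comma-separated factor names; `"(none)"` is the empty model).
#' @slot mip per-factor marginal inclusion probability.
#' @slot mace per-factor model-averaged causal effect.
#' @slot permPvalues per-factor permutation p-values (NA before
#'   [bmaPermutation()] is run).
#' @slot priorInclusion,priorSd prior settings used.
#' @export
setClass("BMAResult",
  slots = c(modelPosteriors = "numeric", mip = "numeric", mace = "numeric",
            permPvalues = "numeric", priorInclusion = "numeric",
            priorSd = "numeric"))

setValidity("BMAResult", function(object) {
  msg <- character()
  if (abs(sum(object@modelPosteriors) - 1) > 1e-9)
    msg <- c(msg, "model posteriors must sum to 1 within 1e-9")
  if (any(object@mip < -1e-12 | object@mip > 1 + 1e-12))
    msg <- c(msg, "each mip must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' ScreenResult: metabolite-wide MR screen
#'
#' @slot rows per-metabolite `data.frame`: `name`, `n_snp`, `b`, `se`,
#'   `pvalue`, `or`, `or_lo`, `or_hi`, `q_value`, `significant`; sorted by
#'   p-value.
#' @slot direction `"metabolite_to_outcome"` or `"exposure_to_metabolite"`.
#' @slot rule significance rule applied (`"nominal"` or `"fdr"`).
#' @export
setClass("ScreenResult",
  slots = c(rows = "data.frame", direction = "character", rule = "character"))

#' MediationResult: two-step MR mediation decomposition
#'
#' Product-of-coefficients mediation on the log scale: indirect effect
#' `beta1 * beta2`, direct effect `total - indirect`, proportion mediated
#' `indirect / total`.
#'
#' @slot beta1 exposure to mediator effect (log scale).
#' @slot beta2 mediator to outcome effect (log-odds).
#' @slot total total exposure to outcome effect (log-odds).
#' @slot beta3Direct direct effect, `total - indirect`.
#' @slot indirect mediated effect, `beta1 * beta2`.
#' @slot proportion proportion mediated, `indirect / total` (signed).
#' @slot seIndirect delta-method standard error of the indirect effect (NA
#'   unless variances were supplied; an extension beyond the usual
#'   summary-data report).
#' @export
setClass("MediationResult",
  slots = c(beta1 = "numeric", beta2 = "numeric", total = "numeric",
            beta3Direct = "numeric", indirect = "numeric",
            proportion = "numeric", seIndirect = "numeric"))

setValidity("MediationResult", function(object) {
  msg <- character()
  if (object@indirect != object@beta1 * object@beta2)
    msg <- c(msg, "indirect must equal beta1 * beta2 exactly")
  if (object@beta3Direct != object@total - object@indirect)
    msg <- c(msg, "beta3Direct must equal total - indirect exactly")
  if (length(msg)) msg else TRUE
})

#' SimConfig: settings for the three-cohort summary-statistic generator
#'
#' Defaults mirror the study conditions the package emulates: 14 exposure
#' instruments, cohort sizes 344,182 (exposure), 7,821 (metabolite) and
#' 218,792 (outcome), and a structural model with true proportion mediated
#' `beta1 * beta2 / (thetaDirect + beta1 * beta2)` = 0.25.
#'
#' @slot k exposure-instrument count.
#' @slot kM mediator-instrument count (variants acting on the outcome only
#'   through the mediator; the mediator's own genome-wide hits).
#' @slot nX,nM,nY cohort sample sizes.
#' @slot mafRange minor-allele-frequency interval.
#' @slot gammaScale SD of true variant-exposure effects.
#' @slot deltaScale SD of true variant-mediator effects for mediator
#'   instruments.
#' @slot beta1,beta2,thetaDirect structural coefficients: exposure to
#'   mediator, mediator to outcome, direct exposure to outcome.
#' @slot pleioMeanM,pleioSdM,pleioMeanY,pleioSdY pleiotropy distribution for
#'   exposure instruments on the mediator and outcome.
#' @slot nOutliers,outlierShift planted outcome outliers (shift in units of
#'   the variant's outcome SE).
#' @slot biomarkerReplicate generate an additional independent replicate of
#'   the exposure GWAS (for biomarker filtering and the colocalization gate).
#' @slot seed RNG seed (mandatory; base R Mersenne-Twister).
#' @export
setClass("SimConfig",
  slots = c(k = "integer", kM = "integer",
            nX = "integer", nM = "integer", nY = "integer",
            mafRange = "numeric", gammaScale = "numeric", deltaScale = "numeric",
            beta1 = "numeric", beta2 = "numeric", thetaDirect = "numeric",
            pleioMeanM = "numeric", pleioSdM = "numeric",
            pleioMeanY = "numeric", pleioSdY = "numeric",
            nOutliers = "integer", outlierShift = "numeric",
            biomarkerReplicate = "logical", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@k < 1) msg <- c(msg, "k must be >= 1")
  if (min(object@nX, object@nM, object@nY) < 100)
    msg <- c(msg, "cohort sizes must be >= 100")
  if (object@mafRange[1] <= 0 || object@mafRange[2] > 0.5)
    msg <- c(msg, "mafRange must lie within (0, 0.5]")
  if (object@nOutliers > object@k)
    msg <- c(msg, "nOutliers cannot exceed k")
  if (length(msg)) msg else TRUE
})

#' TrueParams: ground truth of a simulated dataset
#'
#' @slot gamma per-variant true exposure effects (exposure instruments).
#' @slot delta per-variant true mediator effects (mediator instruments).
#' @slot beta1,beta2,thetaDirect structural coefficients used.
#' @slot totalTrue total exposure-outcome effect,
#'   `thetaDirect + beta1 * beta2`.
#' @slot proportionTrue true proportion mediated,
#'   `beta1 * beta2 / totalTrue`.
#' @slot outlierIds identifiers of variants given a planted outcome shift.
#' @export
setClass("TrueParams",
  slots = c(gamma = "numeric", delta = "numeric",
            beta1 = "numeric", beta2 = "numeric", thetaDirect = "numeric",
            totalTrue = "numeric", proportionTrue = "numeric",
            outlierIds = "character"))

setValidity("TrueParams", function(object) {
  msg <- character()
  if (object@totalTrue != object@thetaDirect + object@beta1 * object@beta2)
    msg <- c(msg, "totalTrue identity violated")
  if (object@totalTrue != 0 &&
      object@proportionTrue != object@beta1 * object@beta2 / object@totalTrue)
    msg <- c(msg, "proportionTrue identity violated")
  if (length(msg)) msg else TRUE
})
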