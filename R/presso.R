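# MR-PRESSO: simulation-based residual tests for horizontal pleiotropy.
#
# The observed statistic is the weighted residual sum of squares of each
# variant against the IVW slope fitted without it. Its null distribution
# is obtained by parametric simulation from the leave-one-out expected
# effects, which also yields per-variant outlier tests (Bonferroni
# adjusted) and a distortion test for the change in estimate after
# removing flagged outliers.

# Leave-one-out IVW slopes for a k x n matrix of simulated (or observed)
# effects; columns are replicates. Returns a k x n matrix of slopes.
.loo_slopes <- function(X, Y, w) {
  t_xy <- w * X * Y
  t_xx <- w * X^2
  S_xy <- rep(colSums(t_xy), each = nrow(X))
  S_xx <- rep(colSums(t_xx), each = nrow(X))
  (S_xy - t_xy) / (S_xx - t_xx)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' For each variant `j` the IVW slope `b(-j)` is fitted without it and the
#' residual `d_j = beta_y_j - b(-j) * beta_x_j` computed; the observed
#' global statistic is `RSS = sum(d_j^2 / se_y_j^2)`. `nSim` replicate
#' datasets are simulated with `beta_y* ~ N(b(-j) * beta_x_j, se_y_j)` and
#' `beta_x* ~ N(beta_x_j, se_x_j)`; the global p-value is the add-one
#' exceedance fraction of the simulated RSS, and per-variant outlier
#' p-values are the add-one exceedance fractions of the squared residuals,
#' Bonferroni-multiplied by `k` and capped at one. Variants with adjusted
#' p below `outlierAlpha` are flagged; if any are flagged the IVW estimate
#' is recomputed without them and a two-sided simulation p-value for the
#' relative change `(b_raw - b_corrected) / b_corrected` is reported
#' (distortion test). The smallest attainable p-value is
#' `1 / (nSim + 1)`.
#'
#' @param h [HarmonizedSet-class] with at least four variants.
#' @param nSim number of simulated replicates (default 1000, minimum 100).
#' @param outlierAlpha significance level for the adjusted outlier test
#'   (default 0.05).
#' @param seed RNG seed (mandatory).
#' @param model IVW model for the raw/corrected estimates.
#' @return A [PressoResult-class].
#' @export
mrPresso <- function(h, nSim = 1000L, outlierAlpha = 0.05, seed,
                     model = "multiplicative_random") {
  k <- nVariants(h)
  if (k < 4) stop("MR-PRESSO requires >= 4 variants")
  if (nSim < 100) stop("nSim must be >= 100")
  bx <- h@betaX; by <- h@betaY
  w <- 1 / h@seY^2

  b_loo <- drop(.loo_slopes(cbind(bx), cbind(by), w))
  d_obs <- by - b_loo * bx
  rss_obs <- sum(w * d_obs^2)

  sim <- .with_seed(seed, {
    X <- matrix(rnorm(k * nSim, h@betaX, h@seX), nrow = k)
    Y <- matrix(rnorm(k * nSim, b_loo * bx, h@seY), nrow = k)
    list(X = X, Y = Y)
  })
  b_loo_sim <- .loo_slopes(sim$X, sim$Y, w)
  D <- sim$Y - b_loo_sim * sim$X
  rss_sim <- colSums(w * D^2)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (nSim + 1)
  exceed <- rowSums(D^2 >= d_obs^2)
  p_var <- pmin(1, k * (1 + exceed) / (nSim + 1))
  names(p_var) <- h@variantId

  outliers <- h@variantId[p_var < outlierAlpha]
  b_raw <- mrIvw(h, model)
  b_corr <- NULL
  distortion_p <- NA_real_
  if (length(outliers) == k)
    stop("no variants remain after outlier removal")
  if (length(outliers) > 0) {
    keep <- !(h@variantId %in% outliers)
    b_corr <- mrIvw(.h_subset(h, which(keep)), model)
    dist_obs <- (b_raw@b - b_corr@b) / b_corr@b
    slope_on <- function(X, Y, idx) {
      colSums(w[idx] * X[idx, , drop = FALSE] * Y[idx, , drop = FALSE]) /
        colSums(w[idx] * X[idx, , drop = FALSE]^2)
    }
    b_raw_sim <- slope_on(sim$X, sim$Y, seq_len(k))
    b_corr_sim <- slope_on(sim$X, sim$Y, which(keep))
    dist_sim <- (b_raw_sim - b_corr_sim) / b_corr_sim
    distortion_p <- (1 + sum(abs(dist_sim) >= abs(dist_obs))) / (nSim + 1)
  }
  new("PressoResult", rssObs = rss_obs, globalPvalue = global_p,
      perVariantPvalues = p_var, outliers = outliers,
      bRaw = b_raw, bCorrected = b_corr, distortionPvalue = distortion_p,
      nSim = as.integer(nSim), seed = as.integer(seed))
}
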