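# Univariable two-sample MR estimator suite.
#
# All estimators consume a HarmonizedSet and return an MREstimate on the
# slope scale (log-odds of outcome per unit exposure for a binary outcome)
# together with the odds-scale conversion. Per-variant ratio estimates are
# theta_j = beta_y_j / beta_x_j with first-order weights
# w_j = beta_x_j^2 / se_y_j^2 (equivalently 1/se(theta_j)^2 ignoring
# exposure noise, the standard two-sample convention).

.ivw_core <- function(bx, by, sey, model = "multiplicative_random") {
  w <- 1 / sey^2
  sxx <- sum(w * bx^2)
  b <- sum(w * bx * by) / sxx
  se0 <- sqrt(1 / sxx)
  k <- length(bx)
  q <- sum(w * (by - b * bx)^2)
  df <- k - 1L
  qp <- if (df > 0) pchisq(q, df, lower.tail = FALSE) else NA_real_
  phi <- if (model == "multiplicative_random" && df > 0) max(1, sqrt(q / df)) else 1
  se <- se0 * phi
  list(b = b, se = se, pvalue = .z_pvalue(b, se), q = q, qPvalue = qp)
}

#' Wald ratio estimate from a single instrument
#'
#' `b = beta_y / beta_x`, first-order `se = se_y / |beta_x|`, two-sided
#' normal p-value.
#'
#' @param h [HarmonizedSet-class] restricted to exactly one variant with a
#'   nonzero exposure effect.
#' @return An [MREstimate-class].
#' @export
waldRatio <- function(h) {
  if (nVariants(h) != 1) stop("waldRatio requires exactly 1 variant")
  if (h@betaX == 0) stop("undefined ratio: exposure effect is zero")
  b <- h@betaY / h@betaX
  se <- h@seY / abs(h@betaX)
  MREstimate("Wald ratio", 1L, b, se, .z_pvalue(b, se))
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of outcome on exposure effects through the origin
#' with weights `1/se_y^2`:
#' `b = sum(w * bx * by) / sum(w * bx^2)`. Under the default
#' multiplicative random-effects model the base standard error
#' `sqrt(1 / sum(w * bx^2))` is inflated by `max(1, sqrt(Q / (k - 1)))`
#' where `Q` is Cochran's Q at the estimate, so it never shrinks below the
#' fixed-effects value. The p-value is two-sided normal.
#'
#' @param h [HarmonizedSet-class] with at least two variants.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An [MREstimate-class] carrying Q and its p-value.
#' @export
mrIvw <- function(h, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  if (nVariants(h) < 2)
    stop("IVW requires >= 2 variants; use waldRatio() for a single instrument")
  fit <- .ivw_core(h@betaX, h@betaY, h@seY, model)
  MREstimate("Inverse variance weighted", nVariants(h),
             fit$b, fit$se, fit$pvalue, q = fit$q, qPvalue = fit$qPvalue)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with an
#' intercept, weights `1/se_y^2`, after jointly sign-flipping variants so
#' all exposure effects are nonnegative. A nonzero intercept indicates
#' directional horizontal pleiotropy. Slope and intercept standard errors
#' are inflated by `max(1, residual scale)` as in the multiplicative IVW
#' model; the slope p-value is normal, the intercept is tested against a
#' t distribution with `k - 2` degrees of freedom.
#'
#' @param h [HarmonizedSet-class] with at least three variants.
#' @return An [MREstimate-class] carrying the intercept diagnostics.
#' @export
mrEgger <- function(h) {
  k <- nVariants(h)
  if (k < 3) stop("Egger requires >=3 instruments")
  s <- sign(h@betaX)
  s[s == 0] <- 1
  bx <- s * h@betaX
  by <- s * h@betaY
  w <- 1 / h@seY^2
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * bx); swx2 <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swx2 - swx^2
  a <- (swx2 * swy - swx * swxy) / det
  b <- (sw * swxy - swx * swy) / det
  rss <- sum(w * (by - a - b * bx)^2)
  phi <- max(1, sqrt(rss / (k - 2)))
  se_b <- phi * sqrt(sw / det)
  se_a <- phi * sqrt(swx2 / det)
  q <- rss
  qp <- pchisq(q, k - 2, lower.tail = FALSE)
  MREstimate("MR Egger", k, b, se_b, .z_pvalue(b, se_b),
             q = q, qPvalue = qp,
             eggerIntercept = a, eggerInterceptSe = se_a,
             eggerInterceptPvalue = 2 * pt(-abs(a / se_a), df = k - 2))
}

# Weighted median of ratio estimates by interpolation of the standardized
# midpoint cumulative weights at 0.5.
.wm_point <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  ww <- w[o]
  s <- (cumsum(ww) - ww / 2) / sum(ww)
  if (0.5 <= s[1]) return(th[1])
  if (0.5 >= s[length(s)]) return(th[length(th)])
  approx(s, th, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap SE over resampled (beta_x, beta_y).
.boot_se <- function(h, point_fun, nBoot, seed) {
  if (nBoot <= 0) return(NA_real_)
  k <- nVariants(h)
  .with_seed(seed, {
    reps <- vapply(seq_len(nBoot), function(i) {
      bx <- rnorm(k, h@betaX, h@seX)
      by <- rnorm(k, h@betaY, h@seY)
      point_fun(bx, by)
    }, numeric(1))
    sd(reps)
  })
}

#' Weighted median estimate
#'
#' Per-variant ratio estimates `theta_j = beta_y_j / beta_x_j` with
#' weights `w_j = beta_x_j^2 / se_y_j^2` are sorted and the estimate is
#' the linear interpolation of theta at standardized midpoint cumulative
#' weight 0.5. Consistent when over half the weight comes from valid
#' instruments. The standard error is the standard deviation of the
#' estimate over `nBoot` seeded parametric bootstrap replicates.
#'
#' @param h [HarmonizedSet-class] with at least three variants.
#' @param nBoot bootstrap replicates (default 1000; 0 skips the SE).
#' @param seed RNG seed for the bootstrap (mandatory).
#' @return An [MREstimate-class].
#' @export
weightedMedian <- function(h, nBoot = 1000L, seed) {
  if (nVariants(h) < 3) stop("weighted median requires >= 3 variants")
  point <- function(bx, by) .wm_point(by / bx, bx^2 / h@seY^2)
  b <- point(h@betaX, h@betaY)
  se <- .boot_se(h, point, nBoot, seed)
  p <- if (is.na(se)) NA_real_ else .z_pvalue(b, se)
  MREstimate("Weighted median", nVariants(h), b, se, p)
}

# Mode of the kernel-smoothed ratio density on a fixed grid.
.mode_point <- function(theta, w, phi, gridN = 512L) {
  k <- length(theta)
  spread <- min(sd(theta), IQR(theta) / 1.349)
  if (spread == 0) spread <- sd(theta)          # IQR can degenerate with ties
  if (spread == 0) return(theta[1])             # all ratios identical
  bw <- phi * 0.9 * spread * k^(-1 / 5)
  grid <- seq(min(theta) - 3 * bw, max(theta) + 3 * bw, length.out = gridN)
  dens <- vapply(grid, function(g) sum(w * dnorm(g, theta, bw)), numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' Forms a Gaussian kernel density over the per-variant ratio estimates
#' (bandwidth `phi * 0.9 * min(sd, IQR/1.349) * k^(-1/5)`) and takes the
#' argmax over a 512-point grid spanning the ratios plus three bandwidths;
#' the causal estimate comes from the largest cluster of agreeing
#' instruments. `weighted = FALSE` uses uniform weights (simple mode),
#' `weighted = TRUE` weights each ratio by its inverse variance. The SE is
#' a seeded parametric bootstrap as in [weightedMedian()].
#'
#' @param h [HarmonizedSet-class] with at least three variants.
#' @param weighted use inverse-variance weights (default `TRUE`).
#' @param phi bandwidth factor (default 1).
#' @param nBoot bootstrap replicates (default 1000; 0 skips the SE).
#' @param seed RNG seed for the bootstrap (mandatory).
#' @return An [MREstimate-class].
#' @export
modeEstimate <- function(h, weighted = TRUE, phi = 1, nBoot = 1000L, seed) {
  if (nVariants(h) < 3) stop("mode estimate requires >= 3 variants")
  weights_for <- function(bx) {
    if (weighted) {
      w <- bx^2 / h@seY^2
      w / sum(w)
    } else rep(1 / length(bx), length(bx))
  }
  point <- function(bx, by) .mode_point(by / bx, weights_for(bx), phi)
  b <- point(h@betaX, h@betaY)
  se <- .boot_se(h, point, nBoot, seed)
  p <- if (is.na(se)) NA_real_ else .z_pvalue(b, se)
  MREstimate(if (weighted) "Weighted mode" else "Simple mode",
             nVariants(h), b, se, p)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j * (theta_j - b)^2)` over ratio estimates with weights
#' `w_j = beta_x_j^2 / se_y_j^2`, referred to a chi-square with `k - 1`
#' degrees of freedom.
#'
#' @param h [HarmonizedSet-class] with at least two variants.
#' @param b causal estimate at which to evaluate heterogeneity.
#' @return list with `q`, `df`, `pvalue`.
#' @export
cochranQ <- function(h, b) {
  k <- nVariants(h)
  if (k < 2) stop("Cochran's Q requires >= 2 variants")
  theta <- h@betaY / h@betaX
  w <- h@betaX^2 / h@seY^2
  q <- sum(w * (theta - b)^2)
  list(q = q, df = k - 1L, pvalue = pchisq(q, k - 1, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate excluding each variant in turn; a stable
#' set of estimates indicates that no single instrument drives the
#' result.
#'
#' @param h [HarmonizedSet-class] with at least three variants.
#' @param model IVW model passed through to [mrIvw()].
#' @return `data.frame` with one row per excluded variant plus a final
#'   `"(full)"` row: columns `excluded`, `n_snp`, `b`, `se`, `pvalue`.
#' @export
leaveOneOut <- function(h, model = "multiplicative_random") {
  k <- nVariants(h)
  if (k < 3) stop("leave-one-out requires >= 3 variants")
  rows <- lapply(seq_len(k), function(j) {
    e <- mrIvw(.h_subset(h, -j), model)
    data.frame(excluded = h@variantId[j], n_snp = e@nSnp,
               b = e@b, se = e@se, pvalue = e@pvalue)
  })
  full <- mrIvw(h, model)
  rbind(do.call(rbind, rows),
        data.frame(excluded = "(full)", n_snp = full@nSnp,
                   b = full@b, se = full@se, pvalue = full@pvalue))
}

#' Full estimator suite in published table layout
#'
#' Runs IVW (multiplicative random effects), MR-Egger, weighted median,
#' weighted mode and simple mode on the same harmonized set, attaches the
#' IVW heterogeneity p-value and the Egger intercept p-value, and formats
#' the published table columns (`Method`, `nsnp`, `b`, `se`, `pval`, `or`,
#' `or_lci95`, `or_uci95`, `P-heterogeneity`, `P-pleiotropy`).
#'
#' @param h [HarmonizedSet-class] with at least three variants.
#' @param seed RNG seed for the bootstrap standard errors.
#' @param nBoot bootstrap replicates for median/mode SEs (default 1000).
#' @return An [MRResultTable-class].
#' @export
mrSummary <- function(h, seed, nBoot = 1000L) {
  if (nVariants(h) < 3) stop("mrSummary requires >= 3 variants")
  ests <- list(
    mrIvw(h, "multiplicative_random"),
    mrEgger(h),
    weightedMedian(h, nBoot = nBoot, seed = seed),
    modeEstimate(h, weighted = TRUE, nBoot = nBoot, seed = seed + 1L),
    modeEstimate(h, weighted = FALSE, nBoot = nBoot, seed = seed + 2L))
  tab <- do.call(rbind, lapply(ests, function(e)
    data.frame(Method = e@method, nsnp = e@nSnp, b = e@b, se = e@se,
               pval = e@pvalue, or = e@orval, or_lci95 = e@orLo,
               or_uci95 = e@orHi,
               `P-heterogeneity` = e@qPvalue,
               `P-pleiotropy` = e@eggerInterceptPvalue,
               check.names = FALSE)))
  new("MRResultTable", estimates = ests, table = tab)
}
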