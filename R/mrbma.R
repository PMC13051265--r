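# Multivariable MR via Bayesian model averaging.
#
# Candidate risk factors (e.g. correlated metabolites) enter a weighted
# multivariable regression of instrument-outcome effects on the matrix of
# instrument-factor effects. Every subset of factors up to a maximum size
# is scored by its marginal likelihood under a conjugate normal prior on
# the scaled coefficients with the residual variance profiled out under
# the reference prior p(sigma^2) proportional to 1/sigma^2:
#
#   log ML(S) = -|S| * log(tau) - 0.5 * log det(X'X + I/tau^2)
#               - (n/2) * log(y'y - y'X (X'X + I/tau^2)^{-1} X'y) + const
#
# on the inverse-variance-weighted scale (rows divided by se_y), with
# tau = priorSd. The model prior is independent inclusion with
# probability priorInclusion per factor; the empty (intercept-free null)
# model is part of the enumeration so that null data return each factor's
# marginal inclusion probability to its prior.

.bma_logml <- function(X, y, tau) {
  n <- length(y)
  yty <- sum(y^2)
  # floor the profiled RSS: an exactly-fitting (or all-zero) outcome would
  # send the marginal likelihood to infinity; the common floor cancels in
  # the normalization, so tied models fall back to their priors
  if (is.null(X) || ncol(X) == 0)
    return(-(n / 2) * log(max(yty, 1e-300)))
  m <- ncol(X)
  A <- crossprod(X) + diag(m) / tau^2
  Xy <- crossprod(X, y)
  bhat <- solve(A, Xy)
  rss <- max(yty - sum(Xy * bhat), 1e-300)
  cholA <- chol(A)
  logdet <- 2 * sum(log(diag(cholA)))
  list(logml = -m * log(tau) - 0.5 * logdet - (n / 2) * log(rss),
       bhat = drop(bhat))
}

#' Bayesian model averaging for multivariable MR
#'
#' Exhaustively enumerates factor subsets of size 0 to `maxModelSize`,
#' scores each by model prior times marginal likelihood, and reports each
#' factor's marginal inclusion probability (MIP; the summed posterior of
#' all models containing it) and model-averaged causal effect (MACE; the
#' posterior-weighted mean of its conditional posterior-mean coefficient,
#' zero in models excluding it).
#'
#' @param betaX instruments-by-factors matrix of instrument-factor
#'   effects (column names become factor names).
#' @param betaY instrument-outcome effects.
#' @param seY outcome standard errors (strictly positive).
#' @param priorInclusion prior inclusion probability per factor (default
#'   0.1).
#' @param priorSd prior SD of scaled causal effects (default 0.5).
#' @param maxModelSize largest subset enumerated (default: all factors).
#' @return A [BMAResult-class].
#' @export
bmaFit <- function(betaX, betaY, seY, priorInclusion = 0.1, priorSd = 0.5,
                   maxModelSize = ncol(betaX)) {
  betaX <- as.matrix(betaX)
  d <- ncol(betaX)
  if (d > 15)
    stop("more than 15 factors: pre-screen candidates before enumeration ",
         "(stochastic model search is out of scope)")
  stopifnot(nrow(betaX) == length(betaY), length(betaY) == length(seY),
            all(seY > 0), maxModelSize <= d)
  nms <- colnames(betaX)
  if (is.null(nms)) nms <- paste0("factor", seq_len(d))
  y <- betaY / seY
  X <- betaX / seY

  subsets <- list(integer(0))
  for (m in seq_len(maxModelSize))
    subsets <- c(subsets, combn(d, m, simplify = FALSE))
  scores <- lapply(subsets, function(S) {
    fit <- .bma_logml(if (length(S)) X[, S, drop = FALSE] else NULL, y, priorSd)
    logml <- if (is.list(fit)) fit$logml else fit
    lprior <- length(S) * log(priorInclusion) +
      (d - length(S)) * log(1 - priorInclusion)
    list(lpost = logml + lprior,
         bhat = if (is.list(fit)) fit$bhat else numeric(0))
  })
  lpost <- vapply(scores, `[[`, numeric(1), "lpost")
  post <- exp(lpost - .logsumexp(lpost))
  post <- post / sum(post)

  mip <- numeric(d)
  mace <- numeric(d)
  for (i in seq_along(subsets)) {
    S <- subsets[[i]]
    if (length(S)) {
      mip[S] <- mip[S] + post[i]
      mace[S] <- mace[S] + post[i] * scores[[i]]$bhat
    }
  }
  model_names <- vapply(subsets, function(S)
    if (length(S)) paste(nms[S], collapse = ",") else "(none)", character(1))
  new("BMAResult",
      modelPosteriors = setNames(post, model_names),
      mip = setNames(mip, nms), mace = setNames(mace, nms),
      permPvalues = setNames(rep(NA_real_, d), nms),
      priorInclusion = priorInclusion, priorSd = priorSd)
}

#' Permutation p-values for marginal inclusion probabilities
#'
#' Jointly permutes the outcome rows (`betaY`, `seY`) `nPerm` times,
#' refits the model averaging each time, and reports the add-one
#' exceedance fraction of permuted MIPs at or above the observed MIP for
#' each factor. The smallest attainable p-value is `1 / (nPerm + 1)`.
#'
#' @inheritParams bmaFit
#' @param nPerm number of permutations (default 1000, minimum 100).
#' @param seed RNG seed (mandatory).
#' @return A [BMAResult-class] equal to the observed fit with
#'   `permPvalues` filled in.
#' @export
bmaPermutation <- function(betaX, betaY, seY, nPerm = 1000L, seed,
                           priorInclusion = 0.1, priorSd = 0.5,
                           maxModelSize = ncol(as.matrix(betaX))) {
  if (nPerm < 100) stop("nPerm must be >= 100")
  obs <- bmaFit(betaX, betaY, seY, priorInclusion, priorSd, maxModelSize)
  k <- length(betaY)
  exceed <- rep(0L, length(obs@mip))
  .with_seed(seed, {
    for (r in seq_len(nPerm)) {
      idx <- sample.int(k)
      fit <- bmaFit(betaX, betaY[idx], seY[idx], priorInclusion, priorSd,
                    maxModelSize)
      exceed <- exceed + as.integer(fit@mip >= obs@mip)
    }
  })
  p <- (1 + exceed) / (nPerm + 1)
  initialize(obs, permPvalues = setNames(p, names(obs@mip)))
}
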