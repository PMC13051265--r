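# Colocalization by approximate Bayes factors.
#
# Enumerates single-causal-variant configurations for two traits over a
# region and weighs them with per-variant priors: H0 no association, H1/H2
# one trait only, H3 two distinct causal variants, H4 a single shared one.
# Everything is computed in log space; the per-variant log approximate
# Bayes factor for trait t is
#   0.5 * log(se^2 / (se^2 + W_t)) + 0.5 * z^2 * W_t / (se^2 + W_t)
# with z = beta / se and W_t the prior variance of a true effect.

.labf <- function(beta, se, W) {
  z2 <- (beta / se)^2
  r <- W / (se^2 + W)
  0.5 * log1p(-r) + 0.5 * z2 * r
}

#' Colocalization of two traits in one region
#'
#' Tests whether two traits share a single causal variant in a region from
#' summary statistics alone, assuming at most one causal variant per trait.
#' Variants are matched by identifier; both traits must cover the same
#' (harmonized) variant set. Priors are per-variant probabilities of a
#' causal variant for trait 1 only (`p1`), trait 2 only (`p2`), or both
#' (`p12`). Prior effect variances default to `0.15^2` for quantitative
#' and `0.2^2` for binary traits.
#'
#' @param trait1,trait2 regional [SummaryStats-class] objects.
#' @param p1,p2,p12 per-variant priors (defaults 1e-4, 1e-4, 1e-5).
#' @param W1,W2 prior effect variances; `NULL` picks the default by trait
#'   type.
#' @return A [ColocResult-class] with posterior probabilities `PP.H0` ..
#'   `PP.H4` summing to one.
#' @export
colocAbf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                     W1 = NULL, W2 = NULL) {
  default_W <- function(s) if (s@traitType == "binary") 0.2^2 else 0.15^2
  if (is.null(W1)) W1 <- default_W(trait1)
  if (is.null(W2)) W2 <- default_W(trait2)
  ids <- intersect(trait1@data$variant_id, trait2@data$variant_id)
  if (length(ids) < 2) stop("region too small: need >= 2 shared variants")
  d1 <- trait1@data[match(ids, trait1@data$variant_id), ]
  d2 <- trait2@data[match(ids, trait2@data$variant_id), ]

  l1 <- .labf(d1$beta, d1$se, W1)
  l2 <- .labf(d2$beta, d2$se, W2)
  lS1 <- .logsumexp(l1)
  lS2 <- .logsumexp(l2)
  lS12 <- .logsumexp(l1 + l2)

  lH0 <- 0
  lH1 <- log(p1) + lS1
  lH2 <- log(p2) + lS2
  lH4 <- log(p12) + lS12
  # sum over ordered pairs j != k, computed as S1*S2 - S12 in log space
  delta <- lS12 - (lS1 + lS2)
  lH3 <- if (delta >= 0) -Inf else log(p1) + log(p2) + lS1 + lS2 + log1p(-exp(delta))

  l <- c(lH0, lH1, lH2, lH3, lH4)
  pp <- exp(l - .logsumexp(l))
  pp <- pp / sum(pp)
  new("ColocResult",
      pp = setNames(pp, c("PP.H0", "PP.H1", "PP.H2", "PP.H3", "PP.H4")),
      nVariants = length(ids),
      priors = setNames(c(p1, p2, p12), c("p1", "p2", "p12")),
      priorVariances = setNames(c(W1, W2), c("W1", "W2")))
}
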