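# Cross-cohort allele harmonization.
#
# Two-sample MR requires every variant's effects to refer to the same
# effect allele in all cohorts. Relative to the exposure orientation a
# second cohort's alleles can be identical, swapped (sign flip), on the
# opposite strand (complement), or both. Palindromic variants (A/T, C/G)
# cannot be resolved from allele letters alone and are handled by policy.

# Classify each row of `oth` against the exposure orientation.
# Returns a character vector: "keep", "flip", or "drop:<reason>".
.align_actions <- function(ea_x, oa_x, eaf_x, ea_o, oa_o, eaf_o,
                           policy, tol) {
  n <- length(ea_x)
  same <- ea_o == ea_x & oa_o == oa_x
  swap <- ea_o == oa_x & oa_o == ea_x
  csame <- ea_o == .complement(ea_x) & oa_o == .complement(oa_x)
  cswap <- ea_o == .complement(oa_x) & oa_o == .complement(ea_x)
  pal <- .is_palindromic(ea_x, oa_x)

  action <- rep("drop:allele mismatch", n)
  keepable <- !pal & (same | csame)
  flippable <- !pal & (swap | cswap)
  action[keepable] <- "keep"
  action[flippable] <- "flip"

  pal_match <- pal & (same | swap | csame | cswap)
  if (policy == "drop") {
    action[pal_match] <- "drop:palindromic"
  } else {
    # infer_by_eaf: orient by matching minor allele; ambiguous near 0.5.
    informative <- pal_match & !is.na(eaf_x) & !is.na(eaf_o) &
      abs(eaf_x - 0.5) > tol & abs(eaf_o - 0.5) > tol
    agree <- (eaf_x < 0.5) == (eaf_o < 0.5)
    action[pal_match] <- "drop:ambiguous palindrome"
    action[informative & agree] <- "keep"
    action[informative & !agree] <- "flip"
  }
  action
}

#' Harmonize summary statistics onto the exposure allele orientation
#'
#' Matches variants by identifier across the exposure and one or two other
#' cohorts and aligns every shared variant to the exposure's effect allele:
#' swapped alleles negate the other cohort's effect and reflect its
#' frequency (`eaf -> 1 - eaf`); strand complements are complemented first;
#' irreconcilable allele pairs are dropped with reason `"allele mismatch"`.
#' Palindromic variants are dropped outright under `palindromePolicy =
#' "drop"`, or aligned by matching minor alleles under `"infer_by_eaf"`
#' when both frequencies lie outside `0.5 +/- eafTolerance` (otherwise
#' dropped as `"ambiguous palindrome"`). Variants absent from any cohort
#' are dropped with a reason naming the cohort. The operation is
#' idempotent: harmonizing already-aligned inputs changes nothing.
#'
#' @param exposure [SummaryStats-class] for the exposure; defines the
#'   reference orientation and the output variant order.
#' @param outcome [SummaryStats-class] for the outcome.
#' @param mediator optional [SummaryStats-class] for a mediator trait.
#' @param palindromePolicy `"infer_by_eaf"` (default) or `"drop"`.
#' @param eafTolerance half-width of the ambiguous frequency zone around
#'   0.5 used by `"infer_by_eaf"` (default 0.08).
#' @return A [HarmonizedSet-class]; excluded variants are listed in
#'   `droppedVariants()` with reasons.
#' @examples
#' ex <- SummaryStats(data.frame(variant_id = "rs1", chrom = "1", pos = 1L,
#'   ea = "A", oa = "G", eaf = 0.3, beta = 0.10, se = 0.01, pvalue = 1e-8,
#'   n = 1e5), "exposure")
#' out <- SummaryStats(data.frame(variant_id = "rs1", chrom = "1", pos = 1L,
#'   ea = "G", oa = "A", eaf = 0.3, beta = -0.05, se = 0.02, pvalue = 0.01,
#'   n = 1e5), "outcome", "binary")
#' h <- harmonize(ex, out)
#' betaY(h)  # +0.05 after the allele swap
#' @export
harmonize <- function(exposure, outcome, mediator = NULL,
                      palindromePolicy = c("infer_by_eaf", "drop"),
                      eafTolerance = 0.08) {
  palindromePolicy <- match.arg(palindromePolicy)
  ex <- exposure@data
  others <- list(outcome = outcome@data)
  if (!is.null(mediator)) others$mediator <- mediator@data

  drop_log <- .empty_drop_log()
  shared <- ex$variant_id
  for (nm in names(others)) {
    absent <- setdiff(shared, others[[nm]]$variant_id)
    drop_log <- .log_drop(drop_log, absent, paste("absent from", nm))
    shared <- setdiff(shared, absent)
  }
  if (length(shared) == 0)
    stop("no shared variants between exposure and other cohorts")

  ex <- ex[match(shared, ex$variant_id), , drop = FALSE]
  aligned <- list()
  keep <- rep(TRUE, length(shared))
  for (nm in names(others)) {
    ot <- others[[nm]][match(shared, others[[nm]]$variant_id), , drop = FALSE]
    action <- .align_actions(ex$ea, ex$oa, ex$eaf, ot$ea, ot$oa, ot$eaf,
                             palindromePolicy, eafTolerance)
    flip <- action == "flip"
    ot$beta[flip] <- -ot$beta[flip]
    ot$eaf[flip] <- 1 - ot$eaf[flip]
    bad <- startsWith(action, "drop:")
    drop_log <- .log_drop(drop_log, shared[bad & keep],
                          sub("^drop:", "", action[bad & keep]))
    keep <- keep & !bad
    aligned[[nm]] <- ot
  }

  HarmonizedSet(
    variantId = shared[keep],
    betaX = ex$beta[keep], seX = ex$se[keep],
    betaY = aligned$outcome$beta[keep], seY = aligned$outcome$se[keep],
    betaM = if (is.null(mediator)) numeric(0) else aligned$mediator$beta[keep],
    seM = if (is.null(mediator)) numeric(0) else aligned$mediator$se[keep],
    dropped = drop_log)
}

#' Orient a harmonized set to the inhibition (exposure-lowering) scale
#'
#' Jointly sign-flips each variant's effect tuple so that every exposure
#' effect is nonnegative. For a drug-target instrument whose exposure is a
#' biomarker the drug lowers, this expresses all downstream estimates per
#' one standard-deviation reduction of the biomarker, i.e. per unit of
#' genetically proxied inhibition. Ratio estimators are invariant to the
#' joint per-variant flip, so this is a presentation convention, not a
#' change of estimate. Variants with an exactly zero exposure effect are
#' dropped (reason `"null exposure effect"`).
#'
#' @param h a [HarmonizedSet-class].
#' @return A [HarmonizedSet-class] with all `betaX >= 0`.
#' @export
orientToInhibition <- function(h) {
  null_x <- h@betaX == 0
  dropped <- .log_drop(h@dropped, h@variantId[null_x], "null exposure effect")
  idx <- which(!null_x)
  s <- sign(h@betaX[idx])
  HarmonizedSet(
    variantId = h@variantId[idx],
    betaX = s * h@betaX[idx], seX = h@seX[idx],
    betaY = s * h@betaY[idx], seY = h@seY[idx],
    betaM = if (length(h@betaM)) s * h@betaM[idx] else numeric(0),
    seM = if (length(h@seM)) h@seM[idx] else numeric(0),
    dropped = dropped)
}
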