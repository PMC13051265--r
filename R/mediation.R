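# Metabolite-wide screening and two-step MR mediation.

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Standard step-up q-values: with `m` tests sorted ascending,
#' `q_(i) = min over j >= i of m * p_(j) / j`, capped at one, returned in
#' the original order. Hypotheses with `q <= qMax` are rejected.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param qMax FDR level for the rejection flags (default 0.10).
#' @return list with `q_values` and logical `rejected`, both in input
#'   order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04), qMax = 0.05)$rejected  # all TRUE
#' @export
bhFdr <- function(pvalues, qMax = 0.10) {
  if (length(pvalues) == 0)
    return(list(q_values = numeric(0), rejected = logical(0)))
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  q <- p.adjust(pvalues, method = "BH")
  list(q_values = q, rejected = q <= qMax)
}

#' Metabolite-wide MR screen
#'
#' Estimates one causal effect per metabolite from its harmonized
#' instrument set -- the Wald ratio for a single instrument, IVW
#' (multiplicative random effects) otherwise -- and controls multiplicity
#' across the panel with Benjamini-Hochberg q-values. Two significance
#' rules are supported: `rule = "nominal"` flags `p < alphaNominal`
#' (forest-plot replication mode) and `rule = "fdr"` flags `q <= qMax`.
#' Metabolites with zero harmonized instruments are excluded with a
#' logged message. Rows are returned sorted by p-value.
#'
#' @param hlist named list of [HarmonizedSet-class] objects, one per
#'   metabolite, with the screened trait as outcome.
#' @param direction `"metabolite_to_outcome"` (step 2 of the mediation
#'   design) or `"exposure_to_metabolite"` (step 1).
#' @param alphaNominal nominal significance level (default 0.05).
#' @param qMax FDR level (default 0.10).
#' @param rule which rule feeds the `significant` flag.
#' @return A [ScreenResult-class]; q-values are reported under both
#'   rules.
#' @export
screenPanel <- function(hlist,
                        direction = c("metabolite_to_outcome",
                                      "exposure_to_metabolite"),
                        alphaNominal = 0.05, qMax = 0.10,
                        rule = c("nominal", "fdr")) {
  direction <- match.arg(direction)
  rule <- match.arg(rule)
  if (is.null(names(hlist)) || any(names(hlist) == ""))
    stop("hlist must be a named list of HarmonizedSet objects")
  empty <- vapply(hlist, nVariants, integer(1)) == 0
  if (any(empty)) {
    message("screenPanel: excluded (zero instruments): ",
            paste(names(hlist)[empty], collapse = ", "))
    hlist <- hlist[!empty]
  }
  if (length(hlist) == 0) stop("no metabolite with instruments to screen")
  rows <- do.call(rbind, lapply(names(hlist), function(nm) {
    h <- hlist[[nm]]
    e <- if (nVariants(h) == 1) waldRatio(h) else mrIvw(h)
    data.frame(name = nm, n_snp = nVariants(h), b = e@b, se = e@se,
               pvalue = e@pvalue, or = e@orval, or_lo = e@orLo,
               or_hi = e@orHi)
  }))
  fdr <- bhFdr(rows$pvalue, qMax)
  rows$q_value <- fdr$q_values
  rows$significant <- if (rule == "nominal") rows$pvalue < alphaNominal
                      else fdr$rejected
  rows <- rows[order(rows$pvalue, rows$name), , drop = FALSE]
  rownames(rows) <- NULL
  new("ScreenResult", rows = rows, direction = direction, rule = rule)
}

#' Two-step MR mediation decomposition
#'
#' Product-of-coefficients mediation on the log scale: the indirect
#' (mediated) effect is `beta1 * beta2`, the proportion mediated is the
#' indirect effect divided by the total effect (signed; multiply by 100
#' for percent), and the direct effect is `total - indirect`. When
#' variances of the path estimates are supplied, a first-order
#' delta-method standard error of the indirect effect,
#' `sqrt(beta2^2 * var1 + beta1^2 * var2)`, is attached as an extension
#' beyond the usual summary-data report.
#'
#' @param beta1 exposure-to-mediator effect (log scale).
#' @param beta2 mediator-to-outcome effect (log-odds).
#' @param total total exposure-to-outcome effect (log-odds); must be
#'   nonzero.
#' @param var1,var2 optional variances of `beta1` and `beta2`.
#' @return A [MediationResult-class].
#' @examples
#' m <- twoStepMediation(log(3.01), log(0.79), -1.16)
#' round(100 * m@proportion, 1)  # 22.4
#' @export
twoStepMediation <- function(beta1, beta2, total, var1 = NULL, var2 = NULL) {
  if (total == 0) stop("undefined proportion: total effect is zero")
  indirect <- beta1 * beta2
  se_ind <- if (!is.null(var1) && !is.null(var2))
    sqrt(beta2^2 * var1 + beta1^2 * var2) else NA_real_
  new("MediationResult", beta1 = beta1, beta2 = beta2, total = total,
      beta3Direct = total - indirect, indirect = indirect,
      proportion = indirect / total, seIndirect = se_ind)
}
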