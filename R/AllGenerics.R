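#' Accessors for mrmediate classes
#'
#' Small accessor family used throughout the package instead of direct slot
#' access: `variantIds()` and `nVariants()` work on summary statistics,
#' harmonized sets, LD matrices and instrument sets; `traitName()` and
#' `traitType()` on [SummaryStats-class]; `betaX()`/`seX()`/`betaY()`/
#' `seY()`/`betaM()`/`seM()` and `droppedVariants()` on
#' [HarmonizedSet-class].
#'
#' @param x object.
#' @return `variantIds()` a character vector; `nVariants()` an integer;
#'   effect accessors numeric vectors; `droppedVariants()` a `data.frame`
#'   of `(variant_id, reason)`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))
#' @rdname accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))
#' @rdname accessors
#' @export
setGeneric("betaX", function(x) standardGeneric("betaX"))
#' @rdname accessors
#' @export
setGeneric("seX", function(x) standardGeneric("seX"))
#' @rdname accessors
#' @export
setGeneric("betaY", function(x) standardGeneric("betaY"))
#' @rdname accessors
#' @export
setGeneric("seY", function(x) standardGeneric("seY"))
#' @rdname accessors
#' @export
setGeneric("betaM", function(x) standardGeneric("betaM"))
#' @rdname accessors
#' @export
setGeneric("seM", function(x) standardGeneric("seM"))
#' @rdname accessors
#' @export
setGeneric("hasMediator", function(x) standardGeneric("hasMediator"))
#' @rdname accessors
#' @export
setGeneric("droppedVariants", function(x) standardGeneric("droppedVariants"))
#' @rdname accessors
#' @export
setGeneric("selectionLog", function(x) standardGeneric("selectionLog"))
#' @rdname accessors
#' @export
setGeneric("fStats", function(x) standardGeneric("fStats"))
#' @rdname accessors
#' @export
setGeneric("posteriorProbs", function(x) standardGeneric("posteriorProbs"))
#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname accessors
#' @export
setMethod("variantIds", "SummaryStats", function(x) x@data$variant_id)
#' @rdname accessors
#' @export
setMethod("variantIds", "HarmonizedSet", function(x) x@variantId)
#' @rdname accessors
#' @export
setMethod("variantIds", "LDMatrix", function(x) x@variantIds)
#' @rdname accessors
#' @export
setMethod("variantIds", "InstrumentSet", function(x) x@variantIds)

#' @rdname accessors
#' @export
setMethod("nVariants", "SummaryStats", function(x) nrow(x@data))
#' @rdname accessors
#' @export
setMethod("nVariants", "HarmonizedSet", function(x) length(x@variantId))
#' @rdname accessors
#' @export
setMethod("nVariants", "InstrumentSet", function(x) length(x@variantIds))

#' @rdname accessors
#' @export
setMethod("traitName", "SummaryStats", function(x) x@trait)
#' @rdname accessors
#' @export
setMethod("traitType", "SummaryStats", function(x) x@traitType)

#' @rdname accessors
#' @export
setMethod("betaX", "HarmonizedSet", function(x) x@betaX)
#' @rdname accessors
#' @export
setMethod("seX", "HarmonizedSet", function(x) x@seX)
#' @rdname accessors
#' @export
setMethod("betaY", "HarmonizedSet", function(x) x@betaY)
#' @rdname accessors
#' @export
setMethod("seY", "HarmonizedSet", function(x) x@seY)
#' @rdname accessors
#' @export
setMethod("betaM", "HarmonizedSet", function(x) x@betaM)
#' @rdname accessors
#' @export
setMethod("seM", "HarmonizedSet", function(x) x@seM)
#' @rdname accessors
#' @export
setMethod("hasMediator", "HarmonizedSet", function(x) length(x@betaM) > 0)
#' @rdname accessors
#' @export
setMethod("droppedVariants", "HarmonizedSet", function(x) x@dropped)

#' @rdname accessors
#' @export
setMethod("selectionLog", "InstrumentSet", function(x) x@selectionLog)
#' @rdname accessors
#' @export
setMethod("fStats", "InstrumentSet", function(x) x@fStats)

#' @rdname accessors
#' @export
setMethod("posteriorProbs", "ColocResult", function(x) x@pp)
#' @rdname accessors
#' @export
setMethod("resultTable", "MRResultTable", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("resultTable", "ScreenResult", function(x) x@rows)

#' Coerce a SummaryStats object to a data.frame
#'
#' @param x a [SummaryStats-class] object.
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return the underlying canonical `data.frame`.
#' @export
as.data.frame.SummaryStats <- function(x, row.names = NULL, optional = FALSE, ...) {
  x@data
}

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats '%s' (%s): %d variants\n",
              object@trait, object@traitType, nrow(object@data)))
  if (nrow(object@data)) {
    print(head(object@data, 4))
    if (nrow(object@data) > 4) cat("...\n")
  }
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet: %d variants%s, %d dropped\n",
              length(object@variantId),
              if (length(object@betaM)) " (with mediator)" else "",
              nrow(object@dropped)))
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("%s (nsnp = %d): b = %.4g (se %.4g), p = %.3g, OR %.3g [%.3g, %.3g]\n",
              object@method, object@nSnp, object@b, object@se, object@pvalue,
              object@orval, object@orLo, object@orHi))
  if (!is.na(object@qPvalue))
    cat(sprintf("  Cochran's Q = %.4g (p = %.3g)\n", object@q, object@qPvalue))
  if (!is.na(object@eggerInterceptPvalue))
    cat(sprintf("  Egger intercept = %.4g (p = %.3g)\n",
                object@eggerIntercept, object@eggerInterceptPvalue))
})

setMethod("show", "MRResultTable", function(object) {
  cat("MR estimator suite\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "ColocResult", function(object) {
  cat(sprintf("Colocalization over %d variants\n", object@nVariants))
  print(round(object@pp, 4))
})

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf("InstrumentSet: %d instruments (min F = %.3g)\n",
              length(object@variantIds),
              if (length(object@fStats)) min(object@fStats) else NA))
  print(object@selectionLog, row.names = FALSE)
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO (n_sim = %d): global p = %.4g, %d outlier(s)\n",
              object@nSim, object@globalPvalue, length(object@outliers)))
  if (length(object@outliers)) {
    cat("  outliers:", paste(object@outliers, collapse = ", "), "\n")
    cat(sprintf("  b raw = %.4g, b corrected = %.4g, distortion p = %.4g\n",
                object@bRaw@b, object@bCorrected@b, object@distortionPvalue))
  }
})

setMethod("show", "BMAResult", function(object) {
  cat(sprintf("MR-BMA (prior inclusion %.3g, prior sd %.3g)\n",
              object@priorInclusion, object@priorSd))
  print(data.frame(factor = names(object@mip), mip = round(object@mip, 4),
                   mace = round(object@mace, 4),
                   perm_p = round(object@permPvalues, 4)), row.names = FALSE)
})

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf("Metabolite screen (%s, rule = %s): %d tested, %d significant\n",
              object@direction, object@rule, nrow(object@rows),
              sum(object@rows$significant)))
})

setMethod("show", "MediationResult", function(object) {
  cat("Two-step MR mediation\n")
  cat(sprintf("  beta1 (exposure -> mediator) = %.4g\n", object@beta1))
  cat(sprintf("  beta2 (mediator -> outcome)  = %.4g\n", object@beta2))
  cat(sprintf("  total effect                 = %.4g\n", object@total))
  cat(sprintf("  indirect (beta1*beta2)       = %.4g\n", object@indirect))
  cat(sprintf("  direct (total - indirect)    = %.4g\n", object@beta3Direct))
  cat(sprintf("  proportion mediated          = %.2f%%\n",
              100 * object@proportion))
})

setMethod("show", "TrueParams", function(object) {
  cat(sprintf(paste0("TrueParams: beta1 = %.3g, beta2 = %.3g, direct = %.3g, ",
                     "total = %.3g, proportion mediated = %.3g\n"),
              object@beta1, object@beta2, object@thetaDirect,
              object@totalTrue, object@proportionTrue))
})
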