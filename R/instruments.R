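# Instrument construction: cis-window screen, biomarker filter, greedy LD
# clumping, strength diagnostics and the metabolite selection cascade.

#' Select cis variants around a gene locus
#'
#' Returns variants on `locusChrom` with position inside the closed
#' interval `[locusStart - windowBp, locusEnd + windowBp]` and p-value
#' strictly below `pMax`, ordered by ascending p-value.
#'
#' @param s [SummaryStats-class] carrying positions.
#' @param locusChrom,locusStart,locusEnd gene locus (1-based, inclusive).
#' @param windowBp flanking window in base pairs (default 250 kb).
#' @param pMax p-value threshold, strict `<` (default 1e-3).
#' @return character vector of variant identifiers; empty when nothing
#'   qualifies (caller decides severity).
#' @export
selectCisVariants <- function(s, locusChrom, locusStart, locusEnd,
                              windowBp = 250000L, pMax = 1e-3) {
  stopifnot(windowBp >= 0)
  d <- s@data
  hit <- d$chrom == locusChrom &
    d$pos >= locusStart - windowBp & d$pos <= locusEnd + windowBp &
    d$pvalue < pMax
  hits <- d[hit, , drop = FALSE]
  if (nrow(hits) == 0)
    message("selectCisVariants: no variant passed the cis window/p filter")
  hits$variant_id[order(hits$pvalue, hits$pos)]
}

#' Filter candidate instruments on a biomarker association
#'
#' Retains candidates whose p-value in the biomarker dataset is strictly
#' below `pMax`; candidate order is preserved. Candidates absent from the
#' biomarker dataset are dropped with a logged message.
#'
#' @param candidates character vector of variant identifiers.
#' @param biomarker [SummaryStats-class] of the biomarker trait.
#' @param pMax p-value threshold, strict `<` (default 1e-4).
#' @return character vector of retained identifiers.
#' @export
filterByBiomarker <- function(candidates, biomarker, pMax = 1e-4) {
  stopifnot(length(candidates) > 0)
  idx <- match(candidates, biomarker@data$variant_id)
  absent <- candidates[is.na(idx)]
  if (length(absent))
    message("filterByBiomarker: dropped (absent from biomarker dataset): ",
            paste(absent, collapse = ", "))
  present <- candidates[!is.na(idx)]
  p <- biomarker@data$pvalue[idx[!is.na(idx)]]
  present[p < pMax]
}

#' Greedy LD clumping
#'
#' Repeatedly takes the lowest-p unassigned candidate as an index variant
#' and removes all unassigned candidates within `windowBp` of it whose
#' squared correlation with it exceeds `r2Max` (strict `>`). Pairs within
#' the window but missing from the LD matrix are conservatively treated as
#' r-squared = 1 (removed) and logged. Ties in p-value break by identifier
#' for determinism.
#'
#' @param s [SummaryStats-class] providing p-values and positions.
#' @param ids candidate identifiers (default: all variants of `s`).
#' @param ld [LDMatrix-class] covering the candidates (missing entries
#'   handled as above).
#' @param r2Max removal threshold on r-squared (e.g. 0.8 for a drug-target
#'   cis instrument, 0.001 for genome-wide metabolite instruments).
#' @param windowBp clumping window in base pairs.
#' @return character vector of index variants in selection order.
#' @export
clumpVariants <- function(s, ids = variantIds(s), ld, r2Max, windowBp) {
  d <- s@data[match(ids, s@data$variant_id), , drop = FALSE]
  if (anyNA(d$variant_id)) stop("clumpVariants: candidate absent from summary stats")
  ord <- order(d$pvalue, d$variant_id)
  d <- d[ord, , drop = FALSE]
  n <- nrow(d)
  ld_idx <- match(d$variant_id, ld@variantIds)
  assigned <- rep(FALSE, n)
  index <- character(0)
  for (i in seq_len(n)) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    index <- c(index, d$variant_id[i])
    in_window <- !assigned & d$chrom == d$chrom[i] &
      abs(d$pos - d$pos[i]) <= windowBp
    if (!any(in_window)) next
    j <- which(in_window)
    r2 <- rep(NA_real_, length(j))
    if (!is.na(ld_idx[i]))
      r2 <- ld@r[ld_idx[i], ld_idx[j]]^2
    missing_pair <- is.na(r2)
    if (any(missing_pair)) {
      message("clumpVariants: missing LD for pair(s) with ", d$variant_id[i],
              ": ", paste(d$variant_id[j][missing_pair], collapse = ", "),
              " (treated as r2 = 1)")
      r2[missing_pair] <- 1
    }
    assigned[j[r2 > r2Max]] <- TRUE
  }
  index
}

#' Per-variant instrument strength (F statistics)
#'
#' Computes `F = (beta / se)^2` for each exposure effect and flags strong
#' instruments at the conventional strict `F > fMin` rule.
#'
#' @param h a [HarmonizedSet-class] (exposure effects are used).
#' @param fMin strength threshold (default 10).
#' @return `data.frame` with columns `variant_id`, `f`, `strong`.
#' @examples
#' h <- HarmonizedSet("rs1", betaX = 0.1, seX = 0.025,
#'                    betaY = 0.05, seY = 0.02)
#' fStatistics(h)$f  # 16
#' @export
fStatistics <- function(h, fMin = 10) {
  f <- (h@betaX / h@seX)^2
  data.frame(variant_id = h@variantId, f = f, strong = f > fMin)
}

#' Select genome-wide instruments for a metabolite
#'
#' Clumps the variants reaching the primary genome-wide threshold; if
#' fewer than `minSnps` survive, the selection is redone at the suggestive
#' fallback threshold. The selection log records counts at each step and
#' which threshold was used. Fewer than `minSnps` (but at least one)
#' instruments after the fallback proceeds with a warning; zero is an
#' error.
#'
#' @param s [SummaryStats-class] for the metabolite.
#' @param ld [LDMatrix-class] for clumping.
#' @param pPrimary genome-wide significance threshold (default 5e-8).
#' @param pFallback suggestive threshold used when the primary yields too
#'   few instruments (default 5e-7); must satisfy `pPrimary <= pFallback`.
#' @param minSnps minimum acceptable instrument count (default 3).
#' @param r2Max,windowBp clumping parameters (defaults 0.001 and 10,000 kb).
#' @return An [InstrumentSet-class].
#' @export
selectMetaboliteInstruments <- function(s, ld, pPrimary = 5e-8,
                                        pFallback = 5e-7, minSnps = 3L,
                                        r2Max = 0.001, windowBp = 1e7) {
  stopifnot(pPrimary <= pFallback)
  d <- s@data
  run <- function(thr) {
    cand <- d$variant_id[d$pvalue < thr]
    kept <- if (length(cand)) clumpVariants(s, cand, ld, r2Max, windowBp)
            else character(0)
    list(cand = cand, kept = kept)
  }
  primary <- run(pPrimary)
  used <- "primary"
  sel <- primary
  log <- data.frame(step = c("p_threshold", "clump"),
                    n_in = c(nrow(d), length(primary$cand)),
                    n_out = c(length(primary$cand), length(primary$kept)),
                    note = c(sprintf("p < %g (primary)", pPrimary), ""))
  if (length(primary$kept) < minSnps) {
    fallback <- run(pFallback)
    used <- "fallback"
    sel <- fallback
    log <- rbind(log, data.frame(
      step = c("p_threshold", "clump"),
      n_in = c(nrow(d), length(fallback$cand)),
      n_out = c(length(fallback$cand), length(fallback$kept)),
      note = c(sprintf("p < %g (fallback)", pFallback), "")))
  }
  kept <- sel$kept
  if (length(kept) == 0)
    stop("no valid instruments for '", s@trait, "' even at the fallback threshold")
  if (length(kept) < minSnps)
    warning("only ", length(kept), " instrument(s) for '", s@trait,
            "' after fallback; proceeding (Wald/IVW still defined)")
  log <- rbind(log, data.frame(step = "threshold_used", n_in = length(kept),
                               n_out = length(kept), note = used))
  sub <- d[match(kept, d$variant_id), , drop = FALSE]
  f <- setNames((sub$beta / sub$se)^2, kept)
  new("InstrumentSet", variantIds = kept,
      stats = SummaryStats(sub, trait = s@trait, traitType = s@traitType),
      fStats = f, selectionLog = log)
}
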