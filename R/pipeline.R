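# Config-driven pipeline: drug-target instrument construction with a
# colocalization gate, exposure-outcome MR with the full estimator suite
# and MR-PRESSO, two-directional metabolite screening, optional MR-BMA on
# survivors, and the two-step mediation computation, with every stage
# written as delimited text plus a run manifest.

.default_pipeline_config <- function() {
  list(
    instruments = list(window_kb = 250, p_cis = 1e-3, p_biomarker = 1e-4,
                       clump_kb = 250, clump_r2 = 0.8, pp_h4_min = 0.70,
                       f_min = 10),
    metabolite_instruments = list(p_primary = 5e-8, p_fallback = 5e-7,
                                  min_snps = 3, clump_kb = 10000,
                                  clump_r2 = 0.001),
    estimators = list(n_boot = 1000, palindrome_policy = "infer_by_eaf",
                      eaf_tolerance = 0.08),
    screening = list(alpha_nominal = 0.05, q_max = 0.10),
    coloc = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
    presso = list(n_sim = 1000, outlier_alpha = 0.05),
    bma = list(prior_inclusion = 0.1, prior_sd = 0.5, n_perm = 0))
}

.merge_config <- function(user, defaults) {
  for (nm in names(defaults)) {
    if (is.null(user[[nm]])) user[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      user[[nm]] <- .merge_config(user[[nm]], defaults[[nm]])
  }
  user
}

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML with required keys `seed`, `exposure.path`,
#' `outcome.path`, `metabolites` (list of `name`/`path` entries), `ld`
#' and `locus` (`chrom`/`start`/`end`), an optional `biomarker.path`, and
#' optional threshold blocks (`instruments`, `metabolite_instruments`,
#' `estimators`, `screening`, `coloc`, `presso`, `bma`) that are filled
#' with package defaults where absent. Validation of key presence,
#' numeric ranges and path existence happens here, before any
#' computation.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return validated config list.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  for (key in c("seed", "exposure", "outcome", "metabolites", "ld", "locus"))
    if (is.null(config[[key]]))
      stop("fatal configuration error: missing key '", key, "'")
  config <- .merge_config(config, .default_pipeline_config())
  config$seed <- as.integer(config$seed)
  paths <- c(config$exposure$path, config$outcome$path, config$ld,
             config$biomarker$path,
             vapply(config$metabolites, `[[`, character(1), "path"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("fatal configuration error: missing input file(s): ",
         paste(missing, collapse = ", "))
  for (met in config$metabolites)
    if (is.null(met$name) || is.null(met$path))
      stop("fatal configuration error: each metabolite needs 'name' and 'path'")
  with(config$locus, stopifnot(start <= end))
  stopifnot(config$instruments$pp_h4_min >= 0,
            config$instruments$pp_h4_min <= 1,
            config$screening$alpha_nominal > 0,
            config$metabolite_instruments$p_primary <=
              config$metabolite_instruments$p_fallback)
  config
}

.plog <- function(state, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  message(line)
  cat(line, "\n", file = state$log_path, append = TRUE)
}

#' Run the full drug-target MR mediation pipeline
#'
#' Executes, in order: drug-target instrument construction (cis-window
#' and p-value screen, optional biomarker filter and colocalization gate,
#' greedy LD clumping, F statistics), exposure-outcome MR (five-estimator
#' table, leave-one-out, MR-PRESSO), metabolite screening in both
#' directions (metabolite to outcome across the panel with BH q-values,
#' then exposure to the surviving metabolites), optional MR-BMA when two
#' or more metabolites survive, and the two-step mediation computation
#' for metabolites significant in both screens. All stage tables, a
#' selection log and a run manifest (config, seed, versions) are written
#' to `outDir`; reruns with the same config produce byte-identical
#' numeric tables. A failed colocalization gate (`PP.H4 <=
#' pp_h4_min`) halts the pipeline with an "instrument not colocalized"
#' error.
#'
#' @param config YAML path or config list, see [readPipelineConfig()].
#' @param outDir output directory (default `out_dir` from the config,
#'   else `"mr_report"`).
#' @return invisibly, a list with the stage results and `out_dir`.
#' @export
runPipeline <- function(config, outDir = NULL) {
  config <- readPipelineConfig(config)
  if (is.null(outDir)) outDir <- config$out_dir %||% "mr_report"
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  state <- list(log_path = file.path(outDir, "pipeline.log"))
  cat("", file = state$log_path)
  seed <- config$seed

  exposure <- readSumstats(config$exposure$path, trait = "exposure",
                           traitType = config$exposure$trait_type %||%
                             "quantitative")
  outcome <- readSumstats(config$outcome$path, trait = "outcome",
                          traitType = config$outcome$trait_type %||% "binary")
  biomarker <- if (!is.null(config$biomarker$path))
    readSumstats(config$biomarker$path, trait = "biomarker") else NULL
  ld <- readLDMatrix(config$ld)
  mets <- lapply(config$metabolites, function(m)
    readSumstats(m$path, trait = m$name))
  names(mets) <- vapply(config$metabolites, `[[`, character(1), "name")
  .plog(state, sprintf("loaded %d exposure, %d outcome variants, %d metabolite(s)",
                       nVariants(exposure), nVariants(outcome), length(mets)))

  ## Stage 1: drug-target instrument construction
  ins <- config$instruments
  sel_log <- data.frame(step = "input", n_in = nVariants(exposure),
                        n_out = nVariants(exposure), note = "")
  cis <- selectCisVariants(exposure, config$locus$chrom, config$locus$start,
                           config$locus$end, ins$window_kb * 1000, ins$p_cis)
  sel_log <- rbind(sel_log, data.frame(
    step = "cis_window", n_in = nVariants(exposure), n_out = length(cis),
    note = sprintf("+/-%d kb, p < %g", ins$window_kb, ins$p_cis)))
  if (length(cis) == 0) stop("no cis variant passed the exposure screen")
  coloc <- NULL
  if (!is.null(biomarker)) {
    filtered <- filterByBiomarker(cis, biomarker, ins$p_biomarker)
    sel_log <- rbind(sel_log, data.frame(
      step = "biomarker_filter", n_in = length(cis), n_out = length(filtered),
      note = sprintf("p < %g", ins$p_biomarker)))
    coloc <- colocAbf(subsetVariants(exposure, cis), subsetVariants(biomarker, cis),
                      p1 = config$coloc$p1, p2 = config$coloc$p2,
                      p12 = config$coloc$p12)
    .plog(state, sprintf("coloc gate: PP.H4 = %.4f", coloc@pp["PP.H4"]))
    if (coloc@pp["PP.H4"] <= ins$pp_h4_min)
      stop(sprintf("instrument not colocalized: PP.H4 = %.4f <= %.2f",
                   coloc@pp["PP.H4"], ins$pp_h4_min))
    cis <- filtered
  } else {
    .plog(state, "no biomarker dataset: biomarker filter and coloc gate skipped")
  }
  instruments <- clumpVariants(exposure, cis, ld, ins$clump_r2,
                               ins$clump_kb * 1000)
  sel_log <- rbind(sel_log, data.frame(
    step = "clump", n_in = length(cis), n_out = length(instruments),
    note = sprintf("kb = %d, r2 = %g", ins$clump_kb, ins$clump_r2)))
  .plog(state, sprintf("instrument construction: %d SNP(s) selected",
                       length(instruments)))

  ## Stage 2: exposure -> outcome MR
  est <- config$estimators
  h_xy <- orientToInhibition(harmonize(
    subsetVariants(exposure, instruments), outcome,
    palindromePolicy = est$palindrome_policy,
    eafTolerance = est$eaf_tolerance))
  fstat <- fStatistics(h_xy, fMin = ins$f_min)
  weak <- fstat$variant_id[!fstat$strong]
  if (length(weak))
    .plog(state, paste("weak instrument(s) F <=", ins$f_min, ":",
                       paste(weak, collapse = ", ")))
  table1 <- mrSummary(h_xy, seed = seed, nBoot = est$n_boot)
  total_est <- table1@estimates[[1]]
  loo <- leaveOneOut(h_xy)
  presso <- if (nVariants(h_xy) >= 4)
    mrPresso(h_xy, nSim = config$presso$n_sim,
             outlierAlpha = config$presso$outlier_alpha, seed = seed + 10L)
    else NULL
  .plog(state, sprintf("exposure->outcome IVW: b = %.4f (se %.4f), OR = %.3f",
                       total_est@b, total_est@se, total_est@orval))

  ## Stage 3: metabolite -> outcome screen across the panel
  mi <- config$metabolite_instruments
  met_sets <- list()
  h_my <- list()
  for (nm in names(mets)) {
    iset <- tryCatch(
      selectMetaboliteInstruments(mets[[nm]], ld, mi$p_primary, mi$p_fallback,
                                  mi$min_snps, mi$clump_r2, mi$clump_kb * 1000),
      error = function(e) {
        .plog(state, sprintf("metabolite '%s' excluded: %s", nm,
                             conditionMessage(e)))
        NULL
      })
    if (is.null(iset)) next
    met_sets[[nm]] <- iset
    h_my[[nm]] <- harmonize(subsetVariants(mets[[nm]], variantIds(iset)), outcome,
                            palindromePolicy = est$palindrome_policy,
                            eafTolerance = est$eaf_tolerance)
  }
  if (length(h_my) == 0) stop("no metabolite with valid instruments")
  screen1 <- screenPanel(h_my, "metabolite_to_outcome",
                         alphaNominal = config$screening$alpha_nominal,
                         qMax = config$screening$q_max, rule = "nominal")
  survivors <- screen1@rows$name[screen1@rows$significant]
  .plog(state, sprintf("metabolite->outcome screen: %d of %d significant",
                       length(survivors), nrow(screen1@rows)))

  ## Stage 4: exposure -> surviving metabolites
  screen2 <- NULL
  h_xm <- list()
  if (length(survivors)) {
    for (nm in survivors)
      h_xm[[nm]] <- orientToInhibition(harmonize(
        subsetVariants(exposure, instruments), mets[[nm]],
        palindromePolicy = est$palindrome_policy,
        eafTolerance = est$eaf_tolerance))
    screen2 <- screenPanel(h_xm, "exposure_to_metabolite",
                           alphaNominal = config$screening$alpha_nominal,
                           qMax = config$screening$q_max, rule = "nominal")
    .plog(state, sprintf("exposure->metabolite screen: %d of %d significant",
                         sum(screen2@rows$significant), nrow(screen2@rows)))
  }

  ## Stage 5: optional MR-BMA on survivors
  bma <- NULL
  if (length(survivors) >= 2) {
    h_multi <- lapply(survivors, function(nm) h_xm[[nm]])
    shared_ids <- Reduce(intersect, lapply(h_multi, variantIds))
    if (length(shared_ids) > length(survivors) + 1) {
      # factor effects: each exposure/metabolite pair stores the aligned
      # metabolite effects in its outcome column; outcome effects come
      # from the exposure-outcome harmonized set
      idx <- match(shared_ids, h_xy@variantId)
      bX <- vapply(survivors, function(nm) {
        h <- h_xm[[nm]]
        h@betaY[match(shared_ids, h@variantId)]
      }, numeric(length(shared_ids)))
      colnames(bX) <- survivors
      keep <- !is.na(idx)
      if (sum(keep) > length(survivors) + 1) {
        bma <- bmaFit(bX[keep, , drop = FALSE], h_xy@betaY[idx[keep]],
                      h_xy@seY[idx[keep]],
                      priorInclusion = config$bma$prior_inclusion,
                      priorSd = config$bma$prior_sd)
        if (config$bma$n_perm >= 100)
          bma <- bmaPermutation(bX[keep, , drop = FALSE],
                                h_xy@betaY[idx[keep]], h_xy@seY[idx[keep]],
                                nPerm = config$bma$n_perm, seed = seed + 20L,
                                priorInclusion = config$bma$prior_inclusion,
                                priorSd = config$bma$prior_sd)
        .plog(state, "MR-BMA fitted on surviving metabolites")
      }
    }
  } else if (length(survivors) == 1) {
    .plog(state, "single surviving metabolite: MR-BMA skipped")
  }

  ## Stage 6: two-step mediation for dual-significant metabolites
  mediation <- list()
  if (!is.null(screen2)) {
    dual <- intersect(screen2@rows$name[screen2@rows$significant],
                      screen1@rows$name[screen1@rows$significant])
    for (nm in dual) {
      r1 <- screen2@rows[screen2@rows$name == nm, ]  # beta1: exposure->met
      r2 <- screen1@rows[screen1@rows$name == nm, ]  # beta2: met->outcome
      mediation[[nm]] <- twoStepMediation(r1$b, r2$b, total_est@b,
                                          var1 = r1$se^2, var2 = r2$se^2)
    }
  }
  .plog(state, if (length(mediation))
    sprintf("mediation computed for: %s", paste(names(mediation), collapse = ", "))
    else "no mediators")

  results <- list(out_dir = outDir, config = config,
                  instruments = instruments, selection_log = sel_log,
                  coloc = coloc, harmonized = h_xy, f_stats = fstat,
                  mr_table = table1, leave_one_out = loo, presso = presso,
                  screen_metabolite_outcome = screen1,
                  screen_exposure_metabolite = screen2,
                  bma = bma, mediation = mediation)
  writeReport(results, outDir)
  .plog(state, paste("report written to", outDir))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write pipeline stage outputs as a delimited-text report
#'
#' Emits fixed-column-order tables for every completed stage: the
#' instrument selection log, the five-method MR table in the published
#' column order (`Method nsnp b se pval or or_lci95 or_uci95
#' P-heterogeneity P-pleiotropy`), leave-one-out estimates, MR-PRESSO
#' results, both screening tables, the optional MR-BMA factor table, the
#' mediation table with a plain-text path diagram, a forest-style text
#' summary sorted by odds ratio, and a JSON run manifest (config, seed,
#' package and R versions). An empty mediation stage writes a "no
#' mediators" statement rather than failing.
#'
#' @param results stage-results list as produced by [runPipeline()].
#' @param outDir output directory.
#' @return `outDir`, invisibly.
#' @export
writeReport <- function(results, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, name)
    write.table(d, file.path(outDir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(results$selection_log, "instrument_selection.tsv")
  tsv(results$mr_table@table, "mr_exposure_outcome.tsv")
  tsv(results$leave_one_out, "leave_one_out.tsv")
  tsv(results$f_stats, "f_statistics.tsv")
  if (!is.null(results$coloc))
    tsv(data.frame(hypothesis = names(results$coloc@pp),
                   pp = unname(results$coloc@pp)), "coloc.tsv")
  if (!is.null(results$presso)) {
    p <- results$presso
    tsv(data.frame(rss_obs = p@rssObs, global_pvalue = p@globalPvalue,
                   n_outliers = length(p@outliers),
                   outliers = paste(p@outliers, collapse = ","),
                   b_raw = p@bRaw@b,
                   b_corrected = if (is.null(p@bCorrected)) NA
                                 else p@bCorrected@b,
                   distortion_pvalue = p@distortionPvalue, n_sim = p@nSim),
        "presso.tsv")
  }
  if (!is.null(results$screen_metabolite_outcome))
    tsv(results$screen_metabolite_outcome@rows, "screen_metabolite_outcome.tsv")
  if (!is.null(results$screen_exposure_metabolite))
    tsv(results$screen_exposure_metabolite@rows, "screen_exposure_metabolite.tsv")
  if (!is.null(results$bma))
    tsv(data.frame(factor = names(results$bma@mip),
                   mip = unname(results$bma@mip),
                   mace = unname(results$bma@mace),
                   perm_p = unname(results$bma@permPvalues)), "mrbma.tsv")

  med_path <- file.path(outDir, "mediation.tsv")
  if (length(results$mediation)) {
    med <- do.call(rbind, lapply(names(results$mediation), function(nm) {
      m <- results$mediation[[nm]]
      data.frame(mediator = nm, beta1 = m@beta1, beta2 = m@beta2,
                 total = m@total, indirect = m@indirect,
                 direct = m@beta3Direct, se_indirect = m@seIndirect,
                 proportion_pct = round(100 * m@proportion, 2))
    }))
    write.table(med, med_path, sep = "\t", quote = FALSE, row.names = FALSE)
    diagram <- unlist(lapply(names(results$mediation), function(nm) {
      m <- results$mediation[[nm]]
      c(sprintf("exposure --[beta1 = %.4f]--> %s --[beta2 = %.4f]--> outcome",
                m@beta1, nm, m@beta2),
        sprintf("exposure --[direct beta3 = %.4f]--> outcome (total %.4f)",
                m@beta3Direct, m@total),
        sprintf("proportion mediated = %.2f%%", 100 * m@proportion), "")
    }))
    writeLines(diagram, file.path(outDir, "mediation_paths.txt"))
  } else {
    writeLines("no mediators", med_path)
  }

  if (!is.null(results$screen_metabolite_outcome)) {
    rows <- results$screen_metabolite_outcome@rows
    rows <- rows[order(rows$or, rows$name), ]
    writeLines(sprintf("%-28s OR %6.3f [%6.3f, %6.3f]  p = %.3g",
                       rows$name, rows$or, rows$or_lo, rows$or_hi,
                       rows$pvalue),
               file.path(outDir, "forest_metabolite_outcome.txt"))
  }

  manifest <- list(seed = results$config$seed,
                   config = results$config,
                   package_version = as.character(packageVersion("mrmediate")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
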