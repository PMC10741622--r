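# End-to-end orchestration: simulate -> preprocess -> features -> behavior
# -> group statistics -> models, with a reproducible run log and table
# rendering. A single master seed fans out to per-stage seeds by fixed
# offsets, so a bundle is bit-identical across reruns of the same config.

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates the cohort described by `config`, preprocesses every
#' recording (segmentation, 1-s epochs, artifact rejection), extracts
#' baseline-corrected normalized PSD and coherence features, simulates
#' behavioral outcomes, compares groups feature-wise, and fits the
#' performance and cognitive-load models.
#'
#' @param config a [CohortConfig-class].
#' @param absThresh,ptpThresh,flatThresh artifact thresholds.
#' @param kaiserBeta Kaiser window shape parameter.
#' @param variant t-test variant for the group report.
#' @param alpha significance level.
#' @param folds CV folds for the Lasso stage.
#' @param outDir if non-NULL, [renderTables()] writes the report bundle
#'   there.
#' @return list: `features` (the [cohortFeatures()] stages), `behavior`,
#'   `comparison` (group report), `edges` (significant connectivity edge
#'   list with direction), `performanceModel`, `tlxModel` ([ModelFit-class]),
#'   `log` (seeds, rejection rates, sizes).
#' @export
runPipeline <- function(config, absThresh = 100, ptpThresh = 200,
                        flatThresh = 0.1, kaiserBeta = 8,
                        variant = "pooled", alpha = 0.05, folds = 5,
                        outDir = NULL) {
  cohort <- simulateCohort(config)
  feats <- cohortFeatures(cohort$recordings, cohort$groups,
                          kaiserBeta = kaiserBeta, absThresh = absThresh,
                          ptpThresh = ptpThresh, flatThresh = flatThresh)
  beh <- simulateBehavior(config, feats$normalized,
                          seed = .fanSeed(config@seed, 0, salt = 3))
  comparison <- compareGroups(feats$normalized, variant = variant,
                              alpha = alpha)
  sig <- comparison[comparison$significant & comparison$kind == "coh", ]
  edges <- data.frame(task = sig$task, band = sig$band,
                      pair = sub("^.*\\.coh\\.", "", sig$feature),
                      direction = ifelse(sig$t > 0,
                                         "experienced>novice",
                                         "novice>experienced"),
                      p = sig$p)
  perfFit <- fitOutcomeModel(feats$normalized, beh$behavior$performance,
                             outcomeName = "performance", alpha = alpha,
                             folds = folds,
                             seed = .fanSeed(config@seed, 0, salt = 5))
  tlxFit <- fitOutcomeModel(feats$normalized, beh$behavior$tlxFraction,
                            outcomeName = "tlx", alpha = alpha,
                            folds = folds,
                            seed = .fanSeed(config@seed, 0, salt = 7))
  bundle <- list(features = feats, behavior = beh, comparison = comparison,
                 edges = edges, performanceModel = perfFit,
                 tlxModel = tlxFit,
                 log = list(masterSeed = config@seed,
                            stageSeeds = c(behavior = .fanSeed(config@seed, 0, salt = 3),
                                           performance = .fanSeed(config@seed, 0, salt = 5),
                                           tlx = .fanSeed(config@seed, 0, salt = 7)),
                            rejectionRates = feats$rejectionRates,
                            nParticipants = length(cohort$recordings),
                            packageVersion = as.character(
                              utils::packageVersion("examEEG"))))
  if (!is.null(outDir)) renderTables(bundle, outDir)
  bundle
}

.fmtP <- function(p) formatC(p, digits = 3, format = "f")

#' Write the report bundle as TSV/JSON artifacts
#'
#' Emits `features.tsv` (participants x features), `group_comparison.tsv`
#' (significant features, 3-decimal p-values), `edges.tsv` (significant
#' connectivity edge list), `behavior.tsv`, `model_performance.json`,
#' `model_tlx.json`, and `run_log.json`. Column order is stable; empty
#' result sets give header-only files.
#'
#' @param bundle result of [runPipeline()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
renderTables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fv <- t(assay(bundle$features$normalized))
  data.table::fwrite(
    data.table::data.table(participant = rownames(fv),
                           group = colData(bundle$features$normalized)$group,
                           fv),
    file.path(dir, "features.tsv"), sep = "\t")

  cmp <- bundle$comparison[bundle$comparison$significant, , drop = FALSE]
  cmp$p <- .fmtP(cmp$p)
  data.table::fwrite(cmp, file.path(dir, "group_comparison.tsv"), sep = "\t")

  edg <- bundle$edges
  if (nrow(edg)) edg$p <- .fmtP(edg$p)
  data.table::fwrite(edg, file.path(dir, "edges.tsv"), sep = "\t")

  data.table::fwrite(bundle$behavior$behavior,
                     file.path(dir, "behavior.tsv"), sep = "\t")

  for (nm in c("performanceModel", "tlxModel")) {
    fit <- bundle[[nm]]
    jsonlite::write_json(
      list(outcome = fit@outcome, selected = fit@selected,
           coefficients = fit@coefficients, r2 = fit@r2,
           lambda = fit@lambda, seed = fit@seed, n = fit@nobs),
      file.path(dir, paste0("model_", fit@outcome, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
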