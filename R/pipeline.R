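# End-to-end orchestration: simulate -> QC -> clean -> lesion-flag ->
# connectivity -> permutation inference -> cohort statistics -> report.

#' Default run configuration
#'
#' Collects every pipeline constant in one place: FD threshold 0.5 mm,
#' cosine high-pass cutoff 128 s, 6 mm smoothing FWHM, 5% Jaccard flagging
#' threshold, 10,000 permutations, and the Huber hyperparameters
#' (epsilon 1.35, alpha 1e-3, tol 1e-5).
#'
#' @param nPermutations permutation count for all permutation tests.
#' @param seed master seed governing every random draw.
#' @return nested named list; see the fields for tunables.
#' @export
defaultRunConfig <- function(nPermutations = 10000, seed = 1L) {
  list(
    cohort = list(nControl = 20, nTia = 25, nStroke = 17,
                  nTimepoints = 160, trSeconds = 3.12,
                  gridShape = c(20L, 20L, 12L), voxelSizeMm = 3),
    qc = list(fdThresholdMm = 0.5),
    clean = list(cosineCutoffS = 128, fwhmMm = 6),
    lesion = list(jaccardThreshold = 0.05, alpha = 0.05, twoSided = TRUE),
    inference = list(nPermutations = nPermutations, twoSided = TRUE,
                     huber = list(epsilon = 1.35, alpha = 1e-3, tol = 1e-5)),
    interaction = list(scores = c("executive", "memory"),
                       edges = "R_DMN__L_DLPFC"),
    stages = list(lesionFlag = TRUE, interaction = TRUE, cohortStats = TRUE),
    seed = seed
  )
}

#' Read a run configuration from YAML
#'
#' Values present in the file override [defaultRunConfig()] entries.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  merge <- function(base, usr) {
    for (nm in names(usr)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(usr[[nm]]))
        merge(base[[nm]], usr[[nm]]) else usr[[nm]]
    }
    base
  }
  merge(base, usr)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Stages, in fixed order: cohort simulation, FD-based QC exclusion, BOLD
#' cleaning (nuisance OLS with cosine high-pass, z-score, smooth,
#' parcellate), lesion-artifact component flagging (flagged non-motion
#' component time courses join that subject's nuisance design),
#' partial-correlation connectivity, maxT permutation contrasts (raw and
#' confound-corrected, both study contrasts), Manly-permutation interaction
#' tests, and a cohort summary table.
#'
#' @param config configuration list (see [defaultRunConfig()]) or a path to a
#'   YAML file.
#' @param outDir optional directory; when given, all result tables are
#'   written there as TSV.
#' @return list: `qc`, `edges` (an \linkS4class{EdgeExperiment}),
#'   `flagTables`, `groupDifferences`, `interactions`, `cohortTable`, `log`.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("pipeline seed %d, %d permutations", config$seed,
      config$inference$nPermutations)
  spec <- cohortSpec(
    nControl = config$cohort$nControl, nTia = config$cohort$nTia,
    nStroke = config$cohort$nStroke, nTimepoints = config$cohort$nTimepoints,
    trSeconds = config$cohort$trSeconds,
    gridShape = config$cohort$gridShape,
    voxelSizeMm = config$cohort$voxelSizeMm, seed = config$seed)
  cohort <- stage("simulate", simulateCohort(spec))
  say("simulated %d subjects", length(cohort$subjects))

  qc <- stage("qc", cohortQc(cohort, config$qc$fdThresholdMm))
  retained <- qc$subject_id[!qc$excluded]
  say("QC: %d/%d subjects retained (mean FD > %.2f mm excluded)",
      length(retained), nrow(qc), config$qc$fdThresholdMm)

  cosBasis <- buildCosineBasis(spec@nTimepoints, spec@trSeconds,
                               config$clean$cosineCutoffS)
  say("cosine high-pass basis: %d regressors", ncol(cosBasis))

  flagTables <- list()
  seriesList <- list()
  for (s in cohort$subjects) {
    if (!s$subjectId %in% retained) next
    stage(paste0("clean:", s$subjectId), {
      comps <- s$components
      flags <- if (isTRUE(config$stages$lesionFlag) && !is.null(s$lesionMask)) {
        flagLesionComponents(comps, s$lesionMask,
                             threshold = config$lesion$jaccardThreshold,
                             alpha = config$lesion$alpha,
                             twoSided = config$lesion$twoSided)
      } else {
        data.frame(component_id = componentIds(comps),
                   jaccard = NA_real_,
                   motion_flagged = motionFlagged(comps),
                   lesion_flagged = FALSE, added_to_design = FALSE)
      }
      flagTables[[s$subjectId]] <- flags
      motionTc <- timeCourses(comps)[, motionFlagged(comps), drop = FALSE]
      lesionTc <- timeCourses(comps)[, flags$added_to_design, drop = FALSE]
      design <- nuisanceDesign(spec@nTimepoints, motion = motionTc,
                               csf = s$csf, cosineBasis = cosBasis,
                               lesionComponents = lesionTc)
      seriesList[[s$subjectId]] <- cleanAndParcellate(
        s$bold, design, cohort$atlas, fwhmMm = config$clean$fwhmMm)
    })
  }
  say("cleaned and parcellated %d subjects (order: regress -> z-score -> smooth -> parcellate)",
      length(seriesList))

  pheno <- cohort$phenotype[cohort$phenotype$subject_id %in% retained, ,
                            drop = FALSE]
  ee <- stage("connectivity",
              computeEdges(seriesList, cohort$atlas$labels, pheno))
  say("connectivity: %d edges x %d subjects", nrow(ee), ncol(ee))

  perms <- config$inference$nPermutations
  hub <- config$inference$huber
  gd <- stage("group-differences", do.call(rbind, lapply(
    c("control-vs-cve", "stroke-vs-tia"), function(ct)
      do.call(rbind, lapply(c("raw", "corrected"), function(md)
        groupDifferenceTest(ee, contrast = ct, model = md,
                            nPermutations = perms, seed = config$seed,
                            twoSided = config$inference$twoSided))))))
  say("group differences: %d significant edges at corrected p <= 0.05",
      sum(gd$p_corrected <= 0.05))

  interactions <- NULL
  if (isTRUE(config$stages$interaction)) {
    combos <- expand.grid(score = config$interaction$scores,
                          edge = config$interaction$edges,
                          model = c("raw", "corrected"),
                          stringsAsFactors = FALSE)
    interactions <- stage("interaction", do.call(rbind, lapply(
      seq_len(nrow(combos)), function(i)
        interactionTest(ee, combos$score[i], combos$edge[i],
                        contrast = "control-vs-cve", model = combos$model[i],
                        nPermutations = perms, seed = config$seed,
                        epsilon = hub$epsilon, alpha = hub$alpha,
                        tol = hub$tol))))
    say("interaction tests: %d score x edge x model combinations",
        nrow(combos))
  }

  cohortTable <- if (isTRUE(config$stages$cohortStats))
    stage("cohort-stats", cohortSummaryTable(pheno)) else NULL

  bundle <- list(qc = qc, edges = ee,
                 flagTables = do.call(rbind, c(
                   lapply(names(flagTables), function(id)
                     cbind(subject_id = id, flagTables[[id]])),
                   list(make.row.names = FALSE))),
                 groupDifferences = gd, interactions = interactions,
                 cohortTable = cohortTable, config = config, log = log)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    .writeTsv(qc, file.path(outDir, "qc.tsv"))
    edgeTab <- data.frame(subject_id = colnames(ee), t(edgeValues(ee)),
                          check.names = FALSE)
    .writeTsv(edgeTab, file.path(outDir, "edges.tsv"))
    .writeTsv(data.frame(edge = rownames(ee),
                         network_pair = networkPairs(ee)),
              file.path(outDir, "edge_networks.tsv"))
    if (!is.null(bundle$flagTables))
      .writeTsv(bundle$flagTables, file.path(outDir, "lesion_flags.tsv"))
    .writeTsv(gd, file.path(outDir, "group_differences.tsv"))
    if (!is.null(interactions))
      .writeTsv(interactions, file.path(outDir, "interactions.tsv"))
    if (!is.null(cohortTable))
      .writeTsv(cohortTable, file.path(outDir, "cohort_table.tsv"))
    writeLines(log, file.path(outDir, "pipeline.log"))
  }
  bundle
}
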