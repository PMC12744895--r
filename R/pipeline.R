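#' Pipeline configuration
#'
#' Collects every tunable of the per-patient pipeline with its default:
#' clustering (k = 5, deterministic quantile initializer), enhancement-model
#' fitting (time origin at the last precontrast frame, optional bolus
#' offset), concentration conversion (SPGR inversion; parenchyma T10 1.4 s,
#' tumor 1.5 s at 3 T; relaxivity 5.0 L/(mmol s)), the population AIF, and
#' seeds. The returned object is recorded alongside results so a run can be
#' replayed exactly.
#'
#' @param k number of clusters (the method fixes 5; overridable).
#' @param clusterInit `"quantile"` (deterministic) or `"random"`.
#' @param clusterSeed seed for the random initializer.
#' @param timeOffset bolus-arrival offset in minutes.
#' @param minEnhancement percent; below it a voxel's fit is flagged
#'   low-enhancement.
#' @param conversionMode `"spgr"` or `"linear"`.
#' @param t10Parenchyma,t10Tumor precontrast T1 in seconds.
#' @param relaxivity contrast-agent relaxivity, L/(mmol s).
#' @param tr repetition time, seconds.
#' @param flipAngle degrees.
#' @param aif a [PopulationAif-class].
#' @param refine Tofts forward-model grid refinement factor.
#' @return A `PipelineConfig` list.
#' @export
pipelineConfig <- function(k = 5L, clusterInit = "quantile",
                           clusterSeed = 1L, timeOffset = 0,
                           minEnhancement = 5,
                           conversionMode = c("spgr", "linear"),
                           t10Parenchyma = 1.4, t10Tumor = 1.5,
                           relaxivity = 5.0, tr = 0.004, flipAngle = 12,
                           aif = populationAif(), refine = 40L) {
  cfg <- list(k = as.integer(k), clusterInit = clusterInit,
              clusterSeed = as.integer(clusterSeed),
              timeOffset = timeOffset, minEnhancement = minEnhancement,
              conversionMode = match.arg(conversionMode),
              t10Parenchyma = t10Parenchyma, t10Tumor = t10Tumor,
              relaxivity = relaxivity, tr = tr, flipAngle = flipAngle,
              aif = aif, refine = as.integer(refine))
  if (cfg$k != 5L)
    warning("k = ", cfg$k, " departs from the method's K = 5", call. = FALSE)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full per-patient analysis
#'
#' Executes the whole chain for one patient: voxelwise PSE and two-parameter
#' enhancement fits in each of the three regions (tumor, ipsilateral and
#' contralateral parenchyma), K = 5 clustering of each region's A*alpha map
#' separately, cluster-mean curves, cluster-level three-parameter fits with
#' AUC30, concentration conversion, extended Tofts fits, and the weighted
#' averages / I/C asymmetry summary. Deterministic for fixed inputs and
#' config.
#'
#' @param series a [DynamicSeries-class].
#' @param labels a [RegionLabels-class] on the same grid.
#' @param covariates optional named list of clinical covariates.
#' @param patient patient identifier.
#' @param config a [pipelineConfig()].
#' @param keepMaps keep the voxelwise parameter maps in the result?
#' @return List: `summary` (from [summarizePatient()]), `clusterFits`
#'   (per-region per-cluster parameter table), `assignments` (list of
#'   [ClusterAssignment-class] per region), `config`, and optionally
#'   `maps`. Any stage failure aborts with the stage named.
#' @export
runPatient <- function(series, labels, covariates = NULL,
                       patient = "patient", config = pipelineConfig(),
                       keepMaps = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!all(dim(labelMap(labels)) == dim(seriesData(series))[1:3]))
    stop("stage validate: label grid does not match series grid")
  regions <- c("ips_parenchyma", "con_parenchyma", "tumor")
  assignments <- list(); maps <- list(); rows <- list()

  for (rg in regions) {
    emm2 <- withCallingHandlers(
      fitEmm2Voxelwise(series, labels, rg,
                       timeOffset = config$timeOffset,
                       minEnhancement = config$minEnhancement),
      error = function(e) stop("stage emm2[", rg, "]: ",
                               conditionMessage(e), call. = FALSE))
    # flagged (low-enhancement) voxels are excluded from cluster statistics
    clusterable <- emm2$valid & !emm2$lowEnhancement
    clus <- tryCatch(
      kmeansCluster(emm2$Aalpha, mask = clusterable, k = config$k,
                    init = config$clusterInit, seed = config$clusterSeed,
                    region = rg),
      error = function(e) stop("stage cluster[", rg, "]: ",
                               conditionMessage(e), call. = FALSE))
    curves <- clusterMeanCurves(series, clus)
    t10 <- if (rg == "tumor") config$t10Tumor else config$t10Parenchyma

    for (j in seq_len(config$k)) {
      emm3 <- tryCatch(
        fitEmm3Curve(curves[[j]], timeOffset = config$timeOffset),
        error = function(e) stop("stage emm3[", rg, " c", j, "]: ",
                                 conditionMessage(e), call. = FALSE))
      conc <- suppressWarnings(
        pseToConcentration(curves[[j]], t10 = t10,
                           relaxivity = config$relaxivity, tr = config$tr,
                           flipAngle = config$flipAngle,
                           mode = config$conversionMode))
      etm <- tryCatch(
        fitEtm(conc, config$aif, refine = config$refine),
        error = function(e) stop("stage etm[", rg, " c", j, "]: ",
                                 conditionMessage(e), call. = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, cluster = j, count = clusterCounts(clus)[j],
        meanAalphaVoxelwise = clusterCenters(clus)[j],
        A = emm3$A, alpha = emm3$alpha, beta = emm3$beta,
        Aalpha = emm3$Aalpha, auc30 = emm3$auc30,
        ktrans = etm$ktrans, ve = etm$ve, vp = etm$vp, kep = etm$kep,
        rss_emm3 = emm3$rss, rss_etm = etm$rss,
        converged = emm3$converged & etm$converged)
    }
    assignments[[rg]] <- clus
    if (keepMaps) maps[[rg]] <- emm2
  }

  clusterFits <- do.call(rbind, rows)
  summary <- summarizePatient(clusterFits, labels = labels,
                              voxelSize = voxelSize(series),
                              covariates = covariates, patient = patient)
  out <- list(summary = summary, clusterFits = clusterFits,
              assignments = assignments, config = config)
  if (keepMaps) out$maps <- maps
  out
}

#' Candidate feature pools for the seven model families
#'
#' @param cohort cohort data.frame (column names define the pools).
#' @return Named list of pool lists for families `"i"` through `"vii"`:
#'   clinical only, kT only, kBPE I/C only, and their pairwise / three-way
#'   combinations. Combined families require at least one feature from each
#'   constituent pool in every candidate subset.
#' @export
modelFamilies <- function(cohort) {
  clinical <- intersect(c("age", "premenopausal", "er_pos", "pr_pos",
                          "her2_pos", "grade3"), names(cohort))
  kt <- grep("^kt_", names(cohort), value = TRUE)
  kbpe <- grep("^kbpe_ic_", names(cohort), value = TRUE)
  list(
    i = list(clinical = clinical),
    ii = list(kt = kt),
    iii = list(kbpe = kbpe),
    iv = list(clinical = clinical, kt = kt),
    v = list(clinical = clinical, kbpe = kbpe),
    vi = list(kt = kt, kbpe = kbpe),
    vii = list(clinical = clinical, kt = kt, kbpe = kbpe)
  )
}

#' Run the cohort-level analysis
#'
#' Group comparisons for every kinetic feature (Wilcoxon rank-sum with
#' single-feature ROC AUC and bootstrap CI) and for the categorical clinical
#' covariates (chi-square), then the exhaustive at-most-3-feature logistic
#' model search for the requested families, each with a 1000-resample
#' bootstrap AUC CI, the Youden operating point, and paired bootstrap
#' z-tests between all family winners (shared resample indices).
#'
#' @param cohort cohort data.frame with an `outcome` factor column.
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed seed for all bootstrap resampling.
#' @param families subset of `c("i", ..., "vii")` to fit.
#' @param lambda ridge penalty for the logistic fits.
#' @return List: `comparisons` (per-feature results), `models` (per-family
#'   report: features, coefficients, auc, auc_ci, sensitivity, specificity,
#'   accuracy, leaderboard, bootstrap AUCs), `pairwise` (data.frame of
#'   paired z-tests between families).
#' @export
runCohort <- function(cohort, nBoot = 1000L, seed = 1L,
                      families = c("i", "ii", "iii", "iv", "v", "vi", "vii"),
                      lambda = 1e-3) {
  if (is.null(cohort$outcome) || length(unique(cohort$outcome)) < 2L)
    stop("cohort must contain both outcome classes")
  pools <- modelFamilies(cohort)[families]

  featCols <- grep("^(kbpe_ic_|kt_)", names(cohort), value = TRUE)
  catCols <- intersect(c("premenopausal", "er_pos", "pr_pos", "her2_pos",
                         "grade3"), names(cohort))
  comparisons <- lapply(c(featCols, "age"[!is.null(cohort$age)], catCols),
                        function(f) compareGroups(cohort, f, nBoot = 0L))
  names(comparisons) <- vapply(comparisons, `[[`, "", "feature")

  models <- list()
  for (fam in names(pools)) {
    search <- exhaustiveModelSearch(cohort, pools[[fam]], lambda = lambda)
    boot <- bootstrapAucCi(cohort, search$features, nBoot = nBoot,
                           seed = seed, lambda = lambda)
    keep <- stats::complete.cases(
      cohort[, c(search$features, "outcome"), drop = FALSE])
    op <- youdenOperatingPoint(search$fit$scores, cohort$outcome[keep])
    models[[fam]] <- list(
      family = fam, features = search$features,
      coefficients = search$fit$coefficients, auc = search$auc,
      auc_ci = boot$ci, sensitivity = op$sensitivity,
      specificity = op$specificity, accuracy = op$accuracy,
      nBoot = nBoot, bootAucs = boot$aucs,
      leaderboard = search$leaderboard)
  }

  pairs <- if (length(models) > 1L)
    utils::combn(names(models), 2, simplify = FALSE) else list()
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    z <- compareModelsZ(models[[pr[1]]]$bootAucs, models[[pr[2]]]$bootAucs)
    data.frame(modelA = pr[1], modelB = pr[2], meanDiff = z$meanDiff,
               z = z$z, p = z$p)
  }))

  list(comparisons = comparisons, models = models, pairwise = pairwise)
}
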