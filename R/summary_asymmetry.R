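#' Weighted parenchymal cluster average
#'
#' (2*c2 + 3*c3 + 4*c4) / 9 over parenchyma clusters 2-4. Clusters 1 and 5
#' are excluded because they frequently contain outliers (low enhancement
#' and noise effects); the weights emphasize the stronger-enhancing of the
#' middle clusters. A missing input makes the result missing - weights are
#' never silently renormalized.
#'
#' @param c2,c3,c4 the parameter value in parenchyma clusters 2, 3 and 4.
#' @return The weighted average, or NA if any input is missing.
#' @export
weightedParenchymaAverage <- function(c2, c3, c4) {
  ifelse(is.na(c2) | is.na(c3) | is.na(c4), NA_real_,
         (2 * c2 + 3 * c3 + 4 * c4) / 9)
}

#' Weighted tumor cluster average
#'
#' (3*c3 + 4*c4 + 5*c5) / 12 over tumor clusters 3-5. The two lowest
#' clusters are excluded for low SNR; cluster 5 gets the strongest weight
#' because it shows the strongest enhancement in tumors. Missing inputs
#' propagate.
#'
#' @param c3,c4,c5 the parameter value in tumor clusters 3, 4 and 5.
#' @return The weighted average, or NA if any input is missing.
#' @export
weightedTumorAverage <- function(c3, c4, c5) {
  ifelse(is.na(c3) | is.na(c4) | is.na(c5), NA_real_,
         (3 * c3 + 4 * c4 + 5 * c5) / 12)
}

#' Ipsilateral / contralateral asymmetry ratio
#'
#' I/C > 1 means the parameter is larger in the ipsilateral normal
#' parenchyma than in the contralateral. The ratio cancels common
#' multiplicative factors (arterial input, cardiac output, relaxivity)
#' between the two breasts.
#'
#' @param ips,con weighted-average parameter values for the ipsilateral and
#'   contralateral parenchyma.
#' @param tol contralateral values with |con| below this are treated as an
#'   undefined denominator.
#' @return ips/con, or NA with a warning when con is (near) zero or either
#'   side is missing.
#' @export
icRatio <- function(ips, con, tol = 1e-9) {
  bad <- is.na(ips) | is.na(con) | abs(con) < tol
  if (any(bad & !is.na(con) & abs(con) < tol))
    warning("contralateral average is zero within tolerance; ",
            "I/C undefined", call. = FALSE)
  ifelse(bad, NA_real_, ips / con)
}

#' Tumor volume from the label map
#'
#' Number of tumor voxels times the voxel volume, in cm^3.
#'
#' @param labels a [RegionLabels-class].
#' @param voxelSize voxel edge lengths in mm (length 3).
#' @return Tumor volume in cm^3 (0 with a warning if no tumor voxels).
#' @export
tumorVolume <- function(labels, voxelSize) {
  if (any(voxelSize <= 0)) stop("voxelSize must be positive")
  nTum <- sum(labelMap(labels) == REGION_CODES[["tumor"]])
  if (nTum == 0L) warning("label map contains no tumor voxels", call. = FALSE)
  nTum * prod(voxelSize) / 1000
}

## Kinetic parameters summarized per patient. Composite identities
## (kep = ktrans/ve, Aalpha = A*alpha) are enforced per cluster BEFORE
## weighted averaging, because weighted averaging does not commute with
## products or ratios.
.summaryParams <- c("A", "alpha", "Aalpha", "beta", "auc30",
                    "ktrans", "ve", "kep", "vp")

#' Collapse per-cluster fits into the per-patient summary
#'
#' Applies the weighted parenchymal average to clusters 2-4 of each breast,
#' the I/C ratio, and the weighted tumor average to clusters 3-5, for every
#' kinetic parameter (A, alpha, A*alpha, beta, AUC30, Ktrans, ve, Kep, vp).
#' A*alpha is the product of the fitted A and alpha per cluster before
#' averaging, and Kep = Ktrans/ve per cluster. A missing or unconverged
#' required cluster makes the affected parameter missing (no reweighting).
#'
#' @param clusterFits data.frame with columns `region`
#'   (`ips_parenchyma` / `con_parenchyma` / `tumor`), `cluster` (1-5) and
#'   the parameter columns in `.summaryParams` (missing composites are
#'   derived); rows with `converged = FALSE` are treated as missing.
#' @param labels optional [RegionLabels-class] for tumor volume.
#' @param voxelSize voxel size in mm (used with `labels`).
#' @param covariates optional named list/row of clinical covariates.
#' @param patient patient identifier.
#' @return List with `patient`, `parameters` (data.frame: parameter,
#'   kbpe_ips, kbpe_con, kbpe_ic, kt_ave), `tumorVolume` (cm^3 or NA), and
#'   `covariates`.
#' @export
summarizePatient <- function(clusterFits, labels = NULL,
                             voxelSize = c(1.5, 1.5, 3), covariates = NULL,
                             patient = "patient") {
  cf <- clusterFits
  if (is.null(cf$Aalpha) && !is.null(cf$A)) cf$Aalpha <- cf$A * cf$alpha
  if (is.null(cf$kep) && !is.null(cf$ktrans)) cf$kep <- cf$ktrans / cf$ve
  if (!is.null(cf$converged)) {
    drop <- !is.na(cf$converged) & !cf$converged
    for (p in intersect(.summaryParams, names(cf))) cf[[p]][drop] <- NA_real_
  }

  pick <- function(region, cluster, param) {
    if (!param %in% names(cf)) return(NA_real_)
    i <- which(cf$region == region & cf$cluster == cluster)
    if (length(i) != 1L) return(NA_real_)
    cf[[param]][i]
  }

  rows <- lapply(.summaryParams, function(p) {
    ips <- weightedParenchymaAverage(pick("ips_parenchyma", 2, p),
                                     pick("ips_parenchyma", 3, p),
                                     pick("ips_parenchyma", 4, p))
    con <- weightedParenchymaAverage(pick("con_parenchyma", 2, p),
                                     pick("con_parenchyma", 3, p),
                                     pick("con_parenchyma", 4, p))
    data.frame(parameter = p, kbpe_ips = ips, kbpe_con = con,
               kbpe_ic = suppressWarnings(icRatio(ips, con)),
               kt_ave = weightedTumorAverage(pick("tumor", 3, p),
                                             pick("tumor", 4, p),
                                             pick("tumor", 5, p)))
  })

  vol <- if (is.null(labels)) NA_real_ else tumorVolume(labels, voxelSize)
  list(patient = patient, parameters = do.call(rbind, rows),
       tumorVolume = vol, covariates = covariates)
}
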