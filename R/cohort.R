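## Default per-feature group distributions: weighted-average bilateral
## asymmetry (kBPE I/C) and tumor kinetic (kT) parameters, mean +/- SD by
## response group, as reported for the 56-patient neoadjuvant-chemotherapy
## cohort this simulator emulates. lower/upper are physical truncation
## bounds (ratios of positive quantities are positive; ve is a volume
## fraction).
.defaultFeatureTable <- function() {
  rbind(
    data.frame(
      feature = paste0("kbpe_ic_",
                       c("A", "alpha", "Aalpha", "beta", "auc30", "ktrans",
                         "ve", "kep", "vp")),
      mean_nonpcr = c(1.21, 1.47, 1.66, 2.06, 1.79, 1.45, 0.88, 5.00, 3.08),
      sd_nonpcr   = c(0.44, 0.93, 0.86, 9.97, 1.29, 0.56, 0.79, 8.13, 3.88),
      mean_pcr    = c(1.19, 1.02, 1.07, 5.57, 1.05, 1.03, 1.05, 1.06, 1.44),
      sd_pcr      = c(0.59, 0.36, 0.26, 24.53, 0.31, 0.12, 0.24, 0.42, 0.85),
      lower = c(0, 0, 0, -Inf, 0, 0, 0, 0, 0),
      upper = Inf),
    data.frame(
      feature = paste0("kt_",
                       c("A", "alpha", "Aalpha", "beta", "auc30", "ktrans",
                         "ve", "kep", "vp")),
      mean_nonpcr = c(1.49, 13.7, 21.1, -0.04, 0.56, 0.21, 0.33, 0.74,
                      0.0062),
      sd_nonpcr   = c(0.44, 7.84, 13.4, 0.16, 0.20, 0.11, 0.17, 0.32,
                      0.0067),
      mean_pcr    = c(1.52, 12.0, 19.5, -0.05, 0.55, 0.18, 0.33, 0.67,
                      0.0060),
      sd_pcr      = c(0.43, 7.6, 14.3, 0.13, 0.20, 0.09, 0.19, 0.26,
                      0.0059),
      lower = c(0, 0, 0, -Inf, 0, 0, 1e-3, 0, 0),
      upper = c(Inf, Inf, Inf, Inf, Inf, Inf, 1, Inf, Inf))
  )
}

#' Specification for the synthetic patient cohort
#'
#' Per-feature group means and SDs for the kBPE I/C and kT features (default:
#' the study cohort's reported group statistics), clinical covariate
#' frequencies per group, and group sizes. Features are drawn as truncated
#' normals (rejection sampling at the physical bounds: ratios and rate
#' constants > 0, ve in (0, 1]); for heavy-tailed features whose SD is large
#' relative to the mean the truncation shifts the realized mean upward,
#' which is documented rather than corrected.
#'
#' @param nNonPcr,nPcr group sizes (default 30 / 26).
#' @param features data.frame with columns `feature`, `mean_nonpcr`,
#'   `sd_nonpcr`, `mean_pcr`, `sd_pcr`, `lower`, `upper`.
#' @param clinical named list of per-group Bernoulli frequencies
#'   (`c(nonpcr, pcr)`) for the binary covariates, plus `age` means.
#' @param seed RNG seed.
#' @return A validated `CohortSpec` list.
#' @export
cohortSpec <- function(nNonPcr = 30L, nPcr = 26L,
                       features = .defaultFeatureTable(),
                       clinical = list(
                         premenopausal = c(15 / 30, 15 / 26),
                         er_pos = c(18 / 30, 15 / 26),
                         pr_pos = c(13 / 30, 8 / 26),
                         her2_pos = c(17 / 30, 14 / 26),
                         grade3 = c(26 / 30, 25 / 26),
                         age_mean = c(53, 50), age_sd = c(11, 11)),
                       seed = 1L) {
  if (nNonPcr < 1L || nPcr < 1L) stop("group sizes must be >= 1")
  if (any(features$sd_nonpcr < 0) || any(features$sd_pcr < 0))
    stop("feature SDs must be >= 0")
  spec <- list(nNonPcr = as.integer(nNonPcr), nPcr = as.integer(nPcr),
               features = features, clinical = clinical,
               seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  spec
}

#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(1000)) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

#' Generate a synthetic patient cohort table
#'
#' Draws per-patient kinetic feature vectors from the group distributions in
#' the spec, attaches binary outcome labels and clinical covariates, and
#' returns the wide cohort table consumed by the statistics stage.
#'
#' @param spec a [cohortSpec()].
#' @return data.frame with columns `patient`, `outcome` (factor
#'   nonpCR/pCR), clinical covariates (`age`, `premenopausal`, `er_pos`,
#'   `pr_pos`, `her2_pos`, `grade3`) and one numeric column per kinetic
#'   feature. Deterministic for a fixed spec (including its seed).
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  n <- c(spec$nNonPcr, spec$nPcr)
  cl <- spec$clinical
  tab <- data.frame(
    patient = sprintf("P%03d", seq_len(sum(n))),
    outcome = factor(rep(c("nonpCR", "pCR"), n), levels = c("nonpCR", "pCR"))
  )
  grp <- rep(1:2, n)
  tab$age <- round(stats::rnorm(sum(n), cl$age_mean[grp], cl$age_sd[grp]))
  tab$age <- pmin(pmax(tab$age, 24), 80)
  for (nm in c("premenopausal", "er_pos", "pr_pos", "her2_pos", "grade3"))
    tab[[nm]] <- stats::rbinom(sum(n), 1, cl[[nm]][grp])

  ft <- spec$features
  for (i in seq_len(nrow(ft))) {
    v <- numeric(sum(n))
    v[grp == 1] <- rtruncnorm(n[1], ft$mean_nonpcr[i], ft$sd_nonpcr[i],
                              ft$lower[i], ft$upper[i])
    v[grp == 2] <- rtruncnorm(n[2], ft$mean_pcr[i], ft$sd_pcr[i],
                              ft$lower[i], ft$upper[i])
    tab[[ft$feature[i]]] <- v
  }
  tab
}
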