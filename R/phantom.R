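#' Specification for the bilateral-breast digital phantom
#'
#' Describes a rectangular bilateral volume split along the second (left-
#' right) axis into two breast blocks, each containing a parenchyma
#' sub-block, with one ellipsoidal tumor and an optional vessel line in the
#' ipsilateral breast (mirrored vessel contralaterally). Geometry is defined
#' by fixed grid fractions so any grid size yields disjoint, bilaterally
#' symmetric regions.
#'
#' Two generation modes: `"signal"` voxels follow the three-parameter
#' empirical enhancement model directly (exact truth for the enhancement-
#' model stages); `"concentration"` voxels follow the extended Tofts model
#' with the population AIF, mapped to signal through the SPGR forward model
#' (exact truth for the pharmacokinetic stage). Within-region heterogeneity
#' is log-normal around the region mean (so K = 5 clustering has genuine
#' structure); contralateral parenchyma voxel draws mirror the ipsilateral
#' ones voxel-for-voxel, and the asymmetry factor `r` then multiplies the
#' ipsilateral alpha (signal mode) or Ktrans (concentration mode), making
#' truth A*alpha (resp. Ktrans) I/C exactly `r` and `r = 1` exactly
#' symmetric.
#'
#' @param grid integer length-3 grid shape; second axis is left-right.
#' @param voxelSize voxel size in mm.
#' @param mode `"signal"` or `"concentration"`.
#' @param nPrecontrast,nPostcontrast frame counts (default 5 + 18).
#' @param spacing inter-frame spacing in seconds (protocol range 3-9 s).
#' @param s0 baseline signal.
#' @param r ipsilateral/contralateral asymmetry factor (> 0).
#' @param noiseModel `"none"`, `"gaussian"` or `"rician"`.
#' @param noiseSd noise SD as a fraction of `s0`.
#' @param dispersion log-normal sdlog of within-region parameter spread.
#' @param laterality ipsilateral side, `"left"` or `"right"`.
#' @param includeVessels add vessel lines?
#' @param parenchyma,tumor,vessel named lists of region kinetic means:
#'   `A` (percent), `alpha`, `beta` (1/min) for signal mode; `ktrans`
#'   (1/min), `ve`, `vp` for concentration mode.
#' @param seed RNG seed.
#' @return A validated `PhantomSpec` list.
#' @export
phantomSpec <- function(grid = c(32, 64, 8), voxelSize = c(1.5, 1.5, 3),
                        mode = c("signal", "concentration"),
                        nPrecontrast = 5L, nPostcontrast = 18L, spacing = 5,
                        s0 = 100, r = 1,
                        noiseModel = c("none", "gaussian", "rician"),
                        noiseSd = 0, dispersion = 0.25,
                        laterality = c("left", "right"),
                        includeVessels = TRUE,
                        parenchyma = list(A = 30, alpha = 2, beta = 0.05,
                                          ktrans = 0.06, ve = 0.3,
                                          vp = 0.005),
                        tumor = list(A = 150, alpha = 12, beta = -0.04,
                                     ktrans = 0.21, ve = 0.33, vp = 0.006),
                        vessel = list(A = 260, alpha = 40, beta = 0.6,
                                      ktrans = 0.3, ve = 0.4, vp = 0.19),
                        seed = 1L) {
  spec <- list(grid = as.integer(grid), voxelSize = voxelSize,
               mode = match.arg(mode),
               nPrecontrast = as.integer(nPrecontrast),
               nPostcontrast = as.integer(nPostcontrast), spacing = spacing,
               s0 = s0, r = r, noiseModel = match.arg(noiseModel),
               noiseSd = noiseSd, dispersion = dispersion,
               laterality = match.arg(laterality),
               includeVessels = includeVessels,
               parenchyma = parenchyma, tumor = tumor, vessel = vessel,
               seed = as.integer(seed))
  if (spec$r <= 0) stop("asymmetry factor r must be > 0")
  if (spec$noiseSd < 0) stop("noise SD must be >= 0")
  if (spacing < 3 || spacing > 9)
    warning("frame spacing ", spacing,
            " s is outside the 3-9 s ultrafast protocol range", call. = FALSE)
  if (any(grid < c(8, 16, 3)))
    stop("degenerate geometry: grid must be at least 8 x 16 x 3")
  class(spec) <- "PhantomSpec"
  spec
}

## Region geometry on one (left) half; right half is the y-mirror.
#' @keywords internal
phantomGeometry <- function(grid) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  mirror <- function(y) ny + 1L - y
  parX <- seq(max(round(0.25 * nx), 2L), round(0.75 * nx))
  parY <- seq(max(round(0.078 * ny), 2L), round(0.3125 * ny))
  parZ <- seq(max(round(0.25 * nz), 1L), max(round(0.875 * nz), 2L))
  tumorRadii <- c(max(0.16 * nx, 1.6), max(0.0625 * ny, 1.4),
                  max(0.3 * nz, 1.1))
  tumorCenter <- c(nx / 2 + 0.5,
                   min(0.41 * ny, ny / 2 - tumorRadii[2] - 0.1),
                   (nz + 1) / 2)
  if (tumorCenter[2] + tumorRadii[2] > ny / 2)
    stop("degenerate geometry: tumor does not fit inside one breast")
  if (tumorCenter[2] - tumorRadii[2] <= max(parY))
    stop("degenerate geometry: tumor overlaps the parenchyma block")
  vessel <- list(x = seq(round(0.2 * nx), round(0.8 * nx)),
                 y = max(round(0.047 * ny), 1L),
                 z = max(round(nz / 4), 1L))
  list(mirror = mirror, parX = parX, parY = parY, parZ = parZ,
       tumorCenter = tumorCenter, tumorRadii = tumorRadii, vessel = vessel)
}

#' Generate a bilateral-breast 4D phantom with known ground truth
#'
#' @param spec a [phantomSpec()].
#' @return List with elements `series` ([DynamicSeries-class]), `labels`
#'   ([RegionLabels-class]) and `truth`: per-region parameter table
#'   (`regions`, with the asymmetry factor already applied to the
#'   ipsilateral parenchyma) and per-voxel truth maps (`voxel`, 3D arrays;
#'   NA outside enhancing regions). Output is bit-identical for a fixed
#'   spec (including its seed).
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  g <- phantomGeometry(spec$grid)
  nx <- spec$grid[1]; ny <- spec$grid[2]; nz <- spec$grid[3]
  lab <- array(REGION_CODES[["background"]], spec$grid)
  ipsLeft <- spec$laterality == "left"

  leftY <- g$parY
  rightY <- g$mirror(g$parY)
  ipsY <- if (ipsLeft) leftY else rightY
  conY <- if (ipsLeft) rightY else leftY
  lab[g$parX, ipsY, g$parZ] <- REGION_CODES[["ips_parenchyma"]]
  lab[g$parX, conY, g$parZ] <- REGION_CODES[["con_parenchyma"]]

  tc <- g$tumorCenter
  if (!ipsLeft) tc[2] <- g$mirror(tc[2])
  coords <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  inTumor <- ((coords$x - tc[1]) / g$tumorRadii[1])^2 +
             ((coords$y - tc[2]) / g$tumorRadii[2])^2 +
             ((coords$z - tc[3]) / g$tumorRadii[3])^2 <= 1
  lab[as.matrix(coords[inTumor, ])] <- REGION_CODES[["tumor"]]

  if (spec$includeVessels) {
    vy <- c(g$vessel$y, g$mirror(g$vessel$y))
    lab[g$vessel$x, vy, g$vessel$z] <- REGION_CODES[["vessel"]]
  }

  n <- spec$nPrecontrast + spec$nPostcontrast
  times <- (seq_len(n) - spec$nPrecontrast) * spec$spacing / 60  # minutes

  ## per-voxel truth: mirrored master draws for parenchyma, then asymmetry
  blank <- array(NA_real_, spec$grid)
  sigParams <- c("A", "alpha", "beta")
  pkParams <- c("ktrans", "ve", "vp")
  truthVox <- setNames(rep(list(blank), 6), c(sigParams, pkParams))

  lnorm <- function(meanVal, nDraw) {
    if (spec$dispersion <= 0 || meanVal == 0) return(rep(meanVal, nDraw))
    sign(meanVal) * stats::rlnorm(nDraw,
      log(abs(meanVal)) - spec$dispersion^2 / 2, spec$dispersion)
  }

  ipsIdx <- which(lab == REGION_CODES[["ips_parenchyma"]], arr.ind = TRUE)
  ipsIdx <- ipsIdx[order(ipsIdx[, 1], ipsIdx[, 2], ipsIdx[, 3]), ,
                   drop = FALSE]
  conIdx <- cbind(ipsIdx[, 1], g$mirror(ipsIdx[, 2]), ipsIdx[, 3])
  nPar <- nrow(ipsIdx)
  for (p in c(sigParams, pkParams)) {
    disperse <- p %in% c("A", "alpha", "ktrans")
    master <- if (disperse) lnorm(spec$parenchyma[[p]], nPar)
              else rep(spec$parenchyma[[p]], nPar)
    ipsVal <- master
    if (p == "alpha" || p == "ktrans") ipsVal <- master * spec$r
    truthVox[[p]][ipsIdx] <- ipsVal
    truthVox[[p]][conIdx] <- master
  }

  tumIdx <- which(lab == REGION_CODES[["tumor"]])
  for (p in c(sigParams, pkParams)) {
    disperse <- p %in% c("A", "alpha", "ktrans")
    truthVox[[p]][tumIdx] <- if (disperse)
      lnorm(spec$tumor[[p]], length(tumIdx)) else spec$tumor[[p]]
  }
  vesIdx <- which(lab == REGION_CODES[["vessel"]])
  for (p in c(sigParams, pkParams))
    truthVox[[p]][vesIdx] <- spec$vessel[[p]]

  ## noiseless signal
  vox <- array(spec$s0, c(spec$grid, n))
  enh <- which(!is.na(truthVox$A))
  nVox <- prod(spec$grid)
  if (spec$mode == "signal") {
    for (ti in seq_len(n)) {
      tt <- max(times[ti], 0)
      if (tt == 0) next
      pse <- emm3Eval(truthVox$A[enh], truthVox$alpha[enh],
                      truthVox$beta[enh], tt)
      vox[enh + (ti - 1) * nVox] <- spec$s0 * (1 + pse / 100)
    }
  } else {
    aif <- populationAif()
    t10 <- ifelse(lab[enh] == REGION_CODES[["tumor"]], 1.5, 1.4)
    cc <- etmForwardBatch(truthVox$ktrans[enh], truthVox$ve[enh],
                          truthVox$vp[enh], aif, times)
    for (ti in seq_len(n))
      vox[enh + (ti - 1) * nVox] <-
        spgrSignal(cc[, ti], s0 = spec$s0, t10 = t10)
  }

  if (spec$noiseModel != "none" && spec$noiseSd > 0) {
    sigma <- spec$noiseSd * spec$s0
    if (spec$noiseModel == "gaussian") {
      vox <- pmax(vox + stats::rnorm(length(vox), 0, sigma), 0)
    } else {
      vox <- sqrt((vox + stats::rnorm(length(vox), 0, sigma))^2 +
                  stats::rnorm(length(vox), 0, sigma)^2)
    }
  }

  regions <- do.call(rbind, lapply(
    c("ips_parenchyma", "con_parenchyma", "tumor", "vessel"),
    function(rn) {
      base <- switch(rn, ips_parenchyma = , con_parenchyma = spec$parenchyma,
                     tumor = spec$tumor, vessel = spec$vessel)
      fac <- if (rn == "ips_parenchyma") spec$r else 1
      data.frame(region = rn, A = base$A, alpha = base$alpha * fac,
                 Aalpha = base$A * base$alpha * fac, beta = base$beta,
                 ktrans = base$ktrans * fac, ve = base$ve, vp = base$vp,
                 dispersion = if (rn == "vessel") 0 else spec$dispersion)
    }))

  list(
    series = DynamicSeries(vox, times, spec$nPrecontrast,
                           voxelSize = spec$voxelSize),
    labels = RegionLabels(lab, spec$laterality),
    truth = list(regions = regions, voxel = truthVox,
                 mode = spec$mode, r = spec$r, seed = spec$seed)
  )
}
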