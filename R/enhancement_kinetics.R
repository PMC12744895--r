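#' Percent signal enhancement of a voxel or region mean
#'
#' PSE(t) = 100 * (S(t) - Spre) / Spre, with Spre the mean signal over the
#' precontrast frames. For a region, the raw signal is averaged over the
#' selected voxels first and the enhancement computed from the mean curve
#' with its own baseline (not by averaging per-voxel PSE).
#'
#' @param series a [DynamicSeries-class].
#' @param voxel integer length-3 voxel index, or
#' @param mask logical/integer 3D array selecting the voxels to average.
#' @return A [PseCurve-class]; errors if the baseline is not positive.
#' @export
computePse <- function(series, voxel = NULL, mask = NULL) {
  v <- seriesData(series)
  nt <- dim(v)[4L]
  if (!is.null(voxel)) {
    sig <- v[voxel[1], voxel[2], voxel[3], ]
    n <- 1L
  } else if (!is.null(mask)) {
    idx <- which(mask != 0)
    if (length(idx) == 0L) stop("mask selects no voxels")
    m <- matrix(v, ncol = nt)[idx, , drop = FALSE]
    sig <- colMeans(m)
    n <- length(idx)
  } else stop("give either voxel or mask")
  npre <- nPrecontrast(series)
  base <- mean(sig[seq_len(npre)])
  if (!is.finite(base) || base <= 0)
    stop("non-positive precontrast baseline: voxel invalid for enhancement")
  PseCurve(frameTimes(series), 100 * (sig - base) / base, base, n)
}

#' Two-parameter empirical enhancement model
#'
#' PSE(t) = A * alpha * t^2 / (1 + alpha * t^2): a monotone saturating uptake
#' curve. A (percent) is the asymptotic enhancement; alpha (1/min) the
#' initial uptake rate; A*alpha is the maximum-enhancement-rate proxy used
#' for clustering.
#'
#' @param A scaling constant, percent.
#' @param alpha uptake rate, 1/min.
#' @param t time since bolus, minutes (model is 0 at t <= 0).
#' @return Modeled percent enhancement, vectorized over `t`.
#' @export
emm2Eval <- function(A, alpha, t) {
  t <- pmax(t, 0)
  A * alpha * t^2 / (1 + alpha * t^2)
}

#' Three-parameter empirical enhancement model
#'
#' PSE(t) = A * alpha * t^2 / (1 + alpha * t^2) * exp(-beta * t). beta
#' (1/min) is the washout rate; beta < 0 describes persistent late uptake
#' and is permitted.
#'
#' @inheritParams emm2Eval
#' @param beta washout rate, 1/min (may be negative).
#' @return Modeled percent enhancement, vectorized over `t`.
#' @export
emm3Eval <- function(A, alpha, beta, t) {
  t <- pmax(t, 0)
  emm2Eval(A, alpha, t) * exp(-beta * t)
}

#' Early area under the modeled enhancement curve (first 30 s)
#'
#' Integrates the three-parameter enhancement model from 0 to t30 = 0.5 min
#' by adaptive quadrature (absolute tolerance 1e-8). With beta = 0 this
#' equals the closed form A * (t30 - atan(sqrt(alpha) * t30) / sqrt(alpha)).
#'
#' @inheritParams emm3Eval
#' @param t30 upper limit in minutes, default 0.5.
#' @return Area in percent * min.
#' @export
auc30 <- function(A, alpha, beta = 0, t30 = 0.5) {
  if (!all(is.finite(c(A, alpha, beta)))) stop("parameters must be finite")
  if (A == 0) return(0)
  stats::integrate(function(t) emm3Eval(A, alpha, beta, t), 0, t30,
                   abs.tol = 1e-8, rel.tol = 1e-10)$value
}

## Postcontrast times relative to the fit origin (last precontrast frame,
## plus an optional bolus-arrival offset).
#' @keywords internal
postTimes <- function(series, timeOffset = 0) {
  tt <- frameTimes(series)
  npre <- nPrecontrast(series)
  post <- (npre + 1L):length(tt)
  list(idx = post, t = tt[post] - tt[npre] - timeOffset)
}

## Separable least squares for the 2-parameter model: for fixed alpha the
## amplitude is linear, A(alpha) = sum(g*y)/sum(g^2) with
## g = alpha t^2/(1+alpha t^2), so the voxel fit is a bounded 1-D search
## over alpha with A profiled out. Y is (nvox x nt).
#' @keywords internal
fitEmm2Matrix <- function(Y, t, alphaMax = 100, aMax = 1000,
                          nGrid = 60L, tol = 1e-12) {
  nvox <- nrow(Y)
  alphaGrid <- c(0, exp(seq(log(1e-3), log(alphaMax), length.out = nGrid - 1)))
  G <- outer(alphaGrid, t, function(a, tt) a * tt^2 / (1 + a * tt^2))
  den <- rowSums(G^2)
  den[den == 0] <- Inf                      # alpha = 0 column: A irrelevant
  NUM <- Y %*% t(G)                         # nvox x nGrid
  yss <- rowSums(Y^2)
  RSS <- yss - sweep(NUM^2, 2, den, "/")
  best <- max.col(-RSS, ties.method = "first")

  A <- numeric(nvox); alpha <- numeric(nvox); rss <- numeric(nvox)
  obj <- function(a, y) {
    g <- a * t^2 / (1 + a * t^2)
    d <- sum(g^2)
    if (d == 0) return(sum(y^2))
    amp <- min(max(sum(g * y) / d, 0), aMax)
    sum((y - amp * g)^2)
  }
  for (i in seq_len(nvox)) {
    j <- best[i]
    lo <- alphaGrid[max(j - 1L, 1L)]
    hi <- alphaGrid[min(j + 1L, nGrid)]
    y <- Y[i, ]
    if (hi > lo) {
      op <- stats::optimize(obj, c(lo, hi), y = y, tol = tol)
      alpha[i] <- op$minimum; rss[i] <- op$objective
    } else {
      alpha[i] <- alphaGrid[j]; rss[i] <- obj(alpha[i], y)
    }
    g <- alpha[i] * t^2 / (1 + alpha[i] * t^2)
    d <- sum(g^2)
    A[i] <- if (d > 0) min(max(sum(g * y) / d, 0), aMax) else 0
  }
  list(A = A, alpha = alpha, rss = rss)
}

#' Voxelwise two-parameter enhancement-model fit over a region
#'
#' Computes each region voxel's PSE curve and fits the two-parameter model to
#' its postcontrast frames by bounded separable least squares
#' (A in [0, 1000] percent, alpha in [0, 100] 1/min). The two-parameter form
#' is used voxelwise to avoid over-fitting noisy single-voxel curves; the
#' A*alpha product map drives the k-means segmentation.
#'
#' @param series a [DynamicSeries-class].
#' @param labels a [RegionLabels-class] on the same grid.
#' @param region region name (see [REGION_CODES]) or integer code.
#' @param timeOffset bolus-arrival offset in minutes subtracted from the
#'   postcontrast times (default 0: origin at the last precontrast frame).
#' @param minEnhancement percent; voxels whose fitted A falls below it are
#'   flagged `lowEnhancement`.
#' @return List of 3D maps (`A`, `alpha`, `Aalpha`, `rss`) plus logical maps
#'   `valid` (positive baseline, fit usable) and `lowEnhancement`, and the
#'   region name. Voxels outside the region are NA / FALSE.
#' @export
fitEmm2Voxelwise <- function(series, labels, region = "ips_parenchyma",
                             timeOffset = 0, minEnhancement = 5) {
  code <- regionCode(region)
  arr <- labelMap(labels)
  v <- seriesData(series)
  if (!all(dim(arr) == dim(v)[1:3]))
    stop("label grid does not match series grid")
  pt <- postTimes(series, timeOffset)
  if (length(pt$t) < 4L)
    stop("need at least 4 postcontrast frames for the voxelwise fit")
  idx <- which(arr == code)
  if (length(idx) == 0L)
    stop("region '", regionName(code), "' has no voxels")
  nt <- dim(v)[4L]
  M <- matrix(v, ncol = nt)[idx, , drop = FALSE]
  base <- rowMeans(M[, seq_len(nPrecontrast(series)), drop = FALSE])
  ok <- is.finite(base) & base > 0
  if (!any(ok))
    stop("all voxels in region '", regionName(code),
         "' have non-positive baselines")
  Y <- 100 * (M[ok, pt$idx, drop = FALSE] - base[ok]) / base[ok]
  fit <- fitEmm2Matrix(Y, pt$t)

  shape <- dim(arr)
  blank <- array(NA_real_, shape)
  out <- list(A = blank, alpha = blank, Aalpha = blank, rss = blank,
              valid = array(FALSE, shape),
              lowEnhancement = array(FALSE, shape),
              region = regionName(code))
  sel <- idx[ok]
  out$A[sel] <- fit$A
  out$alpha[sel] <- fit$alpha
  out$Aalpha[sel] <- fit$A * fit$alpha
  out$rss[sel] <- fit$rss
  out$valid[sel] <- TRUE
  out$lowEnhancement[sel] <- fit$A < minEnhancement
  out
}

#' Cluster-level three-parameter enhancement-model fit with AUC30
#'
#' Fits PSE(t) = A*alpha*t^2/(1+alpha*t^2)*exp(-beta*t) to a cluster-mean
#' curve by bounded Levenberg-Marquardt least squares (A in [0, 1000],
#' alpha in [0, 100], beta in [-2, 10]), initialized from a two-parameter
#' fit with beta = 0. Only postcontrast frames (t > 0) enter the fit. The
#' three-parameter form is reserved for cluster averages, whose SNR supports
#' estimating the washout rate.
#'
#' @param curve a [PseCurve-class] (cluster-mean enhancement).
#' @param timeOffset bolus-arrival offset in minutes.
#' @param betaBounds bounds on beta, 1/min.
#' @return data.frame row: A, alpha, beta, Aalpha, auc30, rss, converged.
#'   Non-convergence is flagged, not hidden; a flat curve yields A ~ 0.
#' @export
fitEmm3Curve <- function(curve, timeOffset = 0, betaBounds = c(-2, 10)) {
  tAll <- curve@times
  origin <- if (any(tAll <= 0)) max(tAll[tAll <= 0]) else 0
  keep <- tAll > origin
  t <- tAll[keep] - origin - timeOffset
  y <- curve@pse[keep]
  if (length(t) < 5L)
    stop("need at least 5 postcontrast frames for the 3-parameter fit")

  init <- fitEmm2Matrix(matrix(y, nrow = 1), t)
  start <- c(A = init$A[1], alpha = max(init$alpha[1], 1e-3), beta = 0)
  lower <- c(0, 0, betaBounds[1])
  upper <- c(1000, 100, betaBounds[2])
  fit <- minpack.lm::nls.lm(
    par = pmin(pmax(start, lower), upper),
    lower = lower, upper = upper,
    fn = function(p) y - emm3Eval(p[1], p[2], p[3], t),
    control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-12,
                                         ftol = 1e-12))
  p <- fit$par
  converged <- fit$info %in% 1:4
  data.frame(A = p[1], alpha = p[2], beta = p[3], Aalpha = p[1] * p[2],
             auc30 = auc30(p[1], p[2], p[3]),
             rss = sum(fit$fvec^2), converged = converged)
}

#' @keywords internal
regionCode <- function(region) {
  if (is.numeric(region)) {
    if (!region %in% REGION_CODES) stop("unknown region code: ", region)
    return(as.integer(region))
  }
  if (!region %in% names(REGION_CODES))
    stop("unknown region name: ", region)
  REGION_CODES[[region]]
}

#' @keywords internal
regionName <- function(code) names(REGION_CODES)[match(code, REGION_CODES)]
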