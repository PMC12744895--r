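#' Evaluate a population arterial input function
#'
#' The built-in form is the bi-Gaussian plus sigmoid-modulated exponential
#' population AIF (Parker et al. 2006): two Gaussian bolus passes plus an
#' exponential washout gated by a sigmoid. Cp(t) = 0 strictly before the
#' bolus arrival time.
#'
#' @param aif a [PopulationAif-class].
#' @param t time(s) in minutes.
#' @return Plasma concentration Cp(t) in mM, vectorized over `t`.
#' @export
evalAif <- function(aif, t) {
  p <- aif@params
  tt <- t - aif@bolusArrival
  cp <- p[["A1"]] / (p[["sigma1"]] * sqrt(2 * pi)) *
          exp(-(tt - p[["T1"]])^2 / (2 * p[["sigma1"]]^2)) +
        p[["A2"]] / (p[["sigma2"]] * sqrt(2 * pi)) *
          exp(-(tt - p[["T2"]])^2 / (2 * p[["sigma2"]]^2)) +
        p[["alpha"]] * exp(-p[["beta"]] * tt) /
          (1 + exp(-p[["s"]] * (tt - p[["tau"]])))
  cp[tt < 0] <- 0
  pmax(cp, 0)
}

#' Convert an enhancement curve to tissue contrast concentration
#'
#' `mode = "spgr"` (default) inverts the spoiled-gradient-echo signal
#' equation: the enhancement ratio S(t)/Spre and the precontrast T1 give
#' E1(t) = exp(-TR * R1(t)); then C(t) = (R1(t) - 1/T10)/r1. Frames whose
#' signal ratio exceeds the invertible range of the SPGR equation are
#' clipped to the bound and flagged. `mode = "linear"` uses the small-
#' enhancement approximation C(t) = PSE(t)/(100 * r1 * T10).
#'
#' @param curve a [PseCurve-class].
#' @param t10 precontrast tissue T1, seconds (defaults: parenchyma 1.4,
#'   tumor 1.5 at 3 T).
#' @param relaxivity contrast-agent longitudinal relaxivity, L/(mmol s).
#' @param tr repetition time, seconds.
#' @param flipAngle flip angle, degrees (0 < angle < 90).
#' @param mode `"spgr"` or `"linear"`.
#' @return A [ConcentrationCurve-class] (mM), with clipped frames flagged.
#' @export
pseToConcentration <- function(curve, t10 = 1.4, relaxivity = 5.0,
                               tr = 0.004, flipAngle = 12,
                               mode = c("spgr", "linear")) {
  mode <- match.arg(mode)
  if (t10 <= 0 || relaxivity <= 0 || tr <= 0)
    stop("t10, relaxivity and tr must be positive")
  if (flipAngle <= 0 || flipAngle >= 90)
    stop("flipAngle must be in (0, 90) degrees")
  pse <- curve@pse
  flagged <- rep(FALSE, length(pse))
  if (mode == "linear") {
    conc <- pse / (100 * relaxivity * t10)
  } else {
    cosa <- cos(flipAngle * pi / 180)
    R10 <- 1 / t10
    E10 <- exp(-tr * R10)
    fpre <- (1 - E10) / (1 - E10 * cosa)
    B <- (1 + pse / 100) * fpre
    bad <- B >= 1
    if (any(bad)) {
      flagged[bad] <- TRUE
      B[bad] <- 1 - 1e-9
      warning(sum(bad), " frame(s) outside the invertible SPGR range; ",
              "clipped", call. = FALSE)
    }
    E1 <- (1 - B) / (1 - B * cosa)
    R1 <- -log(E1) / tr
    conc <- (R1 - R10) / relaxivity
  }
  ConcentrationCurve(curve@times, conc, flagged)
}

#' Forward-simulate SPGR signal from a concentration curve
#'
#' The inverse of [pseToConcentration()] in `"spgr"` mode: R1(t) = 1/T10 +
#' r1 * C(t) mapped through the spoiled-gradient-echo signal equation and
#' scaled so the precontrast signal equals `s0`. Used by the phantom's
#' concentration mode and as the round-trip oracle for the inversion.
#'
#' @param conc concentration values, mM.
#' @param s0 baseline (precontrast) signal.
#' @inheritParams pseToConcentration
#' @return Signal values, same length as `conc`.
#' @export
spgrSignal <- function(conc, s0 = 100, t10 = 1.4, relaxivity = 5.0,
                       tr = 0.004, flipAngle = 12) {
  cosa <- cos(flipAngle * pi / 180)
  R1 <- 1 / t10 + relaxivity * conc
  E1 <- exp(-tr * R1)
  f <- (1 - E1) / (1 - E1 * cosa)
  E10 <- exp(-tr / t10)
  fpre <- (1 - E10) / (1 - E10 * cosa)
  s0 * f / fpre
}

## Exactly uniform fine grid from 0 to max(tpos) whose spacing is at most
## min frame spacing / refine (the recursion below requires uniformity).
#' @keywords internal
uniformFineGrid <- function(tpos, refine) {
  spacing <- min(diff(c(0, tpos)))
  N <- ceiling(max(tpos) / (spacing / refine) - 1e-9)
  list(grid = seq(0, max(tpos), length.out = N + 1L), h = max(tpos) / N)
}

## Exponential-kernel convolution int_0^t Cp(tau) exp(-k (t - tau)) dtau for
## piecewise-linear Cp on a uniform grid, by the exact interval recursion.
#' @keywords internal
expConvolve <- function(cp, h, k) {
  n <- length(cp)
  out <- numeric(n)
  E <- exp(-k * h)
  if (k * h < 1e-4) {
    # closed forms cancel catastrophically for small k*h; use their series
    w1 <- h / 2 - k * h^2 / 6 + k^2 * h^3 / 24
    w0 <- h / 2 - k * h^2 / 3 + k^2 * h^3 / 8
  } else {
    w1 <- (h - (1 - E) / k) / (k * h)                 # weight on cp[i+1]
    w0 <- (1 - E) / k - w1                            # weight on cp[i]
  }
  for (i in seq_len(n - 1L))
    out[i + 1L] <- out[i] * E + w0 * cp[i] + w1 * cp[i + 1L]
  out
}

#' Extended Tofts model forward simulation
#'
#' C(t) = vp * Cp(t) + Ktrans * int_0^t Cp(tau) exp(-(Ktrans/ve)(t - tau))
#' dtau. The convolution is evaluated with the exact exponential-kernel
#' recursion for piecewise-linear Cp on a uniform grid refined at least
#' `refine`-fold over the frame spacing, then read off at the requested
#' times.
#'
#' @param ktrans transfer constant, 1/min.
#' @param ve extravascular extracellular volume fraction (0, 1].
#' @param vp plasma volume fraction.
#' @param aif a [PopulationAif-class].
#' @param times sample times in minutes, increasing; times <= 0 yield 0.
#' @param refine grid refinement factor over the minimum frame spacing.
#' @return A [ConcentrationCurve-class] at `times`.
#' @export
etmForward <- function(ktrans, ve, vp, aif, times, refine = 40L) {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  tpos <- times[times > 0]
  conc <- numeric(length(times))
  if (length(tpos)) {
    g <- uniformFineGrid(tpos, refine)
    grid <- g$grid; h <- g$h
    cp <- evalAif(aif, grid)
    kep <- if (ve > 0) ktrans / ve else 0
    cv <- expConvolve(cp, h, kep)
    # vp * Cp is evaluated exactly at the sample times; only the (smooth)
    # convolution integral is read off the refined grid
    conc[times > 0] <- vp * evalAif(aif, tpos) +
      ktrans * stats::approx(grid, cv, xout = tpos, rule = 2)$y
  }
  ConcentrationCurve(times, conc)
}

## Batched Tofts forward model: many (ktrans, ve, vp) triples sharing one
## AIF and one time grid. The exponential-kernel recursion runs vectorized
## across voxels, one step per refined-grid point.
#' @keywords internal
etmForwardBatch <- function(ktrans, ve, vp, aif, times, refine = 40L) {
  tpos <- times[times > 0]
  nv <- length(ktrans)
  out <- matrix(0, nv, length(times))
  if (!length(tpos)) return(out)
  g <- uniformFineGrid(tpos, refine)
  grid <- g$grid; h <- g$h
  cp <- evalAif(aif, grid)
  k <- ifelse(ve > 0, ktrans / ve, 0)
  E <- exp(-k * h)
  small <- k * h < 1e-4
  w1 <- ifelse(small, h / 2 - k * h^2 / 6 + k^2 * h^3 / 24,
               (h - (1 - E) / k) / (k * h))
  w0 <- ifelse(small, h / 2 - k * h^2 / 3 + k^2 * h^3 / 8,
               (1 - E) / k - w1)
  cv <- matrix(0, nv, length(grid))
  for (i in seq_len(length(grid) - 1L))
    cv[, i + 1L] <- cv[, i] * E + w0 * cp[i] + w1 * cp[i + 1L]
  j <- findInterval(tpos, grid, rightmost.closed = TRUE)
  j <- pmin(j, length(grid) - 1L)
  w <- (tpos - grid[j]) / h
  conv <- cv[, j, drop = FALSE] * rep(1 - w, each = nv) +
          cv[, j + 1L, drop = FALSE] * rep(w, each = nv)
  out[, times > 0] <- ktrans * conv +
    vp %o% evalAif(aif, tpos)
  out
}

#' Fit the extended Tofts model to a tissue concentration curve
#'
#' Bounded Levenberg-Marquardt least squares over (Ktrans, ve, vp), with
#' Ktrans in [0, 5] 1/min, ve in [1e-3, 1], vp in [0, 0.2]. Three
#' deterministic starting points guard against local minima; the best-RSS
#' fit is returned (ties to the first start). Kep is derived as Ktrans/ve
#' after the fit, so kep * ve = ktrans holds exactly in every emitted fit.
#'
#' @param curve a [ConcentrationCurve-class]; only frames with t > 0 enter
#'   the fit (at least 6 required).
#' @param aif a [PopulationAif-class].
#' @param refine forward-model grid refinement (see [etmForward()]).
#' @return data.frame row: ktrans, ve, vp, kep, rss, converged. A zero curve
#'   yields ktrans ~ 0 flagged unconverged-free but trivially fit.
#' @export
fitEtm <- function(curve, aif, refine = 40L) {
  keep <- curve@times > 0
  t <- curve@times[keep]
  y <- curve@conc[keep]
  if (length(t) < 6L)
    stop("need at least 6 postcontrast frames for the Tofts fit")
  lower <- c(ktrans = 0, ve = 1e-3, vp = 0)
  upper <- c(ktrans = 5, ve = 1, vp = 0.2)
  starts <- list(c(ktrans = 0.05, ve = 0.2, vp = 0.005),
                 c(ktrans = 0.2, ve = 0.4, vp = 0.01),
                 c(ktrans = 1.0, ve = 0.6, vp = 0.05))
  resid <- function(p)
    y - etmForward(p[1], p[2], p[3], aif, t, refine = refine)@conc[t > 0]
  best <- NULL
  for (s in starts) {
    fit <- minpack.lm::nls.lm(
      par = s, lower = lower, upper = upper, fn = resid,
      control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-10,
                                           ftol = 1e-10))
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(fit = fit, rss = rss)
  }
  p <- best$fit$par
  data.frame(ktrans = p[[1]], ve = p[[2]], vp = p[[3]],
             kep = p[[1]] / p[[2]], rss = best$rss,
             converged = best$fit$info %in% 1:4)
}
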