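test_that("population AIF is zero before bolus, nonnegative, and peaks where
           a dense-grid oracle says", {
  aif <- populationAif(bolusArrival = 0.2)
  expect_equal(evalAif(aif, c(-1, 0, 0.1, 0.1999)), rep(0, 4))
  tg <- seq(0, 5, by = 0.001)
  cp <- evalAif(aif, tg)
  expect_true(all(cp >= 0))
  # dense argmax oracle: evaluate the same parameter vector independently
  p <- aif@params
  tt <- tg - 0.2
  oracle <- p[["A1"]] / (p[["sigma1"]] * sqrt(2 * pi)) *
              exp(-(tt - p[["T1"]])^2 / (2 * p[["sigma1"]]^2)) +
            p[["A2"]] / (p[["sigma2"]] * sqrt(2 * pi)) *
              exp(-(tt - p[["T2"]])^2 / (2 * p[["sigma2"]]^2)) +
            p[["alpha"]] * exp(-p[["beta"]] * tt) /
              (1 + exp(-p[["s"]] * (tt - p[["tau"]])))
  oracle[tt < 0] <- 0
  expect_equal(which.max(cp), which.max(oracle))
  expect_equal(max(cp), max(oracle), tolerance = 1e-12)
})

test_that("concentration conversion obeys stated formulas and round-trips", {
  times <- c(-0.1, 0, (1:12) * 5 / 60)
  zero <- PseCurve(times, rep(0, length(times)), 100)
  expect_equal(pseToConcentration(zero, mode = "linear")@conc,
               rep(0, length(times)))
  expect_equal(pseToConcentration(zero, mode = "spgr")@conc,
               rep(0, length(times)), tolerance = 1e-12)
  # linear mode arithmetic: PSE 50 %, t10 1.4 s, r1 5.0 -> 0.0714 mM
  half <- PseCurve(times, c(0, 0, rep(50, 12)), 100)
  expect_equal(pseToConcentration(half, t10 = 1.4, relaxivity = 5,
                                  mode = "linear")@conc[3],
               0.5 / (5 * 1.4), tolerance = 1e-12)
  # SPGR round-trip: forward-simulate signal from known C(t), invert
  aif <- populationAif()
  cc <- etmForward(0.21, 0.33, 0.006, aif, times)@conc
  sig <- spgrSignal(cc, s0 = 100, t10 = 1.5)
  pse <- PseCurve(times, 100 * (sig - 100) / 100, 100)
  back <- pseToConcentration(pse, t10 = 1.5, mode = "spgr")
  expect_lt(max(abs(back@conc - cc)), 1e-6)
  expect_false(any(back@flagged))
  # out-of-range frames are clipped and flagged, with warning
  crazy <- PseCurve(times, c(0, 0, rep(1e7, 12)), 100)
  expect_warning(out <- pseToConcentration(crazy, mode = "spgr"),
                 "invertible")
  expect_true(any(out@flagged))
})

test_that("Tofts forward model handles degenerate parameters exactly", {
  aif <- populationAif()
  times <- c(-0.1, 0, (1:12) * 5 / 60)
  expect_equal(etmForward(0, 0.3, 0, aif, times)@conc,
               rep(0, length(times)))
  vpOnly <- etmForward(0, 0.3, 0.05, aif, times)@conc
  expect_equal(vpOnly, 0.05 * evalAif(aif, pmax(times, 0)) *
                 (times > 0), tolerance = 1e-14)
})

test_that("Tofts forward model matches a fine trapezoid oracle", {
  aif <- populationAif()
  times <- c(0, (1:12) * 5 / 60)
  trapOracle <- function(kt, ve, vp) {
    k <- kt / ve
    tp <- times[times > 0]
    conv <- vapply(tp, function(T) {
      g <- seq(0, T, length.out = 4001)
      y <- evalAif(aif, g) * exp(-k * (T - g))
      sum(diff(g) * (y[-1] + y[-length(y)]) / 2)
    }, numeric(1))
    c(0, vp * evalAif(aif, tp) + kt * conv)
  }
  for (p in list(c(0.21, 0.33, 0.006), c(0.5, 0.6, 0.02),
                 c(0.05, 0.2, 0.001))) {
    got <- etmForward(p[1], p[2], p[3], aif, times)@conc
    expect_lt(max(abs(got - trapOracle(p[1], p[2], p[3]))), 1e-5)
  }
})

test_that("forward model is linear in vp and in Ktrans at fixed kep", {
  aif <- populationAif()
  times <- c(0, (1:12) * 5 / 60)
  base <- etmForward(0.2, 0.4, 0, aif, times)@conc
  expect_equal(etmForward(0.4, 0.8, 0, aif, times)@conc, 2 * base,
               tolerance = 1e-12)                  # same kep, double Ktrans
  vp1 <- etmForward(0.2, 0.4, 0.01, aif, times)@conc
  vp2 <- etmForward(0.2, 0.4, 0.02, aif, times)@conc
  expect_equal(vp2 - vp1, vp1 - base, tolerance = 1e-12)
})

test_that("Tofts fit recovers noiseless forward simulations", {
  aif <- populationAif()
  times <- c(-(4:0) * 5 / 60, (1:12) * 5 / 60)     # 60 s window at 5 s
  for (p in list(c(0.21, 0.33, 0.006), c(0.05, 0.2, 0.02),
                 c(0.5, 0.6, 0.001))) {
    cc <- etmForward(p[1], p[2], p[3], aif, times)
    fit <- fitEtm(cc, aif)
    expect_true(fit$converged)
    expect_lt(abs(fit$ktrans - p[1]) / p[1], 0.02)
    expect_lt(abs(fit$vp - p[3]) / max(p[3], 1e-3), 0.02)
    expect_lt(abs(fit$ve - p[2]) / p[2], 0.15)
    expect_equal(fit$kep * fit$ve, fit$ktrans, tolerance = 1e-12)
  }
  # zero curve collapses to zero transfer
  z <- fitEtm(ConcentrationCurve(times, rep(0, length(times))), aif)
  expect_lt(z$ktrans, 1e-8)
})

test_that("ve recovery tightens with a longer acquisition window", {
  aif <- populationAif()
  short <- c(0, (1:12) * 5 / 60)                   # 60 s
  long <- c(0, (1:60) * 5 / 60)                    # 300 s
  p <- c(0.21, 0.33, 0.006)
  fitS <- fitEtm(etmForward(p[1], p[2], p[3], aif, short), aif)
  fitL <- fitEtm(etmForward(p[1], p[2], p[3], aif, long), aif)
  expect_lt(abs(fitL$ve - p[2]) / p[2], 0.02)
  expect_lte(abs(fitL$ve - p[2]), abs(fitS$ve - p[2]) + 1e-9)
})
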