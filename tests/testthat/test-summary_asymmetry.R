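test_that("weighted averages follow the stated weights and propagate NA", {
  expect_equal(weightedParenchymaAverage(1, 1, 1), 1)
  expect_equal(weightedParenchymaAverage(0.9, 1.0, 1.1),
               (1.8 + 3.0 + 4.4) / 9)
  expect_true(is.na(weightedParenchymaAverage(1, NA, 2)))
  expect_equal(weightedTumorAverage(1, 1, 1), 1)
  expect_equal(weightedTumorAverage(0.5, 1.0, 1.5),
               (1.5 + 4.0 + 7.5) / 12)
  expect_equal(weightedTumorAverage(0, 0, 12), 5)
  expect_true(is.na(weightedTumorAverage(NA, 1, 1)))
})

test_that("weighted averages are affine-equivariant", {
  set.seed(8)
  for (i in 1:20) {
    v <- rnorm(3); c0 <- rnorm(1); s0 <- runif(1, 0.1, 10)
    expect_equal(weightedParenchymaAverage(v[1] + c0, v[2] + c0, v[3] + c0),
                 weightedParenchymaAverage(v[1], v[2], v[3]) + c0)
    expect_equal(weightedTumorAverage(s0 * v[1], s0 * v[2], s0 * v[3]),
                 s0 * weightedTumorAverage(v[1], v[2], v[3]))
  }
})

test_that("I/C ratio guards its denominator and propagates missing", {
  expect_equal(icRatio(1.45, 1.0), 1.45)
  expect_equal(icRatio(2, 2), 1)
  expect_warning(r <- icRatio(1, 0), "undefined")
  expect_true(is.na(r))
  expect_true(is.na(suppressWarnings(icRatio(NA, 1))))
})

test_that("tumor volume is count times voxel volume in cm^3", {
  lab <- array(0L, c(10, 10, 10))
  lab[1:10, 1:10, 1:10] <- 0L
  lab[seq_len(1000)] <- REGION_CODES[["tumor"]]
  rl <- RegionLabels(lab, "left")
  expect_equal(tumorVolume(rl, c(1.5, 1.5, 3)), 6.75)
  lab2 <- lab; lab2[] <- 0L; lab2[seq_len(500)] <- REGION_CODES[["tumor"]]
  expect_equal(tumorVolume(RegionLabels(lab2, "left"), c(1.5, 1.5, 3)),
               6.75 / 2)
  empty <- RegionLabels(array(0L, c(4, 4, 4)), "left")
  expect_warning(v <- tumorVolume(empty, c(1, 1, 1)), "no tumor")
  expect_equal(v, 0)
})

makeClusterFits <- function(ips, con, tum) {
  data.frame(
    region = rep(c("ips_parenchyma", "con_parenchyma", "tumor"), each = 5),
    cluster = rep(1:5, 3),
    A = c(ips, con, tum), alpha = rep(2, 15), beta = rep(0.05, 15),
    auc30 = rep(1, 15), ktrans = rep(0.1, 15), ve = rep(0.4, 15),
    vp = rep(0.01, 15))
}

test_that("patient summary applies the weighting and per-cluster identities", {
  cf <- makeClusterFits(ips = c(5, 10, 20, 30, 99),
                        con = c(5, 10, 20, 30, 99),
                        tum = c(1, 2, 50, 100, 200))
  s <- summarizePatient(cf)
  p <- s$parameters
  expect_equal(p$kbpe_ips[p$parameter == "A"],
               (2 * 10 + 3 * 20 + 4 * 30) / 9)
  expect_equal(p$kbpe_ic[p$parameter == "A"], 1)
  expect_equal(p$kt_ave[p$parameter == "A"],
               (3 * 50 + 4 * 100 + 5 * 200) / 12)
  # composites derived per cluster before averaging
  expect_equal(p$kbpe_ips[p$parameter == "Aalpha"],
               (2 * 20 + 3 * 40 + 4 * 60) / 9)
  expect_equal(p$kbpe_ips[p$parameter == "kep"], 0.1 / 0.4)
})

test_that("missing required clusters make the parameter missing", {
  cf <- makeClusterFits(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5),
                        c(1, 2, 3, 4, 5))
  cf$A[cf$region == "ips_parenchyma" & cf$cluster == 3] <- NA
  s <- summarizePatient(cf)
  p <- s$parameters
  expect_true(is.na(p$kbpe_ips[p$parameter == "A"]))
  expect_true(is.na(p$kbpe_ic[p$parameter == "A"]))
  expect_false(is.na(p$kt_ave[p$parameter == "A"]))
  # unconverged rows count as missing
  cf2 <- makeClusterFits(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5),
                         c(1, 2, 3, 4, 5))
  cf2$converged <- TRUE
  cf2$converged[cf2$region == "tumor" & cf2$cluster == 5] <- FALSE
  p2 <- summarizePatient(cf2)$parameters
  expect_true(is.na(p2$kt_ave[p2$parameter == "A"]))
})

test_that("I/C is invariant under common rescaling of both breasts", {
  cf <- makeClusterFits(c(5, 12, 22, 31, 90), c(4, 11, 20, 30, 85),
                        c(1, 2, 50, 100, 200))
  base <- summarizePatient(cf)$parameters
  cf2 <- cf
  scaleCols <- c("A", "alpha", "auc30", "ktrans", "ve", "vp")
  for (cl in scaleCols)
    cf2[[cl]][cf2$region != "tumor"] <- 3.7 * cf2[[cl]][cf2$region != "tumor"]
  scaled <- summarizePatient(cf2)$parameters
  expect_equal(scaled$kbpe_ic, base$kbpe_ic, tolerance = 1e-12)
})

test_that("summaries are order-independent in cluster input order", {
  cf <- makeClusterFits(c(5, 12, 22, 31, 90), c(4, 11, 20, 30, 85),
                        c(1, 2, 50, 100, 200))
  perm <- sample(nrow(cf))
  expect_equal(summarizePatient(cf[perm, ])$parameters,
               summarizePatient(cf)$parameters)
})
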