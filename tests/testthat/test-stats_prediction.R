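test_that("rocAuc equals exhaustive pair counting on random instances", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- if (i %% 3 == 0) sample(1:5, n, replace = TRUE) else rnorm(n)
    expect_equal(rocAuc(s, y), pairCountAuc(s, y), tolerance = 1e-12)
  }
})

test_that("rocAuc satisfies its textbook identities", {
  expect_equal(rocAuc(c(1, 2, 9, 10), c(0, 0, 1, 1)), 1)
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(rocAuc(rep(1, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  set.seed(14)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  expect_equal(rocAuc(s, y) + rocAuc(s, 1 - y), 1)            # complement
  expect_equal(rocAuc(exp(3 * s) + 2, y), rocAuc(s, y))       # monotone inv
  expect_error(rocAuc(s, rep(1, 40)), "both outcome classes")
})

test_that("rocAuc agrees with pROC as an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  s <- rnorm(60); y <- rbinom(60, 1, 0.4); y[1:2] <- c(0, 1)
  oracle <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(rocAuc(s, y), oracle, tolerance = 1e-12)
})

test_that("group comparison reproduces exact small-sample results", {
  co <- data.frame(outcome = factor(rep(c("nonpCR", "pCR"), each = 3),
                                    levels = c("nonpCR", "pCR")),
                   x = c(1, 2, 3, 4, 5, 6))
  r <- compareGroups(co, "x", nBoot = 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$p, enumWilcoxP(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$test, "wilcoxon-exact")
  expect_equal(r$auc, 1)
  # identical groups (fully tied values): p = 1
  co2 <- data.frame(outcome = co$outcome, x = c(1, 2, 3, 1, 2, 3))
  expect_equal(compareGroups(co2, "x", nBoot = 0)$p, 1)
  # balanced 2x2 table: chi-square statistic 0, p = 1
  co3 <- data.frame(outcome = factor(rep(c("nonpCR", "pCR"), each = 20),
                                     levels = c("nonpCR", "pCR")),
                    g = rep(c(0, 1, 0, 1), each = 10))
  r3 <- compareGroups(co3, "g")
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p, 1)
  # constant feature flagged
  co4 <- data.frame(outcome = co3$outcome, x = rep(2.5, 40))
  expect_equal(compareGroups(co4, "x")$type, "degenerate")
})

test_that("youden operating point matches an exhaustive threshold sweep", {
  s <- c(0.1, 0.4, 0.35, 0.8); y <- c(0, 0, 1, 1)
  op <- youdenOperatingPoint(s, y)
  expect_equal(op$threshold, 0.1)                  # tie broken low
  expect_equal(op$sensitivity, 1.0)
  expect_equal(op$specificity, 0.5)
  # random instances vs oracle sweep
  set.seed(16)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    sc <- round(rnorm(n), 2); yy <- rbinom(n, 1, 0.5); yy[1:2] <- c(0, 1)
    op <- youdenOperatingPoint(sc, yy)
    thr <- sort(unique(c(-Inf, sc)))
    J <- vapply(thr, function(th) {
      mean(sc[yy == 1] > th) + mean(sc[yy == 0] <= th) - 1
    }, numeric(1))
    expect_equal(op$youden, max(J), tolerance = 1e-12)
    expect_equal(op$threshold, thr[which(J == max(J))[1]])
  }
  # perfect separation and inverted labels
  perf <- youdenOperatingPoint(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  inv <- youdenOperatingPoint(c(1, 2, 8, 9), c(1, 1, 0, 0))
  expect_lte(inv$youden, 0)
})

test_that("ridge logistic agrees with glm when the penalty vanishes", {
  set.seed(17)
  d <- data.frame(x1 = rnorm(80), x2 = rnorm(80))
  d$outcome <- rbinom(80, 1, plogis(0.8 * d$x1 - 0.5 * d$x2))
  fit <- fitLogistic(d, c("x1", "x2"), lambda = 1e-10)
  ref <- glm(outcome ~ scale(x1) + scale(x2), binomial, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-5)
  expect_equal(unname(fit$auc), unname(rocAuc(fitted(ref), d$outcome)),
               tolerance = 1e-9)
})

test_that("logistic fit handles separation, nulls, and degeneracy", {
  d <- data.frame(x = c(1, 2, 3, 10, 11, 12),
                  outcome = c(0, 0, 0, 1, 1, 1))
  expect_equal(fitLogistic(d, "x")$auc, 1)         # separation: finite fit
  set.seed(18)
  d2 <- data.frame(x = rnorm(2000), outcome = rbinom(2000, 1, 0.5))
  expect_lt(abs(fitLogistic(d2, "x")$auc - 0.5), 0.05)
  f1 <- fitLogistic(d2, "x"); f2 <- fitLogistic(d2, "x")
  expect_identical(f1$coefficients, f2$coefficients)
  d3 <- data.frame(x = rnorm(30), outcome = rbinom(30, 1, 0.5))
  d3$z <- 2 * d3$x
  expect_error(fitLogistic(d3, c("x", "z")), "collinear")
  d3$w <- 1
  expect_error(fitLogistic(d3, "w"), "constant")
  expect_error(fitLogistic(d3, c("x", "z", "w", "x")), "at most 3")
})

test_that("exhaustive search enumerates the right models and picks signal", {
  set.seed(19)
  n <- 120
  co <- data.frame(outcome = factor(rep(c("a", "b"), each = n / 2)))
  co$good <- rnorm(n) + 2 * (co$outcome == "b")
  for (j in 1:4) co[[paste0("noise", j)]] <- rnorm(n)
  pool <- list(all = c("good", paste0("noise", 1:4)))
  res <- exhaustiveModelSearch(co, pool)
  expect_equal(nrow(res$leaderboard), 5 + 10 + 10)   # C(5,1)+C(5,2)+C(5,3)
  expect_true("good" %in% res$features)
  # independent re-enumeration finds no better AUC
  best <- max(vapply(seq_len(nrow(res$leaderboard)), function(i)
    res$leaderboard$auc[i], numeric(1)), na.rm = TRUE)
  expect_equal(res$auc, best)
})

test_that("search ties break to fewer features then lexicographic order", {
  co <- data.frame(outcome = factor(rep(c("a", "b"), each = 10)),
                   bfeat = rep(c(0, 1), each = 10))
  co$afeat <- co$bfeat                                # identical twins
  res <- exhaustiveModelSearch(co, list(p = c("bfeat", "afeat")))
  expect_identical(res$features, "afeat")
})

test_that("combined-family subsets always cover every pool", {
  set.seed(20)
  co <- data.frame(outcome = factor(rep(c("a", "b"), each = 15)))
  for (f in c("c1", "c2", "k1", "k2", "b1"))
    co[[f]] <- rnorm(30) + 0.5 * (co$outcome == "b")
  res <- exhaustiveModelSearch(
    co, list(clin = c("c1", "c2"), kt = c("k1", "k2"), kbpe = "b1"))
  sizes <- res$leaderboard$size
  expect_true(all(sizes == 3))                       # 3 pools -> exactly 3
  expect_equal(nrow(res$leaderboard), 2 * 2 * 1)
  for (fs in strsplit(res$leaderboard$features, "\\+")) {
    expect_true(any(fs %in% c("c1", "c2")))
    expect_true(any(fs %in% c("k1", "k2")))
    expect_true("b1" %in% fs)
  }
})

test_that("bootstrap CI is deterministic, honest about separation, and
           pairs correctly", {
  d <- data.frame(x = c(1:10, 101:110),
                  outcome = rep(c(0, 1), each = 10))
  b1 <- bootstrapAucCi(d, "x", nBoot = 200, seed = 5)
  b2 <- bootstrapAucCi(d, "x", nBoot = 200, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$aucs, b2$aucs)
  expect_equal(b1$ci, c(1, 1))                     # perfect separation
  set.seed(99)
  d2 <- data.frame(x = rnorm(40), outcome = rep(c(0, 1), 20))
  d2$x <- d2$x + 0.8 * d2$outcome
  b3 <- bootstrapAucCi(d2, "x", nBoot = 200, seed = 5)
  b4 <- bootstrapAucCi(d2, "x", nBoot = 200, seed = 6)
  expect_false(identical(b3$aucs, b4$aucs))
  # model vs itself: paired z-test is exactly null
  z <- compareModelsZ(b1$aucs, b1$aucs)
  expect_equal(z$p, 1)
  expect_equal(z$meanDiff, 0)
})

test_that("paired z-statistic matches the hand formula", {
  set.seed(21)
  a <- runif(400, 0.6, 0.9)
  b <- a - rnorm(400, 0.03, 0.01)
  z <- compareModelsZ(a, b)
  d <- a - b
  expect_equal(z$z, mean(d) / (sd(d) / sqrt(length(d))))
  expect_equal(z$p, 2 * pnorm(-abs(z$z)))
  # constant nonzero difference: the zero-SD guard
  zz <- compareModelsZ(a, a - 0.05)
  expect_equal(zz$p, 0)
  expect_error(compareModelsZ(a, a[-1]), "equal length")
})

test_that("bootstrap coverage matches the closed-form Gaussian AUC", {
  # small pilot of the coverage property (the acceptance suite runs the
  # full 500-rep version): Phi(dmu / sqrt(s1^2 + s2^2)) oracle
  trueAuc <- pnorm((1.45 - 1.03) / sqrt(0.56^2 + 0.12^2))
  outcome <- factor(rep(c("nonpCR", "pCR"), c(30, 26)),
                    levels = c("nonpCR", "pCR"))
  hits <- 0
  for (r in 1:25) {
    set.seed(3000 + r)
    d <- data.frame(x = c(rnorm(30, 1.45, 0.56), rnorm(26, 1.03, 0.12)),
                    outcome = outcome)
    ci <- bootstrapAucCi(d, "x", nBoot = 400, seed = r)$ci
    hits <- hits + (ci[1] <= trueAuc && trueAuc <= ci[2])
  }
  expect_gte(hits / 25, 0.8)
})
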