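#' ROC area under the curve (Mann-Whitney formulation)
#'
#' Probability that a random positive outscores a random negative, ties
#' counted half - computed from midranks, which is exactly the normalized
#' Mann-Whitney U statistic.
#'
#' @param scores numeric predictor values (higher = more positive).
#' @param labels binary outcome (0/1, logical, or 2-level factor; the second
#'   level is positive).
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  y <- binarize(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both outcome classes must be present for ROC analysis")
  r <- rank(scores)                     # midranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @keywords internal
binarize <- function(labels) {
  if (is.factor(labels)) return(as.integer(labels == levels(labels)[2L]))
  if (is.logical(labels)) return(as.integer(labels))
  u <- sort(unique(labels))
  if (length(u) > 2L) stop("labels must be binary")
  as.integer(labels == max(u))
}

#' Operating point at the Youden index
#'
#' Sweeps thresholds over the observed scores with decision rule
#' score > threshold, and returns the threshold maximizing
#' J = sensitivity + specificity - 1 (ties broken toward the lowest
#' threshold), with sensitivity, specificity and accuracy there.
#'
#' @inheritParams rocAuc
#' @return List: `threshold`, `sensitivity`, `specificity`, `accuracy`,
#'   `youden`.
#' @export
youdenOperatingPoint <- function(scores, labels) {
  y <- binarize(labels)
  if (!any(y == 1) || !any(y == 0))
    stop("both outcome classes must be present")
  thr <- sort(unique(c(-Inf, scores)))
  stats <- vapply(thr, function(th) {
    pred <- scores > th
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    c(sens, spec)
  }, numeric(2))
  J <- stats[1, ] + stats[2, ] - 1
  i <- which(J == max(J))[1L]           # ties -> lowest threshold
  pred <- scores > thr[i]
  list(threshold = thr[i], sensitivity = stats[1, i],
       specificity = stats[2, i],
       accuracy = mean(pred == (y == 1)), youden = J[i])
}

#' Group comparison of one cohort feature
#'
#' Continuous features: Wilcoxon rank-sum between the pCR and nonpCR groups
#' (exact enumeration when the combined n is at most 20 and there are no
#' ties, normal approximation with tie correction otherwise), plus the
#' single-feature ROC AUC with a bootstrap CI. Categorical features: Pearson
#' chi-square without continuity correction.
#'
#' @param cohort cohort data.frame with an `outcome` column
#'   (nonpCR/pCR factor).
#' @param feature feature column name.
#' @param nBoot bootstrap resamples for the AUC CI (0 to skip).
#' @param seed bootstrap seed.
#' @return List: `feature`, `type`, group `summary` (mean, sd, n per group),
#'   `test`, `p`, and for continuous features `auc` and `auc_ci`.
#' @export
compareGroups <- function(cohort, feature, nBoot = 1000L, seed = 1L) {
  x <- cohort[[feature]]
  if (is.null(x)) stop("no such feature: ", feature)
  y <- binarize(cohort$outcome)
  if (min(table(y)) < 2L) stop("need >= 2 patients per group")
  if (length(unique(x[!is.na(x)])) < 2L)
    return(list(feature = feature, type = "degenerate", p = NA_real_,
                note = "constant feature; test undefined"))
  categorical <- is.factor(x) || is.character(x) || is.logical(x) ||
    length(unique(x[!is.na(x)])) == 2L
  if (categorical) {
    tab <- table(x, y)
    test <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(list(feature = feature, type = "categorical", table = tab,
                test = "chi-square", statistic = unname(test$statistic),
                p = test$p.value))
  }
  g0 <- x[y == 0]; g1 <- x[y == 1]
  exact <- (length(x) <= 20L) && !anyDuplicated(x)
  wt <- suppressWarnings(
    stats::wilcox.test(g0, g1, exact = exact, correct = FALSE))
  # single-feature discrimination AUC: orientation-free (the better of the
  # feature and its negation), the convention of per-feature ROC columns
  auc <- max(rocAuc(x, y), 1 - rocAuc(x, y))
  ci <- if (nBoot > 0) {
    bootstrapAucCi(data.frame(x = x, y = y), "x", "y", nBoot = nBoot,
                   seed = seed)$ci
  } else c(NA_real_, NA_real_)
  list(feature = feature, type = "continuous",
       summary = data.frame(group = c("nonpCR", "pCR"),
                            mean = c(mean(g0), mean(g1)),
                            sd = c(stats::sd(g0), stats::sd(g1)),
                            n = c(length(g0), length(g1))),
       test = if (exact) "wilcoxon-exact" else "wilcoxon-normal",
       p = wt$p.value, auc = auc, auc_ci = ci)
}

#' Ridge-stabilized logistic regression on standardized features
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' with a small ridge penalty on the (standardized) slopes - the penalty
#' keeps coefficients finite under complete separation, which exhaustive
#' small-subset searches on small cohorts regularly produce. The intercept
#' is unpenalized. Standardization uses the full-cohort mean/SD, consistent
#' with apparent (in-sample) evaluation.
#'
#' @param data data.frame containing the features and outcome.
#' @param features character vector of feature column names (at most 3).
#' @param outcome outcome column name (binary).
#' @param lambda ridge penalty on standardized slopes (default 1e-3).
#' @param maxFeatures cap on the number of features.
#' @return List: `coefficients` (on the standardized scale), `scores`
#'   (in-sample probabilities), `auc`, `features`, `center`, `scale`,
#'   `converged`, `nDropped` (patients dropped for missing values).
#' @export
fitLogistic <- function(data, features, outcome = "outcome", lambda = 1e-3,
                        maxFeatures = 3L) {
  if (length(features) > maxFeatures)
    stop("at most ", maxFeatures, " features allowed")
  keep <- stats::complete.cases(data[, c(features, outcome), drop = FALSE])
  nDropped <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  y <- binarize(d[[outcome]])
  X <- as.matrix(d[, features, drop = FALSE])
  storage.mode(X) <- "double"
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0))
    stop("degenerate design: constant feature(s) ",
         paste(features[scl == 0], collapse = ", "))
  Xs <- scale(X, ctr, scl)
  qrX <- qr(cbind(1, Xs))
  if (qrX$rank < ncol(Xs) + 1L)
    stop("degenerate design: collinear features ",
         paste(features, collapse = ", "))
  fit <- ridgeIrls(cbind(1, Xs), y, lambda)
  eta <- drop(cbind(1, Xs) %*% fit$beta)
  scores <- stats::plogis(eta)
  list(coefficients = stats::setNames(fit$beta, c("(Intercept)", features)),
       scores = scores, auc = rocAuc(scores, y), features = features,
       center = ctr, scale = scl, converged = fit$converged,
       nDropped = nDropped)
}

## IRLS for ridge-penalized logistic regression; first column of X is the
## unpenalized intercept.
#' @keywords internal
ridgeIrls <- function(X, y, lambda, maxIter = 50L, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    newBeta <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(newBeta - beta)) < tol) {
      beta <- newBeta; converged <- TRUE; break
    }
    beta <- newBeta
  }
  list(beta = drop(beta), converged = converged)
}

#' Exhaustive best-subset logistic model search
#'
#' Enumerates every feature subset of size 1-3 drawn from the family's
#' candidate pools, fits each by [fitLogistic()], and selects the model with
#' the highest apparent (in-sample) AUC; the cap of three features limits
#' overfitting on a small cohort. For combined families (more than one
#' pool), subsets must include at least one feature from every pool. Ties
#' break toward fewer features, then lexicographic feature order. Subsets
#' whose design is degenerate (constant or collinear) are skipped.
#'
#' @param cohort cohort data.frame.
#' @param pools named list of character vectors: the family's candidate
#'   feature groups (one element = a simple family; several = a combined
#'   family).
#' @param outcome outcome column name.
#' @param maxFeatures subset size cap (default 3).
#' @param lambda ridge penalty passed to [fitLogistic()].
#' @return List: `features` (selected subset), `fit` (its [fitLogistic()]
#'   result), `auc`, and `leaderboard` (data.frame of every fitted subset
#'   with its AUC, best first).
#' @export
exhaustiveModelSearch <- function(cohort, pools, outcome = "outcome",
                                  maxFeatures = 3L, lambda = 1e-3) {
  pools <- lapply(pools, intersect, y = names(cohort))
  if (any(lengths(pools) == 0L)) stop("empty candidate pool")
  all <- unlist(pools, use.names = FALSE)
  groupOf <- rep(seq_along(pools), lengths(pools))
  if (length(pools) > maxFeatures)
    stop("more pools than the feature cap allows")
  subsets <- list()
  for (size in seq_len(min(maxFeatures, length(all)))) {
    if (size < length(pools)) next     # cannot cover every pool
    cmb <- utils::combn(length(all), size, simplify = FALSE)
    cov <- vapply(cmb, function(i)
      length(unique(groupOf[i])) == length(pools), logical(1))
    subsets <- c(subsets, lapply(cmb[cov], function(i) sort(all[i])))
  }
  if (!length(subsets)) stop("no admissible subsets for these pools")

  rows <- vector("list", length(subsets))
  fits <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    f <- subsets[[i]]
    fit <- tryCatch(fitLogistic(cohort, f, outcome, lambda = lambda),
                    error = function(e) NULL)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      features = paste(f, collapse = "+"), size = length(f),
      auc = if (is.null(fit)) NA_real_ else fit$auc)
  }
  lb <- do.call(rbind, rows)
  ok <- which(!is.na(lb$auc))
  if (!length(ok)) stop("all candidate fits degenerate")
  ord <- ok[order(-lb$auc[ok], lb$size[ok], lb$features[ok])]
  best <- ord[1L]
  list(features = subsets[[best]], fit = fits[[best]], auc = lb$auc[best],
       leaderboard = lb[ord, ])
}

#' Bootstrap confidence interval for a model's apparent AUC
#'
#' Resamples patients with replacement; on each resample the already-
#' selected model (feature subset) is refitted and its apparent AUC on that
#' resample recorded - feature selection is NOT repeated inside the
#' bootstrap, an optimism-prone but deliberate evaluation of the selected
#' model. Resamples with a single outcome class are skipped (NA) and
#' counted; more than 50 percent degenerate resamples is an error. The
#' percentile 2.5/97.5 interval is returned. With a fixed seed the resample
#' indices - and hence the interval - are reproducible, and two models
#' bootstrapped with the same seed and cohort share resamples, which is what
#' makes [compareModelsZ()] a paired test.
#'
#' @param cohort cohort data.frame.
#' @param features the selected model's feature subset.
#' @param outcome outcome column name.
#' @param nBoot number of bootstrap resamples (default 1000).
#' @param seed RNG seed for the resample indices.
#' @param stratified resample within outcome classes? Default FALSE.
#' @param lambda ridge penalty passed to [fitLogistic()].
#' @return List: `ci` (length 2), `aucs` (length `nBoot`, NA where
#'   skipped), `nSkipped`, `nBoot`, `seed`.
#' @export
bootstrapAucCi <- function(cohort, features, outcome = "outcome",
                           nBoot = 1000L, seed = 1L, stratified = FALSE,
                           lambda = 1e-3) {
  if (nBoot < 1L) stop("nBoot must be >= 1")
  keep <- stats::complete.cases(cohort[, c(features, outcome),
                                       drop = FALSE])
  d <- cohort[keep, , drop = FALSE]
  y <- binarize(d[[outcome]])
  n <- nrow(d)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  idx1 <- which(y == 1); idx0 <- which(y == 0)

  X <- as.matrix(d[, features, drop = FALSE])
  storage.mode(X) <- "double"
  aucs <- rep(NA_real_, nBoot)
  for (b in seq_len(nBoot)) {
    i <- if (stratified)
      c(sample(idx0, length(idx0), replace = TRUE),
        sample(idx1, length(idx1), replace = TRUE))
    else sample.int(n, n, replace = TRUE)
    yb <- y[i]
    if (all(yb == yb[1L])) next        # single-class resample: skip
    Xb <- X[i, , drop = FALSE]
    ctr <- colMeans(Xb)
    scl <- apply(Xb, 2, stats::sd)
    if (any(scl == 0)) next            # feature constant in this resample
    Xs <- cbind(1, sweep(sweep(Xb, 2, ctr), 2, scl, "/"))
    fit <- tryCatch(ridgeIrls(Xs, yb, lambda), error = function(e) NULL)
    if (!is.null(fit))
      aucs[b] <- rocAuc(drop(Xs %*% fit$beta), yb)
  }
  nSkipped <- sum(is.na(aucs))
  if (nSkipped > nBoot / 2)
    stop("more than half of the bootstrap resamples were degenerate")
  list(ci = unname(stats::quantile(aucs, c(0.025, 0.975), na.rm = TRUE)),
       aucs = aucs, nSkipped = nSkipped, nBoot = nBoot, seed = seed)
}

#' Paired bootstrap z-test between two models' AUCs
#'
#' Takes the two models' AUC vectors over identical bootstrap resamples
#' (same cohort, same seed), forms the paired differences, and tests the
#' mean difference against zero with z = dbar / (SD(d)/sqrt(n)), two-sided
#' normal p. Pairs where either vector is NA (skipped resamples) are
#' dropped. A zero-SD difference vector is the guarded special case: p = 1
#' if the constant difference is zero, else p = 0.
#'
#' @param aucsA,aucsB equal-length AUC vectors from [bootstrapAucCi()] runs
#'   sharing resample indices.
#' @return List: `meanDiff`, `z`, `p`, `n`.
#' @export
compareModelsZ <- function(aucsA, aucsB) {
  if (length(aucsA) != length(aucsB))
    stop("AUC vectors must have equal length (paired resamples)")
  keep <- !is.na(aucsA) & !is.na(aucsB)
  d <- aucsA[keep] - aucsB[keep]
  n <- length(d)
  if (n < 2L) stop("fewer than 2 complete pairs")
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    p <- if (m == 0) 1 else 0
    return(list(meanDiff = m, z = if (m == 0) 0 else sign(m) * Inf,
                p = p, n = n))
  }
  z <- m / (s / sqrt(n))
  list(meanDiff = m, z = z, p = 2 * stats::pnorm(-abs(z)), n = n)
}
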