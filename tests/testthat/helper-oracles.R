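# Independent oracles and fixture builders shared across the suite.

# Composite Simpson quadrature (independent of stats::integrate).
simpsonQuad <- function(f, a, b, panels = 1e4) {
  x <- seq(a, b, length.out = 2 * panels + 1)
  y <- f(x)
  h <- (b - a) / (2 * panels)
  h / 3 * (y[1] + y[length(y)] +
             4 * sum(y[seq(2, length(y) - 1, by = 2)]) +
             2 * sum(y[seq(3, length(y) - 2, by = 2)]))
}

# AUC by exhaustive pair counting (ties count half).
pairCountAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all group
# assignments (no ties assumed).
enumWilcoxP <- function(x, y) {
  all <- c(x, y)
  r <- rank(all)
  m <- length(x)
  obs <- sum(r[seq_len(m)])
  combs <- combn(length(all), m)
  sums <- apply(combs, 2, function(i) sum(r[i]))
  mu <- m * (length(all) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}

# Synthetic single-row series: nVox voxels with given PSE curves.
# pseMat: nVox x nPost percent enhancement at the postcontrast frames.
seriesFromPse <- function(pseMat, nPre = 5, spacing = 5, s0 = 100) {
  nVox <- nrow(pseMat)
  nPost <- ncol(pseMat)
  n <- nPre + nPost
  vox <- array(s0, c(nVox, 1, 1, n))
  for (j in seq_len(nPost))
    vox[, 1, 1, nPre + j] <- s0 * (1 + pseMat[, j] / 100)
  times <- (seq_len(n) - nPre) * spacing / 60
  DynamicSeries(vox, times, nPre, voxelSize = c(1, 1, 1))
}

allIpsLabels <- function(dims) {
  RegionLabels(array(REGION_CODES[["ips_parenchyma"]], dims), "left")
}

postTimesOf <- function(series) {
  tt <- frameTimes(series)
  tt[tt > 0]
}
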