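#' K-means partition of region voxels by maximum enhancement rate
#'
#' One-dimensional Lloyd's algorithm on the scalar A*alpha values of the
#' masked voxels (spatial position is not a feature). The default
#' initializer is deterministic - centers start at the 10th, 30th, 50th,
#' 70th and 90th percentiles of the masked values (generally the k odd
#' 1/(2k) quantiles) - so results are reproducible without a seed; a seeded
#' random initializer is available. After convergence clusters are relabeled
#' so mean A*alpha strictly ascends with the cluster index; relabeling is a
#' pure permutation of labels and never changes the partition. Ties in
#' nearest-center distance break toward the lower cluster index.
#'
#' @param values 3D numeric array (the A*alpha map) or numeric vector.
#' @param mask logical/integer array or vector marking the voxels to
#'   cluster; non-finite values are excluded (they correspond to failed
#'   fits and stay unassigned, label 0).
#' @param k number of clusters (default 5).
#' @param init `"quantile"` (deterministic, default) or `"random"`.
#' @param seed integer seed, used only by the random initializer.
#' @param maxIter iteration cap (default 300).
#' @param region region name recorded in the result.
#' @return A [ClusterAssignment-class].
#' @export
kmeansCluster <- function(values, mask = NULL, k = 5L,
                          init = c("quantile", "random"), seed = 1L,
                          maxIter = 300L, region = "region") {
  init <- match.arg(init)
  vals <- as.vector(values)
  sel <- if (is.null(mask)) rep(TRUE, length(vals)) else as.vector(mask) != 0
  sel <- sel & is.finite(vals)
  idx <- which(sel)
  x <- vals[idx]
  if (length(unique(x)) < k)
    stop("degenerate clustering in region '", region, "': fewer than ", k,
         " distinct finite values")

  if (init == "quantile") {
    probs <- (2 * seq_len(k) - 1) / (2 * k)
    centers <- unname(stats::quantile(x, probs, type = 7))
    # coincident quantiles (heavily tied data): fall back to spread values
    if (any(diff(centers) <= 0))
      centers <- sort(unique(x))[round(seq(1, length(unique(x)),
                                           length.out = k))]
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    centers <- sort(sample(unique(x), k))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }

  assign0 <- integer(length(x))
  for (iter in seq_len(maxIter)) {
    d <- abs(outer(x, centers, "-"))
    a <- max.col(-d, ties.method = "first")   # ties -> lower index
    newCenters <- vapply(seq_len(k), function(j)
      if (any(a == j)) mean(x[a == j]) else centers[j], numeric(1))
    if (identical(a, assign0)) break
    assign0 <- a
    centers <- newCenters
  }
  centers <- vapply(seq_len(k), function(j)
    if (any(a == j)) mean(x[a == j]) else NA_real_, numeric(1))
  if (anyNA(centers))
    stop("degenerate clustering in region '", region, "': empty cluster")

  perm <- order(centers)                      # ascending mean relabel
  relabel <- integer(k); relabel[perm] <- seq_len(k)
  a <- relabel[a]
  centers <- centers[perm]
  if (any(diff(centers) <= 0))
    stop("degenerate clustering in region '", region,
         "': non-distinct cluster means")

  shape <- if (is.null(dim(values))) length(vals) else dim(values)
  lab <- array(0L, shape)
  lab[idx] <- a
  new("ClusterAssignment", labelMap = lab,
      counts = as.integer(tabulate(a, k)),
      centers = centers, region = region)
}

#' Mean enhancement curve of each cluster
#'
#' For each cluster, the raw signal is averaged across the cluster's voxels
#' frame by frame and enhancement is computed from that mean curve with the
#' cluster-mean precontrast baseline (averaging signal, then converting -
#' not averaging per-voxel PSE).
#'
#' @param series a [DynamicSeries-class].
#' @param assignment a [ClusterAssignment-class] on the same grid.
#' @return Named list of [PseCurve-class] objects (`cluster1` ... `clusterK`).
#' @export
clusterMeanCurves <- function(series, assignment) {
  lab <- labelMap(assignment)
  if (!all(dim(lab) == dim(seriesData(series))[1:3]))
    stop("assignment grid does not match series grid")
  k <- length(clusterCenters(assignment))
  out <- vector("list", k)
  names(out) <- paste0("cluster", seq_len(k))
  for (j in seq_len(k)) {
    if (!any(lab == j))
      stop("cluster ", j, " is empty")
    out[[j]] <- computePse(series, mask = lab == j)
  }
  out
}
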