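#' @import methods
NULL

#' Region label codes
#'
#' Integer codes used in label maps: 0 background, 1 ipsilateral parenchyma,
#' 2 contralateral parenchyma, 3 tumor, 4 vessel. Tumor and vessel voxels are
#' never simultaneously parenchyma; that exclusion is assumed to be already
#' applied in any label map handed to the pipeline.
#'
#' @format Named integer vector of length 5.
#' @export
REGION_CODES <- c(
  background = 0L,
  ips_parenchyma = 1L,
  con_parenchyma = 2L,
  tumor = 3L,
  vessel = 4L
)

#' DynamicSeries: a 4D dynamic contrast-enhanced MRI series
#'
#' Holds the 4D signal array (x, y, z, t), per-frame acquisition times in
#' minutes relative to contrast injection (precontrast frames have times
#' \eqn{\le 0}), the number of precontrast frames, and the voxel size in mm.
#'
#' @slot voxels 4D numeric array, arbitrary-unit signal intensity.
#' @slot frameTimes numeric, minutes; strictly increasing, one per frame.
#' @slot nPrecontrast integer, number of precontrast frames (>= 1).
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#' @export
setClass("DynamicSeries",
  representation(
    voxels = "array",
    frameTimes = "numeric",
    nPrecontrast = "integer",
    voxelSize = "numeric"
  )
)

setValidity("DynamicSeries", function(object) {
  v <- object@voxels
  msgs <- character()
  if (length(dim(v)) != 4L)
    msgs <- c(msgs, "voxels must be a 4D array (x, y, z, t)")
  else {
    if (length(object@frameTimes) != dim(v)[4L])
      msgs <- c(msgs, "frameTimes length must equal the number of frames")
    if (object@nPrecontrast < 1L || object@nPrecontrast >= dim(v)[4L])
      msgs <- c(msgs, "nPrecontrast must be >= 1 and < number of frames")
  }
  if (any(diff(object@frameTimes) <= 0))
    msgs <- c(msgs, "frameTimes must be strictly increasing")
  if (anyNA(v) || any(!is.finite(v)))
    msgs <- c(msgs, "voxel values must be finite")
  else if (any(v < 0))
    msgs <- c(msgs, "voxel values must be >= 0")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msgs <- c(msgs, "voxelSize must be 3 positive lengths in mm")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DynamicSeries
#'
#' @param voxels 4D numeric array (x, y, z, t).
#' @param frameTimes per-frame times, strictly increasing.
#' @param nPrecontrast number of precontrast frames.
#' @param voxelSize voxel edge lengths in mm (length 3).
#' @param timeUnit unit of `frameTimes`: `"min"` (default) or `"s"`; seconds
#'   are converted to minutes on construction.
#' @return A [DynamicSeries-class] object (internal times always minutes).
#' @export
DynamicSeries <- function(voxels, frameTimes, nPrecontrast,
                          voxelSize = c(1.5, 1.5, 3), timeUnit = c("min", "s")) {
  timeUnit <- match.arg(timeUnit)
  if (timeUnit == "s") frameTimes <- frameTimes / 60
  new("DynamicSeries",
    voxels = voxels,
    frameTimes = as.numeric(frameTimes),
    nPrecontrast = as.integer(nPrecontrast),
    voxelSize = as.numeric(voxelSize)
  )
}

#' RegionLabels: voxel label map with laterality semantics
#'
#' A 3D integer map on the same grid as its companion [DynamicSeries-class],
#' using the codes in [REGION_CODES]. The second array dimension is the
#' left-right axis; lower indices are the anatomical left.
#'
#' @slot labels 3D integer array with codes 0-4.
#' @slot laterality `"left"` or `"right"`: which side is ipsilateral.
#' @export
setClass("RegionLabels",
  representation(labels = "array", laterality = "character")
)

setValidity("RegionLabels", function(object) {
  msgs <- character()
  if (length(dim(object@labels)) != 3L)
    msgs <- c(msgs, "labels must be a 3D array")
  bad <- setdiff(unique(as.vector(object@labels)), REGION_CODES)
  if (length(bad))
    msgs <- c(msgs, paste0("unknown label code(s): ",
                           paste(bad, collapse = ", ")))
  if (!object@laterality %in% c("left", "right"))
    msgs <- c(msgs, "laterality must be 'left' or 'right'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RegionLabels object
#'
#' @param labels 3D integer array using [REGION_CODES].
#' @param laterality `"left"` or `"right"`; the ipsilateral (tumor-bearing)
#'   side.
#' @return A [RegionLabels-class] object.
#' @export
RegionLabels <- function(labels, laterality = c("left", "right")) {
  laterality <- match.arg(laterality)
  storage.mode(labels) <- "integer"
  new("RegionLabels", labels = labels, laterality = laterality)
}

#' PseCurve: percent signal enhancement over time
#'
#' @slot times numeric, minutes (injection at 0; precontrast times <= 0).
#' @slot pse numeric, percent enhancement per frame.
#' @slot baseline numeric scalar, mean precontrast signal.
#' @slot nVoxels integer, voxels averaged into the curve (1 for a voxel curve).
#' @export
setClass("PseCurve",
  representation(times = "numeric", pse = "numeric", baseline = "numeric",
                 nVoxels = "integer")
)

setValidity("PseCurve", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@pse))
    msgs <- c(msgs, "times and pse must have equal length")
  if (length(object@baseline) != 1L || !is.finite(object@baseline) ||
      object@baseline <= 0)
    msgs <- c(msgs, "baseline must be a positive finite scalar")
  if (any(!is.finite(object@pse)))
    msgs <- c(msgs, "pse values must be finite")
  if (length(msgs)) msgs else TRUE
})

PseCurve <- function(times, pse, baseline, nVoxels = 1L) {
  new("PseCurve", times = as.numeric(times), pse = as.numeric(pse),
      baseline = as.numeric(baseline), nVoxels = as.integer(nVoxels))
}

#' ConcentrationCurve: tissue contrast-agent concentration over time
#'
#' @slot times numeric, minutes.
#' @slot conc numeric, mM tissue concentration.
#' @slot flagged logical, frames where signal-to-concentration inversion was
#'   out of range and clipped.
#' @export
setClass("ConcentrationCurve",
  representation(times = "numeric", conc = "numeric", flagged = "logical")
)

setValidity("ConcentrationCurve", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@conc))
    msgs <- c(msgs, "times and conc must have equal length")
  if (any(!is.finite(object@conc)))
    msgs <- c(msgs, "conc values must be finite")
  if (length(msgs)) msgs else TRUE
})

ConcentrationCurve <- function(times, conc, flagged = rep(FALSE, length(conc))) {
  new("ConcentrationCurve", times = as.numeric(times), conc = as.numeric(conc),
      flagged = as.logical(flagged))
}

#' ClusterAssignment: K-means partition of a region's voxels
#'
#' Cluster indices are relabeled so that cluster mean A*alpha is strictly
#' ascending in the index; 0 marks voxels outside the region or with failed
#' fits.
#'
#' @slot labelMap 3D integer array, 0 = unassigned, 1..k = cluster.
#' @slot counts integer, voxels per cluster.
#' @slot centers numeric, per-cluster mean of the clustered values, ascending.
#' @slot region character, region that was clustered.
#' @export
setClass("ClusterAssignment",
  representation(labelMap = "array", counts = "integer",
                 centers = "numeric", region = "character")
)

setValidity("ClusterAssignment", function(object) {
  msgs <- character()
  k <- length(object@centers)
  if (length(object@counts) != k)
    msgs <- c(msgs, "counts and centers must have equal length")
  if (k > 1 && any(diff(object@centers) <= 0))
    msgs <- c(msgs, "cluster centers must be strictly ascending")
  if (sum(object@counts) != sum(object@labelMap > 0L))
    msgs <- c(msgs, "counts must sum to the number of assigned voxels")
  if (length(msgs)) msgs else TRUE
})

#' PopulationAif: population arterial input function
#'
#' Default functional form is the bi-Gaussian plus sigmoid-modulated
#' exponential population AIF with its literature parameter vector
#' (Parker et al. 2006, Magn Reson Med 56:993-1000); Cp is in mM and time in
#' minutes. Cp(t) = 0 for t before the bolus arrival time.
#'
#' @slot form character, functional form identifier (`"parker2006"`).
#' @slot params named numeric parameter vector.
#' @slot bolusArrival numeric, minutes.
#' @export
setClass("PopulationAif",
  representation(form = "character", params = "numeric",
                 bolusArrival = "numeric")
)

.parkerDefaults <- c(
  A1 = 0.809, A2 = 0.330,      # mmol * min (Gaussian areas)
  T1 = 0.17046, T2 = 0.365,    # min (Gaussian centres)
  sigma1 = 0.0563, sigma2 = 0.132,  # min
  alpha = 1.050,               # mmol/L (exponential amplitude)
  beta = 0.1685,               # 1/min (exponential decay)
  s = 38.078,                  # 1/min (sigmoid width)
  tau = 0.483                  # min (sigmoid centre)
)

#' Construct a population AIF
#'
#' @param form functional form; only `"parker2006"` is built in.
#' @param params named parameter vector; defaults to the literature values.
#' @param bolusArrival bolus arrival time in minutes (Cp = 0 before it).
#' @return A [PopulationAif-class] object.
#' @export
populationAif <- function(form = "parker2006", params = NULL,
                          bolusArrival = 0) {
  if (form != "parker2006")
    stop("unknown AIF form: ", form)
  p <- .parkerDefaults
  if (!is.null(params)) {
    unknown <- setdiff(names(params), names(p))
    if (length(unknown))
      stop("unknown AIF parameter(s): ", paste(unknown, collapse = ", "))
    p[names(params)] <- params
  }
  new("PopulationAif", form = form, params = p,
      bolusArrival = as.numeric(bolusArrival))
}

## ---- show methods -------------------------------------------------------

setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@voxels)
  cat("DynamicSeries:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "frames\n")
  cat("  precontrast frames:", object@nPrecontrast, "\n")
  cat(sprintf("  time span: %.3f to %.3f min\n",
              min(object@frameTimes), max(object@frameTimes)))
  cat("  voxel size (mm):", paste(object@voxelSize, collapse = " x "), "\n")
})

setMethod("show", "RegionLabels", function(object) {
  cat("RegionLabels:", paste(dim(object@labels), collapse = " x "),
      "grid, ipsilateral =", object@laterality, "\n")
  tab <- table(factor(as.vector(object@labels), levels = REGION_CODES,
                      labels = names(REGION_CODES)))
  for (nm in names(tab)) cat(sprintf("  %-16s %d\n", nm, tab[[nm]]))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment (", object@region, "): K =",
      length(object@centers), "\n")
  for (i in seq_along(object@centers))
    cat(sprintf("  cluster %d: n = %d, mean = %.4g\n",
                i, object@counts[i], object@centers[i]))
})

setMethod("show", "PseCurve", function(object) {
  cat("PseCurve:", length(object@times), "frames,",
      object@nVoxels, "voxel(s), baseline", format(object@baseline), "\n")
})

setMethod("show", "ConcentrationCurve", function(object) {
  cat("ConcentrationCurve:", length(object@times), "frames, peak",
      format(max(object@conc)), "mM\n")
})

setMethod("show", "PopulationAif", function(object) {
  cat("PopulationAif (", object@form, "), bolus arrival",
      object@bolusArrival, "min\n")
})

## ---- accessors ----------------------------------------------------------

#' @rdname accessors
#' @param object a package object.
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("nPrecontrast", function(object) standardGeneric("nPrecontrast"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("seriesData", function(object) standardGeneric("seriesData"))

#' @rdname accessors
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))

#' @rdname accessors
#' @export
setGeneric("laterality", function(object) standardGeneric("laterality"))

#' @rdname accessors
#' @export
setGeneric("clusterCounts", function(object) standardGeneric("clusterCounts"))

#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(object) standardGeneric("clusterCenters"))

#' Accessors for dceKMC S4 objects
#'
#' `frameTimes`, `nPrecontrast`, `voxelSize` and `seriesData` read the slots
#' of a [DynamicSeries-class]; `labelMap` and `laterality` those of a
#' [RegionLabels-class] (and `labelMap` also the partition of a
#' [ClusterAssignment-class]); `clusterCounts` / `clusterCenters` the
#' per-cluster sizes and ascending mean values.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("frameTimes", "DynamicSeries", function(object) object@frameTimes)

#' @rdname accessors
#' @export
setMethod("nPrecontrast", "DynamicSeries", function(object) object@nPrecontrast)

#' @rdname accessors
#' @export
setMethod("voxelSize", "DynamicSeries", function(object) object@voxelSize)

#' @rdname accessors
#' @export
setMethod("seriesData", "DynamicSeries", function(object) object@voxels)

#' @rdname accessors
#' @export
setMethod("labelMap", "RegionLabels", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("labelMap", "ClusterAssignment", function(object) object@labelMap)

#' @rdname accessors
#' @export
setMethod("laterality", "RegionLabels", function(object) object@laterality)

#' @rdname accessors
#' @export
setMethod("clusterCounts", "ClusterAssignment", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("clusterCenters", "ClusterAssignment",
          function(object) object@centers)
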