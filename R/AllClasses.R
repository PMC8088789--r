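#' @import methods
NULL

#' VoxelGrid: image geometry shared by masks, maps and streamlines
#'
#' Holds the voxel lattice dimensions and the 4x4 affine mapping 0-based
#' voxel indices to world coordinates (mm) of voxel centres, as in NIfTI.
#' Voxel i covers the half-open world region mapped from
#' [i - 0.5, i + 0.5) along each axis.
#'
#' @slot dim integer(3), lattice dimensions.
#' @slot affine 4x4 numeric matrix, voxel index (0-based) to world mm.
#' @export
setClass("VoxelGrid",
  representation(dim = "integer", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@dim) != 3L || any(object@dim < 1L))
      msg <- c(msg, "'dim' must be three positive integers")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "'affine' must be a 4x4 matrix")
    else if (abs(det(object@affine[1:3, 1:3])) < .Machine$double.eps)
      msg <- c(msg, "'affine' 3x3 block must be invertible")
    if (length(msg)) msg else TRUE
  }
)

#' Bundle: a named set of streamlines
#'
#' Streamlines are polylines in world coordinates (mm), one numeric
#' n-by-3 matrix each. The side is used by [averageHemispheres()] to
#' pair left/right homologues; commissural bundles pass through.
#'
#' @slot name character(1), bundle name.
#' @slot side one of "left", "right", "commissural".
#' @slot streamlines list of n-by-3 numeric matrices (world mm).
#' @export
setClass("Bundle",
  representation(name = "character", side = "character",
                 streamlines = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L)
      msg <- c(msg, "'name' must be a single string")
    if (!object@side %in% c("left", "right", "commissural"))
      msg <- c(msg, "'side' must be left, right or commissural")
    for (s in object@streamlines) {
      if (!is.matrix(s) || ncol(s) != 3L || nrow(s) < 2L) {
        msg <- c(msg, "every streamline must be an n-by-3 matrix, n >= 2")
        break
      }
      if (any(!is.finite(s))) {
        msg <- c(msg, "streamline coordinates must be finite")
        break
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' LesionInteraction: a bundle split into lesioned and spared streamlines
#'
#' Produced by [splitByLesion()]. Keeps the resampled streamlines and the
#' per-point lesion membership flags so that lesionometry sampling
#' ("portion" and "full" modes) is consistent with the voxel sets behind
#' the load measures.
#'
#' @slot bundleName character(1).
#' @slot bundleVoxels integer k-by-3 matrix of 0-based voxel indices
#'   occupied by the bundle.
#' @slot lesionedVoxels integer matrix, subset of bundleVoxels that
#'   intersects the lesion mask.
#' @slot streamlines list of resampled streamlines (world mm).
#' @slot pointInLesion list of logical vectors, one flag per point.
#' @slot lesionedStreamlines integer indices of streamlines with at least
#'   one point in a lesion voxel.
#' @slot step numeric(1), resampling step (mm) used.
#' @export
setClass("LesionInteraction",
  representation(bundleName = "character", bundleVoxels = "matrix",
                 lesionedVoxels = "matrix", streamlines = "list",
                 pointInLesion = "list", lesionedStreamlines = "integer",
                 step = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@streamlines) != length(object@pointInLesion))
      msg <- c(msg, "one flag vector per streamline required")
    flagged <- which(vapply(object@pointInLesion, any, NA))
    if (!identical(sort(flagged), sort(as.integer(object@lesionedStreamlines))))
      msg <- c(msg, "lesionedStreamlines must match the per-point flags")
    if (length(msg)) msg else TRUE
  }
)

#' GradientTable: diffusion gradient scheme
#'
#' @slot bvals numeric b-values (s/mm^2), one per volume.
#' @slot bvecs n-by-3 matrix of gradient directions (unit norm where
#'   b > 0; zero rows allowed for b = 0 volumes).
#' @slot b0Threshold b-values at or below this count as b = 0.
#' @export
setClass("GradientTable",
  representation(bvals = "numeric", bvecs = "matrix",
                 b0Threshold = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@bvecs) != length(object@bvals))
      msg <- c(msg, "one direction per b-value required")
    if (any(object@bvals < 0))
      msg <- c(msg, "b-values must be non-negative")
    dw <- object@bvals > object@b0Threshold
    if (any(dw)) {
      nrm <- sqrt(rowSums(object@bvecs[dw, , drop = FALSE]^2))
      if (any(abs(nrm - 1) > 1e-6))
        msg <- c(msg, "directions must be unit norm (1e-6) where b > 0")
    }
    if (!any(!dw))
      msg <- c(msg, "at least one b = 0 volume required")
    if (length(msg)) msg else TRUE
  }
)

#' TensorMap: per-voxel diffusion tensors
#'
#' Tensor coefficients are stored per voxel in the order
#' Dxx, Dyy, Dzz, Dxy, Dxz, Dyz (mm^2/s). Voxels whose signals had to be
#' clamped to positive values before the log-linear fit are flagged in
#' the QC mask rather than silently accepted.
#'
#' @slot coefficients 4-D array (X, Y, Z, 6).
#' @slot s0 3-D array of fitted S0.
#' @slot mask logical 3-D array of fitted voxels.
#' @slot clamped logical 3-D array; TRUE where non-positive signals were
#'   clamped before fitting.
#' @export
setClass("TensorMap",
  representation(coefficients = "array", s0 = "array", mask = "array",
                 clamped = "array"))

#' ShCoeffMap: real even-order spherical-harmonic coefficients
#'
#' One row per voxel (or sample), (L+1)(L+2)/2 columns for the real,
#' even-only orthonormal basis up to order L. The basis convention is
#' recorded so RISH values from different sources stay comparable.
#'
#' @slot coefficients numeric matrix, voxels x coefficients.
#' @slot lmax even integer, maximum harmonic order.
#' @slot convention character(1) basis identifier.
#' @export
setClass("ShCoeffMap",
  representation(coefficients = "matrix", lmax = "integer",
                 convention = "character"),
  validity = function(object) {
    L <- object@lmax
    if (L %% 2L != 0L)
      return("'lmax' must be even")
    k <- (L + 1) * (L + 2) / 2
    if (ncol(object@coefficients) != k)
      return(sprintf("expected %d coefficients for lmax = %d", k, L))
    TRUE
  }
)

#' FactorModel: per-bundle PCA reduction of microstructure metrics
#'
#' @slot bundle character(1), bundle the factor belongs to.
#' @slot metrics character, input metric names.
#' @slot loadings p-by-k matrix of component loadings (full, unsuppressed).
#' @slot suppressed logical matrix, TRUE where |loading| is below the
#'   reporting threshold.
#' @slot eigenvalues numeric(p), eigenvalues of the correlation matrix.
#' @slot nRetained integer, components with eigenvalue above threshold.
#' @slot scores numeric, standardized first-component scores (NA for
#'   subjects dropped by the complete-case policy).
#' @slot kmo numeric(1) Kaiser-Meyer-Olkin sampling adequacy.
#' @slot bartlett list with statistic, df, p.value of the sphericity test.
#' @slot nUsed integer, subjects entering the PCA.
#' @export
setClass("FactorModel",
  representation(bundle = "character", metrics = "character",
                 loadings = "matrix", suppressed = "matrix",
                 eigenvalues = "numeric", nRetained = "integer",
                 scores = "numeric", kmo = "numeric", bartlett = "list",
                 nUsed = "integer"))

setMethod("show", "VoxelGrid", function(object) {
  vs <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  cat(sprintf("VoxelGrid: %s voxels, %.3g x %.3g x %.3g mm (%.4g mm^3/voxel)\n",
              paste(object@dim, collapse = " x "), vs[1], vs[2], vs[3],
              abs(det(object@affine[1:3, 1:3]))))
})

setMethod("show", "Bundle", function(object) {
  np <- sum(vapply(object@streamlines, nrow, 0L))
  cat(sprintf("Bundle '%s' (%s): %d streamlines, %d points\n",
              object@name, object@side, length(object@streamlines), np))
})

setMethod("show", "LesionInteraction", function(object) {
  cat(sprintf(
    "LesionInteraction '%s': %d/%d streamlines lesioned, %d/%d voxels intersect lesions\n",
    object@bundleName, length(object@lesionedStreamlines),
    length(object@streamlines), nrow(object@lesionedVoxels),
    nrow(object@bundleVoxels)))
})

setMethod("show", "GradientTable", function(object) {
  sh <- shells(object)
  cat(sprintf("GradientTable: %d volumes; shells b = %s (n = %s)\n",
              length(object@bvals),
              paste(unique(sh), collapse = ", "),
              paste(tabulate(factor(sh)), collapse = ", ")))
})

setMethod("show", "ShCoeffMap", function(object) {
  cat(sprintf("ShCoeffMap: %d voxel(s), lmax = %d (%d coefficients), basis '%s'\n",
              nrow(object@coefficients), object@lmax,
              ncol(object@coefficients), object@convention))
})

setMethod("show", "FactorModel", function(object) {
  cat(sprintf("FactorModel '%s': %d metrics, %d component(s) retained (eigenvalue > 1)\n",
              object@bundle, length(object@metrics), object@nRetained))
  cat(sprintf("  KMO = %.3f; Bartlett chi^2(%d) = %.2f, p = %.3g; n = %d\n",
              object@kmo, object@bartlett$df, object@bartlett$statistic,
              object@bartlett$p.value, object@nUsed))
  ld <- round(object@loadings[, 1], 3)
  ld[object@suppressed[, 1]] <- NA
  cat("  component-1 loadings (suppressed |.| < threshold shown as NA):\n")
  print(ld)
})
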