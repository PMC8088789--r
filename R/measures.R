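## The six lesion-interaction measures: voxel-based lesion load,
## whole-brain tractogram load, bundle volume, bundle load, whole-bundle
## Tractometry means and lesion-restricted lesionometry means.
##
## Voxelization dialect: streamlines are resampled to a step of half the
## smallest voxel dimension and voxels are collected by nearest-voxel
## point membership (0-based indices, half-open bounds). Lesion
## "intersection" is defined on the voxel lattice of the lesion mask.

defaultStep <- function(grid) min(voxelSize(grid)) / 2

resampleBundlePoints <- function(bundle, step) {
  lapply(bundle@streamlines, function(s) resamplePolyline(s, step))
}

voxelizePoints <- function(pts, grid, warnOutside = TRUE) {
  idx <- pointToVoxel(grid, pts)
  ok <- inGrid(grid, idx)
  if (warnOutside && any(!ok))
    warning(sum(!ok), " streamline point(s) outside the grid dropped")
  idx[ok, , drop = FALSE]
}

#' Voxelize a bundle
#'
#' The set of voxels containing at least one streamline point after
#' mandatory resampling to `step` (default half the smallest voxel
#' dimension, so point membership cannot skip voxels).
#'
#' @param bundle a [Bundle-class] (an empty bundle gives an empty set).
#' @param grid a [VoxelGrid-class].
#' @param step resampling step in mm.
#' @return integer k-by-3 matrix of 0-based voxel indices, ordered by
#'   linear index.
#' @export
voxelize <- function(bundle, grid, step = defaultStep(grid)) {
  if (length(bundle@streamlines) == 0L)
    return(matrix(integer(), ncol = 3L))
  pts <- do.call(rbind, resampleBundlePoints(bundle, step))
  idx <- voxelizePoints(pts, grid)
  if (nrow(idx) == 0L) return(matrix(integer(), ncol = 3L))
  lin <- sort(unique(voxelLinear(idx, gridDim(grid))))
  linearVoxel(lin, gridDim(grid))
}

voxelizeLinear <- function(bundle, grid, step = defaultStep(grid)) {
  idx <- voxelize(bundle, grid, step)
  if (nrow(idx) == 0L) return(integer())
  voxelLinear(idx, gridDim(grid))
}

#' Voxel-based lesion load normalized by head size
#'
#' Lesion voxel count divided by the brain-mask voxel count (or by an
#' externally supplied intracranial volume). Lesion voxels outside the
#' brain mask are excluded from the numerator with a warning.
#'
#' @param lesionMask,brainMask binary arrays on the same grid.
#' @param grid the [VoxelGrid-class]; needed only when `icv` is given.
#' @param icv optional intracranial volume in mm^3 used as denominator.
#' @return fraction in [0, 1].
#' @export
lesionLoad <- function(lesionMask, brainMask, grid = NULL, icv = NULL) {
  stopifnot(all(dim(lesionMask) == dim(brainMask)))
  if (sum(brainMask > 0) == 0L) stop("empty brain mask")
  outside <- sum(lesionMask > 0 & brainMask == 0)
  if (outside > 0)
    warning(outside, " lesion voxel(s) outside the brain mask excluded")
  num <- sum(lesionMask > 0 & brainMask > 0)
  den <- if (is.null(icv)) sum(brainMask > 0) else {
    if (is.null(grid)) stop("'grid' required when 'icv' is supplied")
    icv / voxelVolume(grid)
  }
  num / den
}

#' Whole-brain tractogram load
#'
#' The tractogram is the concatenation of all segmented bundles; the
#' load is the fraction of its voxelized volume intersecting lesions.
#'
#' @param bundles list of [Bundle-class] objects.
#' @param lesionMask binary array on `grid`.
#' @param grid a [VoxelGrid-class].
#' @param step resampling step in mm.
#' @return fraction in [0, 1].
#' @export
tractogramLoad <- function(bundles, lesionMask, grid,
                           step = defaultStep(grid)) {
  lin <- sort(unique(unlist(lapply(bundles, voxelizeLinear, grid = grid,
                                   step = step))))
  if (length(lin) == 0L) stop("empty tractogram")
  les <- as.vector(lesionMask > 0)
  sum(les[lin]) / length(lin)
}

#' Bundle volume in mm^3
#'
#' Voxelized bundle voxel count times the voxel volume. Duplicate
#' streamlines do not change the result (set semantics).
#'
#' @inheritParams tractogramLoad
#' @param bundle a [Bundle-class].
#' @export
bundleVolume <- function(bundle, grid, step = defaultStep(grid)) {
  lin <- voxelizeLinear(bundle, grid, step)
  if (length(lin) == 0L) stop("empty bundle")
  length(lin) * voxelVolume(grid)
}

#' Bundle load: lesioned fraction of a bundle's volume
#'
#' @inheritParams bundleVolume
#' @param lesionMask binary array on `grid`.
#' @return fraction in [0, 1].
#' @export
bundleLoad <- function(bundle, lesionMask, grid,
                       step = defaultStep(grid)) {
  lin <- voxelizeLinear(bundle, grid, step)
  if (length(lin) == 0L) stop("empty bundle")
  les <- as.vector(lesionMask > 0)
  sum(les[lin]) / length(lin)
}

#' Split a bundle into lesioned and spared streamlines
#'
#' A streamline is lesioned iff at least one of its (resampled) points
#' maps to a lesion voxel. Per-point flags are retained for
#' portion-mode lesionometry sampling.
#'
#' @inheritParams bundleLoad
#' @return A [LesionInteraction-class].
#' @export
splitByLesion <- function(bundle, lesionMask, grid,
                          step = defaultStep(grid)) {
  d <- gridDim(grid)
  les <- as.vector(lesionMask > 0)
  sl <- resampleBundlePoints(bundle, step)
  flags <- lapply(sl, function(s) {
    idx <- pointToVoxel(grid, s)
    ok <- inGrid(grid, idx)
    f <- rep(FALSE, nrow(s))
    if (any(ok))
      f[ok] <- les[voxelLinear(idx[ok, , drop = FALSE], d)]
    f
  })
  lesioned <- which(vapply(flags, any, NA))
  allIdx <- do.call(rbind, lapply(sl, function(s) {
    idx <- pointToVoxel(grid, s)
    idx[inGrid(grid, idx), , drop = FALSE]
  }))
  bundleLin <- sort(unique(voxelLinear(allIdx, d)))
  lesLin <- bundleLin[les[bundleLin]]
  new("LesionInteraction", bundleName = bundle@name,
      bundleVoxels = linearVoxel(bundleLin, d),
      lesionedVoxels = if (length(lesLin)) linearVoxel(lesLin, d)
                       else matrix(integer(), ncol = 3L),
      streamlines = sl, pointInLesion = flags,
      lesionedStreamlines = as.integer(lesioned), step = step)
}

#' @rdname splitByLesion
#' @param x a LesionInteraction.
#' @export
lesionedStreamlines <- function(x) x@lesionedStreamlines

samplePointValues <- function(pts, map, grid) {
  idx <- pointToVoxel(grid, pts)
  ok <- inGrid(grid, idx)
  vals <- rep(NA_real_, nrow(pts))
  if (any(ok))
    vals[ok] <- as.vector(map)[voxelLinear(idx[ok, , drop = FALSE],
                                           gridDim(grid))]
  vals
}

#' Tractometry: whole-bundle mean of a microstructure map
#'
#' The map is sampled at every (resampled) streamline point of the
#' bundle and averaged (point-weighted). NaN/NA voxels are excluded.
#'
#' @param bundle a [Bundle-class].
#' @param map numeric 3-D array on `grid`.
#' @param grid a [VoxelGrid-class].
#' @param step resampling step in mm.
#' @export
tractometry <- function(bundle, map, grid, step = defaultStep(grid)) {
  pts <- do.call(rbind, resampleBundlePoints(bundle, step))
  vals <- samplePointValues(pts, map, grid)
  if (all(is.na(vals))) stop("all sampled values are missing")
  mean(vals, na.rm = TRUE)
}

#' Lesionometry: Tractometry restricted to lesioned streamlines
#'
#' In "portion" mode the map is sampled only at points lying inside
#' lesion voxels; in "full" mode along the entire length of the
#' streamlines that intersect lesions. When no streamline is lesioned
#' the result is missing (NA), never 0.
#'
#' @param interaction a [LesionInteraction-class] from [splitByLesion()].
#' @param map numeric 3-D array on `grid`.
#' @param grid a [VoxelGrid-class].
#' @param mode "portion" or "full".
#' @export
lesionometry <- function(interaction, map, grid,
                         mode = c("portion", "full")) {
  mode <- match.arg(mode)
  li <- interaction@lesionedStreamlines
  if (length(li) == 0L) return(NA_real_)
  vals <- unlist(lapply(li, function(i) {
    s <- interaction@streamlines[[i]]
    keep <- if (mode == "portion") interaction@pointInLesion[[i]]
            else rep(TRUE, nrow(s))
    samplePointValues(s[keep, , drop = FALSE], map, grid)
  }))
  if (all(is.na(vals))) stop("all sampled values are missing")
  mean(vals, na.rm = TRUE)
}

#' Average left/right measures into single per-bundle values
#'
#' Columns named `<bundle>_left.<measure>` / `<bundle>_right.<measure>`
#' are replaced by `<bundle>.<measure>` = (L + R) / 2; commissural
#' bundles and global measures pass through unchanged. A left column
#' without its right twin (or vice versa) is an error. NA on either side
#' propagates to NA.
#'
#' @param table data.frame of subject rows by measure columns.
#' @return data.frame with averaged columns.
#' @export
averageHemispheres <- function(table) {
  nm <- names(table)
  leftCols <- grep("_left\\.", nm, value = TRUE)
  rightCols <- grep("_right\\.", nm, value = TRUE)
  pairsL <- sub("_left\\.", ".", leftCols)
  pairsR <- sub("_right\\.", ".", rightCols)
  if (!setequal(pairsL, pairsR)) {
    orphan <- c(setdiff(pairsL, pairsR), setdiff(pairsR, pairsL))
    stop("unpaired hemisphere column(s): ", paste(orphan, collapse = ", "))
  }
  out <- table[, setdiff(nm, c(leftCols, rightCols)), drop = FALSE]
  for (p in sort(unique(pairsL))) {
    l <- leftCols[pairsL == p]
    r <- rightCols[pairsR == p]
    out[[p]] <- (table[[l]] + table[[r]]) / 2
  }
  out
}

#' All lesion-interaction measures for one subject
#'
#' Computes the global measures (lesion load, tractogram load) and, per
#' bundle, volume, bundle load, per-metric Tractometry means and
#' per-metric lesionometry means in both sampling modes. Subjects with
#' no lesioned streamlines in a bundle get NA lesionometry.
#'
#' @param bundles list of [Bundle-class] objects.
#' @param lesionMask,brainMask binary arrays on `grid`.
#' @param maps named list of scalar 3-D arrays.
#' @param grid a [VoxelGrid-class].
#' @param step resampling step in mm.
#' @param subject subject identifier stored in the first column.
#' @return one-row data.frame.
#' @export
computeSubjectMeasures <- function(bundles, lesionMask, brainMask, maps,
                                   grid, step = defaultStep(grid),
                                   subject = "S001") {
  row <- data.frame(subject = subject, stringsAsFactors = FALSE)
  row$lesionLoad <- lesionLoad(lesionMask, brainMask)
  row$tractogramLoad <- tractogramLoad(bundles, lesionMask, grid, step)
  for (b in bundles) {
    nm <- b@name
    row[[paste0(nm, ".volume")]] <- bundleVolume(b, grid, step)
    row[[paste0(nm, ".load")]] <- bundleLoad(b, lesionMask, grid, step)
    inter <- splitByLesion(b, lesionMask, grid, step)
    for (m in names(maps)) {
      row[[paste0(nm, ".tract.", m)]] <- tractometry(b, maps[[m]], grid, step)
      row[[paste0(nm, ".lesioPortion.", m)]] <-
        lesionometry(inter, maps[[m]], grid, mode = "portion")
      row[[paste0(nm, ".lesioFull.", m)]] <-
        lesionometry(inter, maps[[m]], grid, mode = "full")
    }
  }
  row
}
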