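#' Construct a voxel grid
#'
#' @param dim integer(3) lattice dimensions.
#' @param voxel voxel size in mm; scalar (isotropic) or length 3. Ignored
#'   when `affine` is given.
#' @param origin world coordinate (mm) of the centre of voxel (0,0,0).
#' @param affine optional full 4x4 affine (overrides `voxel`/`origin`).
#' @return A [VoxelGrid-class] object.
#' @examples
#' g <- voxelGrid(c(10, 10, 10), voxel = 2)
#' voxelVolume(g)
#' @export
voxelGrid <- function(dim, voxel = 1, origin = c(0, 0, 0), affine = NULL) {
  if (is.null(affine)) {
    voxel <- rep_len(voxel, 3L)
    affine <- diag(c(voxel, 1))
    affine[1:3, 4] <- origin
  }
  new("VoxelGrid", dim = as.integer(dim), affine = affine)
}

#' @rdname voxelGrid
#' @param grid a VoxelGrid.
#' @export
gridDim <- function(grid) grid@dim

#' @rdname voxelGrid
#' @export
gridAffine <- function(grid) grid@affine

#' @rdname voxelGrid
#' @export
voxelSize <- function(grid) sqrt(colSums(grid@affine[1:3, 1:3]^2))

#' @rdname voxelGrid
#' @export
voxelVolume <- function(grid) abs(det(grid@affine[1:3, 1:3]))

#' Map world points to continuous voxel coordinates
#'
#' @param grid a [VoxelGrid-class].
#' @param pts n-by-3 matrix of world coordinates (mm).
#' @return n-by-3 matrix of continuous 0-based voxel coordinates.
#' @export
worldToVoxel <- function(grid, pts) {
  pts <- rbind(t(pts), 1)
  t(solve(grid@affine, pts))[, 1:3, drop = FALSE]
}

#' Map 0-based voxel indices to world coordinates of voxel centres
#'
#' @inheritParams worldToVoxel
#' @param idx n-by-3 matrix of voxel indices (0-based).
#' @export
voxelToWorld <- function(grid, idx) {
  idx <- rbind(t(idx), 1)
  t(grid@affine %*% idx)[, 1:3, drop = FALSE]
}

# nearest-voxel containment: voxel i covers [i - 0.5, i + 0.5)
pointToVoxel <- function(grid, pts) {
  v <- worldToVoxel(grid, pts)
  storage.mode(v) <- "double"
  matrix(as.integer(floor(v + 0.5)), ncol = 3L)
}

inGrid <- function(grid, idx) {
  d <- grid@dim
  idx[, 1] >= 0L & idx[, 1] < d[1] &
    idx[, 2] >= 0L & idx[, 2] < d[2] &
    idx[, 3] >= 0L & idx[, 3] < d[3]
}

# 0-based voxel triplets <-> 1-based linear indices into an array of dim d
voxelLinear <- function(idx, d) {
  idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3]) + 1L
}

linearVoxel <- function(lin, d) {
  lin <- lin - 1L
  x <- lin %% d[1]
  y <- (lin %/% d[1]) %% d[2]
  z <- lin %/% (d[1] * d[2])
  cbind(x, y, z)
}
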