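# Independent brute-force oracles and small fixture builders, kept
# deliberately naive (explicit loops, no reuse of package internals
# beyond the shared resampling dialect where the check targets voxel
# counting rather than resampling).

# naive point -> voxel mapping: solve the affine per point, floor(v + .5)
oracleVoxelSet <- function(pointList, grid) {
  A <- gridAffine(grid)
  d <- gridDim(grid)
  seen <- character()
  for (pts in pointList) {
    for (i in seq_len(nrow(pts))) {
      v <- solve(A, c(pts[i, ], 1))[1:3]
      ix <- floor(v + 0.5)
      if (all(ix >= 0) && all(ix < d))
        seen <- c(seen, paste(ix, collapse = ","))
    }
  }
  unique(seen)
}

oracleKey <- function(idx) {
  if (nrow(idx) == 0L) return(character())
  apply(idx, 1, paste, collapse = ",")
}

# loads recomputed from scratch by voxel counting
oracleLoads <- function(bundles, lesionMask, brainMask, grid, step) {
  lesKeys <- oracleKey(which(lesionMask > 0, arr.ind = TRUE) - 1L)
  perBundle <- lapply(bundles, function(b) {
    pts <- lesionometry:::resampleBundlePoints(b, step)
    vox <- oracleVoxelSet(pts, grid)
    list(nVox = length(vox), nLes = sum(vox %in% lesKeys), vox = vox)
  })
  names(perBundle) <- vapply(bundles, function(b) b@name, "")
  tracto <- unique(unlist(lapply(perBundle, `[[`, "vox")))
  list(
    lesionLoad = sum(lesionMask > 0 & brainMask > 0) / sum(brainMask > 0),
    tractogramLoad = sum(tracto %in% lesKeys) / length(tracto),
    bundleVolume = vapply(perBundle, function(x)
      x$nVox * voxelVolume(grid), 0),
    bundleLoad = vapply(perBundle, function(x) x$nLes / x$nVox, 0))
}

# a compact two-bundle phantom used across measure tests
smallPhantomSpec <- function(seed = 1L, nStreamlines = 40L,
                             noiseSd = 0, lesions = list(
                               list(center = c(14, 16, 20),
                                    radii = c(5, 6, 5)))) {
  phantomSpec(
    dim = c(20L, 20L, 20L), voxel = 2,
    bundles = list(
      tube_left = list(centerline = rbind(c(14, 4, 20), c(14, 34, 20)),
                       radius = 2.5, n = nStreamlines, dispersion = 0.8),
      tube_right = list(centerline = rbind(c(24, 4, 20), c(24, 34, 20)),
                        radius = 2.5, n = nStreamlines, dispersion = 0.8)),
    lesions = lesions, noiseSd = noiseSd, seed = seed)
}

# samples with exact mean/sd (for effect-size constructions)
exactMoments <- function(n, mean, sd, seed = 1L) {
  set.seed(seed)
  x <- rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  mean + sd * x
}

# x, y with an exact sample correlation r
exactCorPair <- function(n, r, seed = 1L) {
  set.seed(seed)
  x <- scale(rnorm(n))[, 1]
  e <- rnorm(n)
  e <- scale(residuals(lm(e ~ x)))[, 1]
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}
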