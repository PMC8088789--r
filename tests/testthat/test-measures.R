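test_that("voxelize collects exactly the voxels a streamline traverses", {
  g <- voxelGrid(c(12L, 12L, 12L), voxel = 2)
  # axis-aligned line through the centres of 10 voxels along y at x=z=3
  sl <- rbind(c(6, 0, 6), c(6, 18, 6))
  b <- new("Bundle", name = "axis", side = "commissural",
           streamlines = list(sl))
  vox <- voxelize(b, g)
  expect_identical(nrow(vox), 10L)
  expect_true(all(vox[, 1] == 3L & vox[, 3] == 3L))
  expect_identical(sort(vox[, 2]), 0:9)
  # empty bundle -> empty set
  e <- new("Bundle", name = "none", side = "commissural",
           streamlines = list())
  expect_identical(nrow(voxelize(e, g)), 0L)
})

test_that("helical streamlines match the brute-force enumeration oracle", {
  g <- voxelGrid(c(16L, 16L, 16L), voxel = 2)
  t <- seq(0, 6 * pi, length.out = 400)
  helix <- cbind(16 + 6 * cos(t), 16 + 6 * sin(t), 2 + t)
  b <- new("Bundle", name = "helix", side = "commissural",
           streamlines = list(helix))
  vox <- voxelize(b, g)
  oracle <- oracleVoxelSet(lesionometry:::resampleBundlePoints(
    b, min(voxelSize(g)) / 2), g)
  expect_setequal(oracleKey(vox), oracle)
})

test_that("points outside the grid are dropped with a warning", {
  g <- voxelGrid(c(5L, 5L, 5L), voxel = 2)
  sl <- rbind(c(-10, 4, 4), c(4, 4, 4))
  b <- new("Bundle", name = "out", side = "commissural",
           streamlines = list(sl))
  expect_warning(vox <- voxelize(b, g), "outside the grid")
  expect_true(all(vox >= 0 & vox <= 4))
})

test_that("lesion load is the brain-normalized lesion fraction", {
  d <- c(50L, 50L, 40L)
  brain <- array(1L, dim = d)           # 100 000 voxels
  lesion <- array(0L, dim = d)
  lesion[seq_len(550)] <- 1L
  expect_equal(lesionLoad(lesion, brain), 0.0055)
  expect_equal(lesionLoad(array(0L, dim = d), brain), 0)
  expect_equal(lesionLoad(brain, brain), 1)
  # lesion voxels outside the brain are excluded with a warning
  brain2 <- brain; brain2[1:100] <- 0L
  expect_warning(ll <- lesionLoad(lesion, brain2), "outside the brain")
  expect_equal(ll, 450 / sum(brain2))
  # external ICV denominator
  g <- voxelGrid(d, voxel = 1)
  expect_equal(lesionLoad(lesion, brain, g, icv = 2 * prod(d)), 0.00275)
  expect_error(lesionLoad(lesion, array(0L, dim = d)), "empty brain")
})

test_that("tractogram load covers the concatenated bundle set", {
  g <- voxelGrid(c(20L, 20L, 20L), voxel = 2)
  mk <- function(x) new("Bundle", name = paste0("b", x), side = "commissural",
                        streamlines = list(rbind(c(x, 2, 20), c(x, 36, 20))))
  b1 <- mk(10); b2 <- mk(28)
  noLesion <- array(0L, dim = c(20, 20, 20))
  expect_equal(tractogramLoad(list(b1, b2), noLesion, g), 0)
  allLesion <- array(1L, dim = c(20, 20, 20))
  expect_equal(tractogramLoad(list(b1, b2), allLesion, g), 1)
  # sphere overlapping only the first of two disjoint equal bundles
  spec <- phantomSpec(dim = c(20L, 20L, 20L), voxel = 2,
                      lesions = list(list(center = c(10, 20, 20),
                                          radii = c(4, 4, 4))))
  les <- makeLesionMask(spec)
  got <- tractogramLoad(list(b1, b2), les, g)
  oracle <- oracleLoads(list(b1, b2), les, allLesion, g,
                        min(voxelSize(g)) / 2)
  expect_identical(got, oracle$tractogramLoad)
  expect_error(tractogramLoad(list(), les, g), "empty tractogram")
})

test_that("bundle volume uses voxel-set semantics", {
  g <- voxelGrid(c(12L, 12L, 12L), voxel = 2)
  sl <- rbind(c(6, 0, 6), c(6, 18, 6))
  b <- new("Bundle", name = "axis", side = "commissural",
           streamlines = list(sl))
  expect_equal(bundleVolume(b, g), 10 * 8)   # 10 voxels at 8 mm^3
  dup <- new("Bundle", name = "axis", side = "commissural",
             streamlines = list(sl, sl, sl))
  expect_equal(bundleVolume(dup, g), bundleVolume(b, g))
})

test_that("bundle load matches exhaustive voxel enumeration", {
  spec <- smallPhantomSpec(seed = 4L)
  g <- phantomGrid(spec)
  les <- makeLesionMask(spec)
  brain <- makeBrainMask(spec)
  b <- makeBundle(spec, "tube_left")
  step <- min(voxelSize(g)) / 2
  oracle <- oracleLoads(list(b), les, brain, g, step)
  expect_identical(bundleLoad(b, les, g), unname(oracle$bundleLoad))
  expect_identical(bundleVolume(b, g), unname(oracle$bundleVolume))
  # boundary cases
  expect_equal(bundleLoad(b, array(0L, dim = gridDim(g)), g), 0)
  expect_equal(bundleLoad(b, array(1L, dim = gridDim(g)), g), 1)
})

test_that("splitByLesion flags streamlines by per-point membership", {
  spec <- smallPhantomSpec(seed = 6L)
  g <- phantomGrid(spec)
  les <- makeLesionMask(spec)
  b <- makeBundle(spec, "tube_left")
  inter <- splitByLesion(b, les, g)
  # brute-force per-point check
  sl <- lesionometry:::resampleBundlePoints(b, min(voxelSize(g)) / 2)
  lesKeys <- oracleKey(which(les > 0, arr.ind = TRUE) - 1L)
  flagged <- which(vapply(sl, function(s)
    any(oracleVoxelSet(list(s), g) %in% lesKeys), NA))
  expect_identical(lesionedStreamlines(inter), as.integer(flagged))
  # no lesions -> none; full slab -> all
  none <- splitByLesion(b, array(0L, dim = gridDim(g)), g)
  expect_length(lesionedStreamlines(none), 0L)
  slab <- array(0L, dim = gridDim(g)); slab[, 10, ] <- 1L
  all_ <- splitByLesion(b, slab, g)
  expect_length(lesionedStreamlines(all_), length(b@streamlines))
})

test_that("tractometry is the point-weighted map mean along the bundle", {
  g <- voxelGrid(c(12L, 12L, 12L), voxel = 2)
  sl <- rbind(c(6, 0, 6), c(6, 18, 6))
  b <- new("Bundle", name = "axis", side = "commissural",
           streamlines = list(sl))
  const <- array(0.7, dim = c(12, 12, 12))
  expect_equal(tractometry(b, const, g), 0.7)
  # two-valued map with known point counts per region
  twoVal <- array(1, dim = c(12, 12, 12))
  twoVal[, 6:12, ] <- 3
  pts <- lesionometry:::resamplePolyline(sl, 1)
  idx <- lesionometry:::pointToVoxel(g, pts)
  nHigh <- sum(idx[, 2] >= 5)
  want <- (1 * (nrow(pts) - nHigh) + 3 * nHigh) / nrow(pts)
  expect_equal(tractometry(b, twoVal, g), want)
  # NaN outside the bundle leaves the mean unaffected
  withNaN <- const; withNaN[1, 1, 1] <- NaN
  expect_equal(tractometry(b, withNaN, g), 0.7)
  allNaN <- array(NaN, dim = c(12, 12, 12))
  expect_error(tractometry(b, allNaN, g), "missing")
})

test_that("lesionometry separates portion and full sampling modes", {
  g <- voxelGrid(c(12L, 12L, 12L), voxel = 2)
  # streamline crossing a lesion occupying exactly its second half
  sl <- rbind(c(6, 0.5, 6), c(6, 21.5, 6))
  b <- new("Bundle", name = "half", side = "commissural",
           streamlines = list(sl))
  les <- array(0L, dim = c(12, 12, 12))
  les[4, 7:12, 4] <- 1L
  indicator <- array(0, dim = c(12, 12, 12))
  indicator[les == 1L] <- 1
  inter <- splitByLesion(b, les, g)
  expect_equal(lesionometry(inter, indicator, g, "portion"), 1)
  expect_equal(lesionometry(inter, indicator, g, "full"), 0.5)
  # constant map gives the constant in both modes
  const <- array(2.2, dim = c(12, 12, 12))
  expect_equal(lesionometry(inter, const, g, "portion"), 2.2)
  expect_equal(lesionometry(inter, const, g, "full"), 2.2)
  # full mode equals tractometry when every streamline is lesioned
  spec <- smallPhantomSpec(seed = 2L)
  g2 <- phantomGrid(spec)
  b2 <- makeBundle(spec, "tube_left")
  slab <- array(1L, dim = gridDim(g2))
  inter2 <- splitByLesion(b2, slab, g2)
  maps <- makeScalarMaps(spec, makeLesionMask(spec))
  expect_identical(lesionometry(inter2, maps$FA, g2, "full"),
                   tractometry(b2, maps$FA, g2))
  # no lesioned streamline -> missing, never 0
  none <- splitByLesion(b2, array(0L, dim = gridDim(g2)), g2)
  expect_identical(lesionometry(none, maps$FA, g2, "full"), NA_real_)
})

test_that("load measures are monotone under lesion growth", {
  for (seed in 1:5) {
    spec <- smallPhantomSpec(seed = seed)
    g <- phantomGrid(spec)
    brain <- makeBrainMask(spec)
    b <- makeBundle(spec, "tube_left")
    bundles <- list(b, makeBundle(spec, "tube_right"))
    les1 <- makeLesionMask(spec)
    grow <- phantomSpec(dim = spec$dim, voxel = spec$voxel,
                        lesions = list(list(center = c(14, 16, 20),
                                            radii = c(8, 9, 8))),
                        seed = seed)
    les2 <- makeLesionMask(grow)
    expect_true(all(les2[les1 == 1L] == 1L))  # superset by construction
    expect_gte(lesionLoad(les2, brain), lesionLoad(les1, brain))
    expect_gte(tractogramLoad(bundles, les2, g),
               tractogramLoad(bundles, les1, g))
    expect_gte(bundleLoad(b, les2, g), bundleLoad(b, les1, g))
  }
})

test_that("voxelization stabilizes once the step is at most half a voxel", {
  spec <- smallPhantomSpec(seed = 9L)
  g <- phantomGrid(spec)
  b <- makeBundle(spec, "tube_left")
  vHalf <- oracleKey(voxelize(b, g, step = min(voxelSize(g)) / 2))
  vQuarter <- oracleKey(voxelize(b, g, step = min(voxelSize(g)) / 4))
  vCoarse <- oracleKey(voxelize(b, g, step = min(voxelSize(g))))
  # refinement only ever adds voxels
  expect_true(all(vCoarse %in% vHalf))
  expect_true(all(vHalf %in% vQuarter))
  # and has stabilized at half-voxel steps
  expect_setequal(vHalf, vQuarter)
})

test_that("hemisphere averaging pairs left/right columns", {
  tbl <- data.frame(subject = c("a", "b"),
                    lesionLoad = c(0.1, 0.2),
                    slf_left.load = c(0.2, 0.4),
                    slf_right.load = c(0.4, 0.6),
                    genu.load = c(0.5, 0.5))
  out <- averageHemispheres(tbl)
  expect_equal(out$slf.load, c(0.3, 0.5))
  expect_equal(out$genu.load, c(0.5, 0.5))     # commissural passthrough
  expect_equal(out$lesionLoad, c(0.1, 0.2))    # global passthrough
  expect_false(any(grepl("_left|_right", names(out))))
  # L = R = v stays v; random table matches the column-wise oracle
  set.seed(30)
  tbl2 <- data.frame(x_left.m = rnorm(10), x_right.m = rnorm(10))
  expect_equal(averageHemispheres(tbl2)$x.m,
               (tbl2$x_left.m + tbl2$x_right.m) / 2)
  # unpaired side errors
  expect_error(averageHemispheres(data.frame(a_left.m = 1)), "unpaired")
})

test_that("subject measure rows carry loads, means and missingness", {
  spec <- smallPhantomSpec(seed = 3L, noiseSd = 0.01)
  subj <- makePhantomSubject(spec)
  row <- computeSubjectMeasures(subj$bundles, subj$lesionMask,
                                subj$brainMask, subj$maps, subj$grid,
                                subject = "P1")
  expect_identical(row$subject, "P1")
  loads <- unlist(row[grepl("load|Load", names(row))])
  expect_true(all(loads >= 0 & loads <= 1))
  expect_true(all(unlist(row[grepl("volume", names(row))]) > 0))
  # the right tube is lesion-free: its lesionometry must be NA, not 0
  expect_true(is.na(row$tube_right.lesioPortion.FA))
  expect_gt(row$tube_left.lesioPortion.MD, row$tube_left.tract.MD)
})
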