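## Synthetic phantoms: grids, bundles, lesions, scalar maps, DWI and
## cohort tables with known ground truth, so every downstream stage can
## be tested without external data. All generators are pure functions of
## (spec, seed): the global RNG state is saved and restored.

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Derive a per-subject RNG seed from a master seed
#'
#' One independent stream per subject keeps cohorts reproducible even if
#' subjects are generated out of order or in parallel.
#' @param master integer master seed.
#' @param index subject index (1-based).
#' @export
subjectSeed <- function(master, index) {
  as.integer((as.numeric(master) * 1009 + 7919 * as.numeric(index)) %%
               2147483647)
}

#' Specify a synthetic phantom
#'
#' Defines the voxel grid, tube-like bundles, ellipsoidal lesions and
#' tissue parameters from which [makeBundle()], [makeLesionMask()],
#' [makeScalarMaps()] and [makeDwi()] generate data deterministically.
#'
#' Each bundle descriptor is a list with `centerline` (m-by-3 matrix of
#' control points, world mm), `radius` (tube radius, mm), `n` (streamline
#' count) and `dispersion` (sd, mm, of the per-streamline perpendicular
#' offset; offsets are clipped to the tube radius). Each lesion is a list
#' with `center` (mm) and `radii` (mm, per axis).
#'
#' @param dim grid dimensions (voxels).
#' @param voxel isotropic voxel size (mm).
#' @param bundles named list of bundle descriptors.
#' @param lesions list of lesion descriptors (may be empty).
#' @param brain optional list(center, radii) for an ellipsoidal brain
#'   mask; default covers 90% of the grid extent.
#' @param tissue list of tissue parameters; see [phantomTissue()].
#' @param noiseSd relative noise sd applied to scalar maps (fraction of
#'   each metric's baseline).
#' @param seed integer seed.
#' @return A list of class `PhantomSpec`.
#' @export
phantomSpec <- function(dim = c(40L, 40L, 40L), voxel = 2,
                        bundles = list(), lesions = list(),
                        brain = NULL, tissue = phantomTissue(),
                        noiseSd = 0, seed = 1L) {
  dim <- as.integer(dim)
  ext <- (dim - 1) * voxel
  if (is.null(brain))
    brain <- list(center = ext / 2, radii = ext * 0.55)
  for (nm in names(bundles)) {
    b <- bundles[[nm]]
    stopifnot(is.matrix(b$centerline), ncol(b$centerline) == 3,
              b$radius > 0, b$n > 0, b$dispersion >= 0)
  }
  for (l in lesions) {
    stopifnot(all(l$radii > 0))
    v <- l$center / voxel
    if (any(v < 0) || any(v > dim - 1))
      stop("lesion center outside the grid")
  }
  structure(list(dim = dim, voxel = voxel, bundles = bundles,
                 lesions = lesions, brain = brain, tissue = tissue,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Tissue parameters for the phantom
#'
#' Baselines are field-typical healthy white-matter values; lesion
#' multipliers encode the expected direction of lesion effects: MD and RD
#' rise inside lesions while FA, AFD, NuFO, RISH0 and RISH2 fall.
#' Diffusivities are in mm^2/s.
#'
#' @param baselines named numeric of lesion-free metric values.
#' @param lesionMultipliers named numeric factors applied inside lesions.
#' @param axialD,radialD eigenvalues of the intra-bundle tensor used by
#'   [makeDwi()].
#' @param isotropicD diffusivity outside bundles.
#' @param s0 non-diffusion-weighted signal level.
#' @export
phantomTissue <- function(baselines = c(FA = 0.5, MD = 8e-4, RD = 6e-4,
                                        AFD = 0.6, NuFO = 1,
                                        RISH0 = 0.8, RISH2 = 0.25),
                          lesionMultipliers = c(FA = 0.6, MD = 1.5,
                                                RD = 1.6, AFD = 0.6,
                                                NuFO = 0.8, RISH0 = 0.7,
                                                RISH2 = 0.6),
                          axialD = 1.7e-3, radialD = 3e-4,
                          isotropicD = 7e-4, s0 = 1000) {
  list(baselines = baselines, lesionMultipliers = lesionMultipliers,
       axialD = axialD, radialD = radialD, isotropicD = isotropicD,
       s0 = s0)
}

#' Grid of a phantom spec
#' @param spec a `PhantomSpec`.
#' @export
phantomGrid <- function(spec) voxelGrid(spec$dim, voxel = spec$voxel)

#' Default phantom: the seven-bundle inventory at acquisition resolution
#'
#' Twelve tube bundles (genu and isthmus of the corpus callosum plus
#' left/right striato-prefrontal, striato-parietal and SLF I-III),
#' 2000 streamlines each, on a 2 mm isotropic grid, with three
#' periventricular-style ellipsoidal lesions placed to intersect the
#' posterior bundles so bundle loads span a usable range.
#'
#' @param nStreamlines streamlines per bundle.
#' @param seed integer seed.
#' @export
defaultPhantomSpec <- function(nStreamlines = 2000L, seed = 1L) {
  arc <- function(p1, p2, p3, m = 9) {
    # quadratic Bezier through control points
    t <- seq(0, 1, length.out = m)
    (1 - t)^2 %o% p1 + 2 * t * (1 - t) %o% p2 + t^2 %o% p3
  }
  seg <- function(p1, p2) rbind(p1, p2)
  b <- function(cl, radius = 3.5, disp = 1)
    list(centerline = cl, radius = radius, n = nStreamlines,
         dispersion = disp)
  bundles <- list(
    genu        = b(arc(c(26, 60, 40), c(39, 70, 40), c(52, 60, 40))),
    isthmus     = b(arc(c(26, 22, 40), c(39, 13, 40), c(52, 22, 40))),
    st_pref_left  = b(arc(c(32, 40, 22), c(30, 52, 34), c(26, 60, 44))),
    st_pref_right = b(arc(c(46, 40, 22), c(48, 52, 34), c(52, 60, 44))),
    st_par_left   = b(arc(c(32, 40, 22), c(30, 28, 36), c(26, 20, 46))),
    st_par_right  = b(arc(c(46, 40, 22), c(48, 28, 36), c(52, 20, 46))),
    slf1_left   = b(seg(c(25, 16, 50), c(25, 62, 50)), radius = 3),
    slf1_right  = b(seg(c(53, 16, 50), c(53, 62, 50)), radius = 3),
    slf2_left   = b(seg(c(21, 16, 44), c(21, 62, 44)), radius = 3),
    slf2_right  = b(seg(c(57, 16, 44), c(57, 62, 44)), radius = 3),
    slf3_left   = b(seg(c(18, 16, 36), c(18, 62, 36)), radius = 3),
    slf3_right  = b(seg(c(60, 16, 36), c(60, 62, 36)), radius = 3)
  )
  lesions <- list(
    list(center = c(30, 24, 44), radii = c(7, 9, 7)),
    list(center = c(50, 26, 46), radii = c(6, 7, 6)),
    list(center = c(36, 54, 40), radii = c(4, 5, 4))
  )
  phantomSpec(dim = c(40L, 40L, 40L), voxel = 2, bundles = bundles,
              lesions = lesions, noiseSd = 0.02, seed = seed)
}

bundleSide <- function(name) {
  if (grepl("_left$", name)) "left"
  else if (grepl("_right$", name)) "right"
  else "commissural"
}

# resample a polyline to (approximately) equal arc-length steps,
# endpoints preserved
resamplePolyline <- function(pts, step) {
  d <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(d))
  L <- s[length(s)]
  if (L <= 0) stop("degenerate (zero-length) centerline")
  n <- max(2L, as.integer(ceiling(L / step)) + 1L)
  tt <- seq(0, L, length.out = n)
  apply(pts, 2, function(x) stats::approx(s, x, xout = tt, ties = "ordered")$y)
}

#' Generate streamlines for one phantom bundle
#'
#' Streamlines are copies of the (resampled) centerline displaced by a
#' per-streamline offset drawn in the plane perpendicular to the bundle
#' chord; offsets have Gaussian sd `dispersion` per component and are
#' clipped to the tube radius, so every point lies within `radius` mm of
#' the centerline. The resampling step is half the voxel size so that
#' point-membership voxelization cannot skip voxels.
#'
#' @param spec a `PhantomSpec`.
#' @param name bundle name present in `spec$bundles`.
#' @return A [Bundle-class].
#' @export
makeBundle <- function(spec, name) {
  if (!name %in% names(spec$bundles))
    stop("unknown bundle name: ", name)
  b <- spec$bundles[[name]]
  step <- spec$voxel / 2
  cl <- resamplePolyline(b$centerline, step)
  chord <- cl[nrow(cl), ] - cl[1, ]
  if (sqrt(sum(chord^2)) < .Machine$double.eps)
    stop("degenerate centerline for bundle ", name)
  chord <- chord / sqrt(sum(chord^2))
  u <- if (abs(chord[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * chord) * chord
  u <- u / sqrt(sum(u^2))
  v <- c(chord[2] * u[3] - chord[3] * u[2],
         chord[3] * u[1] - chord[1] * u[3],
         chord[1] * u[2] - chord[2] * u[1])
  sl <- withSeed(spec$seed + sum(utf8ToInt(name)), {
    lapply(seq_len(b$n), function(i) {
      off <- stats::rnorm(2, 0, b$dispersion)
      r <- sqrt(sum(off^2))
      if (r > b$radius) off <- off * b$radius / r
      sweep(cl, 2, off[1] * u + off[2] * v, "+")
    })
  })
  new("Bundle", name = name, side = bundleSide(name), streamlines = sl)
}

ellipsoidMask <- function(grid, center, radii) {
  d <- gridDim(grid)
  idx <- linearVoxel(seq_len(prod(d)), d)
  w <- voxelToWorld(grid, idx)
  inside <- ((w[, 1] - center[1]) / radii[1])^2 +
    ((w[, 2] - center[2]) / radii[2])^2 +
    ((w[, 3] - center[3]) / radii[3])^2 <= 1
  array(as.integer(inside), dim = d)
}

#' Binary lesion mask from the phantom's ellipsoidal lesions
#'
#' A voxel is lesioned iff its centre lies inside at least one lesion
#' ellipsoid. An empty lesion list yields an all-zero mask.
#'
#' @param spec a `PhantomSpec`.
#' @param grid the [VoxelGrid-class]; defaults to the spec's own grid.
#' @param brainMask optional binary array; the lesion mask is intersected
#'   with it.
#' @export
makeLesionMask <- function(spec, grid = phantomGrid(spec),
                           brainMask = NULL) {
  m <- array(0L, dim = gridDim(grid))
  for (l in spec$lesions)
    m <- m | ellipsoidMask(grid, l$center, l$radii)
  m <- array(as.integer(m), dim = gridDim(grid))
  if (!is.null(brainMask)) m <- m * (brainMask > 0)
  array(as.integer(m), dim = gridDim(grid))
}

#' Ellipsoidal brain mask of the phantom
#' @inheritParams makeLesionMask
#' @export
makeBrainMask <- function(spec, grid = phantomGrid(spec)) {
  ellipsoidMask(grid, spec$brain$center, spec$brain$radii)
}

#' Scalar microstructure maps with lesion effects
#'
#' Each metric equals its baseline outside lesions and baseline times the
#' lesion multiplier inside, plus optional Gaussian noise with sd
#' `noiseSd * baseline` (relative noise). FA is clamped to [0, 1] and all
#' metrics to non-negative values after noise.
#'
#' @param spec a `PhantomSpec`.
#' @param lesionMask binary array on `grid`.
#' @param grid the [VoxelGrid-class].
#' @return Named list of 3-D arrays, one per metric in the tissue
#'   baselines.
#' @export
makeScalarMaps <- function(spec, lesionMask, grid = phantomGrid(spec)) {
  stopifnot(all(dim(lesionMask) == gridDim(grid)))
  base <- spec$tissue$baselines
  mult <- spec$tissue$lesionMultipliers
  inles <- lesionMask > 0
  withSeed(spec$seed + 211L, {
    maps <- lapply(names(base), function(m) {
      x <- array(base[[m]], dim = gridDim(grid))
      f <- if (m %in% names(mult)) mult[[m]] else 1
      x[inles] <- base[[m]] * f
      if (spec$noiseSd > 0)
        x <- x + array(stats::rnorm(length(x), 0, spec$noiseSd * base[[m]]),
                       dim = dim(x))
      x[x < 0] <- 0
      if (m == "FA") x[x > 1] <- 1
      x
    })
    names(maps) <- names(base)
    maps
  })
}

# mean streamline tangent per occupied voxel, from the resampled bundles
bundleTangentField <- function(spec, grid) {
  d <- gridDim(grid)
  tang <- matrix(0, nrow = prod(d), ncol = 3)
  for (nm in names(spec$bundles)) {
    cl <- resamplePolyline(spec$bundles[[nm]]$centerline, spec$voxel / 2)
    tg <- rbind(diff(cl), cl[nrow(cl), ] - cl[nrow(cl) - 1, ])
    tg <- tg / pmax(sqrt(rowSums(tg^2)), .Machine$double.eps)
    b <- makeBundle(spec, nm)
    for (s in b@streamlines) {
      idx <- pointToVoxel(grid, s)
      ok <- inGrid(grid, idx)
      if (!any(ok)) next
      lin <- voxelLinear(idx[ok, , drop = FALSE], d)
      tgs <- tg[seq_len(nrow(s))[ok], , drop = FALSE]
      # align signs before averaging (tangents are axial)
      ref <- tg[1, ]
      flip <- as.numeric(tgs %*% ref) < 0
      tgs[flip, ] <- -tgs[flip, ]
      tang[lin, ] <- tang[lin, ] + tgs
    }
  }
  nrm <- sqrt(rowSums(tang^2))
  ok <- nrm > 0
  tang[ok, ] <- tang[ok, ] / nrm[ok]
  tang
}

#' Single-tensor DWI phantom
#'
#' Per voxel, the signal is S = S0 exp(-b g' D g). Inside bundles the
#' tensor is cylindrically symmetric about the local streamline tangent
#' (eigenvalues `axialD`, `radialD`, `radialD`); elsewhere it is
#' isotropic with diffusivity `isotropicD`. Inside lesions the radial
#' diffusivity is scaled by the RD lesion multiplier. Rician noise is the
#' magnitude of a complex Gaussian perturbation; a Gaussian option exists
#' for analytic checks.
#'
#' @param spec a `PhantomSpec`.
#' @param gtab a [GradientTable-class].
#' @param grid the [VoxelGrid-class].
#' @param noiseSd noise sd in signal units (0 for noiseless).
#' @param noiseType "rician" or "gaussian".
#' @param lesionMask optional binary array enabling the lesion effect.
#' @return 4-D array (X, Y, Z, volumes).
#' @export
makeDwi <- function(spec, gtab, grid = phantomGrid(spec), noiseSd = 0,
                    noiseType = c("rician", "gaussian"),
                    lesionMask = NULL) {
  noiseType <- match.arg(noiseType)
  if (any(bValues(gtab) < 0)) stop("negative b-values")
  d <- gridDim(grid)
  nvol <- length(bValues(gtab))
  tis <- spec$tissue
  tang <- bundleTangentField(spec, grid)
  nvox <- prod(d)
  inBundle <- rowSums(tang^2) > 0
  rdMult <- rep(1, nvox)
  if (!is.null(lesionMask)) {
    f <- tis$lesionMultipliers[["RD"]]
    if (is.null(f) || is.na(f)) f <- 1
    rdMult[as.vector(lesionMask > 0)] <- f
  }
  g <- bVectors(gtab)
  bv <- bValues(gtab)
  # g' D g for axial tensor about tangent t:
  #   radial + (axial - radial) * (g . t)^2 ; isotropic voxels: isoD
  gt2 <- tcrossprod(tang, g)^2           # nvox x nvol
  adc <- matrix(tis$isotropicD, nrow = nvox, ncol = nvol)
  if (any(inBundle)) {
    rad <- tis$radialD * rdMult[inBundle]
    adc[inBundle, ] <- rad + (tis$axialD - rad) * gt2[inBundle, , drop = FALSE]
  }
  sig <- tis$s0 * exp(-sweep(adc, 2, bv, "*"))
  if (noiseSd > 0) {
    sig <- withSeed(spec$seed + 977L, {
      if (noiseType == "rician") {
        e1 <- matrix(stats::rnorm(length(sig), 0, noiseSd), nrow = nvox)
        e2 <- matrix(stats::rnorm(length(sig), 0, noiseSd), nrow = nvox)
        sqrt((sig + e1)^2 + e2^2)
      } else {
        sig + matrix(stats::rnorm(length(sig), 0, noiseSd), nrow = nvox)
      }
    })
  }
  array(sig, dim = c(d, nvol))
}

#' Generate a complete phantom subject
#'
#' @param spec a `PhantomSpec`.
#' @return list with `grid`, `bundles` (list of [Bundle-class]),
#'   `brainMask`, `lesionMask`, `maps` (named list of scalar arrays).
#' @export
makePhantomSubject <- function(spec) {
  grid <- phantomGrid(spec)
  brain <- makeBrainMask(spec, grid)
  lesion <- makeLesionMask(spec, grid, brainMask = brain)
  list(grid = grid,
       bundles = lapply(names(spec$bundles),
                        function(nm) makeBundle(spec, nm)),
       brainMask = brain, lesionMask = lesion,
       maps = makeScalarMaps(spec, lesion, grid))
}

#' Specify a synthetic cohort
#'
#' The group sizes default to the two-group design the package's
#' statistics stage is aimed at (24 impaired / 16 unimpaired); covariate
#' distributions default to cohort-typical estimated IQ and years of
#' education.
#'
#' @param nPerGroup named integer, subjects per group.
#' @param coupling list(task, measure, beta0, beta1) linking one named
#'   tract measure to one cognitive score.
#' @param betaIQ,betaEdu covariate coefficients in the score model.
#' @param iq,edu c(mean, sd) of the covariates.
#' @param residualSd sd of the Gaussian score residual.
#' @param seed integer seed.
#' @export
cohortSpec <- function(nPerGroup = c(impaired = 24L, unimpaired = 16L),
                       coupling = list(task = "task", measure = NULL,
                                       beta0 = 0, beta1 = 0),
                       betaIQ = 0, betaEdu = 0,
                       iq = c(110, 11), edu = c(15.2, 2.7),
                       residualSd = 1, seed = 1L) {
  stopifnot(all(nPerGroup >= 2L), residualSd >= 0)
  structure(list(nPerGroup = nPerGroup, coupling = coupling,
                 betaIQ = betaIQ, betaEdu = betaEdu, iq = iq, edu = edu,
                 residualSd = residualSd, seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Cohort table: cognitive scores linearly coupled to a tract measure
#'
#' score_i = beta0 + beta1 * measure_i + betaIQ * IQ_i + betaEdu * edu_i
#' + eps_i with eps ~ N(0, residualSd^2). Group labels are appended in
#' the order of `nPerGroup`, matching the measure-table rows.
#'
#' @param cspec a `CohortSpec`.
#' @param measureTable data.frame with a `subject` column and the coupled
#'   measure column; one row per subject, ordered as the groups.
#' @return data.frame with subject, group, iq, edu and the task score.
#' @export
makeCohort <- function(cspec, measureTable) {
  n <- sum(cspec$nPerGroup)
  if (nrow(measureTable) != n)
    stop("measure table must have one row per cohort subject")
  mname <- cspec$coupling$measure
  meas <- if (is.null(mname)) rep(0, n) else {
    if (!mname %in% names(measureTable))
      stop("coupling references missing column: ", mname)
    measureTable[[mname]]
  }
  withSeed(cspec$seed + 101L, {
    iq <- stats::rnorm(n, cspec$iq[1], cspec$iq[2])
    edu <- stats::rnorm(n, cspec$edu[1], cspec$edu[2])
    eps <- if (cspec$residualSd > 0)
      stats::rnorm(n, 0, cspec$residualSd) else rep(0, n)
    score <- cspec$coupling$beta0 + cspec$coupling$beta1 * meas +
      cspec$betaIQ * iq + cspec$betaEdu * edu + eps
    out <- data.frame(
      subject = measureTable$subject,
      group = rep(names(cspec$nPerGroup), cspec$nPerGroup),
      iq = iq, edu = edu, stringsAsFactors = FALSE)
    out[[cspec$coupling$task]] <- score
    out
  })
}

#' Synthetic subject-by-measure table with group structure
#'
#' Draws independent Gaussian measures per subject, with the impaired
#' group's mean shifted by `groupShift` (in sd units) for the named
#' measures. This is the stats-stage analogue of the imaging phantom:
#' group differences enter only through the shifted measures.
#'
#' @param nPerGroup named integer, subjects per group (first group is the
#'   shifted/"impaired" one).
#' @param measures character vector of measure column names.
#' @param groupShift named numeric, mean shift (sd units) applied to the
#'   first group.
#' @param seed integer seed.
#' @export
makeMeasureTable <- function(nPerGroup = c(impaired = 24L, unimpaired = 16L),
                             measures, groupShift = numeric(), seed = 1L) {
  n <- sum(nPerGroup)
  grp <- rep(names(nPerGroup), nPerGroup)
  withSeed(seed + 389L, {
    out <- data.frame(subject = sprintf("S%03d", seq_len(n)),
                      group = grp, stringsAsFactors = FALSE)
    for (m in measures) {
      x <- stats::rnorm(n)
      if (m %in% names(groupShift))
        x[grp == names(nPerGroup)[1]] <-
          x[grp == names(nPerGroup)[1]] + groupShift[[m]]
      out[[m]] <- x
    }
    out
  })
}
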