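#' Construct a gradient table
#'
#' @param bvals numeric b-values (s/mm^2), one per volume.
#' @param bvecs n-by-3 matrix of gradient directions.
#' @param b0Threshold b-values at or below this count as b = 0.
#' @return A [GradientTable-class].
#' @export
gradientTable <- function(bvals, bvecs, b0Threshold = 50) {
  bvecs <- as.matrix(bvecs)
  new("GradientTable", bvals = as.numeric(bvals), bvecs = bvecs,
      b0Threshold = b0Threshold)
}

#' @rdname gradientTable
#' @param gtab a GradientTable.
#' @export
bValues <- function(gtab) gtab@bvals

#' @rdname gradientTable
#' @export
bVectors <- function(gtab) gtab@bvecs

#' @rdname gradientTable
#' @export
shells <- function(gtab) {
  s <- round(gtab@bvals / 50) * 50
  s[gtab@bvals <= gtab@b0Threshold] <- 0
  s
}

# deterministic, roughly uniform directions on the unit sphere
fibonacciDirections <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Multi-shell gradient scheme matching the target acquisition
#'
#' Defaults reproduce the acquisition geometry the package targets:
#' 14 b = 0 volumes, 30 directions at b = 1200 s/mm^2 and 60 directions
#' at b = 2400 s/mm^2. Directions come from a Fibonacci sphere, so the
#' table is deterministic.
#'
#' @param nB0 number of b = 0 volumes.
#' @param shellB b-values of the diffusion-weighted shells.
#' @param shellN direction counts, one per shell.
#' @export
makeGradientTable <- function(nB0 = 14L, shellB = c(1200, 2400),
                              shellN = c(30L, 60L)) {
  stopifnot(length(shellB) == length(shellN))
  bv <- rep(0, nB0)
  gv <- matrix(0, nrow = nB0, ncol = 3)
  for (i in seq_along(shellB)) {
    bv <- c(bv, rep(shellB[i], shellN[i]))
    gv <- rbind(gv, fibonacciDirections(shellN[i]))
  }
  gradientTable(bv, gv)
}

tensorDesign <- function(bvals, bvecs) {
  g <- bvecs
  cbind(1,
        -bvals * g[, 1]^2, -bvals * g[, 2]^2, -bvals * g[, 3]^2,
        -2 * bvals * g[, 1] * g[, 2],
        -2 * bvals * g[, 1] * g[, 3],
        -2 * bvals * g[, 2] * g[, 3])
}

#' Fit diffusion tensors by iteratively weighted least squares
#'
#' Per masked voxel, an ordinary log-linear least-squares fit is followed
#' by reweighting passes with weights equal to the squared predicted
#' signal (the WLS scheme for log-transformed Rician-corrupted data),
#' stopping when the largest coefficient change falls below `tol`.
#' Non-positive signals are clamped to a small positive value with a
#' warning and flagged in the QC mask.
#'
#' @param dwi 4-D array (X, Y, Z, volumes).
#' @param gtab a [GradientTable-class].
#' @param mask logical/binary 3-D array of voxels to fit (default: all).
#' @param shell fit only this shell's volumes (plus b = 0); NULL fits all
#'   volumes.
#' @param maxIter reweighting passes after the initial OLS fit.
#' @param tol convergence tolerance on coefficient change.
#' @return A [TensorMap-class].
#' @export
fitTensorWLS <- function(dwi, gtab, mask = NULL, shell = 1200,
                         maxIter = 2L, tol = 1e-10) {
  d <- dim(dwi)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  mask <- array(mask > 0, dim = d)
  sh <- shells(gtab)
  use <- if (is.null(shell)) rep(TRUE, length(sh)) else
    sh == 0 | sh %in% shell
  if (sum(use) < 7L)
    stop("need at least 7 volumes (b = 0 plus fitted shell)")
  X <- tensorDesign(bValues(gtab)[use], bVectors(gtab)[use, , drop = FALSE])
  if (qr(X)$rank < ncol(X)) stop("rank-deficient tensor design")
  nvox <- prod(d)
  S <- matrix(dwi, nrow = nvox)[, use, drop = FALSE]
  vox <- which(as.vector(mask))
  S <- S[vox, , drop = FALSE]
  clampedVox <- rowSums(S <= 0) > 0
  if (any(clampedVox)) {
    warning(sum(clampedVox), " voxel(s) had non-positive signals; clamped")
    S[S <= 0] <- .Machine$double.eps
  }
  Y <- t(log(S))                           # nvol x nvox
  beta <- qr.solve(X, Y)                   # 7 x nvox, ordinary LS
  for (it in seq_len(maxIter)) {
    pred <- X %*% beta
    betaNew <- beta
    # weights = squared predicted signal, per voxel
    for (j in seq_len(ncol(beta))) {
      w <- exp(2 * pred[, j])
      XtW <- t(X * w)
      betaNew[, j] <- solve(XtW %*% X, XtW %*% Y[, j])
    }
    delta <- max(abs(betaNew - beta))
    beta <- betaNew
    if (delta < tol) break
  }
  coef <- array(0, dim = c(d, 6L))
  s0 <- array(NA_real_, dim = d)
  cl <- array(FALSE, dim = d)
  cm <- matrix(coef, nrow = nvox)
  cm[vox, ] <- t(beta[-1, , drop = FALSE])
  coef <- array(cm, dim = c(d, 6L))
  s0[vox] <- exp(beta[1, ])
  cl[vox] <- clampedVox
  new("TensorMap", coefficients = coef, s0 = s0, mask = mask, clamped = cl)
}

# analytic eigenvalues of symmetric 3x3 tensors, rows = voxels,
# columns of input: Dxx Dyy Dzz Dxy Dxz Dyz; output non-increasing
symEigenvalues <- function(m) {
  m <- matrix(m, ncol = 6L)
  p1 <- m[, 4]^2 + m[, 5]^2 + m[, 6]^2
  q <- (m[, 1] + m[, 2] + m[, 3]) / 3
  p2 <- (m[, 1] - q)^2 + (m[, 2] - q)^2 + (m[, 3] - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  l <- matrix(q, nrow = nrow(m), ncol = 3)
  nz <- p > .Machine$double.eps * pmax(abs(q), 1)
  if (any(nz)) {
    b11 <- (m[nz, 1] - q[nz]) / p[nz]
    b22 <- (m[nz, 2] - q[nz]) / p[nz]
    b33 <- (m[nz, 3] - q[nz]) / p[nz]
    b12 <- m[nz, 4] / p[nz]; b13 <- m[nz, 5] / p[nz]; b23 <- m[nz, 6] / p[nz]
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1 <- q[nz] + 2 * p[nz] * cos(phi)
    l3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    l[nz, ] <- cbind(l1, 3 * q[nz] - l1 - l3, l3)
  }
  l
}

#' Scalar maps from a tensor map: FA, MD and RD
#'
#' MD = (l1 + l2 + l3) / 3; RD = (l2 + l3) / 2 with eigenvalues in
#' non-increasing order; FA = sqrt(3/2) * ||l - MD|| / ||l||, defined as
#' 0 for the all-zero tensor. Negative eigenvalues are reported as-is and
#' flagged via the returned `negEig` mask.
#'
#' @param tmap a [TensorMap-class].
#' @return list of 3-D arrays `FA`, `MD`, `RD` and logical `negEig`.
#' @export
tensorScalars <- function(tmap) {
  d <- dim(tmap@coefficients)[1:3]
  m <- matrix(tmap@coefficients, ncol = 6L)
  lam <- symEigenvalues(m)
  md <- rowMeans(lam)
  rd <- (lam[, 2] + lam[, 3]) / 2
  num <- (lam[, 1] - md)^2 + (lam[, 2] - md)^2 + (lam[, 3] - md)^2
  den <- rowSums(lam^2)
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  msk <- as.vector(tmap@mask)
  fa[!msk] <- NA_real_; md[!msk] <- NA_real_; rd[!msk] <- NA_real_
  list(FA = array(fa, d), MD = array(md, d), RD = array(rd, d),
       negEig = array(msk & lam[, 3] < 0, d))
}

#' Predicted single-tensor signal (forward model)
#'
#' S = S0 exp(-b g' D g), the model [fitTensorWLS()] inverts.
#'
#' @param D symmetric 3x3 diffusion tensor (mm^2/s).
#' @param s0 signal at b = 0.
#' @param gtab a [GradientTable-class].
#' @export
tensorSignal <- function(D, s0, gtab) {
  g <- bVectors(gtab)
  adc <- rowSums((g %*% D) * g)
  s0 * exp(-bValues(gtab) * adc)
}
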