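## Real even-order spherical harmonics, RISH features, AFD and fODF peak
## counting. The basis is the real orthonormal basis (descoteaux07-style
## ordering: within each even l, m runs -l..l; sin terms for m < 0, cos
## terms for m > 0) and the convention string is carried on every
## coefficient map so RISH values from different sources stay comparable.

shIndexTable <- function(lmax) {
  ls <- seq(0L, lmax, by = 2L)
  do.call(rbind, lapply(ls, function(l)
    data.frame(l = l, m = seq(-l, l))))
}

#' Evaluate the real even-order spherical-harmonic basis
#'
#' @param dirs n-by-3 matrix of unit directions.
#' @param lmax even maximum order.
#' @return n-by-K matrix, K = (lmax+1)(lmax+2)/2.
#' @export
shBasis <- function(dirs, lmax) {
  if (lmax %% 2L != 0L) stop("'lmax' must be even")
  dirs <- as.matrix(dirs)
  nrm <- sqrt(rowSums(dirs^2))
  dirs <- dirs / nrm
  ct <- dirs[, 3]
  phi <- atan2(dirs[, 2], dirs[, 1])
  tab <- shIndexTable(lmax)
  B <- matrix(0, nrow = nrow(dirs), ncol = nrow(tab))
  for (l in unique(tab$l)) {
    # rows m = 0..l of the associated Legendre functions at cos(theta)
    P <- pracma::legendre(l, ct)
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in seq(-l, l)) {
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      col <- which(tab$l == l & tab$m == m)
      Pm <- P[am + 1, ]
      B[, col] <- if (m == 0) N * Pm
      else if (m > 0) sqrt(2) * N * Pm * cos(am * phi)
      else sqrt(2) * N * Pm * sin(am * phi)
    }
  }
  B
}

#' Least-squares spherical-harmonic fit of shell signal
#'
#' Projects per-voxel signals measured on `dirs` onto the real even
#' basis up to `lmax`. The direction count must be at least the
#' coefficient count, otherwise the system is under-determined.
#'
#' @param signal numeric vector (one voxel) or voxels-by-directions
#'   matrix.
#' @param dirs n-by-3 matrix of unit directions.
#' @param lmax even maximum order.
#' @param convention basis identifier recorded on the result.
#' @return A [ShCoeffMap-class].
#' @export
fitSH <- function(signal, dirs, lmax,
                  convention = "real-orthonormal-descoteaux07") {
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  k <- (lmax + 1) * (lmax + 2) / 2
  if (nrow(dirs) < k)
    stop("under-determined SH system: ", nrow(dirs), " directions for ",
         k, " coefficients")
  B <- shBasis(dirs, lmax)
  coef <- t(qr.solve(B, t(signal)))
  coef <- matrix(coef, ncol = k)
  new("ShCoeffMap", coefficients = coef, lmax = as.integer(lmax),
      convention = convention)
}

#' Synthesize signal from spherical-harmonic coefficients
#'
#' @param sh a [ShCoeffMap-class] or coefficient matrix.
#' @param dirs n-by-3 matrix of unit directions.
#' @param lmax required when `sh` is a bare matrix.
#' @return voxels-by-directions matrix.
#' @export
synthesizeSH <- function(sh, dirs, lmax = NULL) {
  if (is(sh, "ShCoeffMap")) {
    coef <- sh@coefficients
    lmax <- sh@lmax
  } else coef <- matrix(sh, ncol = (lmax + 1) * (lmax + 2) / 2)
  coef %*% t(shBasis(dirs, lmax))
}

#' Rotationally invariant spherical-harmonic (RISH) features
#'
#' RISH_l = sum_m c_{lm}^2: the signal energy at harmonic order l, which
#' is invariant to rotations of the gradient frame. Order 0 captures the
#' isotropic signal component, order 2 the deviation from isotropy.
#'
#' @param sh a [ShCoeffMap-class].
#' @param order even harmonic order (0 or 2 in typical use).
#' @return numeric vector, one value per voxel.
#' @export
rishFeatures <- function(sh, order) {
  if (order %% 2L != 0L) stop("RISH is defined for even orders only")
  if (order > sh@lmax) stop("order exceeds the fitted lmax")
  tab <- shIndexTable(sh@lmax)
  cols <- which(tab$l == order)
  rowSums(sh@coefficients[, cols, drop = FALSE]^2)
}

#' Total apparent fibre density from fODF coefficients
#'
#' AFD = integral of the fODF over the sphere = c00 * sqrt(4 pi), since
#' all higher-order basis functions integrate to zero.
#'
#' @param fodf a [ShCoeffMap-class] of fODF coefficients.
#' @return numeric vector, one value per voxel.
#' @export
afdTotal <- function(fodf) {
  if (ncol(fodf@coefficients) < 1L) stop("missing order-0 coefficient")
  fodf@coefficients[, 1] * sqrt(4 * pi)
}

# icosphere tessellation with vertex adjacency; nSub = 3 gives 642
# vertices (>= the 362 the peak finder requires)
icosphere <- function(nSub = 3L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(nSub)) {
    mid <- new.env()
    key <- function(a, b) paste(min(a, b), max(a, b))
    getMid <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mid[[k]])) return(mid[[k]])
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- getMid(a, b); bc <- getMid(b, cc); ca <- getMid(cc, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(cc, ca, bc)
      nf[4 * i, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  nb <- vector("list", nrow(v))
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
    nb[[a]] <- c(nb[[a]], b, cc)
    nb[[b]] <- c(nb[[b]], a, cc)
    nb[[cc]] <- c(nb[[cc]], a, b)
  }
  nb <- lapply(nb, unique)
  list(vertices = v, faces = f, neighbours = nb)
}

.sphereCache <- new.env(parent = emptyenv())

sphereTessellation <- function(nSub = 3L) {
  k <- as.character(nSub)
  if (is.null(.sphereCache[[k]])) .sphereCache[[k]] <- icosphere(nSub)
  .sphereCache[[k]]
}

#' Number of fibre orientations (NuFO) from fODF coefficients
#'
#' Counts local maxima of the fODF amplitude on a dense icosphere
#' tessellation, keeping peaks at or above `relThreshold` times the
#' global maximum, merging peaks separated by less than `minSeparation`
#' degrees and counting antipodal pairs once.
#'
#' @param fodf a [ShCoeffMap-class] of fODF coefficients.
#' @param relThreshold relative amplitude threshold in (0, 1).
#' @param minSeparation minimum peak separation (degrees).
#' @param nSub icosphere subdivision level (3 gives 642 vertices).
#' @return integer vector, one count per voxel.
#' @export
nufo <- function(fodf, relThreshold = 0.1, minSeparation = 25,
                 nSub = 3L) {
  if (relThreshold <= 0 || relThreshold >= 1)
    stop("'relThreshold' must be in (0, 1)")
  if (any(!is.finite(fodf@coefficients)))
    stop("non-finite fODF coefficients")
  tess <- sphereTessellation(nSub)
  if (nrow(tess$vertices) < 362L)
    stop("sphere tessellation must have >= 362 vertices")
  amp <- synthesizeSH(fodf, tess$vertices)
  cosSep <- cos(minSeparation * pi / 180)
  vapply(seq_len(nrow(amp)), function(i) {
    a <- amp[i, ]
    mx <- max(a)
    if (mx <= sqrt(.Machine$double.eps)) return(0L)
    isMax <- vapply(seq_along(a), function(j)
      a[j] >= max(a[tess$neighbours[[j]]]), NA)
    cand <- which(isMax & a >= relThreshold * mx & a > 0)
    cand <- cand[order(a[cand], decreasing = TRUE)]
    peaks <- integer()
    for (j in cand) {
      if (length(peaks)) {
        # antipodes merge: compare on |dot|
        d <- abs(tess$vertices[peaks, , drop = FALSE] %*% tess$vertices[j, ])
        if (any(d >= cosSep)) next
      }
      peaks <- c(peaks, j)
    }
    length(peaks)
  }, 0L)
}
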