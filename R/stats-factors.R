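#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' KMO = sum(r^2) / (sum(r^2) + sum(q^2)) over off-diagonal pairwise
#' correlations r and anti-image partial correlations q (computed from
#' the inverse correlation matrix). Values >= 0.7 are conventionally
#' adequate for principal component analysis.
#'
#' @param x numeric matrix or data.frame (subjects by variables).
#' @return value in [0, 1].
#' @export
kmo <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 3L) stop("KMO needs at least 3 variables")
  R <- stats::cor(x, use = "complete.obs")
  Ri <- tryCatch(solve(R), error = function(e)
    stop("singular correlation matrix; KMO undefined"))
  s <- diag(Ri)
  Q <- -Ri / sqrt(outer(s, s))
  off <- row(R) != col(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' Bartlett's test of sphericity
#'
#' chi^2 = -(n - 1 - (2p + 5) / 6) * ln det(R) with df = p (p - 1) / 2,
#' testing whether the correlation matrix is the identity.
#'
#' @param x numeric matrix or data.frame (subjects by variables).
#' @return list with `statistic`, `df`, `p.value`.
#' @export
bartlettSphericity <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("Bartlett's test needs more subjects than variables")
  R <- stats::cor(x)
  dR <- det(R)
  if (dR <= 0) stop("correlation matrix not positive definite")
  stat <- -(n - 1 - (2 * p + 5) / 6) * log(dR)
  df <- p * (p - 1) / 2
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Per-bundle PCA factor of microstructure metrics
#'
#' Metrics are z-scored and decomposed via the correlation matrix.
#' Components with eigenvalue > `eigenThreshold` are retained; loadings
#' below `suppress` in absolute value are masked for reporting (scores
#' always use the full loadings). The factor is the standardized
#' first-component score, sign-oriented so that `orientMetric` loads
#' positively (higher factor = healthier tissue when RISH0 is present).
#' Complete-case subjects enter the PCA; others get NA scores.
#'
#' KMO and Bartlett adequacy checks are computed and a warning recorded
#' when KMO < `kmoMin` or Bartlett p >= `bartlettAlpha`.
#'
#' @param x matrix/data.frame of per-subject metric means (subjects by
#'   metrics).
#' @param bundle bundle name stored on the model.
#' @param eigenThreshold retention threshold on eigenvalues.
#' @param suppress absolute loading below which loadings are masked.
#' @param orientMetric metric whose first-component loading is forced
#'   positive (default RISH0 when present, else the first metric).
#' @param kmoMin,bartlettAlpha adequacy thresholds.
#' @return A [FactorModel-class].
#' @export
buildFactor <- function(x, bundle = "bundle", eigenThreshold = 1,
                        suppress = 0.3, orientMetric = NULL,
                        kmoMin = 0.7, bartlettAlpha = 0.0005) {
  x <- as.data.frame(x)
  metrics <- names(x)
  xm <- as.matrix(x)
  cc <- stats::complete.cases(xm)
  if (sum(cc) < 3L) stop("fewer than 3 complete subjects")
  xc <- xm[cc, , drop = FALSE]
  sds <- apply(xc, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance metric(s): ",
         paste(metrics[sds == 0], collapse = ", "))
  z <- scale(xc)
  R <- stats::cor(xc)
  e <- eigen(R, symmetric = TRUE)
  keep <- which(e$values > eigenThreshold)
  if (length(keep) == 0L) keep <- 1L
  load <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), nrow = length(keep))
  rownames(load) <- metrics
  if (is.null(orientMetric))
    orientMetric <- if ("RISH0" %in% metrics) "RISH0" else metrics[1]
  for (j in seq_len(ncol(load)))
    if (load[orientMetric, j] < 0) {
      load[, j] <- -load[, j]
      e$vectors[, keep[j]] <- -e$vectors[, keep[j]]
    }
  if (length(keep) > 1L)
    warning("more than one component has eigenvalue > ", eigenThreshold,
            "; scores use component 1 only")
  sc <- rep(NA_real_, nrow(xm))
  raw <- z %*% e$vectors[, keep[1]]
  sc[cc] <- as.numeric(raw / stats::sd(raw))
  # degenerate (singular) correlation structures leave the adequacy
  # checks undefined rather than blocking the decomposition
  k <- tryCatch(kmo(xc), error = function(e) NA_real_)
  b <- tryCatch(bartlettSphericity(xc), error = function(e)
    list(statistic = NA_real_, df = ncol(xc) * (ncol(xc) - 1) / 2,
         p.value = NA_real_))
  if (is.na(k) || k < kmoMin)
    warning(sprintf("KMO = %.3f below %.2f for bundle %s", k, kmoMin,
                    bundle))
  if (is.na(b$p.value) || b$p.value >= bartlettAlpha)
    warning(sprintf("Bartlett p = %.3g not below %.4f for bundle %s",
                    b$p.value, bartlettAlpha, bundle))
  new("FactorModel", bundle = bundle, metrics = metrics,
      loadings = load, suppressed = abs(load) < suppress,
      eigenvalues = e$values, nRetained = length(keep),
      scores = sc, kmo = k, bartlett = b, nUsed = as.integer(sum(cc)))
}

#' @rdname buildFactor
#' @param model a FactorModel.
#' @export
factorScores <- function(model) model@scores

#' @rdname buildFactor
#' @param suppressed mask small loadings with NA.
#' @export
factorLoadings <- function(model, suppressed = FALSE) {
  l <- model@loadings
  if (suppressed) l[model@suppressed] <- NA_real_
  l
}
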