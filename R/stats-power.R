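#' Power of the two-sided two-sample t-test
#'
#' Equal group sizes n; power from the noncentral t distribution with
#' noncentrality d * sqrt(n / 2) and 2n - 2 degrees of freedom.
#'
#' @param n per-group sample size.
#' @param d standardized mean difference (Cohen's d).
#' @param alpha two-sided significance level.
#' @export
powerTtest <- function(n, d, alpha = 0.05) {
  df <- 2 * n - 2
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n / 2)
  stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
}

#' Minimum per-group n for a two-sample t-test
#'
#' Smallest integer n per group (equal groups) whose noncentral-t power
#' reaches the target.
#'
#' @param d standardized effect size (> 0).
#' @param alpha two-sided significance level.
#' @param power target power in (alpha, 1).
#' @param nMax search bound.
#' @return integer n per group (>= 2).
#' @export
sampleSizeTtest <- function(d, alpha = 0.05, power = 0.8, nMax = 1e5) {
  stopifnot(alpha > 0, alpha < 1, power > alpha, power < 1)
  if (d <= 0) stop("unreachable power: effect size must be positive")
  for (n in 2:nMax)
    if (powerTtest(n, d, alpha) >= power) return(as.integer(n))
  stop("no n up to ", nMax, " reaches the target power")
}

#' Power of the two-sided test of a Pearson correlation
#'
#' The critical value comes from the exact null distribution of r (via
#' the t transform); power integrates the exact sampling density
#' [dPearson()] outside the acceptance region — the "exact" method of
#' standard power software. A Fisher-z approximation is also available.
#'
#' @param n total sample size (>= 4).
#' @param rho population correlation under the alternative.
#' @param alpha two-sided significance level.
#' @param method "exact" or "fisher-z".
#' @export
powerCorrelation <- function(n, rho, alpha = 0.05,
                             method = c("exact", "fisher-z")) {
  method <- match.arg(method)
  if (method == "fisher-z") {
    se <- 1 / sqrt(n - 3)
    za <- stats::qnorm(1 - alpha / 2)
    z <- atanh(rho)
    return(stats::pnorm(-za - z / se) + stats::pnorm(-za + z / se))
  }
  tc <- stats::qt(1 - alpha / 2, n - 2)
  rc <- tc / sqrt(n - 2 + tc^2)
  acc <- stats::integrate(dPearson, -rc, rc, rho = rho, n = n,
                          rel.tol = 1e-9)$value
  1 - acc
}

#' Minimum total n for detecting a Pearson correlation
#'
#' Smallest integer n with power at or above target for the two-sided
#' test of rho = 0, using the exact sampling distribution of r. The
#' Fisher-z answer is returned alongside for reference.
#'
#' @param r population correlation under the alternative (0 < |r| < 1).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param nMax search bound.
#' @return list with `n` (exact method) and `nFisherZ`.
#' @export
sampleSizeCorrelation <- function(r, alpha = 0.05, power = 0.8,
                                  nMax = 1e5) {
  stopifnot(abs(r) > 0, abs(r) < 1, alpha > 0, alpha < 1,
            power > alpha, power < 1)
  n <- NA_integer_
  for (k in 4:nMax)
    if (powerCorrelation(k, r, alpha) >= power) { n <- as.integer(k); break }
  if (is.na(n)) stop("no n up to ", nMax, " reaches the target power")
  za <- stats::qnorm(1 - alpha / 2); zb <- stats::qnorm(power)
  nz <- as.integer(ceiling(((za + zb) / atanh(abs(r)))^2 + 3))
  list(n = n, nFisherZ = nz)
}
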