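#' ANCOVA with covariates, interaction check and assumption diagnostics
#'
#' Fits score ~ group + covariates by least squares and reports, for the
#' group term and each covariate, a Type-III-style F from full-versus-
#' reduced model comparison with partial eta^2 = SS_effect /
#' (SS_effect + SS_error). A separate slope-homogeneity model adds the
#' group x focal-covariate interaction and reports its F and p.
#' Levene's test (centre = mean) on the dependent variable across groups
#' and the maximum absolute correlation among covariates (collinearity
#' check, conventional bound 0.8) are included. Complete cases only.
#'
#' @param score numeric dependent variable.
#' @param group factor/character group labels (>= 2 groups, >= 2 each).
#' @param covariates data.frame of numeric covariates.
#' @param focal name of the focal covariate for the interaction check
#'   (default: last covariate column).
#' @param collinearityMax warn when covariate |r| reaches this bound.
#' @return list of class `lesionAncova`.
#' @export
ancova <- function(score, group, covariates, focal = NULL,
                   collinearityMax = 0.8) {
  covariates <- as.data.frame(covariates)
  dat <- data.frame(.score = score, .group = factor(group), covariates,
                    check.names = FALSE)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat$.group <- droplevels(dat$.group)
  if (nlevels(dat$.group) < 2L) stop("need at least 2 groups")
  if (any(table(dat$.group) < 2L)) stop("every group needs >= 2 members")
  covNames <- names(covariates)
  if (is.null(focal)) focal <- covNames[length(covNames)]
  n <- nrow(dat)
  if (n <= length(covNames) + nlevels(dat$.group) + 2L)
    stop("too few complete cases for the model")
  terms <- c(".group", covNames)
  fullForm <- stats::reformulate(terms, response = ".score")
  full <- stats::lm(fullForm, data = dat)
  if (any(is.na(stats::coef(full)))) stop("singular design")
  rssFull <- sum(stats::residuals(full)^2)
  dfRes <- full$df.residual
  effects <- lapply(terms, function(tm) {
    red <- stats::lm(stats::reformulate(setdiff(terms, tm),
                                        response = ".score",
                                        intercept = TRUE), data = dat)
    ss <- sum(stats::residuals(red)^2) - rssFull
    dfT <- red$df.residual - dfRes
    Fv <- (ss / dfT) / (rssFull / dfRes)
    list(term = tm, ss = ss, df = dfT,
         F = Fv, p = stats::pf(Fv, dfT, dfRes, lower.tail = FALSE),
         etaP = ss / (ss + rssFull))
  })
  names(effects) <- terms
  # slope homogeneity: group x focal covariate
  intForm <- stats::reformulate(c(terms, paste0(".group:`", focal, "`")),
                                response = ".score")
  intFit <- stats::lm(intForm, data = dat)
  rssInt <- sum(stats::residuals(intFit)^2)
  dfInt <- dfRes - intFit$df.residual
  Fint <- ((rssFull - rssInt) / dfInt) / (rssInt / intFit$df.residual)
  pInt <- stats::pf(Fint, dfInt, intFit$df.residual, lower.tail = FALSE)
  lev <- car::leveneTest(dat$.score, dat$.group, center = mean)
  # model R^2 as partial eta^2 of the whole model
  ssNull <- sum((dat$.score - mean(dat$.score))^2)
  r2 <- (ssNull - rssFull) / ssNull
  dfModel <- n - 1 - dfRes
  Fmodel <- ((ssNull - rssFull) / dfModel) / (rssFull / dfRes)
  coll <- if (length(covNames) >= 2L) {
    cm <- stats::cor(dat[covNames])
    max(abs(cm[row(cm) != col(cm)]))
  } else 0
  if (coll >= collinearityMax)
    warning(sprintf("covariate collinearity |r| = %.2f >= %.2f",
                    coll, collinearityMax))
  structure(list(
    n = n, terms = terms, focal = focal,
    group = effects[[".group"]], covariates = effects[covNames],
    interaction = list(F = Fint, df1 = dfInt, df2 = intFit$df.residual,
                       p = pInt),
    levene = list(F = lev$`F value`[1], df1 = lev$Df[1], df2 = lev$Df[2],
                  p = lev$`Pr(>F)`[1]),
    model = list(F = Fmodel, df1 = dfModel, df2 = dfRes, p = stats::pf(
      Fmodel, dfModel, dfRes, lower.tail = FALSE), etaP = r2),
    collinearity = coll, residualSS = rssFull, residualDf = dfRes),
    class = "lesionAncova")
}

#' @export
print.lesionAncova <- function(x, ...) {
  cat(sprintf("ANCOVA (n = %d): score ~ group + %s\n", x$n,
              paste(setdiff(x$terms, ".group"), collapse = " + ")))
  fmt <- function(e, nm) sprintf(
    "  %-14s F(%d,%d) = %.3f, p = %.4g, eta^2p = %.3f\n",
    nm, e$df, x$residualDf, e$F, e$p, e$etaP)
  cat(fmt(x$group, "group"))
  for (nm in names(x$covariates)) cat(fmt(x$covariates[[nm]], nm))
  cat(sprintf("  group x %s interaction: F(%d,%d) = %.3f, p = %.4g\n",
              x$focal, x$interaction$df1, x$interaction$df2,
              x$interaction$F, x$interaction$p))
  cat(sprintf("  Levene F(%d,%d) = %.3f, p = %.4g; max covariate |r| = %.2f\n",
              x$levene$df1, x$levene$df2, x$levene$F, x$levene$p,
              x$collinearity))
  cat(sprintf("  model: F(%d,%d) = %.3f, p = %.4g, eta^2p (R^2) = %.3f\n",
              x$model$df1, x$model$df2, x$model$F, x$model$p, x$model$etaP))
  invisible(x)
}

#' Two-group comparison with effect sizes
#'
#' Computes both the pooled-variance and Welch t-tests. The reported
#' statistic follows `policy`: "auto" chooses Welch when Levene's test
#' (centre = mean) rejects homogeneity at 0.05, pooled otherwise.
#' Cohen's d uses the pooled sd; Hedges g applies the small-sample
#' correction g = d * (1 - 3 / (4 (n1 + n2) - 9)).
#'
#' @param values numeric vector.
#' @param group two-level factor/character.
#' @param policy "auto", "pooled" or "welch".
#' @return list with pooled and Welch results, the reported t/df/p, and
#'   effect sizes d and g.
#' @export
groupTests <- function(values, group, policy = c("auto", "pooled", "welch")) {
  policy <- match.arg(policy)
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]; group <- factor(group[ok])
  group <- droplevels(group)
  if (nlevels(group) != 2L) stop("exactly 2 groups required")
  if (any(table(group) < 2L)) stop("every group needs >= 2 values")
  g1 <- values[group == levels(group)[1]]
  g2 <- values[group == levels(group)[2]]
  n1 <- length(g1); n2 <- length(g2)
  v1 <- stats::var(g1); v2 <- stats::var(g2)
  if (v1 == 0 && v2 == 0) {
    if (mean(g1) == mean(g2))
      return(list(t = 0, df = n1 + n2 - 2, p.value = 1, d = 0, g = 0,
                  policy = "pooled",
                  pooled = list(t = 0, df = n1 + n2 - 2, p.value = 1),
                  welch = list(t = 0, df = n1 + n2 - 2, p.value = 1),
                  levene.p = 1))
    stop("zero within-group variance in both groups")
  }
  pooled <- stats::t.test(g1, g2, var.equal = TRUE)
  welch <- stats::t.test(g1, g2, var.equal = FALSE)
  lev <- car::leveneTest(values, group, center = mean)
  levP <- lev$`Pr(>F)`[1]
  use <- switch(policy,
                pooled = pooled, welch = welch,
                auto = if (!is.na(levP) && levP < 0.05) welch else pooled)
  sdPool <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- (mean(g1) - mean(g2)) / sdPool
  g <- d * (1 - 3 / (4 * (n1 + n2) - 9))
  list(t = unname(use$statistic), df = unname(use$parameter),
       p.value = use$p.value, d = d, g = g,
       policy = if (policy != "auto") policy
                else if (!is.na(levP) && levP < 0.05) "welch" else "pooled",
       pooled = list(t = unname(pooled$statistic),
                     df = unname(pooled$parameter),
                     p.value = pooled$p.value),
       welch = list(t = unname(welch$statistic),
                    df = unname(welch$parameter),
                    p.value = welch$p.value),
       levene.p = levP)
}
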