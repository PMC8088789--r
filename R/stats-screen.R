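#' Bayes-factor screen followed by covariate modelling
#'
#' For each cognitive task, correlates every white-matter measure with
#' the task score (Bayesian Pearson correlation, complete cases per
#' pair). Measures whose null-over-alternative Bayes factor falls below
#' the threshold are passed to [ancova()] with the IQ and education
#' covariates alongside the measure; the report records, per surviving
#' measure, whether it is a unique predictor (covariate p < alpha) and
#' whether the group effect is attenuated (group p >= alpha). Screening
#' is the only multiplicity control applied. Tasks with an empty
#' surviving set are reported with "no further analyses".
#'
#' @param measureTable data.frame keyed by `subject` with measure
#'   columns.
#' @param cohortTable data.frame keyed by `subject` with `group`, the
#'   covariate columns and the task scores.
#' @param tasks character vector of task columns in `cohortTable`.
#' @param measures measure columns to screen (default: all numeric
#'   columns of `measureTable` except the key).
#' @param covariates covariate columns in `cohortTable`.
#' @param bfThreshold inclusion threshold on the null/alternative BF.
#' @param alpha significance level for covariate and group effects.
#' @param priorScale prior width for [pearsonBF()].
#' @return list of class `lesionScreen`.
#' @export
screenAndModel <- function(measureTable, cohortTable, tasks,
                           measures = NULL, covariates = c("iq", "edu"),
                           bfThreshold = 0.2, alpha = 0.05,
                           priorScale = 1) {
  if (!"subject" %in% names(measureTable) ||
      !"subject" %in% names(cohortTable))
    stop("both tables need a 'subject' key column")
  missingTasks <- setdiff(tasks, names(cohortTable))
  if (length(missingTasks))
    stop("task(s) absent from cohort table: ",
         paste(missingTasks, collapse = ", "))
  if (is.null(measures)) {
    num <- vapply(measureTable, is.numeric, NA)
    measures <- setdiff(names(measureTable)[num], "subject")
  }
  dat <- merge(cohortTable, measureTable, by = "subject",
               suffixes = c("", ".measure"))
  out <- list()
  for (task in tasks) {
    scr <- do.call(rbind, lapply(measures, function(m) {
      ok <- is.finite(dat[[task]]) & is.finite(dat[[m]])
      if (sum(ok) < 5L)
        return(data.frame(measure = m, r = NA, n = sum(ok), bf = NA,
                          p = NA, included = FALSE))
      b <- pearsonBF(dat[[task]][ok], dat[[m]][ok],
                     priorScale = priorScale, threshold = bfThreshold)
      data.frame(measure = m, r = b$r, n = b$n, bf = b$bf, p = b$p.value,
                 included = b$included)
    }))
    surviving <- scr$measure[scr$included]
    models <- list()
    for (m in surviving) {
      cv <- dat[, c(covariates, m), drop = FALSE]
      fit <- ancova(dat[[task]], dat$group, cv, focal = m)
      models[[m]] <- list(
        ancova = fit,
        uniquePredictor = fit$covariates[[m]]$p < alpha,
        groupAttenuated = fit$group$p >= alpha,
        interaction.p = fit$interaction$p)
    }
    out[[task]] <- list(
      correlations = scr, surviving = surviving, models = models,
      note = if (length(surviving) == 0L) "no further analyses" else NULL)
  }
  structure(list(tasks = out, bfThreshold = bfThreshold, alpha = alpha,
                 covariates = covariates,
                 multiplicity = "BF screen only; no further correction"),
            class = "lesionScreen")
}

#' @export
print.lesionScreen <- function(x, ...) {
  cat(sprintf("Bayes-factor screen (BF < %.2g) + ANCOVA (alpha = %.2g)\n",
              x$bfThreshold, x$alpha))
  for (task in names(x$tasks)) {
    t <- x$tasks[[task]]
    cat(sprintf("\nTask '%s': %d/%d measures survive screening\n", task,
                length(t$surviving), nrow(t$correlations)))
    if (!is.null(t$note)) {
      cat("  ", t$note, "\n", sep = "")
      next
    }
    for (m in t$surviving) {
      mod <- t$models[[m]]
      sc <- t$correlations[t$correlations$measure == m, ]
      cat(sprintf(
        "  %-28s r = %+.3f (BF = %.3f, p = %.3g); unique predictor: %s; group attenuated: %s\n",
        m, sc$r, sc$bf, sc$p,
        ifelse(mod$uniquePredictor, "yes", "no"),
        ifelse(mod$groupAttenuated, "yes", "no")))
    }
  }
  invisible(x)
}
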