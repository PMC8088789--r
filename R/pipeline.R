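#' Configuration for the end-to-end phantom pipeline
#'
#' Defines the study conditions for a simulated cohort: per-group lesion
#' severity (a multiplicative scale on the phantom's lesion radii, so the
#' impaired group carries more lesion burden), the measure-score
#' coupling, and the screening/modelling thresholds.
#'
#' @param outDir output directory.
#' @param seed master seed; per-subject streams derive from it.
#' @param spec base `PhantomSpec` (default [defaultPhantomSpec()]).
#' @param nPerGroup named subjects per group; first group is impaired.
#' @param lesionScale named per-group lesion radius scale.
#' @param lesionJitterSd log-normal sd of the per-subject radius jitter.
#' @param coupling list(task, measure, beta0, beta1) passed to the
#'   cohort generator; `measure` names a column of the averaged measure
#'   table.
#' @param residualSd cohort score residual sd.
#' @param bfThreshold,alpha screening and significance thresholds.
#' @param lesionometryMode sampling mode feeding the lesionometry factor
#'   ("full" or "portion"; both means are always in the measure table).
#' @param step streamline resampling step (mm); NULL = half voxel.
#' @export
pipelineConfig <- function(outDir, seed = 1L,
                           spec = defaultPhantomSpec(),
                           nPerGroup = c(impaired = 24L, unimpaired = 16L),
                           lesionScale = c(impaired = 1.25,
                                           unimpaired = 0.7),
                           lesionJitterSd = 0.15,
                           coupling = list(task = "task",
                                           measure = "isthmus.load",
                                           beta0 = 50, beta1 = -20),
                           residualSd = 2,
                           bfThreshold = 0.2, alpha = 0.05,
                           lesionometryMode = c("full", "portion"),
                           step = NULL) {
  stopifnot(bfThreshold >= 0, alpha > 0, alpha < 1)
  list(outDir = outDir, seed = as.integer(seed), spec = spec,
       nPerGroup = nPerGroup, lesionScale = lesionScale,
       lesionJitterSd = lesionJitterSd, coupling = coupling,
       residualSd = residualSd, bfThreshold = bfThreshold, alpha = alpha,
       lesionometryMode = match.arg(lesionometryMode), step = step)
}

factorColumns <- function(tbl, prefixTag) {
  nm <- names(tbl)
  hits <- grep(paste0("\\.", prefixTag, "\\."), nm, value = TRUE)
  split(hits, sub(paste0("\\.", prefixTag, "\\..*$"), "", hits))
}

#' Per-bundle factors appended to an averaged measure table
#'
#' Builds, per bundle, the whole-bundle Tractometry factor (from the
#' `.tract.` metric means) and the lesionometry factor (from the chosen
#' lesionometry mode's means), appending standardized factor-score
#' columns `<bundle>.tractometryFactor` / `<bundle>.lesionometryFactor`.
#'
#' @param tbl averaged measure table (one row per subject).
#' @param lesionometryMode "full" or "portion".
#' @return list with `table` (augmented) and `models` (FactorModel list).
#' @export
appendFactors <- function(tbl, lesionometryMode = "full") {
  lesTag <- if (lesionometryMode == "full") "lesioFull" else "lesioPortion"
  models <- list()
  for (kind in c("tract", lesTag)) {
    byBundle <- factorColumns(tbl, kind)
    out <- if (kind == "tract") "tractometryFactor" else "lesionometryFactor"
    for (b in names(byBundle)) {
      x <- tbl[, byBundle[[b]], drop = FALSE]
      names(x) <- sub(paste0("^", b, "\\.", kind, "\\."), "", names(x))
      fm <- tryCatch(
        withCallingHandlers(
          buildFactor(x, bundle = paste0(b, ".", out)),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) e)
      if (inherits(fm, "error")) {
        # too few subjects with lesioned streamlines (or degenerate
        # metrics): the factor is missing for everyone, never 0
        tbl[[paste0(b, ".", out)]] <- NA_real_
      } else {
        tbl[[paste0(b, ".", out)]] <- factorScores(fm)
        models[[paste0(b, ".", out)]] <- fm
      }
    }
  }
  list(table = tbl, models = models)
}

subjectPhantomSpec <- function(cfg, index, group) {
  scale <- cfg$lesionScale[[group]]
  sseed <- subjectSeed(cfg$seed, index)
  jit <- withSeed(sseed + 13L,
                  exp(stats::rnorm(length(cfg$spec$lesions), 0,
                                   cfg$lesionJitterSd)))
  spec <- cfg$spec
  spec$seed <- sseed
  for (i in seq_along(spec$lesions))
    spec$lesions[[i]]$radii <- spec$lesions[[i]]$radii * scale * jit[i]
  spec
}

#' Run the full phantom-to-report pipeline
#'
#' Generates a phantom subject per cohort member (lesion severity scaled
#' by group), computes the lesion-interaction measure table, averages
#' hemispheres, builds per-bundle Tractometry and lesionometry factors,
#' simulates the coupled cognitive score, runs the Bayes-factor screen
#' plus ANCOVA stage, and writes all artifacts to `outDir`:
#' measures_raw.csv, measures.csv, cohort.csv, report.json,
#' provenance.json and summary.txt. Deterministic for a fixed seed.
#'
#' @param cfg a [pipelineConfig()] list.
#' @param verbose log per-stage progress.
#' @return the screen report, invisibly (artifacts are on disk).
#' @export
runPipeline <- function(cfg, verbose = TRUE) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  n <- sum(cfg$nPerGroup)
  groups <- rep(names(cfg$nPerGroup), cfg$nPerGroup)
  grid <- phantomGrid(cfg$spec)
  step <- if (is.null(cfg$step)) defaultStep(grid) else cfg$step
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- subjectPhantomSpec(cfg, i, groups[i])
    subj <- makePhantomSubject(spec)
    rows[[i]] <- computeSubjectMeasures(
      subj$bundles, subj$lesionMask, subj$brainMask, subj$maps,
      subj$grid, step = step, subject = sprintf("S%03d", i))
    if (i == 1L || i == n)
      say("[phantom] subject %d/%d (%s): lesion load %.4f", i, n,
          groups[i], rows[[i]]$lesionLoad)
  }
  raw <- do.call(rbind, rows)
  utils::write.csv(raw, file.path(cfg$outDir, "measures_raw.csv"),
                   row.names = FALSE)
  avg <- averageHemispheres(raw)
  say("[measures] %d subjects x %d averaged columns", nrow(avg),
      ncol(avg))
  fac <- appendFactors(avg, cfg$lesionometryMode)
  tbl <- fac$table
  utils::write.csv(tbl, file.path(cfg$outDir, "measures.csv"),
                   row.names = FALSE)
  bundles <- unique(sub("\\..*$", "",
                        grep("\\.volume$", names(tbl), value = TRUE)))
  screenCols <- c("lesionLoad", "tractogramLoad",
                  paste0(rep(bundles, each = 4),
                         c(".volume", ".load", ".tractometryFactor",
                           ".lesionometryFactor")))
  screenCols <- intersect(screenCols, names(tbl))
  cspec <- cohortSpec(nPerGroup = cfg$nPerGroup, coupling = cfg$coupling,
                      residualSd = cfg$residualSd,
                      seed = subjectSeed(cfg$seed, 0L))
  cohort <- makeCohort(cspec, tbl)
  utils::write.csv(cohort, file.path(cfg$outDir, "cohort.csv"),
                   row.names = FALSE)
  say("[stats] screening %d measures against task '%s'",
      length(screenCols), cfg$coupling$task)
  report <- screenAndModel(tbl, cohort, tasks = cfg$coupling$task,
                           measures = screenCols,
                           bfThreshold = cfg$bfThreshold,
                           alpha = cfg$alpha)
  reportJson <- lapply(report$tasks, function(t) list(
    correlations = t$correlations,
    surviving = t$surviving,
    note = t$note,
    models = lapply(t$models, function(m) list(
      uniquePredictor = m$uniquePredictor,
      groupAttenuated = m$groupAttenuated,
      group = m$ancova$group[c("F", "df", "p", "etaP")],
      focalCovariate = m$ancova$covariates[[m$ancova$focal]][
        c("F", "df", "p", "etaP")],
      interaction.p = m$interaction.p))))
  jsonlite::write_json(reportJson, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  provenance <- list(
    seed = cfg$seed, nPerGroup = as.list(cfg$nPerGroup),
    lesionScale = as.list(cfg$lesionScale),
    lesionJitterSd = cfg$lesionJitterSd,
    coupling = cfg$coupling, residualSd = cfg$residualSd,
    bfThreshold = cfg$bfThreshold, alpha = cfg$alpha,
    lesionometryMode = cfg$lesionometryMode, resampleStep = step,
    grid = list(dim = gridDim(grid), voxel = voxelSize(grid)),
    nStreamlines = vapply(cfg$spec$bundles, function(b) b$n, 0),
    voxelizationDialect = "point membership after resampling to step",
    lesionIntersection = "voxel lattice of the lesion mask",
    headSizeDenominator = "brain-mask voxel volume",
    factorAdequacy = vapply(fac$models, function(m) m@kmo, 0))
  jsonlite::write_json(provenance,
                       file.path(cfg$outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(cfg$outDir, "summary.txt"))
  say("[done] artifacts in %s", cfg$outDir)
  invisible(report)
}
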