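test_that("the exact correlation density is a proper density", {
  for (n in c(10, 26, 40)) for (rho in c(0, 0.3, 0.52)) {
    expect_equal(integrate(dPearson, -1, 1, rho = rho, n = n,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
  }
  # Monte-Carlo check of the distribution's mass in a central interval
  set.seed(24)
  n <- 20; rho <- 0.5
  L <- chol(matrix(c(1, rho, rho, 1), 2))
  rs <- replicate(4000, {
    z <- matrix(rnorm(2 * n), n, 2) %*% L
    cor(z[, 1], z[, 2])
  })
  mass <- integrate(dPearson, 0.3, 0.7, rho = rho, n = n)$value
  expect_equal(mean(rs > 0.3 & rs < 0.7), mass, tolerance = 0.03)
})

test_that("pearsonBF reports r, orientation and inclusion correctly", {
  b <- pearsonBF(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_equal(b$r, 1)
  expect_true(b$included)   # perfect correlation: overwhelming evidence
  # exact null-ish data favour the null (BF > 1)
  pair <- exactCorPair(40, 0, seed = 25L)
  b0 <- pearsonBF(pair$x, pair$y)
  expect_equal(b0$r, 0, tolerance = 1e-10)
  expect_gt(b0$bf, 1)
  expect_false(b0$included)
  expect_error(pearsonBF(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearsonBF(1:4, 4:1), "at least 5")
})

test_that("the Bayes factor reproduces the reference correlation case", {
  # r = -0.448 at n = 39: published default-prior analyses give
  # BF(null/alt) ~ 0.14; prior sensitivity documented as +/- 50%
  pair <- exactCorPair(39, -0.448, seed = 26L)
  b <- pearsonBF(pair$x, pair$y)
  expect_equal(b$r, -0.448, tolerance = 1e-10)
  expect_gt(b$bf, 0.138 * 0.5)
  expect_lt(b$bf, 0.138 * 1.5)
  expect_true(b$included)
  expect_equal(b$p.value, 0.004, tolerance = 0.25)
})

test_that("BF is monotone in effect size and sample size", {
  bfAt <- function(n, r) pearsonBF(exactCorPair(n, r, seed = 27L)$x,
                                   exactCorPair(n, r, seed = 27L)$y)$bf
  bfs <- vapply(c(0.1, 0.3, 0.5, 0.7), function(r) bfAt(40, r), 0)
  expect_true(all(diff(bfs) < 0))               # decreasing in |r|
  bfn <- vapply(c(20, 40, 80), function(n) bfAt(n, 0.4), 0)
  expect_true(all(diff(bfn) < 0))               # decreasing in n
})

test_that("ANCOVA matches a direct residual-sum-of-squares oracle", {
  # n = 8 hand dataset
  score <- c(10, 12, 9, 14, 20, 22, 19, 24)
  group <- rep(c("a", "b"), each = 4)
  iq <- c(100, 105, 98, 110, 102, 108, 101, 112)
  m <- c(0.2, 0.3, 0.25, 0.4, 0.5, 0.55, 0.45, 0.6)
  fit <- ancova(score, group, data.frame(iq = iq, m = m), focal = "m")
  # oracle: explicit projections
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% score)
    sum((score - X %*% beta)^2)
  }
  gInd <- as.numeric(group == "b")
  Xfull <- cbind(1, gInd, iq, m)
  rssFull <- rss(Xfull)
  dfRes <- 8 - 4
  for (case in list(list(term = "group", X = cbind(1, iq, m),
                         get = fit$group),
                    list(term = "iq", X = cbind(1, gInd, m),
                         get = fit$covariates$iq),
                    list(term = "m", X = cbind(1, gInd, iq),
                         get = fit$covariates$m))) {
    ss <- rss(case$X) - rssFull
    Fo <- (ss / 1) / (rssFull / dfRes)
    expect_equal(case$get$F, Fo, tolerance = 1e-10)
    expect_equal(case$get$etaP, ss / (ss + rssFull), tolerance = 1e-10)
    expect_equal(case$get$p, pf(Fo, 1, dfRes, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # interaction oracle
  Xint <- cbind(Xfull, gInd * m)
  Fint <- ((rssFull - rss(Xint)) / 1) / (rss(Xint) / (8 - 5))
  expect_equal(fit$interaction$F, Fint, tolerance = 1e-10)
})

test_that("ANCOVA reduces to one-way ANOVA with orthogonal covariates", {
  set.seed(28)
  group <- rep(c("a", "b"), each = 12)
  gInd <- as.numeric(group == "b")
  raw <- cbind(rnorm(24), rnorm(24))
  # orthogonalize covariates against the group contrast and intercept
  cv <- apply(raw, 2, function(x) residuals(lm(x ~ gInd)))
  score <- 2 * gInd + rnorm(24)
  fit <- ancova(score, group, data.frame(c1 = cv[, 1], c2 = cv[, 2]),
                focal = "c2")
  aovF <- summary(aov(score ~ factor(group)))[[1]]$`F value`[1]
  # same SS decomposition for group; dfs differ, so compare SS directly
  ssGroup <- summary(aov(score ~ factor(group)))[[1]]$`Sum Sq`[1]
  expect_equal(fit$group$ss, ssGroup, tolerance = 1e-10)
  expect_error(ancova(score, rep("a", 24),
                      data.frame(c1 = cv[, 1])), "2 groups")
})

test_that("a mediating measure attenuates the group effect", {
  # group differs only through the measure; adjusting for it removes
  # the group difference, omitting it leaves a clear one
  mt <- makeMeasureTable(nPerGroup = c(impaired = 60L, unimpaired = 60L),
                         measures = "m", groupShift = c(m = -2),
                         seed = 31L)
  cs <- cohortSpec(nPerGroup = c(impaired = 60L, unimpaired = 60L),
                   coupling = list(task = "y", measure = "m",
                                   beta0 = 0, beta1 = 3),
                   residualSd = 1, seed = 31L)
  co <- makeCohort(cs, mt)
  with_ <- ancova(co$y, co$group,
                  data.frame(iq = co$iq, edu = co$edu, m = mt$m),
                  focal = "m")
  without <- ancova(co$y, co$group, data.frame(iq = co$iq, edu = co$edu),
                    focal = "edu")
  expect_gt(with_$group$p, 0.05)
  expect_lt(without$group$p, 0.05)
  expect_lt(with_$covariates$m$p, 0.05)
})

test_that("group tests match textbook formulas", {
  # identical groups: t = 0, d = 0
  same <- groupTests(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  # constructed means 0 vs 1.2, common sd 1, n = 10/16
  g1 <- exactMoments(10, 1.2, 1, seed = 32L)
  g2 <- exactMoments(16, 0, 1, seed = 33L)
  gt <- groupTests(c(g1, g2), rep(c("a", "b"), c(10, 16)))
  expect_equal(gt$d, 1.2, tolerance = 1e-10)
  expect_equal(gt$g, 1.2 * (1 - 3 / (4 * 26 - 9)), tolerance = 1e-10)
  expect_equal(round(gt$g, 1), 1.2)
  # random samples against explicit formulas
  set.seed(34)
  a <- rnorm(14, 1, 2); b <- rnorm(9, 0, 1)
  gt2 <- groupTests(c(a, b), rep(c("a", "b"), c(14, 9)), policy = "pooled")
  sp <- sqrt((13 * var(a) + 8 * var(b)) / 21)
  tPool <- (mean(a) - mean(b)) / (sp * sqrt(1 / 14 + 1 / 9))
  expect_equal(gt2$t, tPool, tolerance = 1e-10)
  expect_equal(gt2$d, (mean(a) - mean(b)) / sp, tolerance = 1e-10)
  tWelch <- (mean(a) - mean(b)) / sqrt(var(a) / 14 + var(b) / 9)
  expect_equal(gt2$welch$t, tWelch, tolerance = 1e-10)
  dfWelch <- (var(a) / 14 + var(b) / 9)^2 /
    ((var(a) / 14)^2 / 13 + (var(b) / 9)^2 / 8)
  expect_equal(gt2$welch$df, dfWelch, tolerance = 1e-10)
  expect_error(groupTests(rep(c(0, 1), c(3, 3)), rep(c("a", "b"), each = 3)),
               "zero within-group variance")
})

test_that("t-test sample size inverts its own power function", {
  expect_identical(sampleSizeTtest(1.2), 12L)
  expect_identical(sampleSizeTtest(10), 2L)   # boundary: minimum n
  expect_error(sampleSizeTtest(0), "unreachable")
  for (d in c(0.5, 0.8, 1.2)) {
    n <- sampleSizeTtest(d)
    expect_gte(powerTtest(n, d), 0.8)
    if (n > 2) expect_lt(powerTtest(n - 1, d), 0.8)
  }
  # agreement with the built-in noncentral-t power routine
  expect_equal(powerTtest(12, 1.2),
               power.t.test(n = 12, delta = 1.2, sd = 1)$power,
               tolerance = 1e-5)
})

test_that("correlation sample size inverts its own power function", {
  res <- sampleSizeCorrelation(0.52)
  expect_identical(res$n, 26L)
  expect_identical(res$nFisherZ, 27L)
  expect_lte(sampleSizeCorrelation(0.9999)$n, 5L)   # boundary
  for (r in c(0.3, 0.52)) {
    n <- sampleSizeCorrelation(r)$n
    expect_gte(powerCorrelation(n, r), 0.8)
    expect_lt(powerCorrelation(n - 1, r), 0.8)
  }
  # Fisher-z approximation stays close to the exact method
  expect_equal(powerCorrelation(26, 0.52, method = "fisher-z"),
               powerCorrelation(26, 0.52), tolerance = 0.05)
  expect_error(sampleSizeCorrelation(0), "")
})

test_that("screening passes survivors to modelling and reports empties", {
  mt <- makeMeasureTable(nPerGroup = c(impaired = 24L, unimpaired = 16L),
                         measures = c("hit", "miss1", "miss2"),
                         groupShift = c(hit = -1.5), seed = 36L)
  cs <- cohortSpec(coupling = list(task = "y", measure = "hit",
                                   beta0 = 10, beta1 = 4),
                   residualSd = 1, seed = 36L)
  co <- makeCohort(cs, mt)
  rep <- screenAndModel(mt, co, tasks = "y")
  expect_true("hit" %in% rep$tasks$y$surviving)
  expect_true(rep$tasks$y$models$hit$uniquePredictor)
  # BF threshold 0 can never include anything
  rep0 <- screenAndModel(mt, co, tasks = "y", bfThreshold = 0)
  expect_length(rep0$tasks$y$surviving, 0L)
  expect_identical(rep0$tasks$y$note, "no further analyses")
  expect_error(screenAndModel(mt, co, tasks = "absent"), "absent")
  # missing data are handled per-analysis complete-case
  co2 <- co; co2$y[1] <- NA
  rep2 <- screenAndModel(mt, co2, tasks = "y")
  expect_identical(unique(rep2$tasks$y$correlations$n), 39L)
})
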