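test_that("mixture log-likelihood matches a direct-summation oracle", {
  set.seed(10)
  n <- 40
  y <- rnorm(n)
  fam <- sample(1:4, n, replace = TRUE)
  priors <- matrix(rexp(4 * n), n, 4)
  priors <- priors / rowSums(priors)
  means <- effectsToMeans(setNames(rnorm(16, sd = 0.5), iqtlEffectNames()))
  ll <- mixtureLogLik(y, fam, priors, means, sigma2 = 1.3)
  expect_equal(ll, bruteLogLik(y, fam, priors, means, 1.3), tolerance = 1e-10)
  expect_error(mixtureLogLik(y, fam, priors, means, sigma2 = 0), "positive")
})

test_that("degenerate and collapsed mixtures reduce to closed forms", {
  # one individual with a point prior sitting exactly on its cell mean
  means <- effectsToMeans(effectVector(mu = 2))
  ll <- mixtureLogLik(2, 1L, matrix(c(1, 0, 0, 0), 1), means, sigma2 = 0.5)
  expect_equal(ll, dnorm(0, 0, sqrt(0.5), log = TRUE))
  # equal means: the mixture collapses to a single normal for any priors
  set.seed(11)
  y <- rnorm(30); fam <- rep(1:4, length.out = 30)
  priors <- matrix(0.25, 30, 4)
  expect_equal(mixtureLogLik(y, fam, priors, matrix(1.5, 4, 4), 2),
               sum(dnorm(y, 1.5, sqrt(2), log = TRUE)))
})

test_that("EM with degenerate priors equals per-cell means and pooled MLE variance", {
  set.seed(12)
  n <- 400
  fam <- sample(1:4, n, replace = TRUE)
  config <- sample(1:4, n, replace = TRUE)
  means <- effectsToMeans(scenarioEffects("I"))
  y <- means[cbind(fam, config)] + rnorm(n, sd = 0.5)
  priors <- matrix(0, n, 4)
  priors[cbind(seq_len(n), config)] <- 1
  fit <- emFit(priors = priors, phenotype = y, family = fam,
               control = quickControl())
  # closed form: weighted least squares with known cells = per-cell averages
  cellMeans <- matrix(NA_real_, 4, 4)
  for (t in 1:4) for (k in 1:4)
    cellMeans[t, k] <- mean(y[fam == t & config == k])
  expect_equal(effectsToMeans(effectEstimates(fit)), cellMeans,
               tolerance = 1e-6, ignore_attr = TRUE)
  resid <- y - cellMeans[cbind(fam, config)]
  expect_equal(residualVariance(fit), mean(resid^2), tolerance = 1e-6)
  expect_equal(meansToEffects(cellMeans), effectEstimates(fit),
               tolerance = 1e-6)
})

test_that("fully constrained fit equals the single-normal MLE", {
  set.seed(13)
  y <- rnorm(120, mean = 3, sd = 2)
  fam <- rep(1:4, each = 30)
  priors <- matrix(0.25, 120, 4)
  fit <- emFit(priors = priors, phenotype = y, family = fam,
               constraints = testConstraints("existence"),
               control = quickControl())
  expect_equal(unname(effectEstimates(fit)["mu"]), mean(y), tolerance = 1e-7)
  expect_equal(residualVariance(fit), mean((y - mean(y))^2),
               tolerance = 1e-7)
  expect_equal(fit@logLik, iqtlmap:::singleNormalLogLik(y), tolerance = 1e-7)
})

test_that("EM log-likelihood is monotone non-decreasing on every fit", {
  set.seed(14)
  for (rep in 1:5) {
    cr <- quickCross(n = 40, seed = 100 + rep)
    pri <- positionPriors(cr, "1", 35)
    cd <- SummarizedExperiment::colData(cr)
    fit <- emFit(priors = pri, phenotype = cd$phenotype, family = cd$family,
                 control = emControl(nRestarts = 0L))
    expect_true(all(diff(fit@logLikTrace) > -1e-7 * (1 + abs(fit@logLik))))
    expect_true(fit@converged)
  }
})

test_that("constrained log-likelihood never exceeds the unconstrained one", {
  cr <- quickCross(n = 80, seed = 5)
  pri <- positionPriors(cr, "1", 35)
  cd <- SummarizedExperiment::colData(cr)
  full <- emFit(priors = pri, phenotype = cd$phenotype, family = cd$family)
  warm <- list(means = drop(designMatrix() %*% effectEstimates(full)),
               sigma2 = residualVariance(full))
  for (tt in 1:6) {
    nul <- emFit(priors = pri, phenotype = cd$phenotype, family = cd$family,
                 constraints = testConstraints(tt), start = warm)
    expect_lte(nul@logLik, full@logLik + 1e-6)
    expect_true(all(effectEstimates(nul)[testConstraints(tt)] == 0))
  }
})

test_that("constraint sets carry the documented sizes and df bookkeeping", {
  sizes <- vapply(1:6, function(t) length(testConstraints(t)), integer(1))
  expect_equal(sizes, c(13L, 3L, 10L, 3L, 3L, 3L))
  expect_false("mu" %in% unlist(lapply(1:6, testConstraints)))
  expect_equal(testConstraints(6),
               c("i1mp_a", "i1mp_d", "i1mp_i2"))
  expect_equal(testConstraints("i1m"), "i1m")
  expect_error(testConstraints(7), "1..6")
  expect_error(testConstraints("nope"), "unknown")
})

test_that("likelihood ratio test computes df, clips at zero, rejects non-nesting", {
  cr <- quickCross(n = 60, seed = 6)
  pri <- positionPriors(cr, "1", 35)
  cd <- SummarizedExperiment::colData(cr)
  full <- emFit(priors = pri, phenotype = cd$phenotype, family = cd$family,
                control = quickControl())
  self <- likelihoodRatioTest(full, full, name = "self")
  expect_equal(self$lr, 0)
  expect_equal(self$pvalue, 1)
  for (tt in c(1, 2, 3, 4)) {
    nul <- emFit(priors = pri, phenotype = cd$phenotype, family = cd$family,
                 constraints = testConstraints(tt), control = quickControl())
    res <- likelihoodRatioTest(nul, full)
    expect_equal(res$df, length(testConstraints(tt)))
    expect_gte(res$lr, 0)
    expect_true(res$pvalue >= 0 && res$pvalue <= 1)
    # reversed nesting is an error
    expect_error(likelihoodRatioTest(full, nul), "nested")
  }
})

test_that("emFit rejects malformed inputs", {
  y <- rnorm(10); fam <- rep(1:2, 5)
  pri <- matrix(0.25, 10, 4)
  expect_error(emFit(priors = pri, phenotype = y, family = fam,
                     constraints = "mu"), "mean")
  expect_error(emFit(priors = pri, phenotype = y, family = fam,
                     constraints = "zap"), "unknown")
  expect_error(emFit(priors = matrix(0.25, 5, 4), phenotype = y,
                     family = fam), "aligned")
})
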