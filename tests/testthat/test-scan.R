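# Helper to wrap a hand-built LR profile into an IQTLScan for peak calling.
profileScan <- function(chromosome, position, lr) {
  new("IQTLScan",
      profile = data.frame(chromosome = chromosome, position = position,
                           lr = lr),
      step = 2, threshold = NA_real_, alpha = NA_real_,
      peaks = data.frame())
}

test_that("position priors locate the interval and honour the map", {
  cr <- quickCross(n = 30, seed = 21)
  p <- positionPriors(cr, "1", 35)
  expect_equal(dim(p), c(ncol(cr), 4L))
  expect_equal(unname(rowSums(p)), rep(1, ncol(cr)), tolerance = 1e-12)
  expect_error(positionPriors(cr, "99", 10), "not on the map")
  expect_error(positionPriors(cr, "1", 500), "span")
  # at a marker position the left recombination fraction is zero: with
  # phase-known transmission the maternal allele determines the QTL allele
  p0 <- positionPriors(cr, "1", 0)
  ma <- SummarizedExperiment::assay(cr, "maternal")[1, ]
  expect_true(all(abs((p0[, "AA"] + p0[, "Aa"]) - (ma == 1L)) < 1e-12))
})

test_that("scan profile covers markers plus step grid and LR is non-negative", {
  cr <- quickCross(n = 50, seed = 22)
  sc <- scanGenome(cr, step = 10, control = quickControl())
  prof <- scanProfile(sc)
  pos <- SummarizedExperiment::rowData(cr)$position
  expect_true(all(pos %in% prof$position))
  expect_true(all(prof$lr >= 0))
  expect_true(all(diff(prof$position) > 0))
  expect_error(scanGenome(cr, step = 0), "positive")
})

test_that("existence LR is invariant to phenotype shift and scale", {
  cr <- quickCross(n = 50, seed = 23)
  sc1 <- scanGenome(cr, step = 25, control = quickControl())
  shifted <- cr
  SummarizedExperiment::colData(shifted)$phenotype <-
    3 * SummarizedExperiment::colData(cr)$phenotype + 100
  sc2 <- scanGenome(shifted, step = 25, control = quickControl())
  expect_equal(scanProfile(sc1)$lr, scanProfile(sc2)$lr, tolerance = 1e-4)
})

test_that("uninformative genotypes reduce the scan to family means only", {
  cr <- quickCross(n = 40, seed = 24)
  blank <- cr
  for (a in SummarizedExperiment::assayNames(blank))
    SummarizedExperiment::assay(blank, a)[] <- NA_integer_
  cd <- SummarizedExperiment::colData(blank)
  pri <- positionPriors(blank, "1", 35)
  expect_true(all(pri == 0.25))
  fit <- emFit(priors = pri, phenotype = cd$phenotype, family = cd$family,
               control = quickControl())
  # with uniform priors within-family heterozygote labels are exchangeable;
  # the attainable likelihood is bounded below by the family-means model
  fam <- cd$family
  famMeans <- ave(cd$phenotype, fam)
  s2 <- mean((cd$phenotype - famMeans)^2)
  llFam <- sum(dnorm(cd$phenotype, famMeans, sqrt(s2), log = TRUE))
  expect_gte(fit@logLik, llFam - 1e-6)
})

test_that("peak calling applies threshold, separation and valley rules", {
  # monotone profile above threshold: one peak at the maximum
  sc <- profileScan("1", seq(0, 100, 10), seq(1, 11))
  called <- callPeaks(sc, threshold = 0.5, minSeparation = 30)
  expect_equal(nrow(called@peaks), 1L)
  expect_equal(called@peaks$position, 100)
  # two bumps 100 cM apart with a sub-threshold valley: two peaks
  pos <- seq(0, 140, 10)
  lr <- c(2, 8, 12, 8, 2, 0.5, 0.5, 0.5, 0.5, 0.5, 2, 8, 14, 8, 2)
  called <- callPeaks(profileScan("1", pos, lr), threshold = 5,
                      minSeparation = 30)
  expect_equal(called@peaks$position, c(20, 120))
  # same two bumps 5 cM apart: one peak (the higher)
  pos2 <- c(0, 2.5, 5, 7.5, 10)
  lr2 <- c(8, 3, 4, 9, 2)
  called <- callPeaks(profileScan("1", pos2, lr2), threshold = 5,
                      minSeparation = 30)
  expect_equal(nrow(called@peaks), 1L)
  expect_equal(called@peaks$position, 7.5)
  # tie broken to the left
  called <- callPeaks(profileScan("1", c(0, 10, 20), c(7, 7, 3)),
                      threshold = 5, minSeparation = 30)
  expect_equal(called@peaks$position, 0)
  # nothing above threshold: empty, and calling is idempotent
  called <- callPeaks(profileScan("1", c(0, 10), c(1, 2)), threshold = 5)
  expect_equal(nrow(called@peaks), 0L)
  twice <- callPeaks(callPeaks(sc, 0.5), 0.5)
  expect_equal(twice@peaks, callPeaks(sc, 0.5)@peaks)
})

test_that("permutation threshold is deterministic and alpha=1 gives the minimum", {
  cr <- quickCross(n = 40, seed = 25)
  ctl <- quickControl()
  thr1 <- permutationThreshold(cr, step = 50, nPerm = 12, alpha = 0.05,
                               seed = 9, control = ctl)
  thr2 <- permutationThreshold(cr, step = 50, nPerm = 12, alpha = 0.05,
                               seed = 9, control = ctl)
  expect_identical(thr1, thr2)
  maxima <- attr(thr1, "maxima")
  thrMin <- permutationThreshold(cr, step = 50, nPerm = 12, alpha = 1,
                                 seed = 9, control = ctl)
  expect_equal(as.numeric(thrMin), min(attr(thrMin, "maxima")))
  expect_error(permutationThreshold(cr, nPerm = 5), "at least 10")
})

test_that("the scan localises a strong simulated QTL", {
  set.seed(26)
  hits <- 0L
  for (r in 1:5) {
    cr <- simulateCross(scenarioEffects("I"), n = 150, h2 = 0.4)
    sc <- scanGenome(cr, step = 5, control = quickControl(),
                     chromosomes = "1")
    prof <- scanProfile(sc)
    peak <- prof$position[which.max(prof$lr)]
    hits <- hits + (abs(peak - 35) <= 10)
  }
  expect_gte(hits, 4L)
})

test_that("the imprinting test suite reuses one full fit and reports all levels", {
  cr <- quickCross(n = 60, seed = 27)
  res <- imprintingTests(cr, "1", 35, tests = 1:6, singleEffects = TRUE,
                         control = quickControl())
  expect_s4_class(res$fit, "IQTLFit")
  expect_equal(nrow(res$tests), 6L + 15L)
  expect_equal(res$tests$df[1:6], c(13L, 3L, 10L, 3L, 3L, 3L))
  expect_true(all(res$tests$df[7:21] == 1L))
  expect_true(all(res$tests$lr >= 0))
})
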