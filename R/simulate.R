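#' The benchmark simulation map
#'
#' A single linkage group of `length` cM carrying `nMarkers` evenly spaced
#' markers (defaults: 10 markers over 200 cM, so markers every ~22.2 cM);
#' the standard testbed for the power and estimation studies, where the iQTL
#' sits 35 cM from the first marker.
#'
#' @param nMarkers Number of evenly spaced markers.
#' @param length Linkage-group length in cM.
#' @param chromosome Chromosome label.
#' @return A map `data.frame` (`marker`, `chromosome`, `position_cM`).
#' @export
simulationMap <- function(nMarkers = 10L, length = 200, chromosome = "1") {
  data.frame(marker = paste0("M", seq_len(nMarkers)),
             chromosome = chromosome,
             position_cM = seq(0, length, length.out = nMarkers))
}

#' Benchmark effect scenarios
#'
#' The three generating effect vectors of the power study:
#' \describe{
#'   \item{I}{all 15 effects present: F1 imprinting `i1m = i1p = 0.15`,
#'     `i1mp = 0.1`; F2 effects `a = 0.3`, `d = 0.6`, `i2 = 0.2`; all nine
#'     cross-generation interactions `0.04`.}
#'   \item{II}{Scenario I without F2-expressed imprinting: `i2` and the nine
#'     interactions set to zero (the nulls of Tests 3-6 hold).}
#'   \item{III}{no imprinting at all: only `a = 0.3`, `d = 0.6` (the nulls of
#'     all six tests hold; used for type-I error).}
#' }
#'
#' @param scenario `"I"`, `"II"` or `"III"`.
#' @return A named effect vector (see [effectVector()]).
#' @export
scenarioEffects <- function(scenario = c("I", "II", "III")) {
  scenario <- match.arg(scenario)
  base <- effectVector(i1m = 0.15, i1p = 0.15, i1mp = 0.1,
                       a = 0.3, d = 0.6)
  inter <- iqtlEffectNames()[8:16]
  switch(scenario,
         I = { base["i2"] <- 0.2; base[inter] <- 0.04; base },
         II = base,
         III = effectVector(a = 0.3, d = 0.6))
}

#' Residual variance for a target heritability
#'
#' Scales the residual noise so that the broad-sense heritability —
#' [geneticVariance()] over the 16 design cells divided by total variance —
#' equals `h2`: \eqn{\sigma^2 = V_G (1 - h^2)/h^2}.
#'
#' @param effects A 16-effect vector.
#' @param h2 Heritability in (0, 1).
#' @return Residual variance in squared phenotype units.
#' @examples
#' residualVarianceForHeritability(scenarioEffects("I"), 0.4)
#' @export
residualVarianceForHeritability <- function(effects, h2) {
  if (h2 <= 0 || h2 >= 1) stop("'h2' must lie strictly between 0 and 1")
  vg <- geneticVariance(effects)
  if (vg == 0) stop("genetic variance is zero; heritability is undefined")
  vg * (1 - h2) / h2
}

# Simulate one parental gamete per individual along one chromosome:
# origins matrix (n x L), 0 = line 1 (marker allele 1 / QTL allele A).
simulateGametes <- function(n, positions) {
  L <- length(positions)
  orig <- matrix(0L, n, L)
  orig[, 1L] <- as.integer(stats::runif(n) < 0.5)
  if (L > 1L) {
    r <- haldaneR(diff(positions))
    for (j in 2:L) {
      rec <- stats::runif(n) < r[j - 1L]
      orig[, j] <- ifelse(rec, 1L - orig[, j - 1L], orig[, j - 1L])
    }
  }
  orig
}

#' Simulate a reciprocal F2 cross segregating one iQTL
#'
#' @description
#' Draws, for each individual of each of the four F2 families, a maternal and
#' a paternal F1 gamete by sequential per-interval crossover sampling under
#' the Haldane model (no interference) along each chromosome, with the QTL
#' inserted at its position; the ordered QTL configuration (maternal allele
#' first) determines the genotypic value via [effectsToMeans()] for the
#' family's mating type, and the phenotype adds normal residual noise.
#'
#' The parental origin of every transmitted marker allele is recorded in the
#' `"maternal"` and `"paternal"` assays — the traceable transmission that the
#' two-stage reciprocal pedigree provides — so [positionPriors()] can form
#' origin-informative mixture weights that distinguish the Aa and aA
#' configurations.  The hidden truth (configurations, QTL location, effects,
#' residual variance) is kept in `metadata(cross)$truth` for oracle checks.
#'
#' @param effects Generating 16-effect vector (see [scenarioEffects()]).
#' @param n Per-family sample size: a scalar or a length-4 vector.
#' @param h2 Heritability; the residual variance is derived via
#'   [residualVarianceForHeritability()].  Alternatively give `sigma2`.
#' @param sigma2 Residual variance, overriding `h2`.
#' @param map Linkage map `data.frame` (default [simulationMap()]).
#' @param qtlChromosome,qtlPosition Location of the iQTL (default: 35 cM on
#'   the benchmark group).
#' @param seed Optional integer seed; with a fixed seed the simulated cross
#'   is bit-identical across runs.
#' @return A [ReciprocalCross-class] object.
#' @export
simulateCross <- function(effects, n = 300L, h2 = NULL, sigma2 = NULL,
                          map = simulationMap(), qtlChromosome = "1",
                          qtlPosition = 35, seed = NULL) {
  effects <- asEffectVector(effects)
  map <- validateMap(map)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma2)) {
    if (is.null(h2)) stop("give either 'h2' or 'sigma2'")
    sigma2 <- residualVarianceForHeritability(effects, h2)
  }
  if (!qtlChromosome %in% map$chromosome)
    stop("QTL chromosome not on the map")
  qpos <- map$position_cM[map$chromosome == qtlChromosome]
  if (qtlPosition < min(qpos) || qtlPosition > max(qpos))
    stop("QTL position outside the marker span of its chromosome")
  n <- rep_len(as.integer(n), 4L)
  if (any(n < 1L)) stop("per-family sample sizes must be at least 1")
  N <- sum(n)
  fam <- rep(1:4, times = n)
  means <- effectsToMeans(effects)

  dn <- list(map$marker, paste0("F", fam, "_", sequence(n)))
  geno <- matrix(NA_integer_, nrow(map), N, dimnames = dn)
  matAllele <- matrix(NA_integer_, nrow(map), N, dimnames = dn)
  patAllele <- matrix(NA_integer_, nrow(map), N, dimnames = dn)
  config <- integer(N)
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    pos <- map$position_cM[idx]
    hasQtl <- ch == qtlChromosome
    loci <- if (hasQtl) sort(unique(c(pos, qtlPosition))) else pos
    gm <- simulateGametes(N, loci)   # maternal meioses
    gp <- simulateGametes(N, loci)   # paternal meioses
    mcols <- match(pos, loci)
    matAllele[idx, ] <- t(1L + gm[, mcols, drop = FALSE])
    patAllele[idx, ] <- t(1L + gp[, mcols, drop = FALSE])
    geno[idx, ] <- matAllele[idx, ] + patAllele[idx, ] - 1L
    if (hasQtl) {
      q <- match(qtlPosition, loci)
      config <- gm[, q] * 2L + gp[, q] + 1L   # AA, Aa, aA, aa
    }
  }
  phe <- means[cbind(fam, config)] + stats::rnorm(N, 0, sqrt(sigma2))
  makeReciprocalCross(
    geno, map, fam, phe,
    maternal = matAllele, paternal = patAllele,
    metadata = list(truth = list(
      config = config, qtlChromosome = qtlChromosome,
      qtlPosition = qtlPosition, effects = effects,
      sigma2 = sigma2, h2 = if (is.null(h2)) NA_real_ else h2)))
}

#' Power and type-I-error study of the imprinting test hierarchy
#'
#' @description
#' Repeats: simulate the benchmark cross (10 markers / 200 cM, iQTL at
#' 35 cM) under a given scenario, fit the full model and each requested
#' constrained model at the true QTL position (or, with `fullScan = TRUE`,
#' at the genome-scan peak), and reject each test when its chi-square
#' p-value falls below `alpha`.  Returns per-test rejection percentages,
#' the per-replicate p-values and the per-replicate unconstrained effect
#' estimates (whose means and SDs reproduce the estimation study).
#'
#' @param scenario `"I"`, `"II"` or `"III"` (see [scenarioEffects()]), or a
#'   16-effect vector.
#' @param n Per-family sample size.
#' @param h2 Heritability.
#' @param reps Number of simulation replicates (>= 20).
#' @param alpha Nominal test level.
#' @param tests Integer vector of test ids (subset of 1:6).
#' @param seed Integer seed; fixed seed gives a bit-identical study.
#' @param control An [emControl()] list.
#' @param fullScan If `TRUE`, evaluate the tests at each replicate's scan
#'   peak instead of the true position (markedly slower).
#' @param step Scan step used when `fullScan = TRUE`.
#' @return An [IQTLPowerStudy-class] object.
#' @export
runPowerStudy <- function(scenario = "I", n = 300L, h2 = 0.1, reps = 100L,
                          alpha = 0.05, tests = 1:6, seed = NULL,
                          control = emControl(), fullScan = FALSE,
                          step = 2) {
  if (reps < 20L) stop("'reps' must be at least 20")
  if (is.character(scenario)) {
    label <- scenario
    effects <- scenarioEffects(scenario)
  } else {
    label <- "custom"
    effects <- asEffectVector(scenario)
  }
  if (!is.null(seed)) set.seed(seed)
  tests <- sort(unique(as.integer(tests)))
  pv <- matrix(NA_real_, reps, length(tests),
               dimnames = list(NULL, paste0("test", tests)))
  est <- matrix(NA_real_, reps, 16L,
                dimnames = list(NULL, iqtlEffectNames()))
  for (b in seq_len(reps)) {
    cross <- simulateCross(effects, n = n, h2 = h2)
    truth <- S4Vectors::metadata(cross)$truth
    where <- if (fullScan) {
      sc <- scanGenome(cross, step = step, control = control)
      prof <- scanProfile(sc)
      prof[which.max(prof$lr), ]
    } else {
      data.frame(chromosome = truth$qtlChromosome,
                 position = truth$qtlPosition)
    }
    res <- imprintingTests(cross, where$chromosome[1L], where$position[1L],
                           tests = tests, control = control)
    pv[b, ] <- res$tests$pvalue
    est[b, ] <- effectEstimates(res$fit)
  }
  rej <- 100 * colMeans(pv < alpha)
  methods::new("IQTLPowerStudy",
               scenario = label, n = as.integer(rep_len(n, 1L)), h2 = h2,
               alpha = alpha, pvalues = pv, estimates = est,
               rejection = rej, effects = effects)
}
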