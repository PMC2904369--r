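#' Configuration priors of every individual at a genome position
#'
#' Locates the marker interval bracketing `position`, converts the two
#' marker-QTL distances to recombination fractions by the Haldane map
#' function, and returns each individual's conditional distribution over the
#' four ordered QTL configurations.  When the cross records phase-known
#' marker transmission (assays `"maternal"`/`"paternal"`, as written by
#' [simulateCross()]) and `usePhase` is `TRUE`, the origin-informative
#' [orderedConfigPriors()] are used; otherwise the unordered-genotype
#' [configPriors()], under which the two heterozygous configurations are
#' exchangeable.  A missing flank is marginalised; with no flanking
#' information the prior is uniform.
#'
#' @param cross A [ReciprocalCross-class] object.
#' @param chromosome Chromosome name (must be on the map).
#' @param position Position in cM, within the chromosome's marker span.
#' @param usePhase Use the phase-known assays when present.
#' @return An n x 4 matrix of configuration probabilities.
#' @export
positionPriors <- function(cross, chromosome, position, usePhase = TRUE) {
  rd <- SummarizedExperiment::rowData(cross)
  onChr <- which(rd$chromosome == chromosome)
  if (!length(onChr)) stop("chromosome '", chromosome, "' not on the map")
  pos <- rd$position[onChr]
  if (length(onChr) < 2L)
    stop("chromosome '", chromosome, "' has fewer than 2 markers")
  if (position < pos[1L] || position > pos[length(pos)])
    stop("position outside the marker span of chromosome '", chromosome, "'")
  j <- findInterval(position, pos)
  if (j >= length(pos)) j <- length(pos) - 1L
  r1 <- haldaneR(position - pos[j])
  r2 <- haldaneR(pos[j + 1L] - position)
  an <- SummarizedExperiment::assayNames(cross)
  if (usePhase && all(c("maternal", "paternal") %in% an)) {
    gm <- SummarizedExperiment::assay(cross, "maternal")
    gp <- SummarizedExperiment::assay(cross, "paternal")
    orderedConfigPriors(gm[onChr[j], ], gm[onChr[j + 1L], ],
                        gp[onChr[j], ], gp[onChr[j + 1L], ], r1, r2)
  } else {
    g <- SummarizedExperiment::assay(cross, "genotype")
    configPriors(g[onChr[j], ], g[onChr[j + 1L], ], r1, r2)
  }
}

#' Genome scan for iQTL existence
#'
#' At every grid position (each marker plus every `step` cM within each
#' interval) the full 16-effect mixture model is fitted by EM and compared
#' with the QTL-existence null (all 16 genotypic means equal, a single
#' normal), giving the likelihood-ratio profile
#' \eqn{LR = 2(\log L_{full} - \log L_0)}.  Compare the profile maximum with
#' a [permutationThreshold()] and call peaks with [callPeaks()].
#'
#' @param cross A [ReciprocalCross-class] object.
#' @param step Scan step in cM (> 0).
#' @param control An [emControl()] list for the per-position fits.
#' @param chromosomes Optional subset of chromosomes to scan (default: all
#'   chromosomes with at least two markers).
#' @return An [IQTLScan-class] object.
#' @export
scanGenome <- function(cross, step = 2, control = emControl(),
                       chromosomes = NULL) {
  if (step <= 0) stop("'step' must be positive")
  rd <- SummarizedExperiment::rowData(cross)
  cd <- SummarizedExperiment::colData(cross)
  y <- cd$phenotype
  fam <- cd$family
  ll0 <- singleNormalLogLik(y)
  chroms <- unique(rd$chromosome)
  chroms <- chroms[vapply(chroms,
                          function(ch) sum(rd$chromosome == ch) >= 2L,
                          logical(1L))]
  if (!is.null(chromosomes)) chroms <- intersect(chroms, chromosomes)
  if (!length(chroms)) stop("no chromosome with at least 2 markers to scan")
  rows <- list()
  for (ch in chroms) {
    pos <- rd$position[rd$chromosome == ch]
    grid <- sort(unique(c(pos, unlist(lapply(seq_len(length(pos) - 1L),
      function(j) seq(pos[j], pos[j + 1L], by = step))))))
    for (p in grid) {
      pri <- positionPriors(cross, ch, p)
      fit <- emFit(priors = pri, control = control,
                   phenotype = y, family = fam)
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = ch, position = p,
        lr = max(0, 2 * (fit@logLik - ll0)),
        as.list(effectEstimates(fit)), sigma2 = residualVariance(fit),
        converged = fit@converged, check.names = FALSE)
    }
  }
  prof <- do.call(rbind, rows)
  rownames(prof) <- NULL
  methods::new("IQTLScan", profile = prof, step = step,
               threshold = NA_real_, alpha = NA_real_,
               peaks = data.frame())
}

#' Genome-wide permutation threshold
#'
#' Empirical null distribution of the genome-wide maximum existence LR,
#' following the standard permutation approach: phenotypes are shuffled,
#' destroying any genotype-phenotype association, the genome is rescanned and
#' the maximum LR recorded; the threshold is the empirical `1 - alpha`
#' quantile of the maxima.
#'
#' The default scheme shuffles phenotypes across all individuals jointly,
#' consistent with the existence null of equal means in all 16 cells (which
#' includes between-family differences).  `scheme = "within-family"`
#' preserves family means, for users who attribute family differences to
#' non-QTL causes.
#'
#' @inheritParams scanGenome
#' @param nPerm Number of permutation replicates (>= 10; >= 100 recommended).
#' @param alpha Genome-wide significance level.
#' @param seed Integer seed; fixed seed gives a bit-identical threshold.
#' @param scheme `"overall"` (default) or `"within-family"`.
#' @return The threshold, with the vector of permutation maxima as attribute
#'   `"maxima"`.
#' @export
permutationThreshold <- function(cross, step = 2, nPerm = 1000L,
                                 alpha = 0.05, seed = NULL,
                                 scheme = c("overall", "within-family"),
                                 control = emControl(), chromosomes = NULL) {
  if (nPerm < 10L) stop("'nPerm' must be at least 10")
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  cd <- SummarizedExperiment::colData(cross)
  maxima <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    perm <- cross
    y <- cd$phenotype
    if (scheme == "overall") {
      y <- y[sample.int(length(y))]
    } else {
      for (t in 1:4) {
        idx <- which(cd$family == t)
        y[idx] <- y[idx][sample.int(length(idx))]
      }
    }
    SummarizedExperiment::colData(perm)$phenotype <- y
    sc <- scanGenome(perm, step = step, control = control,
                     chromosomes = chromosomes)
    maxima[b] <- max(scanProfile(sc)$lr)
  }
  thr <- stats::quantile(maxima, probs = 1 - alpha, type = 1L, names = FALSE)
  attr(thr, "maxima") <- maxima
  thr
}

#' Call QTL peaks from a scan profile
#'
#' Local maxima of the LR profile above the threshold.  Two maxima on the
#' same chromosome are distinct peaks only if they are at least
#' `minSeparation` cM apart *and* the profile drops below the threshold
#' between them; otherwise the higher (ties: leftmost) survives.
#'
#' @param scan An [IQTLScan-class] object.
#' @param threshold Genome-wide LR threshold (see [permutationThreshold()]).
#' @param minSeparation Minimum cM between distinct peaks on one chromosome.
#' @param alpha Level recorded alongside the threshold.
#' @return The scan object with its `peaks` slot filled (columns
#'   `chromosome`, `position`, `lr`).
#' @export
callPeaks <- function(scan, threshold, minSeparation = 30, alpha = NA_real_) {
  prof <- scanProfile(scan)
  peaks <- list()
  for (ch in unique(prof$chromosome)) {
    p <- prof[prof$chromosome == ch, , drop = FALSE]
    p <- p[order(p$position), , drop = FALSE]
    above <- p$lr >= threshold
    if (!any(above)) next
    ## contiguous above-threshold islands; one candidate peak per island
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    cand <- list()
    for (i in which(runs$values)) {
      seg <- p[starts[i]:ends[i], , drop = FALSE]
      cand[[length(cand) + 1L]] <- seg[which.max(seg$lr), , drop = FALSE]
    }
    cand <- do.call(rbind, cand)
    ## merge islands closer than minSeparation: keep higher, ties leftmost
    keep <- rep(TRUE, nrow(cand))
    repeat {
      idx <- which(keep)
      if (length(idx) < 2L) break
      gaps <- diff(cand$position[idx])
      j <- which(gaps < minSeparation)
      if (!length(j)) break
      j <- j[1L]
      a <- idx[j]; b <- idx[j + 1L]
      keep[if (cand$lr[b] > cand$lr[a]) a else b] <- FALSE
    }
    peaks[[length(peaks) + 1L]] <- cand[keep, , drop = FALSE]
  }
  scan@peaks <- if (length(peaks)) {
    out <- do.call(rbind, peaks)[, c("chromosome", "position", "lr")]
    rownames(out) <- NULL
    out
  } else data.frame(chromosome = character(), position = numeric(),
                    lr = numeric())
  scan@threshold <- as.numeric(threshold)
  scan@alpha <- alpha
  scan
}

#' Imprinting test hierarchy at one position
#'
#' Fits the full 16-effect model once at the given position, then each
#' requested constrained model of [testConstraints()], and returns the
#' likelihood-ratio tests.  Constrained fits are warm-started from the full
#' solution.
#'
#' @inheritParams positionPriors
#' @param tests Integer vector of test ids (subset of 1:6).
#' @param singleEffects If `TRUE`, additionally test each of the 15 non-mean
#'   effects individually (1 df each).
#' @param control An [emControl()] list.
#' @return A list: `fit` (the full-model [IQTLFit-class]) and `tests` (a
#'   `data.frame` of [likelihoodRatioTest()] rows).
#' @export
imprintingTests <- function(cross, chromosome, position, tests = 1:6,
                            singleEffects = FALSE, control = emControl()) {
  priors <- positionPriors(cross, chromosome, position)
  cd <- SummarizedExperiment::colData(cross)
  full <- emFit(priors = priors, control = control,
                phenotype = cd$phenotype, family = cd$family)
  warm <- list(means = drop(designMatrix() %*% effectEstimates(full)),
               sigma2 = residualVariance(full))
  ids <- c(as.list(tests),
           if (singleEffects) as.list(iqtlEffectNames()[-1L]))
  rows <- lapply(ids, function(id) {
    nul <- emFit(priors = priors, constraints = testConstraints(id),
                 control = control, start = warm,
                 phenotype = cd$phenotype, family = cd$family)
    likelihoodRatioTest(nul, full,
                        name = if (is.numeric(id)) paste0("test", id) else id)
  })
  list(fit = full, tests = do.call(rbind, rows))
}
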