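#' Map-distance functions
#'
#' Convert between map distance in centiMorgans and recombination fraction.
#' `haldaneR()`/`haldaneD()` use the Haldane map function (no crossover
#' interference), the model assumed throughout the scan and simulator;
#' `kosambiR()`/`kosambiD()` are provided for map conversion only.
#'
#' @param d Map distance in cM (non-negative).
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return `haldaneR()`, `kosambiR()`: recombination fraction; `haldaneD()`,
#'   `kosambiD()`: distance in cM.
#' @examples
#' haldaneR(10)          # ~0.0906
#' haldaneD(haldaneR(25))
#' @export
haldaneR <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  (1 - exp(-2 * d / 100)) / 2
}

#' @rdname haldaneR
#' @export
haldaneD <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("recombination fraction must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname haldaneR
#' @export
kosambiR <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  tanh(2 * d / 100) / 2
}

#' @rdname haldaneR
#' @export
kosambiD <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("recombination fraction must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Three-locus gamete distribution of an F1 parent
#'
#' Probabilities of the eight left-marker / QTL / right-marker gamete
#' haplotypes produced by one F1 meiosis.  Both grandparental lines are fully
#' inbred and fixed (line 1: marker allele 1 and QTL allele A; line 2: marker
#' allele 2 and QTL allele a), so every F1 parent — whichever configuration it
#' carries — is in coupling phase 1-A-1 / 2-a-2, and the distribution depends
#' only on the two recombination fractions.
#'
#' @param r1 Recombination fraction between the left marker and the QTL.
#' @param r2 Recombination fraction between the QTL and the right marker.
#' @return A numeric vector of length 8 summing to 1, named
#'   `"<left><qtl><right>"` (e.g. `"1A1"`, `"2a1"`).
#' @examples
#' gameteDistribution(0.1, 0.1)["1A1"]  # (1-r1)(1-r2)/2 = 0.405
#' @export
gameteDistribution <- function(r1, r2) {
  if (r1 < 0 || r1 > 0.5 || r2 < 0 || r2 > 0.5)
    stop("recombination fractions must lie in [0, 0.5]")
  p <- c("1A1" = (1 - r1) * (1 - r2) / 2,
         "1A2" = (1 - r1) * r2 / 2,
         "1a1" = r1 * r2 / 2,
         "1a2" = r1 * (1 - r2) / 2,
         "2A1" = r1 * (1 - r2) / 2,
         "2A2" = r1 * r2 / 2,
         "2a1" = (1 - r1) * r2 / 2,
         "2a2" = (1 - r1) * (1 - r2) / 2)
  p
}

# Internal genotype coding at a marker: 1 = 11, 2 = 12, 3 = 22, NA = missing.
# Class index for prior lookup: NA -> 4.
genoClass <- function(g) ifelse(is.na(g), 4L, as.integer(g))

#' Conditional configuration probabilities given flanking markers
#'
#' @description
#' The ordered QTL configuration of an F2 individual (maternal allele first:
#' AA, Aa, aA, aa) is unobserved; its conditional distribution given the
#' unordered genotypes at the two flanking markers is the mixture weight of
#' the likelihood.  `configPriorTable()` tabulates these distributions for all
#' flanking-genotype classes at a given pair of recombination fractions;
#' `configPriors()` looks them up for vectors of observed genotypes.
#'
#' @details
#' The table is built by enumerating the 8 x 8 ordered pairs of maternal and
#' paternal three-locus gametes (meioses independent, each distributed as
#' [gameteDistribution()]), accumulating each pair's probability into its
#' unordered flanking-marker class, and normalising within each class.  A
#' missing flank marginalises over that marker; with both flanks missing the
#' prior is uniform (1/4 each).  The distribution depends only on the marker
#' genotypes and the position, not on the mating type.
#'
#' @param r1,r2 Recombination fractions between the left marker and the QTL
#'   and between the QTL and the right marker.
#' @param left,right Integer genotype codes at the flanking markers
#'   (1 = `11`, 2 = `12`, 3 = `22`, `NA` = missing), recycled to a common
#'   length.
#' @return `configPriorTable()`: a 16 x 4 matrix, rows indexed by
#'   (left class, right class) with classes `11, 12, 22, NA`, columns the
#'   four ordered configurations.  `configPriors()`: an n x 4 matrix of
#'   per-individual configuration probabilities.
#' @examples
#' configPriors(left = 1L, right = 1L, r1 = 0, r2 = 0.1)  # P(AA) = 1
#' @export
configPriorTable <- function(r1, r2) {
  g <- gameteDistribution(r1, r2)
  hapL <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)        # left allele of gametes 1..8
  hapQ <- c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L)        # 1 = A, 2 = a
  hapR <- c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L)
  ## joint over (left class 1:3, right class 1:3, config 1:4)
  joint <- array(0, dim = c(3L, 3L, 4L))
  for (m in 1:8) for (p in 1:8) {
    lc <- hapL[m] + hapL[p] - 1L                   # 11 -> 1, 12 -> 2, 22 -> 3
    rc <- hapR[m] + hapR[p] - 1L
    k <- (hapQ[m] - 1L) * 2L + hapQ[p]             # AA, Aa, aA, aa
    joint[lc, rc, k] <- joint[lc, rc, k] + g[m] * g[p]
  }
  tab <- matrix(0, 16L, 4L)
  cls <- c("11", "12", "22", "NA")
  rownames(tab) <- as.vector(t(outer(cls, cls, paste, sep = "/")))
  colnames(tab) <- iqtlConfigs()
  for (lc in 1:4) for (rc in 1:4) {
    li <- if (lc == 4L) 1:3 else lc
    ri <- if (rc == 4L) 1:3 else rc
    w <- apply(joint[li, ri, , drop = FALSE], 3L, sum)
    tab[(lc - 1L) * 4L + rc, ] <- w / sum(w)
  }
  tab
}

#' Configuration probabilities from phase-known marker transmission
#'
#' When the parental origin of the marker alleles is traceable through the
#' pedigree — the premise of the two-stage reciprocal design, and recorded by
#' [simulateCross()] — each meiosis is informative on its own: the
#' probability that a gamete carries QTL allele A given the marker alleles it
#' transmitted at the flanks is
#' \eqn{P(A \mid L, R) = f_1(L) f_2(R) / \{f_1(L) f_2(R) + \bar f_1(L) \bar
#' f_2(R)\}} with \eqn{f_j(1) = 1 - r_j}, \eqn{f_j(2) = r_j} (a missing
#' allele contributes 1/2).  The ordered-configuration distribution is the
#' product over the maternal and paternal meioses, so Aa and aA are
#' distinguished — unordered genotypes cannot do that (see
#' [configPriors()]).
#'
#' @param maternalLeft,maternalRight Marker alleles (1, 2 or `NA`)
#'   transmitted by the mother's gamete at the left and right flank.
#' @param paternalLeft,paternalRight Same for the father's gamete.
#' @inheritParams configPriorTable
#' @return An n x 4 matrix of ordered-configuration probabilities.
#' @export
orderedConfigPriors <- function(maternalLeft, maternalRight,
                                paternalLeft, paternalRight, r1, r2) {
  if (r1 < 0 || r1 > 0.5 || r2 < 0 || r2 > 0.5)
    stop("recombination fractions must lie in [0, 0.5]")
  f <- function(allele, r)
    ifelse(is.na(allele), 0.5, ifelse(allele == 1L, 1 - r, r))
  pA <- function(L, R) {
    wA <- f(L, r1) * f(R, r2)
    wa <- ifelse(is.na(L), 0.5, ifelse(L == 2L, 1 - r1, r1)) *
          ifelse(is.na(R), 0.5, ifelse(R == 2L, 1 - r2, r2))
    wA / (wA + wa)
  }
  pm <- pA(maternalLeft, maternalRight)
  pp <- pA(paternalLeft, paternalRight)
  out <- cbind(pm * pp, pm * (1 - pp), (1 - pm) * pp, (1 - pm) * (1 - pp))
  colnames(out) <- iqtlConfigs()
  out
}

#' @rdname configPriorTable
#' @export
configPriors <- function(left, right, r1, r2) {
  n <- max(length(left), length(right))
  left <- rep_len(genoClass(left), n)
  right <- rep_len(genoClass(right), n)
  tab <- configPriorTable(r1, r2)
  tab[(left - 1L) * 4L + right, , drop = FALSE]
}
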