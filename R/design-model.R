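#' @details
#' Two inbred lines (alleles A and a at a putative iQTL) are crossed
#' reciprocally to give two F1 configurations, Aa and aA (maternal allele
#' written first).  All four matings among those F1s produce four
#' epigenetically distinct F2 families ("mating types"), each segregating the
#' same four ordered configurations AA, Aa, aA, aa.  The 16 cell means are
#' decomposed into 16 orthogonally coded genetic effects; imprinting expressed
#' in the F1 appears as mating-type contrasts, imprinting expressed in the F2
#' as the Aa-vs-aA contrast within families, and transgenerational
#' transmission as their interactions.
#'
#' @keywords internal
"_PACKAGE"

#' Names and labels of the mating design
#'
#' `iqtlEffectNames()` returns the 16 genetic-effect names in their fixed
#' order: the overall mean `mu`; the F1-expressed maternal imprinting `i1m`,
#' paternal imprinting `i1p` and their interaction `i1mp`; the F2-expressed
#' additive `a`, dominance `d` and imprinting `i2` effects; and the nine
#' cross-generation interactions (`i1m_a`, ..., `i1mp_i2`).
#' `iqtlConfigs()` returns the four ordered QTL configurations (maternal
#' allele first) and `iqtlMatingTypes()` the four reciprocal F2 mating types
#' (mother's F1 configuration first).
#'
#' @return A character vector.
#' @examples
#' iqtlEffectNames()
#' iqtlMatingTypes()
#' @export
iqtlEffectNames <- function() {
  c("mu", "i1m", "i1p", "i1mp", "a", "d", "i2",
    "i1m_a", "i1m_d", "i1m_i2",
    "i1p_a", "i1p_d", "i1p_i2",
    "i1mp_a", "i1mp_d", "i1mp_i2")
}

#' @rdname iqtlEffectNames
#' @export
iqtlConfigs <- function() c("AA", "Aa", "aA", "aa")

#' @rdname iqtlEffectNames
#' @export
iqtlMatingTypes <- function() c("AaxAa", "AaxaA", "aAxAa", "aAxaA")

# Cell labels in t-major order: mating type outer, configuration inner.
iqtlCellNames <- function() {
  as.vector(t(outer(iqtlMatingTypes(), iqtlConfigs(), paste, sep = ":")))
}

#' Construct a genetic-effect vector
#'
#' Builds a named numeric vector of the 16 genetic effects of the
#' transgenerational imprinting model, in the fixed order of
#' [iqtlEffectNames()].  Unspecified effects are zero.
#'
#' @param ... Named effect values, e.g. `a = 0.3, d = 0.6`.  Names must be a
#'   subset of [iqtlEffectNames()].
#' @return A named numeric vector of length 16.
#' @examples
#' effectVector(a = 0.3, d = 0.6, i2 = 0.2)
#' @export
effectVector <- function(...) {
  vals <- c(...)
  eff <- stats::setNames(numeric(16L), iqtlEffectNames())
  if (length(vals)) {
    if (is.null(names(vals)) || any(!nzchar(names(vals))))
      stop("all effects must be named")
    bad <- setdiff(names(vals), iqtlEffectNames())
    if (length(bad))
      stop("unknown effect name(s): ", paste(bad, collapse = ", "))
    eff[names(vals)] <- as.numeric(vals)
  }
  eff
}

# Coerce / validate a user-supplied effect vector.
asEffectVector <- function(effects) {
  nm <- iqtlEffectNames()
  if (!is.numeric(effects) || length(effects) != 16L)
    stop("'effects' must be a numeric vector of length 16")
  if (!is.null(names(effects))) {
    if (!setequal(names(effects), nm))
      stop("'effects' names must be exactly iqtlEffectNames()")
    effects <- effects[nm]
  } else {
    names(effects) <- nm
  }
  if (any(!is.finite(effects))) stop("'effects' must be finite")
  effects
}

#' Design matrix of the 16-cell genotypic-value decomposition
#'
#' Returns the 16 x 16 matrix \eqn{X} mapping the genetic-effect vector to the
#' genotypic values of the 16 (mating type, ordered configuration) cells.
#' Rows are ordered mating-type-major (type 1 AA, Aa, aA, aa; then type 2,
#' ...), columns follow [iqtlEffectNames()].
#'
#' The coding is a full-rank orthogonal contrast system.  With
#' \eqn{x_m = +1} when the F1 mother is Aa (\eqn{-1} when aA), \eqn{x_p}
#' likewise for the father, \eqn{z_a \in \{+1, 0, -1\}} the additive score of
#' the F2 configuration, \eqn{z_d = +1} for heterozygotes and \eqn{-1} for
#' homozygotes, and \eqn{z_i = +1} for Aa, \eqn{-1} for aA and 0 for
#' homozygotes, a row is
#' \deqn{(1,\; x_m,\; x_p,\; x_m x_p,\; z_a,\; z_d,\; z_i,\; x_m z_a,\;
#'   \ldots,\; x_m x_p z_i).}
#' Distinct columns are orthogonal and every non-mean column sums to zero, so
#' `mu` is always the unweighted mean of the 16 cells and the inverse mapping
#' has the closed form of [meansToEffects()].
#'
#' @return A 16 x 16 numeric matrix with cell row names and effect column
#'   names.
#' @examples
#' X <- designMatrix()
#' crossprod(X)  # diagonal: orthogonal columns
#' @export
designMatrix <- function() {
  ## per-configuration codes, k = AA, Aa, aA, aa
  za <- c(1, 0, 0, -1)
  zd <- c(-1, 1, 1, -1)
  zi <- c(0, 1, -1, 0)
  ## per-mating-type parental codes, t = AaxAa, AaxaA, aAxAa, aAxaA
  xm <- c(1, 1, -1, -1)
  xp <- c(1, -1, 1, -1)
  X <- matrix(0, 16L, 16L, dimnames = list(iqtlCellNames(), iqtlEffectNames()))
  for (t in 1:4) for (k in 1:4) {
    X[(t - 1L) * 4L + k, ] <- c(
      1, xm[t], xp[t], xm[t] * xp[t],
      za[k], zd[k], zi[k],
      xm[t] * c(za[k], zd[k], zi[k]),
      xp[t] * c(za[k], zd[k], zi[k]),
      xm[t] * xp[t] * c(za[k], zd[k], zi[k]))
  }
  X
}

#' Convert between genetic effects and genotypic cell means
#'
#' `effectsToMeans()` computes the 4 x 4 matrix of genotypic values (rows:
#' mating types, columns: ordered configurations) implied by an effect
#' vector; `meansToEffects()` is its exact inverse.  Because the coding of
#' [designMatrix()] is orthogonal, each effect is the projection
#' \eqn{\beta_j = c_j^\top g / \lVert c_j \rVert^2} of the 16 cell means
#' \eqn{g} onto column \eqn{c_j}.
#'
#' @param effects A named numeric vector of 16 effects (see [effectVector()]).
#' @param means A 4 x 4 numeric matrix of genotypic values (mating types x
#'   configurations), or a length-16 vector in mating-type-major order.
#' @return `effectsToMeans()`: a 4 x 4 named numeric matrix;
#'   `meansToEffects()`: a named numeric vector of 16 effects.
#' @examples
#' eff <- effectVector(mu = 10, a = 0.3, d = 0.6)
#' m <- effectsToMeans(eff)
#' stopifnot(all.equal(meansToEffects(m), eff))
#' @export
effectsToMeans <- function(effects) {
  effects <- asEffectVector(effects)
  g <- drop(designMatrix() %*% effects)
  matrix(g, 4L, 4L, byrow = TRUE,
         dimnames = list(iqtlMatingTypes(), iqtlConfigs()))
}

#' @rdname effectsToMeans
#' @export
meansToEffects <- function(means) {
  g <- asCellMeans(means)
  X <- designMatrix()
  drop(crossprod(X, g)) / colSums(X * X)
}

# 4x4 (t x k) matrix or t-major length-16 vector -> t-major cell vector
asCellMeans <- function(means) {
  if (is.matrix(means)) {
    if (!all(dim(means) == c(4L, 4L))) stop("'means' must be 4 x 4")
    g <- as.vector(t(means))
  } else {
    if (length(means) != 16L) stop("'means' must have 16 values")
    g <- as.numeric(means)
  }
  if (any(!is.finite(g))) stop("'means' must be finite")
  names(g) <- iqtlCellNames()
  g
}

#' Genetic variance of the 16-cell design
#'
#' Variance of the genotypic values over the 16 (mating type, configuration)
#' cells, each weighted 1/16 — Mendelian segregation of the ordered
#' configurations within each family and equally sized families.  With the
#' orthogonal coding this is \eqn{\sum_j \beta_j^2 \, \overline{c_j^2}} over
#' the non-mean columns; it is the genotypic variance used to scale residual
#' noise to a target heritability in [simulateCross()].
#'
#' @inheritParams effectsToMeans
#' @return Genetic variance, in squared phenotype units.
#' @examples
#' geneticVariance(effectVector(a = 0.3))  # 0.3^2 * 1/2
#' @export
geneticVariance <- function(effects) {
  effects <- asEffectVector(effects)
  X <- designMatrix()
  msq <- colMeans(X * X)
  sum((effects^2 * msq)[-1L])
}
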