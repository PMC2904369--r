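#' Observed-data log-likelihood of the four-family mixture model
#'
#' Evaluates
#' \deqn{\log L = \sum_{t=1}^{4} \sum_{i=1}^{n_t} \log \sum_{k=1}^{4}
#'   \omega_{tik}\, \phi(y_{ti};\, \mu_{tk},\, \sigma^2),}
#' the likelihood that combines the four reciprocal F2 families: each
#' individual's phenotype is a mixture over its four unobserved ordered QTL
#' configurations, weighted by the marker-conditional configuration
#' probabilities, with cell means \eqn{\mu_{tk}} shared within (mating type,
#' configuration) cells and a single residual variance.
#'
#' @param phenotype Numeric vector of trait values.
#' @param family Integer vector (1-4) of mating types, same length.
#' @param priors n x 4 matrix of configuration probabilities (rows sum to 1),
#'   e.g. from [configPriors()].
#' @param means 4 x 4 genotypic-value matrix (mating types x configurations)
#'   or length-16 mating-type-major vector.
#' @param sigma2 Residual variance (> 0).
#' @return The log-likelihood (scalar).
#' @export
mixtureLogLik <- function(phenotype, family, priors, means, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  mu <- matrix(asCellMeans(means), 4L, 4L, byrow = TRUE)
  MU <- mu[family, , drop = FALSE]
  dens <- exp(-((phenotype - MU)^2) / (2 * sigma2))
  sum(log(rowSums(priors * dens))) -
    length(phenotype) * 0.5 * log(2 * pi * sigma2)
}

#' EM control parameters
#'
#' @param tol Convergence tolerance on the change in log-likelihood.
#' @param maxIter Maximum EM iterations per start.
#' @param nRestarts Number of seeded random restarts added to the
#'   deterministic start (mixture likelihoods can be multimodal).
#' @param restartSd Scale, in phenotype SDs, of the random cell-mean
#'   perturbations used by the restarts.
#' @return A list of class `emControl`.
#' @export
emControl <- function(tol = 1e-8, maxIter = 2000L, nRestarts = 4L,
                      restartSd = 1) {
  stopifnot(tol > 0, maxIter >= 1L, nRestarts >= 0L, restartSd > 0)
  structure(list(tol = tol, maxIter = as.integer(maxIter),
                 nRestarts = as.integer(nRestarts), restartSd = restartSd),
            class = "emControl")
}

#' Maximum-likelihood fit of the mixture model by EM
#'
#' @description
#' Fits the genotypic-value decomposition to the four reciprocal F2 families
#' by maximising the mixture likelihood of [mixtureLogLik()], optionally
#' under zero constraints on any subset of the 15 non-mean effects (the null
#' hypotheses of the imprinting test hierarchy, see [testConstraints()]).
#'
#' @details
#' E-step: posterior configuration weights
#' \eqn{P_{tik} \propto \omega_{tik}\phi(y_{ti}; \mu_{tk}, \sigma^2)}.
#' M-step: with cell weights \eqn{W_{tk} = \sum_i P_{tik}} and weighted cell
#' means \eqn{\bar Y_{tk}}, the free effects solve the weighted least-squares
#' problem \eqn{\min_\beta \sum_{tk} W_{tk}(\bar Y_{tk} - (X\beta)_{tk})^2}
#' over the unconstrained columns of [designMatrix()] (with no constraints
#' this reduces to \eqn{\mu_{tk} = \bar Y_{tk}}), and
#' \eqn{\sigma^2 = \sum_{tik} P_{tik}(y_{ti} - \mu_{tk})^2 / N}.  The
#' observed-data log-likelihood is non-decreasing across iterations; the best
#' of the deterministic start (grand mean plus graded offsets) and
#' `nRestarts` random restarts is returned.  Random restarts draw from the
#' current RNG stream, so seed the session (or the calling function) for
#' reproducibility.
#'
#' @param cross A [ReciprocalCross-class], or `NULL` if `phenotype`/`family`
#'   are given directly.
#' @param priors n x 4 configuration-probability matrix for the evaluated
#'   QTL position (see [positionPriors()]).
#' @param constraints Character vector of effect names fixed at zero (never
#'   `"mu"`), or an integer test id for [testConstraints()].
#' @param control An [emControl()] list.
#' @param start Optional warm start: a list with elements `means` (16 cell
#'   means, mating-type-major) and `sigma2`.  When supplied, no restarts are
#'   added.
#' @param phenotype,family Alternative direct interface (used internally and
#'   by the simulator) bypassing `cross`.
#' @return An [IQTLFit-class] object.
#' @export
emFit <- function(cross = NULL, priors, constraints = character(),
                  control = emControl(), start = NULL,
                  phenotype = NULL, family = NULL) {
  if (!is.null(cross)) {
    cd <- SummarizedExperiment::colData(cross)
    phenotype <- cd$phenotype
    family <- cd$family
  }
  if (is.numeric(constraints)) constraints <- testConstraints(constraints)
  if ("mu" %in% constraints) stop("the overall mean cannot be constrained")
  bad <- setdiff(constraints, iqtlEffectNames())
  if (length(bad)) stop("unknown effect name(s): ", paste(bad, collapse = ", "))
  n <- length(phenotype)
  if (n < 1L) stop("no individuals")
  if (!is.matrix(priors) || nrow(priors) != n || ncol(priors) != 4L)
    stop("'priors' must be an n x 4 matrix aligned with the individuals")
  family <- as.integer(family)

  emptyFam <- setdiff(1:4, unique(family))
  identifiable <- !(length(emptyFam) > 0L && length(constraints) < 15L)

  X <- designMatrix()
  free <- setdiff(iqtlEffectNames(), constraints)
  Xf <- X[, free, drop = FALSE]

  ybar <- mean(phenotype)
  ysd <- stats::sd(phenotype)
  if (!is.finite(ysd) || ysd == 0) ysd <- 1
  starts <- list()
  if (!is.null(start)) {
    starts[[1L]] <- list(mu = asCellMeans(start$means), sigma2 = start$sigma2)
  } else {
    ## deterministic start: grand mean with graded offsets across the cells
    starts[[1L]] <- list(mu = ybar + 0.5 * ysd * seq(-1, 1, length.out = 16L),
                         sigma2 = ysd^2)
    for (s in seq_len(control$nRestarts))
      starts[[s + 1L]] <- list(
        mu = ybar + control$restartSd * ysd * stats::rnorm(16L),
        sigma2 = ysd^2 * stats::runif(1L, 0.5, 1.5))
  }

  best <- NULL
  for (st in starts) {
    run <- emRun(phenotype, family, priors, Xf, st$mu, st$sigma2, control)
    if (is.null(best) || run$logLik > best$logLik) best <- run
  }

  eff <- stats::setNames(numeric(16L), iqtlEffectNames())
  eff[free] <- best$beta
  fit <- methods::new("IQTLFit",
    effects = eff, constrained = sort(constraints),
    sigma2 = best$sigma2, logLik = best$logLik,
    nIter = best$iter, converged = best$converged && identifiable,
    logLikTrace = best$trace, nObs = n)
  if (!identifiable)
    warning("family ", paste(emptyFam, collapse = ", "),
            " empty: family-specific effects are not identifiable")
  fit
}

# One EM run from one start; Xf = free design columns.
emRun <- function(y, fam, priors, Xf, mu, sigma2, control) {
  n <- length(y)
  const <- -0.5 * log(2 * pi)
  XtX <- NULL
  loglik <- -Inf
  trace <- numeric(0L)
  converged <- FALSE
  iter <- 0L
  beta <- NULL
  for (iter in seq_len(control$maxIter)) {
    MU <- matrix(mu, 4L, 4L, byrow = TRUE)[fam, , drop = FALSE]
    dens <- exp(-((y - MU)^2) / (2 * sigma2))
    wd <- priors * dens
    rs <- rowSums(wd)
    newll <- sum(log(rs)) + n * (const - 0.5 * log(sigma2))
    trace <- c(trace, newll)
    if (is.finite(loglik) && abs(newll - loglik) < control$tol) {
      loglik <- newll
      converged <- TRUE
      break
    }
    loglik <- newll
    P <- wd / rs
    ## M-step: cell weights by mating type (absent families keep zero rows)
    W <- matrix(0, 4L, 4L)
    Sy <- matrix(0, 4L, 4L)
    tmp <- rowsum(P, fam)
    W[as.integer(rownames(tmp)), ] <- tmp
    tmp <- rowsum(P * y, fam)
    Sy[as.integer(rownames(tmp)), ] <- tmp
    cw <- as.vector(t(W))                            # t-major cell weights
    cy <- as.vector(t(Sy))
    yb <- ifelse(cw > 0, cy / pmax(cw, .Machine$double.eps), 0)
    A <- crossprod(Xf, Xf * cw)
    b <- crossprod(Xf, cw * yb)
    beta <- tryCatch(drop(solve(A, b)),
                     error = function(e) drop(MASS::ginv(A) %*% b))
    mu <- drop(Xf %*% beta)
    MU <- matrix(mu, 4L, 4L, byrow = TRUE)[fam, , drop = FALSE]
    sigma2 <- sum(P * (y - MU)^2) / n
    if (sigma2 <= 0) sigma2 <- .Machine$double.eps
  }
  if (is.null(beta)) {  # maxIter = 0 path cannot occur; defensive
    beta <- drop(MASS::ginv(crossprod(Xf)) %*% crossprod(Xf, mu))
  }
  list(beta = beta, sigma2 = sigma2, logLik = loglik, iter = iter,
       converged = converged, trace = trace)
}

#' Null-hypothesis constraint sets of the imprinting test hierarchy
#'
#' @description
#' Returns the set of effects fixed at zero under each of the six standard
#' null hypotheses, or for a single named effect:
#' \describe{
#'   \item{Test 1 (13 df)}{overall imprinting: all F1 imprinting terms, the
#'     F2 imprinting effect, and every cross-generation interaction.}
#'   \item{Test 2 (3 df)}{imprinting expressed in the F1: `i1m`, `i1p`,
#'     `i1mp`.}
#'   \item{Test 3 (10 df)}{imprinting expressed in the F2: `i2` and the nine
#'     interactions.}
#'   \item{Test 4 (3 df)}{maternal-F1 x F2 interactions: `i1m_a`, `i1m_d`,
#'     `i1m_i2`.}
#'   \item{Test 5 (3 df)}{paternal-F1 x F2 interactions: `i1p_a`, `i1p_d`,
#'     `i1p_i2`.}
#'   \item{Test 6 (3 df)}{three-way interactions: `i1mp_a`, `i1mp_d`,
#'     `i1mp_i2`.}
#' }
#' The QTL-existence null (all 16 means equal) is available as `"existence"`
#' and constrains all 15 non-mean effects.
#'
#' @param test Integer 1-6, `"existence"`, or a single effect name.
#' @return Character vector of constrained effect names.
#' @examples
#' length(testConstraints(1))  # 13
#' testConstraints("i1m")
#' @export
testConstraints <- function(test) {
  nm <- iqtlEffectNames()
  inter <- nm[8:16]
  if (length(test) != 1L) stop("'test' must be a single id")
  if (is.numeric(test)) {
    if (!test %in% 1:6) stop("test id must be 1..6")
    return(switch(test,
      c("i1m", "i1p", "i1mp", "i2", inter),
      c("i1m", "i1p", "i1mp"),
      c("i2", inter),
      c("i1m_a", "i1m_d", "i1m_i2"),
      c("i1p_a", "i1p_d", "i1p_i2"),
      c("i1mp_a", "i1mp_d", "i1mp_i2")))
  }
  if (identical(test, "existence")) return(nm[-1L])
  if (test %in% nm[-1L]) return(test)
  stop("unknown test id or effect name: ", test)
}

#' Likelihood-ratio test between nested fits
#'
#' Computes \eqn{LR = 2(\log L_{full} - \log L_{null})} (clipped at zero),
#' with degrees of freedom equal to the number of additional effects the
#' null fixes at zero, and the upper-tail chi-square p-value.  The null's
#' constraint set must contain the full model's (identical constraint sets
#' give LR 0, p 1).
#'
#' @param fitNull,fitFull [IQTLFit-class] objects fitted to the same data.
#' @param name Optional test label.
#' @return A one-row `data.frame`: `test`, `lr`, `df`, `pvalue`.
#' @export
likelihoodRatioTest <- function(fitNull, fitFull, name = NA_character_) {
  cn <- constrainedEffects(fitNull)
  cf <- constrainedEffects(fitFull)
  if (!all(cf %in% cn))
    stop("models are not nested: the null's constraints must contain the full model's")
  lr <- max(0, 2 * (fitFull@logLik - fitNull@logLik))
  df <- length(cn) - length(cf)
  data.frame(test = name, lr = lr, df = df,
             pvalue = if (df == 0L) 1 else
               stats::pchisq(lr, df, lower.tail = FALSE))
}

# Closed-form single-normal fit: the QTL-existence null (all 16 means equal).
singleNormalLogLik <- function(y) {
  n <- length(y)
  s2 <- sum((y - mean(y))^2) / n
  -n / 2 * (log(2 * pi * s2) + 1)
}
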