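# Small in-code fixtures shared across test files.

# A tiny two-chromosome map.
tinyMap <- function() {
  data.frame(
    marker = c("m1", "m2", "m3", "n1", "n2"),
    chromosome = c("1", "1", "1", "2", "2"),
    position_cM = c(0, 20, 50, 0, 30))
}

# Fast EM settings for unit tests (single deterministic start).
quickControl <- function() emControl(tol = 1e-8, maxIter = 500L, nRestarts = 1L)

# A small simulated cross under the benchmark scenario.
quickCross <- function(n = 60, h2 = 0.4, seed = 42, scenario = "I") {
  simulateCross(scenarioEffects(scenario), n = n, h2 = h2, seed = seed)
}

# Direct-summation oracle for the mixture log-likelihood: plain loops,
# independent of the vectorised implementation.
bruteLogLik <- function(y, fam, priors, means, sigma2) {
  total <- 0
  for (i in seq_along(y)) {
    li <- 0
    for (k in 1:4)
      li <- li + priors[i, k] *
        stats::dnorm(y[i], means[fam[i], k], sqrt(sigma2))
    total <- total + log(li)
  }
  total
}
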