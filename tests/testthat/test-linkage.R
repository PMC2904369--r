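test_that("Haldane map function and its inverse match closed forms", {
  expect_equal(haldaneR(0), 0)
  expect_equal(haldaneR(1e4), 0.5, tolerance = 1e-12)
  expect_equal(haldaneR(10), (1 - exp(-0.2)) / 2)
  d <- c(0, 1, 5, 20, 80)
  expect_equal(haldaneD(haldaneR(d)), d, tolerance = 1e-9)
  expect_error(haldaneR(-1), "non-negative")
  expect_equal(kosambiD(kosambiR(d)), d, tolerance = 1e-9)
})

test_that("gamete distribution follows the product formula and normalises", {
  g <- gameteDistribution(0, 0)
  expect_equal(unname(g[c("1A1", "2a2")]), c(0.5, 0.5))
  expect_equal(sum(g), 1)
  g <- gameteDistribution(0.1, 0.1)
  expect_equal(unname(g["1A1"]), 0.405)
  expect_equal(unname(g["1a1"]), 0.005)
  for (r1 in c(0, 0.07, 0.3)) for (r2 in c(0.02, 0.5)) {
    g <- gameteDistribution(r1, r2)
    expect_equal(sum(g), 1)
    # symmetry under simultaneous allele swap 1<->2, A<->a
    expect_equal(unname(g[c("1A1", "1A2", "1a1", "1a2")]),
                 unname(g[c("2a2", "2a1", "2A2", "2A1")]))
  }
  expect_error(gameteDistribution(0.6, 0.1), "0.5")
})

test_that("configuration priors are proper and respect exchange symmetry", {
  grid <- expand.grid(r1 = c(0.01, 0.1, 0.25), r2 = c(0.05, 0.2))
  for (i in seq_len(nrow(grid))) {
    tab <- configPriorTable(grid$r1[i], grid$r2[i])
    expect_true(all(tab >= 0))
    expect_equal(unname(rowSums(tab)), rep(1, 16))
    # unordered markers cannot separate the heterozygous configurations
    expect_equal(tab[, "Aa"], tab[, "aA"])
  }
})

test_that("deterministic and uninformative flanking cases are exact", {
  # QTL on the left marker, genotype 11: both gametes carry allele 1 -> AA
  p <- configPriors(left = 1L, right = 1L, r1 = 0, r2 = 0.2)
  expect_equal(unname(p[1, ]), c(1, 0, 0, 0))
  p <- configPriors(left = 3L, right = NA, r1 = 0, r2 = 0.2)
  expect_equal(unname(p[1, ]), c(0, 0, 0, 1))
  # both flanks missing: uniform
  p <- configPriors(left = NA, right = NA, r1 = 0.1, r2 = 0.1)
  expect_equal(unname(p[1, ]), rep(0.25, 4))
})

test_that("marginalising the right flank matches single-marker conditioning", {
  # P(maternal A | left only) must agree between the missing-flank path and
  # a direct two-point computation: P(A|11) = 1 - r1.
  r1 <- 0.12
  p <- configPriors(left = 1L, right = NA, r1 = r1, r2 = 0.3)
  expect_equal(unname(p[1, "AA"] + p[1, "Aa"]), 1 - r1, tolerance = 1e-12)
  p12 <- configPriors(left = 2L, right = NA, r1 = r1, r2 = 0.3)
  expect_equal(unname(p12[1, "AA"] + p12[1, "Aa"]), 0.5, tolerance = 1e-12)
})

test_that("priors match a meiosis-simulation oracle within Monte Carlo error", {
  # oracle: sample three-locus gametes by per-interval crossovers, form F2
  # individuals, tabulate configurations within each unordered marker class
  simulateMeioses <- function(n, r1, r2) {
    gam <- function() {
      o1 <- runif(n) < 0.5
      oq <- xor(o1, runif(n) < r1)
      o2 <- xor(oq, runif(n) < r2)
      cbind(L = o1, Q = oq, R = o2)  # FALSE = line 1 / allele A
    }
    m <- gam(); p <- gam()
    list(left = m[, "L"] + p[, "L"] + 1L,
         right = m[, "R"] + p[, "R"] + 1L,
         config = m[, "Q"] * 2L + p[, "Q"] + 1L)
  }
  set.seed(7)
  r1 <- 0.05; r2 <- 0.12
  n <- 2e5
  sim <- simulateMeioses(n, r1, r2)
  tab <- configPriorTable(r1, r2)
  for (lc in 1:3) for (rc in 1:3) {
    idx <- sim$left == lc & sim$right == rc
    freq <- tabulate(sim$config[idx], 4L) / sum(idx)
    se <- sqrt(pmax(freq * (1 - freq), 1e-6) / sum(idx))
    expect_true(all(abs(freq - tab[(lc - 1L) * 4L + rc, ]) <= 3.5 * se + 1e-4))
  }
})

test_that("phase-known priors are origin-informative and consistent", {
  r1 <- 0.1; r2 <- 0.15
  # non-recombinant maternal gamete 1-1 -> QTL allele A almost surely
  p <- orderedConfigPriors(1L, 1L, 2L, 2L, r1, r2)
  pm <- (1 - r1) * (1 - r2) / ((1 - r1) * (1 - r2) + r1 * r2)
  expect_equal(unname(p[1, "Aa"]), pm * pm)
  # Aa and aA are now distinguished
  expect_gt(p[1, "Aa"], p[1, "aA"])
  # summing the phase-known priors over phase assignments recovers the
  # unordered-class prior: check the double-heterozygote class 12/12
  tab <- configPriorTable(r1, r2)
  g <- gameteDistribution(r1, r2)
  combos <- expand.grid(mL = 1:2, mR = 1:2, pL = 1:2, pR = 1:2)
  combos <- combos[combos$mL != combos$pL & combos$mR != combos$pR, ]
  w <- numeric(4)
  for (i in seq_len(nrow(combos))) {
    pm2 <- sum(g[paste0(combos$mL[i], "A", combos$mR[i])]) +
           sum(g[paste0(combos$mL[i], "a", combos$mR[i])])
    pp2 <- sum(g[paste0(combos$pL[i], "A", combos$pR[i])]) +
           sum(g[paste0(combos$pL[i], "a", combos$pR[i])])
    pri <- orderedConfigPriors(combos$mL[i], combos$mR[i],
                               combos$pL[i], combos$pR[i], r1, r2)
    w <- w + pm2 * pp2 * pri[1, ]
  }
  expect_equal(unname(w / sum(w)), unname(tab["12/12", ]), tolerance = 1e-12)
  # missing alleles marginalise to the uniform prior
  p <- orderedConfigPriors(NA, NA, NA, NA, r1, r2)
  expect_equal(unname(p[1, ]), rep(0.25, 4))
})
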