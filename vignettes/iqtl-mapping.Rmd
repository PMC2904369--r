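---
title: "Mapping transgenerational imprinted QTLs in reciprocal F2 families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transgenerational imprinted QTLs in reciprocal F2 families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iqtlmap)
```

## The design and the model

Genetic imprinting — differential expression of the same allele depending on
its parental origin — is invisible to standard QTL mapping, which treats the
two heterozygotes Aa and aA as one genotype class. `iqtlmap` implements a
two-stage reciprocal design that exposes imprinting *and* its transmission
across generations. Two contrasting inbred lines (alleles $A$ and $a$ at a
putative locus) are crossed reciprocally, giving two F1 configurations, $Aa$
and $aA$ (maternal allele written first). All four matings among these F1s
produce four epigenetically distinct F2 families ("mating types"
$Aa \times Aa$, $Aa \times aA$, $aA \times Aa$, $aA \times aA$, mother
first), each segregating the same four ordered configurations $AA$, $Aa$,
$aA$, $aa$.

The $4 \times 4 = 16$ cell means are decomposed as $g = X\beta$ with an
orthogonal $\pm 1/0$ coding (`designMatrix()`): an overall mean $\mu$; the
F1-expressed maternal and paternal imprinting effects `i1m`, `i1p` and their
interaction `i1mp` (contrasts between mating types); the F2-expressed
additive `a`, dominance `d` and imprinting `i2` effects (contrasts between
configurations within families, with `i2` the $Aa$-vs-$aA$ contrast); and the
nine cross-generation interactions. Imprinting that is *transmitted* shows up
in `i2` and in the interaction block. Because the coding is orthogonal with
zero-sum non-mean columns, $\mu$ is always the unweighted mean of the 16
cells and the inverse mapping is the closed-form projection
`meansToEffects()`.

The published coefficient table for this decomposition is not machine-readable
in the source we worked from; the coding used here is reconstructed to
satisfy the three properties the original description states — the mean is
the grand mean, the effects fall into the documented seven groups, and the
system is full rank. Any alternative published coding can differ only by
column scaling or sign, which rescales individual effect estimates but not
likelihood-ratio tests.

## Likelihood and EM

The QTL configuration of an F2 individual is unobserved. Given flanking
markers, each individual contributes a four-component normal mixture
$$\log L = \sum_{t=1}^{4}\sum_{i=1}^{n_t}\log\sum_{k=1}^{4}
  \omega_{tik}\,\phi(y_{ti};\,\mu_{tk},\,\sigma^2),$$
with mixture weights $\omega_{tik}$ the conditional configuration
probabilities at the evaluated position and a single residual variance
shared by all 16 cells. A shared $\sigma^2$ keeps the degrees of freedom of
the test hierarchy at 13/3/10/3/3/3 and matches standard interval mapping;
a configuration-specific variance would confound mean and variance
imprinting.

`emFit()` maximises this likelihood under arbitrary zero constraints on the
15 non-mean effects. The E-step computes posterior configuration weights;
the M-step solves a weighted least-squares problem over the free columns of
the design matrix (with no constraints this is exactly the per-cell weighted
mean) and updates $\sigma^2$ as the posterior-weighted mean squared
residual. The observed-data log-likelihood is non-decreasing by
construction and is recorded per iteration (`@logLikTrace`), which the test
suite asserts on every fit. Convergence is declared when the log-likelihood
changes by less than `tol` ($10^{-8}$ by default, `maxIter = 2000`).
Because mixture likelihoods can be multimodal, the default fit runs one
deterministic start (grand mean plus graded offsets of half a phenotype SD)
and four random restarts and keeps the best; constrained fits inside
`imprintingTests()` are warm-started from the full solution, which is both
faster and keeps the null inside the basin of the same mode.

## Configuration probabilities and parental origin

The mixture weights come from three-locus gamete probabilities under the
Haldane map function (no crossover interference): every F1 parent is in
coupling phase $1\!-\!A\!-\!1 / 2\!-\!a\!-\!2$ because both grandparental
lines are fully inbred, so a gamete's probability factorises over the two
marker–QTL intervals (`gameteDistribution()`).

A point that matters greatly in practice: with *unordered* codominant marker
genotypes, the maternal and paternal meioses are exchangeable, so the
conditional probabilities of the two heterozygous configurations are exactly
equal in every marker class (`configPriors()` — the package tests assert
this symmetry). Under such weights the $Aa$/$aA$ labels are only weakly
identified through the phenotype mixture itself, and the `i2` block of
effects cannot be estimated stably. The premise of the two-stage pedigree,
however, is that allele origin is traceable: every F2 individual's maternal
gamete comes from a known F1 mother. `simulateCross()` therefore records the
transmitted maternal and paternal marker alleles (assays `"maternal"` and
`"paternal"`), and `positionPriors()` uses the origin-informative per-meiosis
probabilities (`orderedConfigPriors()`) whenever phase is available, falling
back to the symmetric unordered weights otherwise. With phase-known
transmission each meiosis pins its QTL allele with probability
$(1-r_1)(1-r_2)/\{(1-r_1)(1-r_2)+r_1r_2\}$ for a non-recombinant flanking
pair — about 0.99 for a 10 cM interval — and the full 16-parameter model is
well identified. Real data sets with only unordered genotypes can still be
analysed, but tests involving `i2` will have essentially no power; this is a
property of the data, not of the fitting algorithm.

Missing flanking genotypes are marginalised (both flanks missing gives the
uniform prior), rather than searching for the nearest informative marker;
this is exact under the two-point model used for the weights.

## The test hierarchy

Six nested null hypotheses probe imprinting at different levels
(`testConstraints()`): Test 1 fixes all 13 imprinting-related terms (overall
imprinting across both generations); Test 2 the three F1-expressed terms;
Test 3 the F2-expressed `i2` plus all nine interactions; Tests 4–6 the three
maternal, paternal and three-way interaction terms respectively. Each test
is a likelihood-ratio statistic referred to a central $\chi^2$ with df equal
to the number of extra constraints; effects are interior, sign-unrestricted
parameters, so no boundary correction is applied, and the LR is clipped at
zero against tiny negative values from finite convergence tolerances.

QTL *existence* (all 16 means equal — a 15-df contrast including
between-family differences) is tested along the genome by `scanGenome()`,
with the genome-wide threshold from `permutationThreshold()`. The default
permutation scheme shuffles phenotypes across all individuals jointly,
consistent with that null; `scheme = "within-family"` preserves family
means for users who attribute family differences to non-QTL causes (diet,
maternal environment). The scan step defaults to 2 cM. `callPeaks()` treats
two local maxima on a chromosome as distinct QTLs only when they are at
least `minSeparation` cM apart (default 30 cM, motivated by typical
interval-mapping resolution) *and* the profile dips below the threshold
between them; ties break leftmost.

## The simulator and the benchmark study

`simulateCross()` draws maternal and paternal gametes by sequential
per-interval crossover sampling (Haldane, no interference) along each
chromosome with the QTL inserted at its position, forms ordered
configurations, and adds $N(0, \sigma^2)$ noise to the cell mean, with
$\sigma^2 = V_G(1-h^2)/h^2$ and $V_G$ the variance of the 16 equally
weighted genotypic values (Mendelian segregation, equal family sizes). The
hidden truth is kept in `metadata()` for oracle checks.

The benchmark study (`runPowerStudy()`) uses a 200 cM linkage group with 10
evenly spaced markers and the iQTL 35 cM from the first marker, per-family
sizes of 300 or 500, heritabilities 0.1 or 0.4, and three effect scenarios
(`scenarioEffects()`): I — all 15 effects present (F1 imprinting 0.15/0.15/
0.1, additive 0.3, dominance 0.6, F2 imprinting 0.2, interactions 0.04,
giving $V_G = 0.4896$); II — scenario I without the F2-expressed block;
III — additive and dominance only (the global null for imprinting, used for
type-I error). Tests are evaluated at the true QTL position by default
(`fullScan = TRUE` reproduces the costlier scan-then-test protocol), with
100 replicates and $\alpha = 0.05$ — replicate counts and level chosen to
make every rejection percentage an integer on a 0–100 scale, the resolution
at which such studies are normally reported. All randomness flows from the
single `seed` argument; a fixed seed reproduces crosses, scans and power
tables bit-identically.

What the simulator does *not* emulate: genotyping error, missing genotypes,
selective genotyping, multiple or linked QTLs, polygenic background,
non-normal phenotypes, and sex-specific recombination. Passing tests on
simulated data therefore demonstrate correctness of the estimator and test
calibration under the model's own assumptions, not robustness to the
additional noise sources of a real cross.

## Numerical choices and degenerate inputs

* EM tolerance $10^{-8}$ on the log-likelihood; LR values are clipped at 0.
* Cells with zero posterior weight contribute nothing to the weighted
  least-squares solve; a singular normal system (possible when a family is
  empty) falls back to the pseudoinverse and the fit is flagged
  non-identifiable.
* `positionPriors()` at a marker position uses $r_1 = 0$, so the prior is
  degenerate on the allele carried by that marker's gamete when phase is
  known.
* Phenotype shift and scale leave all LR statistics unchanged (asserted in
  the tests).
* Map positions are 0-based cM offsets from each chromosome's first marker;
  Haldane conversions are used throughout (Kosambi helpers are provided for
  map conversion only, since $r = r_1 + r_2 - 2 r_1 r_2$ requires the
  no-interference model).

## A worked example

```{r example, eval = FALSE}
cross <- simulateCross(scenarioEffects("I"), n = 300, h2 = 0.4, seed = 1)
scan <- scanGenome(cross, step = 2)
thr <- permutationThreshold(cross, step = 2, nPerm = 200, seed = 2)
scan <- callPeaks(scan, thr, alpha = 0.05)
scan@peaks
res <- imprintingTests(cross, "1", scan@peaks$position[1])
res$tests
```

## Known limitations

* The `i2` effect block is unidentifiable from unordered autosomal marker
  genotypes (exchange symmetry); origin-informative data — recorded
  transmission phase, or in practice very dense maps plus pedigree
  reconstruction — are required.
* X-linked loci, epistasis between distinct QTLs, gene–environment
  interaction and multi-allelic systems are out of scope.
* Standard errors are reported as Monte-Carlo SDs across simulation
  replicates, not from the information matrix.
* The integrated linkage map is taken as given; map construction from the
  four families is not implemented.
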