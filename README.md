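# iqtlmap

Interval mapping of **imprinted quantitative trait loci (iQTLs)** — loci
whose effect depends on the parental origin of the allele — and of how those
parent-of-origin effects are transmitted across generations, from a
two-stage reciprocal cross between two inbred lines.

## The design and the model

Two contrasting inbred lines are crossed reciprocally, giving two F1
configurations `Aa` and `aA` (maternal allele first). All four matings among
these F1s produce four epigenetically distinct F2 families (mating types
`Aa×Aa`, `Aa×aA`, `aA×Aa`, `aA×aA`), each segregating the four ordered QTL
configurations `AA, Aa, aA, aa`. The 16 genotypic cell means are decomposed
orthogonally as

```
g(t, k) = mu + x_m·i1m + x_p·i1p + x_m x_p·i1mp           (F1-expressed imprinting)
        + z_a·a + z_d·d + z_i·i2                           (F2 additive/dominance/imprinting)
        + {x_m, x_p, x_m x_p} × {z_a, z_d, z_i} terms      (9 cross-generation interactions)
```

where `x_m, x_p = ±1` code the mother's and father's F1 configuration and
`z_a, z_d, z_i` code the F2 configuration (`z_i` is the `Aa`-vs-`aA`
parent-of-origin contrast). Because the configuration is unobserved, the
phenotype of each F2 individual is a four-component normal mixture with
marker-conditional weights, fitted by EM under arbitrary zero constraints;
a hierarchy of six likelihood-ratio tests (13/3/10/3/3/3 df) probes
imprinting expressed in the F1, in the F2, and in their interactions.
Genome scans use the existence LR with permutation thresholds.

The package is Bioconductor-style S4: a cross is a `ReciprocalCross`
(extends `SummarizedExperiment`; genotype/phase assays, map in `rowData`,
family and phenotype in `colData`), fits are `IQTLFit`, scans `IQTLScan`,
simulation studies `IQTLPowerStudy`.

## Worked example

```r
library(iqtlmap)

cross <- simulateCross(scenarioEffects("I"), n = 300, h2 = 0.4, seed = 1)
res <- imprintingTests(cross, chromosome = "1", position = 35)
res$fit
#> IQTLFit: 16 free effects
#>   logLik: -1604.24  sigma2: 0.7317  iterations: 18
#>      mu     i1m     i1p    i1mp       a       d      i2   i1m_a   i1m_d  i1m_i2
#> -0.0021  0.1548  0.1364  0.0919  0.2975  0.5497  0.2046  0.0031  0.0536  0.0479
#>   i1p_a   i1p_d  i1p_i2  i1mp_a  i1mp_d i1mp_i2
#>  0.0440  0.0328 -0.0005  0.1055 -0.0045  0.0698
res$tests
#>    test      lr df    pvalue
#> 1 test1 109.627 13 2.210e-17
#> 2 test2  70.263  3 3.748e-15
#> 3 test3  41.967 10 7.600e-06
#> 4 test4   5.041  3 1.688e-01
#> 5 test5   2.687  3 4.425e-01
#> 6 test6  10.429  3 1.525e-02
```

The simulated truth has F1 imprinting 0.15/0.15/0.1, additive 0.3, dominance
0.6, F2 imprinting 0.2 and interactions 0.04: the fit recovers them, the
overall (Test 1), F1-expressed (Test 2) and F2-expressed (Test 3) imprinting
tests reject decisively, and the small interaction blocks (Tests 4–6) are
borderline at this sample size, as expected.

A genome scan on real or simulated CSV data:

```r
map   <- readMarkerMap("map.csv")       # marker,chromosome,position_cM
cross <- readCrossFile("cross.csv", map)  # family,individual,phenotype,<markers>
scan  <- scanGenome(cross, step = 2)
thr   <- permutationThreshold(cross, step = 2, nPerm = 1000, seed = 7)
scan  <- callPeaks(scan, thr, minSeparation = 30, alpha = 0.05)
scan@peaks
```

A command-line front end wrapping the same functions (subcommands
`simulate`, `scan`, `test`, `power`) is at `inst/scripts/iqtl.R`.

**Note on identifiability.** With unordered codominant genotypes the two
heterozygous configurations receive exactly equal mixture weights
(maternal/paternal exchange symmetry), so the F2 parent-of-origin block
(`i2` and its interactions) is only identified when allele origin is
traceable. Simulated crosses record the transmitted maternal/paternal
alleles (phase-known assays, written to CSV as `1|2`-style codes with
`writeCrossFile(ordered = TRUE)`), and `positionPriors()` uses them
automatically. See the vignette for details.

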