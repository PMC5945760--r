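# karyoDosage

Read-depth karyotyping of a synthetic segmental allotetraploid rice
population (*Oryza sativa* japonica × indica, 2n = 4x = 48), for
geneticists working with low-pass whole-genome resequencing of polyploid
populations. Selfed progeny of such newly formed tetraploids segregate
diverse aneuploids — gains and losses of whole chromosomes, chromosome
arms, and compensating combinations — and this package implements the
complete pipeline from 10-kb binned read counts to per-individual
karyotype calls and population-level statistics, together with a seeded
count-level coverage simulator that calibrates and tests the caller
against known truth.

## The method

For an individual with $R_i$ reads on chromosome $i$ (total $R$, relative
chromosome size $s_i$ with $s_1 = 1$), the per-chromosome **Key value**
and normalized coverage are

```
key_i = R_i * 12 / (R * s_i),        v_i = key_i / mean(key)
```

so a proportionally covered euploid gives $v_i = 1$ everywhere, with no
need for a euploid control individual. A chromosome at dosage $4+\delta$
(others euploid) has expected value $v(\delta) = (1 + \delta/4) \cdot 12 /
(12 + \delta/4)$; simulating single-chromosome gains and losses at 1×
depth recovers the calling thresholds $v(+1) = 60/49 \approx 1.2245$ and
$v(-1) = 36/47 \approx 0.766$. Calling proceeds in two criteria, mirroring
the original analysis: thresholded whole-chromosome dosage (with an
integer-dosage baseline refinement so that compound karyotypes with
several co-gained chromosomes stay on the calling scale), then arm-level
refinement from the 10-kb window distributions, which detects segmental
(S/L-arm) aneuploidy. Downstream statistics include exact binomial
gain-vs-loss tests, exact Poisson tests, a Poisson-permutation
prone/resistant classification of the 12 chromosomes, reciprocal-cross
comparison, factor correlations, euploid-vs-aneuploid trait comparison,
and a karyotype-specific association screen.

See the methods vignette (`vignettes/karyotyping-methods.Rmd`) for the
model, its assumptions, and every numerical choice.

## Worked example

Derive thresholds, simulate a small population at 1× depth with the
observed karyotype frequencies, and call it:

```r
library(karyoDosage)

g   <- riceGenome()                                   # 12 chromosomes, 10-kb windows
thr <- deriveThresholds(g, SimConfig(g, meanDepth = 1, seed = 7L), nReps = 3)
thr
#> ThresholdSet: average gain 1.2240, average loss 0.7660 (multinomial, 1x, 3 reps)

pop   <- simulatePopulation(karyotypeFrequencies(), 12,
                            SimConfig(g, meanDepth = 1, seed = 7L))
calls <- callPopulation(pop, thr)
head(callSummary(calls), 3)
#>   individual_id          karyotype_string category is_segmental is_hidden chromosome_number
#> 1        ind001 +1Chr05; +1Chr08; -1Chr12 compound        FALSE     FALSE                49
#> 2        ind002                        WT  euploid        FALSE     FALSE                48
#> 3        ind003                        WT  euploid        FALSE     FALSE                48
```

The derived thresholds sit on the closed-form values 60/49 and 36/47;
individual 1 is a compound aneuploid (49 chromosomes), and every call
carries its classification. The bundled 55-karyotype table reproduces the
population analytics of the observed data:

```r
s <- tabulateKaryotypes(riceKaryotypeTable(), nEuploid = 188)
c(s$aneuploidPlants, s$distinctKaryotypes)          # 124 aneuploids, 55 karyotypes
binomialGainLoss(49, 35)
#> [1] 0.1556565                                      # gain vs loss, simple aneuploidy

prop <- propensityClassification(s$perChromosome$combined,
                                 nPerm = 10000, seed = 7L)
prop[prop$classification != "neutral", ]
#>    chrom count classification
#> 1  chr01     3      resistant
#> 3  chr03     2      resistant
#> 4  chr04    24          prone
#> 9  chr09    24          prone
#> 11 chr11    27          prone
```

Chromosomes 1 and 3 fall below the 5%-probability permutation threshold
(resistant to aneuploidization), chromosomes 4, 9 and 11 above the
95%-probability threshold (prone).

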