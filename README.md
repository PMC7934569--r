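# cosegscan

Marker–trait analysis for recessive monogenic traits in biparental plant
populations, built around the hydrangea (*Hydrangea macrophylla*)
double-flower breeding problem: the double-flower phenotype is a recessive
trait controlled by a single major locus (two such loci are known, *d_jo*
and *d_su*, from different double-flower founders), and breeders need DNA
markers that identify the recessive allele in seedlings long before the
plants flower.

The package is for plant geneticists and breeders who have SNP genotype
calls (e.g. from ddRAD-Seq) for an F2 or similar biparental population
plus a phenotype score per individual, and who want to

* localise the recessive locus by scanning every SNP for co-segregation
  with the trait,
* turn a co-segregating SNP into a screening assay — a CAPS marker
  (restriction digestion of a PCR amplicon) or an INDEL fragment-size
  marker — and
* genotype and classify new accessions with those markers
  (marker-assisted selection).

## The statistic at the core

For a biparental population segregating a recessive allele *d* carried by
the double-flower parent, each SNP's individuals split into three
genotype classes: homozygous for the double-parent allele, heterozygous,
and homozygous for the single-parent allele. The recessive single-locus
model predicts the double phenotype exactly for the first class. With
(d₁, n₁), (d₂, n₂), (d₃, n₃) the (double-phenotype, total) counts per
class — missing genotypes and unknown phenotypes excluded — the **degree
of agreement** of the SNP with the model is

    A = 100 × [ d₁ + (n₂ − d₂) + (n₃ − d₃) ] / (n₁ + n₂ + n₃)   (%)

A = 100 means zero observed recombinants (complete co-segregation). For a
marker at recombination fraction *r* from the causal locus in an F2, the
expected agreement is `50 + 50(1 − r)²` percent, so even an unlinked
marker (*r* = 0.5) scores 62.5 % — which is why the scan reports the
*> 95 %* and *= 100 %* sets rather than a naive ranking.

## Worked example

Replay the bundled per-SNP class-count table for the *d_jo* F2 population
(147 offspring) through the full scan:

```r
library(cosegscan)

fx  <- table_fixture(djo_marker_counts())
fit <- coseg_scan(fx$genotypes, fx$phenotypes,
                  cross_model("P_double", "P_single"))
print(fit, n = 9)
#> Recessive-model co-segregation scan (F2 design)
#>   9 informative SNPs over 147 offspring (0 uninformative)
#>               id chrom      pos agreement
#>     0259F_404610 CHR17 33708714     100.0
#>     1207F_365533 CHR17 34478996     100.0
#>     1207F_372121 CHR17 34485554     100.0
#>   0008F-2_780104 CHR17 43626384     100.0
#>  0008F-2_3250598 CHR17 43855890     100.0
#>  0008F-2_3250523 CHR17 43855965     100.0
#>     0994F_216439 CHR17 35213652      97.9
#>     0437F_170787 CHR17 35610977      97.9
#>     0437F_170821 CHR17 35611011      97.9

rep <- threshold_report(fit, 95)
nrow(rep$above); nrow(rep$cosegregating)
#> [1] 9
#> [1] 6
infer_locus_interval(rep$cosegregating)
#>   chrom start_bp   end_bp start_mb end_mb
#> 1 CHR17 33708714 43855965     33.7   43.8
```

Nine SNPs exceed 95 % agreement, six co-segregate completely, and the
recessive locus maps to 33.7–43.8 Mb on CHR17. The same pattern holds for
the CAPS assay built on one of the co-segregating SNPs:

```r
taqi <- load_enzymes()[["TaqI"]]
# toy 167 bp amplicon for the recessive allele: one TaqI site after bp 117
amp <- paste0(strrep("AC", 58), "TCGA", substr(strrep("AC", 24), 1, 47))
digest(amplicon_allele("117_50", amp), taqi)
#> TaqI digest: 1 cut(s); fragments 117 + 50 bp
```

i.e. the 167 bp amplicon of the recessive allele is cut into 117 + 50 bp,
while the dominant allele stays undigested — a seedling showing only the
117/50 pattern is predicted double-flowered. Fully synthetic populations
(Haldane recombination, negative-binomial read depth, configurable error
and missingness) come from `simulate_population(sim_config(...))`; see
the vignette in `vignettes/` for the model, the simulator's assumptions
and all numerical conventions.

A command-line wrapper for the pipeline (simulate / scan / design-caps /
sizes / genotype) is installed at `inst/scripts/cosegscan-cli.R`.

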