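---
title: "Co-segregation scanning and marker design for a recessive double-flower locus"
author: "cosegscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-segregation scanning and marker design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosegscan)
```

## The genetic model

The double-flower phenotype of hydrangea behaves as a recessive trait
controlled by a single major gene with full penetrance: an individual is
double-flowered if and only if it carries two copies of the recessive
allele *d* inherited from the double-flower founder. In an F2 between a
double-flowered parent (*dd*) and a single-flowered parent (*DD*), loci
therefore segregate 1:2:1 and one quarter of offspring are expected
double. A second supported design, the carrier cross (double parent ×
phenotypically single heterozygote), segregates 1:1.

Everything in the package evaluates SNPs against the prediction

> *double phenotype ⇔ homozygous for the allele contributed by the
> double-flower parent.*

### The degree-of-agreement statistic

At one SNP, genotyped and phenotyped offspring fall into three classes:
homozygous for the double-parent allele, heterozygous, homozygous for the
single-parent allele. With class pairs $(d_i, n_i)$ of
(double-phenotype, total) counts, `score_agreement()` computes

$$A = 100\,\frac{d_1 + (n_2 - d_2) + (n_3 - d_3)}{n_1 + n_2 + n_3}\ \%$$

$A$ is the fraction of individuals whose phenotype matches the model.
Under the F2 design a marker at recombination fraction $r$ from the
causal locus has expected agreement $50 + 50(1-r)^2$ — derived by
enumerating the four F1 gamete types (parental combinations at frequency
$(1-r)/2$, recombinants at $r/2$) over all sixteen gamete pairings; the
package validates the closed form against that brute-force enumeration
in its tests before using it as an oracle. Two consequences matter for
interpretation: an unlinked marker still scores $62.5\%$, so absolute
agreement values are only meaningful near the top of the scale, and
$A = 100$ is equivalent to zero observed recombinants.

### Conventions that affect reported numbers

These choices were genuinely open and are fixed as follows:

* **Exclusions.** Missing genotypes and unknown phenotypes are removed
  from both numerator and denominator, per site. This is why class
  denominators vary between SNPs scored on the same population.
* **Rounding.** Agreement is stored at full precision; displays round
  *half-up* to one decimal (143/146 → 97.9). Threshold comparisons
  (`threshold_report()`, default 95) are strict (`>`) on the unrounded
  value, and the co-segregating set is exactly $A = 100$, which is exact
  in floating point because it arises from integer equality of numerator
  and denominator.
* **Interval endpoints.** `infer_locus_interval()` spans the positioned
  co-segregating SNPs and *truncates* endpoints to 0.1 Mb (floor):
  43,855,965 bp reports as 43.8 Mb. Rounding instead of truncating would
  misstate the upper end. SNPs not assigned to a pseudomolecule are
  excluded from the interval but still scanned.
* **Orientation.** Sites are informative only when the parents' calls
  identify the double-parent allele (F2: opposite homozygotes; carrier
  cross: homozygous double parent, heterozygous partner). Heterozygous
  coding is unphased and the reference strand is never flipped.
* **Ties.** Scan results sort by descending agreement, then chromosome,
  then position.

## Genotype filters

Two missingness conventions coexist deliberately, mirroring the two
filtering stages a ddRAD pipeline applies:

* `apply_depth_missing_rule(min_depth = 5)` — a call under 5 reads
  becomes missing; a call at exactly 5 is kept. The threshold is exposed
  as a flag because depth cutoffs are pipeline-specific.
* `filter_by_missingness(max_missing_fraction = 0.05)` — the scan-stage
  filter drops a site when its missing fraction is **at or above** the
  threshold (5 missing in 100 samples ⇒ dropped).
* `select_map_snps(min_depth = 5, min_quality = 10, max_missing = 0.5)` —
  the map-SNP filter follows the VCFtools `--max-missing` convention and
  **keeps** a site at exactly the boundary, after dropping sites below
  the quality floor.

All filters are pure row/cell masks: surviving calls keep their state and
depth, which makes every filter idempotent (property-tested).

## The population simulator

`simulate_population()` exists so the whole pipeline is testable without
any sequencing data. It emulates the structure the scan assumes:

* **Meiosis.** Gametes are drawn under Haldane's map function
  ($r = (1 - e^{-2d/100})/2$, no interference), independently per
  interval, over the markers plus the causal locus. Kosambi-style
  interference is irrelevant to the pairwise marker–locus properties the
  package tests, so the simpler model is used.
* **Phase.** The double parent is homozygous for the alternate allele at
  every marker and for the recessive causal allele, so marker and causal
  alleles are in coupling and the emitted VCF's `alt` is always the
  double-parent allele (stated in the VCF header source tag convention).
* **Defaults as study conditions.** 147 F2 offspring; nine markers on
  one chromosome spanning 33.7–43.9 Mb with a fully linked cluster and
  flanking markers a few cM away; negative-binomial read depth with mean
  20 and dispersion 5 (overdispersed, ddRAD-like); flat per-genotype
  error 0.005 and per-call missingness 0.03, typical magnitudes for
  reduced-representation genotyping. Calls below the depth threshold are
  still emitted — filtering is the pipeline's job, and the depth model
  is exactly what the depth rule is meant to police.
* **Noise knobs.** Both site-driven (`missing_rate`) and sample-driven
  (`sample_missing_rate`) missingness are available because the true
  mechanism in ddRAD data varies by library; the default is site-driven
  only. The flat per-genotype error is the simplified mode; a read-level
  misread model was considered and rejected as adding parameters the
  tests cannot constrain.
* **Parents.** Parent rows are emitted noise-free at depth ≥ 5. Real
  studies genotype and often re-verify the parents; leaving parental
  calls noisy would make allele orientation fail sporadically for
  reasons unrelated to what a test exercises. This is a simplification:
  real parental calls do fail, and the scan handles that by flagging
  sites uninformative.
* **Determinism.** A fixed seed yields byte-identical output files.

What passing simulator-based tests does **not** show about real data:
there is no linkage-map error, no reference bias, no allele-specific
dropout correlated with restriction sites, no segregation distortion,
and penetrance is exactly 1. The simulator validates the statistics and
the plumbing, not the sequencing process.

`table_fixture()` complements the simulator: it rebuilds a deterministic
population from printed per-SNP class-count rows (greedy assignment of
double- and single-phenotype individuals to genotype classes, missing
calls where a site's denominators fall short of the population), so a
published count table can be replayed through the identical scan code
path. Scanning such a fixture reproduces the input counts exactly
(property-tested), which is what the bundled *d_jo* (n = 147) and *d_su*
(n = 93) tables are for.

## Marker design

* **CAPS screening.** `find_sites()` matches an enzyme's IUPAC
  recognition pattern (Biostrings matching, ambiguity codes expanded)
  on the given strand; each occurrence cuts after
  `site_start − 1 + cut_offset`. `digest()` returns inter-cut fragment
  lengths, which always sum to the amplicon length. `caps_screen()`
  keeps enzymes whose fragment-length multisets differ between the two
  allele sequences. Sites are matched on the reference strand only by
  default — TaqI's T^CGA site is palindromic so this suffices for the
  bundled markers; `both_strands = TRUE` exists for non-palindromic
  enzymes. Digestion is modelled as complete; partial digests are out of
  scope.
* **INDEL sizing.** `predict_indel_allele_sizes()` subtracts each
  allele's deletions from the reference product (280 → 250 → 236 bp for
  the bundled S01 marker, from 30 bp and 14 bp deletions) and refuses
  tables whose alleles collide within the sizing tolerance. Product
  sizes are modelled as the scored sizes; a fluorescent adapter tail on
  the physical product is implicit in them.
* **Genotype calling.** `call_fragment_genotype()` matches observed band
  sizes against expected signatures within a tolerance — 1 bp by default
  (capillary fragment analysis); the CAPS table uses 0 because its
  alleles differ by ≥ 14 bp on a gel. A size no allele explains becomes
  a distinct novel allele labelled by its measured size (the bundled
  accession table contains a 282 bp example); sizing variance as an
  alternative explanation was considered and rejected because 282
  recurs in two accessions. More than two alleles is a ploidy error.
* **Classification.** `classify_accession()` predicts *double* iff the
  accession is homozygous for the recessive allele at ≥ 1 marker and
  reports the explaining locus and carrier status — the decision rule of
  marker-assisted selection with two independent recessive loci.

## Degenerate inputs and numerical edges

Empty VCF bodies give a 0-site matrix with the header's samples; a scan
with no informative site is a warning plus an empty report, not an
error; agreement over zero individuals, fragment calls matching nothing,
and >2-allele matches raise classed errors (`usage` vs `data`) that the
CLI maps to exit codes 2 and 3. `round_half_up()` is used everywhere a
percentage is displayed; base `round()`'s half-to-even rule is never
applied to reported values.

## Problem sizes used in the test-suite

Stochastic properties are checked at sizes chosen to make Monte-Carlo
noise negligible relative to the asserted tolerance: 100,000 gametes for
the Haldane recombination fraction (±0.003), 10,000 offspring for the
1:2:1 chi-square (α = 0.001) and for the agreement-vs-closed-form grid
over r ∈ {0, 0.05, 0.1, 0.25, 0.5} (±2 percentage points). The whole
suite runs in well under a minute on one core.

## Known limitations

* The scan localises by co-segregation only; it is not interval mapping
  and produces no LOD scores or genetic-map ordering.
* Biallelic SNPs only at the VCF boundary; the scan itself also accepts
  indel-style alleles when given a pre-built genotype matrix (the *d_su*
  replay uses two such sites), but `read_vcf()` skips non-SNP records by
  design.
* Single-locus model: two unlinked recessive loci are handled at the
  classification stage (J01/S01-style marker pairs), not in the scan
  itself.
* No primer design: amplicon sequences and primer pairs are taken as
  given.
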