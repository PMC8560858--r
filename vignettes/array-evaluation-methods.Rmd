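---
title: "Evaluating SNV genotyping arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating SNV genotyping arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrayscope)
```

# What this package evaluates

Choosing a genotyping array involves trade-offs that are hard to read off a
vendor manifest: how much of common genome-wide variation the array captures
directly or through linkage disequilibrium (LD), how well its content
supports imputation across ancestries, and whether clinically interesting
content — known GWAS markers, actionable-gene variants, pharmacogene and HLA
star alleles, mitochondrial loci — is actually assayable. `arrayscope`
implements each of those comparisons as a function over plain tibbles, so
the same metrics can be computed for any manifest against any phased
reference panel.

# Genome-wide coverage from LD tagging

The coverage model treats the array as a set of tag SNVs against a phased
reference haplotype panel. For an ancestry subset, the panel is first
restricted to variants with minor allele frequency (MAF) of at least 1%
(inclusive; most arrays are designed for common variation, and comparing
rarer content would mostly measure panel noise). A panel SNV not on the
array counts as *tagged* when some array SNV on the same chromosome within
the search window has squared haplotype correlation strictly above 0.8.
The coverage rate is then

$$CR = \frac{\frac{L}{R-T}(G-T) + T}{G}$$

with `L` the number of tagged off-array panel SNVs, `R` the filtered panel
size, `T` the total number of variants on the array, and `G` the assumed
number of common SNVs in the genome (19 million by default, configurable —
the figure is an order-of-magnitude estimate from variant databases). The
equation extrapolates the panel-level tagged fraction `L/(R−T)` to the
`G−T` SNVs the panel does not represent, then adds the array's own content.

Numerical conventions worth knowing:

* **r² formula.** We use the standard haplotype-based
  $D^2/(p_A p_a p_B p_b)$, computed as the squared Pearson correlation of
  0/1 haplotype indicator vectors (the two are algebraically identical).
  Monomorphic variants have undefined r²; they are signalled as `NA` and can
  never tag or be tagged.
* **Strict thresholds.** A pair at exactly r² = 0.8 is *not* tagged; the
  rule is "greater than".
* **Search window.** LD is only evaluated within a 1 Mb flanking window by
  default. This bounds the otherwise quadratic cost; a property test
  verifies that windowed tagging equals brute-force all-pairs tagging
  whenever the window spans the chromosome, so the window is purely a
  performance device at human LD scales.
* **Double counting.** `L` counts only off-array panel SNVs; array SNVs
  enter the equation through `T` alone, including probes the panel does not
  contain (by the symbol definitions, `T` is total array content).
* **Multi-allelic sites** in VCF input are decomposed to biallelic records;
  indels are excluded from LD computation since the coverage object is SNV
  variation.

`taggability()` reports the complementary upper bound: the fraction of
panel SNVs tagged by *another* panel SNV, with self-pairs excluded (and
only self-pairs — no further exclusion by variant class).

# Imputation evaluation

Pre-imputation QC (`qc_filter()`) applies, in order: SNV call rate
< 0.975, sample call rate < 0.975, Hardy–Weinberg exact-test p < 1e−7 on
autosomes, and excess heterozygosity. The HWE test is the exact conditional
test (enumeration of heterozygote counts given the allele counts, summing
probabilities no larger than the observed configuration), computed in log
space for stability. The excess-heterozygosity rule — which standard QC
names without quantifying — is implemented as a sample inbreeding
coefficient more than 4 SD below the cohort mean, the convention used by
common GWAS pipelines.

Imputed variants are binned twice: by MAF into ultra-rare (< 0.5%), rare
(0.5–1%), low-frequency (1–5%) and common (> 5%) — boundaries are
left-closed/right-open, so MAF 0.01 is low-frequency — and by imputation
R² into low (< 0.3), medium (the closed interval [0.3, 0.8]) and high
(> 0.8). R² is taken from the imputation service's per-variant output; we
do not recompute dosage correlations.

Concordance against exome sequencing (`per_individual_concordance()`)
matches variants on full `(chrom, pos, ref, alt)` identity (strand flips
are not rescued) and compares, per sample, genotypes non-missing in both
callsets. In the ultra-rare and rare bins, homozygous-reference calls are
first masked to missing in *both* callsets: at those frequencies nearly
every genotype is hom-ref, and unmasked concordance would be ~1 regardless
of quality. A sample left with zero comparable genotypes is reported as
undefined and excluded from the aggregate mean.

# GWAS-catalog coverage

`filter_catalog()` reduces a catalog export to clinically interpretable
markers by, in order: odds ratio reported, risk allele frequency reported,
p ≤ 5e−8 (inclusive), removal of duplicate phenotype–locus associations,
case–control design, disease phenotype, and journal impact factor (2019)
strictly above 5. The step order is fixed and the report records per-step
removals, so the filter reconciles exactly and any reordering is
auditable. Duplicates are identified as identical `(trait, rsid)` pairs,
keeping the smallest p (position-based matching would be a defensible
alternative; rsid matching is what catalog exports support directly).
Disease classification uses an explicit `trait_class` column when present
and otherwise a keyword blocklist of non-disease traits that ships with the
package and can be replaced. Hand-curated markers (such as the two causal
APOE coding variants, which scans only see through a nearby tag) can be
appended with `append_extra_markers()`.

Marker coverage counts a marker as genotyped when its position is on the
array, or as covered after imputation when imputed with R² strictly above
0.8.

# Gene-category metrics

* **Actionable genes.** Variants with CADD phred strictly above 20
  (roughly the top 1% most deleterious) falling in the gene set are
  counted per gene; medians and IQRs are over the full gene list including
  zero-count genes. Because genes may overlap, per-gene counts can count a
  variant twice; a distinct-variant total is reported alongside.
* **Star alleles.** An allele is callable only if *every* tag SNV in its
  definition is assayable (all-or-nothing — a partial haplotype does not
  identify the allele). Tag matching requires position and allele identity
  by default; position-only matching is available behind a flag. In imputed
  mode a tag also counts when imputed with R² > 0.8; identifiability, not
  sample-level calling, is what is evaluated, so genotypes are never
  inspected. Alleles defined by copy-number events rather than tag SNVs are
  `not_evaluable` — calling them needs CNV analysis, which is out of scope.
* **HLA.** Tag sets are ancestry-specific, so percentages are computed per
  ancestry and summarised per gene as mean and SD across ancestries. We
  report allele-level percentages only; "fraction of the population
  covered" would need allele frequencies and is deliberately not computed.
* **mtDNA.** Mitochondrial functional loci overlap, so a variant counts in
  every locus containing it while the total counts distinct variants. A
  75-locus synthetic example table ships in `extdata` (generated, not
  copied from any annotation resource).
* **Density.** CDS density is the identity `distance = length / (n + 1)`;
  window density uses fixed non-overlapping windows anchored at position 1,
  with empty windows included in the mean and SD.

# The synthetic-data generators

All inputs can be simulated (`simulate_*`), so the full pipeline runs and
is tested without restricted cohort data. The panel generator uses a
block-copy founder model rather than a coalescent: each block carries
founder haplotypes (two complementary ones by default), each sampled
haplotype copies one founder per block and then flips alleles at a small
mutation rate (0.002 by default). This makes LD structure analytic —
within-block r² is 1 up to mutation noise, between-block r² is sampling
noise — which is exactly what coverage code needs to be tested against;
it does not produce realistic genealogies, recombination maps, or
site-frequency spectra, so passing tests say the *estimators* are right,
not that any particular array will achieve a given coverage on real data.
The default ancestry split (EUR 379, ASN 286, AFR 246 diploids) mirrors
the continental grouping of the public phase-3 reference panel this kind
of comparison is usually run against; test fixtures use smaller sizes
where the property under test permits it, stated per test.

Design choices shared by all generators:

* **Seed determinism.** Every generator runs under a locally seeded RNG
  and restores the caller's RNG state; identical seed and config give
  bit-identical output.
* **Emitted truth.** Generators return machine-readable truth (covered
  blocks, callable flags, planted filter failures) next to the data; tests
  compare results to construction, never to re-derivations from the data.
* **Imputation model.** Off-array R² is drawn from a Beta distribution
  whose mean follows a logistic curve in log10(MAF) (mean ≈ 0.98 at MAF
  0.5, ≈ 0.7 at MAF 0.01), reproducing the qualitative degradation of
  imputation quality with rarity; on-array variants get R² = 1.
* **Exome pairs.** The synthetic exome copy flips each non-missing
  genotype to one of the other two states with probability `e` (default
  0.01), so expected discordance is exactly `e`.

The test suite exercises the estimators at the scales the properties
require — for example tagging-fraction recovery on a 5,000-SNV,
200-diploid panel and flip-rate recovery over one million genotype
comparisons — while oracle-equivalence checks (brute-force all-pairs LD,
full HWE enumeration) run on many small random fixtures.

# Degenerate inputs and edge rules

* Duplicate manifest rows collapse to the first occurrence with a warning.
* Chromosome labels are normalised (`chr` prefix stripped, `M` → `MT`);
  unknown labels are errors, not silently dropped.
* BED input is converted from 0-based half-open to internal 1-based
  coordinates on read and back on write, so round-trips are exact.
* Inter-array overlap matches on `(chrom, pos)` only, as array content
  comparisons conventionally do; a strict-allele mode exists behind a
  flag. Multi-allelic positions are counted once per distinct position.
* `coverage_rate()` refuses `R ≤ T` (the extrapolation is undefined) and
  `L > R − T`.
* Monomorphic variants, empty bins, all-masked samples and genes with no
  defined alleles are reported as undefined (`NA`) rather than 0 or 100.

# Limitations

Probe chemistry, cluster quality, strand flips, CNV calling from
intensities, liftover between builds, running imputation itself, and PRS
construction are all out of scope: manifests, imputed callsets and
annotations are *inputs*. Real-data coverage numbers depend on the
reference panel used and on QC upstream of this package; the synthetic
generators are designed for testability, not realism.
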