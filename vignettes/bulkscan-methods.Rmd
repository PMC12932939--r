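---
title: "Methods: SNP-index bulked segregant analysis with a simulated RIL pool-seq design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-index bulked segregant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkscan)
```

## The problem and the statistic

Bulked segregant analysis (BSA-seq) maps quantitative trait loci by
sequencing pooled DNA from the two phenotypic extremes of a segregating
population. bulkscan implements the QTL-seq flavour of this analysis for
biparental recombinant inbred line (RIL) populations: at every marker
where the two parents are homozygous for opposite alleles, the **SNP
index** of a pool is the fraction of its reads carrying the allele of one
designated parent (parent B by default; the orientation is configurable
and the downstream statistic is orientation-invariant in magnitude). The
**delta SNP index** is

$$\Delta\mathrm{SNPindex} = \mathrm{SNPindex}_{high} - \mathrm{SNPindex}_{low},$$

which is near 0 at unlinked loci and deviates towards $\pm 1$ near a
locus that differentiates the high and low pools.

The motivating use case is nitrogen use efficiency (NUtE, whole-plant dry
weight per gram of plant nitrogen, g·g⁻¹) in a cereal RIL population: 120
F8 lines from a biparental cross, 15 + 15 extreme-NUtE bulks, roughly 23×
pooled coverage. The package treats those numbers as its default study
design throughout, but every one of them is a parameter.

## Pipeline stages

1. **Marker selection** (`read_allele_depths()`,
   `select_homozygous_polymorphic()`): biallelic SNPs with per-sample
   allele depths (VCF `AD`); each parent needs depth ≥ 7 and minor-read
   fraction ≤ 0.1, and the parents must carry opposite alleles. The depth
   floor reuses the pool-depth floor below, a choice the package makes
   explicit because no separate parental threshold is conventional.
2. **SNP index and filters** (`compute_snp_index()`,
   `apply_marker_filters()`, `compute_delta()`): a locus is dropped when
   its index is below 0.3 in *both* pools (error-removal rationale from
   QTL-seq practice: a locus where only one pool is low may be a real
   signal), when its depth is below 7 in *either* pool (one
   under-sequenced pool makes the contrast unreliable), or when an index
   is missing in any pool. Missingness is a distinct state, never coerced
   to zero. The clause grouping is a documented reading of common
   practice; both thresholds are configurable.
3. **Sliding-window scan** (`window_scan()`): 1-Mb windows advanced in
   100-kb steps, anchored at position 1 of each chromosome, final windows
   truncated at the chromosome end. The window statistic is the
   unweighted mean delta of member markers; windows with fewer than
   `min_markers = 3` markers are reported but carry a missing mean, so a
   single-marker spike can never drive a call.
4. **Genome-wide threshold** (`permutation_null()`,
   `threshold_from_null()`): per iteration the per-locus indices are
   regenerated under a no-QTL null, the identical window scan is re-run,
   and the genome-wide maximum |windowed delta| is recorded; the
   95th percentile of those maxima (linear-interpolation percentile,
   R's quantile type 7, documented for bit-exactness) is the
   significance threshold. 1,000 iterations by default.
5. **Region calls and candidates** (`call_regions()`,
   `genes_in_regions()`, `join_deg()`, `prioritize()`): windows at or
   above the threshold merge when overlapping or book-ended; genes
   overlap a region and must carry a nonsynonymous, stop-gain or
   stop-loss variant inside it; candidates additionally need
   |log2FC| > 1 and FDR < 0.05 in a supplied differential-expression
   table (a stricter |log2FC| > 3, FDR < 0.01 preset is available);
   priority flags mark linear |fold change| > 4, ranked by |fold change|
   with lexicographic tie-breaks. Genes absent from the DEG table are
   reported separately rather than silently dropped.

## Choice of the null scheme

What exactly to resample is the one genuinely open design question in
this pipeline, and the three options the package ships differ in which
noise sources they regenerate. Two sources contribute to the delta field
under a no-QTL null:

* **read sampling**: Binomial(depth, freq) noise per locus per pool,
  independent across loci; and
* **pool composition**: each pool is a finite draw of lines, so its true
  allele frequency deviates from 1/2, and — critically — those
  deviations are *correlated across linked markers* because the same
  lines contribute their whole haplotypes.

`label_swap` (swap the two pools' values locus-wise with probability 1/2)
preserves the marginal distribution at each locus but destroys the
linkage autocorrelation; `binomial_null` (redraw reads at frequency 1/2)
drops composition noise entirely. Measured at the default design, their
genome-wide thresholds are anti-conservative: the observed genome-wide
maximum of truly null data exceeds the label-swap threshold in roughly a
quarter of datasets, and the binomial threshold almost always. Both
remain available (`scheme =`) because they are cheap, familiar and
useful for diagnostics, but neither is the default.

The default, `ril_null`, is model-based: per iteration each pool's line
composition is simulated as independent two-state inbred-line genotype
chains along the observed marker positions, with state-switch probability
between adjacent markers equal to the Haldane–Waddington RIL
recombination fraction $R = 2r/(1+2r)$ (Haldane $r$ from physical
distance at `cm_per_mb`, default 3), the pooled true frequency is the
mean over lines, and reads are then drawn Binomial(observed depth,
frequency). This regenerates both noise sources with the right
autocorrelation; its empirical type-I rate at the default design sits at
the nominal 5% (checked in the test suite over hundreds of simulated
null datasets). Its approximations are documented and deliberate: the
chain uses the fixed-line ($F_\infty$) recombination fraction rather than
F8 (residual F8 heterozygosity is $2^{-7} \approx 0.8\%$), treats
recombination as Markov along a chromosome, and needs a genetic-to-
physical rate the user must supply for real data. The scheme is a
parametric simulation null rather than a permutation in the strict
exchange sense — the same tradition as coverage-based QTL-seq confidence
bands — and the threshold it yields is slightly conservative in our
checks, which costs a little power but keeps region calls honest.

## The synthetic-data generator

The generator is first-class, tested code; it produces every input the
pipeline consumes with the statistical structure the analysis assumes.

* **Genetics** (`simulate_ril_genotypes()`): each line is an independent
  single-seed-descent lineage from a heterozygous F1; each generation
  draws two gametes per line with crossovers at Haldane recombination
  fractions, no interference. Residual heterozygosity halves each
  generation, $(1/2)^{n-1}$ at F$_n$ — a property the tests assert.
* **Trait** (`assign_phenotypes()`): baseline + additive effect × B-dose
  (0/0.5/1) + Normal residual. One major QTL, no epistasis.
* **Pools** (`sample_pool_depths()`): pooled frequency is the exact mean
  dose over member lines; depth is Poisson per locus per pool (23 by
  default); reads flip allele with error probability 0.001 (the order of
  magnitude of modern short-read raw error rates); parents are emitted
  as pure homozygotes under the same depth model.
* **Defaults**: nine chromosomes totalling ≈ 400 Mb (a
  foxtail-millet-scale stand-in; the true map length and marker density
  of any real population are free parameters, not estimates), 3 cM/Mb,
  ~2,000 grid markers, 120 lines, F8, 15 + 15 bulks.
* **Bundle** (`write_fixture_set()`): one global seed spawns per-stage
  substreams; the bundle (VCF + GFF3 + CDS FASTA + phenotype and DEG
  TSVs + YAML config) is byte-reproducible, and `truth.json` records
  every seed and the planted truth. The default trait parameters —
  baseline 30 g·g⁻¹, additive effect 54, residual sd 6 — were chosen
  once so that the two homozygote classes reproduce the 25–35 g·g⁻¹
  low-NUtE and > 75 g·g⁻¹ high-NUtE class structure with a high/low pool
  contrast near 3, i.e. a major-effect setting. Six candidate genes are
  planted around the QTL with engineered nonsynonymous sites and a fixed
  fold-change pattern (±3.2 to 30.4); decoys cover the three failure
  modes the intersection must reject (synonymous-only gene in the
  region, non-DE gene in the region, DE nonsynonymous gene outside the
  region).

What the generator does *not* emulate — and therefore what passing tests
cannot certify about real data: alignment and mapping artefacts,
duplicated or repetitive regions, indels and multiallelic sites,
segregation distortion, multiple or epistatic QTL, depth
overdispersion beyond Poisson, and batch structure between pools. Tests
passing on this generator demonstrate the statistical machinery is
correct under its stated model, not that any particular biological
dataset will behave.

## Variant-effect annotation

`classify_variant_effects()` is a deliberately simplified codon
annotator: single-nucleotide substitutions against gene models whose
spliced CDS is supplied explicitly, standard genetic code only,
categories synonymous / nonsynonymous / stop_gain / stop_loss /
noncoding; start-codon loss collapses into nonsynonymous. Models whose
CDS length is not a codon multiple are flagged incomplete and excluded
(their variants report noncoding plus a warning count). Minus-strand
genes are handled by transcript-coordinate mapping with complemented
alleles; a property test asserts exact agreement with an independent
full-transcript translation oracle and strand-mirroring invariance. It
is not a replacement for a full annotator (no splice sites, UTRs,
regulatory features, indels, or alternative transcripts).

## Numerical conventions and degenerate inputs

* Percentile: linear interpolation between closest ranks; percentile
  100 returns the maximum; values outside (0, 100] are rejected.
* Window means: plain sums over member deltas divided by counts; window
  membership is closed on both ends (`start <= pos <= end`).
* Zero-depth pools give missing indices, never zeros; loci missing an
  index in any pool are removed (and counted) before the scan.
* A chromosome with no markers yields windows with missing means; a
  dataset with no informative windows is an error, as is an empty null.
* Ties in candidate ranking break lexicographically by gene id, making
  every output deterministic.
* All stochastic stages take explicit integer seeds; one global seed
  spawns fixed per-stage substreams, so identical configurations produce
  byte-identical artifacts.

## Problem sizes used in the checks

The test-suite and acceptance-script experiments run at the default
design (120 lines, ~2,000 markers, nine chromosomes) with 200 null
iterations per dataset, 200 datasets for type-I calibration, 50
replicates for QTL recovery (30 in the acceptance script), and 1,000
random instances for the annotation oracle — sizes chosen as the
package's own verification budget so the whole suite completes in
minutes while keeping Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

* The genetic-to-physical rate is uniform; real maps vary locally, which
  deforms both the simulator and the `ril_null` threshold.
* The additive single-QTL trait model cannot represent dominance at the
  residual-heterozygote level, linked QTL, or transgressive segregation.
* `select_extreme_bulks()` resolves the over-determination between class
  bounds and pool size by taking the most extreme qualifying lines —
  deterministic and contrast-maximising, but one documented choice among
  several defensible ones.
* DEG tables are consumed, never computed: differential-expression
  modelling (and its normalisation questions) is upstream of this
  package.
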