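---
title: "Detecting parent-of-origin and cis-regulatory effects from reciprocal-hybrid allele-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parent-of-origin and cis-regulatory effects from reciprocal-hybrid allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridase)
```

## The design

Take two highly inbred lines — call them V and G, after the *Nasonia
vitripennis* / *N. giraulti* system this package is modeled on — and cross
them in both directions. The two reciprocal F1 female hybrids, VG (a V
mother) and GV (a G mother), carry identical nuclear genomes; only the
parental origin of each allele is swapped. RNA-seq read counts at sites where
the two lines are fixed for different alleles therefore separate two kinds of
allelic bias that are confounded in any single cross:

* a **parent-of-origin (imprinting) effect** favors whichever allele came
  from one particular parent. The favored *line* switches between the
  reciprocal hybrids: the V-line allele fraction sits on opposite sides of
  0.5 in VG and GV.
* a **species-of-origin (cis-regulatory) effect** favors one line's allele
  regardless of the cross: the V-line fraction sits on the same side of 0.5
  in both hybrids (the two fractions may still differ in magnitude).

`hybridase` implements the full analysis around this contrast: calling fixed
differences from a jointly genotyped parental VCF, building a SNP-substituted
pseudo reference so that reads from either allele align equally well,
aggregating per-SNP allele counts to per-gene ratios, testing the ratio
difference between the reciprocal hybrids, and classifying significant genes
by the corner geometry above. A seeded generator simulates every input, so
each stage is verifiable without touching real data.

## Fixed-difference sites and the pseudo reference

A site is *fixed and different* when it is a biallelic single-base SNP,
homozygous for the reference allele in **every** replicate of line V and
homozygous for the (first) alternate allele in **every** replicate of line G.
Because both lines are inbred, any heterozygous or missing call is treated as
evidence against fixation and disqualifies the site; we chose this
conservative reading rather than, say, requiring a majority of replicates.
Multi-allelic records and indels are excluded outright rather than
decomposed: the downstream substitution step replaces exactly one base, and a
shared gene annotation remains valid on both references only under
length-preserving edits. Sites where line G is homozygous for a *non-first*
alternate allele are also excluded, and counted, since no single substitute
base is defined for such records. Group sizes are configurable (real datasets of
this design have 3–4 parental replicates per line).

`build_pseudo_reference()` substitutes the alternate base at every
fixed-difference position. It refuses to proceed on a reference-base
mismatch (naming the offending `chrom:pos`), which catches assembly/VCF
version skew, and treats two entries at one position as an error rather than
last-wins. Two invariants pin the operation down: sequence lengths are
conserved, and applying the substitution a second time with reference and
alternate roles swapped returns the original genome exactly. The test suite
checks both, plus a brute-force per-position comparison that must recover the
input set exactly.

## From allele counts to per-gene ratios

The unit of input is a per-SNP, per-sample allele-count record (the output
format of a read-level allele counter; producing it from BAMs is outside this
package's scope). Aggregation applies, in order:

1. **Fixed-site restriction** — records are kept only at fixed-difference
   positions *with matching alleles*; a record at the right position with
   swapped or different alleles is dropped and counted separately.
2. **Depth filter** — a SNP observation is *informative* when its total count
   is at least `min_site_depth` (default 30, inclusive).
3. **Gene intersection** — a record is assigned to every gene whose full span
   contains it (1-based inclusive ends). Whole gene spans, not exons, are
   used: hybrid allele counts come from RNA-seq alignments, and intronic or
   UTR SNPs covered by reads are as informative as exonic ones. Records in
   two overlapping genes count for both and carry an ambiguity flag.
4. **Pooling** — counts are **summed** over SNPs and replicates within each
   cross. Summation (rather than averaging of per-replicate ratios) weights
   each read equally and reproduces the single pooled per-hybrid ratio that
   this design reports per gene; per-SNP direction tallies are kept alongside
   as dispersion diagnostics.

A gene is *testable* only with at least `min_snps_per_gene` (default 2)
informative SNPs in **both** crosses.

## The imprinting test

For each testable gene the pooled counts form a 2×2 table (rows: V-line /
G-line allele; columns: VG / GV), tested with a two-sided Fisher's exact
test computed by direct summation of hypergeometric probabilities no larger
than that of the observed table. Benjamini–Hochberg control at
`alpha = 0.05` is applied across the testable set only — untestable genes are
not part of the family. The combined-dataset analysis (records from two
datasets restricted to their allele-consistent shared fixed sites, counts
pooled) forms its own BH family.

Significant genes are classified by where the two V-line fractions fall:

| `frac_vg` | `frac_gv` | category |
|---|---|---|
| < 0.5 | > 0.5 | `paternal_bias` (paternal allele favored in both) |
| > 0.5 | < 0.5 | `maternal_bias` |
| > 0.5 | > 0.5 | `cis_ref_parent` |
| < 0.5 | < 0.5 | `cis_alt_parent` |

A fraction exactly at 0.5 carries no direction: the gene is classified to
the cis side indicated by the other fraction, or `no_difference` when both
are tied. A per-cross exact binomial test of deviation from 0.5 is reported
as a diagnostic but never gates calls: the between-hybrid Fisher test is the
primary criterion, because a gene can deviate from 0.5 identically in both
hybrids (a pure cis pattern) without any parent-of-origin signal.

Numerical notes: both exact tests compare point probabilities with a
relative tolerance of 1e-7 when accumulating the two-sided tail, absorbing
floating-point noise in ties; the BH step-up is implemented directly
(`q_i = min over j with p_(j) >= p_i of p_(j)·m/j`, clipped at 1) and is
cross-checked against `stats::p.adjust` and an independently coded
definition in the tests.

## The expression-QC stage

Counts obtained against the primary and pseudo references are averaged
elementwise (halves are allowed downstream), genes are kept when their mean
FPKM reaches 0.5 in at least one sample group, and expression is reported as
`log2((count + 0.5) / (lib + 1) * 1e6)`. Written descriptions of these two
thresholds are easy to state with inverted inequalities (retaining rather
than removing genes below the FPKM cutoff; fold changes below rather than
above the DE cutoff); this package fixes both in the directions that do what
the filters are for — genes are *kept* when mean FPKM ≥ 0.5 in at least one
group, and DE is *called* at |log2FC| ≥ 2, inclusive at both bounds. The DE
stage itself is a deliberately simple Welch test per gene with BH adjustment
(`q ≤ 0.01`, `|log2FC| ≥ 2`, both inclusive) — a documented stand-in that
lets the pipeline run end to end; it is not an empirical-Bayes linear model,
and no moderation or TMM normalization is attempted. PCA is computed on
centered, unit-scaled genes after dropping zero-variance genes.

## Genetic-map tools

Conversion between two linkage maps generalizes a single conversion ratio to
per-interval piecewise-linear scaling through shared anchor markers (with two
anchors it reduces to one ratio); queries beyond the anchors extrapolate with
the terminal segment. Anchors must be monotone, conversion is exact at
anchors, and an A→B→A round trip at anchors is the identity.

The introgression scan takes array genotype calls (V/G/missing) for markers ×
samples. A marker is usable only when every control sample of each line
calls its own allele with no missing values; a usable marker is flagged when
every test sample calls V, again with no missing values — missingness never
creates a flag, only removes one. Runs of adjacent flagged markers merge
into one locus spanning the interval strictly *between* the nearest usable
non-flagged markers (the flanking markers themselves are excluded). Where no
such flank exists the locus extends to the chromosome end when lengths are
supplied, otherwise to the outermost marker — the honest statement of what
the panel can resolve. Locus–gene overlap requires at least 1 bp; enrichment
of a gene set within a locus uses the one-sided upper-tail hypergeometric
with the testable gene set as the natural default universe (the source
protocol names no test; the hypergeometric is the standard choice for
set-within-universe overlap).

## What the generator emulates — and what it does not

`simulate_experiment()` produces the complete input bundle with known truth.
Its defaults are the study conditions the package targets, chosen once:

* fully homozygous parental lines, 3 replicates each (configurable to 4);
  3 replicates per hybrid cross;
* ~20 fixed-difference SNPs per gene (`snp_density = 10`/kb over 2 kb genes),
  matching the observed mean of ~19.7 informative SNPs per gene in this
  design;
* per-SNP total depth ~ negative binomial with mean 150 (between the two
  hybrids' observed mean per-SNP allele depths of ~150 and ~197) and
  dispersion 5;
* gene classes `null / cis / paternal_imprint / maternal_imprint` at
  0.94 / 0.03 / 0.015 / 0.015 — a predominantly null transcriptome with a
  handful of biased genes, the qualitative finding of this design;
* allelic effect ratio 0.8 for imprinted genes (the favored allele takes 80%
  of reads); cis genes favor one line in *both* crosses but with different
  magnitude (0.8 in one hybrid, 0.65 in the other) — a same-side,
  different-ratio pattern, which is what makes them detectable by a
  between-cross test at all;
* binomial allele counts by default; `overdispersion_rho > 0` switches to
  beta-binomial with that intra-gene correlation;
* expression "biology" (per-gene baselines, transcriptome-wide between-line
  divergence with SD 0.7 log2 units, and a strongly shifted ~10% of genes at
  |log2FC| = 4) drawn from a separate `biology_seed`, so experiments
  simulated with different `seed`s emulate different laboratories assaying
  the same organism — their mean logCPM profiles correlate near 1 and PCA
  separates the lines on PC1, as real data of this design do.

All randomness flows from one base seed through fixed per-component
substreams (genome, genes, VCF, allele counts, expression, markers), so
identical configurations give byte-identical bundles and enlarging one
component does not perturb the others. Genotype errors are simulated as
parental calls corrupted to heterozygous — the realistic failure mode, since
it breaks the homozygosity requirement and can only shrink the
fixed-difference set.

The generator works at the allele-counter output boundary: it does not
simulate reads, alignment, mapping bias, linkage disequilibrium, or
sequence evolution. Passing tests therefore demonstrate the statistical
pipeline's correctness and calibration on data that satisfy its model
assumptions; they say nothing about alignment artifacts or reference bias in
real data — mitigating those is precisely the role of the pseudo-reference
step, whose effect can only be assessed with real reads.

## Calibration and recovery, at the sizes the tests use

The suite checks, among others (sizes chosen to keep the whole suite fast
while leaving Monte-Carlo error well inside the asserted bands):

* Fisher p equals an exhaustive hypergeometric enumeration for every 2×2
  table with grand total ≤ 30 (~46,000 tables), and BH equals the step-up
  definition on 1,000 random p-vectors;
* the fixed-difference classifier equals an independently coded rule oracle
  on all 4,096 genotype combinations of 3+3 samples;
* 2,000 null genes (fraction 0.5 in both crosses, 5 SNPs at depth 100) give
  a raw rejection rate at 0.05 within 3 Monte-Carlo standard errors, and BH
  at 0.05 yields zero discoveries in at least 95 of 100 seeded replicates;
* 100 planted imprinted genes (paternal fraction 0.8, pooled depth 500)
  among 1,900 nulls are recovered with sensitivity ≥ 0.9 and correct labels
  ≥ 0.95, and sensitivity is monotone in effect size under common random
  numbers;
* the published per-gene worked examples (pooled ratios 65.3%/62%,
  65.26%/61.58% with 7 SNPs, 93%/61%, 80.13%/73.54%) are reproduced from
  per-SNP fixtures reconstructed from those printed values. Where a depth was
  not printed, 200× per SNP is assumed; that choice scales power only, not
  the ratios.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)
bundle <- simulate_experiment(cfg, out_dir = "bundle")
res <- run_pipeline(pipeline_config("bundle", out_dir = "results"))

res$report$imprinting
subset(res$imprinting, category %in% c("paternal_bias", "maternal_bias"))
```

The run report carries every filter's in/out counts and md5 hashes of all
inputs and outputs, so two runs on the same bundle are verifiably identical.

## Known limitations

* Replicate-level dispersion is summarized, not modeled: a beta-binomial or
  mixed-model test would borrow strength across replicates instead of
  pooling reads. With strongly overdispersed data the pooled Fisher test is
  anticonservative; the per-replicate tallies emitted alongside are the
  intended QC handle.
* Genes are intersected by span; overlapping genes share SNPs (flagged, with
  a strict-discard option left to the caller via the ambiguity column).
* The DE stage is a stand-in, as described above.
* The scan cannot place locus boundaries more precisely than the marker
  spacing, and terminal loci depend on supplied chromosome lengths.
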