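---
title: "Measuring splice-form abundance from barcoded amplicons: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring splice-form abundance from barcoded amplicons: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicequant)
library(dplyr)
```

## The measurement problem

At some loci, alternative splicing produces several isoforms that differ
only by the presence or absence of short internal exons embedded in long
stretches of shared (homologous) sequence. A canonical example is a
brain-expressed region with two alternatively spliced exons — here called
M ("medium") and L ("little") — giving four splice forms named by their
inclusion pattern: `0-0`, `M-0`, `M-L` and `0-L`. Hydrolysis-probe assays
(ddPCR) can only target junctions with enough unique sequence, so at such
a locus typically only one form (here `M-L`) is directly measurable by
ddPCR. To quantify *all* forms, the region of interest is PCR-amplified
with primers in the constitutive flanks and sequenced; every read then
spans the informative junctions and can be assigned to a form.

splicequant implements this combined design end to end:

1. **Indexed amplicons.** The reverse primer carries an internal 8-nt
   barcode (16 barcodes, one sample each) plus a random 4-nt "quatromer"
   diversity spacer, so 16 samples are multiplexed *within* the amplicon,
   upstream of library preparation.
2. **Processing.** Quality/adapter trimming, fuzzy barcode
   demultiplexing, overlap merging of read pairs, and error-tolerant
   junction classification produce per-sample splice-form counts.
3. **Calibration.** Equimolar synthetic-fragment (gBlock-style) mixtures
   of the five amplicon species quantify length-dependent PCR bias; the
   estimated per-species factors correct the sample counts.
4. **Normalization.** Counts are scaled by the pool-average read total
   and expressed relative to an endogenous control (GUSB).
5. **ddPCR.** The standard Poisson partition estimator converts
   positive/total droplet counts into absolute concentrations, normalized
   to the same control.
6. **Context.** A small utility harmonizes GWAS odds ratios across
   studies onto a common risk-allele orientation (the motivation for the
   locus being of interest in the first place).

Everything is testable without external data because the package ships a
seeded simulator for barcoded read sets, spike-in runs and droplet wells.

## The synthetic design

No public sequence data accompany the assay, so `default_design()` is a
synthetic locus with the *geometry* of the real one: 16 internal 8-nt
barcodes with a 4-nt quatromer, and five amplicon species of 125, 156,
210, 219 and 273 bp. Which fragment length belongs to which species is
not given anywhere; however, template additivity
(`len(0-0) + len(M-L) = len(M-0) + len(0-L)`) admits exactly one
assignment among the five printed lengths, since 156 + 273 = 210 + 219:

```{r}
build_templates(default_design())
```

This forces the control to be the 125-bp fragment and implies a 63-nt M
exon and a 54-nt L exon (consistent with "medium" > "little"). The
sequences themselves are fixed arbitrary DNA. The 16 barcodes were chosen
with minimum pairwise edit distance 3, so one allowed error per barcode
(below) can never convert one barcode into another.

## Stage models and tunable parameters

### Demultiplexing

Barcodes are matched by **semi-global edit distance** (substitutions and
indels both count), with allowed errors `floor(rate × length)`; the
default `max_error_rate = 0.15` allows one edit on an 8-nt barcode. A
read is assigned to the unique barcode at minimal distance; ties and
misses are left unassigned, because a false assignment distorts two
samples while a dropped read only costs depth. The default search window
is the designed barcode position (`quatromer + barcode + k` bases): in a
full-read search, a 260-nt random read lies within one edit of *some*
8-mer surprisingly often, so windowed search is both faster and more
specific. The full-read mode remains available (`window = "full"`).

### Trimming and merging

Quality trimming uses the standard 3' running-sum rule (subtract the
cutoff, cut at the minimum of partial sums from the 3' end); adapter
occurrences are removed by the same error-tolerant matching at
`max_error_rate = 0.1`. With 300-bp reads and amplicons of at most
273 bp, *every* proper pair is a full read-through: each read contains
the entire amplicon plus the reverse complement of the other end's
barcode machinery. The pipeline therefore trims barcode/quatromer tails
during demultiplexing, before merging, and the merger treats containment
layouts as first class. Merging scans all overlap layouts of at least
`min_overlap = 10` bases, picks the layout with minimal mismatch ratio
(ties: longer overlap) and accepts it if the ratio is at most
`max_mismatch_ratio = 0.25` — the cited defaults of the widely used
overlap-merging tools. Consensus takes the higher-quality base;
conflicting bases at equal quality keep read 1's base with the quality
floored to Phred 2. Single-end data pass through unchanged.

### Classification

Splice forms are recognised by **junction probes**: for each exon
adjacency realised by some form (`CL|M`, `CL|L`, `CL|CR`, `M|L`, `M|CR`,
`L|CR`) a probe spans `flank = 10` bases on each side, plus a central
control probe. A form is called iff the read hits *exactly* its probe
set; any foreign probe hit (e.g. a PCR chimera touching two forms) gives
`UNASSIGNED` rather than a majority vote, so chimeras cannot inflate rare
forms. Matching tolerates `floor(0.10 × probe length)` edits — two on a
20-nt probe. Because the constitutive flanks are shared by all forms,
probe sets are validated at build time: classifying the five error-free
templates must yield five distinct correct calls, otherwise the design is
rejected with the collision named. This validation is what makes the
homology hazard explicit.

### Bias calibration

PCR bias is modeled as deterministic geometric amplification: species
`s` is amplified `(1 + e_s)^n` after `n = 32` cycles. Within an
equimolar mixture the expected read share of species `s` is then
proportional to `(1 + e_s)^n`, so `share / (1/5)` estimates the bias
factor directly. Factors are pooled across mixtures by geometric mean
(they are ratios) and renormalized to geometric mean 1; the per-species
CV across mixtures spanning the 16-fold template range (200, 200, 800,
1600, 3200 molecules) is the consistency QC, warning above
`cv_threshold = 0.2`. Correction is per-species multiplicative
(`count / factor`): with five species there are five directly estimated
factors, and a fitted two-parameter length model would add assumptions
without need — the log-factor-vs-length fit is reported as a diagnostic
only. We model the *expected* bias, not stochastic branching; the
calibration estimates a per-species factor regardless of mechanism, which
is all the correction needs.

A note on the mixture count: the assay description mentions six mixtures
but enumerates five template amounts (200 twice, 800, 1600, 3200);
`default_manifests()` follows the enumerated amounts. The estimator is
agnostic to the number of mixtures.

### Normalization

Pool normalization divides each sample's counts by the mean per-sample
read total of its pool, making samples comparable across pools of
different yield. Control normalization divides by the within-sample
control count; when only a fixed volume fraction (5–10 %) of the control
reaction was pooled, `control_volume_fraction` rescales the control to
full-reaction equivalents. This rescaling is **off by default** (fraction
1.0) because how the original normalization treated the spike volume is
not described — and the control's separate-reaction, lower-volume
handling is suspected to be why its cross-platform concordance is weak.
Samples with zero control counts get `NA` (undefined), never zero.

### ddPCR quantification

With `n` droplets of volume `v` (default 0.85 nL, the common
instrument's nominal droplet volume) and `n⁺` positives, mean occupancy
is `λ = −ln(1 − n⁺/n)` and concentration is `λ/v` copies/µL. The
delta-method standard error of `λ` is `sqrt((e^λ − 1)/n)`. Saturated
wells (`n⁺ = n`) are not quantifiable and are an error by default;
`on_saturated = "flag"` marks them `NA` instead (used by the expression
ratio, which flags degenerate controls rather than failing). Group fold
changes default to the **geometric** scale (`2^Δmean-log2`) because
downstream analysis operates on log2-normalized values; the arithmetic
scale is available since the original fold-change formula is unstated.
Cross-platform concordance is Spearman's rank correlation with average
ranks for ties.

### GWAS odds-ratio harmonization

Per locus, the newest study's tested (risk) allele fixes the reference
orientation; studies reporting the opposite allele get `OR ← 1/OR`, then
the whole locus is flipped if the reference OR is below 1, so the
consensus OR is at least 1. Loci are sorted by descending median OR
across studies. Rows whose alleles match in neither orientation are
irreconcilable and are excluded (attached as the `"excluded"`
attribute). The procedure is idempotent.

## What the simulator does and does not emulate

`simulate_readset()` draws each read pair's species from
`proportions × amplification factor`, lays the construct out as
`[quatromer][barcode][reverse-complemented template]` on read 2 (the
barcode side is the reverse primer's, matching the oligo design; the
architecture is configurable in principle because the post-library-prep
read layout is not fixed by the assay description), applies i.i.d.
substitution errors, and emits constant Phred-30 qualities.
Deliberately **not** simulated: PCR chimeras/recombination,
quality-coupled error profiles, indel sequencing errors (the matchers'
indel tolerance is exercised by dedicated perturbation tests instead),
and library-prep yield differences (covered abstractly by the pool
normalization tests). Passing the end-to-end tests therefore shows the
*pipeline logic* recovers what the generative model put in — it does not
certify accuracy on real data, where chimera rates, context-dependent
errors and true bias mechanisms differ.

## Numerical choices and degenerate inputs

- Allowed errors are always `floor(rate × pattern length)` — the
  standard semantics of the error-rate parameter in the cited tools.
- Demultiplexing ties (two barcodes at equal minimal distance) and
  classifier conflicts are unassigned, never arbitrated.
- The merger breaks mismatch-ratio ties toward the longer overlap, which
  selects the full-containment layout for error-free read-through pairs.
- Zero spike-in counts exclude that (species, mixture) cell with a
  warning; a species at zero in all mixtures is an estimation error.
- `log2` values are undefined (`NA`) at zero; zero-control samples are
  flagged, not imputed.
- All sequence handling is uppercase; ambiguity codes are rejected in
  designs but tolerated in reads (they simply never match).
- Every stochastic function takes a `seed`; the pipeline expands one
  run-level seed into its stages, and reruns are byte-identical.

## Problem sizes used in the shipped checks

The test suite exercises the study-scale configuration: a 16-plex run at
50,000 read pairs per sample (0.5 M-read pools are the assay's order of
magnitude), 20 seeded repeats for the recovery error, spike-in runs at
50,000 reads per mixture, 250 simulated wells of 20,000 droplets, and
full sweeps of amplicon lengths 20–580 bp at 300-bp reads. The
acceptance script reports the same quantities at moderately reduced sizes
(stated in its output as `n`), chosen so a complete rerun stays fast
while estimates remain well inside their sampling tolerances.

## Known limitations

- The probe-set classifier quantifies only forms present in the design;
  novel isoforms surface as `UNASSIGNED`, not as discoveries.
- The bias model corrects the combined amplification + bridge-PCR effect
  with one factor per species; it cannot separate mechanisms, and a
  GC-content model is out of scope.
- Fold changes are descriptive; hypothesis testing (ANOVA, t-tests,
  regression on covariates such as RIN, PMI, age) is left to standard
  statistics routines operating on the tidy expression tables this
  package emits.
- The quatromer is a diversity spacer, not a UMI: no deduplication is
  attempted, matching its role in the assay.
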