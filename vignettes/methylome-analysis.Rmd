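---
title: "Methylome analysis with methylscape: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome analysis with methylscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`methylscape` implements the downstream half of a whole-genome bisulfite
sequencing (WGBS) study in a plant-type methylome: per-cytosine counts in,
context-resolved methylation levels, genome-wide window summaries,
functional-element metaprofiles, differentially methylated regions (DMRs)
and genes (DMGs), term over-representation, and a Chou–Talalay
combination-index analysis of drug synergy. This vignette explains the
models behind each step, every tunable parameter with its default and why,
what the synthetic-data generator does and does not emulate, and the design
choices made where more than one convention was defensible.

## The measurement model

After bisulfite treatment, unmethylated cytosines read as T and methylated
cytosines as C. At one cytosine the data are counts `(mC, C)` of reads
supporting methylation and non-methylation; the methylation level is

    ML = mC / (mC + C).

Conversion is imperfect: a fraction *r* of unmethylated molecules escapes
conversion and reads as methylated. A site with true methylation
probability *p* therefore yields methylated reads at rate

    q = p + (1 - p) r.

*r* is estimated by pooling all reads mapped to the unmethylated lambda
spike-in chromosome (everything methylated there is a conversion failure),
and the raw level is corrected by inverting the error model:

    ML_corrected = max(0, (ML_raw - r) / (1 - r)).

The literature this procedure follows cites a correction without printing a
formula; the linear inversion above is used because it is the exact inverse
of the error process, and the clamp at 0 handles sites whose raw level
falls below the error floor. Typical plant WGBS libraries convert at better
than 99.5%, so the generator's default `nonconversionRate` is 0.004.

### Cytosine contexts

Plants methylate cytosines in three sequence contexts read 5'→3' on the
cytosine's own strand: CG, CHG and CHH (H = A, T or C). The caller
inspects the two downstream bases — on the minus strand these lie at lower
reference coordinates and are complemented. Cytosines with fewer than two
downstream bases (chromosome edge) or an N among them have undefined
context and are excluded entirely; exclusion is reproducible, whereas any
imputed context would be a guess. The caller is validated against an
independent brute-force 3-mer scanner in the test suite.

### Calling a site "methylated"

Genome-wide percentages of methylated cytosines need a calling rule, and
none is universal. `callMethylatedSites()` uses the standard binomial test:
a site with coverage ≥ 5 is methylated when the one-sided exact binomial
p-value against the null `Binomial(coverage, r)` survives
Benjamini–Hochberg correction within its context stratum at q < 0.05.
Sites under the coverage floor are *not testable* and are excluded from
numerators and denominators alike. The reported per-context percentage uses
the testable cytosines of **all** contexts as one common denominator, so
the three context percentages add up to the total methylated-cytosine
percentage — the convention that makes a "total mCX" column equal the sum
of its parts.

## Genome-wide summaries

`slidingWindowML()` pools read counts in 3,000-bp windows stepped by
600 bp; `binProfile()` tiles the genome in non-overlapping 10-kb bins
(exactly the window function with window = step). Windows are anchored at
position 1 of every chromosome and the last window is truncated at the
chromosome end; a truncated tail window is kept if at least 1 bp remains.
Anchoring at 1 makes the tiling deterministic and independent of the data.
Windows with no covered site are omitted rather than reported as 0 — a
pooled level of an empty window is undefined, not zero.

## Functional-element metaprofiles

Gene models contribute five element classes: promoter (the 2-kb region
immediately upstream of the TSS, strand-aware, truncated at chromosome
bounds), 5'UTR, exon, intron (the gaps between consecutive exons) and
3'UTR. Each element is divided into 20 equal-length bins with floor
boundaries (`bin k` covers offsets `[floor(kL/20), floor((k+1)L/20))`),
traversed 5'→3' in gene orientation so bin 1 is always biologically 5';
counts of covered sites are pooled per bin across all elements of a class.
Three conventions here were genuinely open:

* **Proportional bins, not fixed-bp bins** — elements vary over two orders
  of magnitude in length; "20 bins per element" only makes sense as a
  fractional tiling. Elements shorter than 20 bp still split; some bins are
  then empty by construction.
* **Minus-strand elements are orientation-flipped.** The source procedure
  does not state this; flipping is asserted because an unflipped average
  would blur 5' and 3' ends of the metaprofile. A property test shows that
  mirroring a minus-strand layout onto the plus strand leaves the profile
  unchanged.
* **Both strands pooled, sites assigned by position only** — one curve per
  context is reported, not per strand.
* **Multi-transcript genes collapse to the longest-span transcript** (ties
  broken by transcript ID). A union-of-exons gene model would make
  "intron" ambiguous.

## DMR calling

Treatment and control are compared per context in 1,000-bp windows stepped
by 100 bp. The cascade, in order:

1. Only cytosines of the tested context covered by **≥ 5 reads in both
   samples** enter a window (the shared-site policy). This makes the
   methylation difference and the 2×2 test table refer to the same loci;
   applying the coverage rule per window or per sample alone would let the
   two samples be summarised over different sites.
2. Pre-filter on pooled effect sizes: `|ml_treat − ml_ctrl| > 0.1`,
   symmetric fold change `max(ml)/max(min(ml), 0.01) > 2`, and strictly
   more than 10 shared cytosines. The fold change is symmetric so the rule
   applies to hyper- and hypomethylation alike, and the 0.01 floor keeps it
   finite when one side is fully unmethylated. "More than 10" is read
   strictly (≥ 11).
3. Two-sided Fisher's exact test of `[[mC_t, C_t], [mC_c, C_c]]` with
   point-probability ordering (the conventional two-sided definition),
   p < 0.05.
4. Benjamini–Hochberg FDR across all windows that passed the pre-filter,
   q < 0.05. BH is computed per contrast and per context; contexts behave
   differently in plants, and pooling them would let an abundant context
   dominate the correction.
5. Surviving windows that overlap or are book-ended and agree in the sign
   of the difference merge into maximal runs; all statistics, including the
   Fisher p, are recomputed on each merged interval from its shared sites,
   and the merged p-values are BH-adjusted. Merging is necessary because a
   true region wider than the step produces a run of overlapping
   significant windows, not one.

DMRs are annotated with every element type they overlap by ≥ 1 bp and
every owning gene; a gene with at least one DMR is a DMG. The per-gene
methylation ratio is the treatment/control ratio of pooled levels over the
distinct shared cytosines of the gene's DMR intervals (denominator floored
at 0.01), classified hyper at ratio ≥ 1.5, hypo at ≤ 1/1.5. DMG sets are
compared across contrasts with exclusive Venn-region counts, and the
gene-by-sample matrix of pooled DMR levels is clustered with average
linkage under the distance `1 − Pearson r` (rows pre-sorted by gene id for
a deterministic leaf order; constant rows dropped with a warning because
their correlation is undefined).

The procedure implemented is the explicitly described sliding-window
Fisher test; smoothing-based callers solve a different problem (gradual
boundaries, replicate dispersion) and are out of scope, as is
replicate-aware dispersion modelling — the design this package mirrors
pooled one library per condition.

## Term over-representation

A generic hypergeometric upper-tail test per term (`p = P[X ≥ k]` with
`K` term genes, `n` hits, background `N`), BH-corrected across terms.
Gene-length bias correction and ontology machinery are deliberately out of
scope; the module exists so the pipeline runs end-to-end against any
two-column term→gene map.

## Median-effect synergy analysis

Growth readout: `fa = 1 − weight_treated/weight_control`, clamped into
[0.005, 0.995] because the log-odds transform diverges at 0 and 1 (the
clamp mirrors instrument precision). Replicate fresh weights are averaged
per dose before computing `fa`; per-replicate fits are noisier and the
source convention is unstated. The median-effect model

    fa / (1 - fa) = (D / Dm)^m

is fitted by OLS on the log-log line; `Dm` is the GI50 when `fa` measures
growth inhibition. For a combination dose pair `(d1, d2)` with observed
`fa`, the combination index is

    CI = d1 / Dx1(fa) + d2 / Dx2(fa),

the classic mutually exclusive two-term form (`CI < 1` synergy, `= 1`
additive, `> 1` antagonism). Whether the original analysis used the
exclusive or non-exclusive form is not stated; the exclusive form is the
default and the non-exclusive third term `d1 d2/(Dx1 Dx2)` sits behind
`nonExclusive = TRUE`. Non-constant-ratio designs (fixed single doses
combined) are supported natively.

## The synthetic-data generator

All testing runs on data from `SimulationConfig()` +
`simulateMethylomeBundle()`, which emulate:

* a multi-chromosome genome of i.i.d. bases at GC fraction 0.36
  (plant-like) plus an unmethylated lambda control chromosome (48,502 bp,
  GC 0.5);
* context-dependent true methylation: per-site Beta draws with means
  CG 0.24 > CHG 0.10 > CHH 0.04 and concentration 20, reproducing the
  canonical plant context ordering; the control chromosome is fixed at 0;
* planted differential regions: by default twenty 2-kb CG regions shifted
  by +0.4 (clamped to [0, 1]), recorded as ground truth; the bundle
  assigns each treatment a slice of a shared gene-anchored pool so the
  three DMG sets overlap partially;
* read counts: coverage ~ Poisson(30) per site, methylated count ~
  Binomial(coverage, `p + (1−p)r`) with r = 0.004. Poisson (not negative
  binomial) coverage is the simplest model sufficient to exercise the
  caller; an overdispersed coverage model would change power but not
  correctness, and is intentionally not a default;
* dose-response tables from the median-effect curve with 5% lognormal
  noise and three replicates (azacitidine m = 1.8, Dm = 10 µM — its GI50;
  AZD Dm = 1 µM; RAP Dm = 5 µM), and combination observations constructed
  to have a chosen true CI (0.45 for RAP + azacitidine, i.e. strong
  synergy; 0.8 for AZD + azacitidine).

Randomness is reproducible: one master seed, with per-sample and per-stage
streams derived by hashing `(seed, label)`, so samples are independent yet
the whole dataset is a pure function of the configuration.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: mapping bias and mappability gaps, PCR
duplicates, strand- or fragment-level correlation between neighbouring
sites, chromosomal methylation gradients (pericentromeric enrichment),
transposon structure, biological replicate variance, and batch effects.
Results on real libraries depend on upstream alignment quality in ways the
synthetic path cannot probe.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere in memory (the per-cytosine
  report convention); BED output alone is 0-based half-open, converted at
  exactly one point (`writeDmrOutputs()`).
* Fisher p-values use point-probability ordering with a relative tolerance
  of 1e-7 for ties, matching `fisher.test`; the implementation is
  vectorised over windows and validated against a full-enumeration oracle
  to 1e-12 on all tables with margins ≤ 12.
* Zero-coverage sites are missing, never 0; windows and bins with no
  covered site are omitted; a zero-coverage side drops the window.
* `q = 0` maps to the BED score cap 1000; `q = 1` to 0.
* Degenerate dose-response inputs fail loudly: fewer than two distinct
  doses, all responses at a clamp bound, or a non-increasing response are
  errors, not warnings.
* Tie-breaks are always lexicographic (transcript choice, cluster leaf
  order, output row order), so byte-identical reruns are a tested
  guarantee of `runPipeline()`.

## Problem sizes used in the checks

The package's own validation runs at deliberately chosen desk scales: the
default pipeline bundle uses two chromosomes totalling 500 kb plus the
lambda control at ~30× coverage; planted-DMR recovery and null calibration
use a 1-Mb genome with twenty 2-kb regions over five (recovery) and twenty
(null) seeded replicates; the Fisher oracle sweep is exhaustive for
margins ≤ 12; the context-caller oracle runs on one hundred random 10-kb
sequences including N runs and chromosome edges. These sizes give the
binomial standard errors needed by the tolerance checks while keeping a
full run in minutes on one core.

## Interface notes and limitations

The package's interface is its functions: `runPipeline()` over a
`RunConfig()` (or YAML file) drives the whole analysis, and each module is
callable on its own. No shell entry point is shipped — in an R workflow
the function layer plus a three-line script replaces one.

Known limitations: no smoothing- or HMM-based DMR calling; no
replicate-aware dispersion; no FASTQ/BAM handling (alignment is upstream
and out of scope); the enrichment module does no ontology propagation or
length-bias correction; the window scan holds per-sample site tables in
memory, which is comfortable for plant-sized genomes at one sample pair
per contrast but untested beyond that.
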