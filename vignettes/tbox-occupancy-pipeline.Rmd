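---
title: "Methods: T-box occupancy analysis from peaks to biophysics"
author: "tboxscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: T-box occupancy analysis from peaks to biophysics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tboxscan)
```

# Overview

`tboxscan` implements the downstream computational analysis of a
multi-factor embryonic ChIP-seq/RNA-seq study of T-box transcription
factors (Brachyury/Xbra, Eomes, VegT and relatives): assigning binding
peaks to genes, classifying where binding falls relative to gene
anatomy, summarising binding per gene as summed peak significance,
quantifying co-occupancy between factor or stage tracks, scanning
summit-flanking sequence for T-box motifs, linking binding to
knockdown-induced expression changes, and interpreting measured binding
affinities against the factor's nuclear concentration.

Every stage can be exercised on synthetic data with planted structure,
so each statistical claim the pipeline can make is testable against a
known truth.

# Data model and coordinate conventions

Peaks are `GRanges` with three metadata columns: `summit` (the base of
maximal read pile-up), `score` (the peak's $-\log_{10} p$ from the peak
caller, used throughout as the quantitative binding level) and `label`
(factor and stage). Gene models are a `GeneModelSet`: a `GRanges` of
gene bodies plus `GRangesList`s of exons and UTRs.

Internally all coordinates are 1-based inclusive, the
`GenomicRanges` convention. BED input/output (0-based, half-open, with
summit offsets relative to the interval start) and Ensembl-style gene
tables (1-based inclusive, strand 1/$-1$) are converted at the reader/
writer boundary only. We chose the native `GRanges` convention over
carrying a bespoke 0-based interval type because every containment,
overlap and distance computation then uses one battle-tested container;
conversions live in exactly two functions (`readPeaks()`/`writeBed()`)
and round-trip exactly, which the test suite asserts on random tracks.
One consequence to keep in mind: positions printed by the R API are
1 larger than the 0-based positions in BED files.

# Peak-to-gene annotation

Assignment is strictly **summit to TSS**: each peak goes to the gene
(same scaffold) whose transcription start site is nearest its summit,
with ties broken to the lexicographically smallest gene id (the tie rule
is arbitrary but declared and deterministic). Peak boundaries never
enter the distance; the signed distance is oriented by the assigned
gene's strand, negative upstream.

Two anchors coexist deliberately:

* **Region bands** (`proximal` $\le 1$ kb, `intermediate` 1–5 kb,
  `distal` $> 5$ kb, upstream and downstream) are measured from the
  nearer *gene-body edge*. Summits inside the body are `gene_body`,
  subclassified as `utr5`/`utr3` (UTR takes precedence), `exon`, or
  `intron` by subtraction — a gene-body summit in no annotated exon is
  an intron.
* **Occupancy bins and windows** are measured from the *TSS*: 400-bp
  bins covering $\pm 10$ kb (25 per side) plus one overflow bin per
  side, each bin holding the sum of its peaks' $-\log_{10} p$ scores.

The two anchors genuinely differ (a 1.2-kb gene's downstream edge is
not its TSS) and we keep both explicit rather than harmonising them.
Window sums over the proximal/intermediate/distal bands are computed
from raw signed distances rather than by re-summing bins, because 1 kb
and 5 kb are not multiples of 400 bp; re-summing would misallocate
band-edge peaks. Band edges are half-open at the upper bound
($(0,1000]$, $(1000,5000]$, $(5000,\infty)$) on the absolute distance.

Binning conserves score exactly: each gene's total equals both the row
sum of its bins (overflow included) and the sum of its assigned peaks'
scores. Distance histograms (200-bp bins over $\pm 20$ kb, TSS- or
TES-anchored) keep an explicit out-of-range counter instead of
clipping, so no peak silently disappears.

Heat-map display of occupancy uses $\ln(-\log_{10} p + 1)$, which
compresses the long significance tail and maps absent binding to 0.

# Co-binding and shared targets

Peak-level co-occupancy is the fraction of query summits whose nearest
reference summit lies within 100 bp (configurable). The measure is
asymmetric by construction, and query peaks on reference-free scaffolds
count against the denominator.

Gene-level sharing uses two occupancy tiers on the per-gene summed
$-\log_{10} p$: **strong** at $\ge 25$ (p $\le 10^{-25}$ equivalent)
and **relaxed** at $\ge 1$ (p $\le 0.1$). A gene enters a factor's
target universe when strong; when comparing factors, a merely relaxed
gene is *rescued* into a factor's set provided it is a strong target of
at least one other factor. A gene relaxed everywhere belongs to no set.
This "strong-anchored relaxed rescue" is one reading of a genuinely
ambiguous published bookkeeping; both thresholds are parameters, and
per-factor totals are reported as strong + rescued so the decomposition
stays auditable. Manual rescue of peaks missed by the caller (visual
re-inspection of browser tracks) is not implementable and is excluded;
counts here correspond to the pre-inspection state.

# Motif scanning

PWMs are $\log_{10}$ likelihood ratios against a background (uniform by
default), built from aligned site counts with a pseudocount, or from a
consensus (IUPAC codes spread their count). The score of a window is
the sum of per-position weights; both strands are scanned by scoring
the forward windows against the PWM and against its reverse complement,
with minus-strand hits reported at the forward window start so a single
coordinate system feeds BED export. Bases outside ACGT (including
repeat-masked N) score $-\infty$, so masked sequence can never produce
a hit; no masking step itself is included. For browser display, raw
scores are clamped to $[1.5, 5]$ and scaled linearly to the BED
0–1000 range.

De novo motif discovery is out of scope: discovery was an
external-tool contribution, while scanning, scaling, coverage and
positional statistics are what the downstream analyses consume. Motif
coverage of a peak set is the fraction of peaks with at least one hit
starting within 100 bp of the summit, with union coverage across a set
of motif variants.

# Expression integration

Fold changes are ratios of replicate means reported in the signed
convention (magnitude $\ge 1$, minus sign = downregulation); the t-test
runs on $\log_2$ replicate values, where fold effects are additive and
symmetric — the published analysis normalises to total RNA and reports
folds without stating the test scale, so the log scale is our choice.
Multiple testing uses Benjamini-Hochberg (`stats::p.adjust`);
misregulation requires both $\ge 1.5$-fold and FDR $< 10\%$.

Set overlap uses the hypergeometric upper tail (one-sided enrichment —
the published "probability of observed overlap" does not state
sidedness) with the expected overlap $|A||B|/N$ reported alongside.

The binding-enrichment test is a one-tailed two-group Mann-Whitney U
("set 1 stochastically greater"). For combined $n \le 20$ the p-value
is exact: the tie-aware U (midranks) is compared against every
$\binom{n_1+n_2}{n_1}$ assignment of the combined values. Beyond that,
a normal approximation with tie-corrected variance and continuity
correction is used; the cutover at 20 keeps the exact branch affordable
while covering the small curated gene sets where exactness matters.
Zero occupancies can be dropped from both sets, mirroring analyses run
with and without unbound genes.

# Biophysics

Binding-response curves are fit to the 1:1 Langmuir isotherm
$R = R_\mathrm{max}\, c/(K_d + c)$ by Levenberg-Marquardt
(`minpack.lm::nlsLM`), initialised at $K_d = \mathrm{median}(c)$,
$R_\mathrm{max} = \max(R)$. The equilibrium response is the amplitude
at the end of the association step; kinetic ($k_{on}/k_{off}$) fitting
is out of scope. Fits require $\ge 3$ points spanning at least a
decade; noiseless curves are recovered to optimizer precision and 1%
response noise yields a median $K_d$ error near 1% over the default
8-point, 3 nM–3.8 µM concentration ladder (chosen to bracket a 14 nM
$K_d$ by more than two decades on both sides).

Nuclear concentration treats the nucleus as a sphere of measured
envelope surface $S$: $r = \sqrt{S/4\pi}$,
$V = \tfrac43 \pi r^3$, and
$c = \mathrm{copies} \times f_\mathrm{nuclear} / (V N_A)$. With
$S = 300\ \mu m^2$ and 90% nuclear localisation, $2.9\ \mu M$
corresponds to $\sim 9.5 \times 10^5$ molecules per cell. Whether a
printed nuclear concentration already incorporates the nuclear fraction
is ambiguous in such legends; both directions are computable
(`nuclearConcentration()` / `copiesForConcentration()`) and each output
labels its assumption through its arguments. The factor's molecular
weight is a required input, never a constant. Fractional site occupancy
is $c/(c+K_d)$: exactly $\tfrac12$ at $c = K_d$.

# The synthetic-data generators

The generators emulate the statistical structure the analysis assumes,
at desk scale:

* **Genome**: genes tiled across scaffolds with exponential intergenic
  gaps (mean 3 kb), uniform body lengths (2–8 kb), random strands, 1–8
  exons; i.i.d. uniform sequence. Defaults: 5 scaffolds × 600 kb,
  300 genes.
* **Peaks**: a target fraction of genes (default 0.5, reflecting that
  roughly half of the genes in the study carried promoter-region
  binding) gets one summit drawn Normal(TSS, 100 bp) — concentrating
  binding within ~400 bp of the TSS — plus uniform background peaks.
  Scores are shifted-exponential ($2 + \mathrm{Exp}(18)$), giving the
  long low-occupancy tail seen in gene-level score histograms.
* **Cofactor tracks**: a shared fraction (default 0.9, echoing the
  $\ge 90\%$ site maintenance and co-recruitment the study reports) of
  primary peaks duplicated with Normal(0, 10 bp) summit jitter and
  independently resampled scores; the rest uniform.
* **Motifs**: instances planted within $\pm 100$ bp of summits with
  probability 0.82 (the fraction of binding sites the motif variants
  jointly covered), half on the minus strand. Planting skips instances
  that would overrun a scaffold or overwrite an earlier instance, so
  the returned truth list is exactly what is in the sequence.
* **Expression**: $\log_2$ control replicates Normal($\mu_g$, 0.5),
  knockdown shifted $-1.5$ (a ~2.8-fold knockdown effect) for genes
  whose planted promoter binding is at or above the median positive
  planted score — planting the higher-binding-in-downregulated-genes
  relationship the integration stage must detect. Three replicates per
  condition, as typical for the underlying qPCR/expression designs.
* **Binding curves**: the isotherm plus Gaussian response noise.

Every generator derives its RNG stream from the single `SimConfig`
seed through per-generator substreams, so outputs are byte-identical
for a fixed seed and insensitive to which other generators run; the
caller's RNG state is restored afterwards.

What the generators do **not** model: read-level noise, chromatin
accessibility, sequence composition bias, peak-width biology,
correlated replicates, or any realistic background-binding model (the
uniform background is a stand-in, not an inference). Passing tests
therefore demonstrate algorithmic correctness and calibrated behaviour
under the planted model, not performance on real embryonic ChIP-seq.

# Numerical choices and degenerate inputs

* Nearest-gene ties: lexicographic gene id (deterministic, declared).
* Empty inputs: empty gene tables/peak files parse to empty objects
  with a warning; empty peak sets are errors where a fraction would be
  undefined (coverage, co-localisation).
* Summits outside their interval, negative BED starts and malformed
  strand fields are rejected at parse time, naming the offending line.
* Zero within-group variance in the t-test: p = 1 when means agree
  (no evidence), p = 0 with a warning otherwise.
* Mann-Whitney with everything tied: the approximate branch's variance
  vanishes; p = 1 is returned.
* Isotherm fits reject `<` 3 points, sub-decade spans and constant
  responses rather than returning an unidentifiable fit.
* BED score scaling clamps (with a warning) rather than errors, since
  out-of-range scores arise routinely from permissive scan thresholds.

# Problem sizes

The bundled tests and the acceptance script run entirely on simulated
data: genomes of 2–5 scaffolds (0.3–0.9 Mb each), 40–350 genes,
peak tracks of 100–1,000 peaks, 50-curve fitting batches and
2,000-draw calibration loops. These sizes were chosen so the whole
validation cycle completes in minutes on a laptop while every
statistical tolerance retains comfortable binomial margins.

# Known limitations

* The shared-target rescue rule is one reading of an ambiguous
  published bookkeeping; alternatives (symmetric relaxation, per-pair
  universes) would change Venn counts and are not implemented.
* The scanner's score algebra (log10 likelihood ratio, uniform
  background) is declared rather than inherited from the original
  discovery tool, whose internal scoring is not public; the 1.5–5
  display range is preserved as the clamp-and-scale rule.
* Region bands use the gene-body edge while windows use the TSS; users
  comparing the two should expect edge effects for short genes.
* No multi-gene (k-nearest) assignment and no enhancer-loop model:
  every peak reports to exactly one gene.
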