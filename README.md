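# tboxscan

Downstream analysis of T-box transcription-factor occupancy in embryonic
genomes: from ChIP-seq peak calls to gene-level binding statistics,
co-occupancy between factors, motif content, the link between binding and
knockdown-induced misregulation, and the equilibrium biophysics of the
binding events themselves.

## Who this is for

Groups analysing multi-factor embryonic ChIP-seq (e.g. Brachyury/Xbra,
Eomes, VegT in *Xenopus*) together with loss-of-function expression data
and in vitro affinity measurements. The package takes standard inputs —
BED/narrowPeak-style peak tables with summits and −log₁₀ p scores,
Ensembl-style gene tables, FASTA sequence, replicate expression tables and
SPR-style concentration/response curves — and implements the downstream
computations such studies report.

## What it computes

* **Peak annotation** — each peak is assigned to the gene with the nearest
  TSS to its summit (deterministic lexicographic tie-break), classified
  into distal/intermediate/proximal bands (>5 kb, 1–5 kb, ≤1 kb from the
  gene-body edge) or gene body with exon/intron/UTR subclasses, and
  summarised per gene as 400-bp binned −log₁₀ p profiles over ±10 kb of
  the TSS (with overflow bins) plus windowed sums. Gene-level occupancy is
  the sum of peak scores, `sum[−log₁₀ p]`.
* **Co-binding** — nearest-summit distances and the fraction of peaks
  co-localised within 100 bp between factor or stage tracks; shared target
  genes under a two-tier rule (strong: `sum[−log₁₀ p] ≥ 25`; relaxed
  rescue down to ≥ 1 when anchored by a strong call in another factor).
* **Motif scanning** — log-odds PWMs from counts or a consensus, scanned
  on both strands of 200/400-bp summit flanks; raw scores 1.5–5 scaled to
  BED 0–1000; motif coverage of peak sets and summit-relative positional
  histograms.
* **Expression integration** — fold change and two-tailed t-test on log₂
  replicates, Benjamini-Hochberg FDR, ≥1.5-fold & FDR<10% misregulation
  calls; Fisher/hypergeometric set overlap with expected counts; a
  one-tailed, tie-aware **exact** Mann-Whitney U test comparing gene-set
  occupancy levels (exact up to combined n = 20, tie-corrected normal
  approximation beyond), with or without zero occupancies; qPCR
  standard-curve quantification and percent-input/IgG enrichment.
* **Biophysics** — 1:1 Langmuir isotherm fits `R = Rmax·c/(Kd+c)` of
  binding-response curves (Levenberg-Marquardt), fractional occupancy
  `c/(c+Kd)`, protein copies from mass and molecular weight, and nuclear
  concentration from copy number, nuclear fraction and envelope-sphere
  geometry (`r = √(S/4π)`).
* **Synthetic data** — seeded generators for genomes, TSS-planted peak
  tracks, jittered cofactor tracks, planted motif instances, linked
  expression tables and noisy binding curves, each returning its planted
  truth, so every stage above is testable end to end.

## Worked example

```r
library(tboxscan)

cfg <- SimConfig(seed = 1)               # 300 genes, 5 x 600 kb scaffolds
sim <- simulateGenome(cfg)
peaks <- simulatePeaks(sim$genes, cfg)   # 250 peaks, half the genes targeted

ann <- classifyRegions(assignNearestGene(peaks, sim$genes), sim$genes)
regionDistribution(ann)$region
#>         distal_up   intermediate_up       proximal_up         gene_body
#>                18                17                85               116
#>     proximal_down intermediate_down       distal_down
#>                 4                 2                 8

occ <- binOccupancy(ann, sim$genes)
occ
#> GeneOccupancy for 300 gene(s)
#>   genes with any binding: 193
#>   grand total sum[-log10 p]: 4808.9
```

Most binding sits in the proximal-upstream band and gene bodies because
summits were planted around TSSs. A cofactor track sharing 90% of sites
is recovered at that rate by the 100-bp summit-distance criterion:

```r
cof <- simulateCofactorTrack(peaks, cfg)
colocalizationFraction(cof, peaks, threshold = 100)
#> [1] 0.9
```

Knockdown expression simulated with extra proximal binding in
downregulated genes, then called and tested:

```r
expr <- simulateExpression(sim$genes, plantedPromoterScores(peaks, sim$genes), cfg)
rec <- callMisregulated(expressionRecords(expr))
table(rec$direction)
#>       down         up unaffected
#>         35          2        263

prox <- windowSum(occ, "proximal", "up") + windowSum(occ, "proximal", "down")
mannWhitneyBinding(prox[rec$gene_id[rec$direction == "down"]],
                   prox[rec$gene_id[rec$direction == "unaffected"]])$p_value
#> [1] 2.978645e-14
```

Downregulated genes carry significantly higher proximal occupancy than
unaffected ones — the planted relationship, detected. Finally the
biophysics: a noisy simulated SPR curve refits its 14 nM Kd, and the
~2.9 µM nuclear concentration exceeds it ~200-fold, i.e. ~99.5% site
occupancy at equilibrium:

```r
pts <- simulateBindingCurve(14e-9, 1, noiseSd = 0.01, seed = 1)
fit <- fitBindingIsotherm(pts$concentration_molar, pts$response)
fit
#> BindingCurve: 8 points, Kd = 1.44e-08 M, Rmax = 1 (resid 0.0166)
concentrationKdRatio(2.9e-6, kdValue(fit))
#> [1] 201.5171
fractionalOccupancy(2.9e-6, kdValue(fit))
#> [1] 0.9950621
```

A thin command-line wrapper over the same functions lives in
`inst/scripts/tboxscan.R` (subcommands `simulate`, `annotate`, `scan`,
`cobind`, `biophys-fit`, `biophys-occupancy`).

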