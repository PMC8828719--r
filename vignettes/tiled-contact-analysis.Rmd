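---
title: "Analysing tiled Capture-C contact matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing tiled Capture-C contact matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TiledContacts)
```

## The assay and the data model

Tiled Capture-C targets every restriction fragment in a single genomic
window (here a 2.5 Mb tile binned at 2 kb, giving 1268 bins) and produces
a Hi-C-like symmetric contact matrix for that window alone. All objects
in this package are indexed by a `BinGrid`: a fixed-width partition of one
region, 0-based and half-open throughout (BED convention). Intervals
published with inclusive ends must be converted by adding 1 to the end on
ingest; `GenomicInterval("chr16", 92496000, 93617999 + 1)` is the package's
rendering of a printed interval `chr16:92,496,000-93,617,999`. Whether
published coordinates are themselves 0- or 1-based is generally
unknowable from published coordinates alone; the ingest rule is a
declared convention, and a 2 kb grid makes the distinction immaterial
for bin assignment in practice.

A `ContactMatrix` stores one value per unordered bin pair (canonical
upper triangle; symmetric access is provided) together with a processing
stage — `raw`, `merged`, `balanced`, `scaled` or `subtraction` — so each
operation can enforce what it may consume. Raw matrices hold integer
counts; subtraction matrices may be negative; everything else is
non-negative.

## Matrix processing

**ICE balancing.** Coverage bias is removed by iterative correction:
bins with zero marginal, plus the lowest 2% of positive-coverage bins
(`lowCovFraction = 0.02`, the common default of HiC-Pro-style pipelines;
configurable), are masked, then every entry is divided by \(b_i b_j\)
with \(b_i \leftarrow b_i \, m_i / \bar m\) until the unmasked marginals
agree to a relative spread of `tol = 1e-4` (at most 300 rounds; a
non-converged result is returned with a warning and flagged). Marginals
count the diagonal once — a convention that must be fixed for the result
to be reproducible, and which matches the "total interactions" definition
below. After convergence the matrix is rescaled to its input total so
that balancing does not change sequencing depth bookkeeping.

**Totals and scaling.** `totalInteractions()` counts every unordered
pair once, diagonal included. `scaleToMeanTotal()` multiplies each
balanced matrix by `mean(totals) / own total`, after which all samples
share the mean total — the cross-sample normalisation used before
computing subtraction matrices and display exports. Within-matrix ratios
are untouched (one global factor per sample).

**Subtraction and display capping.** `subtractMatrices()` is an
entry-wise difference of two scaled samples over the union of supports.
Contact data are heavy-tailed, so displays cap values at a percentile of
the *non-zero* stored values (sparse matrices are dominated by structural
zeros; a percentile over all cells would be degenerate — this choice is
documented because tools differ). For subtraction matrices the cap is
applied symmetrically to positive and negative values (the +/− 97th
percentile convention); ordinary matrices are typically drawn at the 94th
percentile. Percentiles interpolate linearly between order statistics.

## Virtual Capture-C profiles

`virtualCapture()` extracts the row of one viewpoint bin (a promoter,
typically) as a per-bin track. The viewpoint bin itself is always
excluded — it is dominated by self-ligation — and an optional
`exclusionRadius` widens the excluded window; balancing-masked bins are
excluded too. `normalizeProfile()` rescales to contacts per million cis
interactions of the same processed matrix the profile came from, making
tracks comparable across samples regardless of depth; the scale
(per-million) is fixed so that numbers mean the same thing across runs.
`aggregateReplicates()` returns the per-bin mean and sample SD
(denominator \(n-1\); zero for a single replicate), and bins missing in
any replicate are missing in the aggregate. Tracks export as bedGraph.

## Domain and enhancer-promoter quantification

Domains (TADs and sub-TADs) are *inputs* here — in this assay they are
typically called by eye from the merged maps — supplied as named
half-open bin ranges.

**Insulation.** `intraTadRatio()` computes, for every bin of a domain,
the ratio of its summed contacts to other domain bins (self-bin
excluded: a self-ligation count is not an interaction) over its summed
contacts to all bins outside the domain. Bins with zero extra-domain
signal are dropped — not assigned infinity — and the drop count is
reported, keeping the downstream rank tests defined. The per-bin ratios
of one sample form the distribution that enters group testing; ratios
are computed per replicate on scaled matrices by default (raw-count mode
is retained via `allowRaw`).

**Boundary contacts.** `boundaryBinSets()` picks the *k* = 4 outermost
CTCF sites (by start coordinate — a deterministic tie-break) at each end
of a domain and de-duplicates the bins they overlap;
`boundaryContacts()` then returns the full A×B grid of contact values,
zeros included, as the per-sample distribution — a proxy for CTCF-CTCF
corner looping.

**E-P contacts.** `epContacts()` quantifies, from the promoter-bin
viewpoint, the contact to every enhancer's overlapping bins. The total
sums over the de-duplicated union of enhancer bins, so it is invariant
to how enhancer annotations partition the same bins, and the promoter's
own bin never contributes.

## Statistical layer

Per-bin contact quantities are strongly non-normal (the Shapiro-Wilk
gate `normalityCheck()` documents this on each run), so group
comparisons use the tie-corrected Kruskal-Wallis test with Dunn's post
hoc z comparisons and Holm (default) or Benjamini-Hochberg adjustment.
Midranks are used throughout and the tie term is computed over the
pooled data; the fully tied degenerate case is defined as \(H = 0, p =
1\) rather than 0/0. Dunn's test is computed unconditionally but flagged
as not warranted when the omnibus p ≥ 0.05. For two groups, Dunn's
unadjusted p equals the Kruskal-Wallis p on the same ranks — a
consistency property the test suite checks.

Replicate ordination follows the count-based convention: median-of-ratios
size factors, `log2(count/factor + 1)`, then PCA of samples with a
deterministic sign convention (each component is flipped so its
largest-magnitude loading is positive). `pcaSamples()` defaults to all
rows with non-zero variance; the pipeline's ordination step restricts to
the 500 most-variable cells — the documented default of the count-PCA
tooling this step mirrors, and a necessary restriction at desk-scale
depth, where the full table is dominated by shallow-count noise rows
that carry no state signal.

## The synthetic contact-map generator

The generator stands in for sequencing data. Its expected intensity over
the upper triangle is

\[
E_{ij} \propto (1+|i-j|)^{-\alpha}
  \prod_{D:\, i,j \in D} \gamma_D
  \prod_{L} \left(1 + \lambda_L e^{-((i-a_L)^2+(j-b_L)^2)/(2w_L^2)}\right),
\]

a power-law distance decay (\(\alpha = 1\) by default) with
multiplicative block enrichments \(\gamma_D \ge 1\) for (nested) domains
and Gaussian loop anchors of strength \(\lambda_L\) and width \(w = 1\)
bin. Diagonal cells carry the distance term \((1+0)^{-\alpha} = 1\):
real matrices contain self-bin signal, and downstream operations define
their own diagonal handling. Observed counts are a multinomial draw of
`depth` read pairs over the normalised upper triangle — chosen over
independent Poisson cells because fixed totals match the
"scale to the mean total" normalisation downstream; either is
defensible, one had to be picked. Per-replicate seeds are derived from
the master seed with per-state and per-replicate offsets and recorded in
the truth manifest, so replicates are independent yet every file is
byte-reproducible.

`runx1LikeConfig()` instantiates the geometry of a hematopoietic
developmental locus: a 1268-bin tile; a main TAD at bins [465, 1026)
(561 bins, ≈1.1 Mb); two nested sub-TADs sharing an internal boundary
bin next to one promoter, whose boosts rise monotonically over the
states ESC → mesoderm → HPC (γ = 1.0, 1.5, 3.0); enhancer-promoter
loops from the second promoter that strengthen over differentiation;
convergent CTCF corner loops; and, with `knockout = TRUE`, an `HPC_KO`
state in which every loop anchored at the promoter-proximal boundary
bin is removed while all boosts stay put — a boundary-deletion variant.
No quantitative effect sizes for sub-TAD strengthening are available to
copy from real data, so the default γ ladder was chosen once to give
visually and statistically realistic structure at a desk-scale depth of
5×10⁵ read pairs per replicate; everything is overridable.

What the generator does *not* emulate: restriction-fragment-level
(non-uniform) binning, trans contacts, polymer/loop-extrusion mechanics,
mappability structure, or library-complexity artefacts. Passing tests
therefore demonstrate that the pipeline's operations are correct and
that its statistics detect the simulated effects at realistic depth —
not that any biological conclusion transfers to a particular real
dataset.

## Numerical choices and degenerate inputs

* Percentile caps use type-7 (linear-interpolation) quantiles.
* ICE re-balancing of an already balanced matrix changes entries by at
  most the convergence tolerance (checked in the suite).
* A matrix whose every bin is masked refuses to balance; a single
  all-zero bin is masked and reported.
* `scaleToMeanTotal()` refuses zero-total matrices; subtraction drops
  exact zeros from storage.
* The trailing bin of a tile whose length is not a bin multiple is kept
  (no silent truncation).
* All-tied rank tests return \(H = 0, p = 1\); Dunn with zero variance
  returns z = 0, p = 1.

## Problem sizes used by the test suite

The suite exercises the full 1268-bin preset where geometry matters
(insulation, detection power, ordination) and 10-60-bin grids where only
algebra matters. The detection-power check runs two states × 4
replicates at depth 5×10⁵ over 20 simulation seeds per arm — the
smallest design that cleanly separates a 1.5× from a 3.0× sub-domain
boost while keeping a desk-scale runtime — and the type-I-error check
uses 1000 null simulations of 3 × 50 observations.

## Worked example

```{r example, eval = FALSE}
cfg <- runx1LikeConfig(depth = 5e5, seed = 1, replicatesPerState = 3)
outdir <- tempfile("sim")
simulateExperiment(cfg, outdir)

sam <- expand.grid(replicate = 1:3, state = cfg@states,
    stringsAsFactors = FALSE)
sam$path <- file.path(outdir, sprintf("%s_rep%d.tsv", sam$state,
    sam$replicate))

config <- pipelineConfig(
    grid = file.path(outdir, "grid.json"), samples = sam,
    domains = list(main_TAD = c(465L, 1026L),
                   P1_P2_subTAD = c(564L, 630L),
                   P2_3prime_subTAD = c(629L, 720L)),
    features = cfg@features,
    viewpoints = c(P2 = coordToBin(cfg@grid, 92695073)),
    outdir = file.path(outdir, "results"))
summary <- runPipeline(config)
```

The run writes per-state merged scaled matrices, capped subtraction
matrices, mean/SD bedGraph tracks per viewpoint and state, tidy TSV
tables of insulation ratios, boundary contacts and E-P totals, the
Kruskal-Wallis/Dunn comparisons across states, PCA coordinates, and a
JSON summary declaring every output with the parameters that produced
it.

## Known limitations

* Single-chromosome, single-region grids only — the assay is targeted;
  genome-wide containers, multi-resolution pyramids and binary Hi-C
  formats are out of scope (the triplet TSV dialect is the interchange
  format).
* No de novo TAD or loop calling: domains are user inputs.
* The chi-square approximation to the Kruskal-Wallis null is used
  throughout (no exact small-sample p); at the group sizes produced by
  per-bin quantification this is accurate, and the suite checks it
  against a permutation reference at small n.
* Pooling per-bin ratios across replicates treats bins as exchangeable
  observations; bin-level autocorrelation makes the rank tests somewhat
  conservative under the null, which the detection-power checks bear
  out.
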