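# TiledContacts

Analysis of tiled Capture-C (Tiled-C) chromatin contact matrices in R.

Tiled-C targets every restriction fragment in one genomic window and
yields a Hi-C-like contact matrix for that window at high depth — the
assay of choice for following how a single locus (say, a developmental
gene inside its TAD) rewires its enhancer-promoter contacts across cell
states. This package provides the full downstream analysis for such
data, for locus-scale chromatin biologists:

- sparse triplet matrix I/O on a fixed bin grid (0-based, half-open,
  BED-compatible), with replicate merging and self-describing JSON grid
  sidecars;
- **ICE balancing** — iterative correction to equal bin marginals with
  low-coverage masking — followed by **scaling of all samples to their
  mean total interactions**, subtraction matrices between states, and
  percentile-capped display exports;
- **virtual Capture-C** viewpoint profiles (per-million-cis normalised,
  mean ± SD across replicates, bedGraph export);
- **quantification statistics**: the intra-TAD interaction ratio
  (insulation score) per bin, boundary CTCF-CTCF contacts between the
  outermost CTCF bins of a domain, and enhancer-promoter contact totals
  from a promoter viewpoint;
- a **nonparametric statistical layer**: Shapiro-Wilk gate,
  tie-corrected Kruskal-Wallis, Dunn's post hoc z tests, Holm/BH
  adjustment, plus median-of-ratios size factors and sample PCA for
  replicate ordination;
- a **synthetic contact-map generator** — power-law distance decay with
  nested domain boosts and Gaussian loop anchors, multinomial count
  sampling — that emulates a developmental ESC → mesoderm → HPC time
  course and a CTCF-boundary-knockout variant, so the whole pipeline
  runs and is tested without any sequencing data.

## The core statistics

For a domain \(D\) and bin \(b \in D\) on a balanced, depth-scaled
matrix \(M\), the insulation (intra-TAD interaction) ratio is

```
ratio(b) = sum_{j in D, j != b} M[b, j]  /  sum_{j not in D} M[b, j]
```

and the per-bin ratios of each sample are compared across states with a
tie-corrected Kruskal-Wallis test

```
H = [ 12 / (N(N+1)) * sum_i n_i (rbar_i - (N+1)/2)^2 ] / [ 1 - sum_t (t^3 - t) / (N^3 - N) ]
```

followed by Dunn's pairwise z statistics on the same ranks with Holm or
Benjamini-Hochberg adjustment. The generator's expected intensity is

```
E[i, j] ~ (1 + |i-j|)^-alpha * prod_{D: i,j in D} gamma_D * prod_L (1 + lambda_L * exp(-((i-a)^2 + (j-b)^2) / (2 w^2)))
```

normalised over the upper triangle; counts are a multinomial draw of
`depth` read pairs.

## Worked example

Simulate the developmental preset (1268 bins at 2 kb; main TAD at bins
[465, 1026); two nested sub-TADs whose boosts rise over ESC → mesoderm →
HPC) and run the full pipeline:

```r
library(TiledContacts)

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

read.delim(file.path(outdir, "results", "group_tests.tsv"))
```

The group-test table from this exact run (seed 1):

```
                     statistic   group1   group2        z      p_adj
1          insulation_main_TAD      ESC mesoderm  -3.9289  8.532e-05
4      insulation_P1_P2_subTAD      ESC mesoderm  -8.7583  1.981e-18
5      insulation_P1_P2_subTAD      ESC      HPC -20.1274  1.273e-89
6      insulation_P1_P2_subTAD mesoderm      HPC -11.3691  1.192e-29
8  insulation_P2_3prime_subTAD      ESC      HPC -22.8495 4.437e-115
14                       ep_P2      ESC      HPC  -2.6833  2.187e-02
```

Negative z means the later state has the higher ranks: both sub-TADs
strengthen significantly at every step of the time course (Holm-adjusted
p down to 1e-115 at this simulated depth), and total enhancer-P2
contacts are significantly higher in HPC than ESC (p = 0.022) — the
qualitative behaviour the generator encodes. The run also writes merged
scaled matrices per state, ±97th-percentile-capped subtraction matrices
between consecutive states, mean/SD virtual Capture-C bedGraphs for the
P2 viewpoint, insulation/boundary/E-P TSV tables, and PCA coordinates of
the 9 replicates (PC1 explains 34% of variance and separates the three
states).

`renderMatrix(m, 94, "map.pdf")` draws any matrix as the usual rotated
triangle, capped at the 94th percentile (diverging palette with
symmetric limits for subtraction matrices).

## Documentation

The methods vignette (`vignettes/tiled-contact-analysis.Rmd`) describes
the processing model, the generator and its defaults, the statistical
conventions, numerical edge cases, and what the synthetic data do and do
not establish about real data.
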