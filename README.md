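# apaxis

Reconstructing a one-dimensional anterior–posterior (AP) body axis from 2-D
embeddings of single-nucleus RNA-seq data of segmenting arthropod embryos, and
mining the resulting expression profiles for segmentation-stripe genes.

## The problem

In embryos such as the spider germ band, ectoderm cells at different AP
positions are in measurably different transcriptional states: segmental
stripes emerge by bi-splitting of broad expression domains in the head,
tri-splitting in the thorax, and oscillatory (clock-like) expression in the
posterior. When nuclei from such an embryo are sequenced and run through the
standard single-cell reduction stack (log-normalization → PCA → graph
clustering → UMAP), the ectoderm forms an elongated supercluster whose long
axis recapitulates the AP order of the tissue. `apaxis` exploits this to put
the spatial coordinate back:

1. **Axis reconstruction** — a spline through the density ridge of the
   ectoderm supercluster, oriented by terminal marker-gene density peaks,
   discretized into 10,000 arc-length points; each nucleus gets the position
   of its nearest curve point, `position = s(nearest point)`, and its
   `distance` to it. Nuclei beyond the spline termini are omitted.
2. **Expression profiles** — nuclei within a distance threshold of the curve
   are mirrored at both termini and each gene's expression is
   loess-smoothed (span 0.05, local quadratic) onto 160 grid points, trimmed
   to the central 80: a genome-wide matrix of profiles
   `E[g, p], p = 1..80` along the axis.
3. **Pattern-gene mining** — sparse genes are excluded by the minimum
   expression gap along the axis (Ward 2-group cut); pattern genes are
   selected by two rounds of Ward clustering on profile features
   (mean, max − min); first derivatives
   `d[i] = (E[i+1] − E[i−1]) / 2` expose expression-domain boundaries,
   position–position Pearson maps expose segmental periodicity, and
   windowed single-nucleus gene–gene correlations expose co-expression.
4. **Perturbation experiments** — rebuild the analysis from only the selected
   genes (submatrix A) vs all remaining genes (submatrix B), and randomize
   expression within single clusters at graded fractions, scoring recovery by
   absolute Spearman rho and a k-nearest-neighbor continuity index.

Because dissociated data carry no per-nucleus ground truth, the package ships
a negative-binomial germ-band simulator (`simulate_embryo`,
`embed_ground_truth`) with known latent positions and stripe specifications;
the entire pipeline is validated against that truth. Intended users are
developmental biologists and computational people working on axial patterning
in non-model arthropods (or any tissue whose embedding linearizes a spatial
axis).

## Worked example

```r
library(apaxis)

panel <- default_gene_panel()              # 40 patterned / 400 uniform / 60 sparse genes
gs    <- panel_gene_sets(panel)
sim   <- simulate_embryo(3000, 400, panel, seed = 7)
emb   <- embed_ground_truth(sim$truth, "arc", noise_sd = 0.5, seed = 7)
nm    <- log_normalize(sim$counts)

rcp   <- extract_ridge_control_points(emb, paste0("ecto_", 1:10),
           anchor_genes = list(anterior = gs$anchors_anterior,
                               posterior = gs$anchors_posterior), nm = nm)
curve <- fit_axis_curve(rcp$control_points, anchors = rcp, n_polyline = 10000)
curve
#> Reconstructed AP axis
#>   control points : 11
#>   polyline points: 10000
#>   termini at arc positions 0.881 (anterior), 9.696 (posterior)
#>   terminus-to-terminus length 8.815 embedding units

pos <- assign_positions(emb, curve, paste0("ecto_", 1:10))
u   <- setNames(sim$truth$nuclei$u, sim$truth$nuclei$nucleus_id)
abs(cor(pos$position, u[pos$nucleus_id], method = "spearman"))
#> [1] 0.9798047
```

The reconstructed arc-length positions of 2,555 retained nuclei rank-correlate
at |ρ| ≈ 0.98 with the latent positions the simulator drew, under embedding
noise equal to 5% of the curve length. Continuing:

```r
prof <- build_profile_matrix(nm, pos, smoothing_params(near_axis_threshold = 1.5))
sf   <- sparse_gene_filter(nm, select_near_axis(pos, 1.5))
sel  <- two_round_select(compute_pattern_features(prof[sf$retained, ]))
sum(sel$selected)
#> [1] 40
mean(gs$patterned %in% sel$gene_id[sel$selected])
#> [1] 1
```

All 40 simulated pattern genes (and nothing else) are selected: sensitivity 1
at zero false selection for this seed. The threshold 1.5 is the synthetic-scale
near-axis cutoff (3 × the embedding noise sd); on the UMAP scale the method was
developed for, the conventional value is 0.3 units.

A single call runs everything (simulate → QC → cluster → axis → profiles →
selection → derivatives) and writes stage outputs plus a manifest:

```r
res <- run_pipeline(pipeline_config(), outdir = "out")
str(res$manifest)
```

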