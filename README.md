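# relayvelo

Cell-specific RNA velocity for single-cell RNA-seq, by a relay of local
kinetics.

RNA velocity infers where a cell is heading from the balance of nascent
(unspliced, `u`) and mature (spliced, `s`) mRNA. The classic first-order
model per gene is

    du/dt = alpha - beta * u
    ds/dt = beta * u  - gamma * s

with transcription rate `alpha`, splicing rate `beta` and degradation rate
`gamma`. Conventional velocity tools fit one set of rates per gene for all
cells, which fails whenever subpopulations follow different kinetics —
transcriptional bursts mid-differentiation ("boost"/MURK genes) or
lineage-specific rates (branching genes).

`relayvelo` instead trains one small neural network per gene that maps each
cell's `(u, s)` to cell-specific `(alpha, beta, gamma)` in `[0, 1]`. The
training signal is local: the velocity vector predicted for a cell by one
Euler step of the kinetics must point toward some observed neighbor in the
gene's phase portrait (a hard-max cosine-similarity loss, summed over
cells). Chaining these local constraints across the manifold "relays" the
direction of change from cell to cell, so rates are resolved at single-cell
resolution without assuming shared kinetics. An orientation device based on
the classic steady-state balance line selects the physical arrow of time
among the cosine-equivalent solutions (see the methods vignette).

The package also ships everything needed to benchmark the method without
external data:

* a kinetic simulator with four regimes (mono-kinetic two-step
  transcription, transcriptional boost, multi-lineage forward and backward
  branching), Gaussian expression noise, imbalanced-lineage downsampling,
  and Poisson technical dropout with first-moment recovery;
* neighbor machinery (gene-specific phase-plane kNN, gene-shared kNN,
  first-moment smoothing, density-normalizing downsampling);
* projection of the high-dimensional velocity field onto any 2-D embedding
  through a correlation-based transition kernel;
* a gene-shared pseudotime built from stochastic streamlines over a
  meta-cell grid, with graph-based merging of trajectory "time zones";
* benchmark metrics: cosine error rate (0.7 cutoff), rate-ratio recovery,
  convergence-epoch detection.

## Worked example

```r
library(relayvelo)

# simulate a two-step ("on, then off") transcription benchmark
spec <- regime_spec("mono_kinetic", n_cells = 1000, n_genes = 10, seed = 1)
ds <- generate_dataset(spec)

# one small network per gene learns cell-specific (alpha, beta, gamma)
vr <- train_dataset(ds, config = train_config(seed = 1))
#> velocity_result: 10 genes x 1000 cells, median loss 0.0807

# percentage of cells whose predicted velocity direction disagrees with
# the ground truth (cosine similarity < 0.7)
round(benchmark_error_rates(vr, ds), 1)
#> gene_0001 gene_0002 gene_0003 gene_0004 gene_0005 gene_0006 gene_0007
#>       4.3       5.7       4.7       3.6       3.7       4.1       4.7
#> gene_0008 gene_0009 gene_0010
#>       4.7       3.9       4.4

# squared Pearson correlation between predicted and true alpha/beta,
# pooled over genes and kinetic phases
rec <- benchmark_recovery(vr, ds)
recovery_r2(rec$ab_pred, rec$ab_true)
#> [1] 0.9853566

# the cell-specific transcription rate separates the two phases without
# any prior two-step constraint
fit <- vr$fits[[1]]
tapply(fit$rates$alpha,
       ifelse(ds$true_alpha[, 1] > 0, "induction", "repression"), mean)
#>  induction repression
#> 0.51916524 0.07075392
```

So on this benchmark ~4–6% of cells per gene miss the 0.7-cosine cutoff,
the predicted transcription-to-splicing ratios track the truth at
R² ≈ 0.99, and the inferred `alpha` is high in the induction phase and
near zero in repression — two clusters, recovered from the data alone.

Downstream, `transition_matrix()` + `project_velocity()` place the
velocity field on an embedding, and `estimate_pseudotime()` orders cells
along it; `run_pipeline()` chains all stages and writes CSV tables plus a
provenance JSON. A thin command-line front end with `simulate`,
`velocity`, `project`, `pseudotime`, `evaluate` and `run` subcommands is
installed at `system.file("scripts", "relayvelo", package = "relayvelo")`.

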