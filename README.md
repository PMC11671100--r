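# mitodemux

Donor demultiplexing and cross-genotype doublet detection for pooled
single-cell genomic libraries, using only mitochondrial germline variants.

## Why mitochondrial variants

Pooling cells from several donors in one single-cell run cuts costs and
removes batch effects, but every barcode must then be traced back to its
donor. Nuclear-variant demultiplexers need per-cell nuclear coverage that
chromatin assays (scATAC-seq, mtscATAC-seq, ASAP-seq, DOGMA-seq) rarely
provide. The mitochondrial genome — 16,569 bp at hundreds of copies per
cell — is covered well by exactly these assays, and each maternal lineage
carries a private set of homoplasmic germline substitutions (VAF ≈ 1 in
every cell). Those variants are an endogenous barcode: cells of the same
donor share them, cross-donor doublets mix two sets.

## The model

For cell *c* and genotype cluster *i* with sample-specific variant set
*G<sub>i</sub>*, let *A₁* and *A₀* be the summed alternative and reference
allele counts over the variants of *G<sub>i</sub>* observed in *c*. With

*A₁* ~ Binomial(*A₀* + *A₁*, *p*),  *p* ~ Beta(α, β),
α = 1 + mean per-variant alternative count in cluster *i*, β = 1,

the posterior is Beta(α + *A₁*, β + *A₀*), summarised by its mode
(α + *A₁* − 1)/(α + β + *A₁* + *A₀* − 2). `p1` is the posterior for the
cell's own (first-fitted) cluster, `p2` the best among the others.
Singlets have p1 ≈ 1 and low p2; cross-genotype doublets have
intermediate p1 and elevated p2. Threshold rules (singlet: p1 > 0.99;
doublet: p1 < 0.8 or p2 > 0.2) label most cells and a 5-nearest-neighbour
vote in (p1, p2) space resolves the rest; singlets are assigned to the
argmax-posterior cluster.

Upstream, candidate SNVs are called from a barcode-aware mitochondrial
pileup with VarScan-style thresholds (depth ≥ 8, ≥ 2 alt reads,
VAF ≥ 1%) and kept as potential germline variants when the bulk VAF lies
strictly between 1% and 99%; high-confidence germline variants are those
homoplasmic (VAF > 0.99) in more than half of their non-zero cells, and
per-cluster variant sets lose any variant shared between clusters.
The number of pooled donors can be estimated by silhouette score, and a
"direct" mode clusters the variants instead of the cells when depth is
too low for cell clustering. See `vignettes/mitodemux-methods.Rmd` for
the full account.

## Worked example

Simulate a 4-donor pool (100 cells each, ~4× mitochondrial coverage,
8% doublets), demultiplex it, and score the result against the truth:

```r
library(mitodemux)

hap <- simulate_haplotypes(4, n_private = c(5, 30), n_shared = 2, seed = 1)
#> mito_haplotypes: 4 donors, 53 private + 2 shared variants
sim <- simulate_cells(hap, cells_per_donor = 100, reads_per_cell = 1000,
                      doublet_fraction = 0.08, error_rate = 0.002, seed = 1)
#> mito_sim: 400 barcodes ( 32 doublets ), 55 variants, 4 donors

run <- demux_pool(as_allele_matrices(sim), K = 4)
run
#> demux_run: K = 4 | Doublet 32, Singlet 368
run$model
#> genotype_clusters: K = 4 | 29/8/5/11 specific variants | alpha = 5.03, 4.95, 4.90, 5.08

pool_metrics(sim, run$result)[c("accuracy", "donor_tpr", "doublet_tpr",
                                "doublet_auc_cross", "ari_singlets")]
#> accuracy 0.970 | donor TPR 0.984 | doublet TPR 1.000 | AUC(cross) 1.000 | ARI 1.000
```

Reading the numbers: the four clusters recovered 29/8/5/11 sample-specific
variants (the simulated private sets) and α ≈ 5 reflects the ~4 reads per
site per cell plus the uniform prior. Every cross-genotype doublet was
caught (doublet TPR 1.0) and singlet clustering is perfect (ARI 1.0);
overall accuracy is capped near 0.97 because a quarter of the simulated
doublets pair two cells of the *same* donor, which no genotype-based
method can see — they carry one genotype.

For files rather than in-memory matrices, `run_pipeline()` chains pileup →
variant calling → matrices → clustering → doublet detection and writes
`demux_result.tsv`, the variant table (TSV + VCF), MatrixMarket matrices,
the model, the effective configuration and a stage-timing log. A thin CLI
wraps the same functions:

```sh
Rscript inst/cli/mitodemux.R simulate --donors 8 --cells-per-donor 100 \
    --reads-per-cell 1000 --doublet-frac 0.08 --seed 1 --out-dir sim/
Rscript inst/cli/mitodemux.R demux --matrices sim/ --samples 8 --out-dir out/
Rscript inst/cli/mitodemux.R evaluate --truth sim/truth.tsv \
    --pred out/demux_result.tsv --out metrics.json
```

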