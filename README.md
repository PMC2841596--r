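# specfam

Spectral clustering of protein sequence similarity graphs: inference of
protein families and superfamilies from pairwise BLAST E-values alone.

## Who this is for

Anyone with an all-against-all BLAST result (or just a FASTA file and the
BLAST+ executables) who wants sequences grouped into putative homolog
families. Single-threshold methods work for close homologs but miss remote
relationships; `specfam` implements a *global* method — spectral clustering
of the whole similarity graph — together with the two classical local
baselines (E-value-threshold connected components and average-linkage
hierarchical clustering), internal quality statistics, gold-standard
evaluation, and annotation-enrichment assessment.

## The method

E-values are mapped to evolutionary-relatedness probabilities by a logistic
model on x = −log₁₀(max(E, 10⁻¹⁸⁰)) and symmetrized by taking the smaller
E-value of the two BLAST directions, giving a sparse symmetric affinity
matrix **S** with unit diagonal. After peeling connected components of
fewer than five sequences (they return unchanged as final clusters) and
connecting the remaining components with random bridge edges of weight
0.005, the pipeline forms

&nbsp;&nbsp;&nbsp;&nbsp;**L** = **D**^(−1/2) **S**′ **D**^(−1/2),&nbsp;&nbsp;
d_i = Σ_j s_ij,

computes the leading eigenpairs (ARPACK), selects the number of clusters K
as the smallest k with λ_k/λ_{k+1} > ε (ε = 1.02 by default; or bound K, or
fix it), row-normalizes the n × K eigenvector matrix, and runs k-means with
orthogonally-placed initial centroids. Quality is reported as mass fraction
and weighted Newman modularity; against a gold standard the size-weighted
combined F-score F = (1/n) Σ_i n_i· max_j 2p_ij r_ij/(p_ij + r_ij); against
flat annotations, hypergeometric term enrichment with Benjamini–Hochberg
FDR control at α = 0.05.

## Worked example

A bundled 12-sequence, 3-family toy instance (ids `glb*`, `efh*`, `cup*`
with hand-written E-values, connected by a few weak cross-family hits):

```r
library(specfam)
toy <- toy_worked_example()
fit <- specfam(toy$records, opts = spectral_opts(mode = "exact", k_exact = 3),
               gold = toy$gold)
summary(fit)
#> spectral clustering of 12 sequences
#> Clusters: 3 (sizes: 4, 4, 4)
#> Spectral K = 3; leading eigenvalues: 1.0000, 0.9956, 0.9923
#> Mass fraction: 0.9946
#> Modularity:    0.6612
#> Combined F-score: 1.0000
```

The three top eigenvalues near 1 are the spectral signature of three
well-separated families; F-score 1 means the gold families were recovered
exactly, and modularity 0.66 says two-thirds more weight sits inside the
clusters than degree-preserving chance would put there. Fully automatic
mode on synthetic data with planted structure:

```r
sim <- generate_planted(planted_spec(seed = 7))   # 3 families of 20
fit2 <- specfam(sim$records, gold = sim$gold)
fit2
#> Protein family clustering (spectral): 60 sequences in 3 clusters
#>   mass fraction 0.9962, modularity 0.6627
#>   combined F-score vs gold standard: 1.0000
head(fit2$eigenvalues, 5)
#> [1] 1.0000000 0.9955384 0.9936334 0.1616405 0.1425104
```

The eigengap after position 3 (0.994 → 0.162) is what the automatic mode
detects. `plot(fit2)` draws the cluster-rearranged greyscale heatmap;
`write_clusters_txt()`, `write_xgmml()` and `write_heatmap_png()` export
results for downstream tools (XGMML loads into Cytoscape).

## Command line

```sh
Rscript inst/cli/specfam.R generate --out-prefix demo --sizes 20,20,20 --seed 1
Rscript inst/cli/specfam.R cluster --input demo.evalues.tsv --format triplet \
    --gold demo.gold.tsv --out-prefix demo
Rscript inst/cli/specfam.R eigs --input demo.evalues.tsv --max-clusters 10
Rscript inst/cli/specfam.R evaluate --clusters demo.clusters.txt --gold demo.gold.tsv
```

`cluster` accepts `--method {spectral,cca,hierarchical}`, the spectral
flags `--mode/--epsilon/--max-clusters/--clusters/--seed/--bridge-weight/
--min-component-size`, and `--annotations` for the enrichment report; FASTA
input triggers an all-vs-all BLAST run through the installed BLAST+
binaries.

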