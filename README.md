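# atmnet

Network-centric analysis of the adipose tissue microenvironment in obesity:
discovery of BMI-associated gene modules in bulk adipose transcriptomes, and
subtyping of macrophages by *how their genes are wired* rather than by what
they express.

## The problem

Obesity remodels adipose tissue, and macrophages are central to that
remodeling. Two analytical obstacles motivate this package:

1. **Bulk cohorts**: thousands of genes change with body-mass index (BMI);
   the interesting unit is not the single gene but the co-expression module
   whose activity tracks BMI, and the hub genes inside it.
2. **Single cells**: macrophage subtypes in fat can share marker-gene
   expression yet differ in their gene *regulatory* wiring, so clustering
   cells on expression misses them. A per-cell network statistic makes the
   wiring itself the feature.

## The methods

**Bulk module pipeline.** Counts are CPM-normalized; differentially
expressed genes between obese (BMI ≥ 25 kg/m²) and healthy samples are
called by Welch's t-test (|log₂FC| > 0.25, P < 0.05); a co-expression
network over the DEGs in the obese group keeps gene pairs with |PCC| > 0.65
and P < 0.05 and restricts to the largest connected component. Multilevel
(Louvain) communities larger than 20 genes are summarized by their first
principal component — the community feature vector (CFV) — and refined by a
k-means that uses CFVs as centroids and 1 − PCC as the distance. The module
whose CFV has the largest |Spearman ρ| with BMI is the key module; its hub
genes are ranked by PageRank on a protein–protein interaction network
(top 25), and a random forest regressing BMI on the hubs screens key genes
(%IncMSE > 5.3 and IncNodePurity > 2.9).

**Cell-specific networks (CSN).** For genes *x*, *y* in cell *k*, with
boxes (expression neighborhoods) of sizes nₓ(k), n_y(k), overlap n_{xy}(k)
and n cells in the region:

    ρ_xy(k) = n_xy(k)/n − (n_x(k)/n)·(n_y(k)/n)

standardized as z = ρ·n·√(n−1) / √(nₓ·n_y·(1−nₓ/n)·(1−n_y/n)); an edge
enters cell *k*'s network when z exceeds the one-sided normal quantile at
α = 0.01 (an exact finite-sample hypergeometric test is also provided).
Degrees of every gene in every cell's network form the **network
characterization matrix (NCM)**, which is clustered (log1p → z-score → PCA →
shared-nearest-neighbor graph → Louvain at resolution 0.5) to define
macrophage subtypes. Per subtype, Wilcoxon tests on degrees give
differential degree genes (DDGs; |log₂FC| > 0.25, P < 0.05) and an AUC
screen gives featured degree genes (FDGs; log₂FC > 0.5, AUC > 0.75).

**Subtype-specific GRNs.** Genes connected in ≥ 50 % of a subtype's cells
are drivers; edges among drivers present in ≥ 50 % of cells form the ssGRN.
DeepWalk-style random walks embedded by PPMI + truncated SVD, cosine
similarity, and a Gaussian-mixture model (BIC-selected k) yield gene
modules, whose hypergeometric GO-style enrichment is aggregated per term by
the maximum −log₁₀ P across modules.

A synthetic-data module generates bulk cohorts with planted BMI-linked
modules, cell populations whose subtypes differ only in dependency
structure (Gaussian copula over negative-binomial marginals, equal means),
scale-free interaction networks, and GMT term sets — so the entire workflow
is testable without downloads.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data (each writes tables under `results/`):

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_bulk_modules.R
Rscript analysis/03_sc_preprocess.R
Rscript analysis/04_subtype_networks.R
Rscript analysis/05_ssgrn_modules.R
```

`02_bulk_modules.R` prints, for the default cohort (150 genes × 200
samples, four planted 30-gene modules, module 2 tied to BMI at ρ ≈ 0.7):

```
differential genes: 121 of 150
network: 120 genes, 1932 edges (largest of 2 components)
modules: 30/30/30/30
module recovery ARI vs planted: 1.000
key module: M2 (Spearman rho 0.69 with BMI)
```

All four planted modules are recovered exactly (adjusted Rand index 1.0)
and the planted BMI module is identified as the key module at its
calibrated correlation. `04_subtype_networks.R` prints, for 600 cells in
three subtypes that share marginal expression and differ only in which
gene blocks co-vary:

```
per-cell networks: 65667 edges over 600 cells (109.4 per cell)
clusters found: 3, sizes 200/200/200
ARI vs planted subtypes: 1.000
  subtype 0: 20 up, 40 down DDGs, 20 FDGs
```

Expression-level clustering cannot separate these populations (their means
are identical); degree-profile clustering recovers them perfectly, and each
subtype's coupled gene blocks surface as its featured degree genes.

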