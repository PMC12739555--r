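---
title: "Methods: degree-based macrophage subtyping and BMI-linked gene modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degree-based macrophage subtyping and BMI-linked gene modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, the parameters
that matter, the numerical choices behind them, and what the synthetic
cohorts do and do not establish about real data.

## 1. The bulk module pipeline

### Model and assumptions

The bulk pipeline assumes a cohort of adipose transcriptomes with per-sample
BMI, in which co-regulated gene programs ("modules") exist and at most a few
of them track adiposity. The chain is: CPM normalization → Welch t-test
differential expression between obese (BMI ≥ 25 kg/m²) and healthy samples →
Pearson co-expression network over the differential genes in the obese group
→ Multilevel (Louvain) communities → first-PC community feature vectors
(CFVs) → correlation-distance k-means refinement → Spearman association of
each module's CFV with BMI → PageRank hubs on a protein interaction network →
random-forest key-gene screen.

Key parameter defaults, all exposed as arguments:

| parameter | default | role |
|---|---|---|
| `lfc_thresh` | 0.25 (log₂) | differential-gene fold cutoff |
| `p_thresh` | 0.05 | differential-gene p cutoff |
| `pcc_thresh` | 0.65 | absolute correlation for a network edge |
| `min_community_size` | 21 genes | smallest retained community (more than 20) |
| PageRank damping | 0.85 | standard random-surfer value |
| forest | 500 trees, mtry = ⌊p/3⌋ | regression convention |
| `incmse_thresh`, `purity_thresh` | 5.3, 2.9 | key-gene importance cutoffs |

Choices the procedure leaves open, and what this package does:

* **Fold-change scale.** The fold change is `log2((mean_obese + 1) /
  (mean_healthy + 1))` on the CPM scale, with the t-test on `log2(CPM + 1)`.
  A log₂ ratio of group means with a pseudocount is the field convention
  that makes a 0.25 threshold meaningful; the test on log-CPM keeps the
  t-statistic roughly variance-stable.
* **Which t-test.** Welch's unequal-variance form: obese/healthy cohorts
  are typically very unbalanced, and Welch is the safe default there.
* **Which samples carry the BMI association.** The network is built in the
  obese group, but CFVs and the module–BMI Spearman correlation use the full
  cohort. Restricting the correlation to obese samples range-restricts BMI
  and roughly halves every ρ, destroying the contrast between the key
  module and the rest; the association question ("does this program track
  BMI?") naturally spans the whole BMI range.
* **k-means semantics.** "CFVs as centroids with PCC distance" can be read
  as a one-shot assignment or as full Lloyd iteration. The default runs
  Lloyd (assignment by maximal correlation, centroid = mean standardized
  member profile, stop when assignments stabilize); `assign_only = TRUE`
  gives the one-shot reading. Distance is 1 − PCC, not 1 − |PCC|: an
  anti-correlated gene is a poor module member, not a perfect one.
* **Sign of a CFV.** PC1 is sign-fixed to correlate nonnegatively with the
  community's mean standardized profile, so "module up" means its genes go
  up. Zero-variance communities are an error; zero-variance genes fall into
  a reported null module.
* **Ties.** Top-25 hub selection breaks score ties lexicographically after
  rounding scores to 12 significant digits (PageRank on symmetric graphs
  yields floating-point-distinct copies of the same value).

### Degenerate inputs

All-zero genes are removed before CPM; an all-zero sample is an error naming
the sample. A network in which no pair passes both thresholds is an error
with diagnostic counts. A group with fewer than two samples is an error.
Constant genes get p = 1 rather than NaN.

## 2. Cell-specific networks and degree-based subtyping

### The statistic

For genes $x,y$ in cell $k$: the *box* of a gene is the
$\lceil 0.1\,n \rceil$ cells whose expression of that gene is nearest to
cell $k$'s value (ties broken by cell index; the focal cell is always
inside). With box sizes $n_x, n_y$, overlap $n_{xy}$ and $n$ cells in the
region,

$$\rho_{xy}(k) = \frac{n_{xy}(k)}{n} - \frac{n_x(k)}{n}\cdot\frac{n_y(k)}{n},$$

standardized as
$z = \rho\, n\sqrt{n-1} \,/\, \sqrt{n_x n_y (1 - n_x/n)(1 - n_y/n)}$ and
thresholded one-sided at $\alpha = 0.01$. Independence of the two boxes
gives $\rho = 0$; local co-variation inflates the overlap.

### Finite-sample behavior of the edge test

Under independence the box overlap is exactly
$1 + \mathrm{Hypergeometric}(n-1,\, n_x-1,\, n_y-1)$: both boxes contain
cell $k$ by construction, and for an independent second gene the other
$n_y - 1$ box members are a uniform random subset. Two consequences at
region sizes of a few hundred cells: the null mean exceeds the $n_x n_y/n$
the statistic subtracts (by ≈ 0.8 cells at $n = 200$, box 20), and the
discrete overlap distribution is right-skewed. The asymptotic normal test
is therefore anti-conservative at small $n$ — its realized edge rate at
$n = 200$, $\alpha = 0.01$ is several times the nominal level — while being
correct as $n$ grows (the bias is a vanishing fraction of the overlap's
standard deviation). The package keeps the normal test as the default
(`edge_test = "z"`) and provides `edge_test = "exact"`, which thresholds
the exact hypergeometric upper tail; the exact test is valid and slightly
conservative, because no deterministic cut of an integer overlap can
realize 0.01 exactly. Extra per-cell edges from the z-test's optimism act
as a uniform background degree and do not reorder degree profiles, which is
why subtype recovery is unaffected by the choice.

Ties deserve a note: cells with identical expression (zeros, in sparse
data) share one large tie-box resolved deterministically by cell index.
This makes the whole construction RNG-free: identical inputs give identical
networks on any platform.

### Degree clustering

The NCM (gene × cell degrees) is normalized by `log1p` then per-gene
z-score — chosen so hub genes do not dominate the PCA; `rank` and `raw`
alternatives are exposed — reduced to 10 PCs, turned into a kNN graph
(k = 20, self included), re-weighted by Jaccard overlap of neighbor sets
pruned below 1/15, and partitioned by Louvain at resolution 0.5. These
mirror the defaults of the standard single-cell toolchain the procedure
names. Differential degree genes use one-vs-rest two-sided Wilcoxon tests
with `logFC = log2((mean_in + 1)/(mean_rest + 1))`; the pseudocount of 1 is
appropriate because degrees are small integers that are often zero. The
down-regulated threshold is read as logFC < −0.25 (the symmetric
counterpart of the up rule). The FDG screen computes AUC by the
Mann–Whitney midrank identity, which equals the all-pairs count with ties
at one half, exactly.

### QC and feature selection

Cell filters remove cells with UMI < 500 or > 3500, fewer than 200 detected
genes, or more than 10 % mitochondrial UMIs (prefix `MT-`/`mt-`,
configurable). Removal inequalities are strict, so boundary cells survive —
the procedure states removal conditions only, and equality is not a removal
condition. Normalization is `ln(1 + 10^4 · count/total)`. Highly variable
genes are the top 5000 by the Shannon entropy of each gene's cell-wise
distribution ($p_i = x_i/\sum x$, $0\log 0 = 0$); the named intrinsic-
entropy score has no published formula, so plain entropy is the default and
the score function is pluggable (`score_fun`). Entropy is scale-invariant,
all-zero genes rank last at $-\infty$, and ties break by gene identifier.

## 3. Subtype-specific networks, embeddings, modules

Drivers are genes connected in at least $\lceil 0.5\,m\rceil$ of a
subtype's $m$ cells — the boundary is inclusive, so "half the cells"
qualifies; both the threshold and the rule are parameters. Edges among
drivers prevalent at the same level form the ssGRN; prevalence is stored
per edge.

Embeddings follow the DeepWalk recipe: 10 uniform random walks of 80
vertices from every non-isolated node, co-occurrence within a window of 5,
and factorization of the positive pointwise-mutual-information matrix by
truncated SVD at dimension 64 (capped at the node count). PPMI + SVD
factorizes the same matrix that skip-gram training with negative sampling
implicitly factorizes, and—unlike stochastic skip-gram training—is exactly
reproducible given the walk seed; SVD sign ambiguity is fixed by making the
largest-magnitude entry of each column positive. Isolated drivers embed at
the origin, are flagged, and have all cosine similarities defined as 0.

Gene modules come from a Gaussian mixture with diagonal/spherical
covariance families fitted to the rows of the cosine-similarity matrix
(the `--on embeddings` reading is available by passing the embedding matrix
directly), with the number of components selected by BIC over 2–12 and a
fixed-k override. The fit uses a conjugate prior on component parameters:
rows belonging to one well-connected community are near-duplicates, and
without regularization their variance estimates collapse and BIC splinters
communities into micro-clusters. Enrichment is the exact hypergeometric
upper tail per module × term, the top 60 terms per module by ascending raw
p (the procedure applies no multiplicity correction to this ranking; a BH
column can be added by the user from the returned p-values), and the
per-term summary is the maximum −log₁₀ p across modules, base 10.

## 4. What the synthetic cohorts emulate — and what they do not

`simulate_bulk` draws per-module latent factors that share a global
"adiposity programme" (between-module correlation 0.4), attaches genes by a
lognormal mean model (within-module latent correlation 0.95), and samples
Poisson counts. BMI is lognormal around 25 kg/m², loaded on the target
module's factor partly through the shared programme, calibrated through the
Gaussian–Spearman identity $\rho_S = \tfrac{6}{\pi}\arcsin(\rho/2)$ so the
target factor's Spearman correlation with BMI hits `bmi_effect`; off-target
modules inherit 0.65 × that correlation through the shared programme —
which is also what makes their genes differential between BMI groups and
thus visible to the network stage at all. Three design features are
deliberate and load-bearing:

* **Housekeeping background.** Non-module genes are highly expressed and
  stable. Without them, CPM normalization converts module swings into
  compositional anti-correlations across modules and destroys the planted
  structure — a reminder that the pipeline's correlation stage sees
  relative, not absolute, expression.
* **Bridge genes.** The last 3 genes of each module also track the next
  module (latent correlations 0.88 own / 0.8 next, solved jointly under the
  factor correlation). Real differential-gene networks form one connected
  component; with strictly disjoint modules the |PCC| > 0.65 graph is
  disconnected and the largest-component step would discard all but one
  module. Bridges emulate overlapping program membership at a strength that
  yields cross-module edges without confusing Louvain.
* **Spearman calibration before truncation.** BMI is a monotone transform
  of its latent, so the calibrated rank correlation survives the mapping to
  kg/m² exactly.

`simulate_cells` gives every subtype the same negative-binomial marginals
(mean scale 25, dispersion 0.3, lognormal depth sd 0.2) and a private
dependency template: two disjoint 10-gene blocks at correlation 0.97,
mapped through a Gaussian copula. Equal means force the degree pipeline —
not mean-expression clustering — to do the separating, which is the
premise the subtyping method rests on. Two blocks per subtype rather than
one larger block keep per-cell degree profiles even across the factor
range; with a single strong factor, cells at the factor's extremes acquire
systematically higher degrees than central cells, and that within-subtype
gradient is real structure that SNN–Louvain will split. Mitochondrial genes
and the depth spread place cells on both sides of the mito and UMI QC
cutoffs (a wider-spread configuration, used by the QC driver and tests,
also straddles the detected-genes cutoff, which a 60-gene matrix cannot).

What passing these tests does **not** show: robustness to batch effects,
doublets, ambient RNA, cell-type hierarchies, zero-inflation beyond the NB
marginals, or module structure that is weaker, overlapping, or
BMI-confounded in more adversarial ways. The generator's correlation levels
(0.95 within-module, 0.97 within-block) describe tightly co-regulated
programs; real modules are looser, and recovery rates on real cohorts will
be lower.

## 5. Problem sizes and reproducibility

The shipped analyses and the acceptance script use the generator's default
study conditions: 200 bulk samples × 150 genes with four 30-gene modules,
and 600 cells × 60 genes (plus 5 mitochondrial) in three equal subtypes —
sizes at which every stage, including the 1,770 gene-pair × 600-cell
network construction, runs in seconds on one CPU. One global integer seed
fans out to per-stage child seeds via a Lehmer-style mix over the stage
name (`child_seed`), so the bulk cohort, the cell population, walks,
forests and clustering are individually reproducible and jointly
independent. Every randomized component (Louvain, forests, walks, GMM) is
seeded; the cell-specific network construction itself uses no randomness
at all.

## 6. Known limitations

* The z-form edge test is anti-conservative for regions under ~1000 cells
  (Section 2); use `edge_test = "exact"` when calibrated error control
  matters more than continuity with the published statistic.
* `build_cell_networks` stores per-gene box membership densely; the
  `max_pairs` guard (default 60,000 pairs ≈ 350 genes) asks for HVG
  reduction rather than attempting matrices that would not fit.
* The GMM stage assigns every gene to exactly one module; overlapping
  modules are out of scope.
* Enrichment treats gene sets as flat lists (GMT); no ontology topology.
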