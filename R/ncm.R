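#' Network characterization matrix (per-cell gene degrees)
#'
#' Collects the degree vector of every cell's network into a gene x cell
#' matrix: entry (g, k) is the number of neighbors of gene g in cell k's
#' network (0 when the gene is isolated in that cell).
#'
#' @param nets a `cell_network_set`.
#' @return integer gene x cell matrix.
#' @export
build_ncm <- function(nets) {
  if (length(nets$cells) == 0L) stop("empty network set", call. = FALSE)
  gg <- length(nets$genes)
  nn <- length(nets$cells)
  ncm <- matrix(0L, gg, nn, dimnames = list(nets$genes, nets$cells))
  if (nrow(nets$edges) > 0L) {
    ci <- match(nets$edges$cell, nets$cells)
    gi <- match(nets$edges$gene_a, nets$genes)
    gj <- match(nets$edges$gene_b, nets$genes)
    inc <- c(gi + (ci - 1L) * gg, gj + (ci - 1L) * gg)
    tab <- tabulate(inc, nbins = gg * nn)
    ncm[] <- as.integer(tab)
  }
  ncm
}

## Shared-nearest-neighbor graph from an n x d score matrix: kNN by
## Euclidean distance (self included among neighbors), Jaccard overlap of
## neighbor sets as edge weight, pruned below `prune`.
.snn_graph <- function(scores, snn_k, prune = 1 / 15) {
  n <- nrow(scores)
  d <- as.matrix(stats::dist(scores))
  nb <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    nb[i, ord[seq_len(snn_k)]] <- 1
  }
  shared <- nb %*% t(nb)
  jac <- shared / (2 * snn_k - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE)
}

#' Cluster cells on their network-degree profiles
#'
#' The degree matrix is log1p-transformed and per-gene standardized, reduced
#' to `n_pcs` principal components, turned into a shared-nearest-neighbor
#' graph (kNN with `snn_k` neighbors including self, Jaccard edge weights
#' pruned below 1/15), and partitioned by Louvain modularity at the given
#' resolution.
#'
#' @param ncm gene x cell degree matrix from [build_ncm()].
#' @param n_pcs principal components to keep (default 10).
#' @param snn_k neighbors for the kNN graph (default 20).
#' @param resolution Louvain resolution (default 0.5).
#' @param seed integer seed (Louvain is stochastic).
#' @param normalization `"log1p_z"` (default), `"rank"` or `"raw"`.
#' @return a `subtype_labels` object: `labels` (cell -> subtype id, 0-based
#'   contiguous), `params`.
#' @export
cluster_cells <- function(ncm, n_pcs = 10L, snn_k = 20L, resolution = 0.5,
                          seed = 1L,
                          normalization = c("log1p_z", "rank", "raw")) {
  normalization <- match.arg(normalization)
  n <- ncol(ncm)
  if (n < snn_k + 1L) {
    stop("need more cells (", n, ") than snn_k (", snn_k, ")", call. = FALSE)
  }
  x <- switch(normalization,
    log1p_z = .row_standardize(log1p(ncm)),
    rank = t(apply(ncm, 1L, rank)),
    raw = ncm
  )
  x <- x[apply(x, 1L, stats::sd) > 0, , drop = FALSE]
  n_pcs <- min(n_pcs, nrow(x) - 1L, n - 1L)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  g <- .snn_graph(scores, snn_k)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(cl)) - 1L
  names(labels) <- colnames(ncm)
  structure(list(labels = labels,
                 params = list(n_pcs = n_pcs, snn_k = snn_k,
                               resolution = resolution, seed = seed,
                               normalization = normalization)),
            class = "subtype_labels")
}

#' Differential degree genes per subtype (one vs rest)
#'
#' For each subtype and gene, a two-sided Wilcoxon rank-sum test compares
#' the gene's degrees in the subtype's cells against all remaining cells;
#' `logFC = log2((mean_in + 1) / (mean_rest + 1))` with a pseudocount of 1
#' since degrees are small integers. Up-regulated rows need `logFC > lfc`
#' and `p < p_thresh`; down-regulated rows `logFC < -lfc` and
#' `p < p_thresh`.
#'
#' @param ncm gene x cell degree matrix.
#' @param labels a `subtype_labels` (or cell -> subtype vector).
#' @param lfc absolute log2 fold-change cutoff (default 0.25).
#' @param p_thresh p-value cutoff (default 0.05).
#' @return data.frame (`gene`, `subtype`, `logFC`, `p_value`, `direction`,
#'   `auc` = NA until [find_fdgs()]); only rows passing the thresholds.
#' @export
find_ddgs <- function(ncm, labels, lfc = 0.25, p_thresh = 0.05) {
  lab <- if (inherits(labels, "subtype_labels")) labels$labels else labels
  subtypes <- sort(unique(lab))
  if (length(subtypes) < 2L) stop("need at least 2 subtypes", call. = FALSE)
  if (min(table(lab)) < 3L) {
    stop("every subtype needs at least 3 cells", call. = FALSE)
  }
  rows <- list()
  for (s in subtypes) {
    ins <- lab == s
    m_in <- rowMeans(ncm[, ins, drop = FALSE])
    m_out <- rowMeans(ncm[, !ins, drop = FALSE])
    lfc_g <- log2((m_in + 1) / (m_out + 1))
    p_g <- vapply(seq_len(nrow(ncm)), function(gi) {
      a <- ncm[gi, ins]
      b <- ncm[gi, !ins]
      if (all(a == a[1]) && all(b == a[1])) return(1)
      suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE)$p.value)
    }, numeric(1))
    keep <- (lfc_g > lfc | lfc_g < -lfc) & p_g < p_thresh &
      is.finite(lfc_g) & !is.na(p_g)
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = rownames(ncm)[keep], subtype = s,
        logFC = lfc_g[keep], p_value = p_g[keep],
        direction = ifelse(lfc_g[keep] > 0, "up", "down"),
        auc = NA_real_, row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene = character(0), subtype = integer(0),
                      logFC = numeric(0), p_value = numeric(0),
                      direction = character(0), auc = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Featured degree genes: differential degree genes with discriminative AUC
#'
#' The AUC is the probability that a random in-subtype cell has a higher
#' degree than a random rest cell, ties counting one half (the Mann-Whitney
#' identity, computed exactly from midranks). Rows are retained when
#' `logFC > lfc` and `AUC > auc_min`.
#'
#' @param ddg table from [find_ddgs()].
#' @param ncm gene x cell degree matrix.
#' @param labels subtype labels.
#' @param lfc log2 fold-change cutoff (default 0.5).
#' @param auc_min AUC cutoff (default 0.75).
#' @return the qualifying subset of `ddg`, with `auc` filled in.
#' @export
find_fdgs <- function(ddg, ncm, labels, lfc = 0.5, auc_min = 0.75) {
  lab <- if (inherits(labels, "subtype_labels")) labels$labels else labels
  if (nrow(ddg) == 0L) return(ddg)
  ddg$auc <- vapply(seq_len(nrow(ddg)), function(r) {
    ins <- lab == ddg$subtype[r]
    auc_mann_whitney(ncm[ddg$gene[r], ins], ncm[ddg$gene[r], !ins])
  }, numeric(1))
  out <- ddg[ddg$logFC > lfc & ddg$auc > auc_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}
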