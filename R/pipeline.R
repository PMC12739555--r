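#' Run the cell-specific-network subtyping pipeline
#'
#' Lognormalizes counts, builds one cell-specific network per cell,
#' assembles the network degree matrix and clusters cells on it. QC and HVG
#' selection are applied first only when requested (simulated matrices that
#' already match the analysis gene set can skip them).
#'
#' @param sc an `sc_expression`.
#' @param qc apply [qc_filter()] first.
#' @param n_hvgs when non-NULL, reduce to this many entropy-ranked genes.
#' @param k_frac,alpha cell-specific network parameters.
#' @param scope region definition passed to [build_cell_networks()].
#' @param n_pcs,snn_k,resolution,seed clustering parameters.
#' @param exclude_mito drop `MT-*` genes before network construction
#'   (default TRUE; mitochondrial load is a QC covariate, not regulation).
#' @return list with `norm`, `nets`, `ncm`, `clusters` and (when available)
#'   the true subtype labels carried through filtering.
#' @export
run_subtype_pipeline <- function(sc, qc = FALSE, n_hvgs = NULL,
                                 k_frac = 0.1, alpha = 0.01,
                                 scope = "all_cells",
                                 n_pcs = 10L, snn_k = 20L,
                                 resolution = 0.5, seed = 1L,
                                 exclude_mito = TRUE) {
  if (qc) sc <- qc_filter(sc)
  norm <- lognormalize(sc)
  if (exclude_mito) {
    norm <- norm[!grepl("^MT-|^mt-", rownames(norm)), , drop = FALSE]
  }
  if (!is.null(n_hvgs)) {
    hvgs <- entropy_hvgs(norm, n_top = n_hvgs)
    norm <- norm[hvgs, , drop = FALSE]
  }
  groups <- if (!is.null(sc$cell_meta)) sc$cell_meta$group else NULL
  nets <- build_cell_networks(norm, k_frac = k_frac, alpha = alpha,
                              scope = scope, groups = groups)
  ncm <- build_ncm(nets)
  clusters <- cluster_cells(ncm, n_pcs = n_pcs, snn_k = snn_k,
                            resolution = resolution, seed = seed)
  list(norm = norm, nets = nets, ncm = ncm, clusters = clusters,
       truth = sc$subtype)
}
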