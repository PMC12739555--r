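#' Quality-control filter for single-cell counts
#'
#' Removal criteria mirror the usual droplet QC: fewer than `umi_min` or
#' more than `umi_max` total UMIs, fewer than `min_genes` detected genes, or
#' more than `max_mito` of UMIs from mitochondrial genes. The removal
#' inequalities are strict, so cells sitting exactly on a threshold are
#' retained. UMI totals, detected-gene counts and mito fractions are
#' recomputed from the matrix (mito genes identified by prefix) rather than
#' trusted from metadata.
#'
#' @param cells an `sc_expression`.
#' @param umi_min,umi_max UMI bounds (defaults 500 and 3500).
#' @param min_genes minimum detected genes (default 200).
#' @param max_mito maximum mitochondrial UMI fraction (default 0.10).
#' @param mito_prefix regular expression identifying mitochondrial genes.
#' @return the filtered `sc_expression`; per-criterion removal counts are
#'   attached as attribute `qc_removed`.
#' @export
qc_filter <- function(cells, umi_min = 500, umi_max = 3500,
                      min_genes = 200, max_mito = 0.10,
                      mito_prefix = "^MT-|^mt-") {
  m <- cells$counts
  umi <- Matrix::colSums(m)
  ngene <- Matrix::colSums(m > 0)
  is_mito <- grepl(mito_prefix, rownames(m))
  mito <- if (any(is_mito)) {
    Matrix::colSums(m[is_mito, , drop = FALSE]) / pmax(umi, 1)
  } else if (!is.null(cells$cell_meta$mito_fraction)) {
    cells$cell_meta$mito_fraction
  } else {
    stop("no mitochondrial genes found and no precomputed mito_fraction",
         call. = FALSE)
  }
  low_umi <- umi < umi_min
  high_umi <- umi > umi_max
  few_genes <- ngene < min_genes
  high_mito <- mito > max_mito
  keep <- !(low_umi | high_umi | few_genes | high_mito)
  tally <- c(low_umi = sum(low_umi), high_umi = sum(high_umi),
             few_genes = sum(few_genes), high_mito = sum(high_mito))
  if (!any(keep)) {
    stop("no cells survive QC (removed - low_umi: ", tally[1],
         ", high_umi: ", tally[2], ", few_genes: ", tally[3],
         ", high_mito: ", tally[4], ")", call. = FALSE)
  }
  out <- cells
  out$counts <- m[, keep, drop = FALSE]
  if (!is.null(cells$cell_meta)) {
    out$cell_meta <- cells$cell_meta[keep, , drop = FALSE]
    out$cell_meta$umi_total <- umi[keep]
    out$cell_meta$n_genes_detected <- ngene[keep]
    out$cell_meta$mito_fraction <- mito[keep]
  }
  if (!is.null(cells$subtype)) out$subtype <- cells$subtype[keep]
  attr(out, "qc_removed") <- tally
  out
}

#' Depth-normalize single-cell counts
#'
#' Per cell, `ln(1 + scale * count / umi_total)` -- the log-normalization
#' convention of the standard single-cell toolchain.
#'
#' @param cells an `sc_expression` (QC-filtered counts).
#' @param scale depth scale factor (default 1e4).
#' @return normalized gene x cell matrix (sparse when the input is sparse).
#' @export
lognormalize <- function(cells, scale = 1e4) {
  m <- if (inherits(cells, "sc_expression")) cells$counts else cells
  tot <- Matrix::colSums(m)
  if (any(tot == 0)) {
    stop("cell(s) with zero total counts: ",
         paste(colnames(m)[tot == 0], collapse = ", "), call. = FALSE)
  }
  norm <- m %*% Matrix::Diagonal(x = scale / tot)
  colnames(norm) <- colnames(m)
  log1p(norm)
}

#' Entropy scores of gene expression distributions
#'
#' For each gene, the Shannon entropy of the cell-wise distribution
#' `p_i = x_i / sum(x)` with the `0 * log 0 = 0` convention. All-zero genes
#' score `-Inf` and rank last.
#'
#' @param norm normalized gene x cell matrix.
#' @return named numeric vector of entropies (natural log).
#' @export
entropy_scores <- function(norm) {
  norm <- as.matrix(norm)
  tot <- rowSums(norm)
  h <- vapply(seq_len(nrow(norm)), function(i) {
    if (tot[i] == 0) return(-Inf)
    p <- norm[i, ] / tot[i]
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  stats::setNames(h, rownames(norm))
}

#' Highly variable genes by expression entropy
#'
#' Genes are ranked by descending entropy score (pluggable via `score_fun`;
#' default [entropy_scores()]), with ties broken by gene identifier.
#'
#' @param norm normalized gene x cell matrix.
#' @param n_top number of genes to return (default 5000); when fewer genes
#'   are available all are returned with a warning.
#' @param score_fun function mapping the matrix to a named score vector.
#' @return character vector of selected genes, scores attached as attribute
#'   `scores`.
#' @export
entropy_hvgs <- function(norm, n_top = 5000L, score_fun = entropy_scores) {
  h <- score_fun(norm)
  if (n_top > length(h)) {
    warning("fewer genes (", length(h), ") than n_top; returning all")
    n_top <- length(h)
  }
  ord <- order(-h, names(h))
  sel <- names(h)[ord[seq_len(n_top)]]
  attr(sel, "scores") <- h[sel]
  sel
}
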