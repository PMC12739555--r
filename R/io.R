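#' Write / read a MatrixMarket single-cell bundle
#'
#' The usual trio: `matrix.mtx` plus `genes.tsv` and `barcodes.tsv`, with a
#' `cell_meta.tsv` alongside when metadata is present.
#'
#' @param x an `sc_expression` object (or any list with `counts`, `genes`,
#'   `cell_meta`).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sc_bundle <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(x$cell_meta)) {
    utils::write.table(x$cell_meta, file.path(dir, "cell_meta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_sc_bundle
#' @export
read_sc_bundle <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(genes, cells)
  meta_path <- file.path(dir, "cell_meta.tsv")
  meta <- if (file.exists(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else NULL
  structure(list(counts = m, genes = genes, cell_meta = meta),
            class = "sc_expression")
}

#' Write a bulk cohort as counts + metadata TSVs
#'
#' @param x a `bulk_expression` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bulk_tsv <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(gene = rownames(x$counts), x$counts,
                                check.names = FALSE),
                     file.path(dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = x$samples, bmi = x$bmi,
                                group = x$group),
                     file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_bulk_tsv
#' @export
read_bulk_tsv <- function(dir) {
  cts <- utils::read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"),
                            stringsAsFactors = FALSE)
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts$gene
  bulk_expression(m, bmi = meta$bmi, group = meta$group)
}

#' Construct a bulk expression container
#'
#' @param counts gene x sample nonnegative matrix.
#' @param bmi per-sample BMI (kg/m2), finite and positive.
#' @param group per-sample label, `healthy` or `obese`.
#' @return a `bulk_expression` object.
#' @export
bulk_expression <- function(counts, bmi, group) {
  stopifnot(is.matrix(counts), ncol(counts) == length(bmi),
            length(bmi) == length(group))
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("bmi must be finite and > 0", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  structure(list(counts = counts, genes = rownames(counts),
                 samples = colnames(counts), bmi = bmi, group = group),
            class = "bulk_expression")
}

#' Read / write gene sets in GMT format
#'
#' One term per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-c(1L, 2L)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @param gene_sets named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "synthetic", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a cell-network set as a triplet TSV plus a JSON-ish manifest
#'
#' Rows are `(cell, gene_a, gene_b, z)` in cell-major, pair-lexicographic
#' order; the manifest records the gene/cell universe and parameters so the
#' set reads back losslessly.
#'
#' @param nets a `cell_network_set`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cell_networks <- function(nets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(nets$edges, file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(
    paste0("genes\t", paste(nets$genes, collapse = ",")),
    paste0("cells\t", paste(nets$cells, collapse = ",")),
    paste0("k_frac\t", nets$params$k_frac),
    paste0("alpha\t", nets$params$alpha),
    paste0("scope\t", nets$params$scope),
    paste0("n\t", paste(nets$params$n, collapse = ","))
  )
  writeLines(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' @rdname write_cell_networks
#' @export
read_cell_networks <- function(dir) {
  edges <- utils::read.delim(file.path(dir, "edges.tsv"),
                             stringsAsFactors = FALSE)
  man <- strsplit(readLines(file.path(dir, "manifest.tsv")), "\t", fixed = TRUE)
  kv <- stats::setNames(vapply(man, `[`, character(1), 2L),
                        vapply(man, `[`, character(1), 1L))
  structure(list(
    genes = strsplit(kv[["genes"]], ",", fixed = TRUE)[[1]],
    cells = strsplit(kv[["cells"]], ",", fixed = TRUE)[[1]],
    edges = edges,
    params = list(k_frac = as.numeric(kv[["k_frac"]]),
                  alpha = as.numeric(kv[["alpha"]]),
                  scope = kv[["scope"]],
                  n = as.numeric(strsplit(kv[["n"]], ",", fixed = TRUE)[[1]]))
  ), class = "cell_network_set")
}
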