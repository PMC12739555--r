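#' Expression neighborhood (box) of a cell for one gene
#'
#' The box of cell `k` for a gene is the `ceiling(k_frac * n)` cells whose
#' expression of that gene is nearest to cell `k`'s value. Ties in distance
#' are broken by cell index (lowest first), which makes the construction
#' fully deterministic; with heavy ties (e.g. all-zero expression) the box
#' is simply the lowest-index cells.
#'
#' @param values numeric expression of one gene across cells.
#' @param k index of the focal cell.
#' @param k_frac box size as a fraction of the number of cells (0 < k_frac
#'   <= 1).
#' @return sorted integer vector of cell indices (the box), of length
#'   `ceiling(k_frac * length(values))`.
#' @export
csn_neighborhood <- function(values, k, k_frac = 0.1) {
  n <- length(values)
  stopifnot(n >= 2L, k >= 1L, k <= n, k_frac > 0, k_frac <= 1)
  m <- ceiling(k_frac * n)
  ord <- order(abs(values - values[k]), seq_len(n))
  sort(ord[seq_len(m)])
}

#' The cell-specific network statistic
#'
#' For genes x and y in cell k with box sizes `nx`, `ny`, box overlap `nxy`
#' and `n` cells in the region under consideration:
#' `rho = nxy/n - (nx/n) * (ny/n)`. Independence of the two boxes gives
#' `rho = 0`; local co-variation inflates the overlap and makes `rho`
#' positive.
#'
#' @param nxy box overlap count.
#' @param nx,ny box sizes.
#' @param n total cells in the region.
#' @return the statistic (numeric scalar).
#' @export
csn_statistic <- function(nxy, nx, ny, n) {
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  if (nxy < 0 || nx < 0 || ny < 0 || nxy > min(nx, ny) || max(nx, ny) > n) {
    stop("bounds violated: need 0 <= nxy <= min(nx, ny) <= n", call. = FALSE)
  }
  nxy / n - (nx / n) * (ny / n)
}

#' Normalized test for a cell-specific edge
#'
#' Under independence the standardized statistic
#' `z = rho * n * sqrt(n - 1) / sqrt(nx * ny * (1 - nx/n) * (1 - ny/n))`
#' is asymptotically standard normal; an edge is kept when `z` exceeds the
#' upper one-sided normal quantile at level `alpha`. Degenerate boxes
#' (`nx` or `ny` equal to 0 or `n`) never yield an edge.
#'
#' The asymptotic approximation is anti-conservative for small regions
#' (a few hundred cells): both boxes contain the focal cell by
#' construction, which shifts the null overlap mean above `nx*ny/n`, and
#' the discrete overlap distribution is right-skewed. `method = "exact"`
#' instead uses the exact null -- under independence the overlap is
#' `1 + Hypergeometric(n - 1, nx - 1, ny - 1)` -- and keeps an edge when
#' the exact upper-tail probability of the observed overlap is at most
#' `alpha` (a valid, slightly conservative finite-sample test).
#'
#' @param rho the statistic from [csn_statistic()].
#' @param nx,ny,n as in [csn_statistic()].
#' @param alpha one-sided significance level.
#' @param method `"z"` (normal approximation, default) or `"exact"`.
#' @return list with `keep` (logical) and `z`.
#' @export
csn_edge_test <- function(rho, nx, ny, n, alpha = 0.01,
                          method = c("z", "exact")) {
  method <- match.arg(method)
  if (nx %in% c(0, n) || ny %in% c(0, n)) {
    return(list(keep = FALSE, z = 0))
  }
  z <- rho * n * sqrt(n - 1) /
    sqrt(nx * ny * (1 - nx / n) * (1 - ny / n))
  if (method == "z") {
    keep <- z > stats::qnorm(1 - alpha)
  } else {
    nxy <- round(n * (rho + (nx / n) * (ny / n)))
    p <- stats::phyper(nxy - 2, nx - 1, n - nx, ny - 1, lower.tail = FALSE)
    keep <- p <= alpha
  }
  list(keep = keep, z = z)
}

## Box membership matrix for one gene: B[j, k] = TRUE iff cell j lies in
## the box of cell k. O(n^2 log n).
.box_matrix <- function(values, m) {
  n <- length(values)
  B <- matrix(FALSE, n, n)
  idx <- seq_len(n)
  for (k in idx) {
    ord <- order(abs(values - values[k]), idx)
    B[ord[seq_len(m)], k] <- TRUE
  }
  B
}

## CSN edges for one block of cells (one region). Returns a data.frame of
## (cell, i, j, z) with i < j gene indices local to `gene_names`.
.csn_block <- function(X, k_frac, alpha, gene_names, cell_names,
                       edge_test = "z") {
  n <- ncol(X)
  gg <- nrow(X)
  m <- ceiling(k_frac * n)
  if (m >= n) { # saturated boxes are degenerate: no edges
    return(data.frame(cell = character(0), gene_a = character(0),
                      gene_b = character(0), z = numeric(0),
                      stringsAsFactors = FALSE))
  }
  boxes <- lapply(seq_len(gg), function(g) .box_matrix(X[g, ], m))
  scale_z <- n * sqrt(n - 1) / (m * (1 - m / n))
  thr <- if (edge_test == "z") {
    stats::qnorm(1 - alpha) # cut on z
  } else {
    # smallest overlap whose exact null upper-tail prob is <= alpha,
    # translated to the equivalent z cut
    tail_p <- stats::phyper((1:m) - 2, m - 1, n - m, m - 1,
                            lower.tail = FALSE)
    t_min <- min(which(tail_p <= alpha))
    ((t_min - 0.5) / n - (m / n)^2) * scale_z
  }
  out_cell <- integer(0); out_i <- integer(0); out_j <- integer(0)
  out_z <- numeric(0)
  for (i in seq_len(gg - 1L)) {
    Bi <- boxes[[i]]
    for (j in (i + 1L):gg) {
      nxy <- colSums(Bi & boxes[[j]])
      rho <- nxy / n - (m / n)^2
      z <- rho * scale_z
      keep <- which(z > thr)
      if (length(keep) > 0L) {
        out_cell <- c(out_cell, keep)
        out_i <- c(out_i, rep(i, length(keep)))
        out_j <- c(out_j, rep(j, length(keep)))
        out_z <- c(out_z, z[keep])
      }
    }
  }
  ord <- order(out_cell, out_i, out_j)
  data.frame(cell = cell_names[out_cell[ord]],
             gene_a = gene_names[out_i[ord]],
             gene_b = gene_names[out_j[ord]],
             z = out_z[ord], stringsAsFactors = FALSE)
}

#' Build one cell-specific network per cell
#'
#' For every cell `k` and unordered gene pair `(x, y)`: expression boxes of
#' size `ceiling(k_frac * n)` are intersected, the statistic
#' [csn_statistic()] is standardized by [csn_edge_test()], and edges with
#' `z` above the one-sided normal quantile at `alpha` enter cell `k`'s
#' network. `scope` controls the region under consideration: all cells
#' jointly (default) or each metadata group separately (then `n` is the
#' group size).
#'
#' @param norm normalized gene x cell matrix (genes should already be
#'   reduced to HVGs; pair count is capped by `max_pairs`).
#' @param k_frac box fraction (default 0.1).
#' @param alpha edge significance level (default 0.01).
#' @param scope `"all_cells"` or `"per_group"`.
#' @param groups per-cell group labels (required for `"per_group"`).
#' @param edge_test `"z"` (normal approximation, default) or `"exact"`
#'   (finite-sample hypergeometric null); see [csn_edge_test()].
#' @param max_pairs guard on the number of gene pairs; larger inputs should
#'   be reduced to fewer highly variable genes first.
#' @return a `cell_network_set`: `genes`, `cells`, `edges` data.frame
#'   (`cell`, `gene_a`, `gene_b`, `z`; cell-major, pair-lexicographic), and
#'   `params`.
#' @export
build_cell_networks <- function(norm, k_frac = 0.1, alpha = 0.01,
                                scope = c("all_cells", "per_group"),
                                groups = NULL, max_pairs = 60000L,
                                edge_test = c("z", "exact")) {
  scope <- match.arg(scope)
  edge_test <- match.arg(edge_test)
  X <- as.matrix(norm)
  gg <- nrow(X)
  n <- ncol(X)
  if (gg < 2L) stop("need at least 2 genes", call. = FALSE)
  if (n < 10L) stop("need at least 10 cells", call. = FALSE)
  if (choose(gg, 2) > max_pairs) {
    stop("gene pair count ", choose(gg, 2), " exceeds max_pairs (",
         max_pairs, "); reduce to fewer highly variable genes first",
         call. = FALSE)
  }
  gene_names <- rownames(X)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(gg))
  cell_names <- colnames(X)
  if (is.null(cell_names)) cell_names <- paste0("c", seq_len(n))
  if (scope == "all_cells") {
    edges <- .csn_block(X, k_frac, alpha, gene_names, cell_names, edge_test)
    region_n <- n
  } else {
    if (is.null(groups) || length(groups) != n) {
      stop("per_group scope requires one group label per cell", call. = FALSE)
    }
    parts <- lapply(split(seq_len(n), groups), function(idx) {
      .csn_block(X[, idx, drop = FALSE], k_frac, alpha,
                 gene_names, cell_names[idx], edge_test)
    })
    edges <- do.call(rbind, parts)
    # restore global cell-major order
    edges <- edges[order(match(edges$cell, cell_names),
                         match(edges$gene_a, gene_names),
                         match(edges$gene_b, gene_names)), , drop = FALSE]
    rownames(edges) <- NULL
    region_n <- vapply(split(seq_len(n), groups), length, integer(1))
  }
  structure(list(genes = gene_names, cells = cell_names, edges = edges,
                 params = list(k_frac = k_frac, alpha = alpha,
                               scope = scope, edge_test = edge_test,
                               n = region_n)),
            class = "cell_network_set")
}

#' Binary adjacency matrix of one cell's network
#'
#' @param nets a `cell_network_set`.
#' @param cell a cell identifier (or index into `nets$cells`).
#' @return sparse symmetric binary gene x gene adjacency with zero diagonal.
#' @export
cell_adjacency <- function(nets, cell) {
  if (is.numeric(cell)) cell <- nets$cells[cell]
  e <- nets$edges[nets$edges$cell == cell, , drop = FALSE]
  gg <- length(nets$genes)
  i <- match(e$gene_a, nets$genes)
  j <- match(e$gene_b, nets$genes)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(gg, gg),
                              dimnames = list(nets$genes, nets$genes))
  adj@x[] <- 1
  adj
}
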