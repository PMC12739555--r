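#' Driver genes of a macrophage subtype
#'
#' A gene is a driver when it has at least one network connection (degree
#' >= 1) in at least `ceiling(prevalence * m)` of the subtype's `m` cells;
#' the boundary is inclusive, so a gene connected in exactly half of an
#' even-sized subtype qualifies at the default prevalence 0.5.
#'
#' @param nets a `cell_network_set`.
#' @param cells_of_subtype cell identifiers of the subtype (at least 2).
#' @param prevalence required cell fraction (default 0.5).
#' @return character vector of driver genes, with per-gene cell counts as
#'   attribute `n_cells_connected`.
#' @export
driver_genes <- function(nets, cells_of_subtype, prevalence = 0.5) {
  m <- length(cells_of_subtype)
  if (m < 2L) stop("subtype needs at least 2 cells", call. = FALSE)
  e <- nets$edges[nets$edges$cell %in% cells_of_subtype, , drop = FALSE]
  need <- ceiling(prevalence * m)
  counts <- integer(length(nets$genes))
  names(counts) <- nets$genes
  if (nrow(e) > 0L) {
    seen <- unique(rbind(data.frame(cell = e$cell, gene = e$gene_a),
                         data.frame(cell = e$cell, gene = e$gene_b)))
    tab <- table(seen$gene)
    counts[names(tab)] <- as.integer(tab)
  }
  drivers <- names(counts)[counts >= need]
  attr(drivers, "n_cells_connected") <- counts[drivers]
  drivers
}

#' Subtype-specific gene regulatory network by edge prevalence
#'
#' Keeps the unordered driver-gene pairs whose edge appears in at least
#' `ceiling(prevalence * m)` of the subtype's `m` cell networks, storing the
#' observed prevalence per edge.
#'
#' @param nets a `cell_network_set`.
#' @param cells_of_subtype cell identifiers of the subtype.
#' @param drivers driver genes from [driver_genes()].
#' @param prevalence required cell fraction (default 0.5).
#' @param subtype optional subtype id recorded on the object.
#' @return an `ssgrn`: `subtype`, `driver_genes`, `edges` data.frame
#'   (`gene_a`, `gene_b`, `prevalence`).
#' @export
ssgrn_edges <- function(nets, cells_of_subtype, drivers, prevalence = 0.5,
                        subtype = NA) {
  m <- length(cells_of_subtype)
  need <- ceiling(prevalence * m)
  e <- nets$edges[nets$edges$cell %in% cells_of_subtype &
                    nets$edges$gene_a %in% drivers &
                    nets$edges$gene_b %in% drivers, , drop = FALSE]
  if (nrow(e) > 0L) {
    key <- paste(e$gene_a, e$gene_b, sep = "\r")
    tab <- table(key)
    keep <- tab[tab >= need]
    parts <- strsplit(names(keep), "\r", fixed = TRUE)
    edges <- data.frame(
      gene_a = vapply(parts, `[`, character(1), 1L),
      gene_b = vapply(parts, `[`, character(1), 2L),
      prevalence = as.integer(keep) / m,
      stringsAsFactors = FALSE)
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        prevalence = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(subtype = subtype, driver_genes = drivers, edges = edges,
                 n_cells = m, prevalence_threshold = prevalence),
            class = "ssgrn")
}

## Uniform random walks over an igraph: `num_walks` walks of `walk_length`
## vertices from every non-isolated vertex. Returns a list of integer
## vertex-id vectors. Seeded by the caller.
.random_walks <- function(g, num_walks, walk_length) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  walks <- list()
  for (rep in seq_len(num_walks)) {
    for (v in seq_len(n)) {
      if (length(adj[[v]]) == 0L) next
      w <- integer(walk_length)
      w[1L] <- v
      cur <- v
      for (t in 2:walk_length) {
        nbrs <- as.integer(adj[[cur]])
        cur <- if (length(nbrs) == 1L) nbrs else nbrs[sample.int(length(nbrs), 1L)]
        w[t] <- cur
      }
      walks[[length(walks) + 1L]] <- w
    }
  }
  walks
}

#' DeepWalk-style gene embeddings of a subtype-specific network
#'
#' Uniform random walks are started `num_walks` times from every
#' non-isolated gene; co-occurrences within a `window` along the walks form
#' a positive pointwise-mutual-information matrix which is factorized by
#' truncated SVD (the matrix that skip-gram training implicitly
#' factorizes). The route is fully deterministic given the seed. Isolated
#' driver genes receive zero vectors and are flagged.
#'
#' @param grn an `ssgrn` (or any list with `driver_genes` and `edges`).
#' @param num_walks walks per node (default 10).
#' @param walk_length vertices per walk (default 80).
#' @param window co-occurrence window (default 5).
#' @param d embedding dimension (default 64, capped at the node count).
#' @param seed integer seed for the walks.
#' @param method embedding route; `"pmi-svd"` is the implemented method.
#' @return gene x d numeric matrix with attribute `isolated` (gene names
#'   embedded as zero vectors).
#' @export
deepwalk_embed <- function(grn, num_walks = 10L, walk_length = 80L,
                           window = 5L, d = 64L, seed = 1L,
                           method = "pmi-svd") {
  method <- match.arg(method, "pmi-svd")
  genes <- grn$driver_genes
  if (length(genes) == 0L || (nrow(grn$edges) == 0L && length(genes) == 0L)) {
    stop("empty graph", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(grn$edges[, c("gene_a", "gene_b")],
                                     directed = FALSE, vertices = genes)
  g <- igraph::simplify(g)
  n <- igraph::vcount(g)
  set.seed(seed)
  walks <- .random_walks(g, num_walks, walk_length)
  if (length(walks) == 0L) stop("empty graph: no walkable edges", call. = FALSE)
  C <- matrix(0, n, n)
  for (w in walks) {
    L <- length(w)
    for (off in seq_len(min(window, L - 1L))) {
      a <- w[seq_len(L - off)]
      b <- w[seq_len(L - off) + off]
      for (t in seq_along(a)) {
        C[a[t], b[t]] <- C[a[t], b[t]] + 1
        C[b[t], a[t]] <- C[b[t], a[t]] + 1
      }
    }
  }
  tot <- sum(C)
  rs <- rowSums(C)
  active <- rs > 0
  P <- matrix(0, n, n)
  P[active, active] <- log(
    (C[active, active] * tot) / (rs[active] %o% rs[active]))
  P[C == 0] <- 0
  P[P < 0] <- 0
  d_eff <- min(d, n)
  sv <- svd(P, nu = d_eff, nv = 0)
  emb <- sv$u %*% diag(sqrt(sv$d[seq_len(d_eff)]), d_eff)
  # fix SVD sign ambiguity: largest-magnitude entry of each column positive
  for (j in seq_len(ncol(emb))) {
    i0 <- which.max(abs(emb[, j]))
    if (emb[i0, j] < 0) emb[, j] <- -emb[, j]
  }
  emb[!active, ] <- 0
  rownames(emb) <- igraph::V(g)$name
  emb <- emb[genes, , drop = FALSE]
  attr(emb, "isolated") <- genes[!active[match(genes, igraph::V(g)$name)]]
  emb
}

#' Cosine similarity between gene embeddings
#'
#' Zero embedding vectors (isolated genes) get similarity 0 everywhere,
#' including the diagonal, and are flagged.
#'
#' @param emb gene x d embedding matrix.
#' @return symmetric gene x gene similarity matrix with attribute
#'   `zero_vectors`.
#' @export
gene_similarity <- function(emb) {
  stopifnot(all(is.finite(emb)))
  nrm <- sqrt(rowSums(emb^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  u <- emb / nrm
  s <- tcrossprod(u)
  s[zero, ] <- 0
  s[, zero] <- 0
  diag(s)[!zero] <- 1
  attr(s, "zero_vectors") <- rownames(emb)[zero]
  s
}

#' Gene modules by Gaussian-mixture clustering of similarity profiles
#'
#' A diagonal-covariance Gaussian mixture is fitted to the rows of the
#' cosine-similarity matrix; the number of components is selected by BIC
#' over `k_range` (singular fits at some k are skipped by the fitter), and
#' genes are hard-assigned by maximum posterior. The fit uses a conjugate
#' prior on the component parameters: similarity rows of well-connected
#' graph communities are near-duplicates, and without the prior the
#' variance estimates of such components collapse and BIC splinters the
#' communities into micro-clusters.
#'
#' @param sim similarity matrix from [gene_similarity()] (or, optionally,
#'   the raw embedding matrix).
#' @param k_range integer interval of candidate module counts (default
#'   c(2, 12)); a single repeated value forces that k.
#' @param seed integer seed.
#' @param model_names mclust model families to consider (diagonal and
#'   spherical by default).
#' @return a `gene_module_set`: `module_of` (gene -> module id, contiguous
#'   from 1), `n_modules`, `bic_table`, `enrichment` (NULL until
#'   [enrich_modules()]).
#' @importFrom mclust Mclust mclustBIC priorControl
#' @export
gmm_modules <- function(sim, k_range = c(2L, 12L), seed = 1L,
                        model_names = c("EII", "VII", "EEI", "VEI", "EVI", "VVI")) {
  x <- as.matrix(sim)
  if (nrow(x) < 4L) stop("need at least 4 genes", call. = FALSE)
  ks <- seq(k_range[1], k_range[2])
  ks <- ks[ks < nrow(x)]
  set.seed(seed)
  fit <- Mclust(x, G = ks, modelNames = model_names,
                prior = priorControl(), verbose = FALSE)
  if (is.null(fit)) stop("no Gaussian-mixture fit succeeded", call. = FALSE)
  mod <- as.integer(fit$classification)
  names(mod) <- rownames(x)
  structure(list(module_of = mod, n_modules = fit$G,
                 model = fit$modelName, bic_table = fit$BIC,
                 enrichment = NULL, term_summary = NULL),
            class = "gene_module_set")
}

#' Hypergeometric enrichment of gene modules, aggregated per term
#'
#' For each module (size n) and term (size K in a universe of N genes) with
#' overlap k, the upper-tail hypergeometric p-value
#' `P(X >= k)` is computed exactly. Per module the `top_terms` terms by
#' ascending p are kept; the union of kept terms forms the term x module
#' `-log10 p` matrix, and the per-term maximum across modules summarizes
#' the subtype.
#'
#' @param modules a `gene_module_set`.
#' @param gene_sets named list of term gene sets (e.g. from [read_gmt()]).
#' @param universe gene universe; must contain every module gene.
#' @param top_terms terms kept per module (default 60).
#' @return `modules` with `enrichment` (term x module matrix of -log10 p)
#'   and `term_summary` (per-term max) filled in.
#' @export
enrich_modules <- function(modules, gene_sets, universe, top_terms = 60L) {
  mod <- modules$module_of
  if (!all(names(mod) %in% universe)) {
    stop("universe must contain every module gene", call. = FALSE)
  }
  N <- length(universe)
  sets <- lapply(gene_sets, intersect, universe)
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) {
    message("skipping ", sum(empty), " term(s) with no genes in the universe")
    sets <- sets[!empty]
  }
  ids <- sort(unique(mod))
  pmat <- sapply(ids, function(m) {
    genes_m <- names(mod)[mod == m]
    n_m <- length(genes_m)
    vapply(sets, function(term) {
      K <- length(term)
      k <- length(intersect(genes_m, term))
      stats::phyper(k - 1, K, N - K, n_m, lower.tail = FALSE)
    }, numeric(1))
  })
  pmat <- matrix(pmat, nrow = length(sets),
                 dimnames = list(names(sets), paste0("module", ids)))
  kept <- unique(unlist(lapply(seq_along(ids), function(j) {
    ord <- order(pmat[, j], rownames(pmat))
    rownames(pmat)[ord[seq_len(min(top_terms, nrow(pmat)))]]
  })))
  kept <- sort(kept)
  enr <- -log10(pmat[kept, , drop = FALSE])
  modules$enrichment <- enr
  modules$term_summary <- apply(enr, 1L, max)
  modules
}
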