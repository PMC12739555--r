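#' Counts-per-million normalization
#'
#' Genes with zero expression across all samples are removed first, then each
#' sample column is scaled to one million.
#'
#' @param x a `bulk_expression` with raw nonnegative counts.
#' @return a `bulk_expression` whose matrix holds CPM values (each column
#'   sums to 1e6).
#' @export
normalize_cpm <- function(x) {
  stopifnot(inherits(x, "bulk_expression"))
  m <- x$counts
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  cs <- colSums(m)
  if (any(cs == 0)) {
    bad <- colnames(m)[cs == 0]
    stop("all-zero sample column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cpm <- sweep(m, 2L, cs, `/`) * 1e6
  out <- x
  out$counts <- cpm
  out$genes <- rownames(cpm)
  out$normalized <- TRUE
  out
}

#' Subset a bulk cohort by sample
#'
#' @param x a `bulk_expression`.
#' @param idx logical or integer sample index.
#' @return the subsetted `bulk_expression`.
#' @export
subset_samples <- function(x, idx) {
  out <- x
  out$counts <- x$counts[, idx, drop = FALSE]
  out$samples <- colnames(out$counts)
  out$bmi <- x$bmi[idx]
  out$group <- x$group[idx]
  out
}

## Vectorized Welch two-sample t-test on rows of a matrix.
.welch_rows <- function(m1, m2) {
  n1 <- ncol(m1); n2 <- ncol(m2)
  mu1 <- rowMeans(m1); mu2 <- rowMeans(m2)
  v1 <- rowSums((m1 - mu1)^2) / (n1 - 1)
  v2 <- rowSums((m2 - mu2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (mu1 - mu2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[se2 == 0] <- 1 # constant gene in both groups
  list(t = tt, df = df, p = p)
}

#' Differentially expressed genes between obese and healthy samples
#'
#' Welch two-sample t-test per gene on `log2(CPM + 1)`; the fold change is
#' `log2((mean_obese + 1) / (mean_healthy + 1))` on the CPM scale. Retained
#' rows satisfy `|logFC| > lfc_thresh` and `p < p_thresh`.
#'
#' @param expr a CPM-normalized `bulk_expression` with groups
#'   `healthy`/`obese`.
#' @param lfc_thresh absolute log2 fold-change cutoff.
#' @param p_thresh p-value cutoff.
#' @return data.frame of retained genes (`gene`, `logFC`, `p_value`,
#'   `direction`); the unfiltered table is attached as attribute `all`.
#' @export
find_degs <- function(expr, lfc_thresh = 0.25, p_thresh = 0.05) {
  stopifnot(inherits(expr, "bulk_expression"))
  ob <- expr$group == "obese"
  he <- expr$group == "healthy"
  if (sum(ob) < 2L || sum(he) < 2L) {
    stop("each group needs at least 2 samples (obese: ", sum(ob),
         ", healthy: ", sum(he), ")", call. = FALSE)
  }
  lg <- log2(expr$counts + 1)
  w <- .welch_rows(lg[, ob, drop = FALSE], lg[, he, drop = FALSE])
  lfc <- log2((rowMeans(expr$counts[, ob, drop = FALSE]) + 1) /
                (rowMeans(expr$counts[, he, drop = FALSE]) + 1))
  all_tab <- data.frame(gene = rownames(expr$counts), logFC = lfc,
                        p_value = w$p,
                        direction = ifelse(lfc > 0, "up", "down"),
                        row.names = NULL, stringsAsFactors = FALSE)
  keep <- abs(all_tab$logFC) > lfc_thresh & all_tab$p_value < p_thresh
  out <- all_tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- all_tab
  out
}

#' Gene co-expression network over differential genes
#'
#' Pearson correlation on `log2(CPM + 1)` between every pair of the supplied
#' genes; an edge is kept when `|PCC| > pcc_thresh` and the two-sided
#' correlation-test p-value is below `p_thresh`. The result is restricted to
#' the largest connected component.
#'
#' @param expr_obese CPM `bulk_expression` restricted to the obese group.
#' @param deg_genes genes to correlate (at least 2 present in `expr_obese`).
#' @param pcc_thresh absolute correlation cutoff.
#' @param p_thresh correlation-test p-value cutoff.
#' @return a `coexpr_network`: igraph `graph` (edge attributes `weight` =
#'   signed PCC and `pvalue`), `edges` data.frame, `nodes`, and counts of
#'   genes/edges dropped along the way.
#' @export
build_coexpr_network <- function(expr_obese, deg_genes,
                                 pcc_thresh = 0.65, p_thresh = 0.05) {
  genes <- intersect(deg_genes, rownames(expr_obese$counts))
  if (length(genes) < 2L) stop("need at least 2 genes", call. = FALSE)
  lg <- log2(expr_obese$counts[genes, , drop = FALSE] + 1)
  n <- ncol(lg)
  C <- suppressWarnings(stats::cor(t(lg)))
  C[!is.finite(C)] <- 0
  df <- n - 2
  tt <- C * sqrt(df / pmax(1 - C^2, 1e-300))
  P <- 2 * stats::pt(-abs(tt), df)
  ut <- upper.tri(C)
  pass <- ut & abs(C) > pcc_thresh & P < p_thresh
  idx <- which(pass, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("empty network: no gene pair passed |PCC| > ", pcc_thresh,
         " & p < ", p_thresh, " (", length(genes), " genes, ",
         sum(ut), " pairs tested)", call. = FALSE)
  }
  edges <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                      weight = C[idx], pvalue = P[idx],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = genes)
  comp <- igraph::components(g)
  keep_comp <- which.max(comp$csize)
  vs <- names(comp$membership)[comp$membership == keep_comp]
  g2 <- igraph::induced_subgraph(g, vs)
  e2 <- igraph::as_data_frame(g2, what = "edges")
  names(e2)[1:2] <- c("gene_a", "gene_b")
  structure(list(graph = g2, edges = e2, nodes = igraph::V(g2)$name,
                 dropped_genes = setdiff(genes, vs),
                 n_components = comp$no,
                 thresholds = c(pcc = pcc_thresh, p = p_thresh)),
            class = "coexpr_network")
}

#' Multilevel (Louvain) gene communities
#'
#' Modularity maximization on `|PCC|` edge weights; communities of
#' `min_size` genes or more are kept, genes of smaller communities are
#' flagged unassigned pending the k-means refinement stage.
#'
#' @param network a `coexpr_network`.
#' @param min_size minimum retained community size (default 21, i.e. more
#'   than 20 genes).
#' @param seed integer seed for the Louvain pass.
#' @return list with `membership` (gene -> community id, `NA` when
#'   unassigned), `sizes`, and `unassigned` gene names.
#' @export
detect_communities <- function(network, min_size = 21L, seed = 1L) {
  g <- network$graph
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = abs(igraph::E(g)$weight))
  mem <- igraph::membership(cl)
  sizes <- table(mem)
  keep_ids <- as.integer(names(sizes)[sizes >= min_size])
  out <- ifelse(mem %in% keep_ids, mem, NA_integer_)
  # renumber retained communities 1..K in order of first appearance
  kept <- sort(unique(out[!is.na(out)]))
  out <- match(out, kept)
  names(out) <- names(mem)
  list(membership = out,
       sizes = table(out[!is.na(out)]),
       unassigned = names(mem)[is.na(out)])
}

## Standardized log2(CPM + 1) gene profiles.
.gene_profiles <- function(expr, genes) {
  lg <- log2(expr$counts[genes, , drop = FALSE] + 1)
  .row_standardize(lg)
}

#' Community feature vectors (first principal components)
#'
#' For each community, PCA of the standardized within-community expression
#' (samples x genes); the CFV is the sample score vector of PC1, with sign
#' fixed so it correlates nonnegatively with the community's mean
#' standardized expression profile. Loading vectors have unit norm.
#'
#' @param expr CPM `bulk_expression`.
#' @param communities output of [detect_communities()] (or any gene ->
#'   community id vector with `NA` for unassigned).
#' @return list per community: `cfv` (sample scores), `loadings`,
#'   `var_explained`.
#' @export
community_feature_vectors <- function(expr, communities) {
  mem <- if (is.list(communities)) communities$membership else communities
  ids <- sort(unique(mem[!is.na(mem)]))
  out <- lapply(ids, function(id) {
    genes <- names(mem)[!is.na(mem) & mem == id]
    if (length(genes) < 2L) stop("community ", id, " has < 2 genes",
                                 call. = FALSE)
    X <- .gene_profiles(expr, genes)
    if (all(attr(X, "zero_var"))) {
      stop("community ", id, " has zero variance", call. = FALSE)
    }
    pc <- stats::prcomp(t(X), center = FALSE, scale. = FALSE)
    cfv <- pc$x[, 1L]
    mean_prof <- colMeans(X)
    s <- stats::cor(cfv, mean_prof)
    if (is.finite(s) && s < 0) {
      cfv <- -cfv
      pc$rotation[, 1L] <- -pc$rotation[, 1L]
    }
    list(cfv = cfv, loadings = pc$rotation[, 1L],
         var_explained = pc$sdev[1L]^2 / sum(pc$sdev^2))
  })
  names(out) <- paste0("M", ids)
  out
}

#' Refine gene modules by correlation-distance k-means
#'
#' Lloyd iterations with distance `1 - PCC` between a gene's standardized
#' expression profile and the module centroid; centroids are initialized at
#' the community feature vectors and updated as the mean standardized
#' profile of current members. `assign_only = TRUE` performs the single
#' assignment pass against the fixed CFV centroids.
#'
#' @param expr CPM `bulk_expression`.
#' @param genes genes to partition (typically all largest-component genes).
#' @param cfvs output of [community_feature_vectors()].
#' @param max_iter Lloyd iteration cap.
#' @param assign_only if TRUE, no centroid updates.
#' @return a `module_partition`: `module_of` (gene -> module id, `NA` for
#'   zero-variance genes reported in `null_genes`), `centroids`,
#'   `iterations`, `converged`.
#' @export
refine_modules_kmeans <- function(expr, genes, cfvs, max_iter = 100L,
                                  assign_only = FALSE) {
  stopifnot(length(cfvs) >= 1L)
  X <- .gene_profiles(expr, genes)
  zv <- attr(X, "zero_var")
  cent <- sapply(cfvs, function(m) as.numeric(scale(m$cfv)))
  active <- which(!zv)
  assign <- rep(NA_integer_, length(genes))
  names(assign) <- genes
  it <- 0L
  converged <- FALSE
  repeat {
    R <- suppressWarnings(stats::cor(t(X[active, , drop = FALSE]), cent))
    R[!is.finite(R)] <- -Inf
    new_assign <- max.col(R, ties.method = "first")
    if (!is.na(assign[active][1]) && all(new_assign == assign[active])) {
      converged <- TRUE
      break
    }
    assign[active] <- new_assign
    it <- it + 1L
    if (assign_only || it >= max_iter) {
      converged <- assign_only
      break
    }
    for (m in seq_len(ncol(cent))) {
      members <- active[new_assign == m]
      if (length(members) > 0L) {
        cent[, m] <- colMeans(X[members, , drop = FALSE])
      }
    }
  }
  structure(list(module_of = assign, centroids = cent,
                 null_genes = genes[zv], iterations = it,
                 converged = converged),
            class = "module_partition")
}

#' Spearman association between module feature vectors and BMI
#'
#' @param cfvs output of [community_feature_vectors()] (or a named list of
#'   numeric sample-score vectors).
#' @param bmi per-sample BMI aligned with the CFVs.
#' @return list with `table` (module, rho, p_value) and `key_module` (the
#'   unique argmax of `|rho|`; ties broken by module order) plus its sign.
#' @export
module_bmi_association <- function(cfvs, bmi) {
  if (length(bmi) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(bmi) == 0) stop("BMI is constant", call. = FALSE)
  vecs <- lapply(cfvs, function(m) if (is.list(m)) m$cfv else m)
  res <- lapply(vecs, function(v) {
    ct <- suppressWarnings(
      stats::cor.test(v, bmi, method = "spearman", exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  tab <- data.frame(module = names(vecs),
                    rho = vapply(res, `[[`, numeric(1), "rho"),
                    p_value = vapply(res, `[[`, numeric(1), "p"),
                    row.names = NULL, stringsAsFactors = FALSE)
  key <- which.max(abs(tab$rho))
  list(table = tab, key_module = tab$module[key],
       key_rho = tab$rho[key])
}

#' PageRank hub genes of a protein-protein interaction network
#'
#' Damping 0.85; scores sum to one over nodes. The top `k` genes by score
#' are the hubs, ties broken lexicographically by gene identifier.
#'
#' @param ppi data.frame with columns `gene_a`, `gene_b` (simple undirected
#'   graph).
#' @param k number of hubs (default 25).
#' @param damping PageRank damping factor.
#' @return data.frame (`gene`, `score`) sorted by descending score.
#' @export
pagerank_hubs <- function(ppi, k = 25L, damping = 0.85) {
  g <- igraph::graph_from_data_frame(ppi[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) == 0L) stop("empty graph", call. = FALSE)
  pr <- igraph::page_rank(g, damping = damping)$vector
  # group floating-point-identical scores before the lexicographic tie-break
  ord <- order(-signif(pr, 12), names(pr))
  if (k > length(pr)) {
    warning("k exceeds node count; returning all ", length(pr), " nodes")
    k <- length(pr)
  }
  sel <- ord[seq_len(k)]
  data.frame(gene = names(pr)[sel], score = unname(pr[sel]),
             stringsAsFactors = FALSE)
}

#' Random-forest key-gene selection among hub genes
#'
#' A regression forest predicts BMI from hub-gene `log2(CPM + 1)` profiles;
#' permutation importance (%IncMSE, out-of-bag) and total node-purity
#' decrease (IncNodePurity) are extracted per gene, and key genes are those
#' exceeding both thresholds.
#'
#' @param expr CPM `bulk_expression`.
#' @param hubs hub genes (character vector, or the data.frame from
#'   [pagerank_hubs()]).
#' @param bmi per-sample BMI response.
#' @param incmse_thresh %IncMSE cutoff (default 5.3).
#' @param purity_thresh IncNodePurity cutoff (default 2.9).
#' @param seed integer seed (forest growth is stochastic).
#' @param ntree trees in the forest.
#' @return a `key_gene_report`: `importance` table (gene, inc_mse,
#'   inc_node_purity), `key_genes`, and forest parameters.
#' @export
rf_key_genes <- function(expr, hubs, bmi, incmse_thresh = 5.3,
                         purity_thresh = 2.9, seed = 1L, ntree = 500L) {
  if (is.data.frame(hubs)) hubs <- hubs$gene
  if (length(hubs) == 0L) stop("empty hub list", call. = FALSE)
  if (length(bmi) < 10L) stop("need at least 10 samples", call. = FALSE)
  missing <- setdiff(hubs, rownames(expr$counts))
  if (length(missing) > 0L) {
    stop("hub genes absent from expression: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- t(log2(expr$counts[hubs, , drop = FALSE] + 1))
  colnames(x) <- hubs
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = bmi, ntree = ntree,
    mtry = max(1L, floor(length(hubs) / 3)), importance = TRUE)
  imp <- randomForest::importance(rf)
  tab <- data.frame(gene = rownames(imp),
                    inc_mse = imp[, "%IncMSE"],
                    inc_node_purity = imp[, "IncNodePurity"],
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$inc_mse, tab$gene), ]
  rownames(tab) <- NULL
  key <- tab$gene[tab$inc_mse > incmse_thresh &
                    tab$inc_node_purity > purity_thresh]
  structure(list(importance = tab, key_genes = key,
                 params = list(ntree = ntree, seed = seed,
                               mtry = max(1L, floor(length(hubs) / 3)),
                               incmse_thresh = incmse_thresh,
                               purity_thresh = purity_thresh)),
            class = "key_gene_report")
}

#' Run the full bulk module-discovery pipeline
#'
#' CPM normalization, differential expression, obese-group co-expression
#' network (largest connected component), Multilevel communities, community
#' feature vectors, correlation-distance k-means refinement, module-BMI
#' Spearman association, and (when a PPI edge list is supplied) PageRank
#' hubs plus random-forest key genes on the key module.
#'
#' @param bulk raw-count `bulk_expression`.
#' @param ppi optional PPI edge list restricted to (or intersected with) the
#'   key module's genes.
#' @param lfc_thresh,p_thresh DEG thresholds.
#' @param pcc_thresh,cor_p_thresh network thresholds.
#' @param min_community_size minimum retained community size.
#' @param seed seed for community detection and the forest.
#' @return list with every intermediate stage.
#' @export
run_bulk_pipeline <- function(bulk, ppi = NULL, lfc_thresh = 0.25,
                              p_thresh = 0.05, pcc_thresh = 0.65,
                              cor_p_thresh = 0.05,
                              min_community_size = 21L, seed = 1L) {
  cpm <- normalize_cpm(bulk)
  degs <- find_degs(cpm, lfc_thresh, p_thresh)
  obese <- subset_samples(cpm, cpm$group == "obese")
  net <- build_coexpr_network(obese, degs$gene, pcc_thresh, cor_p_thresh)
  comm <- detect_communities(net, min_size = min_community_size, seed = seed)
  # feature vectors and the BMI association use the full cohort: the
  # association question spans the whole BMI range, and obese-only
  # restriction would truncate it
  cfvs <- community_feature_vectors(cpm, comm)
  part <- refine_modules_kmeans(cpm, net$nodes, cfvs)
  mod_cfvs <- community_feature_vectors(
    cpm, stats::setNames(part$module_of, names(part$module_of)))
  assoc <- module_bmi_association(mod_cfvs, cpm$bmi)
  out <- list(cpm = cpm, degs = degs, network = net, communities = comm,
              cfvs = cfvs, partition = part, module_cfvs = mod_cfvs,
              bmi_association = assoc)
  if (!is.null(ppi)) {
    key_id <- as.integer(sub("^M", "", assoc$key_module))
    key_genes <- names(part$module_of)[!is.na(part$module_of) &
                                         part$module_of == key_id]
    sub_ppi <- ppi[ppi$gene_a %in% key_genes & ppi$gene_b %in% key_genes, ]
    if (nrow(sub_ppi) > 0L) {
      hubs <- pagerank_hubs(sub_ppi, k = min(25L, length(key_genes)))
      out$hubs <- hubs
      out$key_report <- rf_key_genes(cpm, hubs, cpm$bmi, seed = seed)
    }
  }
  out
}
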