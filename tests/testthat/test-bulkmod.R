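test_that("CPM normalization scales columns and drops silent genes", {
  counts <- matrix(c(2, 3, 5), ncol = 1,
                   dimnames = list(c("a", "b", "c"), "s1"))
  x <- make_bulk(counts, bmi = 30)
  cpm <- normalize_cpm(x)
  expect_equal(unname(cpm$counts[, 1]), c(2e5, 3e5, 5e5))

  counts2 <- rbind(counts, d = 0)
  x2 <- make_bulk(counts2, bmi = 30)
  cpm2 <- normalize_cpm(x2)
  expect_false("d" %in% rownames(cpm2$counts))
  expect_equal(unname(colSums(cpm2$counts)), 1e6, tolerance = 1e-6)

  counts3 <- cbind(counts2, s2 = 0)
  x3 <- make_bulk(counts3, bmi = c(30, 22))
  expect_error(normalize_cpm(x3), "s2")
})

test_that("differential testing matches the reference t-test", {
  set.seed(42)
  counts <- matrix(rpois(30 * 24, 60), 30, 24,
                   dimnames = list(sprintf("g%02d", 1:30),
                                   sprintf("s%02d", 1:24)))
  bmi <- c(runif(12, 18, 24.5), runif(12, 26, 40))
  x <- normalize_cpm(make_bulk(counts, bmi))
  tab <- attr(find_degs(x), "all")
  lg <- log2(x$counts + 1)
  ob <- x$group == "obese"
  for (g in rownames(lg)) {
    ref <- t.test(lg[g, ob], lg[g, !ob])$p.value
    expect_equal(tab$p_value[tab$gene == g], ref, tolerance = 1e-10)
  }
})

test_that("differential gene filtering behaves at the boundaries", {
  set.seed(1)
  counts <- matrix(50, 4, 20,
                   dimnames = list(c("null", "up", "down", "background"),
                                   sprintf("s%02d", 1:20)))
  counts["up", 11:20] <- rpois(10, 200)
  counts["up", 1:10] <- rpois(10, 50)
  counts["down", 11:20] <- rpois(10, 20)
  counts["down", 1:10] <- rpois(10, 70)
  counts[c("null", "background"), ] <-
    counts[c("null", "background"), ] + matrix(rpois(40, 3), 2)
  counts["background", ] <- counts["background", ] + 5000 # stable library
  bmi <- c(rep(20, 10), rep(32, 10))
  x <- normalize_cpm(make_bulk(counts, bmi))
  degs <- find_degs(x)
  expect_true(all(c("up", "down") %in% degs$gene))
  expect_identical(degs$direction[degs$gene == "up"], "up")
  expect_identical(degs$direction[degs$gene == "down"], "down")
  expect_false("null" %in% degs$gene)
  # vacuous thresholds return every gene
  all_tab <- find_degs(x, lfc_thresh = 0, p_thresh = 1)
  expect_setequal(all_tab$gene, rownames(x$counts))
  # degenerate group sizes are rejected
  y <- subset_samples(x, c(1, 11:20))
  expect_error(find_degs(y), "at least 2 samples")
})

test_that("co-expression network keeps the largest connected component", {
  set.seed(7)
  n <- 400
  # explicit chain in correlation space: corr(A,B) = corr(B,C) = 0.75,
  # corr(A,C) = 0.5625, comfortably straddling the 0.65 edge threshold
  zA <- rnorm(n)
  zB <- 0.75 * zA + sqrt(1 - 0.75^2) * rnorm(n)
  zC <- 0.75 * zB + sqrt(1 - 0.75^2) * rnorm(n)
  counts <- rbind(
    A = 1000 + 100 * zA,
    B = 1000 + 100 * zB,
    C = 1000 + 100 * zC,
    D = 1000 + 100 * rnorm(n),
    E = 1000 + 100 * rnorm(n),
    background = 50000)
  counts <- round(pmax(counts, 1))
  colnames(counts) <- sprintf("s%03d", 1:n)
  x <- make_bulk(counts, bmi = rep(30, n))
  cpmx <- normalize_cpm(x)
  net <- build_coexpr_network(cpmx, c("A", "B", "C", "D", "E"))
  # A-B and B-C correlate strongly; A-C is attenuated; D,E are noise
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_true(igraph::is_connected(net$graph))
  # a duplicated gene always gets an edge at PCC 1
  counts2 <- rbind(counts, A2 = counts["A", ])
  x2 <- normalize_cpm(make_bulk(counts2, bmi = rep(30, n)))
  net2 <- build_coexpr_network(x2, rownames(counts2))
  e2 <- net2$edges
  hit <- (e2$gene_a == "A" & e2$gene_b == "A2") |
    (e2$gene_a == "A2" & e2$gene_b == "A")
  expect_true(any(hit))
  expect_equal(e2$weight[hit], 1, tolerance = 1e-12)
  # nothing passing is an informative error
  expect_error(build_coexpr_network(cpmx, c("D", "E")), "empty network")
})

test_that("raising the correlation threshold never adds edges", {
  b <- simulate_bulk(sim_config(seed = 3, n_samples = 60))
  cpmx <- normalize_cpm(b)
  genes <- rownames(cpmx$counts)[b$module_truth[rownames(cpmx$counts)] > 0]
  edge_key <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  nets <- lapply(c(0.5, 0.65, 0.8), function(th) {
    build_coexpr_network(cpmx, genes, pcc_thresh = th)
  })
  # compare raw passing pairs (pre component filtering) via full edge lists
  for (i in 1:2) {
    eh <- edge_key(nets[[i + 1]])
    el <- edge_key(nets[[i]])
    expect_true(all(eh %in% el))
  }
})

test_that("community detection splits cliques and drops small communities", {
  clique_edges <- function(genes) {
    t(combn(genes, 2))
  }
  g1 <- sprintf("a%02d", 1:30); g2 <- sprintf("b%02d", 1:30)
  e <- rbind(clique_edges(g1), clique_edges(g2), c(g1[1], g2[1]))
  edges <- data.frame(gene_a = e[, 1], gene_b = e[, 2], weight = 1,
                      pvalue = 0)
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE)
  net <- structure(list(graph = gr, edges = edges,
                        nodes = igraph::V(gr)$name),
                   class = "coexpr_network")
  comm <- detect_communities(net, seed = 1)
  expect_equal(length(unique(na.omit(comm$membership))), 2L)
  expect_equal(length(comm$unassigned), 0L)
  # the same partition comes back under the same seed
  comm2 <- detect_communities(net, seed = 1)
  expect_identical(comm$membership, comm2$membership)
  # a 15-gene community falls below the retention threshold
  g3 <- sprintf("c%02d", 1:15)
  e3 <- rbind(e, clique_edges(g3), c(g2[1], g3[1]))
  edges3 <- data.frame(gene_a = e3[, 1], gene_b = e3[, 2], weight = 1,
                       pvalue = 0)
  gr3 <- igraph::graph_from_data_frame(edges3, directed = FALSE)
  net3 <- structure(list(graph = gr3, edges = edges3,
                         nodes = igraph::V(gr3)$name),
                    class = "coexpr_network")
  comm3 <- detect_communities(net3, seed = 1)
  expect_setequal(comm3$unassigned, g3)
})

test_that("community feature vectors follow the PCA conventions", {
  set.seed(5)
  n <- 30
  prof <- rnorm(n)
  counts <- do.call(rbind, lapply(1:4, function(i) 100 + 10 * prof))
  counts <- rbind(counts, 50000) # stable background so CPM keeps the signal
  dimnames(counts) <- list(c(paste0("g", 1:4), "background"),
                           sprintf("s%02d", 1:n))
  x <- normalize_cpm(make_bulk(round(pmax(counts, 1)) + 1, rep(30, n)))
  mem <- setNames(rep(1L, 4), paste0("g", 1:4))
  cf <- community_feature_vectors(x, mem)
  expect_length(cf, 1L)
  expect_equal(sum(cf$M1$loadings^2), 1)
  # near-identical genes: CFV reproduces the standardized profile
  prof_std <- as.numeric(scale(log2(x$counts[1, ] + 1)))
  expect_gt(abs(cor(cf$M1$cfv, prof_std)), 0.999)
  # sign convention: nonnegative correlation with the mean profile
  expect_gte(cor(cf$M1$cfv, colMeans(atmnet:::.gene_profiles(
    x, names(mem)))), 0)
})

test_that("correlation-distance k-means refines planted modules", {
  cfg <- sim_config(seed = 6, module_sizes = rep(30L, 3L),
                    n_genes_bulk = 120L, bmi_module_index = 1L)
  b <- simulate_bulk(cfg)
  res <- run_bulk_pipeline(b)
  truth <- b$module_truth[names(res$partition$module_of)]
  ari <- mclust::adjustedRandIndex(res$partition$module_of, truth)
  expect_gte(ari, 0.9)
  # a gene equal to a centroid lands in that module in the one-shot reading
  part0 <- refine_modules_kmeans(res$cpm, names(res$partition$module_of),
                                 res$cfvs, assign_only = TRUE)
  expect_true(all(!is.na(part0$module_of)))
  # k = 1 collapses everything into one module
  part1 <- refine_modules_kmeans(res$cpm, names(res$partition$module_of),
                                 res$cfvs[1])
  expect_true(all(part1$module_of == 1L))
})

test_that("module-BMI association is rank-based and well guarded", {
  bmi <- c(21, 24, 27, 30, 33, 36)
  cfvs <- list(M1 = c(1, 2, 3, 4, 5, 6) * 2 - 3, M2 = c(2, 1, 3, 6, 4, 5))
  assoc <- module_bmi_association(cfvs, bmi)
  expect_equal(assoc$table$rho[1], 1)
  expect_identical(assoc$key_module, "M1")
  # consistent permutation leaves rho unchanged
  perm <- sample(6)
  assoc2 <- module_bmi_association(lapply(cfvs, `[`, perm), bmi[perm])
  expect_equal(assoc2$table$rho, assoc$table$rho)
  expect_error(module_bmi_association(cfvs, rep(25, 6)), "constant")
  expect_error(module_bmi_association(lapply(cfvs, `[`, 1:2), bmi[1:2]),
               "3 samples")
})

test_that("PageRank hubs respect symmetry, normalization and ties", {
  ring <- data.frame(gene_a = paste0("n", 1:10),
                     gene_b = paste0("n", c(2:10, 1)))
  hubs <- pagerank_hubs(ring, k = 10)
  expect_equal(hubs$score, rep(0.1, 10), tolerance = 1e-9)
  expect_equal(sum(hubs$score), 1, tolerance = 1e-9)
  # lexicographic tie-break on equal scores
  expect_identical(hubs$gene, sort(paste0("n", 1:10)))
  star <- data.frame(gene_a = "hub", gene_b = paste0("leaf", 1:6))
  top <- pagerank_hubs(star, k = 1)
  expect_identical(top$gene, "hub")
  expect_warning(pagerank_hubs(star, k = 99), "node count")
})

test_that("random-forest key genes surface true predictors", {
  set.seed(1)
  counts <- matrix(rpois(25 * 100, 100), 25, 100,
                   dimnames = list(sprintf("H%02d", 1:25),
                                   sprintf("S%03d", 1:100)))
  bmi <- runif(100, 18, 45)
  counts[1, ] <- round(bmi * 10)
  x <- normalize_cpm(make_bulk(counts, bmi))
  rep <- rf_key_genes(x, rownames(counts), bmi, seed = 1)
  expect_identical(rep$importance$gene[1], "H01")
  expect_true("H01" %in% rep$key_genes)
  # vacuous thresholds admit the full hub set
  rep2 <- rf_key_genes(x, rownames(counts), bmi, incmse_thresh = -Inf,
                       purity_thresh = -Inf, seed = 1)
  expect_setequal(rep2$key_genes, rownames(counts))
  expect_error(rf_key_genes(x, character(0), bmi), "empty hub")
  expect_error(rf_key_genes(x, "nope", bmi), "absent")
})
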