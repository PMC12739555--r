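test_that("driver prevalence uses the inclusive ceiling rule", {
  genes <- c("a", "b", "c")
  cells <- paste0("c", 1:10)
  # a-b edge in 5/10 cells (exactly half), a-c in 4/10
  e <- rbind(
    data.frame(cell = cells[1:5], gene_a = "a", gene_b = "b", z = 3),
    data.frame(cell = cells[6:9], gene_a = "a", gene_b = "c", z = 3))
  nets <- make_nets(genes, cells, e)
  drivers <- driver_genes(nets, cells)
  expect_true("a" %in% drivers)  # connected in 9 cells
  expect_true("b" %in% drivers)  # connected in exactly 5 = ceiling(0.5*10)
  expect_false("c" %in% drivers) # 4 < 5
  expect_error(driver_genes(nets, cells[1]), "2 cells")
  # prevalence 1 keeps only the always-connected
  expect_setequal(driver_genes(nets, cells[1:5], prevalence = 1),
                  c("a", "b"))
})

test_that("subtype network edges respect prevalence and the driver domain", {
  genes <- c("a", "b", "c", "d")
  cells <- paste0("c", 1:10)
  e <- rbind(
    data.frame(cell = cells, gene_a = "a", gene_b = "b", z = 3),
    data.frame(cell = cells[1:4], gene_a = "a", gene_b = "c", z = 3),
    data.frame(cell = cells, gene_a = "b", gene_b = "d", z = 3))
  nets <- make_nets(genes, cells, e)
  drivers <- c("a", "b", "c") # exclude d on purpose
  grn <- ssgrn_edges(nets, cells, drivers)
  expect_equal(nrow(grn$edges), 1L)
  expect_identical(grn$edges$gene_a, "a")
  expect_identical(grn$edges$gene_b, "b")
  expect_equal(grn$edges$prevalence, 1)
  # a-c present in 4 < ceiling(5) cells: excluded; b-d touches a non-driver
  expect_false(any(grn$edges$gene_b == "d"))
})

test_that("prevalence boundaries behave exactly for m = 2..11", {
  for (m in 2:11) {
    cells <- paste0("c", seq_len(m))
    need <- ceiling(0.5 * m)
    e_at <- data.frame(cell = cells[seq_len(need)], gene_a = "a",
                       gene_b = "b", z = 3)
    e_below <- data.frame(cell = cells[seq_len(need - 1)],
                          gene_a = rep("a", need - 1),
                          gene_b = rep("b", need - 1), z = rep(3, need - 1))
    nets_at <- make_nets(c("a", "b"), cells, e_at)
    nets_below <- make_nets(c("a", "b"), cells, e_below)
    expect_setequal(driver_genes(nets_at, cells), c("a", "b"))
    expect_length(driver_genes(nets_below, cells), 0L)
    expect_equal(nrow(ssgrn_edges(nets_at, cells, c("a", "b"))$edges), 1L)
    expect_equal(nrow(ssgrn_edges(nets_below, cells, c("a", "b"))$edges), 0L)
  }
})

test_that("raising prevalence never adds drivers or edges", {
  set.seed(13)
  X <- matrix(rnorm(6 * 40), 6, 40,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:40)))
  X[2, ] <- X[1, ] + rnorm(40, sd = 0.2)
  nets <- build_cell_networks(X)
  cells <- nets$cells
  prev <- c(0.3, 0.5, 0.7)
  drs <- lapply(prev, function(p) driver_genes(nets, cells, prevalence = p))
  for (i in 1:2) expect_true(all(drs[[i + 1]] %in% drs[[i]]))
  grns <- lapply(prev, function(p) {
    ssgrn_edges(nets, cells, drs[[1]], prevalence = p)$edges
  })
  key <- function(e) paste(e$gene_a, e$gene_b)
  for (i in 1:2) expect_true(all(key(grns[[i + 1]]) %in% key(grns[[i]])))
})

test_that("the subtype network is a subgraph of the per-cell union", {
  set.seed(14)
  X <- matrix(rnorm(8 * 30), 8, 30,
              dimnames = list(paste0("g", 1:8), paste0("c", 1:30)))
  X[2, ] <- X[1, ] + rnorm(30, sd = 0.1)
  X[4, ] <- X[3, ] + rnorm(30, sd = 0.1)
  nets <- build_cell_networks(X)
  drivers <- driver_genes(nets, nets$cells, prevalence = 0.2)
  grn <- ssgrn_edges(nets, nets$cells, drivers, prevalence = 0.2)
  union_key <- unique(paste(nets$edges$gene_a, nets$edges$gene_b))
  expect_true(all(paste(grn$edges$gene_a, grn$edges$gene_b) %in% union_key))
  expect_true(all(grn$edges$gene_a %in% drivers))
  expect_true(all(grn$edges$gene_b %in% drivers))
  expect_true(all(grn$edges$prevalence >= 0.2))
})

test_that("graph embeddings separate disconnected cliques", {
  cl <- function(genes) {
    cc <- t(combn(genes, 2))
    data.frame(gene_a = cc[, 1], gene_b = cc[, 2], prevalence = 1,
               stringsAsFactors = FALSE)
  }
  g1 <- paste0("a", 1:6); g2 <- paste0("b", 1:6)
  grn <- structure(list(driver_genes = c(g1, g2, "iso"),
                        edges = rbind(cl(g1), cl(g2))), class = "ssgrn")
  emb <- deepwalk_embed(grn, seed = 3)
  sim <- gene_similarity(emb)
  within <- c(sim[g1, g1][upper.tri(diag(6))], sim[g2, g2][upper.tri(diag(6))])
  between <- as.vector(sim[g1, g2])
  expect_gt(mean(within), mean(between))
  # the isolated driver is flagged and embedded at the origin
  expect_identical(attr(emb, "isolated"), "iso")
  expect_equal(unname(emb["iso", ]), rep(0, ncol(emb)))
  expect_equal(unname(sim["iso", ]), rep(0, ncol(sim)))
  # determinism of the walk + factorization route
  expect_identical(emb, deepwalk_embed(grn, seed = 3))
})

test_that("cosine similarity follows its closed forms", {
  emb <- rbind(x = c(1, 0, 2), y = c(2, 0, 4), z = c(0, 3, 0))
  s <- gene_similarity(emb)
  expect_equal(s["x", "y"], 1)
  expect_equal(s["x", "z"], 0)
  expect_equal(diag(s), c(x = 1, y = 1, z = 1))
  # scale invariance
  emb2 <- emb; emb2["x", ] <- emb2["x", ] * 3
  expect_equal(gene_similarity(emb2), s)
})

test_that("mixture-model modules honor a forced component count", {
  g <- plant_two_community_graph(1)
  sim <- gene_similarity(deepwalk_embed(g$grn, seed = 1))
  mods <- gmm_modules(sim, k_range = c(3, 3), seed = 1)
  expect_equal(mods$n_modules, 3L)
  expect_identical(sort(unique(unname(mods$module_of))), 1:3)
  expect_error(gmm_modules(sim[1:3, 1:3]), "4 genes")
})

test_that("module assignment is equivariant under gene relabeling", {
  g <- plant_two_community_graph(1)
  sim <- gene_similarity(deepwalk_embed(g$grn, seed = 1))
  mods <- gmm_modules(sim, seed = 1)
  perm <- sample(nrow(sim))
  simp <- sim[perm, perm]
  modsp <- gmm_modules(simp, seed = 1)
  expect_equal(
    mclust::adjustedRandIndex(mods$module_of[rownames(simp)],
                              modsp$module_of), 1)
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  # module identical to the term inside a 100-gene universe
  universe <- sprintf("u%03d", 1:100)
  mod_genes <- universe[1:10]
  modules <- structure(list(module_of = setNames(rep(1L, 10), mod_genes)),
                       class = "gene_module_set")
  out <- enrich_modules(modules, list(T1 = mod_genes), universe)
  expect_equal(10^(-out$enrichment["T1", 1]), 1 / choose(100, 10),
               tolerance = 1e-12)
  # disjoint term: p = 1, -log10 p = 0
  out2 <- enrich_modules(modules, list(T2 = universe[50:60]), universe)
  expect_equal(unname(out2$enrichment["T2", 1]), 0)
  # printed example: N=20, K=5, n=5, overlap=5 -> 1/15504
  uni <- sprintf("v%02d", 1:20)
  m3 <- structure(list(module_of = setNames(rep(1L, 5), uni[1:5])),
                  class = "gene_module_set")
  out3 <- enrich_modules(m3, list(T3 = uni[1:5]), uni)
  expect_equal(10^(-out3$enrichment["T3", 1]), 1 / 15504, tolerance = 1e-12)
  # exhaustive enumeration oracle on small universes
  cases <- list(c(k = 2, K = 6, N = 15, n = 5),
                c(k = 3, K = 8, N = 20, n = 6),
                c(k = 1, K = 4, N = 12, n = 3))
  for (cs in cases) {
    p_pkg <- phyper(cs["k"] - 1, cs["K"], cs["N"] - cs["K"], cs["n"],
                    lower.tail = FALSE)
    p_oracle <- hyper_tail_oracle(cs["k"], cs["K"], cs["N"], cs["n"])
    expect_equal(unname(p_pkg), p_oracle, tolerance = 1e-12)
  }
})

test_that("enrichment keeps top terms per module and aggregates by max", {
  universe <- sprintf("u%03d", 1:60)
  mo <- setNames(c(rep(1L, 10), rep(2L, 10)), universe[1:20])
  modules <- structure(list(module_of = mo), class = "gene_module_set")
  sets <- list(hitA = universe[1:10],   # enriched in module 1
               hitB = universe[11:20],  # enriched in module 2
               bland = universe[40:50])
  out <- enrich_modules(modules, sets, universe, top_terms = 2)
  expect_true(all(c("hitA", "hitB") %in% rownames(out$enrichment)))
  expect_equal(unname(out$term_summary["hitA"]),
               max(out$enrichment["hitA", ]))
  # the module gene universe precondition is enforced
  expect_error(enrich_modules(modules, sets, universe[1:5]), "universe")
})
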