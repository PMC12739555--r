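# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain loops and enumeration only.

# Literal triple-loop cell-specific network construction: for every cell and
# gene pair, build both boxes by sorting distances, count the overlap, and
# apply the normalized test.
csn_oracle <- function(X, k_frac = 0.1, alpha = 0.01) {
  n <- ncol(X)
  gg <- nrow(X)
  m <- ceiling(k_frac * n)
  thr <- qnorm(1 - alpha)
  out <- list()
  for (k in seq_len(n)) {
    for (i in seq_len(gg - 1)) {
      for (j in (i + 1):gg) {
        bi <- order(abs(X[i, ] - X[i, k]), seq_len(n))[1:m]
        bj <- order(abs(X[j, ] - X[j, k]), seq_len(n))[1:m]
        nxy <- length(intersect(bi, bj))
        rho <- nxy / n - (m / n) * (m / n)
        z <- rho * n * sqrt(n - 1) / sqrt(m * m * (1 - m / n) * (1 - m / n))
        if (z > thr) {
          out[[length(out) + 1]] <- data.frame(
            cell = k, i = i, j = j, z = z)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(cell = integer(0), i = integer(0), j = integer(0),
                      z = numeric(0)))
  }
  do.call(rbind, out)
}

# All-pairs AUC with the tie-half rule, by explicit double loop.
auc_oracle <- function(pos, neg) {
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of a
# universe of size N and count how many overlap the K-set by >= k.
hyper_tail_oracle <- function(k, K, N, n) {
  universe <- seq_len(N)
  term <- seq_len(K)
  sets <- combn(N, n)
  hits <- 0
  for (c in seq_len(ncol(sets))) {
    if (length(intersect(sets[, c], term)) >= k) hits <- hits + 1
  }
  hits / ncol(sets)
}

# Two-community planted-partition graph wrapped as an ssgrn-like object.
plant_two_community_graph <- function(seed, n1 = 20, n2 = 20,
                                      p_in = 0.3, p_out = 0.01) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n1 + n2))
  memb <- rep(1:2, c(n1, n2))
  ea <- character(0); eb <- character(0)
  for (i in seq_len(n1 + n2 - 1)) {
    for (j in (i + 1):(n1 + n2)) {
      p <- if (memb[i] == memb[j]) p_in else p_out
      if (runif(1) < p) {
        ea <- c(ea, genes[i]); eb <- c(eb, genes[j])
      }
    }
  }
  list(grn = structure(list(driver_genes = genes,
                            edges = data.frame(gene_a = ea, gene_b = eb,
                                               prevalence = 1,
                                               stringsAsFactors = FALSE)),
                       class = "ssgrn"),
       truth = memb)
}

# Assemble a cell_network_set directly from an edge table (for boundary and
# prevalence tests that need exact control over which cell has which edge).
make_nets <- function(genes, cells, edges) {
  structure(list(genes = genes, cells = cells,
                 edges = edges,
                 params = list(k_frac = NA, alpha = NA, scope = "all_cells",
                               n = length(cells))),
            class = "cell_network_set")
}

# Small raw-count bulk cohort wrapper.
make_bulk <- function(counts, bmi, group = NULL) {
  if (is.null(group)) group <- ifelse(bmi >= 25, "obese", "healthy")
  bulk_expression(counts, bmi = bmi, group = group)
}
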