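#' Simulation configuration for synthetic adipose cohorts
#'
#' Bundles every knob of the synthetic-data generator: a bulk cohort with
#' planted co-expression modules of which one tracks BMI, and a single-cell
#' population whose subtypes differ only in gene-gene dependency structure
#' (equal marginal means), plus negative-binomial marginals and mitochondrial
#' content spanning the usual QC thresholds.
#'
#' @param seed global integer seed; fans out to per-stage child seeds via
#'   [child_seed()].
#' @param n_samples bulk cohort size.
#' @param n_genes_bulk total bulk genes (module genes plus independent noise
#'   genes).
#' @param module_sizes integer vector of planted module sizes; must sum to at
#'   most `n_genes_bulk`.
#' @param bmi_module_index which planted module carries the BMI signal.
#' @param bmi_effect target Spearman correlation (0-1) between the BMI-module
#'   latent factor and BMI.
#' @param within_module_cor target gene-gene correlation inside a module (on
#'   the latent log scale).
#' @param between_module_cor correlation between module latent factors (a
#'   shared adiposity programme; also what makes every module's genes
#'   differential between BMI groups when one module carries the BMI
#'   signal).
#' @param n_bridge_genes genes per module with overlapping membership: they
#'   stay members of their own module (latent correlation 0.88) but also
#'   track the next module in ring order at `bridge_beta`. Bridges keep the
#'   thresholded co-expression graph connected across modules, as in real
#'   cohorts where the differential-gene network forms one component.
#' @param bridge_beta latent correlation between a bridge gene and its
#'   secondary module.
#' @param n_cells single-cell population size.
#' @param n_genes_sc number of (non-mitochondrial) single-cell genes.
#' @param subtype_proportions proportions per subtype; must sum to 1.
#' @param dependency_networks list of gene-gene correlation templates, one
#'   per subtype, each `n_genes_sc x n_genes_sc`. Defaults to
#'   [block_dependency_templates()] with one 20-gene correlated block per
#'   subtype.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param mito_fraction_range range of per-cell target mitochondrial UMI
#'   fractions.
#' @param n_mito_genes number of mitochondrial genes (named `MT-*`).
#' @param sc_mean_expr mean expression scale of single-cell genes.
#' @param sc_depth_sd lognormal sd of per-cell size factors.
#' @param psd_tol most negative template eigenvalue repairable by
#'   [nearest_psd()]; templates worse than this raise a configuration error.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 200L,
                       n_genes_bulk = 150L,
                       module_sizes = rep(30L, 4L),
                       bmi_module_index = 2L,
                       bmi_effect = 0.7,
                       within_module_cor = 0.95,
                       between_module_cor = 0.4,
                       n_bridge_genes = 3L,
                       bridge_beta = 0.8,
                       n_cells = 600L,
                       n_genes_sc = 60L,
                       subtype_proportions = c(1, 1, 1) / 3,
                       dependency_networks = NULL,
                       nb_dispersion = 0.3,
                       mito_fraction_range = c(0, 0.15),
                       n_mito_genes = 5L,
                       sc_mean_expr = 25,
                       sc_depth_sd = 0.2,
                       psd_tol = 1e-2) {
  cfg <- list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    n_genes_bulk = as.integer(n_genes_bulk),
    module_sizes = as.integer(module_sizes),
    bmi_module_index = as.integer(bmi_module_index),
    bmi_effect = bmi_effect,
    within_module_cor = within_module_cor,
    between_module_cor = between_module_cor,
    n_bridge_genes = as.integer(n_bridge_genes),
    bridge_beta = bridge_beta,
    n_cells = as.integer(n_cells), n_genes_sc = as.integer(n_genes_sc),
    subtype_proportions = subtype_proportions,
    dependency_networks = dependency_networks,
    nb_dispersion = nb_dispersion,
    mito_fraction_range = mito_fraction_range,
    n_mito_genes = as.integer(n_mito_genes),
    sc_mean_expr = sc_mean_expr, sc_depth_sd = sc_depth_sd,
    psd_tol = psd_tol
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config a `sim_config` object.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 1L) {
    stop("configuration error: n_samples must be >= 1", call. = FALSE)
  }
  if (any(config$module_sizes < 2L)) {
    stop("configuration error: every module needs >= 2 genes", call. = FALSE)
  }
  if (sum(config$module_sizes) > config$n_genes_bulk) {
    stop("configuration error: module_sizes sum exceeds n_genes_bulk",
         call. = FALSE)
  }
  k <- length(config$module_sizes)
  if (config$bmi_module_index < 1L || config$bmi_module_index > k) {
    stop("configuration error: bmi_module_index out of range", call. = FALSE)
  }
  if (abs(sum(config$subtype_proportions) - 1) > 1e-8 ||
      any(config$subtype_proportions < 0)) {
    stop("configuration error: subtype_proportions must be nonnegative and sum to 1",
         call. = FALSE)
  }
  if (config$nb_dispersion <= 0) {
    stop("configuration error: nb_dispersion must be > 0", call. = FALSE)
  }
  r <- config$mito_fraction_range
  if (length(r) != 2L || r[1] < 0 || r[2] > 1 || r[1] > r[2]) {
    stop("configuration error: mito_fraction_range must be within [0, 1]",
         call. = FALSE)
  }
  if (!is.null(config$dependency_networks)) {
    if (length(config$dependency_networks) != length(config$subtype_proportions)) {
      stop("configuration error: one dependency template per subtype required",
           call. = FALSE)
    }
    for (tpl in config$dependency_networks) {
      if (!is.matrix(tpl) || nrow(tpl) != config$n_genes_sc ||
          ncol(tpl) != config$n_genes_sc) {
        stop("configuration error: template dimensions must match n_genes_sc",
             call. = FALSE)
      }
      if (max(abs(tpl - t(tpl))) > 1e-8) {
        stop("configuration error: dependency template must be symmetric",
             call. = FALSE)
      }
      ev <- eigen(tpl, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -config$psd_tol) {
        stop("configuration error: dependency template is not positive ",
             "semi-definite within tolerance", call. = FALSE)
      }
    }
  }
  invisible(config)
}

#' Block-structured dependency templates
#'
#' Template `s` assigns subtype `s` a private set of tightly coupled gene
#' programs: `blocks_per_subtype` disjoint blocks of `block_size` genes,
#' each internally correlated at `block_cor`, with every other gene
#' independent. Subtypes share marginal means and differ only in which gene
#' blocks co-vary. Splitting a subtype's signature over several independent
#' blocks mimics co-regulated programs of modest size and keeps per-cell
#' network degree profiles even across the factor range.
#'
#' @param n_genes number of genes.
#' @param n_subtypes number of templates.
#' @param block_cor within-block correlation.
#' @param block_size genes per block (default 10).
#' @param blocks_per_subtype coupled blocks per subtype (default 2).
#' @return list of correlation matrices.
#' @export
block_dependency_templates <- function(n_genes, n_subtypes,
                                       block_cor = 0.97, block_size = 10L,
                                       blocks_per_subtype = 2L) {
  stopifnot(block_size >= 2L,
            n_subtypes * blocks_per_subtype * block_size <= n_genes)
  lapply(seq_len(n_subtypes), function(s) {
    tpl <- diag(n_genes)
    for (h in seq_len(blocks_per_subtype)) {
      off <- (s - 1L) * blocks_per_subtype * block_size +
        (h - 1L) * block_size
      idx <- (off + 1L):(off + block_size)
      tpl[idx, idx] <- block_cor
    }
    diag(tpl) <- 1
    tpl
  })
}

## Gaussian -> Spearman calibration: for a bivariate normal with correlation
## rho, the Spearman correlation is (6/pi) asin(rho/2); invert to hit a
## requested Spearman target.
.gauss_for_spearman <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Simulate a bulk adipose cohort with planted BMI-linked modules
#'
#' Samples module latent factors that share a global adiposity programme
#' (between-module correlation `between_module_cor`), attaches genes to
#' modules through a lognormal mean model, and Poisson-samples counts. BMI is
#' generated so that the latent factor of the module at `bmi_module_index`
#' has Spearman correlation approximately `bmi_effect` with BMI; other
#' modules inherit only the weaker residual correlation that flows through
#' the shared programme. Samples are labeled obese at BMI >= 25 kg/m2.
#'
#' @param config a [sim_config()].
#' @return a `bulk_expression` object with elements `counts` (gene x sample
#'   integer matrix), `genes`, `samples`, `bmi`, `group`
#'   (healthy/obese), `module_truth` (0 for noise genes) and `factors`
#'   (sample x module latent matrix).
#' @export
simulate_bulk <- function(config) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, "bulk"))
  n <- config$n_samples
  sizes <- config$module_sizes
  k <- length(sizes)
  rb <- config$between_module_cor
  w <- config$within_module_cor

  g <- stats::rnorm(n)
  z <- sapply(seq_len(k), function(m) {
    sqrt(rb) * g + sqrt(1 - rb) * stats::rnorm(n)
  })
  colnames(z) <- paste0("M", seq_len(k))

  # BMI loads on the target module's latent partly through the shared
  # programme g, so that all module genes differ between BMI groups while
  # only the target module reaches the calibrated correlation; off-target
  # modules sit at bmi_shared_frac (0.65) of the target correlation.
  q <- .gauss_for_spearman(config$bmi_effect)
  ct <- 0.35 * q / (1 - rb)
  cg <- (q - ct) / sqrt(rb)
  v <- ct^2 + cg^2 + 2 * ct * cg * sqrt(rb)
  if (v > 1) { # very strong effects: rescale, correlation caps below target
    ct <- ct / sqrt(v); cg <- cg / sqrt(v); v <- 1
  }
  bmi_lat <- ct * z[, config$bmi_module_index] + cg * g +
    sqrt(1 - v) * stats::rnorm(n)
  bmi <- round(25 * exp(0.22 * bmi_lat), 1)
  group <- ifelse(bmi >= 25, "obese", "healthy")

  n_mod_genes <- sum(sizes)
  n_noise <- config$n_genes_bulk - n_mod_genes
  module_truth <- c(rep(seq_len(k), times = sizes), rep(0L, n_noise))
  genes <- sprintf("G%04d", seq_len(config$n_genes_bulk))

  # Module genes ride their module's latent factor; the remaining genes are
  # a stable, highly expressed housekeeping background. The background
  # dominates the library so that CPM normalization does not convert module
  # swings into spurious compositional (anti-)correlations.
  is_mod <- module_truth > 0L
  base <- numeric(config$n_genes_bulk)
  base[is_mod] <- exp(stats::rnorm(sum(is_mod), log(300), 0.4))
  base[!is_mod] <- exp(stats::rnorm(sum(!is_mod), log(12000), 0.3))
  sigma <- sqrt(1 / w - 1) # within-module gene noise on the log scale
  depth <- exp(stats::rnorm(n, 0, 0.2))

  # The last n_bridge_genes genes of each module also track the next module
  # (ring order): their latent has correlation 0.88 with the own-module
  # factor and bridge_beta with the next one, solved through the bivariate
  # system so both targets are met under the factor correlation rb.
  nb <- if (k >= 2L) min(config$n_bridge_genes, min(sizes)) else 0L
  c_own <- 0.88
  c_next <- config$bridge_beta
  al <- (c_own - rb * c_next) / (1 - rb^2)
  be <- (c_next - rb * c_own) / (1 - rb^2)
  vb <- al^2 + be^2 + 2 * al * be * rb
  if (vb > 1) { # infeasible targets: rescale to a unit-variance latent
    al <- al / sqrt(vb); be <- be / sqrt(vb); vb <- 1
  }
  mod_end <- cumsum(sizes)
  bridge_idx <- unlist(lapply(seq_len(k), function(m) {
    if (nb == 0L) integer(0) else (mod_end[m] - nb + 1L):mod_end[m]
  }))
  logmu <- matrix(0, config$n_genes_bulk, n)
  for (gi in seq_len(config$n_genes_bulk)) {
    m <- module_truth[gi]
    if (m > 0L) {
      lat <- if (gi %in% bridge_idx) {
        m2 <- (m %% k) + 1L
        al * z[, m] + be * z[, m2] + sqrt(1 - vb) * stats::rnorm(n)
      } else {
        z[, m]
      }
      sig <- lat + sigma * stats::rnorm(n)
    } else {
      sig <- 0.3 * stats::rnorm(n)
    }
    logmu[gi, ] <- log(base[gi]) + sig
  }
  mu <- sweep(exp(logmu), 2L, depth, `*`)
  counts <- matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
  dimnames(counts) <- list(genes, sprintf("S%03d", seq_len(n)))

  structure(list(
    counts = counts, genes = genes, samples = colnames(counts),
    bmi = bmi, group = group, module_truth = stats::setNames(module_truth, genes),
    factors = z, config = config
  ), class = "bulk_expression")
}

## Deterministic subtype allocation: floor(p * n) per subtype, remaining
## cells to the largest fractional parts (ties to the lower index).
.allocate_subtypes <- function(proportions, n) {
  raw <- proportions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Simulate a single-cell population with subtype-specific dependency
#'
#' Per subtype, draws latent multivariate Gaussians under the subtype's
#' correlation template and maps the marginals to negative-binomial counts
#' through a Gaussian copula, so all subtypes share marginal means and
#' differ only in which gene pairs co-vary -- the structure a cell-specific
#' network statistic detects and mean-expression clustering does not.
#' Mitochondrial genes and lognormal per-cell depths give UMI totals, gene
#' counts and mito fractions that straddle the standard QC cutoffs.
#'
#' @param config a [sim_config()] whose `dependency_networks` (or the
#'   default block templates) define the subtypes.
#' @return an `sc_expression` object: `counts` (gene x cell sparse matrix,
#'   mito genes last), `genes`, `cell_meta` (barcode, sample, group,
#'   umi_total, n_genes_detected, mito_fraction) and `subtype` (true labels).
#' @export
simulate_cells <- function(config) {
  validate_sim_config(config)
  tpls <- config$dependency_networks
  if (is.null(tpls)) {
    tpls <- block_dependency_templates(config$n_genes_sc,
                                       length(config$subtype_proportions))
  }
  tpls <- lapply(tpls, nearest_psd)
  set.seed(child_seed(config$seed, "cells"))

  n <- config$n_cells
  gg <- config$n_genes_sc
  alloc <- .allocate_subtypes(config$subtype_proportions, n)
  subtype <- rep(seq_along(alloc), times = alloc)

  mu_g <- config$sc_mean_expr * exp(stats::rnorm(gg, 0, 0.4) - 0.08)
  size <- 1 / config$nb_dispersion
  sf <- exp(stats::rnorm(n, 0, config$sc_depth_sd))

  counts <- matrix(0L, gg, n)
  col0 <- 0L
  for (s in seq_along(alloc)) {
    ns <- alloc[s]
    if (ns == 0L) next
    ch <- chol(tpls[[s]])
    zz <- matrix(stats::rnorm(ns * gg), ns, gg) %*% ch
    uu <- stats::pnorm(zz)
    idx <- col0 + seq_len(ns)
    for (gi in seq_len(gg)) {
      counts[gi, idx] <- stats::qnbinom(uu[, gi], size = size,
                                        mu = mu_g[gi] * sf[idx])
    }
    col0 <- col0 + ns
  }

  # mitochondrial genes: per-cell target fraction drawn over the configured
  # range, split over n_mito_genes with fixed gene weights
  nm <- config$n_mito_genes
  f <- stats::runif(n, config$mito_fraction_range[1], config$mito_fraction_range[2])
  wts <- stats::runif(nm, 0.5, 1.5)
  wts <- wts / sum(wts)
  nonmito_tot <- pmax(colSums(counts), 1)
  mito_mu <- outer(wts, nonmito_tot * f / pmax(1 - f, 1e-6))
  mito <- matrix(stats::rpois(length(mito_mu), mito_mu), nrow = nm)

  genes <- c(sprintf("G%04d", seq_len(gg)), sprintf("MT-%d", seq_len(nm)))
  full <- rbind(counts, mito)
  dimnames(full) <- list(genes, sprintf("cell%04d", seq_len(n)))

  groups <- c("HD", "MO", "SO")
  samples <- paste0(rep(groups, each = 2L), rep(1:2, times = 3L))
  cell_sample <- sample(samples, n, replace = TRUE)
  umi <- colSums(full)
  meta <- data.frame(
    barcode = colnames(full),
    sample = cell_sample,
    group = substr(cell_sample, 1L, 2L),
    umi_total = umi,
    n_genes_detected = colSums(full > 0),
    mito_fraction = colSums(full[grepl("^MT-", genes), , drop = FALSE]) / pmax(umi, 1),
    stringsAsFactors = FALSE
  )
  structure(list(
    counts = methods::as(Matrix::Matrix(full, sparse = TRUE), "CsparseMatrix"),
    genes = genes, cell_meta = meta,
    subtype = stats::setNames(subtype, colnames(full)),
    config = config
  ), class = "sc_expression")
}

#' Simulate a scale-free protein-protein interaction network
#'
#' Preferential attachment over the supplied genes: the first two genes form
#' an unconnected seed; every later gene attaches `m` edges to distinct
#' earlier genes chosen with probability proportional to degree + 1 (the +1
#' makes the zero-degree seed reachable). The result is connected, simple
#' and has exactly `m * (n - 2)` edges when `m = 2`.
#'
#' @param genes character vector of at least 3 gene identifiers.
#' @param seed integer seed.
#' @param m edges added per arriving gene.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
simulate_ppi <- function(genes, seed = 1L, m = 2L) {
  if (length(genes) < 3L) {
    stop("configuration error: at least 3 genes required", call. = FALSE)
  }
  set.seed(child_seed(seed, "ppi"))
  n <- length(genes)
  deg <- integer(n)
  ea <- integer(0)
  eb <- integer(0)
  for (i in 3:n) {
    existing <- seq_len(i - 1L)
    mi <- min(m, length(existing))
    tgt <- sample(existing, mi, prob = deg[existing] + 1)
    ea <- c(ea, rep(i, mi))
    eb <- c(eb, tgt)
    deg[tgt] <- deg[tgt] + 1L
    deg[i] <- deg[i] + mi
  }
  a <- pmin(ea, eb)
  b <- pmax(ea, eb)
  data.frame(gene_a = genes[a], gene_b = genes[b], stringsAsFactors = FALSE)
}

#' Simulate term gene sets (a synthetic stand-in for ontology annotations)
#'
#' Random gene subsets over a universe, usable through the GMT reader/writer
#' so enrichment code paths run without any ontology download.
#'
#' @param genes gene universe.
#' @param n_terms number of terms.
#' @param seed integer seed.
#' @param size_range min/max genes per term.
#' @return named list of character vectors.
#' @export
simulate_gene_sets <- function(genes, n_terms = 20L, seed = 1L,
                               size_range = c(5L, 40L)) {
  set.seed(child_seed(seed, "genesets"))
  size_range[2] <- min(size_range[2], length(genes))
  out <- lapply(seq_len(n_terms), function(i) {
    sz <- sample(seq(size_range[1], size_range[2]), 1L)
    sort(sample(genes, sz))
  })
  names(out) <- sprintf("TERM%03d", seq_len(n_terms))
  out
}
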