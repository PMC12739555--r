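#!/usr/bin/env Rscript
# Generate the synthetic study data: a bulk adipose cohort with four planted
# co-expression modules (module 2 tracks BMI at Spearman ~0.7), a 600-cell
# macrophage population whose three subtypes differ only in gene-gene
# dependency structure, a scale-free interaction network over the BMI
# module's genes, and synthetic term gene sets for enrichment.

suppressPackageStartupMessages(library(atmnet))

seed <- 1L
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)

bulk <- simulate_bulk(cfg)
write_bulk_tsv(bulk, file.path(out, "bulk"))
write.table(data.frame(gene = names(bulk$module_truth),
                       module = bulk$module_truth),
            file.path(out, "bulk", "module_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("bulk cohort: %d genes x %d samples, %d obese / %d healthy\n",
            nrow(bulk$counts), ncol(bulk$counts),
            sum(bulk$group == "obese"), sum(bulk$group == "healthy")))
rho <- apply(bulk$factors, 2, function(z) cor(z, bulk$bmi, method = "spearman"))
cat("module-factor vs BMI Spearman:",
    paste(sprintf("%s=%.2f", colnames(bulk$factors), rho), collapse = ", "),
    "\n")

sc <- simulate_cells(cfg)
write_sc_bundle(sc, file.path(out, "cells"))
write.table(data.frame(barcode = names(sc$subtype), subtype = sc$subtype),
            file.path(out, "cells", "subtype_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("cells: %d genes x %d cells, subtype sizes %s\n",
            nrow(sc$counts), ncol(sc$counts),
            paste(table(sc$subtype), collapse = "/")))

# a QC-demonstration cohort with wide depth spread (cells on both sides of
# every filter threshold)
qc_cfg <- sim_config(seed = seed, n_cells = 400, n_genes_sc = 250,
                     subtype_proportions = 1,
                     dependency_networks = list(diag(250)),
                     sc_mean_expr = 6, sc_depth_sd = 0.6,
                     mito_fraction_range = c(0, 0.2))
write_sc_bundle(simulate_cells(qc_cfg), file.path(out, "cells_qc_demo"))

# interaction network over the BMI module's genes
bmi_genes <- names(bulk$module_truth)[bulk$module_truth == cfg$bmi_module_index]
ppi <- simulate_ppi(bmi_genes, seed = seed)
write.table(ppi, file.path(out, "ppi.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("interaction network: %d genes, %d edges\n",
            length(bmi_genes), nrow(ppi)))

# term gene sets over the single-cell genes (enrichment stand-in)
sets <- simulate_gene_sets(rownames(sc$counts)[!grepl("^MT-", rownames(sc$counts))],
                           n_terms = 30, seed = seed)
write_gmt(sets, file.path(out, "terms.gmt"))
cat("wrote", out, "\n")
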