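#!/usr/bin/env Rscript
# Bulk pipeline: CPM -> differential genes -> obese co-expression network
# -> Multilevel communities -> CFV k-means modules -> module-BMI Spearman
# -> PageRank hubs -> random-forest key genes.

suppressPackageStartupMessages(library(atmnet))

sim <- "results/simdata"
out <- "results/bulk"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

bulk <- read_bulk_tsv(file.path(sim, "bulk"))
truth <- read.delim(file.path(sim, "bulk", "module_truth.tsv"))
ppi <- read.delim(file.path(sim, "ppi.tsv"))

res <- run_bulk_pipeline(bulk, ppi = ppi, seed = 1L)

write.table(res$degs, file.path(out, "degs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$network$edges, file.path(out, "coexpr_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
mods <- data.frame(gene = names(res$partition$module_of),
                   community = res$communities$membership[
                     names(res$partition$module_of)],
                   module = res$partition$module_of)
write.table(mods, file.path(out, "modules.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$bmi_association$table, file.path(out, "module_bmi.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("differential genes: %d of %d\n",
            nrow(res$degs), nrow(bulk$counts)))
cat(sprintf("network: %d genes, %d edges (largest of %d components)\n",
            length(res$network$nodes), nrow(res$network$edges),
            res$network$n_components))
cat(sprintf("modules: %s\n",
            paste(table(res$partition$module_of), collapse = "/")))
tr <- truth$module[match(names(res$partition$module_of), truth$gene)]
cat(sprintf("module recovery ARI vs planted: %.3f\n",
            mclust::adjustedRandIndex(res$partition$module_of, tr)))
cat(sprintf("key module: %s (Spearman rho %.2f with BMI)\n",
            res$bmi_association$key_module, res$bmi_association$key_rho))

if (!is.null(res$key_report)) {
  write.table(res$hubs, file.path(out, "hubs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$key_report$importance, file.path(out, "key_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("hub genes: %d; key genes passing importance thresholds: %s\n",
              nrow(res$hubs),
              paste(res$key_report$key_genes, collapse = ", ")))
}
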