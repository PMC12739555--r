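#!/usr/bin/env Rscript
# Subtype-specific gene regulatory networks: edges among driver genes
# prevalent in at least half of a subtype's cells, DeepWalk-style graph
# embeddings, Gaussian-mixture gene modules and hypergeometric enrichment
# aggregated per term.

suppressPackageStartupMessages(library(atmnet))

sim <- "results/simdata"
sub_dir <- "results/subtypes"
out <- "results/ssgrn"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

nets <- read_cell_networks(file.path(sub_dir, "cell_networks"))
labels <- read.delim(file.path(sub_dir, "subtype_labels.tsv"))
gene_sets <- read_gmt(file.path(sim, "terms.gmt"))
universe <- nets$genes

for (s in sort(unique(labels$subtype))) {
  cells_s <- labels$barcode[labels$subtype == s]
  drv <- driver_genes(nets, cells_s)
  grn <- ssgrn_edges(nets, cells_s, drv, subtype = s)
  cat(sprintf("subtype %d: %d cells, %d drivers, %d prevalent edges\n",
              s, length(cells_s), length(drv), nrow(grn$edges)))
  write.table(grn$edges, file.path(out, sprintf("ssgrn_C%d_edges.tsv", s)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(grn$edges) < 2 || length(drv) < 4) {
    cat("  too small for module detection; skipping\n")
    next
  }
  emb <- deepwalk_embed(grn, seed = 1L)
  mods <- gmm_modules(gene_similarity(emb), seed = 1L)
  cat(sprintf("  gene modules: %d (model %s)\n", mods$n_modules, mods$model))
  mods <- enrich_modules(mods, gene_sets, universe)
  write.table(data.frame(gene = names(mods$module_of),
                         module = mods$module_of),
              file.path(out, sprintf("modules_C%d.tsv", s)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(term = rownames(mods$enrichment),
                         round(mods$enrichment, 4),
                         max_neglog10p = round(mods$term_summary, 4)),
              file.path(out, sprintf("enrichment_C%d.tsv", s)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  top <- names(sort(mods$term_summary, decreasing = TRUE))[1:3]
  cat(sprintf("  top terms by max -log10 p: %s\n",
              paste(top, collapse = ", ")))
}
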