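#!/usr/bin/env Rscript
# Macrophage subtyping by regulation rather than expression: one
# cell-specific network per cell, the gene x cell degree matrix (NCM),
# SNN-Louvain clustering of degree profiles, and differential / featured
# degree genes per subtype.

suppressPackageStartupMessages(library(atmnet))

sim <- "results/simdata"
out <- "results/subtypes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sc <- read_sc_bundle(file.path(sim, "cells"))
truth <- read.delim(file.path(sim, "cells", "subtype_truth.tsv"))
sc$subtype <- setNames(truth$subtype, truth$barcode)

res <- run_subtype_pipeline(sc, seed = 1L)

write_cell_networks(res$nets, file.path(out, "cell_networks"))
invisible(Matrix::writeMM(Matrix::Matrix(res$ncm, sparse = TRUE),
                          file.path(out, "ncm.mtx")))
writeLines(rownames(res$ncm), file.path(out, "ncm_genes.tsv"))
writeLines(colnames(res$ncm), file.path(out, "ncm_cells.tsv"))
write.table(data.frame(barcode = names(res$clusters$labels),
                       subtype = res$clusters$labels),
            file.path(out, "subtype_labels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("per-cell networks: %d edges over %d cells (%.1f per cell)\n",
            nrow(res$nets$edges), length(res$nets$cells),
            nrow(res$nets$edges) / length(res$nets$cells)))
cat(sprintf("clusters found: %d, sizes %s\n",
            length(unique(res$clusters$labels)),
            paste(table(res$clusters$labels), collapse = "/")))
cat(sprintf("ARI vs planted subtypes: %.3f\n",
            mclust::adjustedRandIndex(res$clusters$labels, res$truth)))

ddg <- find_ddgs(res$ncm, res$clusters$labels)
fdg <- find_fdgs(ddg, res$ncm, res$clusters$labels)
write.table(ddg, file.path(out, "ddg.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(fdg, file.path(out, "fdg.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("differential degree genes: %d rows; featured degree genes: %d\n",
            nrow(ddg), nrow(fdg)))
for (s in sort(unique(ddg$subtype))) {
  cat(sprintf("  subtype %s: %d up, %d down DDGs, %d FDGs\n", s,
              sum(ddg$subtype == s & ddg$direction == "up"),
              sum(ddg$subtype == s & ddg$direction == "down"),
              sum(fdg$subtype == s)))
}
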