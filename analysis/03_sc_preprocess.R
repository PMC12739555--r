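#!/usr/bin/env Rscript
# Single-cell preprocessing on the QC-demonstration cohort: droplet QC
# (UMI bounds, detected genes, mitochondrial load), depth normalization and
# entropy-ranked highly variable genes.

suppressPackageStartupMessages(library(atmnet))

sim <- "results/simdata"
out <- "results/scprep"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cells <- read_sc_bundle(file.path(sim, "cells_qc_demo"))
cat(sprintf("input: %d genes x %d cells\n", nrow(cells$counts),
            ncol(cells$counts)))

filtered <- qc_filter(cells)
tally <- attr(filtered, "qc_removed")
cat(sprintf("QC removed - low UMI: %d, high UMI: %d, few genes: %d, high mito: %d\n",
            tally["low_umi"], tally["high_umi"], tally["few_genes"],
            tally["high_mito"]))
cat(sprintf("retained %d cells\n", ncol(filtered$counts)))
write.table(filtered$cell_meta, file.path(out, "qc_cell_meta.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

norm <- lognormalize(filtered)
hvgs <- entropy_hvgs(norm, n_top = 50)
write.table(data.frame(gene = as.character(hvgs),
                       entropy = attr(hvgs, "scores")),
            file.path(out, "hvgs.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("top-50 entropy genes written; score range %.2f .. %.2f\n",
            min(attr(hvgs, "scores")), max(attr(hvgs, "scores"))))
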