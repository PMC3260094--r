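#!/usr/bin/env Rscript
# QQ summaries of the gene-level p-values for the four design x model
# panels, with exact pointwise beta envelopes.
suppressPackageStartupMessages(library(triadscan))

panels <- list()
for (design in c("triad", "hybrid")) for (width in c(1, 3)) {
  gp <- read.delim(sprintf("results/scan_%s_w%d_genes.tsv", design, width))
  nm <- sprintf("%s, %s", design,
                if (width == 1) "single locus" else "haplotype")
  panels[[nm]] <- qq_data(gp$p_gene)
  write.table(panels[[nm]],
              sprintf("results/qq_%s_w%d.tsv", design, width),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
render_qq(panels, "results/qq_panels.png", width = 7, height = 7)
cat("wrote results/qq_panels.png and per-panel QQ tables\n")
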