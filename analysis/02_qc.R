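#!/usr/bin/env Rscript
# Quality control: marker filters (call-rate, X chromosome, exact HWE in
# control mothers, founder MAF) and family filters (Mendelian rate,
# sample call-rates), plus the fixed accounting benchmark.
suppressPackageStartupMessages(library(triadscan))

dd <- read_dataset("results/data/study")
qc <- apply_qc(dd$families, dd$panel)
print(qc$report)
write.table(qc_report_table(qc$report), "results/qc_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_dataset(qc$families, qc$panel, "results/data/study_qc")

# the constructed benchmark: every marker rule at a known truth
bench <- simulate_qc_benchmark()
bqc <- apply_qc(bench$families, bench$panel)
cat(sprintf("benchmark panel: %d/%d SNPs and %d/%d genes retained\n",
            bqc$report$n_retained_snps, bqc$report$n_input_snps,
            bqc$report$n_retained_genes, bqc$report$n_input_genes))
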