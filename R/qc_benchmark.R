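# A constructed benchmark panel for auditing the QC filter cascade.

#' Construct the QC-accounting benchmark dataset
#'
#' Builds a fully deterministic synthetic panel of 1,443 SNPs (all with
#' complete calls) in 167 genes, together with 50 case triads and 100
#' control-mother dyads, engineered so that the filter cascade excludes
#' exactly: 31 X-chromosome SNPs, 18 SNPs failing the exact
#' Hardy-Weinberg test in control mothers at p < 0.01, and 68 SNPs with
#' founder minor allele frequency below 5% -- disjoint categories whose
#' excluded SNPs fully cover 8 genes, leaving 1,326 SNPs in 159 genes.
#' This mirrors the marker accounting of a GoldenGate candidate-gene panel
#' after pre-processing and exercises every marker-level rule at a known
#' truth.
#'
#' @return List with `families` and `panel`, ready for [apply_qc()].
#' @export
simulate_qc_benchmark <- function() {
  n_ctrl <- 100L
  n_case <- 50L
  n_x <- 31L; n_hwe <- 18L; n_maf <- 68L
  n_norm <- 1443L - n_x - n_hwe - n_maf

  # per-SNP genotype columns for control mothers (length n_ctrl) and case
  # parents (length n_case, used for both mother and father)
  # normal SNPs: near-exact HWE at allele frequency 0.3
  norm_ctrl <- rep(c(2L, 1L, 0L), c(9, 42, 49))
  norm_case <- rep(c(2L, 1L, 0L), c(5, 21, 24))
  # HWE-failing SNPs: every control mother heterozygous (extreme excess)
  hwe_ctrl <- rep(1L, n_ctrl)
  hwe_case <- rep(1L, n_case)
  # low-MAF SNPs: six heterozygous control mothers, founder MAF = 0.015
  maf_ctrl <- rep(c(1L, 0L), c(6, 94))
  maf_case <- rep(0L, n_case)

  col_for <- function(type, who) {
    switch(paste(type, who),
           "norm ctrl" = norm_ctrl, "norm case" = norm_case,
           "x ctrl" = norm_ctrl, "x case" = norm_case,
           "hwe ctrl" = hwe_ctrl, "hwe case" = hwe_case,
           "maf ctrl" = maf_ctrl, "maf case" = maf_case)
  }
  types <- rep(c("x", "hwe", "maf", "norm"), c(n_x, n_hwe, n_maf, n_norm))

  # gene assignment: 8 genes fully covered by the excluded SNPs
  maf_genes <- rep(paste0("GMAF", 1:6), c(12, 12, 12, 12, 10, 10))
  n_per <- rep(8L, 159L); n_per[seq_len(1326 - 8 * 159)] <- 9L
  keep_genes <- rep(paste0("G", seq_len(159)), n_per)
  gene <- c(rep("GX", n_x), rep("GHWE", n_hwe), maf_genes, keep_genes)

  gene_ids <- unique(gene[gene != "GX"])
  chrom <- ifelse(gene == "GX", "X",
                  as.character(1 + (match(gene, gene_ids) - 1) %% 22))
  panel <- data.frame(snp_id = sprintf("snp%04d", seq_along(types)),
                      chromosome = chrom, position = 0L,
                      allele1 = "1", allele2 = "2", gene = gene,
                      stringsAsFactors = FALSE)
  panel <- panel[order(panel$chromosome != "X", panel$gene), ]
  panel$position <- stats::ave(seq_len(nrow(panel)), panel$chromosome,
                               FUN = seq_along) * 1000L
  rownames(panel) <- NULL
  types <- types[match(panel$snp_id, sprintf("snp%04d", seq_along(gene)))]

  ctrl_geno <- sapply(types, col_for, who = "ctrl")   # n_ctrl x n_snp
  case_geno <- sapply(types, col_for, who = "case")   # n_case x n_snp

  families <- c(
    lapply(seq_len(n_case), function(i) {
      g <- case_geno[i, ]
      # identical parents and child: always Mendelian-consistent
      family_record(sprintf("CASE%03d", i), "case",
                    mother = g, child = g, father = g)
    }),
    lapply(seq_len(n_ctrl), function(i) {
      g <- ctrl_geno[i, ]
      family_record(sprintf("CTRL%03d", i), "control",
                    mother = g, child = g)
    }))
  list(families = families, panel = marker_panel(panel))
}
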