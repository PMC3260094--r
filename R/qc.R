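# Marker- and family-level quality control for triad/dyad genotype data.
#
# SNP filters are applied sequentially -- call-rate, X chromosome,
# Hardy-Weinberg (exact test in control mothers), minor allele frequency --
# with each excluded SNP attributed to the first rule it fails.  Family
# filters: Mendelian-inconsistency rate, mother/child call-rate; fathers
# with low call-rate are dropped individually while the family remains.

#' Fraction of non-missing genotype calls
#'
#' @param calls Vector of genotype calls (dosages), `NA` = missing.
#' @return Call rate in `[0, 1]`.
#' @export
snp_call_rate <- function(calls) {
  if (length(calls) == 0) stop("no calls supplied", call. = FALSE)
  mean(!is.na(calls))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the allele counts: the p-value is the
#' sum of probabilities of all heterozygote counts no more probable than the
#' observed one, where the conditional probability of `h` heterozygotes
#' among `n` genotypes carrying `n1` minor alleles is
#' `n! / (nAA! h! naa!) * 2^h * n1! n2! / (2n)!`.
#'
#' @param n_aa_hom,n_het,n_ref_hom Genotype counts (minor homozygote,
#'   heterozygote, major homozygote; the labelling is symmetric).
#' @return P-value in `(0, 1]`; monomorphic markers return 1 by convention.
#' @export
hwe_exact_test <- function(n_aa_hom, n_het, n_ref_hom) {
  counts <- c(n_aa_hom, n_het, n_ref_hom)
  if (any(counts < 0) || sum(counts) == 0)
    stop("genotype counts must be non-negative with positive total",
         call. = FALSE)
  n <- sum(counts)
  n1 <- 2 * n_aa_hom + n_het           # allele-1 count
  if (n1 == 0 || n1 == 2 * n) return(1)
  n_minor <- min(n1, 2 * n - n1)
  # possible heterozygote counts share the parity of the minor-allele count
  h <- seq(n_minor %% 2, n_minor, by = 2)
  log_p <- lfactorial(n) - lfactorial((n_minor - h) / 2) - lfactorial(h) -
    lfactorial(n - (n_minor + h) / 2) + h * log(2) +
    lfactorial(n_minor) + lfactorial(2 * n - n_minor) - lfactorial(2 * n)
  p_h <- exp(log_p - max(log_p))
  p_h <- p_h / sum(p_h)
  p_obs <- p_h[match(n_het, h)]
  min(1, sum(p_h[p_h <= p_obs * (1 + 1e-12)]))
}

#' Minor allele frequency from founder genotypes
#'
#' @param dosages Variant-allele counts (0/1/2, `NA` missing) of founder
#'   individuals at one SNP.
#' @return Frequency of the less common allele, in `[0, 0.5]`.
#' @export
minor_allele_freq <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0) stop("all founder genotypes missing", call. = FALSE)
  f <- sum(d) / (2 * length(d))
  min(f, 1 - f)
}

# transmissible alleles (variant-allele indicator sets) per dosage
trio_snp_consistent <- function(m, f, c) {
  # child dosage c must decompose as a maternal + a paternal transmissible
  # allele: maternal in {0}|{0,1}|{1} for m = 0|1|2, likewise paternal
  lo <- (m == 2) + (f == 2)
  hi <- (m >= 1) + (f >= 1)
  c >= lo & c <= hi
}

dyad_snp_consistent <- function(m, c) {
  !((m == 0 & c == 2) | (m == 2 & c == 0))
}

#' Mendelian-inconsistency rate of one family
#'
#' Over SNPs at which every available family member has a genotype call,
#' the fraction whose joint genotypes are incompatible with Mendelian
#' inheritance (full trio check for triads, mother-child compatibility for
#' dyads).
#'
#' @param family A [family_record()].
#' @return Fraction in `[0, 1]`.
#' @export
mendelian_error_rate <- function(family) {
  m <- family$mother; c <- family$child
  if (is.null(family$father)) {
    ok <- !is.na(m) & !is.na(c)
    if (!any(ok)) stop("no jointly called SNPs in family ",
                       family$family_id, call. = FALSE)
    mean(!dyad_snp_consistent(m[ok], c[ok]))
  } else {
    f <- family$father
    ok <- !is.na(m) & !is.na(f) & !is.na(c)
    if (!any(ok)) stop("no jointly called SNPs in family ",
                       family$family_id, call. = FALSE)
    mean(!trio_snp_consistent(m[ok], f[ok], c[ok]))
  }
}

# stack one role's genotypes across families into a matrix (rows = persons)
stack_genotypes <- function(families, role) {
  rows <- lapply(families, function(fam) fam[[role]])
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Apply the full QC filter cascade
#'
#' SNP filters, in order and each SNP counted once under the first rule it
#' fails: call-rate (over all genotyped individuals) below
#' `snp_call_rate`; X chromosome; Hardy-Weinberg exact test in control
#' mothers at `hwe_p`; minor allele frequency among founders (case parents
#' and control mothers) below `maf`.  Family filters: Mendelian-
#' inconsistency rate above `family_mendel` removes the family; mother or
#' child call-rate below `sample_call_rate` removes the family; a father
#' below `sample_call_rate` is dropped individually.  Within retained
#' families, residual SNP-wise Mendelian-inconsistent genotype sets are set
#' to missing.
#'
#' @param families List of [family_record()].
#' @param panel Marker panel data frame.
#' @param thresholds Named list; defaults
#'   `list(snp_call_rate = 0.90, hwe_p = 0.01, maf = 0.05,
#'   sample_call_rate = 0.95, family_mendel = 0.01)`.
#' @return List with `families`, `panel` (both filtered) and `report`, a
#'   `qc_report` list of exclusion counts and identities.
#' @export
apply_qc <- function(families, panel,
                     thresholds = list()) {
  th <- utils::modifyList(list(snp_call_rate = 0.90, hwe_p = 0.01,
                               maf = 0.05, sample_call_rate = 0.95,
                               family_mendel = 0.01),
                          thresholds)
  panel <- marker_panel(panel)
  n_input <- nrow(panel)
  mothers <- stack_genotypes(families, "mother")
  fathers <- stack_genotypes(families, "father")
  children <- stack_genotypes(families, "child")
  all_geno <- rbind(mothers, fathers, children)

  is_control <- vapply(families, function(f) f$status == "control",
                       logical(1))
  ctrl_mothers <- stack_genotypes(families[is_control], "mother")
  case_mothers <- stack_genotypes(families[!is_control], "mother")
  case_fathers <- stack_genotypes(families[!is_control], "father")
  founders <- rbind(case_mothers, case_fathers, ctrl_mothers)

  status <- rep("retained", n_input)

  call_rates <- colMeans(!is.na(all_geno))
  status[call_rates < th$snp_call_rate] <- "call_rate"

  status[status == "retained" &
           toupper(panel$chromosome) %in% c("X", "23")] <- "x_chromosome"

  if (!is.null(ctrl_mothers)) {
    for (s in which(status == "retained")) {
      d <- ctrl_mothers[, s]
      d <- d[!is.na(d)]
      if (length(d) == 0) next
      p <- hwe_exact_test(sum(d == 2), sum(d == 1), sum(d == 0))
      if (p < th$hwe_p) status[s] <- "hwe"
    }
  }

  for (s in which(status == "retained")) {
    d <- founders[, s]
    if (all(is.na(d))) next
    if (minor_allele_freq(d) < th$maf) status[s] <- "maf"
  }

  keep_snps <- which(status == "retained")
  if (length(keep_snps) == 0)
    stop("no SNPs survive QC", call. = FALSE)

  sub_family <- function(fam) {
    family_record(fam$family_id, fam$status,
                  mother = fam$mother[keep_snps],
                  child = fam$child[keep_snps],
                  father = if (is.null(fam$father)) NULL
                           else fam$father[keep_snps])
  }
  fam2 <- lapply(families, sub_family)

  excluded_families <- list()
  fathers_dropped <- character(0)
  keep_fam <- logical(length(fam2))
  for (i in seq_along(fam2)) {
    fam <- fam2[[i]]
    mrate <- tryCatch(mendelian_error_rate(fam), error = function(e) NA)
    if (!is.na(mrate) && mrate > th$family_mendel) {
      excluded_families[[length(excluded_families) + 1]] <-
        list(family_id = fam$family_id, reason = "mendelian",
             value = mrate)
      next
    }
    if (snp_call_rate(fam$mother) < th$sample_call_rate ||
        snp_call_rate(fam$child) < th$sample_call_rate) {
      excluded_families[[length(excluded_families) + 1]] <-
        list(family_id = fam$family_id, reason = "sample_call_rate",
             value = min(snp_call_rate(fam$mother),
                         snp_call_rate(fam$child)))
      next
    }
    if (!is.null(fam$father) &&
        snp_call_rate(fam$father) < th$sample_call_rate) {
      fathers_dropped <- c(fathers_dropped, fam$family_id)
      fam["father"] <- list(NULL)  # drop the father, keep the slot
      fam2[[i]] <- fam
    }
    keep_fam[i] <- TRUE
  }
  fam2 <- fam2[keep_fam]
  if (length(fam2) == 0)
    stop("no families survive QC", call. = FALSE)

  # residual per-SNP Mendelian clashes are zeroed (set missing) so that
  # downstream likelihood enumeration never sees impossible configurations
  fam2 <- lapply(fam2, function(fam) {
    m <- fam$mother; c <- fam$child
    if (is.null(fam$father)) {
      bad <- !is.na(m) & !is.na(c) & !dyad_snp_consistent(m, c)
    } else {
      f <- fam$father
      bad <- !is.na(m) & !is.na(f) & !is.na(c) &
        !trio_snp_consistent(m, f, c)
      fam$father[bad] <- NA_integer_
    }
    fam$mother[bad] <- NA_integer_
    fam$child[bad] <- NA_integer_
    fam
  })

  panel2 <- marker_panel(panel[keep_snps, , drop = FALSE])
  rownames(panel2) <- NULL
  report <- structure(list(
    n_input_snps = n_input,
    n_excluded_callrate = sum(status == "call_rate"),
    n_excluded_x = sum(status == "x_chromosome"),
    n_excluded_hwe = sum(status == "hwe"),
    n_excluded_maf = sum(status == "maf"),
    n_retained_snps = length(keep_snps),
    n_retained_genes = length(unique(panel2$gene)),
    n_input_genes = length(unique(panel$gene)),
    excluded_families = excluded_families,
    fathers_dropped = fathers_dropped,
    snp_status = data.frame(snp_id = panel$snp_id, status = status,
                            stringsAsFactors = FALSE)),
    class = "qc_report")
  list(families = fam2, panel = panel2, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  SNPs in: %d  excluded: call-rate %d, X %d, HWE %d, MAF %d\n",
              x$n_input_snps, x$n_excluded_callrate, x$n_excluded_x,
              x$n_excluded_hwe, x$n_excluded_maf))
  cat(sprintf("  SNPs retained: %d in %d genes (of %d)\n",
              x$n_retained_snps, x$n_retained_genes, x$n_input_genes))
  cat(sprintf("  families excluded: %d; fathers dropped: %d\n",
              length(x$excluded_families), length(x$fathers_dropped)))
  invisible(x)
}

#' Tabular QC exclusion report
#'
#' One row per excluded entity, for export as TSV.
#'
#' @param report A `qc_report` from [apply_qc()].
#' @return Data frame with columns `entity_type`, `id`, `rule`.
#' @export
qc_report_table <- function(report) {
  snps <- report$snp_status
  snps <- snps[snps$status != "retained", , drop = FALSE]
  rows <- data.frame(entity_type = character(0), id = character(0),
                     rule = character(0), stringsAsFactors = FALSE)
  if (nrow(snps))
    rows <- rbind(rows, data.frame(entity_type = "snp", id = snps$snp_id,
                                   rule = snps$status,
                                   stringsAsFactors = FALSE))
  for (ex in report$excluded_families)
    rows <- rbind(rows, data.frame(entity_type = "family",
                                   id = ex$family_id, rule = ex$reason,
                                   stringsAsFactors = FALSE))
  if (length(report$fathers_dropped))
    rows <- rbind(rows, data.frame(entity_type = "father",
                                   id = report$fathers_dropped,
                                   rule = "sample_call_rate",
                                   stringsAsFactors = FALSE))
  rows
}
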