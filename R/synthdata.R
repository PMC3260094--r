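# Synthetic triad/dyad genotype data with known haplotype frequencies and
# fetal/maternal relative risks.
#
# Internal genotype representation: one integer "dosage" per SNP per person,
# the count of the variant allele ("2") among the two carried alleles, with
# NA for a missing call.  Biallelic markers make this lossless with respect
# to the unordered allele-pair representation of PED files.

#' Specify one gene for the synthetic-data generator
#'
#' A gene is a block of tightly linked SNPs carrying a small set of
#' haplotypes.  Parental haplotypes are drawn independently from
#' `haplotype_freqs` (random mating, Hardy-Weinberg equilibrium) and
#' transmitted without recombination within the block.  Relative risks act
#' multiplicatively per copy of a haplotype carried by the child
#' (`fetal_rr`) or by the mother (`maternal_rr`); the most frequent
#' haplotype is the reference and must have both risks fixed at 1.
#'
#' @param name Gene label.
#' @param chromosome Chromosome label (autosome number or `"X"`).
#' @param haplotypes Character vector of allele strings over `"1"`/`"2"`,
#'   all of the same length (the number of SNPs in the gene).
#' @param haplotype_freqs Numeric simplex vector, one frequency per
#'   haplotype, summing to 1.
#' @param fetal_rr,maternal_rr Per-haplotype relative risks; strictly
#'   positive, equal to 1 for the most frequent (reference) haplotype.
#' @return A `gene_spec` list.
#' @export
gene_spec <- function(name, chromosome, haplotypes, haplotype_freqs,
                      fetal_rr = rep(1, length(haplotypes)),
                      maternal_rr = rep(1, length(haplotypes))) {
  stopifnot(is.character(haplotypes), length(haplotypes) >= 1)
  n_snps <- nchar(haplotypes[1])
  if (!all(nchar(haplotypes) == n_snps))
    stop("all haplotypes must have the same length", call. = FALSE)
  if (anyDuplicated(haplotypes))
    stop("duplicated haplotypes in gene ", name, call. = FALSE)
  if (!all(strsplit(paste(haplotypes, collapse = ""), "")[[1]] %in% c("1", "2")))
    stop("haplotype alleles must be '1' or '2'", call. = FALSE)
  if (length(haplotype_freqs) != length(haplotypes) ||
      any(haplotype_freqs < 0) ||
      abs(sum(haplotype_freqs) - 1) > 1e-12)
    stop("haplotype_freqs must be a simplex vector over the haplotypes",
         call. = FALSE)
  if (length(fetal_rr) != length(haplotypes) || any(fetal_rr <= 0) ||
      length(maternal_rr) != length(haplotypes) || any(maternal_rr <= 0))
    stop("relative risks must be strictly positive, one per haplotype",
         call. = FALSE)
  ref <- which.max(haplotype_freqs)
  if (fetal_rr[ref] != 1 || maternal_rr[ref] != 1)
    stop("the most frequent haplotype is the reference; its relative risks ",
         "must equal 1", call. = FALSE)
  structure(list(name = as.character(name),
                 chromosome = as.character(chromosome),
                 n_snps = n_snps,
                 haplotypes = haplotypes,
                 haplotype_freqs = haplotype_freqs,
                 fetal_rr = fetal_rr,
                 maternal_rr = maternal_rr),
            class = "gene_spec")
}

#' Configure a synthetic triad/dyad study
#'
#' Defaults emulate a candidate-gene preterm-delivery study: 196 case-parent
#' triads, 211 control-mother dyads, roughly 5% of case fathers without DNA,
#' sporadic missing genotype calls and rare Mendelian-error substitutions.
#'
#' @param genes List of [gene_spec()] objects.
#' @param n_case_triads,n_control_dyads Positive family counts.
#' @param father_missing_prob Probability that a case father's DNA is
#'   unavailable, leaving a case-mother dyad.
#' @param genotype_missing_rate Per-genotype-call missing probability.
#' @param mendelian_error_rate Per transmitted child allele, the probability
#'   of substitution by an allele drawn uniformly from the two marker
#'   alleles.
#' @param baseline_risk Disease probability for a family whose child and
#'   mother carry only reference haplotypes.
#' @param seed Integer seed fixing the generated dataset byte-for-byte.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genes,
                       n_case_triads = 196L,
                       n_control_dyads = 211L,
                       father_missing_prob = 0.05,
                       genotype_missing_rate = 0.005,
                       mendelian_error_rate = 0.001,
                       baseline_risk = 0.01,
                       seed = 1L) {
  if (inherits(genes, "gene_spec")) genes <- list(genes)
  stopifnot(length(genes) >= 1,
            all(vapply(genes, inherits, logical(1), "gene_spec")))
  probs <- c(father_missing_prob, genotype_missing_rate,
             mendelian_error_rate, baseline_risk)
  if (any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (n_case_triads < 1 || n_control_dyads < 0)
    stop("need n_case_triads >= 1 and n_control_dyads >= 0", call. = FALSE)
  structure(list(genes = genes,
                 n_case_triads = as.integer(n_case_triads),
                 n_control_dyads = as.integer(n_control_dyads),
                 father_missing_prob = father_missing_prob,
                 genotype_missing_rate = genotype_missing_rate,
                 mendelian_error_rate = mendelian_error_rate,
                 baseline_risk = baseline_risk,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Construct a family record
#'
#' @param family_id Label.
#' @param status `"case"` or `"control"`.
#' @param mother,child Integer dosage vectors (variant-allele counts 0/1/2,
#'   `NA` = missing call), one entry per panel SNP.
#' @param father Dosage vector, or `NULL` when the father is absent
#'   (control-mother dyads, case fathers without DNA).
#' @return A `family_record` list.
#' @export
family_record <- function(family_id, status, mother, child, father = NULL) {
  status <- match.arg(status, c("case", "control"))
  stopifnot(length(mother) == length(child),
            is.null(father) || length(father) == length(mother))
  structure(list(family_id = as.character(family_id), status = status,
                 mother = as.integer(mother),
                 father = if (is.null(father)) NULL else as.integer(father),
                 child = as.integer(child)),
            class = "family_record")
}

# allele matrix of a gene's haplotypes: rows = haplotypes, 0/1 = variant allele
hap_allele_matrix <- function(haplotypes) {
  L <- nchar(haplotypes[1])
  m <- vapply(strsplit(haplotypes, ""),
              function(a) as.integer(a == "2"), integer(L))
  if (L == 1L) matrix(m, ncol = 1L) else t(m)
}

# Draw a batch of nuclear families (haplotype indices + disease status)
# from the forward model, before ascertainment.  Batching keeps the
# rejection sampler cheap at rare baseline risks.
draw_population_batch <- function(config, n) {
  genes <- config$genes
  risk <- rep(config$baseline_risk, n)
  hm <- hf <- hc <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    gs <- genes[[g]]
    K <- length(gs$haplotypes)
    m <- matrix(sample.int(K, 2 * n, replace = TRUE,
                           prob = gs$haplotype_freqs), n, 2)
    f <- matrix(sample.int(K, 2 * n, replace = TRUE,
                           prob = gs$haplotype_freqs), n, 2)
    tm <- m[cbind(seq_len(n), sample.int(2, n, replace = TRUE))]
    tf <- f[cbind(seq_len(n), sample.int(2, n, replace = TRUE))]
    hm[[g]] <- m; hf[[g]] <- f; hc[[g]] <- cbind(tm, tf)
    risk <- risk * gs$fetal_rr[tm] * gs$fetal_rr[tf] *
      gs$maternal_rr[m[, 1]] * gs$maternal_rr[m[, 2]]
  }
  list(hm = hm, hf = hf, hc = hc,
       capped = risk > 1,
       diseased = stats::runif(n) < pmin(risk, 1))
}

# haplotype index pairs per gene -> genome-wide dosage vector
haps_to_dosage <- function(hpairs, genes) {
  unlist(lapply(seq_along(genes), function(g) {
    A <- hap_allele_matrix(genes[[g]]$haplotypes)
    A[hpairs[[g]][1], ] + A[hpairs[[g]][2], ]
  }), use.names = FALSE)
}

apply_missingness <- function(dosage, rate) {
  if (rate > 0) dosage[stats::runif(length(dosage)) < rate] <- NA_integer_
  dosage
}

#' Simulate a single case or control family
#'
#' Parents' haplotypes are drawn independently from the configured
#' haplotype frequencies per gene; the child receives one haplotype from
#' each parent, chosen uniformly from the parent's two, without
#' recombination.  Disease probability is
#' `baseline_risk * prod(fetal_rr over child haplotypes) *
#' prod(maternal_rr over mother haplotypes)`, capped at 1.  Case families
#' are obtained by rejection sampling on disease and emitted as triads
#' (with the father masked entirely with probability `father_missing_prob`);
#' control families are drawn from the non-diseased and emitted as
#' mother-child dyads.  Genotype missingness and Mendelian-error allele
#' substitution in the child are applied after sampling.
#'
#' Uses the current RNG state; [simulate_dataset()] manages seeding.
#'
#' @param config A [sim_config()].
#' @param status `"case"` or `"control"`.
#' @param family_id Label for the emitted record.
#' @return A [family_record()], with attribute `"capped_draws"` counting
#'   rejected draws whose pre-cap risk exceeded 1 (used by
#'   [simulate_dataset()] to police the multiplicative regime).
#' @export
simulate_family <- function(config, status, family_id = "fam") {
  status <- match.arg(status, c("case", "control"))
  want_disease <- status == "case"
  n_draws <- 0L
  n_capped <- 0L
  batch_size <- if (want_disease)
    max(32L, ceiling(2 / max(config$baseline_risk, 1e-4))) else 8L
  repeat {
    batch <- draw_population_batch(config, batch_size)
    acc <- which(batch$diseased == want_disease)
    used <- if (length(acc)) acc[1] else batch_size
    n_draws <- n_draws + used
    n_capped <- n_capped + sum(batch$capped[seq_len(used)])
    if (length(acc)) break
    if (n_draws > 1e6)
      stop("rejection sampling failed to produce a ", status,
           " family within 1e6 draws; check baseline_risk", call. = FALSE)
  }
  pick <- acc[1]
  fam <- list(hm = lapply(batch$hm, function(m) m[pick, ]),
              hf = lapply(batch$hf, function(m) m[pick, ]),
              hc = lapply(batch$hc, function(m) m[pick, ]))
  genes <- config$genes
  mother <- haps_to_dosage(fam$hm, genes)
  child <- haps_to_dosage(fam$hc, genes)
  father <- haps_to_dosage(fam$hf, genes)

  # Mendelian errors: each of the child's two transmitted alleles, at each
  # SNP, is replaced with probability mendelian_error_rate by an allele
  # drawn uniformly from {1, 2}.
  er <- config$mendelian_error_rate
  if (er > 0) {
    n_snps <- length(child)
    for (a in 1:2) {
      hit <- stats::runif(n_snps) < er
      if (any(hit)) {
        new_allele <- stats::rbinom(sum(hit), 1L, 0.5)  # variant-allele ind.
        # recompute dosage: remove the allele contributed by this transmission
        # and add the substitute.  Transmission a=1 is maternal, a=2 paternal.
        old_allele <- vapply(which(hit), function(s) {
          # reconstruct transmitted variant indicator from hap draws
          g_idx <- snp_gene_index(genes, s)
          A <- hap_allele_matrix(genes[[g_idx$gene]]$haplotypes)
          A[fam$hc[[g_idx$gene]][a], g_idx$snp]
        }, integer(1))
        child[hit] <- child[hit] - old_allele + new_allele
      }
    }
  }

  mr <- config$genotype_missing_rate
  mother <- apply_missingness(mother, mr)
  child <- apply_missingness(child, mr)
  if (status == "case") {
    if (stats::runif(1) < config$father_missing_prob) {
      father <- NULL
    } else {
      father <- apply_missingness(father, mr)
    }
  } else {
    father <- NULL
  }
  out <- family_record(family_id, status, mother, child, father)
  attr(out, "capped_draws") <- n_capped
  attr(out, "total_draws") <- n_draws
  out
}

# map a genome-wide SNP index to (gene index, within-gene SNP index)
snp_gene_index <- function(genes, s) {
  sizes <- vapply(genes, `[[`, integer(1), "n_snps")
  ends <- cumsum(sizes)
  g <- which(s <= ends)[1]
  list(gene = g, snp = s - c(0L, ends)[g])
}

#' Marker panel implied by a simulation configuration
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `snp_id`, `chromosome`, `position`,
#'   `allele1`, `allele2`, `gene` (one row per SNP, in map order).
#' @export
sim_panel <- function(config) {
  rows <- lapply(config$genes, function(gs) {
    data.frame(snp_id = paste0(gs$name, "_s", seq_len(gs$n_snps)),
               chromosome = gs$chromosome,
               position = NA_integer_,
               allele1 = "1", allele2 = "2",
               gene = gs$name,
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  # positions: 10 kb spacing within chromosome, genes laid end to end
  panel$position <- stats::ave(seq_len(nrow(panel)), panel$chromosome,
                               FUN = seq_along) * 10000L
  rownames(panel) <- NULL
  marker_panel(panel)
}

#' Validate a marker panel
#'
#' @param panel Data frame with columns `snp_id`, `chromosome`, `position`,
#'   `allele1`, `allele2`, `gene`.
#' @return The panel, invisibly checked: unique SNP ids, one gene per SNP,
#'   non-decreasing positions within chromosome.
#' @export
marker_panel <- function(panel) {
  need <- c("snp_id", "chromosome", "position", "allele1", "allele2", "gene")
  if (!all(need %in% names(panel)))
    stop("panel must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(panel$snp_id))
    stop("duplicate snp_id in panel", call. = FALSE)
  pos_ok <- tapply(panel$position, panel$chromosome,
                   function(p) !is.unsorted(p))
  if (!all(unlist(pos_ok)))
    stop("positions must be non-decreasing within chromosome", call. = FALSE)
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' Simulate a complete triad/dyad dataset
#'
#' One RNG stream per dataset: the stream for family `i` is derived
#' deterministically from `config$seed` and `i`, so the output is
#' reproducible byte-for-byte and individual families can be regenerated
#' independently.
#'
#' @param config A [sim_config()].
#' @return A list with `families` (list of [family_record()]), `panel`
#'   (marker data frame, see [sim_panel()]) and `truth` (data frame of the
#'   generating haplotype frequencies and relative risks per gene).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_fam <- config$n_case_triads + config$n_control_dyads
  statuses <- rep(c("case", "control"),
                  c(config$n_case_triads, config$n_control_dyads))
  families <- vector("list", n_fam)
  capped <- 0L
  total <- 0L
  for (i in seq_len(n_fam)) {
    set.seed(derive_seed(config$seed, i))
    fid <- sprintf("F%04d", i)
    families[[i]] <- simulate_family(config, statuses[i], fid)
    capped <- capped + attr(families[[i]], "capped_draws")
    total <- total + attr(families[[i]], "total_draws")
  }
  if (capped > 0.01 * total)
    stop(sprintf(paste0("disease probability exceeded 1 before capping for ",
                        "%.1f%% of draws: the configured relative risks are ",
                        "outside the multiplicative regime"),
                 100 * capped / total), call. = FALSE)
  truth <- do.call(rbind, lapply(config$genes, function(gs) {
    data.frame(gene = gs$name, haplotype = gs$haplotypes,
               freq = gs$haplotype_freqs,
               fetal_rr = gs$fetal_rr, maternal_rr = gs$maternal_rr,
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  list(families = families, panel = sim_panel(config), truth = truth)
}

# deterministic per-family sub-seed below 2^31
derive_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 16807) %% 2147483629
}

dosage_to_alleles <- function(d, allele1, allele2) {
  # unordered allele pair per SNP, missing = "0 0"
  a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, allele2, allele1))
  a2 <- ifelse(is.na(d), "0", ifelse(d == 2, allele2, allele1))
  paste(a1, a2)
}

#' Write a dataset as PED/MAP-style text files
#'
#' Emits `<prefix>.ped` (whitespace-delimited: family id, individual id,
#' father id, mother id, sex, phenotype, two allele columns per SNP, missing
#' allele `"0"`; phenotype 2 = affected child, 1 = unaffected child, 0 =
#' parent), `<prefix>.map` (chromosome, snp id, genetic distance placeholder
#' 0, position), `<prefix>.genes.tsv` (snp_id, gene) and, when `truth` is
#' given, `<prefix>.truth.tsv`.
#'
#' @param families List of [family_record()]; must be non-empty.
#' @param panel Marker panel data frame.
#' @param out_prefix Output path prefix.
#' @param truth Optional truth table from [simulate_dataset()].
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(families, panel, out_prefix, truth = NULL) {
  if (length(families) == 0)
    stop("no families to write", call. = FALSE)
  panel <- marker_panel(panel)
  lines <- character(0)
  for (fam in families) {
    fid <- fam$family_id
    mid <- paste0(fid, "_M"); cid <- paste0(fid, "_C")
    did <- if (is.null(fam$father)) "0" else paste0(fid, "_F")
    pheno <- if (fam$status == "case") "2" else "1"
    row_of <- function(ind_id, fa, mo, sex, ph, d)
      paste(fid, ind_id, fa, mo, sex, ph,
            paste(dosage_to_alleles(d, panel$allele1, panel$allele2),
                  collapse = " "))
    lines <- c(lines,
               row_of(mid, "0", "0", "2", "0", fam$mother),
               if (!is.null(fam$father))
                 row_of(did, "0", "0", "1", "0", fam$father),
               row_of(cid, did, mid, "0", pheno, fam$child))
  }
  ped <- paste0(out_prefix, ".ped")
  map <- paste0(out_prefix, ".map")
  genes <- paste0(out_prefix, ".genes.tsv")
  ok <- tryCatch({
    writeLines(lines, ped)
    writeLines(paste(panel$chromosome, panel$snp_id, 0, panel$position),
               map)
    utils::write.table(panel[, c("snp_id", "gene")], genes,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) {
    stop("failed writing dataset to prefix '", out_prefix, "': ",
         conditionMessage(e), call. = FALSE)
  })
  paths <- c(ped, map, genes)
  if (!is.null(truth)) {
    tr <- paste0(out_prefix, ".truth.tsv")
    utils::write.table(truth, tr, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, tr)
  }
  invisible(paths)
}

#' Read a PED/MAP-style dataset
#'
#' Inverse of [write_dataset()]: reconstructs family records (roles inferred
#' from the pedigree columns, case status from the child phenotype) and the
#' marker panel (gene labels from the annotation TSV).
#'
#' @param prefix Path prefix as used by [write_dataset()], or give the three
#'   paths explicitly.
#' @param ped,map,genes Optional explicit file paths.
#' @return A list with `families` and `panel`.
#' @export
read_dataset <- function(prefix = NULL, ped = NULL, map = NULL, genes = NULL) {
  if (!is.null(prefix)) {
    ped <- paste0(prefix, ".ped")
    map <- paste0(prefix, ".map")
    genes <- paste0(prefix, ".genes.tsv")
  }
  map_df <- utils::read.table(map, header = FALSE, sep = "",
                              col.names = c("chromosome", "snp_id",
                                            "cm", "position"),
                              colClasses = c("character", "character",
                                             "numeric", "integer"))
  gene_df <- utils::read.table(genes, header = TRUE, sep = "\t",
                               colClasses = "character")
  raw <- utils::read.table(ped, header = FALSE, sep = "",
                           colClasses = "character")
  n_snps <- nrow(map_df)
  if (ncol(raw) != 6 + 2 * n_snps)
    stop("PED column count does not match MAP: expected ", 6 + 2 * n_snps,
         ", found ", ncol(raw), call. = FALSE)
  allele_cols <- as.matrix(raw[, -(1:6), drop = FALSE])
  a1 <- allele_cols[, seq(1, 2 * n_snps, 2), drop = FALSE]
  a2 <- allele_cols[, seq(2, 2 * n_snps, 2), drop = FALSE]
  # determine allele coding per SNP from observed non-missing alleles
  dos <- matrix(NA_integer_, nrow(raw), n_snps)
  allele1 <- allele2 <- character(n_snps)
  for (s in seq_len(n_snps)) {
    obs <- c(a1[, s], a2[, s])
    lv <- sort(unique(obs[obs != "0"]))
    if (length(lv) > 2)
      stop("more than two alleles at SNP ", map_df$snp_id[s], call. = FALSE)
    if (length(lv) == 0) lv <- c("1", "2")
    if (length(lv) == 1) lv <- unique(c(lv, setdiff(c("1", "2"), lv)))[1:2]
    allele1[s] <- lv[1]; allele2[s] <- lv[2]
    miss <- a1[, s] == "0" | a2[, s] == "0"
    dos[, s] <- (a1[, s] == lv[2]) + (a2[, s] == lv[2])
    dos[miss, s] <- NA_integer_
  }
  panel <- marker_panel(data.frame(
    snp_id = map_df$snp_id, chromosome = map_df$chromosome,
    position = map_df$position, allele1 = allele1, allele2 = allele2,
    gene = gene_df$gene[match(map_df$snp_id, gene_df$snp_id)],
    stringsAsFactors = FALSE))
  fam_ids <- unique(raw[[1]])
  families <- lapply(fam_ids, function(fid) {
    rows <- which(raw[[1]] == fid)
    child_row <- rows[raw[[3]][rows] != "0" | raw[[4]][rows] != "0"]
    if (length(child_row) != 1)
      stop("family ", fid, " must contain exactly one child", call. = FALSE)
    mother_id <- raw[[4]][child_row]
    father_id <- raw[[3]][child_row]
    mother_row <- rows[raw[[2]][rows] == mother_id]
    father_row <- if (father_id != "0") rows[raw[[2]][rows] == father_id]
                  else integer(0)
    family_record(
      fid,
      status = if (raw[[6]][child_row] == "2") "case" else "control",
      mother = dos[mother_row, ],
      child = dos[child_row, ],
      father = if (length(father_row)) dos[father_row, ] else NULL)
  })
  list(families = families, panel = panel)
}

#' Example candidate-gene panel for the generator
#'
#' Builds a list of [gene_spec()]s with block-haplotype structure: each gene
#' carries 3-6 haplotypes over its SNPs with frequencies drawn from a
#' Dirichlet-like stick-breaking scheme (deterministic given `seed`).  All
#' relative risks are 1 unless overridden afterwards.
#'
#' @param n_genes Number of genes.
#' @param snps_per_gene Integer vector (recycled) of SNP counts per gene.
#' @param n_x_genes How many genes are placed on the X chromosome.
#' @param seed RNG seed for the haplotype structures.
#' @return List of `gene_spec` objects.
#' @export
example_gene_panel <- function(n_genes = 10, snps_per_gene = 8,
                               n_x_genes = 0, seed = 100) {
  set.seed(seed)
  snps_per_gene <- rep_len(snps_per_gene, n_genes)
  chroms <- c(rep("X", n_x_genes),
              as.character(rep_len(1:22, n_genes - n_x_genes)))
  lapply(seq_len(n_genes), function(g) {
    L <- snps_per_gene[g]
    n_hap <- sample(3:min(6, 2^L), 1)
    haps <- character(0)
    while (length(haps) < n_hap) {
      h <- paste(sample(c("1", "2"), L, replace = TRUE,
                        prob = c(0.7, 0.3)), collapse = "")
      haps <- unique(c(haps, h))
    }
    w <- sort(stats::rgamma(n_hap, 1.5), decreasing = TRUE)
    freqs <- w / sum(w)
    # nudge near-monomorphic SNPs: flip the second-commonest haplotype's
    # allele where the implied MAF would be < 5%
    hm <- hap_allele_matrix(haps)
    for (s in seq_len(L)) {
      f <- sum(freqs[hm[, s] == 1])
      if (f < 0.05 && hm[2, s] == 0) hm[2, s] <- 1L
      if (f > 0.95 && hm[2, s] == 1) hm[2, s] <- 0L
    }
    haps <- apply(hm, 1, function(r)
      paste(ifelse(r == 1, "2", "1"), collapse = ""))
    if (anyDuplicated(haps)) {  # rare collision after nudging: keep as-is
      haps <- unique(haps)
      freqs <- freqs[seq_along(haps)]
      freqs <- freqs / sum(freqs)
    }
    gene_spec(paste0("G", g), chroms[g], haps, freqs)
  })
}
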