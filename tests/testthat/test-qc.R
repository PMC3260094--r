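# Marker- and family-level QC filters.

test_that("snp_call_rate counts non-missing calls", {
  expect_equal(snp_call_rate(c(rep(1L, 9), NA)), 0.9)
  expect_equal(snp_call_rate(rep(NA_integer_, 5)), 0)
  expect_equal(snp_call_rate(c(0L, 1L, 2L)), 1)
  expect_error(snp_call_rate(integer(0)), "no calls")
})

test_that("exact HWE test matches the conditional-enumeration oracle", {
  cases <- list(c(25, 50, 25), c(50, 0, 50), c(9, 42, 49), c(0, 6, 94),
                c(3, 14, 83), c(20, 20, 60), c(1, 1, 98))
  for (cc in cases) {
    expect_equal(hwe_exact_test(cc[1], cc[2], cc[3]),
                 oracle_hwe_p(cc[1], cc[2], cc[3]), tolerance = 1e-10,
                 info = paste(cc, collapse = ","))
  }
  # balanced counts sit at the modal heterozygote count
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-12)
  expect_equal(hwe_exact_test(10, 0, 0), 1)  # monomorphic convention
  expect_error(hwe_exact_test(0, 0, 0), "positive total")
})

test_that("minor allele frequency is computed over non-missing founders", {
  # 95 ref-homozygous, 5 heterozygous founders: MAF 5/200
  expect_equal(minor_allele_freq(rep(c(0L, 1L), c(95, 5))), 0.025)
  expect_equal(minor_allele_freq(rep(c(0L, 2L), c(50, 50))), 0.5)
  expect_equal(minor_allele_freq(rep(0L, 100)), 0)
  expect_equal(minor_allele_freq(c(NA, 2L, 2L)), 0)
  expect_error(minor_allele_freq(c(NA_integer_, NA_integer_)), "missing")
})

test_that("mendelian_error_rate flags impossible genotype sets", {
  # one clash (mother 0, father 0, child 1) among 100 SNPs
  fam <- family_record("t", "case",
                       mother = rep(0L, 100), father = rep(0L, 100),
                       child = c(1L, rep(0L, 99)))
  expect_equal(mendelian_error_rate(fam), 0.01)
  dyad <- family_record("d", "control", mother = c(0L, 1L),
                        child = c(2L, 2L))
  expect_equal(mendelian_error_rate(dyad), 0.5)
  # het x het parents: any child genotype is consistent
  fam2 <- family_record("t2", "case", mother = rep(1L, 3),
                        father = rep(1L, 3), child = c(0L, 1L, 2L))
  expect_equal(mendelian_error_rate(fam2), 0)
  fam3 <- family_record("t3", "case", mother = NA_integer_,
                        father = 0L, child = 0L)
  expect_error(mendelian_error_rate(fam3), "jointly called")
})

test_that("apply_qc leaves a clean dataset untouched", {
  g <- gene_spec("g", "3", c("11", "12", "22"), c(0.5, 0.3, 0.2))
  cfg <- sim_config(list(g), n_case_triads = 60, n_control_dyads = 60,
                    genotype_missing_rate = 0, mendelian_error_rate = 0,
                    father_missing_prob = 0, seed = 2)
  dd <- simulate_dataset(cfg)
  res <- apply_qc(dd$families, dd$panel)
  expect_equal(res$report$n_retained_snps, 2)
  expect_equal(res$report$n_excluded_callrate +
                 res$report$n_excluded_x + res$report$n_excluded_hwe +
                 res$report$n_excluded_maf, 0)
  expect_equal(length(res$report$excluded_families), 0)
  expect_identical(res$panel$snp_id, dd$panel$snp_id)
})

test_that("apply_qc is idempotent and its accounting is consistent", {
  g1 <- gene_spec("a", "2", c("111", "122", "212"), c(0.55, 0.3, 0.15))
  g2 <- gene_spec("b", "X", c("11", "22"), c(0.7, 0.3))
  g3 <- gene_spec("c", "5", c("1", "2"), c(0.99, 0.01))  # low MAF
  cfg <- sim_config(list(g1, g2, g3), n_case_triads = 80,
                    n_control_dyads = 80, genotype_missing_rate = 0.01,
                    mendelian_error_rate = 0.002, seed = 3)
  dd <- simulate_dataset(cfg)
  r1 <- apply_qc(dd$families, dd$panel)
  rep1 <- r1$report
  expect_equal(rep1$n_retained_snps,
               rep1$n_input_snps - rep1$n_excluded_callrate -
                 rep1$n_excluded_x - rep1$n_excluded_hwe -
                 rep1$n_excluded_maf)
  expect_equal(rep1$n_excluded_x, 2)
  expect_gte(rep1$n_excluded_maf, 1)
  r2 <- apply_qc(r1$families, r1$panel)
  expect_equal(r2$report$n_excluded_callrate +
                 r2$report$n_excluded_x + r2$report$n_excluded_hwe +
                 r2$report$n_excluded_maf, 0)
  expect_equal(length(r2$families), length(r1$families))
  expect_identical(r2$panel$snp_id, r1$panel$snp_id)
  # second pass keeps genotypes identical (residual clashes already zeroed)
  for (i in seq_along(r1$families))
    expect_identical(r2$families[[i]], r1$families[[i]])
})

test_that("injected Mendelian-error rates are recovered within binomial
           error and error-heavy families are excluded", {
  genes <- lapply(1:30, function(i)
    gene_spec(paste0("g", i), as.character(1 + (i - 1) %% 22),
              c("1", "2"), c(0.6, 0.4)))
  cfg <- sim_config(genes, n_case_triads = 150, n_control_dyads = 1,
                    father_missing_prob = 0, genotype_missing_rate = 0,
                    mendelian_error_rate = 0.08, baseline_risk = 0.9,
                    seed = 12)
  dd <- simulate_dataset(cfg)
  triads <- Filter(function(f) f$status == "case", dd$families)
  rates <- vapply(triads, mendelian_error_rate, numeric(1))
  # detection probability from the enumeration used in the generator tests
  hw <- c(0.36, 0.48, 0.16)
  # substitution w.p. e by a uniform allele: allele flips w.p. e/2
  final_allele <- function(a, e) {
    pr <- c(e / 2, e / 2); pr[a + 1] <- 1 - e / 2; pr
  }
  p_det <- 0
  for (m in 0:2) for (f in 0:2) {
    Tm <- switch(m + 1, 0, 0:1, 1); Tf <- switch(f + 1, 0, 0:1, 1)
    for (am in Tm) for (af in Tf) {
      p_cfg <- hw[m + 1] * hw[f + 1] / (length(Tm) * length(Tf))
      for (a1 in 0:1) for (a2 in 0:1) {
        child <- a1 + a2
        lo <- (m == 2) + (f == 2); hi <- (m >= 1) + (f >= 1)
        if (child < lo || child > hi)
          p_det <- p_det + p_cfg * final_allele(am, 0.08)[a1 + 1] *
            final_allele(af, 0.08)[a2 + 1]
      }
    }
  }
  se <- sqrt(p_det * (1 - p_det) / (30 * length(triads)))
  expect_lt(abs(mean(rates) - p_det), 4 * se + 1e-3)
})

test_that("family filters: Mendelian-heavy families out, low call-rate
           mothers/children out, low call-rate fathers dropped", {
  genes <- lapply(1:20, function(i)
    gene_spec(paste0("g", i), as.character(1 + (i - 1) %% 22),
              c("1", "2"), c(0.6, 0.4)))
  cfg <- sim_config(genes, n_case_triads = 30, n_control_dyads = 20,
                    father_missing_prob = 0, genotype_missing_rate = 0,
                    mendelian_error_rate = 0, seed = 8)
  dd <- simulate_dataset(cfg)
  fams <- dd$families
  # corrupt family 1: make the child clash with the parents at 3 SNPs
  fams[[1]]$mother[1:3] <- 0L; fams[[1]]$father[1:3] <- 0L
  fams[[1]]$child[1:3] <- 2L
  # family 2: mother mostly missing
  fams[[2]]$mother[1:10] <- NA_integer_
  # family 3: father mostly missing (but family stays)
  fams[[3]]$father[1:10] <- NA_integer_
  res <- apply_qc(fams, dd$panel)
  excl <- vapply(res$report$excluded_families, `[[`, character(1),
                 "family_id")
  reasons <- vapply(res$report$excluded_families, `[[`, character(1),
                    "reason")
  expect_setequal(excl, c(fams[[1]]$family_id, fams[[2]]$family_id))
  expect_equal(reasons[match(fams[[1]]$family_id, excl)], "mendelian")
  expect_equal(res$report$fathers_dropped, fams[[3]]$family_id)
  kept3 <- Filter(function(f) f$family_id == fams[[3]]$family_id,
                  res$families)
  expect_null(kept3[[1]]$father)
  # tabular report mirrors the exclusions
  tab <- qc_report_table(res$report)
  expect_true(all(c(fams[[1]]$family_id, fams[[2]]$family_id) %in%
                    tab$id[tab$entity_type == "family"]))
})

test_that("residual single-SNP Mendelian clashes are zeroed in retained
           families", {
  genes <- lapply(1:40, function(i)
    gene_spec(paste0("g", i), as.character(1 + (i - 1) %% 22),
              c("1", "2"), c(0.6, 0.4)))
  cfg <- sim_config(genes, n_case_triads = 20, n_control_dyads = 10,
                    father_missing_prob = 0, genotype_missing_rate = 0,
                    mendelian_error_rate = 0, seed = 14)
  dd <- simulate_dataset(cfg)
  fams <- dd$families
  fams[[5]]$mother[7] <- 0L; fams[[5]]$father[7] <- 0L
  fams[[5]]$child[7] <- 2L  # one clash: below the 1% family threshold? 1/40
  res <- suppressWarnings(apply_qc(fams, dd$panel,
                                   thresholds = list(family_mendel = 0.05)))
  fam5 <- Filter(function(f) f$family_id == fams[[5]]$family_id,
                 res$families)[[1]]
  s7 <- match(dd$panel$snp_id[7], res$panel$snp_id)
  expect_true(is.na(fam5$mother[s7]) && is.na(fam5$child[s7]) &&
                is.na(fam5$father[s7]))
  expect_equal(mendelian_error_rate(fam5), 0)
})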