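# The likelihood core: configuration enumeration, family likelihood
# against brute-force oracles, estimation and tests.

test_that("configuration enumeration handles the canonical cases", {
  # all members homozygous reference at one SNP: a single configuration
  fam <- family_record("a", "case", mother = 0L, child = 0L, father = 0L)
  cfg <- enumerate_configurations(fam, 1L)
  expect_equal(nrow(cfg), 1)
  expect_equal(unlist(cfg[1, c("m1", "m2", "f1", "f2", "tm", "tf")]),
               c(m1 = 1, m2 = 1, f1 = 1, f2 = 1, tm = 1, tf = 1))
  expect_equal(cfg$n_equiv, 4)  # all four transmission choices coincide

  # fully heterozygous trio: 4 ordered phase-equivalent configurations
  fam <- family_record("b", "case", mother = 1L, child = 1L, father = 1L)
  cfg <- enumerate_configurations(fam, 1L)
  expect_equal(nrow(cfg), 8)  # 2 phases x 2 phases x 2 child origins
  # the child's allele origin is genuinely ambiguous: both (tm, tf)
  # assignments appear
  expect_setequal(unique(paste(cfg$tm, cfg$tf)), c("1 2", "2 1"))

  # dyad with homozygous calls: paternal transmitted haplotype pinned to
  # the child's non-maternal haplotype
  fam <- family_record("c", "control", mother = c(0L, 0L, 0L),
                       child = c(1L, 1L, 1L))
  cfg <- enumerate_configurations(fam, 1:3)
  haps <- attr(cfg, "haplotypes")
  expect_true(all(haps[cfg$tm] == "111"))
  expect_true(all(haps[cfg$tf] == "222"))

  # Mendelian clash: no configuration
  fam <- family_record("d", "case", mother = 0L, child = 2L, father = 0L)
  expect_null(enumerate_configurations(fam, 1L))
})

test_that("family log-likelihood agrees with the brute-force enumeration
           oracle across designs, phase ambiguity and missingness", {
  set.seed(501)
  for (L in 1:3) {
    K <- 2^L
    for (rep in 1:12) {
      freqs <- as.numeric(rmultinom(1, 40, rep(1, K)) + 1)
      freqs <- freqs / sum(freqs)
      fetal <- exp(runif(K, -0.7, 0.7)); fetal[1] <- 1
      maternal <- exp(runif(K, -0.7, 0.7)); maternal[1] <- 1
      status <- sample(c("case", "control"), 1)
      dyad <- status == "control" || runif(1) < 0.3
      geno <- function() {
        d <- sample(0:2, L, replace = TRUE)
        d[runif(L) < 0.25] <- NA_integer_
        as.integer(d)
      }
      fam <- family_record("x", status, mother = geno(), child = geno(),
                           father = if (dyad) NULL else geno())
      got <- tryCatch(family_loglik(fam, seq_len(L), freqs, fetal, maternal),
                      error = function(e) e)
      if (inherits(got, "error")) {
        expect_null(enumerate_configurations(fam, seq_len(L)))
        next
      }
      want <- oracle_family_loglik(fam, seq_len(L), freqs, fetal, maternal)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("with all relative risks 1 the case likelihood reduces to the
           population probability, and common rescaling is absorbed by the
           ascertainment normalisation", {
  fam <- family_record("t", "case", mother = c(1L, 0L), child = c(1L, 1L),
                       father = c(1L, 2L))
  freqs <- c(0.4, 0.3, 0.2, 0.1)
  ll_null <- family_loglik(fam, 1:2, freqs)
  # population probability via the oracle with no risk terms
  fam_pop <- family_record("t", "control", mother = c(1L, 0L),
                          child = c(1L, 1L), father = c(1L, 2L))
  expect_equal(ll_null, oracle_family_loglik(fam_pop, 1:2, freqs),
               tolerance = 1e-12)
  fetal <- c(1, 2, 0.5, 3); maternal <- c(1, 1.2, 1, 0.8)
  ll1 <- family_loglik(fam, 1:2, freqs, fetal, maternal)
  ll2 <- family_loglik(fam, 1:2, freqs, fetal * 7, maternal * 0.1)
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("the analytic gradient matches finite differences", {
  g <- gene_spec("g", "1", c("11", "12", "21"), c(0.5, 0.3, 0.2),
                 fetal_rr = c(1, 1.5, 1), maternal_rr = c(1, 1, 1.3))
  dd <- simulate_dataset(sim_config(list(g), n_case_triads = 40,
                                    n_control_dyads = 40,
                                    genotype_missing_rate = 0.05,
                                    seed = 17))
  wd <- triadscan:::build_window_data(dd$families, 1:2, "hybrid")
  K <- wd$K
  cls <- seq_len(K)
  n_beta <- K - 1L; n_gamma <- K - 1L
  set.seed(99)
  par <- runif(K - 1 + n_beta + n_gamma, -0.4, 0.4)
  ll <- triadscan:::window_loglik(par, wd, cls, n_beta, n_gamma,
                                  grad = TRUE)
  g_ana <- attr(ll, "gradient")
  g_num <- vapply(seq_along(par), function(j) {
    h <- 1e-6
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    (triadscan:::window_loglik(pp, wd, cls, n_beta, n_gamma) -
       triadscan:::window_loglik(pm, wd, cls, n_beta, n_gamma)) / (2 * h)
  }, numeric(1))
  expect_equal(g_ana, g_num, tolerance = 1e-5)
})

test_that("maximised log-likelihood matches a dense grid search on small
           complete-triad data (single-locus, fetal model)", {
  fams <- make_complete_triads(20, c(0.6, 0.4), L = 1,
                               fetal = c(1, 1.8), seed = 7)
  fit <- fit_window(fams, 1L, effects = "fetal", design = "triad")
  tables <- lapply(fams, oracle_config_table, snp_idx = 1L)
  grid_best <- -Inf
  qs <- seq(0.05, 0.95, length.out = 61)
  rrs <- exp(seq(-1.5, 1.5, length.out = 61))
  for (pass in 1:3) {
    vals <- outer(seq_along(qs), seq_along(rrs), Vectorize(function(i, j)
      oracle_total_loglik(tables, c(1 - qs[i], qs[i]), c(1, rrs[j]),
                          c(1, 1))))
    top <- arrayInd(which.max(vals), dim(vals))
    grid_best <- max(grid_best, vals[top])
    # zoom
    qr <- qs[pmax(1, top[1] - 1)]; qh <- qs[pmin(length(qs), top[1] + 1)]
    rl <- rrs[pmax(1, top[2] - 1)]; rh <- rrs[pmin(length(rrs), top[2] + 1)]
    qs <- seq(qr, qh, length.out = 41)
    rrs <- exp(seq(log(rl), log(rh), length.out = 41))
  }
  expect_equal(fit$loglik, grid_best, tolerance = 1e-4)
  expect_gte(fit$loglik, grid_best - 1e-4)
})

test_that("likelihood-ratio p-values follow the chi-squared reference", {
  mk <- function(ll, df) structure(list(loglik = ll, df = df),
                                   class = "haplotype_fit")
  expect_equal(lrt_pvalue(mk(-100, 1), mk(-100, 0)), 1)
  expect_equal(lrt_pvalue(mk(-100 + 3.84 / 2, 1), mk(-100, 0)),
               pchisq(3.84, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(lrt_pvalue(mk(-101, 2), mk(-100, 0)), "below the null")
  expect_error(lrt_pvalue(mk(-99, 1), mk(-100, 1)), "nested")
})

test_that("Wald second-genome test: null estimate gives p = 1, and the
           block test uses the right degrees of freedom", {
  fit <- structure(list(effects_requested = "both", converged = TRUE,
                        K = 2L, n_beta = 1L, n_gamma = 1L,
                        par = c(0.2, 0, 0.5),
                        vcov = diag(c(0.01, 0.04, 0.04))),
                   class = "haplotype_fit")
  expect_equal(wald_second_genome(fit, "fetal"), 1)
  expect_equal(wald_second_genome(fit, "maternal"),
               pchisq(0.5^2 / 0.04, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("swapping allele labels at a SNP maps fits to fits: identical
           log-likelihood and p-values, relabelled haplotypes", {
  g <- gene_spec("g", "9", c("11", "12", "21"), c(0.5, 0.3, 0.2),
                 fetal_rr = c(1, 1.7, 1))
  dd <- simulate_dataset(sim_config(list(g), n_case_triads = 120,
                                    n_control_dyads = 120, seed = 23,
                                    genotype_missing_rate = 0.01))
  fit1 <- fit_window(dd$families, 1:2, effects = "both", design = "hybrid")
  flipped <- lapply(dd$families, function(f) {
    f$mother[2] <- 2L - f$mother[2]
    f$child[2] <- 2L - f$child[2]
    if (!is.null(f$father)) f$father[2] <- 2L - f$father[2]
    f
  })
  fit2 <- fit_window(flipped, 1:2, effects = "both", design = "hybrid")
  # agreement is bounded by the optimizer's stopping tolerance, not exact
  # arithmetic: zero-frequency haplotypes make the surface flat at the top
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-4)
  expect_equal(fit2$loglik_null, fit1$loglik_null, tolerance = 1e-4)
  expect_equal(fit2$p_overall, fit1$p_overall, tolerance = 0.05)
  relabel <- function(h) paste0(substr(h, 1, 1),
                                ifelse(substr(h, 2, 2) == "1", "2", "1"))
  expect_equal(fit2$freqs[order(relabel(fit2$haplotypes))],
               fit1$freqs[order(fit1$haplotypes)], tolerance = 1e-3)
})

test_that("masking fathers loses information: Wald intervals widen on
           average and the likelihood still matches the oracle", {
  g <- gene_spec("g", "4", c("1", "2"), c(0.65, 0.35),
                 fetal_rr = c(1, 1.6))
  dd <- simulate_dataset(sim_config(list(g), n_case_triads = 250,
                                    n_control_dyads = 1,
                                    father_missing_prob = 0,
                                    genotype_missing_rate = 0,
                                    mendelian_error_rate = 0, seed = 31))
  triads <- Filter(function(f) f$status == "case", dd$families)
  dyads <- lapply(triads, function(f) {
    f["father"] <- list(NULL)
    f
  })
  fit_full <- fit_window(triads, 1L, effects = "fetal", design = "triad")
  fit_masked <- fit_window(dyads, 1L, effects = "fetal", design = "triad")
  w_full <- log(fit_full$effects$ci_hi) - log(fit_full$effects$ci_lo)
  w_masked <- log(fit_masked$effects$ci_hi) - log(fit_masked$effects$ci_lo)
  expect_gte(w_masked, w_full)
})

test_that("families that are Mendelian-incompatible at a window are
           dropped with a warning, not fatal", {
  fams <- make_complete_triads(30, c(0.6, 0.4), L = 1, seed = 3)
  fams[[1]]$mother <- 0L; fams[[1]]$father <- 0L; fams[[1]]$child <- 2L
  expect_warning(fit <- fit_window(fams, 1L, effects = "fetal",
                                   design = "triad"),
                 "Mendelian clash")
  expect_equal(fit$n_families_used, 29)
  expect_equal(fit$n_dropped, 1)
})

test_that("monomorphic windows return a degenerate but valid fit", {
  fams <- lapply(1:10, function(i)
    family_record(paste0("f", i), "case", mother = 0L, child = 0L,
                  father = 0L))
  fit <- fit_window(fams, 1L, effects = "both", design = "triad")
  expect_equal(fit$p_overall, 1)
  expect_equal(fit$df, 0)
  expect_true(fit$converged)
})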