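# Independent oracles used across the test suite.  These deliberately
# re-derive quantities by brute force (explicit nested loops, closed-form
# enumeration) and share no code with the package's likelihood machinery.

# lexicographic haplotype strings and allele indicators for L biallelic SNPs
oracle_haps <- function(L) {
  haps <- sort(apply(expand.grid(rep(list(c("1", "2")), L)), 1, paste,
                     collapse = ""))
  A <- do.call(rbind, lapply(strsplit(haps, ""),
                             function(a) as.integer(a == "2")))
  list(haps = haps, A = matrix(A, ncol = L))
}

# Brute-force log-likelihood of one family at a window: loops over every
# ordered haplotype assignment and transmission choice, checks genotype
# compatibility per SNP, and accumulates probability mass directly.
oracle_family_loglik <- function(fam, snp_idx, freqs, fetal = NULL,
                                 maternal = NULL) {
  L <- length(snp_idx)
  oh <- oracle_haps(L)
  A <- oh$A
  K <- nrow(A)
  if (is.null(fetal)) fetal <- rep(1, K)
  if (is.null(maternal)) maternal <- rep(1, K)
  md <- fam$mother[snp_idx]; cd <- fam$child[snp_idx]
  fd <- if (is.null(fam$father)) NULL else fam$father[snp_idx]
  geno_ok <- function(h1, h2, d) {
    for (s in seq_len(L)) {
      if (!is.na(d[s]) && A[h1, s] + A[h2, s] != d[s]) return(FALSE)
    }
    TRUE
  }
  num <- 0; den <- 0
  if (!is.null(fd)) {
    for (m1 in 1:K) for (m2 in 1:K) for (f1 in 1:K) for (f2 in 1:K)
      for (tmc in 1:2) for (tfc in 1:2) {
        tm <- c(m1, m2)[tmc]; tf <- c(f1, f2)[tfc]
        w <- freqs[m1] * freqs[m2] * freqs[f1] * freqs[f2] / 4
        if (fam$status == "case")
          w <- w * fetal[tm] * fetal[tf] * maternal[m1] * maternal[m2]
        den <- den + w
        if (geno_ok(m1, m2, md) && geno_ok(f1, f2, fd) &&
            geno_ok(tm, tf, cd))
          num <- num + w
      }
  } else {
    for (m1 in 1:K) for (m2 in 1:K) for (tmc in 1:2) for (tf in 1:K) {
      tm <- c(m1, m2)[tmc]
      w <- freqs[m1] * freqs[m2] * freqs[tf] / 2
      if (fam$status == "case")
        w <- w * fetal[tm] * fetal[tf] * maternal[m1] * maternal[m2]
      den <- den + w
      if (geno_ok(m1, m2, md) && geno_ok(tm, tf, cd))
        num <- num + w
    }
  }
  if (fam$status == "case") log(num) - log(den) else log(num)
}

# Exponent table of one family's compatible configurations (brute loops):
# each row gives, per haplotype, the frequency / fetal / maternal exponents
# and a base weight.  Used to evaluate likelihood surfaces over grids.
oracle_config_table <- function(fam, snp_idx) {
  L <- length(snp_idx)
  oh <- oracle_haps(L)
  A <- oh$A; K <- nrow(A)
  md <- fam$mother[snp_idx]; cd <- fam$child[snp_idx]
  fd <- if (is.null(fam$father)) NULL else fam$father[snp_idx]
  geno_ok <- function(h1, h2, d) {
    for (s in seq_len(L)) {
      if (!is.na(d[s]) && A[h1, s] + A[h2, s] != d[s]) return(FALSE)
    }
    TRUE
  }
  rows <- list()
  add <- function(freq_idx, fet_idx, mat_idx, base) {
    rows[[length(rows) + 1]] <<- c(tabulate(freq_idx, K),
                                   tabulate(fet_idx, K),
                                   tabulate(mat_idx, K), base)
  }
  if (!is.null(fd)) {
    for (m1 in 1:K) for (m2 in 1:K) for (f1 in 1:K) for (f2 in 1:K)
      for (tmc in 1:2) for (tfc in 1:2) {
        tm <- c(m1, m2)[tmc]; tf <- c(f1, f2)[tfc]
        if (geno_ok(m1, m2, md) && geno_ok(f1, f2, fd) &&
            geno_ok(tm, tf, cd))
          add(c(m1, m2, f1, f2), c(tm, tf), c(m1, m2), 1 / 4)
      }
  } else {
    for (m1 in 1:K) for (m2 in 1:K) for (tmc in 1:2) for (tf in 1:K) {
      tm <- c(m1, m2)[tmc]
      if (geno_ok(m1, m2, md) && geno_ok(tm, tf, cd))
        add(c(m1, m2, tf), c(tm, tf), c(m1, m2), 1 / 2)
    }
  }
  mat <- do.call(rbind, rows)
  list(K = K, nfreq = mat[, 1:K, drop = FALSE],
       nfet = mat[, K + 1:K, drop = FALSE],
       nmat = mat[, 2 * K + 1:K, drop = FALSE],
       base = mat[, 3 * K + 1],
       is_case = fam$status == "case",
       father = !is.null(fd))
}

# total log-likelihood of a family set at given parameters, from the
# brute-force configuration tables (risk terms applied to cases only)
oracle_total_loglik <- function(tables, freqs, fetal, maternal) {
  lfr <- log(freqs); lfe <- log(fetal); lma <- log(maternal)
  a <- sum(freqs * fetal); b <- sum(freqs * maternal)
  cc <- sum(freqs * fetal * maternal)
  sum(vapply(tables, function(tb) {
    lw <- tb$nfreq %*% lfr + log(tb$base)
    if (tb$is_case) {
      lw <- lw + tb$nfet %*% lfe + tb$nmat %*% lma
      log(sum(exp(lw))) - log(a * b * cc)
    } else log(sum(exp(lw)))
  }, numeric(1)))
}

# Exact child genotype distribution among cases at one biallelic SNP under
# HWE parents and multiplicative fetal/maternal dose risks: enumerates all
# 27 ordered (mother, father, child) dosage configurations.
oracle_case_child_dist <- function(q, fetal_per_copy, maternal_per_copy = 1) {
  hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  # transmission: P(child | m, f)
  trans <- function(g) switch(g + 1L, c(1, 0), c(0.5, 0.5), c(0, 1))
  joint <- array(0, c(3, 3, 3))
  for (m in 0:2) for (f in 0:2) {
    pm <- trans(m); pf <- trans(f)
    for (am in 0:1) for (af in 0:1) {
      c_dos <- am + af
      joint[m + 1, f + 1, c_dos + 1] <- joint[m + 1, f + 1, c_dos + 1] +
        hw[m + 1] * hw[f + 1] * pm[am + 1] * pf[af + 1]
    }
  }
  risk <- outer(0:2, 0:2, function(m, c_dos)
    maternal_per_copy^m * fetal_per_copy^c_dos)
  w <- array(0, c(3, 3, 3))
  for (m in 0:2) for (f in 0:2) for (cd in 0:2)
    w[m + 1, f + 1, cd + 1] <- joint[m + 1, f + 1, cd + 1] *
      risk[m + 1, cd + 1]
  child <- apply(w, 3, sum)
  child / sum(child)
}

# Exact Hardy-Weinberg test oracle: conditional on the allele count, the
# heterozygote-count distribution is the multinomial HWE law renormalised
# within the allele-count slice (independent of the allele frequency used).
oracle_hwe_p <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  n1 <- 2 * nAA + nAa
  if (n1 == 0 || n1 == 2 * n) return(1)
  hs <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  pr <- vapply(hs, function(h) {
    aa <- (n1 - h) / 2
    stats::dmultinom(c(aa, h, n - aa - h), prob = c(0.25, 0.5, 0.25))
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAa, hs)] * (1 + 1e-9)])
}

# deterministic complete-triad families drawn from explicit haplotype
# frequencies, for oracle-equivalence tests (no missingness, no errors)
make_complete_triads <- function(n, freqs, L, fetal = NULL, seed = 1) {
  set.seed(seed)
  oh <- oracle_haps(L)
  A <- oh$A; K <- nrow(A)
  if (is.null(fetal)) fetal <- rep(1, K)
  fams <- list()
  while (length(fams) < n) {
    m <- sample.int(K, 2, TRUE, freqs); f <- sample.int(K, 2, TRUE, freqs)
    tm <- m[sample.int(2, 1)]; tf <- f[sample.int(2, 1)]
    # ascertain cases by fetal multiplicative risk (baseline cancels)
    if (runif(1) > fetal[tm] * fetal[tf] / max(fetal)^2) next
    dos <- function(h1, h2) as.integer(A[h1, ] + A[h2, ])
    fams[[length(fams) + 1]] <- family_record(
      paste0("T", length(fams) + 1), "case",
      mother = dos(m[1], m[2]), child = dos(tm, tf),
      father = dos(f[1], f[2]))
  }
  fams
}

# quick null-simulation of families for calibration-style tests
sim_null_families <- function(n_triads, n_dyads, q, seed) {
  g <- gene_spec("N", "1", c("1", "2"), c(1 - q, q))
  cfg <- sim_config(list(g), n_case_triads = n_triads,
                    n_control_dyads = max(n_dyads, 1L),
                    father_missing_prob = 0, genotype_missing_rate = 0,
                    mendelian_error_rate = 0, seed = seed)
  fams <- simulate_dataset(cfg)$families
  if (n_dyads == 0)
    fams <- fams[vapply(fams, function(f) f$status == "case", logical(1))]
  fams
}

# Frequencies-only (no-effect) log-likelihood over a grid of haplotype
# frequency vectors, vectorised across the grid: P is a G x K matrix of
# simplex rows.  Under all-RR-1 the case ascertainment normalisation is 1,
# so case and control families share the formula.
oracle_null_loglik_grid <- function(tables, P) {
  logP <- log(pmax(P, 1e-300))
  ll <- numeric(nrow(P))
  for (tb in tables) {
    lw <- logP %*% t(tb$nfreq)                      # G x C
    lw <- sweep(lw, 2, log(tb$base), "+")
    ll <- ll + log(rowSums(exp(lw)))
  }
  ll
}

# dense + zoomed grid search for the frequencies-only maximum; returns the
# best log-likelihood found (within ~1e-4 of the optimum for K <= 4)
oracle_null_grid_best <- function(tables, K) {
  simplex_grid <- function(center, half_width, n_steps) {
    axes <- rep(list(seq(-half_width, half_width,
                         length.out = n_steps)), K - 1)
    D <- as.matrix(expand.grid(axes))
    first <- sweep(D, 2, center[-K], "+")
    last <- 1 - rowSums(first)
    P <- cbind(first, last)
    P[apply(P, 1, function(r) all(r > 1e-9)), , drop = FALSE]
  }
  center <- rep(1 / K, K)
  width <- 0.5
  best_ll <- -Inf; best_p <- center
  for (step in c(0.025, 0.003, 3e-4, 3e-5)) {
    n_steps <- min(31, max(11, ceiling(2 * width / step) + 1))
    P <- simplex_grid(best_p, width, n_steps)
    if (nrow(P) == 0) break
    ll <- oracle_null_loglik_grid(tables, P)
    i <- which.max(ll)
    if (ll[i] > best_ll) { best_ll <- ll[i]; best_p <- as.numeric(P[i, ]) }
    width <- max(step * 2, (2 * width / (n_steps - 1)) * 2)
  }
  best_ll
}

# two-parameter grid search (allele frequency x fetal RR) for single-locus
# fetal-effect fits on complete triads
oracle_fetal_grid_best <- function(tables) {
  qs <- seq(0.02, 0.98, length.out = 61)
  rrs <- exp(seq(-2, 2, length.out = 61))
  best <- -Inf
  for (pass in 1:4) {
    vals <- matrix(NA_real_, length(qs), length(rrs))
    for (i in seq_along(qs)) for (j in seq_along(rrs))
      vals[i, j] <- oracle_total_loglik(tables, c(1 - qs[i], qs[i]),
                                        c(1, rrs[j]), c(1, 1))
    top <- arrayInd(which.max(vals), dim(vals))
    best <- max(best, max(vals))
    ql <- qs[max(1, top[1] - 1)]; qh <- qs[min(length(qs), top[1] + 1)]
    rl <- rrs[max(1, top[2] - 1)]; rh <- rrs[min(length(rrs), top[2] + 1)]
    qs <- seq(ql, qh, length.out = 41)
    rrs <- exp(seq(log(rl), log(rh), length.out = 41))
  }
  best
}
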