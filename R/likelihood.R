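# Full-likelihood estimation of haplotype frequencies and fetal/maternal
# relative risks from case-parent triads, alone or combined with
# control-mother dyads (hybrid design).
#
# Model.  Within a marker window, parental haplotypes are assumed drawn
# independently from population frequencies p (random mating, HWE, mating
# symmetry); the child receives one haplotype from each parent with equal
# probability.  Disease risk is multiplicative per haplotype copy: a fetal
# relative risk F_h per copy carried by the child and a maternal relative
# risk M_h per copy carried by the mother, both relative to the most
# frequent (reference) haplotype.  Case families contribute
#
#   P(genotypes | case) = sum over compatible configurations of
#       p(m1) p(m2) p(f1) p(f2) * (1/4) * F(tm) F(tf) * M(m1) M(m2)
#     normalised by the same sum over all configurations,
#
# which has the closed form a * b * c with a = sum p F, b = sum p M,
# c = sum p F M (identically for a wholly missing father, where the
# untransmitted paternal haplotype is marginalised analytically).  Control
# dyads contribute the population probability of the mother-child pair
# with the paternal transmission marginalised and carry no risk terms:
# they inform the frequencies only.  Phase ambiguity and missing genotypes
# (including absent fathers) are handled by summing over all compatible
# configurations.

# ---- haplotype bookkeeping -------------------------------------------------

# all 2^L haplotypes over L biallelic SNPs, as 0/1 variant-indicator rows,
# ordered lexicographically by allele string ("111" < "112" < ...)
all_haplotypes <- function(L) {
  A <- as.matrix(expand.grid(rep(list(0:1), L))[, L:1, drop = FALSE])
  dimnames(A) <- NULL
  A[order(apply(A, 1, paste, collapse = "")), , drop = FALSE]
}

hap_labels <- function(A) {
  apply(A, 1, function(r) paste(ifelse(r == 1, "2", "1"), collapse = ""))
}

# ordered haplotype-index pairs compatible with one member's window dosages
compatible_pairs <- function(dosage, A) {
  K <- nrow(A)
  pairs <- cbind(rep(seq_len(K), each = K), rep(seq_len(K), times = K))
  ok <- rep(TRUE, nrow(pairs))
  for (s in seq_along(dosage)) {
    if (is.na(dosage[s])) next
    ok <- ok & (A[pairs[, 1], s] + A[pairs[, 2], s] == dosage[s])
  }
  pairs[ok, , drop = FALSE]
}

# haplotype pairs compatible with the child given a fixed maternal
# transmitted haplotype index tm: returns compatible paternal haplotypes
child_ok <- function(tm, tf, child_dosage, A) {
  ok <- rep(TRUE, length(tf))
  for (s in seq_along(child_dosage)) {
    if (is.na(child_dosage[s])) next
    ok <- ok & (A[tm, s] + A[tf, s] == child_dosage[s])
  }
  ok
}

#' Enumerate haplotype configurations compatible with one family
#'
#' A configuration assigns ordered haplotype pairs to the mother and (if
#' genotyped) the father, and designates the transmitted haplotypes; every
#' configuration consistent with all non-missing genotypes appears once.
#' Missing genotypes, including a wholly absent father, are marginalised by
#' inclusion of all compatible assignments; for an absent father only the
#' transmitted paternal haplotype is enumerated.
#'
#' @param family A [family_record()].
#' @param snp_idx Integer indices of the window's SNPs into the family's
#'   genotype vectors.
#' @return Data frame with columns `m1`, `m2`, `f1`, `f2` (NA when the
#'   father is absent), `tm`, `tf` (haplotype indices into
#'   `attr(, "haplotypes")`, the lexicographic 2^L haplotype set) and
#'   `n_equiv`, the number of equivalent transmission choices collapsed
#'   into the row; NULL when no configuration is compatible (a Mendelian
#'   clash).
#' @export
enumerate_configurations <- function(family, snp_idx) {
  L <- length(snp_idx)
  A <- all_haplotypes(L)
  md <- family$mother[snp_idx]
  cd <- family$child[snp_idx]
  Mp <- compatible_pairs(md, A)
  out <- NULL
  if (!is.null(family$father)) {
    fd <- family$father[snp_idx]
    Fp <- compatible_pairs(fd, A)
    if (nrow(Mp) && nrow(Fp)) {
      grid <- expand.grid(mi = seq_len(nrow(Mp)), fi = seq_len(nrow(Fp)),
                          tmc = 1:2, tfc = 1:2)
      tm <- Mp[cbind(grid$mi, grid$tmc)]
      tf <- Fp[cbind(grid$fi, grid$tfc)]
      keep <- child_ok(tm, tf, cd, A)
      if (any(keep)) {
        g <- grid[keep, , drop = FALSE]
        out <- data.frame(m1 = Mp[g$mi, 1], m2 = Mp[g$mi, 2],
                          f1 = Fp[g$fi, 1], f2 = Fp[g$fi, 2],
                          tm = tm[keep], tf = tf[keep])
      }
    }
  } else {
    K <- nrow(A)
    if (nrow(Mp)) {
      grid <- expand.grid(mi = seq_len(nrow(Mp)), tmc = 1:2,
                          tf = seq_len(K))
      tm <- Mp[cbind(grid$mi, grid$tmc)]
      keep <- child_ok(tm, grid$tf, cd, A)
      if (any(keep)) {
        g <- grid[keep, , drop = FALSE]
        out <- data.frame(m1 = Mp[g$mi, 1], m2 = Mp[g$mi, 2],
                          f1 = NA_integer_, f2 = NA_integer_,
                          tm = tm[keep], tf = g$tf)
      }
    }
  }
  if (is.null(out) || nrow(out) == 0) return(NULL)
  # collapse transmission choices that select the same haplotype assignment
  key <- do.call(paste, out)
  first <- !duplicated(key)
  n_equiv <- as.numeric(table(key)[key[first]])
  out <- out[first, , drop = FALSE]
  out$n_equiv <- n_equiv
  rownames(out) <- NULL
  attr(out, "haplotypes") <- hap_labels(A)
  out
}

# ---- window data: collapsed configuration matrices -------------------------

# Cache of per-genotype-pattern configuration count matrices.  Patterns
# recur heavily both across families and across bootstrap replicates; the
# cache is keyed by (status, father presence, window dosages) and bounded.
.pattern_cache <- new.env(parent = emptyenv())

# Count matrices for one family's genotype pattern at a window: rows =
# distinct configurations, columns = haplotypes; nf counts frequency
# factors, nfet/nmat the fetal and maternal risk exponents (zero rows for
# control dyads), lw the log base weights including phase multiplicity.
pattern_counts <- function(fam, snp_idx, cache_key) {
  hit <- .pattern_cache[[cache_key]]
  if (!is.null(hit)) return(if (is.logical(hit)) NULL else hit)
  cfg <- enumerate_configurations(fam, snp_idx)
  if (is.null(cfg)) {
    .pattern_cache[[cache_key]] <- FALSE  # incompatible pattern
    return(NULL)
  }
  K <- 2^length(snp_idx)
  C <- nrow(cfg)
  father_present <- !is.null(fam$father)
  count_mat <- function(idx_cols) {
    m <- matrix(0L, C, K)
    for (col in idx_cols) {
      v <- cfg[[col]]
      m[cbind(seq_len(C), v)] <- m[cbind(seq_len(C), v)] + 1L
    }
    m
  }
  nf <- if (father_present) count_mat(c("m1", "m2", "f1", "f2"))
        else count_mat(c("m1", "m2", "tf"))
  if (fam$status == "case") {
    nfet <- count_mat(c("tm", "tf"))
    nmat <- count_mat(c("m1", "m2"))
  } else {
    nfet <- nmat <- matrix(0L, C, K)
  }
  base <- if (father_present) -log(4) else -log(2)
  # merge phase-equivalent configurations (identical count rows), summing
  # the collapsed transmission multiplicities
  ckey <- do.call(paste, c(asplit(cbind(nf, nfet, nmat), 2), sep = ","))
  first <- !duplicated(ckey)
  mult <- as.numeric(rowsum(cfg$n_equiv, ckey, reorder = FALSE))
  out <- list(nf = nf[first, , drop = FALSE],
              nfet = nfet[first, , drop = FALSE],
              nmat = nmat[first, , drop = FALSE],
              lw = base + log(mult))
  if (length(ls(.pattern_cache)) > 20000)
    rm(list = ls(.pattern_cache), envir = .pattern_cache)
  .pattern_cache[[cache_key]] <- out
  out
}

# Build the per-window sufficient structure.  Families are collapsed by
# genotype pattern; configurations by (frequency, fetal, maternal) count
# rows.  Returned matrices are over the K_used haplotypes with any support.
build_window_data <- function(families, snp_idx, design) {
  design <- match.arg(design, c("triad", "hybrid"))
  use <- if (design == "triad")
    vapply(families, function(f) f$status == "case", logical(1))
  else rep(TRUE, length(families))
  families <- families[use]
  if (length(families) == 0) stop("no families for this design", call. = FALSE)

  L <- length(snp_idx)
  A <- all_haplotypes(L)
  K <- nrow(A)
  # numeric pattern key: base-4 digits over (mother, father, child) window
  # dosages (NA -> 3, absent father -> all 3s) plus status/father flags;
  # exact in doubles for L <= 3 windows
  pow4 <- 4^(seq_len(3 * L) - 1)
  key <- vapply(families, function(f) {
    d <- c(f$mother[snp_idx],
           if (is.null(f$father)) rep(NA_integer_, L) else f$father[snp_idx],
           f$child[snp_idx])
    d[is.na(d)] <- 3L
    sum(d * pow4) * 4 + 2 * (f$status == "case") + is.null(f$father)
  }, numeric(1))
  patt <- match(key, unique(key))
  reps <- which(!duplicated(key))

  NFREQ_l <- NFET_l <- NMAT_l <- logw0_l <- list()
  n_pat <- numeric(0)
  is_case <- logical(0)
  dropped <- character(0)
  p_id <- 0L
  for (j in seq_along(reps)) {
    fam <- families[[reps[j]]]
    pat <- pattern_counts(fam, snp_idx,
                          paste0("k", L, "_", format(key[reps[j]],
                                                     digits = 18)))
    members <- which(patt == j)
    if (is.null(pat)) {
      dropped <- c(dropped,
                   vapply(families[members], `[[`, character(1),
                          "family_id"))
      next
    }
    p_id <- p_id + 1L
    NFREQ_l[[p_id]] <- pat$nf
    NFET_l[[p_id]] <- pat$nfet
    NMAT_l[[p_id]] <- pat$nmat
    logw0_l[[p_id]] <- pat$lw
    n_pat <- c(n_pat, length(members))
    is_case <- c(is_case, fam$status == "case")
  }
  NFREQ <- do.call(rbind, NFREQ_l)
  NFET <- do.call(rbind, NFET_l)
  NMAT <- do.call(rbind, NMAT_l)
  logw0 <- unlist(logw0_l)
  pat_of <- rep(seq_len(p_id),
                vapply(NFREQ_l, nrow, integer(1))[seq_len(p_id)])
  if (p_id == 0L)
    stop("no family has a compatible configuration at this window",
         call. = FALSE)
  if (length(dropped))
    warning(length(dropped), " famil", if (length(dropped) == 1) "y" else "ies",
            " dropped at this window (Mendelian clash): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)

  used <- which(colSums(NFREQ) + colSums(NFET) + colSums(NMAT) > 0)
  list(NFREQ = NFREQ[, used, drop = FALSE],
       NFET = NFET[, used, drop = FALSE],
       NMAT = NMAT[, used, drop = FALSE],
       logw0 = logw0, pat = pat_of,
       idx_by_pat = split(seq_along(pat_of), pat_of),
       n_pat = n_pat, is_case = is_case,
       n_case = sum(n_pat[is_case]),
       n_families = sum(n_pat), n_dropped = length(dropped),
       haplotypes = hap_labels(all_haplotypes(L))[used],
       K = length(used))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# ---- log-likelihood and analytic gradient ----------------------------------

# Parameter layout: eta = freq logits (K-1, first haplotype fixed at 0),
# beta = log fetal RR per non-reference effect class, gamma = log maternal
# RR per class.  `cls` maps haplotypes to effect classes (class 1 =
# reference, RR fixed at 1).
window_loglik <- function(par, wd, cls, n_beta, n_gamma, grad = FALSE) {
  K <- wd$K
  eta <- c(0, par[seq_len(K - 1)])
  beta <- c(0, par[K - 1 + seq_len(n_beta)])
  gamma <- c(0, par[K - 1 + n_beta + seq_len(n_gamma)])
  lp <- eta - logsumexp(eta)
  p <- exp(lp)
  lF <- if (n_beta) beta[cls] else numeric(K)
  lM <- if (n_gamma) gamma[cls] else numeric(K)
  Fh <- exp(lF); Mh <- exp(lM)

  lw <- as.numeric(wd$NFREQ %*% lp + wd$NFET %*% lF + wd$NMAT %*% lM) +
    wd$logw0
  ll_pat <- log(as.numeric(rowsum(exp(lw), wd$pat)))
  if (any(!is.finite(ll_pat)))  # underflow guard: shifted summation
    ll_pat <- vapply(wd$idx_by_pat, function(ix) logsumexp(lw[ix]),
                     numeric(1))
  a <- sum(p * Fh); b <- sum(p * Mh); cc <- sum(p * Fh * Mh)
  ll <- sum(wd$n_pat * ll_pat) - wd$n_case * (log(a) + log(b) + log(cc))
  if (!is.finite(ll))
    stop("non-finite window log-likelihood", call. = FALSE)
  if (!grad) return(ll)

  w <- exp(lw - ll_pat[wd$pat]) * wd$n_pat[wd$pat]
  E_freq <- as.numeric(crossprod(wd$NFREQ, w))
  E_fet <- as.numeric(crossprod(wd$NFET, w))
  E_mat <- as.numeric(crossprod(wd$NMAT, w))

  # d/d log p_h of the case-normalisation term log(a b c)
  dnorm_lp <- wd$n_case * (p * Fh / a + p * Mh / b + p * Fh * Mh / cc)
  glp <- E_freq - dnorm_lp
  geta <- glp - p * sum(glp)

  g <- geta[-1]
  if (n_beta) {
    dnorm_b <- wd$n_case *
      (rowsum_by(p * Fh, cls) / a + rowsum_by(p * Fh * Mh, cls) / cc)
    gb <- rowsum_by(E_fet, cls) - dnorm_b
    g <- c(g, gb[-1])
  }
  if (n_gamma) {
    dnorm_g <- wd$n_case *
      (rowsum_by(p * Mh, cls) / b + rowsum_by(p * Fh * Mh, cls) / cc)
    gg <- rowsum_by(E_mat, cls) - dnorm_g
    g <- c(g, gg[-1])
  }
  attr(ll, "gradient") <- g
  ll
}

rowsum_by <- function(x, cls) {
  as.numeric(rowsum(x, cls, reorder = TRUE))
}

#' Log-likelihood of one family at a window
#'
#' Evaluates the family's contribution to the model log-likelihood under
#' given parameters (see the module header for the model): case families
#' include the ascertainment normalisation, control dyads contribute the
#' population probability of the mother-child pair only.
#'
#' @param family A [family_record()].
#' @param snp_idx Window SNP indices.
#' @param freqs Haplotype frequency simplex over the lexicographic 2^L
#'   haplotype set of the window.
#' @param fetal_rr,maternal_rr Per-haplotype relative risks (length 2^L).
#' @return Log-likelihood value.
#' @export
family_loglik <- function(family, snp_idx, freqs,
                          fetal_rr = rep(1, length(freqs)),
                          maternal_rr = rep(1, length(freqs))) {
  stopifnot(abs(sum(freqs) - 1) < 1e-8, all(freqs >= 0),
            all(fetal_rr > 0), all(maternal_rr > 0))
  cfg <- enumerate_configurations(family, snp_idx)
  if (is.null(cfg))
    stop("family ", family$family_id,
         " has no compatible configuration at this window", call. = FALSE)
  lp <- log(freqs)
  lF <- log(fetal_rr); lM <- log(maternal_rr)
  father_present <- !is.null(family$father)
  lw <- apply(cfg, 1, function(r) {
    freq_idx <- if (father_present) c(r["m1"], r["m2"], r["f1"], r["f2"])
                else c(r["m1"], r["m2"], r["tf"])
    base <- if (father_present) -log(4) else -log(2)
    val <- sum(lp[freq_idx]) + base + log(r["n_equiv"])
    if (family$status == "case")
      val <- val + lF[r["tm"]] + lF[r["tf"]] + lM[r["m1"]] + lM[r["m2"]]
    val
  })
  ll <- logsumexp(lw)
  if (family$status == "case") {
    a <- sum(freqs * fetal_rr)
    b <- sum(freqs * maternal_rr)
    cc <- sum(freqs * fetal_rr * maternal_rr)
    ll <- ll - log(a) - log(b) - log(cc)
  }
  if (!is.finite(ll))
    stop("non-finite log-likelihood for family ", family$family_id,
         call. = FALSE)
  ll
}

# ---- model fitting ---------------------------------------------------------

#' Fit the haplotype relative-risk model at one window
#'
#' Maximises the joint likelihood over haplotype frequencies
#' (softmax-parametrised) and log relative risks (reference fixed at 0) by
#' quasi-Newton (BFGS) iteration with analytic gradients, starting from the
#' null: smoothed empirical haplotype frequencies and all log-RR zero.
#' Haplotypes with estimated null frequency below `pool_threshold` are
#' pooled into one composite effect class before effect estimation (their
#' frequencies remain separate).  The reference haplotype is the most
#' frequent under the null fit, ties broken lexicographically by allele
#' string.  95% confidence intervals are Wald intervals on the log-RR scale
#' from the inverse observed information; the overall p-value is a
#' likelihood-ratio test of the fitted model against the no-effect null.
#'
#' @param families List of [family_record()].
#' @param snp_idx Integer indices of the window SNPs into the genotype
#'   vectors (see [make_windows()] for panel-driven construction).
#' @param effects `"fetal"`, `"maternal"` or `"both"`.
#' @param design `"triad"` (case families only) or `"hybrid"` (case
#'   families plus control dyads).
#' @param pool_threshold Frequency below which non-reference haplotypes
#'   share one pooled effect class.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum BFGS iterations.
#' @param compute_se Compute the observed information (standard errors,
#'   Wald intervals and per-haplotype p-values)?  Disabled by bootstrap
#'   refits that need only the likelihood-ratio statistic.
#' @param window_label Optional label stored in the fit.
#' @return A `haplotype_fit` object: estimated `freqs`, `effects` table
#'   (per effect class: fetal/maternal RR, 95% CI, Wald p), `loglik`,
#'   `loglik_null`, `p_overall`, `df`, `converged`, `n_families_used`.
#' @export
fit_window <- function(families, snp_idx, effects = "both",
                       design = "hybrid", pool_threshold = 0.01,
                       tol = 1e-8, max_iter = 200L, compute_se = TRUE,
                       window_label = NULL) {
  effects <- match.arg(effects, c("fetal", "maternal", "both"))
  design <- match.arg(design, c("triad", "hybrid"))
  if (design == "hybrid" &&
      !any(vapply(families, function(f) f$status == "control", logical(1))))
    stop("hybrid design requires at least one control dyad", call. = FALSE)
  if (!any(vapply(families, function(f) f$status == "case", logical(1))))
    stop("at least one case family is required", call. = FALSE)
  wd <- build_window_data(families, snp_idx, design)
  K <- wd$K

  if (K == 1) {  # monomorphic window: nothing to estimate
    return(new_haplotype_fit(
      haplotypes = wd$haplotypes, freqs = 1, freqs_null = 1,
      reference = wd$haplotypes,
      effects_requested = effects, design = design,
      eff_table = empty_effects_table(),
      loglik = window_loglik(numeric(0), wd, 1L, 0, 0),
      loglik_null = window_loglik(numeric(0), wd, 1L, 0, 0),
      df = 0L, p_overall = 1, converged = TRUE,
      n_families_used = wd$n_families, n_dropped = wd$n_dropped,
      window_label = window_label, vcov = NULL, par = numeric(0),
      cls = 1L, wd = wd))
  }

  ctl <- list(maxit = max_iter, reltol = tol)
  # empirical start: configuration-averaged haplotype counts, +1 smoothing
  emp <- colSums(wd$NFREQ / rowSums(wd$NFREQ) *
                   (wd$n_pat / tabulate(wd$pat))[wd$pat])
  p0 <- (emp + 1) / sum(emp + 1)
  eta0 <- log(p0) - log(p0[1])

  nll_null <- function(par) -window_loglik(par, wd, seq_len(K), 0, 0)
  gr_null <- function(par)
    -attr(window_loglik(par, wd, seq_len(K), 0, 0, grad = TRUE), "gradient")
  opt0 <- stats::optim(eta0[-1], nll_null, gr_null, method = "BFGS",
                       control = ctl)
  eta_hat <- c(0, opt0$par)
  p_null <- exp(eta_hat - logsumexp(eta_hat))
  ll_null <- -opt0$value

  # reference = most frequent under the null; lexicographic tie-break is
  # inherent in the haplotype ordering (which.max takes the first maximum)
  ref <- which.max(round(p_null, 12))
  # effect classes: reference -> 1; common haplotypes own classes in
  # lexicographic order; rare haplotypes pooled
  # haplotypes with negligible null frequency (< 0.1%, i.e. about one
  # chromosome at study scale) carry no effect
  # information: tie their RR to the reference rather than spend a
  # parameter on them
  absent <- p_null < 1e-3 & seq_len(K) != ref
  rare <- p_null >= 1e-3 & p_null < pool_threshold & seq_len(K) != ref
  cls <- integer(K)
  cls[ref] <- 1L
  cls[absent] <- 1L
  own <- which(!rare & !absent & seq_len(K) != ref)
  cls[own] <- 1L + seq_along(own)
  if (any(rare)) cls[rare] <- max(cls) + 1L
  n_cls <- max(cls)
  class_labels <- character(n_cls)
  class_labels[1] <- wd$haplotypes[ref]
  for (k in seq_len(n_cls)[-1]) {
    members <- wd$haplotypes[cls == k]
    class_labels[k] <- if (length(members) == 1) members
                       else paste0("pooled(", paste(members, collapse = "+"),
                                   ")")
  }

  n_eff_cls <- n_cls - 1L
  n_beta <- if (effects %in% c("fetal", "both")) n_eff_cls else 0L
  n_gamma <- if (effects %in% c("maternal", "both")) n_eff_cls else 0L

  if (n_beta + n_gamma == 0L || n_eff_cls == 0L) {
    return(new_haplotype_fit(
      haplotypes = wd$haplotypes, freqs = p_null, freqs_null = p_null,
      reference = wd$haplotypes[ref], effects_requested = effects,
      design = design, eff_table = empty_effects_table(),
      loglik = ll_null, loglik_null = ll_null, df = 0L, p_overall = 1,
      converged = opt0$convergence == 0,
      n_families_used = wd$n_families, n_dropped = wd$n_dropped,
      window_label = window_label, vcov = NULL, par = opt0$par,
      cls = cls, wd = wd))
  }

  # class map with reference relabelled to class 1 ordering for parameters
  nll <- function(par) -window_loglik(par, wd, cls, n_beta, n_gamma)
  gr <- function(par)
    -attr(window_loglik(par, wd, cls, n_beta, n_gamma, grad = TRUE),
          "gradient")
  par0 <- c(opt0$par, rep(0, n_beta + n_gamma))
  opt <- stats::optim(par0, nll, gr, method = "BFGS", control = ctl)
  ll_full <- -opt$value
  converged <- opt$convergence == 0
  eta_hat <- c(0, opt$par[seq_len(K - 1)])
  p_hat <- exp(eta_hat - logsumexp(eta_hat))
  beta_hat <- if (n_beta) opt$par[K - 1 + seq_len(n_beta)] else numeric(0)
  gamma_hat <- if (n_gamma) opt$par[K - 1 + n_beta + seq_len(n_gamma)]
               else numeric(0)

  boundary <- c(abs(beta_hat), abs(gamma_hat)) > 10
  if (any(boundary))
    warning("relative-risk estimate at boundary (|log RR| > 10); ",
            "one-sided confidence interval reported", call. = FALSE)

  V <- se <- NULL
  if (converged && compute_se) {
    H <- stats::optimHess(opt$par, nll, gr)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      if (any(dv <= 0)) V <- NULL else se <- sqrt(dv)
    }
    if (is.null(V))
      warning("observed information singular; standard errors suppressed",
              call. = FALSE)
  }

  mk_eff <- function(est, off, label) {
    if (!length(est)) return(NULL)
    s <- if (is.null(se)) rep(NA_real_, length(est))
         else se[off + seq_along(est)]
    at_bound <- abs(est) > 10
    lo <- exp(est - 1.96 * s); hi <- exp(est + 1.96 * s)
    lo[at_bound & est > 0] <- exp(est - 1.96 * s)[at_bound & est > 0]
    hi[at_bound & est > 0] <- Inf
    lo[at_bound & est < 0] <- 0
    p <- if (converged && !is.null(se))
      2 * stats::pnorm(-abs(est / s)) else rep(NA_real_, length(est))
    data.frame(component = label,
               haplotype = class_labels[-1],
               rr = exp(est), ci_lo = lo, ci_hi = hi, p = p,
               stringsAsFactors = FALSE)
  }
  eff_table <- rbind(
    if (n_beta) mk_eff(beta_hat, K - 1L, "fetal"),
    if (n_gamma) mk_eff(gamma_hat, K - 1L + n_beta, "maternal"))

  df <- n_beta + n_gamma
  if (ll_full < ll_null - 1e-6)
    stop("optimizer failure: full-model log-likelihood below the null",
         call. = FALSE)
  p_overall <- if (converged)
    stats::pchisq(2 * max(ll_full - ll_null, 0), df, lower.tail = FALSE)
  else NA_real_

  new_haplotype_fit(
    haplotypes = wd$haplotypes, freqs = p_hat, freqs_null = p_null,
    reference = wd$haplotypes[ref], effects_requested = effects,
    design = design, eff_table = eff_table,
    loglik = ll_full, loglik_null = ll_null, df = df,
    p_overall = p_overall, converged = converged,
    n_families_used = wd$n_families, n_dropped = wd$n_dropped,
    window_label = window_label, vcov = V, par = opt$par, cls = cls,
    wd = wd, n_beta = n_beta, n_gamma = n_gamma, K = K)
}

empty_effects_table <- function() {
  data.frame(component = character(0), haplotype = character(0),
             rr = numeric(0), ci_lo = numeric(0), ci_hi = numeric(0),
             p = numeric(0), stringsAsFactors = FALSE)
}

new_haplotype_fit <- function(...) {
  structure(list(...), class = "haplotype_fit")
}

#' @export
print.haplotype_fit <- function(x, ...) {
  cat("Haplotype relative-risk fit",
      if (!is.null(x$window_label)) paste0(" [", x$window_label, "]"), "\n",
      sep = "")
  cat(sprintf("  design %s, effects %s, %d families%s\n", x$design,
              x$effects_requested, x$n_families_used,
              if (x$n_dropped) sprintf(" (%d dropped)", x$n_dropped) else ""))
  freq_df <- data.frame(haplotype = x$haplotypes,
                        freq = round(x$freqs, 4))
  freq_df$ref <- ifelse(freq_df$haplotype == x$reference, "*", "")
  print(freq_df, row.names = FALSE)
  if (nrow(x$effects)) {
    eff <- x$effects
    eff$rr <- round(eff$rr, 3); eff$ci_lo <- round(eff$ci_lo, 3)
    eff$ci_hi <- round(eff$ci_hi, 3); eff$p <- signif(eff$p, 3)
    print(eff, row.names = FALSE)
  }
  cat(sprintf("  loglik %.4f (null %.4f), LRT df %d, overall p = %s%s\n",
              x$loglik, x$loglik_null, x$df,
              format.pval(x$p_overall, digits = 3),
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

# Access the effects table; stored under `eff_table` at construction
#' @export
`$.haplotype_fit` <- function(x, name) {
  if (name == "effects") return(.subset2(x, "eff_table"))
  .subset2(x, name)
}

#' Likelihood-ratio test between nested window fits
#'
#' @param fit_full,fit_null `haplotype_fit` objects for the same families,
#'   window and design, the null nested in the full.
#' @return P-value from the chi-squared distribution with degrees of
#'   freedom equal to the difference in free relative-risk parameters.
#' @export
lrt_pvalue <- function(fit_full, fit_null) {
  if (fit_full$loglik < fit_null$loglik - 1e-6)
    stop("full-model log-likelihood below the null: optimizer failure",
         call. = FALSE)
  df <- fit_full$df - fit_null$df
  if (df <= 0) stop("null model is not nested with fewer parameters",
                    call. = FALSE)
  stats::pchisq(2 * max(fit_full$loglik - fit_null$loglik, 0), df,
                lower.tail = FALSE)
}

#' Wald test for the contribution of a second genome
#'
#' Given a joint fit with both fetal and maternal effects, tests the joint
#' nullity of all log relative risks of one component using the
#' corresponding block of the inverse observed information.
#'
#' @param fit_joint Converged `haplotype_fit` with both effects.
#' @param component `"fetal"` or `"maternal"`.
#' @return Chi-squared p-value with df = number of effect classes of the
#'   component.
#' @export
wald_second_genome <- function(fit_joint, component = c("fetal", "maternal")) {
  component <- match.arg(component)
  if (fit_joint$effects_requested != "both" || !fit_joint$converged)
    stop("requires a converged joint fit with both effects", call. = FALSE)
  K <- fit_joint$K
  n_beta <- fit_joint$n_beta
  n_gamma <- fit_joint$n_gamma
  idx <- if (component == "fetal") K - 1L + seq_len(n_beta)
         else K - 1L + n_beta + seq_len(n_gamma)
  b <- fit_joint$par[idx]
  V <- fit_joint$vcov
  if (is.null(V)) {
    warning("information matrix unavailable; Wald p suppressed",
            call. = FALSE)
    return(NA_real_)
  }
  Vb <- V[idx, idx, drop = FALSE]
  Vi <- tryCatch(solve(Vb), error = function(e) NULL)
  if (is.null(Vi)) {
    warning("singular information block; Wald p suppressed", call. = FALSE)
    return(NA_real_)
  }
  stat <- as.numeric(t(b) %*% Vi %*% b)
  stats::pchisq(stat, length(b), lower.tail = FALSE)
}
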