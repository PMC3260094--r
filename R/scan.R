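# Single-locus and sliding-window haplotype scans across a marker panel,
# with one overall p-value per gene from a min-p parametric bootstrap.

#' Sliding windows over a marker panel
#'
#' Per gene, all contiguous runs of `width` SNPs in map order with stride
#' 1; genes with fewer than `width` SNPs yield a single window of all their
#' SNPs.  Windows never span gene boundaries.
#'
#' @param panel Marker panel data frame.
#' @param width Window width in SNPs (1 = single-locus scan, 3 = the
#'   standard haplotype scan).
#' @return List of window specs: `gene`, `snp_ids`, `snp_idx` (indices
#'   into the panel rows), `chromosome`, `start_position`.
#' @export
make_windows <- function(panel, width = 3L) {
  panel <- marker_panel(panel)
  if (nrow(panel) == 0) stop("empty panel", call. = FALSE)
  stopifnot(width >= 1)
  out <- list()
  for (g in unique(panel$gene)) {
    idx <- which(panel$gene == g)
    idx <- idx[order(panel$position[idx])]
    starts <- if (length(idx) < width) 1L
              else seq_len(length(idx) - width + 1L)
    for (s in starts) {
      w_idx <- idx[s:min(s + width - 1L, length(idx))]
      out[[length(out) + 1L]] <- list(
        gene = g,
        snp_ids = panel$snp_id[w_idx],
        snp_idx = w_idx,
        chromosome = panel$chromosome[w_idx[1]],
        start_position = panel$position[w_idx[1]])
    }
  }
  out
}

#' Run a window scan across the panel
#'
#' Applies [fit_window()] to every window; individual window failures are
#' recorded rather than fatal.  Optionally computes a gene-level overall
#' p-value per gene via [gene_pvalue()].
#'
#' @param families QC'd list of [family_record()].
#' @param panel QC'd marker panel.
#' @param width Window width in SNPs.
#' @param design,effects Passed to [fit_window()].
#' @param gene_p Logical: compute gene-level bootstrap p-values?
#' @param B Bootstrap replicates per gene (when `gene_p`).
#' @param seed Integer seed for the gene-level bootstrap.
#' @param ... Further arguments to [fit_window()].
#' @return A `scan_result`: `windows` (data frame, one row per window,
#'   ordered by chromosome and position), `fits` (list of
#'   `haplotype_fit`), `genes` (data frame `gene`, `p_gene`, `n_windows`,
#'   present when `gene_p`), plus the configuration used.
#' @export
run_scan <- function(families, panel, width = 3L, design = "hybrid",
                     effects = "both", gene_p = FALSE, B = 1000L,
                     seed = 1L, ...) {
  windows <- make_windows(panel, width)
  ord <- order(vapply(windows, `[[`, character(1), "chromosome"),
               vapply(windows, `[[`, numeric(1), "start_position"))
  windows <- windows[ord]
  fits <- vector("list", length(windows))
  rows <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    label <- paste(w$snp_ids, collapse = "-")
    fit <- tryCatch(
      suppressWarnings(fit_window(families, w$snp_idx, effects = effects,
                                  design = design, window_label = label,
                                  ...)),
      error = function(e) e)
    failed <- inherits(fit, "error")
    fits[[i]] <- if (failed) NULL else fit
    rows[[i]] <- data.frame(
      gene = w$gene, window = label, chromosome = w$chromosome,
      position = w$start_position,
      n_snps = length(w$snp_idx),
      p_overall = if (failed) NA_real_ else fit$p_overall,
      loglik = if (failed) NA_real_ else fit$loglik,
      converged = if (failed) FALSE else fit$converged,
      error = if (failed) conditionMessage(fit) else "",
      stringsAsFactors = FALSE)
  }
  window_df <- do.call(rbind, rows)
  if (all(!window_df$converged))
    stop("all windows failed to fit", call. = FALSE)
  res <- structure(list(windows = window_df, fits = fits,
                        window_specs = windows,
                        design = design, effects = effects, width = width),
                   class = "scan_result")
  if (gene_p) {
    genes <- unique(window_df$gene)
    gp <- vapply(seq_along(genes), function(gi) {
      gene_pvalue(res, genes[gi], families, B = B,
                  seed = derive_seed(seed, gi))
    }, numeric(1))
    res$genes <- data.frame(
      gene = genes, p_gene = gp,
      n_windows = as.integer(table(window_df$gene)[genes]),
      stringsAsFactors = FALSE)
  }
  res
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Window scan: %d windows (width %d), design %s, effects %s\n",
              nrow(x$windows), x$width, x$design, x$effects))
  print(utils::head(x$windows[order(x$windows$p_overall),
                              c("gene", "window", "p_overall", "converged")],
                    10), row.names = FALSE)
  if (!is.null(x$genes)) {
    cat("Gene-level overall p-values:\n")
    print(utils::head(x$genes[order(x$genes$p_gene), ], 10),
          row.names = FALSE)
  }
  invisible(x)
}

# ---- gene-level overall p-value --------------------------------------------

# Stitched null haplotype sampler for one gene.  Consecutive sliding
# windows overlap by width-1 SNPs; a gene-wide haplotype is drawn by
# sampling the first window's haplotype from its null-fitted frequencies
# and extending one SNP at a time from each subsequent window's
# frequencies conditional on the already-drawn overlap (an order-(width-1)
# Markov approximation to the gene's haplotype distribution, exact within
# any single window).
make_gene_sampler <- function(win_fits, win_specs) {
  # per window: haplotype allele matrices and null-fitted frequencies
  parts <- lapply(win_fits, function(f) {
    A <- do.call(rbind, lapply(strsplit(f$haplotypes, ""),
                               function(a) as.integer(a == "2")))
    list(A = A, p = f$freqs_null)
  })
  pos_of <- sort(unique(unlist(lapply(win_specs, `[[`, "snp_idx"))))
  col_of <- function(snp_idx) match(snp_idx, pos_of)
  first_cols <- col_of(win_specs[[1]]$snp_idx)
  function(n) {
    H <- matrix(NA_integer_, n, length(pos_of))
    k <- sample.int(length(parts[[1]]$p), n, replace = TRUE,
                    prob = parts[[1]]$p)
    H[, first_cols] <- parts[[1]]$A[k, , drop = FALSE]
    for (w in seq_along(parts)[-1]) {
      cols <- col_of(win_specs[[w]]$snp_idx)
      new_cols <- cols[is.na(H[1, cols])]
      if (!length(new_cols)) next
      known_cols <- setdiff(cols, new_cols)
      A <- parts[[w]]$A; p <- parts[[w]]$p
      kpos <- match(known_cols, cols)
      npos <- match(new_cols, cols)
      if (!length(known_cols)) {  # disjoint window: draw independently
        k <- sample.int(length(p), n, replace = TRUE, prob = p)
        H[, new_cols] <- A[k, npos, drop = FALSE]
        next
      }
      ctx <- apply(H[, known_cols, drop = FALSE], 1, paste, collapse = "")
      hap_ctx <- apply(A[, kpos, drop = FALSE], 1, paste, collapse = "")
      for (u in unique(ctx)) {
        rows <- which(ctx == u)
        match_h <- which(hap_ctx == u & p > 1e-12)
        if (!length(match_h)) {  # unseen context: marginal fallback
          for (jj in seq_along(npos)) {
            pr1 <- sum(p * A[, npos[jj]])
            H[rows, new_cols[jj]] <- stats::rbinom(length(rows), 1, pr1)
          }
        } else {
          pick <- match_h[sample.int(length(match_h), length(rows),
                                     replace = TRUE,
                                     prob = p[match_h])]
          H[rows, new_cols] <- A[pick, npos, drop = FALSE]
        }
      }
    }
    H
  }
}

#' Gene-level overall p-value by min-p parametric bootstrap
#'
#' The observed statistic is the minimum over the gene's converged windows
#' of the window LRT p-value.  Its null distribution is obtained by
#' parametric bootstrap: `B` datasets are simulated from the null
#' (no-effect) haplotype frequencies fitted to the observed data, with the
#' observed family structure (status, father presence) and missingness
#' pattern preserved, the scan is recomputed on each and the min-p
#' statistic collected.  `p_gene = (1 + #{null <= observed}) / (B + 1)`.
#' Because overlapping windows are resampled from a common stitched
#' haplotype distribution, the correction honours within-gene linkage
#' disequilibrium rather than penalising redundant windows.
#'
#' @param scan A `scan_result` from [run_scan()].
#' @param gene Gene label.
#' @param families The families that produced the scan.
#' @param B Bootstrap replicates, at least 100.
#' @param seed Integer seed.
#' @return P-value in `(0, 1]`.
#' @export
gene_pvalue <- function(scan, gene, families, B = 1000L, seed = 1L) {
  if (B < 100) stop("B must be at least 100 (unstable tail otherwise)",
                    call. = FALSE)
  in_gene <- which(scan$windows$gene == gene)
  if (!length(in_gene)) stop("gene not in scan: ", gene, call. = FALSE)
  conv <- in_gene[scan$windows$converged[in_gene]]
  if (!length(conv))
    stop("no converged window fit for gene ", gene, call. = FALSE)
  obs <- min(scan$windows$p_overall[conv])
  win_fits <- scan$fits[conv]
  win_specs <- scan$window_specs[conv]

  design <- scan$design
  use <- if (design == "triad")
    vapply(families, function(f) f$status == "case", logical(1))
  else rep(TRUE, length(families))
  fams <- families[use]

  gene_snp_idx <- sort(unique(unlist(lapply(win_specs, `[[`, "snp_idx"))))
  local_idx <- lapply(win_specs, function(w) match(w$snp_idx, gene_snp_idx))
  # missingness masks on the gene's SNPs
  masks <- lapply(fams, function(f) {
    list(m = is.na(f$mother[gene_snp_idx]),
         c = is.na(f$child[gene_snp_idx]),
         f = if (is.null(f$father)) NULL else is.na(f$father[gene_snp_idx]),
         status = f$status)
  })
  sampler <- make_gene_sampler(win_fits, win_specs)
  n_fam <- length(fams)

  # pre-stacked missingness masks for vectorised replicate construction
  Mm <- do.call(rbind, lapply(masks, `[[`, "m"))
  Mc <- do.call(rbind, lapply(masks, `[[`, "c"))
  has_f <- !vapply(masks, function(m) is.null(m$f), logical(1))
  Mf <- do.call(rbind, lapply(masks[has_f], `[[`, "f"))
  statuses <- vapply(masks, `[[`, character(1), "status")

  set.seed(seed %% 2147483647)
  n_le <- 0L
  for (b in seq_len(B)) {
    haps <- sampler(4L * n_fam)  # m1, m2, f1/tf, f2 per family
    m1 <- haps[seq(1L, by = 4L, length.out = n_fam), , drop = FALSE]
    m2 <- haps[seq(2L, by = 4L, length.out = n_fam), , drop = FALSE]
    f1 <- haps[seq(3L, by = 4L, length.out = n_fam), , drop = FALSE]
    f2 <- haps[seq(4L, by = 4L, length.out = n_fam), , drop = FALSE]
    tm <- m1
    swap <- stats::runif(n_fam) < 0.5
    tm[swap, ] <- m2[swap, , drop = FALSE]
    mo <- m1 + m2; ch <- tm + f1; fa <- f1 + f2
    mo[Mm] <- NA_integer_; ch[Mc] <- NA_integer_
    if (any(has_f)) {
      fsub <- fa[has_f, , drop = FALSE]
      fsub[Mf] <- NA_integer_
      fa[has_f, ] <- fsub
    }
    sim_fams <- lapply(seq_len(n_fam), function(i)
      structure(list(family_id = paste0("B", i), status = statuses[i],
                     mother = mo[i, ], father = if (has_f[i]) fa[i, ],
                     child = ch[i, ]),
                class = "family_record"))
    pmin_b <- Inf
    for (w in seq_along(win_specs)) {
      fit <- tryCatch(
        suppressWarnings(fit_window(sim_fams, local_idx[[w]],
                                    effects = scan$effects,
                                    design = design, compute_se = FALSE)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$converged && !is.na(fit$p_overall))
        pmin_b <- min(pmin_b, fit$p_overall)
    }
    if (is.finite(pmin_b) && pmin_b <= obs) n_le <- n_le + 1L
  }
  (1 + n_le) / (B + 1)
}
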