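# QQ-plot summaries of gene-level p-values with exact pointwise null
# envelopes.  Under the global null the i-th smallest of n p-values follows
# Beta(i, n - i + 1); expected values are the Beta medians and the 95%
# envelope the 2.5%/97.5% Beta quantiles, displayed on the -log10 scale.

#' QQ-plot data with pointwise beta envelope
#'
#' @param p_values P-values in `(0, 1]`.
#' @return Data frame of class `qq_data`, one row per rank in order of
#'   increasing expected value: `rank` (1 = smallest p), `expected`
#'   (`-log10` of the Beta order-statistic median), `observed` (`-log10`
#'   of the rank-paired observed p), `band_lo`, `band_hi` (95% pointwise
#'   envelope), plus raw-scale columns `expected_p`, `observed_p`.
#' @export
qq_data <- function(p_values) {
  n <- length(p_values)
  if (n == 0) stop("no p-values supplied", call. = FALSE)
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  i <- seq_len(n)                 # rank of the i-th smallest p-value
  exp_p <- stats::qbeta(0.5, i, n - i + 1)
  lo_p <- stats::qbeta(0.025, i, n - i + 1)
  hi_p <- stats::qbeta(0.975, i, n - i + 1)
  obs_p <- sort(p_values)
  out <- data.frame(rank = i,
                    expected = -log10(exp_p),
                    observed = -log10(obs_p),
                    band_lo = -log10(hi_p),   # larger p => lower -log10
                    band_hi = -log10(lo_p),
                    expected_p = exp_p,
                    observed_p = obs_p)
  # order of increasing expected -log10 is decreasing rank; keep rank order
  # ascending in expected by reversing
  out <- out[order(out$expected), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("qq_data", "data.frame")
  out
}

#' Render QQ plots to an image file
#'
#' Draws `-log10` observed against expected p-values with the shaded 95%
#' pointwise envelope and the identity line; with a named list of inputs,
#' one panel per element (e.g. design by model).
#'
#' @param qq A `qq_data` object, or a named list of them for a multi-panel
#'   figure.
#' @param out Output image path (extension selects the device, e.g. `.png`
#'   or `.svg`).
#' @param width,height Device size in inches.
#' @return Invisibly, `out`.
#' @export
render_qq <- function(qq, out, width = 7, height = 7) {
  if (inherits(qq, "qq_data")) qq <- list(` ` = qq)
  if (!is.list(qq) || length(qq) == 0)
    stop("no QQ panels to render", call. = FALSE)
  if (is.null(names(qq)) || any(names(qq) == ""))
    names(qq) <- paste("panel", seq_along(qq))
  df <- do.call(rbind, lapply(names(qq), function(nm) {
    d <- as.data.frame(qq[[nm]])
    d$panel <- nm
    d
  }))
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = expected)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = band_lo, ymax = band_hi),
                         fill = "grey80") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = observed), size = 0.9) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = expression(-log[10] ~ "expected p"),
                  y = expression(-log[10] ~ "observed p")) +
    ggplot2::theme_bw()
  ggplot2::ggsave(out, gp, width = width, height = height, dpi = 150)
  invisible(out)
}
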