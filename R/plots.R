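#' Plot entry probability against aneurysm size
#'
#' Base-graphics summary plots of the transport metrics: entry probability
#' per passage versus body-to-neck ratio (one line per condition), and
#' residence-time bars with bootstrap intervals.
#'
#' @param df data frame with columns `bnr`, `probability`, optionally
#'   `lo`, `hi` (interval) and `condition`
#' @param ... passed to [graphics::plot()]
#' @return invisibly, the input
#' @export
plot_entry_probability <- function(df, ...) {
  conds <- unique(df$condition %||% "all")
  graphics::plot(range(df$bnr), c(0, max(df$probability, df$hi %||% 0,
                                         na.rm = TRUE)),
                 type = "n", xlab = "body-to-neck ratio",
                 ylab = "platelet entry probability per passage", ...)
  for (i in seq_along(conds)) {
    d <- if (is.null(df$condition)) df else df[df$condition == conds[i], ]
    d <- d[order(d$bnr), ]
    graphics::lines(d$bnr, d$probability, type = "b", col = i, pch = 16)
    if (!is.null(d$lo)) {
      graphics::arrows(d$bnr, d$lo, d$bnr, d$hi, angle = 90, code = 3,
                       length = 0.03, col = i)
    }
  }
  if (length(conds) > 1) {
    graphics::legend("topleft", legend = conds, col = seq_along(conds),
                     lty = 1, pch = 16, bty = "n")
  }
  invisible(df)
}

#' @rdname plot_entry_probability
#' @param res data frame with columns `label`, `mean`, optionally `lo`, `hi`
#' @export
plot_residence_times <- function(res, ...) {
  bp <- graphics::barplot(res$mean, names.arg = res$label,
                          ylab = "residence time (s)", ...)
  if (!is.null(res$lo)) {
    graphics::arrows(bp, res$lo, bp, res$hi, angle = 90, code = 3,
                     length = 0.04)
  }
  invisible(res)
}
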