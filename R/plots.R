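utils::globalVariables(c("mid", "log_ratio", "flagged", "d", "positive",
                         "contig"))

#' Manhattan-style plot of the F_ST log-ratio scan
#'
#' One point per window: `ln(fst_A_target / fst_B_target)` along the genome,
#' flagged windows highlighted, a dashed line at zero.
#'
#' @param scan An `"fst_scan"`.
#' @return A ggplot object.
#' @export
plot_fst_scan <- function(scan) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_fst_scan requires the ggplot2 package")
  }
  w <- scan$windows[scan$windows$ratio_defined, , drop = FALSE]
  w$mid <- (w$start + w$end) / 2
  ggplot2::ggplot(w, ggplot2::aes(x = mid, y = log_ratio, colour = flagged)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::facet_grid(cols = ggplot2::vars(contig),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red"), guide = "none") +
    ggplot2::labs(x = "position (bp)",
                  y = expression(ln(F[ST]^{"A-target"} / F[ST]^{"B-target"}))) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of the windowed D scan
#'
#' Per-window D along the genome with positive windows highlighted.
#'
#' @param dscan A `"d_scan"`.
#' @return A ggplot object.
#' @export
plot_d_scan <- function(dscan) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_d_scan requires the ggplot2 package")
  }
  w <- dscan$windows[dscan$windows$defined, , drop = FALSE]
  w$mid <- (w$start + w$end) / 2
  w$positive <- w$d > 0
  ggplot2::ggplot(w, ggplot2::aes(x = mid, y = d, colour = positive)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::facet_grid(cols = ggplot2::vars(contig),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red"), guide = "none") +
    ggplot2::labs(x = "position (bp)", y = "D") +
    ggplot2::theme_minimal()
}
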