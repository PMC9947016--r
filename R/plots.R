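# Optional diagnostic figures (ggplot2 in Suggests); never required by
# the computational pipeline.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("the 'ggplot2' package is required for plotting", call. = FALSE)
}

#' Plot observed viability against model fits
#'
#' One panel per condition class, observations as points and the fitted
#' model as lines over a dense time grid.
#'
#' @param fit A `fit_result` from [fit_td_simultaneous()].
#' @param data The viability data the fit used.
#' @param d The [degradation_params()] used in the fit.
#' @return A ggplot object.
#' @export
plot_viability_fit <- function(fit, data, d = default_degradation_params()) {
  need_ggplot()
  cond <- unique(data[, c("c_dox0", "c_dex0")])
  tt <- seq(0, max(data$time_h), length.out = 73)
  m <- predict_viability_matrix(cond, fit$estimates, d, tt)
  lines <- do.call(rbind, lapply(seq_len(nrow(cond)), function(i)
    data.frame(c_dox0 = cond$c_dox0[i], c_dex0 = cond$c_dex0[i],
               time_h = tt, viability = m[, i])))
  lab <- function(cd, cx) paste0("DOX ", cd, " / DEX ", cx, " uM")
  data$cond <- lab(data$c_dox0, data$c_dex0)
  lines$cond <- lab(lines$c_dox0, lines$c_dex0)
  cls <- condition_class(data$c_dox0, data$c_dex0)
  data$class <- cls
  lines$class <- condition_class(lines$c_dox0, lines$c_dex0)
  ggplot2::ggplot(data, ggplot2::aes(time_h, viability,
                                     colour = cond)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = lines) +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "viability (%)", colour = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot an AUEC dose-ratio scan
#'
#' Bar chart of the protection metric `AUEC(DOX+DEX)/AUEC(DOX)` per
#' DEX:DOX ratio, highlighting the selected optimum.
#'
#' @param scan A `ratio_scan` from [scan_dose_ratios()].
#' @return A ggplot object.
#' @export
plot_ratio_scan <- function(scan) {
  need_ggplot()
  tab <- scan$table
  tab$optimal <- tab$ratio == scan$optimum
  ggplot2::ggplot(tab, ggplot2::aes(factor(ratio),
                                    auec_ratio,
                                    fill = optimal)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "steelblue")) +
    ggplot2::labs(x = "DEX:DOX dose ratio",
                  y = "AUEC(DOX+DEX) / AUEC(DOX)") +
    ggplot2::coord_cartesian(
      ylim = c(min(tab$auec_ratio) * 0.995, max(tab$auec_ratio) * 1.005)) +
    ggplot2::theme_bw()
}
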