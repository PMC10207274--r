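#' Plot site titration profiles
#'
#' ASP (fraction protonated) or pASPA (averaged acidity, log10 units)
#' profiles for every site, one colored line per group. For pASPA the
#' identity line `pASPA = pH` is drawn dashed: each profile crosses it at
#' the site's pK50.
#'
#' @param object a `titration_profile` from [site_profile()].
#' @param metric `"asp"` or `"paspa"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.titration_profile <- function(object, metric = c("asp", "paspa"), ...) {
  metric <- match.arg(metric)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$pH, y = .data[[metric]],
                                            colour = .data$label)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(colour = "site",
                  y = if (metric == "asp") "ASP (fraction protonated)" else "pASPA") +
    ggplot2::theme_minimal()
  if (metric == "paspa") {
    p <- p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                                  colour = "grey40")
  }
  p
}

#' @export
plot.titration_profile <- function(x, ...) print(autoplot.titration_profile(x, ...))

#' Plot macrostate populations across pH
#'
#' Stacked-area distribution of the proton-count macrostates over a pH
#' grid.
#'
#' @param system a [microstate_system()].
#' @param pH ascending pH grid.
#' @return A ggplot object.
#' @export
plot_macrostates <- function(system, pH = seq(0, 14, by = 0.1)) {
  mac <- macrostate_populations(system, pH)
  mac$macrostate <- factor(paste0(mac$n_protons, "H"),
                           levels = paste0(rev(sort(unique(mac$n_protons))), "H"))
  ggplot2::ggplot(mac, ggplot2::aes(x = .data$pH, y = .data$fraction,
                                    fill = .data$macrostate)) +
    ggplot2::geom_area() +
    ggplot2::labs(y = "macrostate fraction", fill = "bound protons") +
    ggplot2::theme_minimal()
}

#' Plot the Bjerrum (average bound protons) profile
#'
#' @param system a [microstate_system()].
#' @param pH ascending pH grid.
#' @return A ggplot object.
#' @export
plot_bjerrum <- function(system, pH = seq(0, 14, by = 0.1)) {
  ggplot2::ggplot(bjerrum(system, pH), ggplot2::aes(x = .data$pH, y = .data$nbar)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(y = "average bound protons") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
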