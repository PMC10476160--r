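#' Broom-style tidiers and autoplot methods
#'
#' `tidy()` returns the component-level estimates of a fitted object as a
#' tibble, `glance()` a one-row model summary, and `autoplot()` a ggplot of
#' the fit over the data.
#'
#' @name wgdtrace-tidiers
NULL

#' @rdname wgdtrace-tidiers
#' @param x A `ks_peak_fit`.
#' @param ... Unused.
#' @export
tidy.ks_peak_fit <- function(x, ...) {
  x$components
}

#' @rdname wgdtrace-tidiers
#' @export
glance.ks_peak_fit <- function(x, ...) {
  tibble(k = x$k, n_blocks = x$n_blocks, loglik = x$loglik, bic = x$bic,
         converged = x$converged, correction_factor = x$correction_factor)
}

#' @rdname wgdtrace-tidiers
#' @param object A fitted object.
#' @export
autoplot.ks_peak_fit <- function(object, ...) {
  dat <- tibble(ks = object$data)
  comp <- object$components
  grid <- tibble(ks = seq(max(min(dat$ks) - 0.1, 1e-4), max(dat$ks) + 0.1,
                          length.out = 400))
  curves <- purrr::pmap(comp, function(component, mu, sigma, weight) {
    grid |> mutate(component = factor(component),
                   density = weight * dnorm(.data$ks, mu, sigma))
  }) |> bind_rows()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ks)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component),
                       linewidth = 0.8) +
    ggplot2::labs(x = "block-median Ks", y = "density",
                  colour = "component") +
    ggplot2::theme_minimal()
}

#' @rdname wgdtrace-tidiers
#' @export
tidy.geom_loss_fit <- function(x, ...) {
  n1 <- x$run_counts$n_k[x$run_counts$k == min(x$run_counts$k)]
  x$run_counts |>
    mutate(expected = n1 * x$p_hat^(.data$k - min(.data$k)))
}

#' @rdname wgdtrace-tidiers
#' @export
glance.geom_loss_fit <- function(x, ...) {
  tibble(p_hat = x$p_hat, p_mle = x$p_mle, f_stat = x$f_stat,
         p_value = x$p_value, n_runs = x$n_runs,
         excluded_runs = x$excluded_runs)
}

#' @rdname wgdtrace-tidiers
#' @export
autoplot.geom_loss_fit <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_k), fill = "grey80",
                      colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), colour = "firebrick",
                       linewidth = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "consecutive genes lost (run length)",
                  y = "number of runs (log scale)") +
    ggplot2::theme_minimal()
}

#' Dot plot of ranked homologous gene hits
#'
#' @param coords Output of [dotplot_coords()].
#' @return A ggplot faceted by chromosome pair, hits coloured by rank
#'   (best = red, second = blue, other = grey, following the field's
#'   convention).
#' @export
plot_dotplot <- function(coords) {
  p <- ggplot2::ggplot(coords, ggplot2::aes(x = .data$idx_a, y = .data$idx_b))
  if ("rank" %in% names(coords)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$rank), size = 0.4) +
      ggplot2::scale_colour_manual(values = c(best = "red", second = "blue",
                                              other = "grey70"))
  } else {
    p <- p + ggplot2::geom_point(size = 0.4, colour = "grey30")
  }
  p + ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom_b),
                          cols = ggplot2::vars(.data$chrom_a),
                          scales = "free", space = "free") +
    ggplot2::labs(x = "gene order (genome A)", y = "gene order (genome B)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0, "pt"))
}

#' Retention-rate bar plot per chromosome and subgenome
#'
#' @param profile A `retention_profile`.
#' @return A ggplot.
#' @export
plot_retention <- function(profile) {
  stopifnot(inherits(profile, "retention_profile"))
  dat <- profile$rates |> filter(.data$chrom != "genome")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$chrom, y = .data$retention_rate,
                                    fill = .data$subgenome)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "reference chromosome", y = "retention rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
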