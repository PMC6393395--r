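#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a force-extension trace
#'
#' Force against trap separation, with detected events marked if an event
#' table is supplied.
#'
#' @param object A [fe_trace()].
#' @param events Optional event tibble from [detect_events()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fe_trace
#' @export
autoplot.fe_trace <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$separation_nm,
                                    y = .data$force_pN)) +
    ggplot2::geom_path(linewidth = 0.2, colour = "grey30") +
    ggplot2::labs(x = "trap separation (nm)", y = "force (pN)",
                  title = sprintf("%s (%s)", attr(object, "tether_id"),
                                  attr(object, "direction"))) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events)) {
    ev <- dplyr::mutate(events,
                        separation_nm = object$separation_nm[.data$index])
    p <- p + ggplot2::geom_point(
      data = ev,
      ggplot2::aes(x = .data$separation_nm, y = .data$force_at_event,
                   colour = .data$label), size = 2) +
      ggplot2::labs(colour = "event")
  }
  p
}

#' Plot a contour-length-change population fit
#'
#' Histogram of the contour-length changes (0.5 nm bins) with the two
#' fitted Gaussian components and their mixture overlaid.
#'
#' @param object A [fit_bimodal()] result.
#' @param data The numeric vector or event tibble the fit was computed
#'   from.
#' @param binwidth Histogram bin width in nm (presentation only; the fit
#'   never uses binned data).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot population_fit
#' @export
autoplot.population_fit <- function(object, data, binwidth = 0.5, ...) {
  x <- if (is.data.frame(data)) data$delta_L_nm else data
  x <- x[is.finite(x)]
  grid <- seq(min(x) - 2, max(x) + 2, length.out = 400)
  dens <- purrr::imap_dfr(c(short_DeltaL = 1, long_DeltaL = 2), function(k, nm)
    tibble::tibble(component = nm, delta_L_nm = grid,
                   density = object$weights[k] *
                     stats::dnorm(grid, object$means[k], object$sds[k])))
  mix <- tibble::tibble(delta_L_nm = grid,
                        density = colSums(matrix(dens$density, nrow = 2,
                                                 byrow = TRUE)))
  ggplot2::ggplot(tibble::tibble(delta_L_nm = x),
                  ggplot2::aes(x = .data$delta_L_nm)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, fill = "grey80",
                            colour = "grey50") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_line(data = mix, ggplot2::aes(y = .data$density),
                       linetype = 2) +
    ggplot2::labs(x = expression(Delta * L ~ "(nm)"), y = "density",
                  colour = "conformer") +
    ggplot2::theme_minimal()
}

#' Plot ensemble class occupancies
#'
#' @param object An `ensemble_occupancy`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-class Boltzmann probabilities.
#' @method autoplot ensemble_occupancy
#' @export
autoplot.ensemble_occupancy <- function(object, ...) {
  ggplot2::ggplot(object$by_class,
                  ggplot2::aes(x = .data$class, y = .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "Boltzmann occupancy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot per-strand straight-fold probabilities of a site screen
#'
#' @param object A [screen_sites()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot site_screen
#' @export
autoplot.site_screen <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object$sites, !.data$unfoldable),
                  ggplot2::aes(x = .data$strand,
                               y = .data$p_straight_canonical)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = "strand", y = "p(canonical straight fold)") +
    ggplot2::theme_minimal()
}
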