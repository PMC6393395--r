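#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-component population fit
#'
#' @param x A [fit_bimodal()] result.
#' @param ... Unused.
#' @return One row per mixture component: `component`, `mean_nm`, `sd_nm`,
#'   `weight`.
#' @method tidy population_fit
#' @export
tidy.population_fit <- function(x, ...) {
  tibble::tibble(component = c("short_DeltaL", "long_DeltaL"),
                 mean_nm = x$means, sd_nm = x$sds, weight = x$weights)
}

#' @rdname tidy.population_fit
#' @return `glance()`: a one-row tibble with `n_events`, `n_tethers`,
#'   `logLik`, `iterations`, `first_pull_only`, `degenerate`.
#' @method glance population_fit
#' @export
glance.population_fit <- function(x, ...) {
  tibble::tibble(n_events = x$n_events, n_tethers = x$n_tethers,
                 logLik = x$loglik[length(x$loglik)],
                 iterations = length(x$loglik),
                 first_pull_only = x$first_pull_only,
                 degenerate = x$degenerate)
}

#' Tidy a trace fit
#'
#' @param x A [fit_segments()] result.
#' @param ... Unused.
#' @return The per-event tibble with contour-length changes.
#' @method tidy trace_fit
#' @export
tidy.trace_fit <- function(x, ...) x$events

#' @rdname tidy.trace_fit
#' @method glance trace_fit
#' @export
glance.trace_fit <- function(x, ...) {
  tibble::tibble(tether_id = x$tether_id, direction = x$direction,
                 p_dsDNA_nm = x$handles_fit$persistence_length,
                 n_events = nrow(x$events),
                 n_segments = nrow(x$ssdna_fits),
                 residual_rms_pN = x$residual_rms)
}

#' Tidy an ensemble occupancy
#'
#' @param x A [boltzmann_occupancy()] / [classify_ensemble()] result.
#' @param ... Unused.
#' @return The per-structure tibble (`free_energy`, `class`,
#'   `probability`).
#' @method tidy ensemble_occupancy
#' @export
tidy.ensemble_occupancy <- function(x, ...) x$structures

#' @rdname tidy.ensemble_occupancy
#' @return `glance()`: the per-class probability tibble in wide form with
#'   `temperature`.
#' @method glance ensemble_occupancy
#' @export
glance.ensemble_occupancy <- function(x, ...) {
  out <- tidyr::pivot_wider(x$by_class, names_from = "class",
                            values_from = "probability")
  out$temperature_K <- x$temperature
  out
}

#' Tidy a site screen
#'
#' @param x A [screen_sites()] result.
#' @param ... Unused.
#' @return `tidy()`: the per site-strand tibble; `glance()`: the
#'   per-strand cohort summary.
#' @method tidy site_screen
#' @export
tidy.site_screen <- function(x, ...) x$sites

#' @rdname tidy.site_screen
#' @method glance site_screen
#' @export
glance.site_screen <- function(x, ...) x$summary
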