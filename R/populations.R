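#' Fit a two-component Gaussian mixture to contour-length changes
#'
#' Contour-length changes of the major unfolding event pool into two
#' populations, one per hairpin conformer (kinked, smaller apical stem;
#' straight, larger apical stem). This fits a two-component univariate
#' Gaussian mixture with unequal variances by expectation-maximization.
#' The fit is deterministic given the data and the initial means (there
#' are no random restarts), and the log-likelihood is non-decreasing over
#' iterations by construction.
#'
#' @param data A numeric vector of contour-length changes (nm), or a data
#'   frame containing the column named by `delta_L`.
#' @param delta_L Column name holding the contour-length changes when
#'   `data` is a data frame; default `"delta_L_nm"`.
#' @param init_means Initial component means (nm); default `c(20.3, 24.1)`,
#'   the empirical positions of the kinked and straight populations.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param sd_floor Lower bound on component standard deviations (nm);
#'   collapsing components are re-floored with a warning (default 0.05).
#' @param first_pull_only Flag recorded in the result (set by the caller
#'   when the data were restricted with [filter_first_pulls()]).
#' @return An object of class `population_fit` with ascending component
#'   `means`, `sds`, `weights`, the per-iteration `loglik` trajectory,
#'   `n_events`, `n_tethers` (when `data` carries a `tether_id` column)
#'   and a `degenerate` flag.
#' @examples
#' x <- c(rnorm(80, 24.3, 1.3), rnorm(20, 20.4, 0.9))
#' fit <- fit_bimodal(x)
#' tidy(fit)
#' @export
fit_bimodal <- function(data, delta_L = "delta_L_nm",
                        init_means = c(20.3, 24.1), max_iter = 500,
                        tol = 1e-8, sd_floor = 0.05,
                        first_pull_only = FALSE) {
  n_tethers <- NA_integer_
  if (is.data.frame(data)) {
    if (!delta_L %in% names(data))
      rlang::abort(sprintf("column `%s` not found in `data`.", delta_L))
    if ("tether_id" %in% names(data))
      n_tethers <- length(unique(data$tether_id))
    x <- data[[delta_L]]
  } else {
    x <- data
  }
  x <- x[is.finite(x)]
  if (length(x) < 20)
    rlang::abort("at least 20 finite contour-length changes are required.")
  stopifnot(length(init_means) == 2)

  n <- length(x)
  mu <- sort(init_means)
  s2 <- rep(stats::var(x) / 2, 2)
  degenerate <- FALSE
  if (s2[1] < sd_floor^2) {           # all values (nearly) identical
    degenerate <- TRUE
    s2 <- rep(sd_floor^2, 2)
    mu <- rep(mean(x), 2)
  }
  w <- c(0.5, 0.5)
  ll <- numeric(0)
  refloored <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- w[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll[it] <- sum(log(tot))
    r <- d1 / tot
    n1 <- sum(r); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) {      # one component lost all weight
      degenerate <- TRUE
      break
    }
    w <- c(n1, n2) / n
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    s2 <- c(sum(r * (x - mu[1])^2) / n1,
            sum((1 - r) * (x - mu[2])^2) / n2)
    if (any(s2 < sd_floor^2)) {
      s2 <- pmax(s2, sd_floor^2)
      refloored <- TRUE
    }
    if (it > 1 && abs(ll[it] - ll[it - 1]) < tol) break
  }
  if (refloored)
    rlang::warn("a mixture component collapsed; its s.d. was floored.")
  ord <- order(mu)
  structure(
    list(means = mu[ord], sds = sqrt(s2[ord]), weights = w[ord],
         loglik = ll, n_events = n, n_tethers = n_tethers,
         first_pull_only = first_pull_only,
         degenerate = degenerate || refloored),
    class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf(
    "<population_fit> n = %d%s\n  short_DeltaL: %.2f +/- %.2f nm (%.0f%%)\n  long_DeltaL:  %.2f +/- %.2f nm (%.0f%%)\n",
    x$n_events,
    if (isTRUE(x$first_pull_only)) " (first pulls only)" else "",
    x$means[1], x$sds[1], 100 * x$weights[1],
    x$means[2], x$sds[2], 100 * x$weights[2]))
  if (x$degenerate) cat("  (degenerate fit)\n")
  invisible(x)
}

#' Assign contour-length changes to a conformer population
#'
#' Maximum-posterior assignment under a fitted two-component mixture. The
#' component with the smaller mean is labelled `short_DeltaL` (kinked-like)
#' and the larger one `long_DeltaL` (straight-like).
#'
#' @param delta_L Contour-length change(s) in nm.
#' @param fit A [fit_bimodal()] result.
#' @return A tibble with `delta_L_nm`, `label` and `posterior` (the
#'   posterior probability of the assigned component).
#' @export
assign_conformer <- function(delta_L, fit) {
  stopifnot(inherits(fit, "population_fit"), is.numeric(delta_L))
  d1 <- fit$weights[1] * stats::dnorm(delta_L, fit$means[1], fit$sds[1])
  d2 <- fit$weights[2] * stats::dnorm(delta_L, fit$means[2], fit$sds[2])
  p1 <- d1 / (d1 + d2)
  lab <- ifelse(p1 >= 0.5, "short_DeltaL", "long_DeltaL")
  tibble::tibble(delta_L_nm = delta_L, label = lab,
                 posterior = pmax(p1, 1 - p1))
}

#' Restrict an event table to the first unfolding per tether
#'
#' Keeps, for every tether, only the first unfolding event of the first
#' pulling cycle after tether formation. Comparing the population weights
#' of this subset with the cumulative ones tests whether repeated
#' refolding under load biases the conformer distribution.
#'
#' @param events An event tibble carrying `tether_id` and chronological
#'   order (`pull` and/or `time_s`/`index` columns).
#' @return The subset tibble, one row per tether that unfolded.
#' @export
filter_first_pulls <- function(events) {
  stopifnot(is.data.frame(events), "tether_id" %in% names(events))
  ev <- events
  if ("direction" %in% names(ev))
    ev <- dplyr::filter(ev, .data$direction == "unfold")
  ord <- intersect(c("pull", "time_s", "index"), names(ev))
  ev |>
    dplyr::group_by(.data$tether_id) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(ord)), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}
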