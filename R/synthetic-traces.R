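#' Bell-model kinetic parameters for hairpin (un)folding
#'
#' Holds zero-force rates (1/s) and distances to the transition state (nm)
#' for the transitions of the three-state scheme
#' folded -> intermediate -> unfolded and its reverse. Force dependence is
#' exponential (Bell): `k(F) = k0 * exp(+F dx / kBT)` for unfolding and
#' `k(F) = k0 * exp(-F dx / kBT)` for refolding.
#'
#' The default constants are calibration choices, not measurements: with
#' the default construct (580 nm handles, 64-nt hairpin, 0.06 pN/nm trap)
#' pulled at 200 nm/s they place the mean major rip near 5.7 pN and the
#' mean minor rip near 2.8 pN.
#'
#' @param k0_minor,dx_minor Zero-force rate and barrier distance of the
#'   minor unfolding step (folded -> intermediate).
#' @param k0_major,dx_major Same for the major step
#'   (intermediate -> unfolded); also used for the single transition when a
#'   hairpin is simulated without an intermediate.
#' @param k0_refold_major,dx_refold_major Refolding
#'   (unfolded -> intermediate).
#' @param k0_refold_minor,dx_refold_minor Refolding
#'   (intermediate -> folded).
#' @return An object of class `sim_kinetics`.
#' @export
sim_kinetics <- function(k0_minor = 2.5e-3, dx_minor = 12,
                         k0_major = 1.07e-5, dx_major = 10,
                         k0_refold_major = 1e4, dx_refold_major = 10,
                         k0_refold_minor = 1, dx_refold_minor = 7) {
  vals <- c(k0_minor, dx_minor, k0_major, dx_major,
            k0_refold_major, dx_refold_major, k0_refold_minor,
            dx_refold_minor)
  if (any(!is.finite(vals)) || any(vals <= 0))
    rlang::abort("all rates and barrier distances must be positive.")
  structure(list(k0_minor = k0_minor, dx_minor = dx_minor,
                 k0_major = k0_major, dx_major = dx_major,
                 k0_refold_major = k0_refold_major,
                 dx_refold_major = dx_refold_major,
                 k0_refold_minor = k0_refold_minor,
                 dx_refold_minor = dx_refold_minor),
            class = "sim_kinetics")
}

# ssDNA contour length (nm) released in each state of an n-nt hairpin with
# an optional intermediate of `inter` nt
state_contours <- function(total_nt, intermediate_nt) {
  L_full <- total_nt * hp_constants$nm_per_nt
  if (is.null(intermediate_nt)) {
    list(folded = 0, unfolded = L_full)
  } else {
    list(folded = 0,
         intermediate = (total_nt - intermediate_nt) * hp_constants$nm_per_nt,
         unfolded = L_full)
  }
}

state_model <- function(state, L_ss, handles, trap_stiffness, temperature) {
  if (state == "folded") {
    construct_model(handles, NULL,
                    folded_end_to_end = hp_constants$hairpin_closure_nm,
                    trap_stiffness = trap_stiffness)
  } else {
    construct_model(handles, wlc_params(2, L_ss[[state]], temperature),
                    trap_stiffness = trap_stiffness)
  }
}

# Force of one construct state as a function of trap separation, solved on
# a fine grid by safeguarded Newton on F/k + xi(F) = s and returned as a
# spline interpolator (error << 1e-6 pN).
state_force_spline <- function(model, s_lo, s_hi) {
  k <- model$trap_stiffness
  grid <- seq(s_lo, s_hi, length.out = 1500)
  F <- rep(1, length(grid))
  for (it in 1:80) {
    g <- F / k + construct_extension(model, F) - grid
    dg <- 1 / k + construct_compliance(model, F)
    Fn <- F - g / dg
    F <- pmax(Fn, F / 2)       # keep positive; halves instead of overshooting
    if (max(abs(g)) < 1e-10) break
  }
  stats::splinefun(grid, F, method = "natural")
}

#' Simulate a single optical-tweezers pulling or relaxation cycle
#'
#' Quasi-static sweep of the trap separation at constant velocity. At every
#' internal sample (50 kHz by default) the force of the current state is
#' the solution of the force balance `F = k_trap (s - xi_construct(F))`;
#' stochastic transitions between folded, intermediate and unfolded states
#' are drawn from Bell rates integrated along the sweep. White Gaussian
#' force noise is added to the output, which is decimated by `decimation`
#' to keep traces compact.
#'
#' @param handles [wlc_params()] of the dsDNA handles.
#' @param total_nt Total hairpin length in nucleotides (default 64).
#' @param intermediate_nt Size of the mechanically stable intermediate in
#'   nt (the apical stem; 35 for a straight, 28 for a kinked conformer), or
#'   `NULL` for single-step unfolding.
#' @param trap_stiffness Effective trap stiffness (pN/nm).
#' @param kinetics A [sim_kinetics()] object.
#' @param velocity Pulling velocity (nm/s, default 200).
#' @param sampling_rate Internal sampling rate (Hz, default 50000).
#' @param noise_sd Gaussian force noise s.d. (pN, default 0.35).
#' @param seed Integer seed; `NULL` uses (and advances) the session RNG.
#' @param transitions_enabled Set `FALSE` to freeze the initial state.
#' @param initial_state `"folded"` (pull) or `"unfolded"` (relax).
#' @param direction `"pull"` or `"relax"`.
#' @param s_range Optional length-2 separation range (nm); by default spans
#'   0.5 pN (folded) to 8 pN (unfolded).
#' @param decimation Output decimation factor (default 10).
#' @param temperature Temperature (K).
#' @param tether_id Identifier stored in the trace metadata.
#' @return A list of class `sim_pull` with elements `trace` (a
#'   [fe_trace()]) and `events` (ground-truth tibble: output-sample index,
#'   time, states, noiseless force and contour-length change per
#'   transition).
#' @export
simulate_pull <- function(handles = wlc_params(22, 580), total_nt = 64,
                          intermediate_nt = 35, trap_stiffness = 0.06,
                          kinetics = sim_kinetics(), velocity = 200,
                          sampling_rate = 50000, noise_sd = 0.35,
                          seed = NULL, transitions_enabled = TRUE,
                          initial_state = NULL,
                          direction = c("pull", "relax"), s_range = NULL,
                          decimation = 10,
                          temperature = hp_constants$T_default,
                          tether_id = "sim-tether") {
  direction <- match.arg(direction)
  stopifnot(velocity > 0, sampling_rate > 0, decimation >= 1)
  run <- function() {
    L_ss <- state_contours(total_nt, intermediate_nt)
    states <- names(L_ss)
    models <- lapply(states, state_model, L_ss = L_ss, handles = handles,
                     trap_stiffness = trap_stiffness,
                     temperature = temperature)
    names(models) <- states
    if (is.null(s_range)) {
      s_lo <- construct_extension(models$folded, 0.5) + 0.5 / trap_stiffness
      s_hi <- construct_extension(models$unfolded, 8) + 8 / trap_stiffness
    } else {
      s_lo <- min(s_range); s_hi <- max(s_range)
    }
    n <- ceiling((s_hi - s_lo) / velocity * sampling_rate) + 1
    tvec <- (seq_len(n) - 1) / sampling_rate
    s <- if (direction == "pull") s_lo + velocity * tvec
         else s_hi - velocity * tvec
    splines <- lapply(models, state_force_spline, s_lo = s_lo - 1,
                      s_hi = s_hi + 1)
    F_state <- lapply(splines, function(f) pmax(f(s), 1e-6))

    if (is.null(initial_state))
      initial_state <- if (direction == "pull") "folded" else "unfolded"
    kT <- kBT(temperature)
    # transition table: from, to, k0, dx, sign (+1 unfold, -1 refold)
    tr <- if (is.null(intermediate_nt)) {
      list(folded = list(list("unfolded", kinetics$k0_major,
                              kinetics$dx_major, +1)),
           unfolded = list(list("folded", kinetics$k0_refold_major,
                                kinetics$dx_refold_major, -1)))
    } else {
      list(folded = list(list("intermediate", kinetics$k0_minor,
                              kinetics$dx_minor, +1)),
           intermediate = list(list("unfolded", kinetics$k0_major,
                                    kinetics$dx_major, +1),
                               list("folded", kinetics$k0_refold_minor,
                                    kinetics$dx_refold_minor, -1)),
           unfolded = list(list("intermediate", kinetics$k0_refold_major,
                                kinetics$dx_refold_major, -1)))
    }

    dt <- 1 / sampling_rate
    state <- initial_state
    i0 <- 1L
    force <- numeric(n)
    ev <- list()
    n_ev <- 0L
    while (i0 <= n) {
      if (!transitions_enabled || length(tr[[state]]) == 0) {
        force[i0:n] <- F_state[[state]][i0:n]
        break
      }
      idx <- i0:n
      Fv <- F_state[[state]][idx]
      rates <- vapply(tr[[state]], function(trn)
        trn[[2]] * exp(trn[[4]] * Fv * trn[[3]] / kT),
        numeric(length(idx)))
      rates <- matrix(rates, nrow = length(idx))
      tot <- rowSums(rates)
      ch <- cumsum(tot) * dt
      u <- stats::rexp(1)
      j <- findInterval(u, ch) + 1L
      if (j > length(idx)) {               # no transition before sweep end
        force[idx] <- Fv
        break
      }
      force[idx[1:j]] <- Fv[1:j]
      which_tr <- if (ncol(rates) == 1) 1L
                  else sample.int(ncol(rates), 1, prob = rates[j, ])
      to <- tr[[state]][[which_tr]][[1]]
      raw <- abs(L_ss[[to]] - L_ss[[state]])
      dL <- raw - if (state == "folded" || to == "folded")
        hp_constants$hairpin_closure_nm else 0
      n_ev <- n_ev + 1L
      ev[[n_ev]] <- tibble::tibble(
        internal_index = idx[j],
        state_from = state, state_to = to,
        direction = if (L_ss[[to]] > L_ss[[state]]) "unfold" else "refold",
        force_pN = Fv[j], delta_L_nm = dL)
      state <- to
      i0 <- idx[j] + 1L
      if (n_ev > 1000L) rlang::abort("runaway hopping in simulation.")
    }

    # output = block-averaged decimation of the noisy 50 kHz signal, so
    # the white force noise scales down by sqrt(decimation)
    keep <- seq(1L, n, by = decimation)
    out_force <- force[keep] +
      stats::rnorm(length(keep), 0, noise_sd / sqrt(decimation))
    trace <- fe_trace(tvec[keep], s[keep], out_force,
                      pulling_velocity = velocity,
                      sampling_rate = sampling_rate / decimation,
                      trap_stiffness = trap_stiffness,
                      direction = direction, tether_id = tether_id)
    events <- if (n_ev > 0) dplyr::bind_rows(ev) else
      tibble::tibble(internal_index = integer(), state_from = character(),
                     state_to = character(), direction = character(),
                     force_pN = numeric(), delta_L_nm = numeric())
    if (n_ev == 0 && transitions_enabled)
      rlang::warn("no transition occurred within the sweep range.")
    events$index <- (events$internal_index - 1L) %/% decimation + 1L
    events$time_s <- tvec[pmin(events$internal_index, n)]
    events$tether_id <- tether_id
    structure(list(trace = trace,
                   events = events[, c("tether_id", "index", "time_s",
                                       "state_from", "state_to", "direction",
                                       "force_pN", "delta_L_nm")]),
              class = "sim_pull")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a cohort of tethers with a two-conformer mixture
#'
#' Generates pulling traces for `n_tethers` tethers with `pulls_per_tether`
#' cycles each. Every pull starts from a freshly folded hairpin whose
#' conformer (and hence intermediate size) is drawn from
#' `conformer_weights`, emulating refolding into either the straight or
#' the kinked structure. Per tether, the handle persistence length is drawn
#' uniformly from `p_handles_range` and the trap stiffness from
#' `trap_stiffness_range` (the calibration spread of the instrument).
#'
#' @param n_tethers Number of tethers (default 65).
#' @param pulls_per_tether Pulling cycles per tether (default 7).
#' @param conformer_weights Named probabilities for the conformers,
#'   summing to 1; default `c(straight = 0.8, kinked = 0.2)`.
#' @param intermediate_nt Named intermediate sizes in nt; default
#'   `c(straight = 35, kinked = 28)`.
#' @param total_nt Hairpin length (nt, default 64).
#' @param noise_sd Force noise s.d. (pN, default 0.35).
#' @param seed Integer seed (required: cohorts are reproducible).
#' @param p_handles_range Range of per-tether handle persistence lengths
#'   (nm), default `c(20, 27)`.
#' @param trap_stiffness_range Range of per-tether trap stiffnesses
#'   (pN/nm), default `c(0.056, 0.062)`.
#' @param ... Further arguments passed to [simulate_pull()].
#' @return A list of class `sim_cohort`: `traces` (list of [fe_trace()]),
#'   `ground_truth` (tibble of true transitions with tether, pull and
#'   conformer) and `spec` (the generator settings).
#' @export
generate_cohort <- function(n_tethers = 65, pulls_per_tether = 7,
                            conformer_weights = c(straight = 0.8,
                                                  kinked = 0.2),
                            intermediate_nt = c(straight = 35, kinked = 28),
                            total_nt = 64, noise_sd = 0.35, seed,
                            p_handles_range = c(20, 27),
                            trap_stiffness_range = c(0.056, 0.062), ...) {
  if (missing(seed)) rlang::abort("`seed` is mandatory for cohorts.")
  stopifnot(abs(sum(conformer_weights) - 1) < 1e-9,
            all(conformer_weights >= 0),
            all(names(conformer_weights) %in% names(intermediate_nt)))
  with_seed(seed, {
    traces <- list()
    gt <- list()
    conf_names <- names(conformer_weights)
    for (t in seq_len(n_tethers)) {
      tid <- sprintf("tether-%03d", t)
      p_h <- stats::runif(1, p_handles_range[1], p_handles_range[2])
      k_t <- stats::runif(1, trap_stiffness_range[1], trap_stiffness_range[2])
      for (p in seq_len(pulls_per_tether)) {
        conf <- sample(conf_names, 1, prob = conformer_weights)
        sim <- simulate_pull(handles = wlc_params(p_h, 580),
                             total_nt = total_nt,
                             intermediate_nt = unname(intermediate_nt[conf]),
                             trap_stiffness = k_t, noise_sd = noise_sd,
                             seed = NULL, tether_id = tid, ...)
        ev <- sim$events
        ev$pull <- p
        ev$conformer <- conf
        traces[[length(traces) + 1L]] <- sim$trace
        gt[[length(gt) + 1L]] <- ev
      }
    }
    structure(list(traces = traces,
                   ground_truth = dplyr::bind_rows(gt),
                   spec = list(n_tethers = n_tethers,
                               pulls_per_tether = pulls_per_tether,
                               conformer_weights = conformer_weights,
                               intermediate_nt = intermediate_nt,
                               total_nt = total_nt, noise_sd = noise_sd,
                               seed = seed)),
              class = "sim_cohort")
  })
}

#' Analyze every trace of a cohort
#'
#' Runs [analyze_trace()] (method `"events"`) or [analyze_major_event()]
#' (method `"major"`, for hairpins unfolding via an intermediate) over a
#' list of traces (or a `sim_cohort`) and binds the per-event results,
#' adding a `pull` counter per tether.
#'
#' @param traces A list of [fe_trace()] objects or a `sim_cohort`.
#' @param method `"events"` (full event table) or `"major"` (one row per
#'   trace: the major unfolding event).
#' @param ... Passed to the per-trace analysis.
#' @return A tibble of events across the cohort.
#' @export
analyze_cohort <- function(traces, method = c("events", "major"), ...) {
  method <- match.arg(method)
  if (inherits(traces, "sim_cohort")) traces <- traces$traces
  fun <- if (method == "major") analyze_major_event else analyze_trace
  res <- purrr::imap_dfr(traces, function(tr, i) {
    out <- suppressWarnings(fun(tr, ...))
    if (nrow(out)) out$pull <- i
    out
  })
  if (nrow(res)) res <- dplyr::group_by(res, .data$tether_id) |>
    dplyr::mutate(pull = match(.data$pull, sort(unique(.data$pull)))) |>
    dplyr::ungroup()
  res
}
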