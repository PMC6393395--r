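#' Force-extension trace container
#'
#' A `fe_trace` is a tibble of sampled optical-tweezers data with one row
#' per sample and columns `time_s`, `separation_nm` (trap-trap separation)
#' and `force_pN`, plus acquisition metadata stored as attributes:
#' pulling velocity (nm/s), sampling rate (Hz), effective trap stiffness
#' (pN/nm), sweep direction (`"pull"` or `"relax"`) and a tether identifier.
#'
#' @param time_s Strictly increasing sample times (s).
#' @param separation_nm Trap-trap separation (nm).
#' @param force_pN Measured force (pN).
#' @param pulling_velocity Pulling velocity (nm/s).
#' @param sampling_rate Sampling rate (Hz, > 0).
#' @param trap_stiffness Effective trap stiffness (pN/nm).
#' @param direction `"pull"` or `"relax"`.
#' @param tether_id Identifier of the tether the trace was recorded on.
#' @return A tibble of class `fe_trace`.
#' @export
fe_trace <- function(time_s, separation_nm, force_pN,
                     pulling_velocity, sampling_rate, trap_stiffness,
                     direction = c("pull", "relax"), tether_id = "tether-1") {
  direction <- match.arg(direction)
  n <- length(time_s)
  if (length(separation_nm) != n || length(force_pN) != n)
    rlang::abort("time, separation and force must have equal lengths.")
  if (n < 2 || any(diff(time_s) <= 0))
    rlang::abort("`time_s` must be strictly increasing.")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    rlang::abort("`sampling_rate` must be > 0.")
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        separation_nm = as.numeric(separation_nm),
                        force_pN = as.numeric(force_pN))
  structure(out,
            class = c("fe_trace", class(out)),
            pulling_velocity = pulling_velocity,
            sampling_rate = sampling_rate,
            trap_stiffness = trap_stiffness,
            direction = direction,
            tether_id = tether_id)
}

trace_meta <- function(trace) {
  list(pulling_velocity = attr(trace, "pulling_velocity"),
       sampling_rate = attr(trace, "sampling_rate"),
       trap_stiffness = attr(trace, "trap_stiffness"),
       direction = attr(trace, "direction"),
       tether_id = attr(trace, "tether_id"))
}

#' Read / write force-extension traces
#'
#' Traces are stored as a CSV with columns `time_s`, `separation_nm`,
#' `force_pN` and a JSON metadata sidecar (same path with extension
#' `.json`) holding `pulling_velocity_nm_s`, `sampling_rate_hz`,
#' `trap_stiffness_pN_nm`, `direction` and `tether_id`.
#'
#' @param path Path to the trace CSV file.
#' @return `read_fe_trace()` returns a [fe_trace()]; `write_fe_trace()`
#'   returns `path` invisibly.
#' @export
read_fe_trace <- function(path) {
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(path)) rlang::abort(paste0("trace file not found: ", path))
  if (!file.exists(sidecar))
    rlang::abort(paste0("metadata sidecar not found: ", sidecar))
  dat <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "separation_nm", "force_pN")
  if (!all(need %in% names(dat)))
    rlang::abort("trace CSV must have columns time_s, separation_nm, force_pN.")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  fe_trace(dat$time_s, dat$separation_nm, dat$force_pN,
           pulling_velocity = meta$pulling_velocity_nm_s,
           sampling_rate = meta$sampling_rate_hz,
           trap_stiffness = meta$trap_stiffness_pN_nm,
           direction = meta$direction, tether_id = meta$tether_id)
}

#' @rdname read_fe_trace
#' @param trace A [fe_trace()].
#' @export
write_fe_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fe_trace"))
  m <- trace_meta(trace)
  readr::write_csv(tibble::as_tibble(trace), path)
  jsonlite::write_json(
    list(pulling_velocity_nm_s = m$pulling_velocity,
         sampling_rate_hz = m$sampling_rate,
         trap_stiffness_pN_nm = m$trap_stiffness,
         direction = m$direction, tether_id = m$tether_id),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Detect unfolding / refolding events in a force-extension trace
#'
#' Smooths the force channel with a Savitzky-Golay filter and flags
#' transitions where the smoothed force drops (pull) or rises (relax) by at
#' least `min_force_drop` within half a smoothing window. Events whose
#' force lies below `reliable_floor` are labelled `"unassigned"`: rips that
#' shallow cannot be attributed reliably. Among the remaining events of a
#' trace the one with the deepest force step is labelled `"major"`, any
#' others `"minor"`.
#'
#' @param trace A [fe_trace()].
#' @param min_force_drop Minimum smoothed force change (pN) to call an
#'   event; default 0.5.
#' @param smoothing_window Savitzky-Golay window in samples (odd);
#'   default 51.
#' @param reliable_floor Force (pN) below which events are flagged
#'   `"unassigned"`; default 1.
#' @return A tibble with one row per event: `index`, `time_s`,
#'   `force_at_event`, `drop_pN` (size of the detected force step),
#'   `direction` (`"unfold"`/`"refold"`), `delta_L_nm` (`NA` until
#'   [fit_segments()] is run) and `label`.
#' @export
detect_events <- function(trace, min_force_drop = 0.5, smoothing_window = 51,
                          reliable_floor = 1) {
  stopifnot(inherits(trace, "fe_trace"))
  if (min_force_drop <= 0) rlang::abort("`min_force_drop` must be > 0.")
  n <- nrow(trace)
  if (smoothing_window %% 2 == 0) smoothing_window <- smoothing_window + 1
  if (n <= smoothing_window)
    rlang::abort("trace is shorter than the smoothing window.")
  pull <- attr(trace, "direction") == "pull"
  fs <- signal::sgolayfilt(trace$force_pN, p = 3, n = smoothing_window)
  h <- max(2L, smoothing_window %/% 2L)
  # trend-cancelling double difference: a force step of size D between
  # sample i and i+h contributes -D (drop) or +D (rise) regardless of the
  # smooth loading slope, which cancels exactly
  i <- (h + 1L):(n - h)
  d <- fs[i + h] + fs[i - h] - 2 * fs[i]
  sep_ok <- if (pull) trace$separation_nm[i + h] > trace$separation_nm[i - h]
            else trace$separation_nm[i + h] < trace$separation_nm[i - h]
  cand <- if (pull) (d <= -min_force_drop & sep_ok)
          else (d >= min_force_drop & sep_ok)
  cand_idx <- i[cand]                          # trace sample positions
  if (length(cand_idx) == 0) return(empty_events())
  # contiguous candidate runs -> one event each, at the steepest slope
  runs <- split(cand_idx, cumsum(c(1, diff(cand_idx) > h)))
  dmap <- stats::setNames(d, i)
  ev <- purrr::map_dfr(runs, function(idx) {
    lo <- min(idx); hi <- min(max(idx) + h, n - 1)
    slopes <- fs[(lo + 1):(hi + 1)] - fs[lo:hi]
    at <- lo + (if (pull) which.min(slopes) else which.max(slopes)) - 1L
    pre <- max(1L, lo - h)
    f_ev <- if (pull) max(fs[pre:at]) else min(fs[at:min(hi + h, n)])
    tibble::tibble(index = at, time_s = trace$time_s[at],
                   force_at_event = f_ev,
                   drop_pN = max(abs(dmap[as.character(idx)])))
  })
  ev <- dplyr::arrange(ev, .data$index)
  ev$direction <- if (pull) "unfold" else "refold"
  ev$delta_L_nm <- NA_real_
  ev$label <- "minor"
  ev$label[ev$force_at_event < reliable_floor] <- "unassigned"
  scored <- which(ev$label != "unassigned")
  if (length(scored))                   # the deepest rip is the major event
    ev$label[scored[which.max(ev$drop_pN[scored])]] <- "major"
  ev
}

empty_events <- function() {
  tibble::tibble(index = integer(), time_s = numeric(),
                 force_at_event = numeric(), drop_pN = numeric(),
                 direction = character(), delta_L_nm = numeric(),
                 label = character())
}

#' Fit WLC models to trace segments and extract contour-length changes
#'
#' Splits a pulling trace at its detected events and fits each segment
#' with a worm-like chain model of the tether in series with the trap:
#' least squares between the measured force and the force balance
#' `F = k_trap (separation - xi_construct(F))` at the measured trap
#' separations (the separation, unlike the force, carries no measurement
#' noise, so fitting in this coordinate avoids errors-in-variables bias;
#' the tether extension is `separation - force / trap_stiffness`). The
#' pre-event (folded) segment is fit with the handles-only model (fixed contour
#' length, fixed folded end-to-end offset, free dsDNA persistence length).
#' Each post-event segment is fit with the serial handles + ssDNA model,
#' sharing the fitted persistence length, with the ssDNA contour length
#' free. The contour-length change of an event is the difference of the
#' ssDNA contour lengths fitted after and before it; for the first event
#' out of the fully folded state the hairpin closure distance (2 nm) is
#' subtracted, so that complete unfolding of an n-nt hairpin reads
#' `n * 0.68 - 2` nm.
#'
#' Only samples with force above `fit_floor` (default 2 pN, below which WLC
#' fitting is unstable) and more than `rip_margin` below the next rip force
#' enter a fit. Segments with fewer than `min_points` usable samples are
#' skipped: their events keep `delta_L_nm = NA` and a warning is raised.
#'
#' @param trace A [fe_trace()] (direction `"pull"`).
#' @param events Event tibble from [detect_events()].
#' @param fixed Named list of fixed parameters: `L_handles` (nm, default
#'   580) and `p_ssDNA` (nm, default 2).
#' @param first_segment State model of the segment before the first
#'   detected event. `"folded"` (default): handles-only with the fixed
#'   closure offset, the state of a freshly formed tether. `"combined"`:
#'   serial handles + ssDNA with both the persistence length and the
#'   ssDNA contour length free; use this when the hairpin has already
#'   passed a low-force unfolding step too shallow to detect, so only the
#'   major rip segments are analysed (no closure correction is applied
#'   then).
#' @param fit_floor Minimum force (pN) included in fits; default 2.
#' @param rip_margin Excluded force band (pN) below each rip; default 0.5.
#' @param min_points Minimum usable samples per segment; default 30.
#' @param max_fit_points Segments are thinned evenly to at most this many
#'   samples before fitting; default 400.
#' @param temperature Temperature (K).
#' @return An object of class `trace_fit`: list with `handles_fit`
#'   ([wlc_params()]), `ssdna_fits` (tibble of per-segment ssDNA contour
#'   lengths), `events` (the event tibble with `delta_L_nm` filled in),
#'   `residual_rms` (pN) and the trace metadata.
#' @export
fit_segments <- function(trace, events,
                         fixed = list(L_handles = 580, p_ssDNA = 2),
                         first_segment = c("folded", "combined"),
                         fit_floor = 2, rip_margin = 0.5, min_points = 30,
                         max_fit_points = 300,
                         temperature = hp_constants$T_default) {
  stopifnot(inherits(trace, "fe_trace"))
  first_segment <- match.arg(first_segment)
  events <- dplyr::arrange(events, .data$index)
  k_trap <- attr(trace, "trap_stiffness")
  L_h <- fixed$L_handles %||% 580
  p_ss <- fixed$p_ssDNA %||% 2
  n <- nrow(trace)
  force <- trace$force_pN
  sep <- trace$separation_nm
  # Residuals are taken between the measured force and the force balance
  # F = k (s - xi(F)) at the measured trap separation, which is free of
  # measurement noise; converting separation to extension with the noisy
  # force itself would put correlated noise on both axes and bias the
  # fits. The smoothed force is used only where an extension coordinate
  # is needed for the closed-form contour profile.
  sm_win <- min(51L, (n %/% 2) * 2 - 1L)
  fsm <- signal::sgolayfilt(force, p = 3, n = max(sm_win, 5L))
  ext_sm <- sep - fsm / k_trap
  skip <- 40L                     # samples dropped around each rip (wider
                                  # than half the smoothing window)
  bnd <- sort(unique(events$index))
  starts <- c(1L, pmin(bnd + skip, n))
  ends <- c(pmax(bnd - skip, 1L), n)
  n_seg <- length(starts)

  seg_points <- function(s) {
    idx <- starts[s]:ends[s]
    keep <- fsm[idx] >= fit_floor
    if (s < n_seg) {           # stay clear of the next rip force
      f_rip <- events$force_at_event[s]
      keep <- keep & force[idx] <= f_rip - rip_margin
    }
    idx <- idx[keep]
    if (length(idx) > max_fit_points)
      idx <- idx[unique(round(seq(1, length(idx), length.out = max_fit_points)))]
    idx
  }

  closure <- hp_constants$hairpin_closure_nm
  kT <- kBT(temperature)
  # force balance F = k (s - xi(F)) of a construct state, vectorised;
  # extension and compliance come from a single cubic inversion per
  # element per iteration
  balance_force <- function(model, s, Finit = NULL) {
    p_h <- model$handles$persistence_length
    Lh <- model$handles$contour_length
    has_ss <- !is.null(model$ssdna) && model$ssdna$contour_length > 0
    off <- if (is.null(model$ssdna)) model$folded_end_to_end else 0
    F <- if (is.null(Finit)) rep(2, length(s)) else Finit
    for (it in 1:40) {
      hh <- wlc_ext_slope(p_h, Lh, kT, F)
      g <- F / k_trap + hh$x + off - s
      dg <- 1 / k_trap + hh$dxdF
      if (has_ss) {
        ss <- wlc_ext_slope(model$ssdna$persistence_length,
                            model$ssdna$contour_length, kT, F)
        g <- g + ss$x
        dg <- dg + ss$dxdF
      }
      if (max(abs(g)) < 1e-6) break
      F <- pmax(F - g / dg, F / 2)
    }
    F
  }
  # residuals against the smoothed force: the Savitzky-Golay filter
  # preserves the smooth loading curve essentially exactly away from rips
  # (segments keep a guard band wider than half the filter window), while
  # suppressing the noise whose squared magnitude otherwise biases the
  # nonlinear fit
  seg_ss <- function(model, idx, Finit = NULL)
    sum((fsm[idx] - balance_force(model, sep[idx], Finit))^2)

  # folded segment: handles + fixed closure offset, free p
  fit_folded <- function(idx) {
    Fc <- NULL
    obj <- function(p) {
      model <- construct_model(wlc_params(p, L_h, temperature), NULL,
                               folded_end_to_end = closure,
                               trap_stiffness = k_trap)
      Fm <- balance_force(model, sep[idx], Fc)
      Fc <<- Fm
      sum((fsm[idx] - Fm)^2)
    }
    op <- stats::optimize(obj, c(5, 80), tol = 1e-4)
    list(p = op$minimum, ss = op$objective, n = length(idx))
  }
  # unfolded segment: serial handles + ssDNA, free L_ss, p fixed
  fit_unfolded <- function(idx, p_hat) {
    handles <- wlc_params(p_hat, L_h, temperature)
    Fc <- NULL
    obj <- function(L_ss) {
      model <- construct_model(handles, wlc_params(p_ss, L_ss, temperature),
                               trap_stiffness = k_trap)
      Fm <- balance_force(model, sep[idx], Fc)
      Fc <<- Fm
      sum((fsm[idx] - Fm)^2)
    }
    op <- stats::optimize(obj, c(0.5, 200), tol = 1e-4)
    list(L_ss = op$minimum, ss = op$objective, n = length(idx))
  }

  # Joint fit of several partially/fully unfolded segments with a shared
  # persistence length: for a trial p the best ssDNA contour of each
  # segment is closed-form in the extension coordinate (the ssDNA
  # extension is linear in L at fixed force), and the objective is the
  # force residual sum of squares at the measured separations. The joint
  # profile pins p even though a single segment leaves p and L nearly
  # degenerate.
  fit_combined_joint <- function(idx_list) {
    Fcache <- vector("list", length(idx_list))
    eval_p <- function(p, want_fit = FALSE) {
      handles <- wlc_params(p, L_h, temperature)
      ss <- 0; n_pts <- 0; L <- numeric(length(idx_list))
      for (k in seq_along(idx_list)) {
        idx <- idx_list[[k]]
        fk <- pmax(fsm[idx], 0.25)
        z <- wlc_extension(wlc_params(p_ss, 1, temperature), fk)
        xh <- wlc_extension(handles, fk)
        # closed-form seed in the extension coordinate, then Gauss-Newton
        # on the exact force-balance residuals (near-linear in L)
        Lk <- max(sum(z * (ext_sm[idx] - xh)) / sum(z^2), 0.5)
        Fm <- Fcache[[k]]
        for (gn in 1:3) {
          model <- construct_model(handles,
                                   wlc_params(p_ss, Lk, temperature),
                                   trap_stiffness = k_trap)
          Fm <- balance_force(model, sep[idx], Fm)
          r <- fsm[idx] - Fm
          J <- -wlc_extension(wlc_params(p_ss, 1, temperature), Fm) /
            (1 / k_trap + construct_compliance(model, Fm))
          Lk <- max(Lk + sum(r * J) / sum(J^2), 0.5)
        }
        L[k] <- Lk
        model <- construct_model(handles, wlc_params(p_ss, Lk, temperature),
                                 trap_stiffness = k_trap)
        ss <- ss + seg_ss(model, idx, Fm)
        Fcache[[k]] <<- Fm
        n_pts <- n_pts + length(idx)
      }
      if (want_fit) list(ss = ss, L = L, n = n_pts) else list(ss = ss)
    }
    op <- stats::optimize(function(p) eval_p(p)$ss, c(8, 60), tol = 5e-3)
    c(list(p = op$minimum), eval_p(op$minimum, want_fit = TRUE))
  }

  idx_by_seg <- lapply(seq_len(n_seg), seg_points)
  ok <- vapply(idx_by_seg, length, 1L) >= min_points
  if (!all(ok))
    rlang::warn(sprintf(
      "%d segment(s) had fewer than %d samples above %g pN; their delta_L is NA.",
      sum(!ok), min_points, fit_floor))

  L_fit <- rep(NA_real_, n_seg)   # fitted ssDNA contour per segment
  ss_tot <- 0; n_tot <- 0
  if (first_segment == "combined") {
    usable <- which(ok)
    # with >= 2 events the first segment is usually the still-folded
    # state; keep it out of the joint (p, L) fit and profile it afterwards
    joint <- if (length(usable) > 2) setdiff(usable, 1L) else usable
    if (length(joint)) {
      fj <- fit_combined_joint(idx_by_seg[joint])
      p_hat <- fj$p
      n_tot <- fj$n
      # polish every contour at the shared p in the full objective
      for (s in usable) {
        fu <- fit_unfolded(idx_by_seg[[s]], p_hat)
        L_fit[s] <- fu$L_ss
        ss_tot <- ss_tot + fu$ss
        if (!s %in% joint) n_tot <- n_tot + fu$n
      }
    } else p_hat <- 25
  } else {
    if (ok[1]) {
      f0 <- fit_folded(idx_by_seg[[1]])
      p_hat <- f0$p
      L_fit[1] <- 0
      ss_tot <- ss_tot + f0$ss; n_tot <- n_tot + f0$n
    } else {
      p_hat <- 25                 # fall back to a typical fitted value
    }
    if (n_seg > 1) {
      for (s in 2:n_seg) {
        if (!ok[s]) next
        fu <- fit_unfolded(idx_by_seg[[s]], p_hat)
        L_fit[s] <- fu$L_ss
        ss_tot <- ss_tot + fu$ss; n_tot <- n_tot + fu$n
      }
    }
  }

  ev <- dplyr::arrange(events, .data$index)
  if (nrow(ev)) {
    for (e in seq_len(nrow(ev))) {
      before <- L_fit[e]; after <- L_fit[e + 1]
      if (is.na(before) || is.na(after)) next
      dL <- after - before
      if (e == 1 && ok[1] && first_segment == "folded") dL <- dL - closure
      ev$delta_L_nm[e] <- dL
    }
  }
  m <- trace_meta(trace)
  structure(
    list(handles_fit = wlc_params(p_hat, L_h, temperature),
         ssdna_fits = tibble::tibble(
           segment = seq_len(n_seg),
           L_ssDNA_nm = L_fit,
           n_points = vapply(idx_by_seg, length, 1L)),
         events = ev,
         residual_rms = if (n_tot > 0) sqrt(ss_tot / n_tot) else NA_real_,
         tether_id = m$tether_id, direction = m$direction,
         trap_stiffness = m$trap_stiffness),
    class = "trace_fit")
}

#' @export
print.trace_fit <- function(x, ...) {
  cat(sprintf("<trace_fit> tether %s (%s): %d event(s), p_dsDNA = %.1f nm, rms = %.3g pN\n",
              x$tether_id, x$direction, nrow(x$events),
              x$handles_fit$persistence_length, x$residual_rms))
  invisible(x)
}

#' Detect and fit a trace in one call
#'
#' Convenience pipeline: [detect_events()] followed by [fit_segments()],
#' returning a tidy per-event table ready for population analysis.
#'
#' @inheritParams detect_events
#' @inheritParams fit_segments
#' @param ... Passed on to [fit_segments()].
#' @return A tibble with one row per event: `tether_id`, `direction`,
#'   `index`, `time_s`, `force_pN`, `delta_L_nm`, `nt_estimate`, `label`.
#' @export
analyze_trace <- function(trace, min_force_drop = 0.5, smoothing_window = 51,
                          reliable_floor = 1,
                          first_segment = c("folded", "combined"), ...) {
  first_segment <- match.arg(first_segment)
  ev <- detect_events(trace, min_force_drop, smoothing_window, reliable_floor)
  if (nrow(ev) == 0) {
    return(tibble::tibble(tether_id = character(), direction = character(),
                          index = integer(), time_s = numeric(),
                          force_pN = numeric(), delta_L_nm = numeric(),
                          nt_estimate = numeric(), label = character()))
  }
  fit <- fit_segments(trace, ev, first_segment = first_segment, ...)
  ev <- fit$events
  # a single rip out of the folded state is complete unfolding
  full <- nrow(ev) == 1 && first_segment == "folded"
  tibble::tibble(
    tether_id = fit$tether_id,
    direction = ev$direction,
    index = ev$index, time_s = ev$time_s,
    force_pN = ev$force_at_event,
    delta_L_nm = ev$delta_L_nm,
    nt_estimate = ifelse(is.na(ev$delta_L_nm), NA_real_,
                         delta_L_to_nucleotides(pmax(ev$delta_L_nm, 1e-9),
                                                full_unfolding = full)$nt),
    label = ev$label)
}

#' Measure the contour-length change of the major unfolding event
#'
#' Two-pass analysis of a pulling trace of a hairpin that unfolds through
#' a mechanically stable intermediate. The major rip is located with a
#' robust detection threshold (`major_drop`). Because the preceding minor
#' step can be too shallow to detect reliably, the region before the
#' major rip is then re-scanned at a sensitive threshold (`minor_drop`)
#' and the last candidate transition is taken as the lower segment
#' boundary: whatever that candidate is, the segment between it and the
#' major rip is in the intermediate state. Both flanking segments are fit
#' jointly ([fit_segments()] with `first_segment = "combined"`) and the
#' major contour-length change is the difference of their fitted ssDNA
#' contours.
#'
#' @param trace A [fe_trace()] pulling trace.
#' @param major_drop Detection threshold for the major rip (pN,
#'   default 0.35, several times the smoothed noise floor).
#' @param minor_drop Sensitive re-scan threshold (pN, default 0.15).
#' @param ... Passed to [fit_segments()].
#' @return A one-row tibble (`tether_id`, `direction`, `index`, `time_s`,
#'   `force_pN`, `delta_L_nm`, `nt_estimate`, `label = "major"`), or a
#'   zero-row tibble if no major rip was found.
#' @export
analyze_major_event <- function(trace, major_drop = 0.35, minor_drop = 0.15,
                                ...) {
  empty <- tibble::tibble(tether_id = character(), direction = character(),
                          index = integer(), time_s = numeric(),
                          force_pN = numeric(), delta_L_nm = numeric(),
                          nt_estimate = numeric(), label = character())
  ev <- detect_events(trace, min_force_drop = major_drop)
  maj <- ev[ev$label == "major" & ev$direction == "unfold", ]
  if (nrow(maj) != 1) return(empty)
  sens <- detect_events(trace, min_force_drop = minor_drop)
  pre <- sens[sens$index < maj$index - 300L, ]   # leave room to fit
  bounds <- maj
  if (nrow(pre) > 0) {
    last_pre <- pre[nrow(pre), ]
    last_pre$label <- "minor"
    bounds <- dplyr::bind_rows(last_pre, maj)
  }
  fit <- fit_segments(trace, bounds, first_segment = "combined", ...)
  evf <- fit$events[fit$events$label == "major", ]
  if (nrow(evf) != 1 || is.na(evf$delta_L_nm)) return(empty)
  tibble::tibble(tether_id = fit$tether_id, direction = "unfold",
                 index = evf$index, time_s = evf$time_s,
                 force_pN = evf$force_at_event,
                 delta_L_nm = evf$delta_L_nm,
                 nt_estimate = evf$delta_L_nm / hp_constants$nm_per_nt,
                 label = "major")
}

#' Convert a contour-length change to nucleotides
#'
#' Uses the ssDNA contour length of 0.68 nm per nucleotide. For complete
#' unfolding of a hairpin the 2 nm end-to-end distance of the closed
#' hairpin is restored before dividing, `nt = (delta_L + 2) / 0.68`, so a
#' 64-nt hairpin corresponds to a 41.52 nm contour-length change. For an
#' intermediate (partial) step no closure term applies and
#' `nt = delta_L / 0.68`, matching the 23.8 nm released by a 35-nt apical
#' stem.
#'
#' @param delta_L Contour-length change(s) in nm (> 0).
#' @param full_unfolding Logical: complete unfolding (`TRUE`) or an
#'   intermediate step (`FALSE`, default).
#' @param delta_L_sd Optional standard deviation(s) of `delta_L`;
#'   propagated linearly.
#' @return A tibble with columns `delta_L_nm`, `nt` and `nt_sd`.
#' @examples
#' delta_L_to_nucleotides(41.52, full_unfolding = TRUE)  # 64 nt
#' delta_L_to_nucleotides(23.8)                          # 35 nt
#' @export
delta_L_to_nucleotides <- function(delta_L, full_unfolding = FALSE,
                                   delta_L_sd = NULL) {
  stopifnot(is.numeric(delta_L), all(delta_L > 0))
  add <- if (full_unfolding) hp_constants$hairpin_closure_nm else 0
  nt <- (delta_L + add) / hp_constants$nm_per_nt
  sd <- if (is.null(delta_L_sd)) rep(NA_real_, length(nt))
        else delta_L_sd / hp_constants$nm_per_nt
  tibble::tibble(delta_L_nm = delta_L, nt = nt, nt_sd = sd)
}

#' Expected contour-length change for a given number of nucleotides
#'
#' Inverse of [delta_L_to_nucleotides()]: `nt * 0.68 - 2` nm for complete
#' unfolding, `nt * 0.68` nm for an intermediate step.
#'
#' @param nt Number(s) of nucleotides (>= 1).
#' @param full_unfolding Logical, as in [delta_L_to_nucleotides()].
#' @return Contour-length change(s) in nm.
#' @examples
#' expected_delta_L(64, full_unfolding = TRUE)  # 41.52 nm
#' expected_delta_L(35)                         # 23.8 nm
#' @export
expected_delta_L <- function(nt, full_unfolding = FALSE) {
  stopifnot(is.numeric(nt), all(nt >= 1))
  sub <- if (full_unfolding) hp_constants$hairpin_closure_nm else 0
  nt * hp_constants$nm_per_nt - sub
}
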