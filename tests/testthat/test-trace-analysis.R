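test_that("contour-length / nucleotide conversions match the ruler", {
  # complete unfolding restores the 2 nm closure before dividing
  expect_equal(delta_L_to_nucleotides(41.52, full_unfolding = TRUE)$nt, 64)
  expect_equal(delta_L_to_nucleotides(23.8)$nt, 35)
  expect_equal(delta_L_to_nucleotides(0.68)$nt, 1)
  expect_equal(expected_delta_L(64, full_unfolding = TRUE), 41.52)
  expect_equal(expected_delta_L(35), 23.8)
  expect_equal(expected_delta_L(28), 19.04)
  # exact inverses for any count, both conventions
  nt <- 1:80
  expect_equal(delta_L_to_nucleotides(expected_delta_L(nt + 3,
                                                       full_unfolding = TRUE),
                                      full_unfolding = TRUE)$nt, nt + 3)
  expect_equal(delta_L_to_nucleotides(expected_delta_L(nt))$nt, nt)
  # linear uncertainty propagation
  expect_equal(delta_L_to_nucleotides(23.8, delta_L_sd = 1.36)$nt_sd, 2)
})

test_that("a noiseless single rip is detected at the right place", {
  sim <- simulate_pull(seed = 71, noise_sd = 0, intermediate_nt = NULL)
  expect_equal(nrow(sim$events), 1)
  ev <- detect_events(sim$trace)
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$index - sim$events$index), 3)
  expect_equal(ev$direction, "unfold")
  expect_equal(ev$label, "major")
})

test_that("a monotone trace yields no events and short traces error", {
  sim <- simulate_pull(seed = 72, noise_sd = 0, transitions_enabled = FALSE)
  expect_equal(nrow(detect_events(sim$trace)), 0)
  short <- fe_trace(seq(0, 0.001, length.out = 40), 1:40, rep(1, 40),
                    200, 50000, 0.06)
  expect_error(detect_events(short), "smoothing window")
})

test_that("a low-noise two-step trace yields two ordered events", {
  sim <- simulate_pull(seed = 77, noise_sd = 0.05)
  expect_equal(sim$events$state_to, c("intermediate", "unfolded"))
  ev <- detect_events(sim$trace, min_force_drop = 0.15)
  unf <- ev[ev$direction == "unfold", ]
  expect_equal(nrow(unf), 2)
  expect_true(all(diff(unf$index) > 0))
  expect_equal(unf$label, c("minor", "major"))
})

test_that("rips below the reliable-detection floor are unassigned", {
  # fast unfolding with refolding disabled puts the single rip below 1 pN
  kin <- sim_kinetics(k0_major = 8, dx_major = 10, k0_refold_major = 1e-30)
  sim <- simulate_pull(seed = 73, noise_sd = 0, intermediate_nt = NULL,
                       kinetics = kin)
  expect_equal(nrow(sim$events), 1)
  expect_lt(sim$events$force_pN[1], 1)
  ev <- detect_events(sim$trace, min_force_drop = 0.1)
  expect_true(all(ev$label == "unassigned"))
})

test_that("zero-noise fits recover the contour-length change nearly exactly", {
  sim <- simulate_pull(seed = 74, noise_sd = 0, intermediate_nt = NULL)
  fit <- fit_segments(sim$trace, detect_events(sim$trace))
  expect_lt(abs(fit$events$delta_L_nm - 41.52), 0.05)
  expect_lt(abs(fit$handles_fit$persistence_length - 22), 0.1)
  expect_lt(fit$residual_rms, 1e-3)
})

test_that("noisy single-rip pulls recover randomized contour changes", {
  set.seed(21)
  err <- c()
  for (rep in 1:60) {
    dl_true <- runif(1, 15, 45)
    nt <- round((dl_true + 2) / 0.68)
    sim <- simulate_pull(seed = 9000 + rep, intermediate_nt = NULL,
                         total_nt = nt)
    ev <- detect_events(sim$trace, min_force_drop = 0.3)
    if (nrow(ev) != 1) next
    fit <- suppressWarnings(fit_segments(sim$trace, ev))
    err <- c(err, fit$events$delta_L_nm - expected_delta_L(nt, TRUE))
  }
  expect_gt(length(err), 45)
  expect_lte(median(abs(err)), 0.5)
  expect_lte(abs(mean(err)), 0.2)
})

test_that("segments entirely below the fit floor give NA without crashing", {
  sim <- simulate_pull(seed = 75, noise_sd = 0, intermediate_nt = NULL)
  # fabricate an event while the force is still far below 2 pN
  early <- max(which(sim$trace$force_pN < 1))
  ev <- tibble::tibble(index = c(early %/% 2, sim$events$index),
                       time_s = sim$trace$time_s[c(early %/% 2,
                                                   sim$events$index)],
                       force_at_event = c(0.5, sim$events$force_pN),
                       drop_pN = c(0.2, 0.8), direction = "unfold",
                       delta_L_nm = NA_real_, label = c("minor", "major"))
  expect_warning(fit <- fit_segments(sim$trace, ev), "fewer than")
  expect_true(is.na(fit$events$delta_L_nm[1]))
})

test_that("fits are stable under uniform subsampling of the trace", {
  sim <- simulate_pull(seed = 76, intermediate_nt = NULL)
  tr <- sim$trace
  fit1 <- fit_segments(tr, detect_events(tr))
  keep <- seq(1, nrow(tr), by = 5)
  tr5 <- fe_trace(tr$time_s[keep], tr$separation_nm[keep],
                  tr$force_pN[keep],
                  pulling_velocity = attr(tr, "pulling_velocity"),
                  sampling_rate = attr(tr, "sampling_rate") / 5,
                  trap_stiffness = attr(tr, "trap_stiffness"),
                  direction = attr(tr, "direction"),
                  tether_id = attr(tr, "tether_id"))
  fit5 <- fit_segments(tr5, detect_events(tr5, smoothing_window = 11))
  expect_lt(abs(fit1$events$delta_L_nm[1] - fit5$events$delta_L_nm[1]), 0.3)
})

test_that("trace files round-trip through CSV plus JSON sidecar", {
  sim <- simulate_pull(seed = 78, intermediate_nt = NULL)
  path <- file.path(tempdir(), "trace-rt.csv")
  write_fe_trace(sim$trace, path)
  back <- read_fe_trace(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(sim$trace),
               tolerance = 1e-12)
  expect_equal(attr(back, "trap_stiffness"), attr(sim$trace, "trap_stiffness"))
  expect_equal(attr(back, "direction"), "pull")
  expect_error(read_fe_trace(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("relax sweeps show refolding events detectable as force rises", {
  sim <- simulate_pull(seed = 79, direction = "relax", noise_sd = 0.05)
  refolds <- sim$events[sim$events$direction == "refold", ]
  expect_gt(nrow(refolds), 0)
  ev <- detect_events(sim$trace, min_force_drop = 0.15)
  expect_true(all(ev$direction == "refold"))
  expect_gt(nrow(ev), 0)
})
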