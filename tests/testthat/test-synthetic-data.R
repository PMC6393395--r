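test_that("with transitions disabled the trace lies on the folded WLC curve", {
  sim <- simulate_pull(seed = 81, noise_sd = 0, transitions_enabled = FALSE)
  expect_equal(nrow(sim$events), 0)
  m <- construct_model(wlc_params(22, 580), NULL, folded_end_to_end = 2,
                       trap_stiffness = 0.06)
  ext <- sim$trace$separation_nm - sim$trace$force_pN / 0.06
  resid <- sim$trace$force_pN - construct_force(m, ext)
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("ground-truth contour changes follow the nucleotide ruler", {
  sim <- simulate_pull(seed = 82, intermediate_nt = 35, total_nt = 64)
  ev <- sim$events
  # the intermediate -> unfolded step releases the apical stem exactly
  expect_equal(ev$delta_L_nm[ev$state_to == "unfolded"],
               expected_delta_L(35))
  # steps out of the folded state carry the closure correction
  expect_equal(ev$delta_L_nm[ev$state_from == "folded"],
               expected_delta_L(64 - 35) - 2)
  expect_true(all(ev$force_pN > 0))
})

test_that("identical seeds give identical traces and cohorts", {
  a <- simulate_pull(seed = 83)
  b <- simulate_pull(seed = 83)
  expect_identical(a$trace$force_pN, b$trace$force_pN)
  expect_identical(a$events, b$events)
  ca <- generate_cohort(n_tethers = 2, pulls_per_tether = 2, seed = 84)
  cb <- generate_cohort(n_tethers = 2, pulls_per_tether = 2, seed = 84)
  expect_identical(ca$ground_truth, cb$ground_truth)
  expect_identical(ca$traces[[3]]$force_pN, cb$traces[[3]]$force_pN)
})

test_that("degenerate mixture weights pin every pull to one conformer", {
  coh <- generate_cohort(n_tethers = 3, pulls_per_tether = 2,
                         conformer_weights = c(straight = 1, kinked = 0),
                         seed = 85)
  gt <- coh$ground_truth
  expect_true(all(gt$conformer == "straight"))
  expect_equal(unique(gt$delta_L_nm[gt$state_to == "unfolded"]),
               expected_delta_L(35))
})

test_that("conformer draws stay inside the binomial 95% band", {
  coh <- generate_cohort(n_tethers = 65, pulls_per_tether = 1, seed = 86)
  gt <- coh$ground_truth
  draws <- gt$conformer[!duplicated(paste(gt$tether_id, gt$pull))]
  n <- length(draws)
  k <- sum(draws == "straight")
  expect_gte(k, qbinom(0.025, n, 0.8))
  expect_lte(k, qbinom(0.975, n, 0.8))
})

test_that("the default calibration puts the major rip near 5.7 pN", {
  set.seed(87)
  forces <- replicate(150, {
    sim <- simulate_pull(seed = sample.int(2^31 - 1, 1))
    f <- sim$events$force_pN[sim$events$state_to == "unfolded"]
    if (length(f)) f[1] else NA
  })
  expect_lt(abs(mean(forces, na.rm = TRUE) - 5.7), 0.3)
})

test_that("detection recovers the simulated rip count for rips above 2 pN", {
  # single-step unfolding gives one well-resolved rip per pull
  hits <- 0; n_ok <- 0
  for (s in 1:40) {
    sim <- simulate_pull(seed = 8800 + s, intermediate_nt = NULL)
    truth <- sim$events[sim$events$force_pN >= 2, ]
    if (nrow(truth) != 1) next
    n_ok <- n_ok + 1
    ev <- detect_events(sim$trace)
    hits <- hits + (sum(ev$direction == "unfold") == 1)
  }
  expect_gte(hits / n_ok, 0.95)
})

test_that("kinetics with no reachable rip warn and return an empty log", {
  kin <- sim_kinetics(k0_minor = 1e-30, k0_major = 1e-30)
  expect_warning(sim <- simulate_pull(seed = 89, kinetics = kin),
                 "no transition")
  expect_equal(nrow(sim$events), 0)
  expect_gt(nrow(sim$trace), 1000)
})

test_that("designed sites verify their intended ensembles", {
  site <- generate_attc_like_site(seed = 90)
  ens <- subopt_window(site$sequence)
  expect_equal(as.character(classify_conformation(ens[[1]], site$boxes)),
               "straight_complete")
  expect_equal(intermediate_size(ens[[1]], site$boxes), 35L)
  shifted <- generate_attc_like_site(seed = 91, register_shift = TRUE)
  cls <- vapply(subopt_window(shifted$sequence), function(st)
    as.character(classify_conformation(st, shifted$boxes)), "")
  expect_true("kinked_complete" %in% cls)
  # annotations come out ordered R'' < L'' < VTS < L' < R'
  bx <- site$boxes
  expect_true(bx$R_outer[2] < bx$L_outer[1] &&
                bx$L_outer[2] < bx$vts[1] &&
                bx$vts[2] < bx$L_inner[1] &&
                bx$L_inner[2] < bx$R_inner[1])
  expect_error(generate_attc_like_site(seed = 1, r_stem = 4, l_stem = 6,
                                       vts = 4), "50-80")
})

test_that("trace plots render with event annotations", {
  sim <- simulate_pull(seed = 92)
  ev <- detect_events(sim$trace, min_force_drop = 0.3)
  expect_s3_class(autoplot(sim$trace, events = ev), "ggplot")
})
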