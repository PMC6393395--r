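test_that("WLC force reproduces closed-form anchor points", {
  # at half extension the bracket equals 1.25 exactly
  handles <- wlc_params(20, 580, 298.15)
  expect_equal(wlc_force(handles, 0), 0)
  expect_equal(wlc_force(handles, 290), 1.25 * 0.0138065 * 298.15 / 20,
               tolerance = 1e-12)
  ssdna <- wlc_params(2, 41.52, 298.15)
  expect_equal(wlc_force(ssdna, 20.76), 1.25 * 0.0138065 * 298.15 / 2,
               tolerance = 1e-12)
  # force scales linearly with temperature at fixed fractional extension
  hot <- wlc_params(20, 580, 350)
  expect_equal(wlc_force(hot, 290) / wlc_force(handles, 290), 350 / 298.15)
})

test_that("WLC force is strictly increasing and diverges toward L", {
  set.seed(11)
  for (rep in 1:10) {
    p <- runif(1, 0.5, 60); L <- runif(1, 10, 1000)
    pars <- wlc_params(p, L)
    x <- seq(0, 0.999 * L, length.out = 400)
    expect_true(all(diff(wlc_force(pars, x)) > 0))
  }
  pars <- wlc_params(20, 580)
  expect_gt(wlc_force(pars, 580 * (1 - 1e-6)), 1e8 * wlc_force(pars, 290))
})

test_that("force and extension invert each other to stated tolerances", {
  set.seed(12)
  for (rep in 1:1000) {
    pars <- wlc_params(runif(1, 0.5, 60), runif(1, 5, 1000),
                       runif(1, 273, 320))
    x0 <- runif(1, 1e-3, 0.995) * pars$contour_length
    expect_lt(abs(wlc_extension(pars, wlc_force(pars, x0)) - x0), 1e-6)
    F0 <- runif(1, 1e-3, 80)
    expect_lt(abs(wlc_force(pars, wlc_extension(pars, F0)) - F0), 1e-9)
  }
  # extension vanishes with the force
  expect_lt(wlc_extension(wlc_params(20, 580), 1e-8), 1e-3)
})

test_that("domain violations are rejected", {
  pars <- wlc_params(20, 580)
  expect_error(wlc_force(pars, -1), "extension")
  expect_error(wlc_force(pars, 580), "extension")
  expect_error(wlc_extension(pars, 0), "positive")
  expect_error(wlc_extension(pars, -2), "positive")
  expect_error(wlc_params(-1, 580), "persistence")
  expect_error(wlc_params(20, 0), "contour")
  expect_error(construct_model(pars, trap_stiffness = 100), "trap_stiffness")
})

test_that("low-extension WLC force approaches the entropic spring", {
  set.seed(13)
  for (rep in 1:20) {
    pars <- wlc_params(runif(1, 1, 50), runif(1, 20, 800))
    x <- runif(1, 0.01, 0.1) * pars$contour_length
    spring <- 1.5 * 0.0138065 * pars$temperature * x /
      (pars$persistence_length * pars$contour_length)
    expect_lt(abs(wlc_force(pars, x) - spring) / spring, 0.10)
  }
})

test_that("the serial construct adds element extensions at equal force", {
  handles <- wlc_params(20, 580)
  ssdna <- wlc_params(2, 41.52)
  m <- construct_model(handles, ssdna, trap_stiffness = 0.06)
  F <- c(0.5, 2.573, 5, 12)
  expect_equal(construct_extension(m, F),
               wlc_extension(handles, F) + wlc_extension(ssdna, F))
  # folded hairpin contributes only its fixed end-to-end distance
  mf <- construct_model(handles, NULL, folded_end_to_end = 2,
                        trap_stiffness = 0.06)
  expect_equal(construct_extension(mf, F), wlc_extension(handles, F) + 2)
  # zero-contour ssDNA degenerates to bare handles
  m0 <- construct_model(handles, wlc_params(2, 1e-12),
                        folded_end_to_end = 0, trap_stiffness = 0.06)
  expect_equal(construct_extension(m0, F), wlc_extension(handles, F),
               tolerance = 1e-9)
})

test_that("construct force inverts construct extension and is monotone", {
  m <- construct_model(wlc_params(22, 580), wlc_params(2, 43.52),
                       trap_stiffness = 0.06)
  F <- seq(0.05, 25, length.out = 50)
  xi <- construct_extension(m, F)
  expect_true(all(diff(construct_force(m, xi)) > 0))
  expect_lt(max(abs(construct_extension(m, construct_force(m, xi)) - xi)),
            1e-6)
  expect_lt(max(abs(construct_force(m, xi) - F)), 1e-6)
  expect_error(construct_force(m, 1e5), "reachable")
  expect_error(construct_force(m, -3), "reachable")
})
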