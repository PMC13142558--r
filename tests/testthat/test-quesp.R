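# QUESP: saturation efficiency, the CW MTRasym solution, the three fitting
# routes, steady-state warnings, MTRasym extraction.

test_that("saturation efficiency limits are exact", {
  kb <- 700
  b1_eq <- kb / GAMMA_RAD_PER_UT  # w1 == kb
  expect_equal(alpha_efficiency(b1_eq, kb), 0.5)
  expect_equal(alpha_efficiency(0, 500), 0)
  expect_equal(alpha_efficiency(3, 0), 1)
})

test_that("the CW MTRasym solution vanishes at tp = 0 for random draws", {
  set.seed(77)
  for (k in 1:200) {
    v <- mtrasym_model(runif(1, 1e-5, 5e-3), runif(1, 10, 5000),
                       runif(1, 0.5, 8), runif(1, 0.2, 2), 0,
                       zi = runif(1, -1, 1))
    expect_lt(abs(v), 1e-12)
  }
})

test_that("the tp -> infinity limit equals the steady-state ratio", {
  # choose fb*kb*alpha = R1a so the limit is exactly 0.5
  r1a <- 0.33; kb <- 1000; b1 <- 4
  a <- alpha_efficiency(b1, kb)
  fb <- r1a / (kb * a)
  expect_equal(mtrasym_model(fb, kb, b1, r1a, 1e4), 0.5, tolerance = 1e-12)
})

test_that("the model matches an independently coded evaluation to 1e-12", {
  # second evaluator, written directly from the closed-form solution
  oracle <- function(fb, kb, b1, r1a, tp, zi) {
    g <- 2 * pi * 42.577
    w1 <- g * b1
    a <- w1^2 / (w1^2 + kb^2)
    R <- r1a + fb * kb * a
    (fb * kb * a) / R + (zi - 1) * exp(-r1a * tp) -
      (zi - r1a / R) * exp(-R * tp)
  }
  set.seed(88)
  for (k in 1:100) {
    fb <- runif(1, 1e-5, 5e-3); kb <- runif(1, 50, 5000)
    b1 <- runif(1, 0.5, 8); r1a <- runif(1, 0.2, 2)
    tp <- runif(1, 0.1, 10); zi <- runif(1, -1, 1)
    expect_equal(mtrasym_model(fb, kb, b1, r1a, tp, zi),
                 oracle(fb, kb, b1, r1a, tp, zi), tolerance = 1e-12)
  }
  expect_equal(mtrasym_model(1e-3, 1000, 4, 0.33, 4, 1),
               oracle(1e-3, 1000, 4, 0.33, 4, 1), tolerance = 1e-12)
})

test_that("noiseless MTRasym series are inverted within 1%", {
  b1 <- c(1, 2, 3, 4, 6); fb <- 7.2e-4; kb <- 800; r1a <- 0.33; tp <- 4
  y <- mtrasym_model(fb, kb, b1, r1a, tp)
  fit <- fit_quesp(quesp_series(b1, tp, mtr_asym = y, r1a = r1a), "mtr_asym")
  expect_lt(abs(fit$fb$values[1, 1] / fb - 1), 0.01)
  expect_lt(abs(fit$kb$values[1, 1] / kb - 1), 0.01)
})

test_that("mtr_rex and omega_plot agree as algebraic rearrangements", {
  b1 <- c(1, 2, 3, 4, 6); fb <- 9e-4; kb <- 1200; r1a <- 0.4
  rex <- mtrrex_model(fb, kb, b1, r1a)
  z_ref <- rep(0.95, length(b1))
  z_lab <- 1 / (rex + 1 / z_ref)
  s <- quesp_series(b1, tp_s = 15, z_lab = z_lab, z_ref = z_ref, r1a = r1a)
  f_rex <- fit_quesp(s, "mtr_rex")
  f_om <- fit_quesp(s, "omega_plot")
  for (f in list(f_rex, f_om)) {
    expect_lt(abs(f$fb$values[1, 1] / fb - 1), 0.01)
    expect_lt(abs(f$kb$values[1, 1] / kb - 1), 0.01)
  }
  expect_lt(abs(f_rex$fb$values[1, 1] / f_om$fb$values[1, 1] - 1), 0.01)
  expect_lt(abs(f_rex$kb$values[1, 1] / f_om$kb$values[1, 1] - 1), 0.01)
})

test_that("all-zero MTRasym collapses to the fb lower bound, flagged", {
  b1 <- c(1, 2, 3, 4)
  f <- fit_quesp(quesp_series(b1, 4, mtr_asym = rep(0, 4), r1a = 0.33),
                 "mtr_asym")
  expect_lt(f$fb$values[1, 1], 1e-5)
  expect_true(is.na(f$r2$values[1, 1]) || f$r2$values[1, 1] < 0.5)
})

test_that("parameter recovery under noise keeps median kb error < 15%", {
  b1 <- c(1, 2, 3, 4, 6); fb <- 7.2e-4; kb <- 800; r1a <- 0.33; tp <- 4
  y0 <- mtrasym_model(fb, kb, b1, r1a, tp)
  set.seed(55)
  errs <- vapply(1:100, function(k) {
    y <- y0 + stats::rnorm(length(b1), sd = 0.002)
    f <- fit_quesp(quesp_series(b1, tp, mtr_asym = y, r1a = r1a), "mtr_asym")
    abs(f$kb$values[1, 1] / kb - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.15)
})

test_that("the CW solution matches full simulation in the dilute regime", {
  r1a <- 0.33
  w <- pool_parameters("water", 1, 0, 0, r1 = r1a, r2 = 0.5)
  for (kb in c(200, 800, 2000)) {
    fb <- 5e-4
    s <- pool_parameters("solute", fb, kb, 3.5, r1 = 1, r2 = 30)
    for (b1 in c(1, 2)) {
      tp <- 6
      zlab <- simulate_z(list(w, s), saturation_event(b1, tp, 3.5), 300)
      zref <- simulate_z(list(w, s), saturation_event(b1, tp, -3.5), 300)
      pred <- mtrasym_model(fb, kb, b1, r1a, tp)
      expect_lt(abs((zref - zlab) / pred - 1), 0.10)
    }
  }
})

test_that("steady-state warnings trigger on the stated conditions", {
  p_ok <- acquisition_params(sat_time_s = 10, recovery_time_s = 10)
  expect_silent(msgs <- steady_state_warning(p_ok, r1a = 1 / 1.8))
  expect_length(msgs, 0)
  p_short <- acquisition_params(sat_time_s = 2, recovery_time_s = 10)
  expect_warning(m1 <- steady_state_warning(p_short, 1 / 1.8),
                 "steady-state")
  expect_length(m1, 1)
  p_rec <- acquisition_params(sat_time_s = 10, recovery_time_s = 1)
  expect_warning(m2 <- steady_state_warning(p_rec, 1 / 1.8), "relax")
})

test_that("MTRasym extraction is zero on symmetric spectra, errors one-sided", {
  offs <- seq(-5, 5, by = 0.5)
  z <- 1 - lorentzian(0.8, 1.4, 0, offs)   # symmetric water line
  data <- array(rep(z, each = 1), dim = c(length(offs), 4, 4))
  for (k in seq_along(offs)) data[k, , ] <- z[k]
  st <- offset_stack(data, offs, normalized = TRUE)
  st$normalized <- TRUE
  asym <- mtrasym_from_stack(st, 3.5)
  expect_lt(max(abs(asym)), 1e-12)
  # add a label dip at +2 ppm -> positive MTRasym
  z2 <- z - lorentzian(0.05, 1, 2, offs)
  for (k in seq_along(offs)) data[k, , ] <- z2[k]
  st2 <- offset_stack(data, offs, normalized = TRUE)
  st2$normalized <- TRUE
  expect_gt(min(mtrasym_from_stack(st2, 2)), 0.02)
  one_sided <- offset_stack(data[offs >= -1, , , drop = FALSE], offs[offs >= -1])
  one_sided$normalized <- TRUE
  expect_error(mtrasym_from_stack(one_sided, 2), "one-sided")
})

test_that("QUESP series validation enforces the B1 precondition", {
  expect_error(quesp_series(c(1, 1, 2), 4, mtr_asym = 1:3, r1a = 1),
               "3 distinct")
  expect_error(quesp_series(c(1, 2, 3), 0, mtr_asym = 1:3, r1a = 1), "tp")
})
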