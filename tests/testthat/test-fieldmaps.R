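# WASSR B0, double-angle B1, spline upsampling, T1 mapping, per-segment
# field statistics.

test_that("WASSR recovers uniform and symmetric dips", {
  spec <- phantom_spec(shape = c(6, 6),
                       regions = list(all = matrix(TRUE, 6, 6)),
                       truth = list(all = list(b0_ppm = 0.12)), seed = 2)
  b <- make_field_fixtures(spec)
  w <- normalize_zspectrum(b$members$wassr)
  m <- wassr_b0(w)
  expect_true(all(m$valid_mask))
  expect_lt(max(abs(m$values - 0.12)), 0.005)
  spec0 <- phantom_spec(shape = c(4, 4),
                        regions = list(all = matrix(TRUE, 4, 4)),
                        truth = list(all = list(b0_ppm = 0)), seed = 2)
  m0 <- wassr_b0(normalize_zspectrum(make_field_fixtures(spec0)$members$wassr))
  expect_lt(max(abs(m0$values)), 1e-3)
})

test_that("WASSR tracks a linear B0 gradient within 0.01 ppm", {
  n <- 8
  grad <- matrix(seq(-0.2, 0.2, length.out = n), n, n, byrow = TRUE)
  spec <- phantom_spec(shape = c(n, n),
                       regions = list(all = matrix(TRUE, n, n)),
                       truth = list(all = list(b0_ppm = grad)), seed = 4)
  b <- make_field_fixtures(spec)
  m <- wassr_b0(normalize_zspectrum(b$members$wassr))
  expect_lt(max(abs(m$values - grad)), 0.01)
  expect_gt(stats::cor(as.vector(m$values), as.vector(grad)), 0.999)
})

test_that("WASSR axis shifts move every fitted center equivariantly", {
  spec <- phantom_spec(shape = c(4, 4),
                       regions = list(all = matrix(TRUE, 4, 4)),
                       truth = list(all = list(b0_ppm = 0.05)), seed = 6)
  b <- make_field_fixtures(spec)
  w <- normalize_zspectrum(b$members$wassr)
  m1 <- wassr_b0(w)
  w2 <- w
  w2$offsets_ppm <- w$offsets_ppm + 0.1
  m2 <- wassr_b0(w2)
  expect_equal(m2$values, m1$values + 0.1, tolerance = 1e-3)
})

test_that("double-angle kappa follows the arccosine identity", {
  # M_theta = M_2theta -> cos(theta) = 1/2 -> theta = 60 deg
  m1 <- matrix(0.866, 3, 3)
  k <- dam_b1(m1, m1, 60)
  expect_equal(k$values, matrix(1, 3, 3), tolerance = 1e-6)
  # equal unit signals at 45 deg nominal: theta = 60, kappa = 60/45
  k2 <- dam_b1(matrix(1, 2, 2), matrix(1, 2, 2), 45)
  expect_equal(k2$values[1, 1], 60 / 45, tolerance = 1e-10)
  # domain violation -> invalid pixel
  k3 <- dam_b1(matrix(1, 2, 2), matrix(2.2, 2, 2), 45)
  expect_false(any(k3$valid_mask))
  expect_error(dam_b1(matrix(1, 2, 2), matrix(1, 3, 3), 45), "dimensions")
})

test_that("kappa is invariant to common scaling of the image pair", {
  spec <- phantom_spec(shape = c(8, 8),
                       regions = list(all = matrix(TRUE, 8, 8)),
                       truth = list(all = list(kappa = 1.1)), seed = 9)
  b <- make_field_fixtures(spec)
  th <- b$members$truth$theta_nominal_deg
  k1 <- dam_b1(b$members$dam_theta$image, b$members$dam_2theta$image, th)
  k2 <- dam_b1(3.7 * b$members$dam_theta$image,
               3.7 * b$members$dam_2theta$image, th)
  expect_equal(k1$values, k2$values, tolerance = 1e-12)
  expect_lt(max(abs(k1$values - 1.1)), 1e-6)
})

test_that("a kappa ramp is recovered within 1%", {
  n <- 10
  ramp <- matrix(seq(0.8, 1.2, length.out = n), n, n)
  spec <- phantom_spec(shape = c(n, n),
                       regions = list(all = matrix(TRUE, n, n)),
                       truth = list(all = list(kappa = ramp)), seed = 10)
  b <- make_field_fixtures(spec)
  k <- dam_b1(b$members$dam_theta$image, b$members$dam_2theta$image,
              b$members$truth$theta_nominal_deg)
  expect_lt(max(abs(k$values / ramp - 1)), 0.01)
})

test_that("spline upsampling preserves constants, ramps and identity", {
  const <- pixel_map(matrix(3.2, 4, 4))
  up <- upsample_map(const, c(9, 9))
  expect_equal(up$values, matrix(3.2, 9, 9), tolerance = 1e-12)
  ramp <- pixel_map(outer(seq(0, 1, length.out = 6),
                          seq(0, 2, length.out = 6), `+`))
  up2 <- upsample_map(ramp, c(11, 11))
  oracle <- outer(seq(0, 1, length.out = 11), seq(0, 2, length.out = 11), `+`)
  expect_equal(up2$values, oracle, tolerance = 1e-10)
  same <- upsample_map(ramp, c(6, 6))
  expect_identical(same$values, ramp$values)
  expect_error(upsample_map(ramp, c(4, 4)), "target size")
})

test_that("variable-TR T1 fitting recovers truth and compartments", {
  trs <- c(0.3, 0.6, 1, 1.5, 2.5, 4, 6.5, 10)
  spec <- phantom_spec(shape = c(6, 6),
                       regions = list(all = matrix(TRUE, 6, 6)),
                       truth = list(all = list(t1_s = 1.8)), seed = 12)
  b <- make_field_fixtures(spec, tr_list_s = trs)
  t1 <- t1_map(b$members$t1_series$data, trs)
  expect_lt(max(abs(t1$values - 1.8)), 0.01)
  two <- matrix(1.0, 8, 8); two[, 5:8] <- 2.5
  spec2 <- phantom_spec(shape = c(8, 8),
                        regions = list(all = matrix(TRUE, 8, 8)),
                        truth = list(all = list(t1_s = two)), seed = 12)
  b2 <- make_field_fixtures(spec2, tr_list_s = trs)
  t2 <- t1_map(b2$members$t1_series$data, trs)
  expect_lt(abs(mean(t2$values[, 1:4]) / 1.0 - 1), 0.02)
  expect_lt(abs(mean(t2$values[, 5:8]) / 2.5 - 1), 0.02)
  expect_error(t1_map(b2$members$t1_series$data, rep(10, 8)), "degenerate")
})

test_that("T1 recovery stays unbiased at SNR 50", {
  trs <- c(0.3, 0.6, 1, 1.5, 2.5, 4, 6.5, 10)
  spec <- phantom_spec(shape = c(10, 10),
                       regions = list(all = matrix(TRUE, 10, 10)),
                       truth = list(all = list(t1_s = 1.8)),
                       noise_sd = 0.02, seed = 14)  # SNR 50
  b <- make_field_fixtures(spec, tr_list_s = trs)
  t1 <- t1_map(b$members$t1_series$data, trs)
  v <- t1$values[t1$valid_mask]
  expect_lt(abs(mean(v) / 1.8 - 1), 0.02)                 # bias < 2%
  expect_lt(sqrt(mean((v - 1.8)^2)) / 1.8, 0.05)          # RMSE < 5%
})

test_that("per-segment field statistics order with an imposed gradient", {
  n <- 64
  segs <- lv_segments(default_lv_geometry(), c(n, n))
  grad <- matrix(seq(-0.2, 0.2, length.out = n), n, n, byrow = TRUE)
  fmaps <- list(b0_ppm = pixel_map(grad, "B0 shift", "ppm"),
                kappa = pixel_map(matrix(1, n, n), "kappa", ""))
  st <- segment_field_stats(fmaps, segs)
  su <- st$summary[st$summary$quantity == "b0_ppm", ]
  med <- stats::setNames(su$median, su$segment)
  # free wall sits at higher column indices than the septum -> higher B0
  expect_gt(med[["anterolateral"]], med[["anteroseptal"]])
  expect_gt(med[["inferolateral"]], med[["inferoseptal"]])
  # uniform kappa: all segment medians equal
  ku <- st$summary[st$summary$quantity == "kappa", ]
  expect_true(all(ku$median == 1))
  # empty segment omitted with warning
  segs2 <- segment_set(list(a = segs$masks[[1]],
                            b = matrix(FALSE, n, n)), kind = "manual")
  expect_warning(st2 <- segment_field_stats(fmaps, segs2), "no valid")
  expect_false("b" %in% st2$summary$segment)
})
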