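# Shared fixture builders. All expected values in the tests are computed
# either from these generators (the truth tables) or from independent
# brute-force oracles coded inline.

# canonical three-pool truth used across the Z-spectral tests
zspec_truth <- function() {
  data.frame(name = c("water", "MT", "amide"),
             A = c(0.9, 0.1, 0.05),
             gamma_ppm = c(1.4, 25, 1.0),
             omega_ppm = c(0, -2.5, 3.5))
}

# forward sum-of-Lorentzians Z-spectrum, independent of the package's
# generator internals (re-derived from the lineshape definition)
forward_z <- function(offsets, truth = zspec_truth(), shift = 0) {
  z <- rep(1, length(offsets))
  for (i in seq_len(nrow(truth))) {
    h <- truth$gamma_ppm[i]^2 / 4
    z <- z - truth$A[i] * h / (h + (offsets - shift - truth$omega_ppm[i])^2)
  }
  z
}

std_offsets <- function() seq(-6, 6, by = 0.2)

# small offset stack with M0 frames for io / preprocessing tests
small_stack <- function(nr = 8, nc = 8, offsets = seq(-5, 5, by = 0.5),
                        m0_value = 2000, seed = 7) {
  set.seed(seed)
  all_offs <- c(-100, 100, offsets)
  z <- forward_z(offsets)
  data <- array(0, dim = c(length(all_offs), nr, nc))
  data[1, , ] <- m0_value
  data[2, , ] <- m0_value
  for (k in seq_along(offsets)) data[k + 2, , ] <- z[k] * m0_value
  offset_stack(data, all_offs,
               acquisition_params(offsets_ppm = all_offs, sat_b1_uT = 2,
                                  sat_time_s = 4,
                                  frame_times_s = seq_along(all_offs)))
}

# brute-force even-odd point-in-polygon (crossing number), used as the
# rasterization oracle
brute_inside <- function(px, py, vx, vy) {
  n <- length(vx)
  cross <- 0L
  j <- n
  for (i in seq_len(n)) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])) {
      cross <- cross + 1L
    }
    j <- i
  }
  cross %% 2L == 1L
}

circle_polygon <- function(center, radius, n = 180) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] - radius * sin(th), center[2] + radius * cos(th))
}

default_lv_geometry <- function(center = c(32, 32), r_out = 20, r_in = 12,
                                ant_deg = 180, inf_deg = 270) {
  pt <- function(deg) {
    th <- deg * pi / 180
    c(center[1] - r_out * sin(th), center[2] + r_out * cos(th))
  }
  lv_geometry(circle_polygon(center, r_out), circle_polygon(center, r_in),
              pt(ant_deg), pt(inf_deg))
}

cw_schedule <- function(b1 = rep(c(1, 3, 5, 2, 6, 4), 5), tp = 2,
                        recovery = 1.5, flip = 60, offset = 2) {
  events <- lapply(b1, function(b) saturation_event(b, tp, offset))
  mrf_schedule(events, recovery_s = recovery, flip_deg = flip)
}

small_scenario <- function(fb = seq(2e-4, 1.4e-3, length.out = 5),
                           kb = seq(200, 1400, length.out = 5),
                           r1a = c(0.3, 0.4), r2a = c(0.45, 0.55),
                           schedule = cw_schedule()) {
  mrf_scenario(field_MHz = 300, fb_grid = fb, kb_grid = kb, r1a_grid = r1a,
               r2a_grid = r2a, r1b = 1, r2b = 50, dw_ppm = 2,
               schedule = schedule)
}
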