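# Synthetic phantom generators. Every fixture ships its ground-truth table,
# so downstream tests compare estimates against the generator truth rather
# than hard-coded numbers. Geometries emulate the two experimental settings
# the toolkit targets: multi-vial creatine phantoms and mid-ventricular
# cardiac short-axis slices.

#' Specify a synthetic phantom
#'
#' @param shape image dimensions `c(rows, cols)`.
#' @param regions named list of logical matrices (pairwise disjoint) or
#'   `NULL` to use a single centered disc.
#' @param truth named list: per-region parameter lists (free-form; each
#'   generator documents what it reads).
#' @param noise_sd Gaussian noise standard deviation on the normalized
#'   signal.
#' @param seed integer seed recorded in every output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64), regions = NULL, truth = list(),
                         noise_sd = 0, seed = 1L) {
  if (is.null(regions)) {
    regions <- list(disc = disc_mask(shape, shape / 2, min(shape) / 3))
  }
  if (length(regions) > 1) {
    acc <- regions[[1]]
    for (i in 2:length(regions)) {
      if (any(acc & regions[[i]])) stop("phantom regions must be disjoint")
      acc <- acc | regions[[i]]
    }
  }
  structure(list(shape = shape, regions = regions, truth = truth,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Circular region mask
#'
#' @param shape image dimensions `c(rows, cols)`.
#' @param center `(row, col)` center.
#' @param radius radius in pixels.
#' @return logical matrix.
#' @export
disc_mask <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

#' Annulus region mask
#'
#' @param shape image dimensions.
#' @param center `(row, col)` center.
#' @param r_outer,r_inner outer and inner radii in pixels.
#' @return logical matrix.
#' @export
annulus_mask <- function(shape, center, r_outer, r_inner) {
  disc_mask(shape, center, r_outer) & !disc_mask(shape, center, r_inner)
}

# Sum-of-Lorentzians Z-spectrum from a pool parameter data frame
# (columns A, gamma_ppm, omega_ppm), evaluated at offsets shifted by b0.
zspec_forward <- function(pools_df, offsets, b0 = 0) {
  z <- rep(1, length(offsets))
  for (i in seq_len(nrow(pools_df))) {
    z <- z - lorentzian(pools_df$A[i], pools_df$gamma_ppm[i],
                        pools_df$omega_ppm[i], offsets - b0)
  }
  z
}

default_zspec_truth <- function() {
  data.frame(name = c("water", "MT", "amide"),
             A = c(0.9, 0.1, 0.05),
             gamma_ppm = c(1.4, 25, 1.0),
             omega_ppm = c(0, -2.5, 3.5))
}

#' Generate a Z-spectroscopy phantom bundle
#'
#' Per-pixel Z-spectra are produced either by the sum-of-Lorentzians forward
#' model (fast path) or by full Bloch-McConnell simulation (physics path),
#' scaled by `m0_value`, with far-off-resonance M0 frames appended and
#' optional Gaussian noise and per-region B0 shifts.
#'
#' @param spec a [phantom_spec()]; each region's truth entry may carry
#'   `pools` (data frame with A, gamma_ppm, omega_ppm; fast path) or
#'   `bm_pools` (list of [pool_parameters()]; physics path) plus optional
#'   `b0_ppm`.
#' @param offsets_ppm spectral offsets in ppm.
#' @param m0_offsets_ppm far-off-resonance M0 frame offsets.
#' @param sat_b1_uT,sat_time_s,field_MHz acquisition parameters (physics
#'   path saturation, metadata otherwise).
#' @param m0_value raw M0 signal level.
#' @return an [experiment_bundle()] with a `cest` member and a `truth`
#'   member (the per-region truth).
#' @export
make_zspec_phantom <- function(spec, offsets_ppm = seq(-6, 6, by = 0.25),
                               m0_offsets_ppm = c(-100, 100),
                               sat_b1_uT = 2, sat_time_s = 4,
                               field_MHz = 300, m0_value = 2000) {
  set.seed(spec$seed)
  shape <- spec$shape
  all_offs <- c(m0_offsets_ppm, offsets_ppm)
  data <- array(0, dim = c(length(all_offs), shape[1], shape[2]))
  n_m0 <- length(m0_offsets_ppm)
  data[seq_len(n_m0), , ] <- m0_value
  for (rg in names(spec$regions)) {
    mask <- spec$regions[[rg]]
    tr <- spec$truth[[rg]]
    if (is.null(tr)) tr <- list(pools = default_zspec_truth())
    b0 <- if (is.null(tr$b0_ppm)) 0 else tr$b0_ppm
    if (!is.null(tr$bm_pools)) {
      z <- vapply(offsets_ppm, function(o) {
        simulate_z(tr$bm_pools,
                   saturation_event(sat_b1_uT, sat_time_s, o - b0), field_MHz)
      }, numeric(1))
    } else {
      z <- zspec_forward(tr$pools, offsets_ppm, b0)
    }
    for (k in seq_along(offsets_ppm)) {
      fr <- data[n_m0 + k, , ]
      fr[mask] <- z[k] * m0_value
      data[n_m0 + k, , ] <- fr
    }
  }
  if (spec$noise_sd > 0) {
    data <- data + stats::rnorm(length(data), sd = spec$noise_sd * m0_value)
  }
  params <- acquisition_params(offsets_ppm = all_offs, sat_b1_uT = sat_b1_uT,
                               sat_time_s = sat_time_s, field_MHz = field_MHz,
                               frame_times_s = seq_along(all_offs) * 10)
  st <- offset_stack(data, all_offs, params)
  experiment_bundle(list(cest = st, truth = spec$truth),
                    provenance = list(source = "synthetic",
                                      dialect = "cestkit-fixture",
                                      seed = spec$seed))
}

#' Generate field-mapping fixtures (WASSR, DAM pair, variable-TR series)
#'
#' WASSR dips are single Lorentzians centered at each region's true B0
#' shift; the double-angle pair follows `S(theta) = M0 * sin(kappa * theta)`
#' and `S(2 theta) = M0 * sin(2 * kappa * theta)`; the TR series follows the
#' saturation-recovery T1 model. Region truth entries may carry `b0_ppm`,
#' `kappa`, `t1_s` (scalars or full matrices for gradient phantoms).
#'
#' @param spec a [phantom_spec()].
#' @param wassr_offsets_ppm narrow-band WASSR offsets.
#' @param theta_nominal_deg nominal DAM flip angle in degrees.
#' @param tr_list_s variable-TR repetition times in seconds.
#' @param m0_value raw signal level.
#' @param wassr_width_ppm FWHM of the WASSR dip.
#' @return an [experiment_bundle()] with `wassr`, `dam_theta`, `dam_2theta`
#'   and `t1_series` members plus `truth`.
#' @export
make_field_fixtures <- function(spec,
                                wassr_offsets_ppm = seq(-1, 1, by = 0.1),
                                theta_nominal_deg = 60,
                                tr_list_s = c(0.3, 0.6, 1, 1.5, 2.5, 4, 6.5, 10),
                                m0_value = 1000, wassr_width_ppm = 0.6) {
  set.seed(spec$seed + 1L)
  shape <- spec$shape
  field_of <- function(key, default) {
    out <- matrix(default, shape[1], shape[2])
    for (rg in names(spec$regions)) {
      v <- spec$truth[[rg]][[key]]
      if (is.null(v)) next
      if (is.matrix(v)) out[spec$regions[[rg]]] <- v[spec$regions[[rg]]]
      else out[spec$regions[[rg]]] <- v
    }
    out
  }
  b0 <- field_of("b0_ppm", 0)
  kappa <- field_of("kappa", 1)
  t1 <- field_of("t1_s", 1.8)
  all_offs <- c(-100, wassr_offsets_ppm)
  wassr <- array(0, dim = c(length(all_offs), shape[1], shape[2]))
  wassr[1, , ] <- m0_value
  for (k in seq_along(wassr_offsets_ppm)) {
    z <- 1 - 0.8 * (wassr_width_ppm^2 / 4) /
      (wassr_width_ppm^2 / 4 + (wassr_offsets_ppm[k] - b0)^2)
    wassr[k + 1, , ] <- z * m0_value
  }
  th <- theta_nominal_deg * pi / 180
  dam_theta <- m0_value * sin(kappa * th)
  dam_2theta <- m0_value * sin(2 * kappa * th)
  t1s <- array(0, dim = c(length(tr_list_s), shape[1], shape[2]))
  for (k in seq_along(tr_list_s)) {
    t1s[k, , ] <- m0_value * (1 - exp(-tr_list_s[k] / t1))
  }
  if (spec$noise_sd > 0) {
    wassr <- wassr + stats::rnorm(length(wassr), sd = spec$noise_sd * m0_value)
    dam_theta <- dam_theta + stats::rnorm(length(dam_theta),
                                          sd = spec$noise_sd * m0_value)
    dam_2theta <- dam_2theta + stats::rnorm(length(dam_2theta),
                                            sd = spec$noise_sd * m0_value)
    t1s <- t1s + stats::rnorm(length(t1s), sd = spec$noise_sd * m0_value)
  }
  wassr_params <- acquisition_params(offsets_ppm = all_offs, sat_b1_uT = 0.3,
                                     sat_time_s = 1,
                                     flip_angles_deg = theta_nominal_deg,
                                     frame_times_s = seq_along(all_offs) * 5)
  t1_params <- acquisition_params(offsets_ppm = rep(0, length(tr_list_s)),
                                  tr_list_s = tr_list_s)
  t1_stack <- offset_stack(t1s, rep(0, length(tr_list_s)), t1_params)
  experiment_bundle(
    list(wassr = offset_stack(wassr, all_offs, wassr_params),
         dam_theta = list(image = dam_theta),
         dam_2theta = list(image = dam_2theta),
         t1_series = t1_stack,
         truth = list(b0_ppm = b0, kappa = kappa, t1_s = t1,
                      theta_nominal_deg = theta_nominal_deg)),
    provenance = list(source = "synthetic", dialect = "cestkit-fixture",
                      seed = spec$seed))
}

#' Generate a radial projection series with respiratory corruption
#'
#' Projections are parallel-beam sinogram rows of a centered annulus at
#' golden-angle-like view angles, grouped into acquisition segments per
#' offset. Listed segments are corrupted by amplitude attenuation plus a
#' small shift, emulating respiratory motion.
#'
#' @param spec a [phantom_spec()] (`shape`, `noise_sd`, `seed` used).
#' @param n_offsets number of frequency-offset frames.
#' @param segments_per_offset,segment_size acquisition structure.
#' @param corrupt list of `c(offset, segment)` pairs to corrupt, or a plain
#'   vector of segment indices corrupted at every offset.
#' @param attenuation multiplicative signal loss applied to corrupted
#'   segments (0.6 means 40 percent attenuation).
#' @return list with `series` (a [projection_series()]) and `corrupt`
#'   (the realized corruption table).
#' @export
make_radial_series <- function(spec, n_offsets = 4, segments_per_offset = 10,
                               segment_size = 8, corrupt = list(),
                               attenuation = 0.6) {
  set.seed(spec$seed + 2L)
  n_samp <- spec$shape[2]
  xs <- seq(-1, 1, length.out = n_samp)
  base_proj <- function(angle) {
    # parallel projection of an annulus is analytic: chord lengths
    chord <- function(r, x) 2 * sqrt(pmax(r^2 - x^2, 0))
    chord(0.8, xs) - chord(0.45, xs)
  }
  if (!is.list(corrupt)) {
    corrupt <- unlist(lapply(seq_len(n_offsets), function(o) {
      lapply(corrupt, function(s) c(o, s))
    }), recursive = FALSE)
  }
  corrupt_tbl <- if (length(corrupt)) {
    do.call(rbind, lapply(corrupt, function(p) {
      data.frame(offset = p[1], segment = p[2])
    }))
  } else data.frame(offset = integer(), segment = integer())
  n_proj <- n_offsets * segments_per_offset * segment_size
  projections <- matrix(0, n_proj, n_samp)
  offsets_index <- integer(n_proj)
  row <- 0L
  ga <- pi * (3 - sqrt(5))
  for (o in seq_len(n_offsets)) {
    for (s in seq_len(segments_per_offset)) {
      bad <- any(corrupt_tbl$offset == o & corrupt_tbl$segment == s)
      for (p in seq_len(segment_size)) {
        row <- row + 1L
        pr <- base_proj(ga * row)
        if (bad) pr <- attenuation * c(pr[-1], 0)
        if (spec$noise_sd > 0) {
          pr <- pr + stats::rnorm(n_samp, sd = spec$noise_sd)
        }
        projections[row, ] <- pr
        offsets_index[row] <- o
      }
    }
  }
  list(series = projection_series(projections, segment_size, offsets_index),
       corrupt = corrupt_tbl)
}

#' Generate an MRF trajectory fixture
#'
#' Per-vial signal trajectories are simulated with the Bloch-McConnell
#' propagator at the truth parameters and laid out as circular vials on a
#' 64 x 64 matrix, with optional Gaussian noise.
#'
#' @param scenario an [mrf_scenario()] (supplies schedule, field and fixed
#'   solute properties).
#' @param truth data frame with one row per vial: `fb`, `kb`, `r1a`, `r2a`.
#' @param noise_sd Gaussian noise sd on the (unnormalized) trajectory.
#' @param shape image dimensions.
#' @param seed integer seed.
#' @return list with `images` (3D array, schedule length x row x col),
#'   `vials` (list of masks), `truth`.
#' @export
make_mrf_fixture <- function(scenario, truth, noise_sd = 0,
                             shape = c(64, 64), seed = 1L) {
  set.seed(seed)
  n_vial <- nrow(truth)
  len <- length(scenario$schedule)
  images <- array(0, dim = c(len, shape[1], shape[2]))
  cols <- ceiling(sqrt(n_vial))
  rows <- ceiling(n_vial / cols)
  radius <- floor(min(shape / c(rows, cols)) / 2) - 2
  vials <- list()
  for (v in seq_len(n_vial)) {
    ri <- (v - 1) %/% cols; ci <- (v - 1) %% cols
    center <- c((ri + 0.5) * shape[1] / rows, (ci + 0.5) * shape[2] / cols)
    mask <- disc_mask(shape, center, radius)
    vials[[paste0("vial", v)]] <- mask
    water <- pool_parameters("water", 1, 0, 0, truth$r1a[v], truth$r2a[v])
    pools <- list(water)
    if (truth$fb[v] > 0) {
      pools <- c(pools, list(pool_parameters("solute", truth$fb[v],
                                             truth$kb[v], scenario$dw_ppm,
                                             scenario$r1b, scenario$r2b)))
    }
    traj <- simulate_trajectory(pools, scenario$schedule, scenario$field_MHz)
    for (k in seq_len(len)) {
      fr <- images[k, , ]
      fr[mask] <- traj[k]
      images[k, , ] <- fr
    }
  }
  if (noise_sd > 0) {
    images <- images + stats::rnorm(length(images), sd = noise_sd)
  }
  list(images = images, vials = vials, truth = truth, seed = seed)
}
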