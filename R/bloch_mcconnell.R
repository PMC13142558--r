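# Multi-pool Bloch-McConnell simulation under continuous-wave saturation.
#
# The coupled system for N exchanging proton pools is linear in the rotating
# frame of the saturation pulse, so each constant-amplitude segment is solved
# exactly by the matrix exponential of the augmented homogeneous (3N+1) system.
# exp(A t) is evaluated through the eigendecomposition of A, which is exact for
# the diagonalizable matrices that arise here and fast enough for dictionary
# generation.

#' Gyromagnetic ratio of the proton in rad s^-1 per microtesla
#'
#' `2 * pi * 42.577` rad/s/uT, i.e. gamma/2pi = 42.577 MHz/T.
#' @export
GAMMA_RAD_PER_UT <- 2 * pi * 42.577

#' Define one proton pool for Bloch-McConnell simulation
#'
#' The first pool passed to the simulator must be free water (`fb = 1`,
#' `dw_ppm = 0` by convention). Solute pools exchange with water only
#' (two-site exchange per solute); the water-to-solute rate is `kb * fb`
#' so that detailed balance holds at thermal equilibrium.
#'
#' @param name pool label, e.g. `"water"`, `"creatine"`.
#' @param fb proton volume fraction relative to water (water has 1).
#' @param kb solute-to-water exchange rate in s^-1 (0 for water).
#' @param dw_ppm chemical shift relative to water in ppm.
#' @param r1,r2 longitudinal and transverse relaxation rates in s^-1.
#' @return an object of class `pool_parameters`.
#' @export
pool_parameters <- function(name, fb, kb = 0, dw_ppm = 0, r1, r2) {
  vals <- c(fb = fb, kb = kb, dw_ppm = dw_ppm, r1 = r1, r2 = r2)
  if (any(!is.finite(vals))) {
    stop("pool_parameters: all parameters must be finite (pool '", name, "')")
  }
  if (fb < 0 || fb > 1) stop("fb must lie in [0, 1]")
  if (kb < 0) stop("kb must be >= 0")
  if (r1 <= 0 || r2 <= 0) stop("r1 and r2 must be > 0")
  structure(list(name = name, fb = fb, kb = kb, dw_ppm = dw_ppm,
                 r1 = r1, r2 = r2),
            class = "pool_parameters")
}

#' Define a continuous-wave saturation event
#'
#' @param b1_uT peak saturation amplitude in microtesla.
#' @param duration_s saturation time in seconds (>= 0).
#' @param offset_ppm saturation frequency offset from water in ppm.
#' @param shape pulse shape; only `"cw"` (continuous wave) is supported.
#' @return an object of class `saturation_event`.
#' @export
saturation_event <- function(b1_uT, duration_s, offset_ppm, shape = "cw") {
  shape <- match.arg(shape, "cw")
  if (!is.finite(b1_uT) || b1_uT < 0) stop("b1_uT must be finite and >= 0")
  if (!is.finite(duration_s) || duration_s < 0) stop("duration_s must be >= 0")
  if (!is.finite(offset_ppm)) stop("offset_ppm must be finite")
  structure(list(b1_uT = b1_uT, duration_s = duration_s,
                 offset_ppm = offset_ppm, shape = shape),
            class = "saturation_event")
}

#' Define an acquisition schedule for trajectory simulation
#'
#' @param events list of [saturation_event()] objects, one per image.
#' @param recovery_s recovery delay after each readout (recycled to length).
#' @param flip_deg readout excitation flip angle in degrees (recycled).
#' @return an object of class `mrf_schedule`.
#' @export
mrf_schedule <- function(events, recovery_s, flip_deg) {
  if (length(events) == 0) stop("schedule must be nonempty")
  n <- length(events)
  structure(list(events = events,
                 recovery_s = rep_len(recovery_s, n),
                 flip_deg = rep_len(flip_deg, n)),
            class = "mrf_schedule")
}

#' @export
length.mrf_schedule <- function(x) length(x$events)

check_pools <- function(pools) {
  if (!length(pools) || length(pools) > 4) {
    stop("between 1 and 4 pools are supported")
  }
  if (abs(pools[[1]]$fb - 1) > 1e-12) {
    stop("the first pool must be water with fb = 1")
  }
  invisible(pools)
}

# Augmented (3N+1) x (3N+1) generator of the Bloch-McConnell system for one CW
# segment. State ordering: (Mx, My, Mz) per pool, then the constant 1.
# Rotating frame of the saturation pulse; B1 along +x.
bm_generator <- function(pools, b1_uT, offset_ppm, field_MHz) {
  n <- length(pools)
  dim <- 3L * n + 1L
  A <- matrix(0, dim, dim)
  w1 <- GAMMA_RAD_PER_UT * b1_uT
  fb <- vapply(pools, `[[`, numeric(1), "fb")
  kb <- vapply(pools, `[[`, numeric(1), "kb")
  # water loses magnetization to each solute at rate kb_j * fb_j
  k_water_out <- sum(kb[-1] * fb[-1])
  for (i in seq_len(n)) {
    p <- pools[[i]]
    ix <- 3L * (i - 1L) + 1L; iy <- ix + 1L; iz <- ix + 2L
    delta <- 2 * pi * field_MHz * (p$dw_ppm - offset_ppm)  # rad/s
    k_out <- if (i == 1L) k_water_out else p$kb
    A[ix, ix] <- -p$r2 - k_out; A[ix, iy] <- delta
    A[iy, ix] <- -delta;        A[iy, iy] <- -p$r2 - k_out
    A[iy, iz] <- w1
    A[iz, iy] <- -w1;           A[iz, iz] <- -p$r1 - k_out
    meq <- if (i == 1L) 1 else p$fb
    A[iz, dim] <- p$r1 * meq
    if (i > 1L) {
      # cross terms: solute i <-> water, component by component
      for (d in 0:2) {
        A[1L + d, ix + d] <- A[1L + d, ix + d] + p$kb        # water gains
        A[ix + d, 1L + d] <- A[ix + d, 1L + d] + p$kb * p$fb # solute gains
      }
    }
  }
  A
}

# Eigendecomposition of a generator, reusable across durations.
bm_propagator <- function(A) {
  e <- eigen(A)
  list(V = e$vectors, Vinv = solve(e$vectors), lambda = e$values)
}

bm_apply <- function(prop, state, t) {
  if (t == 0) return(state)
  y <- prop$Vinv %*% state
  y <- y * exp(prop$lambda * t)
  out <- Re(prop$V %*% y)
  drop(out)
}

bm_equilibrium_state <- function(pools, z_init = 1) {
  n <- length(pools)
  state <- numeric(3L * n + 1L)
  for (i in seq_len(n)) {
    meq <- if (i == 1L) 1 else pools[[i]]$fb
    state[3L * (i - 1L) + 3L] <- z_init * meq
  }
  state[3L * n + 1L] <- 1
  state
}

#' Simulate water Z magnetization after one CW saturation event
#'
#' Propagates the coupled Bloch-McConnell system through a single
#' continuous-wave saturation segment and returns the longitudinal water
#' magnetization fraction Z = Mza / M0a.
#'
#' @param pools list of [pool_parameters()]; the first must be water.
#' @param event a [saturation_event()].
#' @param field_MHz scanner proton frequency in MHz (e.g. 300.0 at 7 T).
#' @param z_init initial longitudinal magnetization fraction; all pools start
#'   at `z_init` times their equilibrium value, transverse components at zero.
#' @return scalar Z in `[-1, 1]`.
#' @export
simulate_z <- function(pools, event, field_MHz, z_init = 1) {
  check_pools(pools)
  if (!is.finite(field_MHz) || field_MHz <= 0) stop("field_MHz must be > 0")
  if (event$duration_s == 0) return(z_init)
  A <- bm_generator(pools, event$b1_uT, event$offset_ppm, field_MHz)
  state <- bm_equilibrium_state(pools, z_init)
  out <- bm_apply(bm_propagator(A), state, event$duration_s)
  out[3L]
}

#' Simulate a signal trajectory over an acquisition schedule
#'
#' Magnetization is carried across schedule entries (no full-relaxation
#' assumption). Each entry applies its saturation event, samples the signal as
#' `sin(flip) * Mz` of water, scales all longitudinal components by
#' `cos(flip)` (spoiled single-shot readout approximation; configurable via
#' `readout_scaling`), and then relaxes for the recovery delay with the
#' saturation off.
#'
#' @param pools list of [pool_parameters()]; the first must be water.
#' @param schedule an [mrf_schedule()].
#' @param field_MHz scanner proton frequency in MHz.
#' @param readout_scaling multiplier applied to longitudinal magnetization at
#'   readout in addition to `cos(flip)`; `1` models an ideally spoiled
#'   excitation, lower values approximate additional saturation by the readout
#'   train.
#' @return numeric vector of one signal value per schedule entry.
#' @export
simulate_trajectory <- function(pools, schedule, field_MHz,
                                readout_scaling = 1) {
  check_pools(pools)
  if (!inherits(schedule, "mrf_schedule")) stop("schedule must be an mrf_schedule")
  n <- length(schedule)
  npool <- length(pools)
  iz <- 3L * (seq_len(npool) - 1L) + 3L
  state <- bm_equilibrium_state(pools)
  sig <- numeric(n)
  cache <- new.env(parent = emptyenv())
  get_prop <- function(b1, off) {
    key <- paste(b1, off, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- bm_propagator(bm_generator(pools, b1, off, field_MHz))
    cache[[key]] <- p
    p
  }
  for (j in seq_len(n)) {
    ev <- schedule$events[[j]]
    if (ev$duration_s > 0) {
      state <- bm_apply(get_prop(ev$b1_uT, ev$offset_ppm), state, ev$duration_s)
    }
    th <- schedule$flip_deg[j] * pi / 180
    sig[j] <- sin(th) * state[3L]
    # spoiled readout: transverse destroyed, longitudinal scaled
    mz <- state[iz] * cos(th) * readout_scaling
    state[] <- 0
    state[iz] <- mz
    state[length(state)] <- 1
    rec <- schedule$recovery_s[j]
    if (rec > 0) state <- bm_apply(get_prop(0, 0), state, rec)
  }
  sig
}
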