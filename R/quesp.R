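# QUESP: quantitative fb / kb mapping from CEST signal versus saturation
# power, by three analytical routes (MTRasym model fit, MTRRex fit, and the
# omega-plot linearization), with steady-state validity warnings.

#' Saturation efficiency
#'
#' `alpha = w1^2 / (w1^2 + kb^2)` with `w1 = gamma * B1` in rad/s.
#'
#' @param b1_uT saturation amplitude in microtesla.
#' @param kb solute-water exchange rate in s^-1.
#' @return saturation efficiency in `[0, 1]`.
#' @export
alpha_efficiency <- function(b1_uT, kb) {
  if (any(kb < 0)) stop("kb must be >= 0")
  w1 <- GAMMA_RAD_PER_UT * b1_uT
  ifelse(w1 == 0 & kb == 0, 1, w1^2 / (w1^2 + kb^2))
}

#' Analytical MTRasym under continuous-wave saturation
#'
#' Closed-form two-pool solution of the Bloch-McConnell equations for the
#' asymmetry magnetization transfer ratio at saturation time `tp`:
#' the steady-state term `fb*kb*alpha / (R1a + fb*kb*alpha)` plus the two
#' transient exponentials in `Zi`. Identically 0 at `tp = 0`.
#'
#' @param fb solute proton volume fraction.
#' @param kb solute-water exchange rate in s^-1.
#' @param b1_uT saturation amplitude in microtesla.
#' @param r1a water longitudinal relaxation rate in s^-1.
#' @param tp_s saturation time in seconds.
#' @param zi initial longitudinal magnetization (default 1).
#' @return MTRasym value (dimensionless).
#' @export
mtrasym_model <- function(fb, kb, b1_uT, r1a, tp_s, zi = 1) {
  a <- alpha_efficiency(b1_uT, kb)
  fka <- fb * kb * a
  r <- r1a + fka
  fka / r + (zi - 1) * exp(-r1a * tp_s) - (zi - r1a / r) * exp(-r * tp_s)
}

#' Steady-state MTRRex model
#'
#' `MTRRex = 1/Zlab - 1/Zref = fb * kb * alpha / R1a`, valid when
#' `tp >> T1a` and the longitudinal magnetization fully relaxes between
#' readouts.
#'
#' @inheritParams mtrasym_model
#' @return MTRRex value (dimensionless).
#' @export
mtrrex_model <- function(fb, kb, b1_uT, r1a) {
  fb * kb * alpha_efficiency(b1_uT, kb) / r1a
}

#' QUESP measurement series
#'
#' @param b1_uT saturation amplitudes; at least 3 distinct nonzero values.
#' @param tp_s saturation time in seconds (> 0).
#' @param mtr_asym per-B1 MTRasym values: a vector (single pixel/ROI) or a
#'   3D array (B1 index x row x col).
#' @param z_lab,z_ref label and reference Z values per B1, same layout as
#'   `mtr_asym` (needed for the MTRRex and omega-plot routes).
#' @param r1a water R1 in s^-1: scalar or pixel matrix.
#' @param zi initial longitudinal magnetization.
#' @param dw_ppm solute offset in ppm (metadata).
#' @return an object of class `quesp_series`.
#' @export
quesp_series <- function(b1_uT, tp_s, mtr_asym = NULL, z_lab = NULL,
                         z_ref = NULL, r1a, zi = 1, dw_ppm = NA_real_) {
  nz <- unique(b1_uT[b1_uT > 0])
  if (length(nz) < 3) stop("QUESP needs at least 3 distinct nonzero B1 values")
  if (tp_s <= 0) stop("tp_s must be > 0")
  if (is.null(mtr_asym) && (is.null(z_lab) || is.null(z_ref))) {
    stop("supply mtr_asym or the z_lab/z_ref pair")
  }
  structure(list(b1_uT = b1_uT, tp_s = tp_s, mtr_asym = mtr_asym,
                 z_lab = z_lab, z_ref = z_ref, r1a = r1a, zi = zi,
                 dw_ppm = dw_ppm),
            class = "quesp_series")
}

#' Steady-state and relaxation warnings for QUESP acquisitions
#'
#' Warns when the saturation time is too short for steady state
#' (`tp < ss_factor * T1a`, relevant to the MTRRex and omega-plot routes)
#' and when the recovery time does not allow full longitudinal relaxation
#' between readouts (`recovery < ss_factor * T1a`).
#'
#' @param params an [acquisition_params()].
#' @param r1a water R1 in s^-1.
#' @param ss_factor multiple of T1a regarded as sufficient (default 5).
#' @return character vector of warning messages (empty when none apply);
#'   also raised as R warnings.
#' @export
steady_state_warning <- function(params, r1a, ss_factor = 5) {
  t1a <- 1 / r1a
  msgs <- character()
  if (params$sat_time_s < ss_factor * t1a) {
    msgs <- c(msgs, sprintf(
      "saturation time %.3g s is below %g x T1a (%.3g s): steady-state assumption (MTRRex/omega-plot) not met",
      params$sat_time_s, ss_factor, ss_factor * t1a))
  }
  if (params$recovery_time_s < ss_factor * t1a) {
    msgs <- c(msgs, sprintf(
      "recovery time %.3g s is below %g x T1a (%.3g s): longitudinal magnetization does not fully relax between readouts",
      params$recovery_time_s, ss_factor, ss_factor * t1a))
  }
  for (m in msgs) warning(m, call. = FALSE)
  invisible(msgs)
}

#' Pixelwise MTRasym images from a normalized Z stack
#'
#' `MTRasym = Z(-dw) - Z(+dw)` at the solute offset, per pixel, with linear
#' interpolation onto +-dw when those offsets are not sampled exactly.
#'
#' @param stack a normalized [offset_stack()] containing both sides of the
#'   spectrum around `dw_ppm`.
#' @param dw_ppm solute offset in ppm (> 0).
#' @return matrix of MTRasym values.
#' @export
mtrasym_from_stack <- function(stack, dw_ppm) {
  if (!isTRUE(stack$normalized)) stop("stack must be normalized first")
  offs <- stack$offsets_ppm
  if (min(offs) > -dw_ppm || max(offs) < dw_ppm) {
    stop("stack does not cover both -dw and +dw (one-sided acquisition)")
  }
  d <- dim(stack$data)
  interp_frame <- function(target) {
    apply(stack$data, c(2, 3), function(z) stats::approx(offs, z, xout = target)$y)
  }
  interp_frame(-dw_ppm) - interp_frame(dw_ppm)
}

fit_quesp_pixel <- function(b1, y, tp, zi, r1a, method, bounds, init) {
  if (method == "mtr_asym") {
    fit <- tryCatch(minpack.lm::nls.lm(
      par = init, lower = bounds$lower, upper = bounds$upper,
      fn = function(p) mtrasym_model(p[1], p[2], b1, r1a, tp, zi) - y,
      control = minpack.lm::nls.lm.control(ftol = 1e-12, maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4)) return(NULL)
    pred <- mtrasym_model(fit$par[1], fit$par[2], b1, r1a, tp, zi)
    par <- fit$par
  } else if (method == "mtr_rex") {
    fit <- tryCatch(minpack.lm::nls.lm(
      par = init, lower = bounds$lower, upper = bounds$upper,
      fn = function(p) mtrrex_model(p[1], p[2], b1, r1a) - y,
      control = minpack.lm::nls.lm.control(ftol = 1e-12, maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4)) return(NULL)
    pred <- mtrrex_model(fit$par[1], fit$par[2], b1, r1a)
    par <- fit$par
  } else { # omega_plot
    w1sq <- (GAMMA_RAD_PER_UT * b1)^2
    xv <- 1 / w1sq
    yv <- 1 / y
    if (any(!is.finite(yv))) return(NULL)
    ols <- stats::lm(yv ~ xv)
    itc <- stats::coef(ols)[[1]]; slp <- stats::coef(ols)[[2]]
    if (!is.finite(itc) || !is.finite(slp) || itc <= 0 || slp <= 0) return(NULL)
    kb <- sqrt(slp / itc)
    fb <- r1a / (itc * kb)
    par <- c(fb, kb)
    pred <- 1 / (itc + slp * xv)
  }
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum((y - pred)^2) / ss_tot else NA_real_
  c(par, r2)
}

#' Fit quantitative QUESP parameter maps
#'
#' Three routes are available: `mtr_asym` fits the full CW analytical
#' MTRasym model over (fb, kb) by bounded nonlinear least squares;
#' `mtr_rex` fits the steady-state MTRRex expression; `omega_plot` performs
#' ordinary least squares of `1/MTRRex` against `1/w1^2` and recovers
#' `kb = sqrt(slope/intercept)`, `fb = R1a / (intercept * kb)`. Pixels with
#' failed fits (including nonpositive omega-plot intercepts) are invalid.
#'
#' @param series a [quesp_series()]. For `mtr_rex`/`omega_plot`, MTRRex data
#'   are formed from `z_lab`/`z_ref` if present, else from
#'   `mtr_asym` approximated as `1/Zlab - 1/Zref` is required.
#' @param method one of `"mtr_asym"`, `"mtr_rex"`, `"omega_plot"`.
#' @param fb_bounds,kb_bounds fit bounds; defaults fb in [1e-6, 0.05],
#'   kb in [10, 2e4] s^-1.
#' @param init initial values `c(fb, kb)`.
#' @return an object of class `quesp_fit`: [pixel_map()]s `fb`, `kb`, `r2`,
#'   plus `method`.
#' @export
fit_quesp <- function(series, method = c("mtr_asym", "mtr_rex", "omega_plot"),
                      fb_bounds = c(1e-6, 0.05), kb_bounds = c(10, 2e4),
                      init = c(1e-3, 1000)) {
  method <- match.arg(method)
  if (method == "mtr_asym") {
    y <- series$mtr_asym
    if (is.null(y)) stop("mtr_asym data required for the mtr_asym route")
  } else {
    if (!is.null(series$z_lab) && !is.null(series$z_ref)) {
      y <- 1 / series$z_lab - 1 / series$z_ref
    } else {
      stop("z_lab and z_ref required for the ", method, " route")
    }
  }
  if (is.null(dim(y)) || length(dim(y)) == 1) {
    y <- array(y, dim = c(length(y), 1, 1))
  }
  d <- dim(y)
  if (d[1] != length(series$b1_uT)) stop("one value per B1 required")
  r1a_mat <- series$r1a
  if (length(r1a_mat) == 1) r1a_mat <- matrix(r1a_mat, d[2], d[3])
  bounds <- list(lower = c(fb_bounds[1], kb_bounds[1]),
                 upper = c(fb_bounds[2], kb_bounds[2]))
  fb <- kb <- r2 <- matrix(NA_real_, d[2], d[3])
  valid <- matrix(FALSE, d[2], d[3])
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    res <- fit_quesp_pixel(series$b1_uT, y[, i, j], series$tp_s, series$zi,
                           r1a_mat[i, j], method, bounds, init)
    if (is.null(res) || any(!is.finite(res[1:2]))) next
    fb[i, j] <- res[1]; kb[i, j] <- res[2]; r2[i, j] <- res[3]
    valid[i, j] <- TRUE
  }
  structure(list(fb = pixel_map(fb, "fb", "", valid),
                 kb = pixel_map(kb, "kb", "1/s", valid),
                 r2 = pixel_map(r2, "fit R2", "",
                                valid & is.finite(r2)),
                 method = method),
            class = "quesp_fit")
}
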