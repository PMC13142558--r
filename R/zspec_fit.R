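# Two-step Lorentzian fitting of Z-spectra with internal B0 correction.
#
# The Z-spectrum is modeled as Z(dw) = 1 - sum_i L_i(dw) with Lorentzian
# lines L_i. Water and semisolid MT are first fitted over the whole spectrum;
# the fitted water center provides the per-spectrum B0 correction. Water and
# MT are refitted on the corrected axis with the CEST/rNOE band excluded, and
# the remaining contrasts are fitted to the Lorentzian difference
# (reference fit minus measured Z, so CEST peaks are positive).

#' Lorentzian lineshape
#'
#' `L(dw) = A * (g^2/4) / (g^2/4 + (dw - w)^2)` with amplitude `A`, full
#' width at half maximum `g` and center `w` (all offsets in ppm).
#'
#' @param A peak amplitude (fraction of M0).
#' @param gamma_ppm full width at half maximum in ppm (> 0).
#' @param omega_ppm center offset relative to water in ppm.
#' @param offsets evaluation offsets in ppm.
#' @return numeric vector of lineshape values.
#' @export
lorentzian <- function(A, gamma_ppm, omega_ppm, offsets) {
  if (gamma_ppm <= 0) stop("gamma_ppm must be > 0")
  h <- gamma_ppm^2 / 4
  A * h / (h + (offsets - omega_ppm)^2)
}

#' Default Lorentzian pool table
#'
#' Centers, FWHM initial values and bounds follow common high-field (7 T)
#' literature conventions; all of them are user-editable because two-step
#' fits are sensitive to initial conditions and bounds. Amplitude units are
#' fractions of M0, widths and centers ppm.
#'
#' @param names optional subset of pool names to return.
#' @return data frame with one row per pool: `name`, `A_init`, `A_lo`,
#'   `A_hi`, `g_init`, `g_lo`, `g_hi`, `w_init`, `w_lo`, `w_hi`.
#' @export
default_pools <- function(names = NULL) {
  tbl <- data.frame(
    name  = c("water", "MT", "amide", "creatine", "amine", "hydroxyl", "rNOE"),
    A_init = c(0.8, 0.1, 0.02, 0.02, 0.02, 0.01, 0.02),
    A_lo  = c(0.02, 0, 0, 0, 0, 0, 0),
    A_hi  = c(1, 0.4, 0.3, 0.3, 0.3, 0.3, 0.3),
    g_init = c(1.4, 25, 1.0, 1.0, 1.0, 1.0, 3.0),
    g_lo  = c(0.3, 10, 0.3, 0.3, 0.3, 0.3, 1),
    g_hi  = c(10, 100, 6, 4, 4, 4, 8),
    w_init = c(0, -2.5, 3.5, 2.0, 2.0, 1.0, -3.5),
    w_lo  = c(-1, -2.6, 3.1, 1.6, 1.6, 0.6, -4.2),
    w_hi  = c(1, -2.4, 3.9, 2.4, 2.4, 1.4, -2.8),
    stringsAsFactors = FALSE)
  if (!is.null(names)) {
    miss <- setdiff(names, tbl$name)
    if (length(miss)) stop("unknown pool(s): ", paste(miss, collapse = ", "))
    tbl <- tbl[match(names, tbl$name), ]
  }
  tbl
}

#' Fitting configuration for the two-step Lorentzian fit
#'
#' @param exclude_band CEST/rNOE band excluded from the water+MT refit:
#'   offsets with `exclude_band[1] <= |dw| <= exclude_band[2]` ppm.
#' @param pool_table pool table as returned by [default_pools()].
#' @param ftol,maxfev least-squares convergence tolerance and maximum number
#'   of residual evaluations (trust-region Levenberg-Marquardt).
#' @return list of settings.
#' @export
zspec_config <- function(exclude_band = c(1.4, 4), pool_table = default_pools(),
                         ftol = 1e-8, maxfev = 400) {
  list(exclude_band = exclude_band, pool_table = pool_table,
       ftol = ftol, maxfev = maxfev)
}

# Bounded least-squares fit of 1 - sum of Lorentzians to z over offsets.
# rows: pool table subset. Returns list(par matrix, rmse, model fn).
fit_lorentzian_sum <- function(offsets, z, rows, config, baseline = 1) {
  n <- nrow(rows)
  par0 <- as.numeric(t(as.matrix(rows[, c("A_init", "g_init", "w_init")])))
  lower <- as.numeric(t(as.matrix(rows[, c("A_lo", "g_lo", "w_lo")])))
  upper <- as.numeric(t(as.matrix(rows[, c("A_hi", "g_hi", "w_hi")])))
  model <- function(par, x) {
    out <- rep(baseline, length(x))
    for (i in seq_len(n)) {
      p <- par[(3 * i - 2):(3 * i)]
      out <- out - lorentzian(p[1], p[2], p[3], x)
    }
    out
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(par) model(par, offsets) - z,
    control = minpack.lm::nls.lm.control(ftol = config$ftol,
                                         maxiter = min(config$maxfev, 1024)))
  par <- fit$par
  pmat <- matrix(par, ncol = 3, byrow = TRUE,
                 dimnames = list(rows$name, c("A", "gamma_ppm", "omega_ppm")))
  resid <- model(par, offsets) - z
  list(pools = pmat, rmse = sqrt(mean(resid^2)), model = model, par = par,
       converged = fit$info %in% 1:4)
}

#' Two-step Lorentzian fit of a single Z-spectrum
#'
#' Step 0 fits water + MT over the entire spectrum; the fitted water center
#' is the per-spectrum B0 shift and is subtracted from the frequency axis.
#' Step 1 refits water + MT on the corrected axis with the exclusion band
#' (default 1.4 <= |dw| <= 4 ppm) removed. Step 2 subtracts the reference
#' water+MT fit from the measured spectrum to form the Lorentzian difference
#' and fits the requested CEST/rNOE pools to it.
#'
#' @param offsets_ppm offsets in ppm; at least 10, spanning beyond +-4 ppm.
#' @param z normalized Z values, same length as `offsets_ppm`.
#' @param pools_requested character vector of CEST/rNOE pool names from the
#'   pool table (water and MT are always fitted and need not be listed).
#' @param config a [zspec_config()].
#' @return an object of class `zspec_fit`: `pools` (fitted parameter matrix),
#'   `b0_shift_ppm`, `rmse_step1`, `rmse_step2`, `lorentzian_difference`,
#'   `offsets_corrected_ppm`, `converged`.
#' @export
fit_two_step <- function(offsets_ppm, z, pools_requested = "amide",
                         config = zspec_config()) {
  if (length(offsets_ppm) < 10) stop("need at least 10 offsets")
  if (max(offsets_ppm) <= 4 || min(offsets_ppm) >= -4) {
    stop("offsets must span beyond +-4 ppm")
  }
  if (length(z) != length(offsets_ppm)) stop("z and offsets differ in length")
  tbl <- config$pool_table
  wm <- tbl[match(c("water", "MT"), tbl$name), ]
  # step 0: water + MT on the full, uncorrected spectrum
  f0 <- fit_lorentzian_sum(offsets_ppm, z, wm, config)
  b0 <- f0$pools["water", "omega_ppm"]
  x <- offsets_ppm - b0
  # step 1: refit on the corrected axis, CEST/rNOE band excluded
  band <- config$exclude_band
  keep <- !(abs(x) >= band[1] & abs(x) <= band[2])
  if (sum(keep) < 7) stop("too few offsets outside the exclusion band")
  f1 <- fit_lorentzian_sum(x[keep], z[keep], wm, config)
  # recentre the corrected axis on the refitted water line; the fitted
  # centers move with it so the model is unchanged in the original frame
  w1 <- f1$pools["water", "omega_ppm"]
  b0 <- b0 + w1
  x <- offsets_ppm - b0
  f1$par[c(3, 6)] <- f1$par[c(3, 6)] - w1
  f1$pools[, "omega_ppm"] <- f1$pools[, "omega_ppm"] - w1
  ld <- f1$model(f1$par, x) - z
  # step 2: requested pools against the Lorentzian difference
  sol <- tbl[match(pools_requested, tbl$name), ]
  if (any(is.na(sol$name))) stop("unknown requested pool(s)")
  pools_mat <- f1$pools
  rmse2 <- 0
  conv2 <- TRUE
  if (nrow(sol) > 0) {
    f2 <- fit_lorentzian_sum(x, -ld, sol, config, baseline = 0)
    # baseline 0 and negated difference: residual model is -sum L_i vs -ld
    pools_mat <- rbind(pools_mat, f2$pools)
    rmse2 <- f2$rmse
    conv2 <- f2$converged
  }
  structure(list(pools = pools_mat, b0_shift_ppm = b0,
                 rmse_step1 = f1$rmse, rmse_step2 = rmse2,
                 lorentzian_difference = ld,
                 offsets_corrected_ppm = x,
                 converged = f0$converged && f1$converged && conv2),
            class = "zspec_fit")
}

#' Pixelwise two-step Lorentzian fitting
#'
#' Applies [fit_two_step()] to every masked pixel. Pixels whose fit fails or
#' does not converge are marked invalid in every returned map; they never
#' abort the batch.
#'
#' @param stack a normalized [offset_stack()].
#' @param mask logical matrix of pixels to fit (default: all).
#' @param pools_requested CEST/rNOE pool names.
#' @param config a [zspec_config()].
#' @return named list of [pixel_map()]s: one amplitude map per fitted pool,
#'   plus `b0_shift_ppm`, `rmse_step1` and `rmse_step2`.
#' @export
fit_pixelwise <- function(stack, mask = NULL, pools_requested = "amide",
                          config = zspec_config()) {
  if (!isTRUE(stack$normalized)) stop("stack must be normalized first")
  d <- dim(stack$data)
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  all_pools <- c("water", "MT", pools_requested)
  maps <- lapply(all_pools, function(p) matrix(NA_real_, d[2], d[3]))
  names(maps) <- all_pools
  b0 <- rmse1 <- rmse2 <- matrix(NA_real_, d[2], d[3])
  valid <- matrix(FALSE, d[2], d[3])
  px <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(px))) {
    i <- px[k, 1]; j <- px[k, 2]
    fit <- tryCatch(fit_two_step(stack$offsets_ppm, stack$data[, i, j],
                                 pools_requested, config),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    valid[i, j] <- TRUE
    for (p in all_pools) maps[[p]][i, j] <- fit$pools[p, "A"]
    b0[i, j] <- fit$b0_shift_ppm
    rmse1[i, j] <- fit$rmse_step1
    rmse2[i, j] <- fit$rmse_step2
  }
  out <- lapply(all_pools, function(p) {
    pixel_map(maps[[p]], quantity = paste(p, "amplitude"), units = "fraction of M0",
              valid_mask = valid)
  })
  names(out) <- all_pools
  out$b0_shift_ppm <- pixel_map(b0, "B0 shift", "ppm", valid)
  out$rmse_step1 <- pixel_map(rmse1, "step-1 RMSE", "", valid)
  out$rmse_step2 <- pixel_map(rmse2, "step-2 RMSE", "", valid)
  out
}

#' Segmentwise two-step Lorentzian fitting
#'
#' Averages the Z-spectrum over each segment mask and fits the mean spectrum
#' with [fit_two_step()]. Empty segments are skipped with a warning.
#'
#' @param stack a normalized [offset_stack()].
#' @param segments a [segment_set()].
#' @param pools_requested CEST/rNOE pool names.
#' @param config a [zspec_config()].
#' @return named list of `zspec_fit` objects, one per non-empty segment.
#' @export
fit_segmentwise <- function(stack, segments, pools_requested = "amide",
                            config = zspec_config()) {
  if (!isTRUE(stack$normalized)) stop("stack must be normalized first")
  fits <- list()
  for (lab in names(segments$masks)) {
    m <- segments$masks[[lab]]
    if (!any(m)) {
      warning("segment '", lab, "' is empty: skipped")
      next
    }
    zbar <- apply(stack$data, 1, function(fr) mean(fr[m]))
    fits[[lab]] <- fit_two_step(stack$offsets_ppm, zbar, pools_requested, config)
  }
  fits
}

#' Tabulate segmentwise fit results
#'
#' @param fits named list of `zspec_fit` objects from [fit_segmentwise()].
#' @return data frame with one row per segment: pool amplitudes, B0 shift
#'   and both RMSEs.
#' @export
segment_fit_table <- function(fits) {
  if (!length(fits)) {
    return(data.frame(segment = character()))
  }
  rows <- lapply(names(fits), function(lab) {
    f <- fits[[lab]]
    amps <- stats::setNames(as.list(f$pools[, "A"]),
                            paste0(rownames(f$pools), "_amplitude"))
    cbind(data.frame(segment = lab), as.data.frame(amps),
          data.frame(b0_shift_ppm = f$b0_shift_ppm,
                     rmse_step1 = f$rmse_step1, rmse_step2 = f$rmse_step2))
  })
  do.call(rbind, rows)
}
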