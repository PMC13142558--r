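# Field mapping: WASSR B0, double-angle B1 (kappa) with spline upsampling,
# and variable-TR T1 mapping.

#' WASSR B0 map
#'
#' Per pixel, the narrow-band WASSR spectrum is interpolated onto 1000
#' uniform points with a cubic spline, and a single Lorentzian on a free
#' baseline, `Z(dw) = b - L(A, g, w; dw)`, is fitted by bounded least
#' squares. The fitted center `w` is the B0 shift.
#'
#' @param stack a normalized [offset_stack()] of WASSR images (narrow sweep,
#'   typically within +-1 ppm).
#' @param mask optional logical matrix of pixels to fit.
#' @param n_interp number of spline interpolation points.
#' @param baseline_bounds allowed range for the free baseline `b`.
#' @return a [pixel_map()] of B0 shift in ppm; failed fits are invalid.
#' @export
wassr_b0 <- function(stack, mask = NULL, n_interp = 1000,
                     baseline_bounds = c(0.8, 1.2)) {
  if (!isTRUE(stack$normalized)) stop("stack must be normalized first")
  d <- dim(stack$data)
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  offs <- stack$offsets_ppm
  grid <- seq(min(offs), max(offs), length.out = n_interp)
  vals <- matrix(NA_real_, d[2], d[3])
  valid <- matrix(FALSE, d[2], d[3])
  px <- which(mask, arr.ind = TRUE)
  half_sweep <- (max(offs) - min(offs)) / 2
  for (k in seq_len(nrow(px))) {
    i <- px[k, 1]; j <- px[k, 2]
    z <- stack$data[, i, j]
    zi <- stats::spline(offs, z, xout = grid, method = "fmm")$y
    init <- c(A = max(0.1, 1 - min(zi)), g = 0.5, w = grid[which.min(zi)],
              b = 1)
    fit <- tryCatch(minpack.lm::nls.lm(
      par = init,
      lower = c(0, 0.05, min(offs), baseline_bounds[1]),
      upper = c(1.5, 4 * half_sweep + 0.5, max(offs), baseline_bounds[2]),
      fn = function(p) p[4] - lorentzian(p[1], p[2], p[3], grid) - zi,
      control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4)) next
    vals[i, j] <- fit$par[3]
    valid[i, j] <- TRUE
  }
  pixel_map(vals, "B0 shift", "ppm", valid)
}

#' Double-angle B1 map (kappa)
#'
#' The true flip angle at each pixel is `theta = acos(M2t / (2 * Mt))` from
#' image pairs acquired at nominal flip angles theta and 2*theta; the
#' relative scaling factor is `kappa = theta / theta_nominal`. Pixels where
#' the arccosine argument leaves [-1, 1] or where `Mt` falls below the noise
#' floor are marked invalid.
#'
#' @param m_theta,m_2theta image matrices at flip angles theta and 2*theta.
#' @param theta_nominal_deg nominal flip angle in degrees, in (0, 90).
#' @param noise_floor signal threshold on `m_theta` (default `5 * noise_sd`).
#' @param noise_sd background noise standard deviation used for the default
#'   noise floor.
#' @return a [pixel_map()] of kappa (dimensionless).
#' @export
dam_b1 <- function(m_theta, m_2theta, theta_nominal_deg,
                   noise_floor = 5 * noise_sd, noise_sd = 0) {
  m_theta <- as.matrix(m_theta); m_2theta <- as.matrix(m_2theta)
  if (!identical(dim(m_theta), dim(m_2theta))) {
    stop("flip-angle image pair must share dimensions")
  }
  if (theta_nominal_deg <= 0 || theta_nominal_deg >= 90) {
    stop("theta_nominal_deg must lie in (0, 90)")
  }
  arg <- m_2theta / (2 * m_theta)
  ok <- is.finite(arg) & abs(arg) <= 1 & m_theta > noise_floor
  theta <- matrix(NA_real_, nrow(m_theta), ncol(m_theta))
  theta[ok] <- acos(arg[ok]) * 180 / pi
  kappa <- theta / theta_nominal_deg
  pixel_map(kappa, "kappa", "", ok)
}

# Separable cubic-spline interpolation of a matrix onto a finer grid.
spline_resize <- function(m, target_shape) {
  src <- dim(m)
  x1 <- seq(0, 1, length.out = src[1]); x2 <- seq(0, 1, length.out = src[2])
  t1 <- seq(0, 1, length.out = target_shape[1])
  t2 <- seq(0, 1, length.out = target_shape[2])
  tmp <- matrix(0, src[1], target_shape[2])
  for (i in seq_len(src[1])) {
    tmp[i, ] <- stats::spline(x2, m[i, ], xout = t2, method = "fmm")$y
  }
  out <- matrix(0, target_shape[1], target_shape[2])
  for (j in seq_len(target_shape[2])) {
    out[, j] <- stats::spline(x1, tmp[, j], xout = t1, method = "fmm")$y
  }
  out
}

#' Upsample a pixel map by 2D cubic-spline interpolation
#'
#' Used to match a low-resolution B1 map to the reference image matrix size.
#' The validity mask is resampled by nearest neighbor so invalid regions
#' grow consistently with the interpolation.
#'
#' @param map a [pixel_map()].
#' @param target_shape `c(rows, cols)`, at least the source size.
#' @return an upsampled [pixel_map()].
#' @export
upsample_map <- function(map, target_shape) {
  src <- dim(map$values)
  if (any(target_shape < src)) stop("target size must be >= source size")
  if (all(target_shape == src)) return(map)
  vals <- map$values
  # fill invalid pixels with the valid mean so splines stay finite
  if (any(!map$valid_mask)) vals[!map$valid_mask] <- mean(vals[map$valid_mask])
  out_vals <- spline_resize(vals, target_shape)
  ri <- round(seq(1, src[1], length.out = target_shape[1]))
  ci <- round(seq(1, src[2], length.out = target_shape[2]))
  out_mask <- map$valid_mask[ri, ci, drop = FALSE]
  out_vals[!out_mask] <- NA_real_
  pixel_map(out_vals, map$quantity, map$units, out_mask)
}

#' Variable-TR T1 map
#'
#' Per pixel, fits the saturation-recovery signal model
#' `S(TR) = M0 * (1 - exp(-TR / T1))` to a variable-TR series by bounded
#' least squares.
#'
#' @param images 3D array (TR index x row x col) or list of matrices.
#' @param tr_list_s repetition times in seconds (at least 4, spanning from
#'   below to well above the expected T1).
#' @param mask optional logical matrix of pixels to fit.
#' @param t1_bounds_s allowed T1 range in seconds.
#' @return a [pixel_map()] of T1 in seconds.
#' @export
t1_map <- function(images, tr_list_s, mask = NULL, t1_bounds_s = c(0.05, 20)) {
  if (is.list(images)) {
    images <- aperm(simplify2array(images), c(3, 1, 2))
  }
  d <- dim(images)
  if (d[1] != length(tr_list_s)) stop("one image per TR required")
  if (length(tr_list_s) < 4) stop("need at least 4 TR values")
  if (diff(range(tr_list_s)) <= 0) {
    stop("TR values must span a range (degenerate TR list)")
  }
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  vals <- matrix(NA_real_, d[2], d[3])
  valid <- matrix(FALSE, d[2], d[3])
  px <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(px))) {
    i <- px[k, 1]; j <- px[k, 2]
    s <- images[, i, j]
    m0_init <- max(s)
    if (!is.finite(m0_init) || m0_init <= 0) next
    fit <- tryCatch(minpack.lm::nls.lm(
      par = c(m0 = m0_init, t1 = stats::median(tr_list_s)),
      lower = c(1e-9, t1_bounds_s[1]), upper = c(10 * m0_init, t1_bounds_s[2]),
      fn = function(p) p[1] * (1 - exp(-tr_list_s / p[2])) - s,
      control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4)) next
    vals[i, j] <- fit$par[2]
    valid[i, j] <- TRUE
  }
  pixel_map(vals, "T1", "s", valid)
}

#' Per-segment field-map statistics
#'
#' Collects the valid B0 and kappa values within each segment and summarizes
#' them (median and quartiles), ready for boxplots and CSV export. Empty
#' segments are omitted with a warning.
#'
#' @param fieldmaps list with elements `b0_ppm` and/or `kappa`
#'   ([pixel_map()]s).
#' @param segments a [segment_set()].
#' @return list with `values` (long data frame: segment, quantity, value)
#'   and `summary` (per segment and quantity: n, median, q1, q3).
#' @export
segment_field_stats <- function(fieldmaps, segments) {
  long <- list()
  for (lab in names(segments$masks)) {
    m <- segments$masks[[lab]]
    any_vals <- FALSE
    for (q in intersect(c("b0_ppm", "kappa"), names(fieldmaps))) {
      pm <- fieldmaps[[q]]
      sel <- m & pm$valid_mask
      v <- pm$values[sel]
      if (length(v)) {
        any_vals <- TRUE
        long[[length(long) + 1L]] <-
          data.frame(segment = lab, quantity = q, value = v)
      }
    }
    if (!any_vals) warning("segment '", lab, "' has no valid field-map pixels")
  }
  values <- if (length(long)) do.call(rbind, long) else
    data.frame(segment = character(), quantity = character(), value = numeric())
  if (nrow(values)) {
    summary <- do.call(rbind, lapply(
      split(values, list(values$segment, values$quantity), drop = TRUE),
      function(g) data.frame(segment = g$segment[1], quantity = g$quantity[1],
                             n = nrow(g), median = stats::median(g$value),
                             q1 = stats::quantile(g$value, 0.25, names = FALSE),
                             q3 = stats::quantile(g$value, 0.75, names = FALSE))))
    rownames(summary) <- NULL
  } else {
    summary <- data.frame(segment = character(), quantity = character(),
                          n = integer(), median = numeric(), q1 = numeric(),
                          q3 = numeric())
  }
  list(values = values, summary = summary)
}
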