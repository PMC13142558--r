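# Pre-processing: respiratory motion binning for radial acquisitions,
# global PCA Z-spectral denoising, thermal drift correction, orientation.

#' Radial projection series with per-offset acquisition segments
#'
#' @param projections matrix, projection index x readout sample (magnitude).
#' @param segment_size projections per acquisition segment.
#' @param offsets_index integer vector mapping each projection to its
#'   frequency-offset frame (1-based).
#' @return an object of class `projection_series`.
#' @export
projection_series <- function(projections, segment_size, offsets_index) {
  projections <- as.matrix(projections)
  if (nrow(projections) != length(offsets_index)) {
    stop("offsets_index must have one entry per projection")
  }
  per_offset <- table(offsets_index)
  if (any(per_offset %% segment_size != 0)) {
    stop("projection count per offset must divide into whole segments")
  }
  structure(list(projections = projections, segment_size = segment_size,
                 offsets_index = as.integer(offsets_index)),
            class = "projection_series")
}

#' Bin out motion-corrupted acquisition segments
#'
#' Sums projections within each acquisition segment, takes a centered moving
#' average of the segment sums (in acquisition order), and flags segments
#' whose sum falls below `moving average - n_sigma * sd(moving average)` as
#' motion-corrupted. To keep quantified contrasts comparable, the same number
#' of segments is then discarded at every frequency offset: at each offset
#' the `k` lowest-sum segments are dropped, where `k` is the maximum flagged
#' count over offsets.
#'
#' @param series a [projection_series()].
#' @param window moving-average window in segments.
#' @param n_sigma threshold in standard deviations of the moving average.
#' @return a `binning_result` list: `kept_segments` (per-offset retained
#'   segment indices), `discarded` per offset, `threshold` offset from the
#'   moving average, `moving_average`, `segment_sums`.
#' @export
motion_bin <- function(series, window = 5, n_sigma = 1.0) {
  seg_sz <- series$segment_size
  offs <- sort(unique(series$offsets_index))
  # each projection belongs to segment (offset, local index by within-offset
  # acquisition position); segments ordered by first appearance for the
  # moving average
  pos <- stats::ave(seq_along(series$offsets_index), series$offsets_index,
                    FUN = seq_along)
  local_idx <- (pos - 1L) %/% seg_sz + 1L
  key <- paste(series$offsets_index, local_idx)
  first_row <- tapply(seq_along(key), key, min)
  seg_keys <- names(sort(first_row))
  seg_of <- match(key, seg_keys)
  n_seg <- length(seg_keys)
  seg_offsets <- as.integer(vapply(strsplit(seg_keys, " "), `[[`, character(1), 1))
  seg_local <- as.integer(vapply(strsplit(seg_keys, " "), `[[`, character(1), 2))
  per_offset <- table(seg_offsets)
  if (any(per_offset < 3)) stop("need at least 3 segments per offset")
  sums <- vapply(seq_len(n_seg),
                 function(s) sum(series$projections[seg_of == s, ]),
                 numeric(1))
  half <- floor(window / 2)
  mav <- vapply(seq_len(n_seg), function(s) {
    idx <- max(1L, s - half):min(n_seg, s + half)
    mean(sums[idx])
  }, numeric(1))
  thr_off <- n_sigma * stats::sd(mav)
  tol <- 1e-9 * max(abs(sums), 1)  # guard against pure rounding flags
  flagged <- sums < (mav - thr_off - tol)
  k <- max(vapply(offs, function(o) sum(flagged[seg_offsets == o]), integer(1)))
  kept <- list()
  discarded <- list()
  for (o in offs) {
    sel <- which(seg_offsets == o)
    if (length(sel) - k < 1L) {
      stop("discarding ", k, " segments would leave no data at offset frame ", o)
    }
    drop_local <- if (k > 0L) order(sums[sel])[seq_len(k)] else integer()
    local_index <- seg_local[sel]
    kept[[as.character(o)]] <- sort(local_index[setdiff(seq_along(sel), drop_local)])
    discarded[[as.character(o)]] <- sort(local_index[drop_local])
  }
  structure(list(kept_segments = kept, discarded = discarded,
                 threshold = thr_off, moving_average = mav,
                 segment_sums = sums, n_discarded_per_offset = k),
            class = "binning_result")
}

#' Extract the retained projections after motion binning
#'
#' Membership-only: retained projection values are returned unaltered, in
#' their original order, ready for export to an external gridding/NUFFT
#' reconstruction.
#'
#' @param series a [projection_series()].
#' @param binning a `binning_result` from [motion_bin()].
#' @return a [projection_series()] holding only retained projections.
#' @export
apply_binning <- function(series, binning) {
  keep_rows <- logical(nrow(series$projections))
  seg_sz <- series$segment_size
  counter <- list()
  seg_no <- integer(nrow(series$projections))
  for (i in seq_len(nrow(series$projections))) {
    o <- as.character(series$offsets_index[i])
    c0 <- counter[[o]]
    if (is.null(c0)) c0 <- 0L
    seg_no[i] <- c0 %/% seg_sz + 1L
    counter[[o]] <- c0 + 1L
    keep_rows[i] <- seg_no[i] %in% binning$kept_segments[[o]]
  }
  projection_series(series$projections[keep_rows, , drop = FALSE],
                    seg_sz, series$offsets_index[keep_rows])
}

malinowski_rank <- function(lambda, r, c) {
  # lambda: eigenvalues of the offset-covariance (descending), length c
  nmax <- c - 1L
  ind <- rep(NA_real_, nmax)
  for (n in seq_len(nmax)) {
    re <- sqrt(sum(lambda[(n + 1):c]) / (r * (c - n)))
    ind[n] <- re / (c - n)^2
  }
  which.min(ind)  # first index attaining the minimum
}

#' PCA denoising of a Z-spectral stack
#'
#' Casefolds the stack into a pixels x offsets matrix (globally, over all
#' pixels rather than per tissue), mean-centers over the offset dimension,
#' and keeps the number of principal components that minimizes Malinowski's
#' empirical indicator function
#' `IND(n) = RE(n) / (c - n)^2`, `RE(n) = sqrt(sum_{j>n} lambda_j / (r (c-n)))`
#' with `c` offsets, `r` pixels and `lambda_j` the residual eigenvalues.
#'
#' @param stack an [offset_stack()] (at least 3 offsets).
#' @param mask optional logical matrix restricting which pixels enter the
#'   factorization; must contain at least as many pixels as offsets.
#' @return denoised [offset_stack()] with the selected rank in
#'   `attr(, "pca_rank")`.
#' @export
pca_denoise <- function(stack, mask = NULL) {
  d <- dim(stack$data)
  c_off <- d[1]
  if (c_off < 3) stop("need at least 3 offsets for PCA denoising")
  X <- matrix(stack$data, nrow = c_off)  # offsets x all-pixels
  X <- t(X)                               # pixels x offsets
  if (!is.null(mask)) {
    sel <- as.vector(mask)
    if (sum(sel) < c_off) {
      stop("mask holds fewer pixels (", sum(sel), ") than offsets (", c_off, ")")
    }
  } else {
    sel <- rep(TRUE, nrow(X))
  }
  Xs <- X[sel, , drop = FALSE]
  r <- nrow(Xs)
  if (r < c_off) stop("need at least as many pixels as offsets")
  mu <- colMeans(Xs)
  Xc <- sweep(Xs, 2, mu)
  if (max(abs(Xc)) < 1e-14 * max(1, max(abs(Xs)))) {
    out <- stack
    attr(out, "pca_rank") <- 0L
    return(out)
  }
  sv <- svd(Xc)
  lambda <- c(sv$d^2, rep(0, c_off - length(sv$d)))
  # eigenvalues at numerical-noise level count as exactly zero, so the
  # indicator settles on the first rank that explains the data
  lambda[lambda < lambda[1] * (.Machine$double.eps * max(dim(Xc)))^2] <- 0
  n_star <- malinowski_rank(lambda, r, c_off)
  keep <- seq_len(n_star)
  recon <- sv$u[, keep, drop = FALSE] %*%
    (sv$d[keep] * t(sv$v[, keep, drop = FALSE]))
  recon <- sweep(recon, 2, mu, `+`)
  X[sel, ] <- recon
  out <- stack
  out$data <- array(t(X), dim = d)
  attr(out, "pca_rank") <- n_star
  out
}

#' Correct a global multiplicative thermal drift
#'
#' Fits a straight line through the mean intensities of time-stamped
#' reference (M0) frames and divides each frame of the stack by the fitted
#' drift factor at its acquisition time, normalized so the factor is 1 at the
#' first reference time.
#'
#' @param stack an [offset_stack()]; frame acquisition times are taken from
#'   `stack$params$frame_times_s` unless `frame_times_s` is given.
#' @param reference_frames list of 2D reference images in time order.
#' @param reference_times_s acquisition times of the reference frames.
#' @param frame_times_s optional per-frame acquisition times.
#' @return drift-corrected [offset_stack()]; the fitted line is recorded in
#'   `attr(, "drift_fit")`.
#' @export
thermal_drift_correct <- function(stack, reference_frames, reference_times_s,
                                  frame_times_s = NULL) {
  if (length(reference_frames) != length(reference_times_s)) {
    stop("one time per reference frame required")
  }
  if (length(reference_frames) < 2) {
    warning("single reference frame: no drift correction applied")
    return(stack)
  }
  if (is.null(frame_times_s)) frame_times_s <- stack$params$frame_times_s
  if (is.null(frame_times_s)) stop("frame acquisition times are required")
  if (length(frame_times_s) != dim(stack$data)[1]) {
    stop("need one acquisition time per frame")
  }
  means <- vapply(reference_frames, mean, numeric(1))
  fit <- stats::lm(means ~ reference_times_s)
  a <- stats::coef(fit)[[1]]; b <- stats::coef(fit)[[2]]
  t0 <- reference_times_s[1]
  base <- a + b * t0
  out <- stack
  for (i in seq_len(dim(stack$data)[1])) {
    factor_i <- (a + b * frame_times_s[i]) / base
    out$data[i, , ] <- stack$data[i, , ] / factor_i
  }
  attr(out, "drift_fit") <- c(intercept = a, slope = b, base = base)
  out
}

rotate90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

orient_matrix <- function(m, rotations_90, flip_h, flip_v) {
  r <- ((rotations_90 %% 4) + 4) %% 4
  for (i in seq_len(r)) m <- rotate90_cw(m)
  if (flip_h) m <- m[, ncol(m):1, drop = FALSE]
  if (flip_v) m <- m[nrow(m):1, , drop = FALSE]
  m
}

#' Rotate and flip all frames of a stack
#'
#' Applies `rotations_90` clockwise quarter-turns, then an optional
#' horizontal flip (left-right) and vertical flip (up-down), identically to
#' every frame and to the M0 image. The operation is appended to
#' `orientation_ops`. Automatic LV segmentation expects the result to follow
#' radiological short-axis display convention.
#'
#' @param stack an [offset_stack()].
#' @param rotations_90 integer number of clockwise 90-degree rotations.
#' @param flip_h,flip_v logical flips applied after rotation.
#' @return the reoriented [offset_stack()].
#' @export
orient <- function(stack, rotations_90 = 0, flip_h = FALSE, flip_v = FALSE) {
  d <- dim(stack$data)
  probe <- orient_matrix(matrix(0, d[2], d[3]), rotations_90, flip_h, flip_v)
  new_data <- array(0, dim = c(d[1], nrow(probe), ncol(probe)))
  for (i in seq_len(d[1])) {
    new_data[i, , ] <- orient_matrix(stack$data[i, , ], rotations_90,
                                     flip_h, flip_v)
  }
  out <- stack
  out$data <- new_data
  if (!is.null(stack$m0)) {
    out$m0 <- orient_matrix(stack$m0, rotations_90, flip_h, flip_v)
  }
  out$orientation_ops <- c(stack$orientation_ops,
                           list(list(rotations_90 = rotations_90,
                                     flip_h = flip_h, flip_v = flip_v)))
  out
}
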