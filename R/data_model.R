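# Core domain types. Plain S3 lists, following the field's convention of
# lightweight containers with validating constructors.

#' Acquisition parameters for a CEST-type experiment
#'
#' @param offsets_ppm ordered saturation frequency offsets in ppm.
#' @param sat_b1_uT peak saturation amplitude in microtesla.
#' @param sat_time_s saturation pulse time tp in seconds.
#' @param recovery_time_s post-readout recovery delay in seconds.
#' @param field_MHz scanner proton frequency in MHz (ppm to Hz conversion).
#' @param readout `"rectilinear"` or `"radial"`.
#' @param flip_angles_deg nominal readout flip angle(s) in degrees.
#' @param tr_list_s repetition times for a variable-TR series (optional).
#' @param b1_list_uT per-image saturation amplitudes for QUESP/MRF schedules
#'   (optional; QUESP requires at least 3 distinct nonzero values).
#' @param frame_times_s acquisition time of each frame in seconds (optional,
#'   used by thermal drift correction).
#' @return an object of class `acquisition_params`.
#' @export
acquisition_params <- function(offsets_ppm = numeric(), sat_b1_uT = 0,
                               sat_time_s = 0, recovery_time_s = 0,
                               field_MHz = 300.0,
                               readout = c("rectilinear", "radial"),
                               flip_angles_deg = 90, tr_list_s = NULL,
                               b1_list_uT = NULL, frame_times_s = NULL) {
  readout <- match.arg(readout)
  if (length(offsets_ppm) && any(!is.finite(offsets_ppm))) {
    stop("offsets_ppm must be finite")
  }
  if (!is.finite(field_MHz) || field_MHz <= 0) stop("field_MHz must be > 0")
  if (sat_time_s < 0) stop("sat_time_s must be >= 0")
  if (sat_b1_uT < 0 || any(b1_list_uT < 0)) stop("B1 values must be >= 0")
  structure(list(offsets_ppm = as.numeric(offsets_ppm),
                 sat_b1_uT = sat_b1_uT, sat_time_s = sat_time_s,
                 recovery_time_s = recovery_time_s, field_MHz = field_MHz,
                 readout = readout, flip_angles_deg = flip_angles_deg,
                 tr_list_s = tr_list_s, b1_list_uT = b1_list_uT,
                 frame_times_s = frame_times_s),
            class = "acquisition_params")
}

#' Stack of 2D images indexed by saturation frequency offset
#'
#' Frames are stored as a 3D array (offset, row, col) in raw signal units
#' until [normalize_zspectrum()] is applied. Row index increases downward
#' (radiological display after orientation fixes).
#'
#' @param data 3D numeric array, offset x row x col.
#' @param offsets_ppm per-frame offsets; length must equal `dim(data)[1]`.
#' @param params an [acquisition_params()] object.
#' @param m0 optional explicit 2D reference image.
#' @param normalized logical, whether `data` already holds Z values.
#' @return an object of class `offset_stack`.
#' @export
offset_stack <- function(data, offsets_ppm, params = acquisition_params(offsets_ppm),
                         m0 = NULL, normalized = FALSE) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3D array (offset x row x col)")
  if (dim(data)[1] != length(offsets_ppm)) {
    stop(sprintf("frame count (%d) does not match offset count (%d)",
                 dim(data)[1], length(offsets_ppm)))
  }
  structure(list(data = data, offsets_ppm = as.numeric(offsets_ppm),
                 params = params, m0 = m0, normalized = normalized,
                 orientation_ops = list()),
            class = "offset_stack")
}

#' @export
dim.offset_stack <- function(x) dim(x$data)

#' A per-pixel parameter map with validity mask
#'
#' @param values 2D numeric matrix.
#' @param quantity name of the mapped quantity (e.g. `"B0 shift"`).
#' @param units physical units (e.g. `"ppm"`).
#' @param valid_mask 2D logical matrix of successfully fitted pixels.
#' @return an object of class `pixel_map`.
#' @export
pixel_map <- function(values, quantity = "value", units = "",
                      valid_mask = NULL) {
  values <- as.matrix(values)
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  valid_mask <- as.matrix(valid_mask)
  if (!identical(dim(values), dim(valid_mask))) {
    stop("values and valid_mask must share dimensions")
  }
  if (any(!is.finite(values[valid_mask]))) {
    stop("values must be finite wherever valid_mask is TRUE")
  }
  structure(list(values = values, quantity = quantity, units = units,
                 valid_mask = valid_mask),
            class = "pixel_map")
}

#' Role-tagged collection of experiment members
#'
#' Holds one member per experiment role (`cest`, `wassr`, `dam_theta`,
#' `dam_2theta`, `t1_series`, `quesp`, `mrf`), each an [offset_stack()] or a
#' list of images, plus provenance.
#'
#' @param members named list keyed by role.
#' @param provenance list with at least `source` and `dialect`.
#' @return an object of class `experiment_bundle`.
#' @export
experiment_bundle <- function(members = list(), provenance = list()) {
  roles <- c("cest", "wassr", "dam_theta", "dam_2theta", "t1_series",
             "quesp", "mrf", "truth")
  bad <- setdiff(names(members), roles)
  if (length(bad)) stop("unknown bundle roles: ", paste(bad, collapse = ", "))
  structure(list(members = members, provenance = provenance),
            class = "experiment_bundle")
}

#' Normalize an offset stack to Z values
#'
#' Divides every frame pixelwise by the M0 reference. Frames whose offset
#' magnitude is at least `m0_threshold_ppm` are treated as M0 references
#' (multiple M0 frames are averaged pixelwise) and removed from the spectral
#' axis; alternatively an explicit `m0` image carried by the stack is used.
#' Offsets are returned sorted ascending.
#'
#' @param stack an [offset_stack()].
#' @param m0_threshold_ppm offsets at or beyond this magnitude count as M0.
#' @return a normalized [offset_stack()] with M0 frames removed.
#' @export
normalize_zspectrum <- function(stack, m0_threshold_ppm = 20) {
  is_m0 <- abs(stack$offsets_ppm) >= m0_threshold_ppm
  if (!any(is_m0) && is.null(stack$m0)) {
    stop("no M0 frame found (|offset| >= ", m0_threshold_ppm,
         " ppm) and no explicit m0 image; supply one of the two")
  }
  if (any(is_m0)) {
    m0_frames <- stack$data[is_m0, , , drop = FALSE]
    m0 <- apply(m0_frames, c(2, 3), mean)
  } else {
    m0 <- stack$m0
  }
  keep <- which(!is_m0)
  ord <- keep[order(stack$offsets_ppm[keep])]
  z <- stack$data[ord, , , drop = FALSE]
  for (i in seq_len(dim(z)[1])) z[i, , ] <- z[i, , ] / m0
  out <- stack
  out$data <- z
  out$offsets_ppm <- stack$offsets_ppm[ord]
  out$params$offsets_ppm <- out$offsets_ppm
  out$m0 <- m0
  out$normalized <- TRUE
  out
}

#' Write per-segment fit results to CSV
#'
#' One row per segment, one column per fitted quantity, values written with
#' at least 6 significant digits (RFC 4180 CSV).
#'
#' @param fits data frame (or coercible) of per-segment results; row names or
#'   a `segment` column identify segments.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(fits, path) {
  fits <- as.data.frame(fits)
  if (!"segment" %in% names(fits) && !is.null(rownames(fits))) {
    fits <- cbind(segment = rownames(fits), fits)
  }
  num <- vapply(fits, is.numeric, logical(1))
  fits[num] <- lapply(fits[num], function(x) formatC(x, digits = 8, format = "g"))
  utils::write.csv(fits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
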