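# Manual polygon ROIs and semi-automated six-segment left-ventricular
# myocardial segmentation from a single mid-ventricular short-axis image.

#' Rasterize a polygon ROI to a boolean mask
#'
#' Pixel centers strictly inside the polygon (even-odd fill rule) are TRUE.
#' Pixel (i, j) has center (row = i, col = j).
#'
#' @param vertices two-column matrix of (row, col) polygon vertices, at
#'   least 3.
#' @param shape image dimensions `c(rows, cols)`.
#' @return logical matrix of dimension `shape`.
#' @export
polygon_mask <- function(vertices, shape) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3) stop("a polygon needs at least 3 vertices")
  area2 <- abs(sum(vertices[, 1] * c(vertices[-1, 2], vertices[1, 2]) -
                   vertices[, 2] * c(vertices[-1, 1], vertices[1, 1])))
  if (area2 < .Machine$double.eps) {
    warning("degenerate (zero-area) polygon: returning an empty mask")
    return(matrix(FALSE, shape[1], shape[2]))
  }
  centers <- cbind(rep(seq_len(shape[1]), times = shape[2]),
                   rep(seq_len(shape[2]), each = shape[1]))
  inside <- mgcv::in.out(rbind(vertices, vertices[1, ]), centers)
  matrix(inside, shape[1], shape[2])
}

#' Left-ventricular geometry for automatic segmentation
#'
#' @param epicardium,endocardium two-column (row, col) polygons; the
#'   endocardial contour must lie strictly inside the epicardial one.
#' @param anterior_insertion,inferior_insertion (row, col) points where the
#'   right-ventricular wall meets the LV.
#' @return an object of class `lv_geometry`.
#' @export
lv_geometry <- function(epicardium, endocardium, anterior_insertion,
                        inferior_insertion) {
  if (all(abs(anterior_insertion - inferior_insertion) < 1e-9)) {
    stop("insertion points must be distinct")
  }
  structure(list(epicardium = as.matrix(epicardium),
                 endocardium = as.matrix(endocardium),
                 anterior_insertion = as.numeric(anterior_insertion),
                 inferior_insertion = as.numeric(inferior_insertion)),
            class = "lv_geometry")
}

#' A named, pairwise-disjoint set of segmentation masks
#'
#' @param masks named list of logical matrices.
#' @param kind `"manual"` or `"lv_auto"`.
#' @return an object of class `segment_set`.
#' @export
segment_set <- function(masks, kind = c("manual", "lv_auto")) {
  kind <- match.arg(kind)
  if (length(masks) > 1) {
    acc <- masks[[1]]
    for (i in 2:length(masks)) {
      if (any(acc & masks[[i]])) stop("segment masks must be pairwise disjoint")
      acc <- acc | masks[[i]]
    }
  }
  structure(list(masks = masks, kind = kind), class = "segment_set")
}

# Pixel angle in the centered, y-up (radiological row-down) coordinate
# system, rotated so the inferior insertion point sits at 0 degrees.
# Angles increase counterclockwise, returned in [0, 2*pi).
lv_pixel_angles <- function(rows, cols, center, rotate_by) {
  x <- cols - center[2]
  y <- center[1] - rows
  th <- atan2(y, x) - rotate_by
  (th %% (2 * pi))
}

#' Six-segment LV myocardial segmentation
#'
#' The LV myocardial mask is the epicardial area minus the endocardial area.
#' All pixel coordinates are centered on the LV mask centroid, per-pixel
#' angles are computed with the two-argument arctangent, and the coordinate
#' system is rotated so the inferior insertion point lies at 0 degrees. The
#' arc between the inferior and anterior insertion points whose angular span
#' is below 180 degrees is the septum (override with `septum_arc`), split
#' into two equal angular halves: inferoseptal adjacent to the inferior
#' point, anteroseptal adjacent to the anterior point. The remaining free
#' wall is split into four equal angular quarters ordered anterior,
#' anterolateral, inferolateral, inferior starting from the anterior
#' insertion point. Sector intervals are half-open, so boundary pixels are
#' assigned deterministically.
#'
#' @param geom an [lv_geometry()].
#' @param shape image dimensions `c(rows, cols)`.
#' @param septum_arc `"auto"` picks the arc spanning < 180 degrees;
#'   `"ccw"`/`"cw"` force the counterclockwise or clockwise arc from the
#'   inferior to the anterior insertion point.
#' @param insertion_tol_px maximum allowed distance (pixels) from each
#'   insertion point to the LV myocardial mask.
#' @return a [segment_set()] with labels `anteroseptal`, `inferoseptal`,
#'   `anterior`, `anterolateral`, `inferolateral`, `inferior`; the union of
#'   the six masks equals the LV mask exactly.
#' @export
lv_segments <- function(geom, shape, septum_arc = c("auto", "ccw", "cw"),
                        insertion_tol_px = 4) {
  septum_arc <- match.arg(septum_arc)
  epi <- polygon_mask(geom$epicardium, shape)
  endo <- polygon_mask(geom$endocardium, shape)
  lv <- epi & !endo
  if (!any(lv)) stop("empty LV mask")
  idx <- which(lv, arr.ind = TRUE)
  center <- c(mean(idx[, 1]), mean(idx[, 2]))
  # insertion points must sit on or near the annulus
  for (pt in list(geom$anterior_insertion, geom$inferior_insertion)) {
    d <- sqrt((idx[, 1] - pt[1])^2 + (idx[, 2] - pt[2])^2)
    if (min(d) > insertion_tol_px) {
      stop("insertion point (", pt[1], ", ", pt[2],
           ") lies outside the LV annulus neighborhood")
    }
  }
  ang_at <- function(pt) atan2(center[1] - pt[1], pt[2] - center[2])
  th_inf <- ang_at(geom$inferior_insertion)
  th_ant <- (ang_at(geom$anterior_insertion) - th_inf) %% (2 * pi)
  theta <- lv_pixel_angles(idx[, 1], idx[, 2], center, th_inf)
  septum_ccw <- switch(septum_arc,
                       auto = th_ant <= pi,
                       ccw = TRUE,
                       cw = FALSE)
  labels <- c("anteroseptal", "inferoseptal", "anterior", "anterolateral",
              "inferolateral", "inferior")
  seg_id <- integer(nrow(idx))
  if (septum_ccw) {
    a <- th_ant                      # septum = [0, a), free wall = [a, 2pi)
    q <- (2 * pi - a) / 4
    breaks <- c(0, a / 2, a, a + q, a + 2 * q, a + 3 * q, 2 * pi)
    order_lab <- c("inferoseptal", "anteroseptal", "anterior",
                   "anterolateral", "inferolateral", "inferior")
  } else {
    a <- th_ant                      # septum = [a, 2pi), free wall = [0, a)
    s <- (2 * pi - a) / 2
    q <- a / 4
    breaks <- c(0, q, 2 * q, 3 * q, a, a + s, 2 * pi)
    order_lab <- c("inferior", "inferolateral", "anterolateral",
                   "anterior", "anteroseptal", "inferoseptal")
  }
  seg_id <- findInterval(theta, breaks, rightmost.closed = FALSE,
                         left.open = FALSE)
  seg_id[seg_id > 6L] <- 6L  # theta == 2*pi wraps to the last sector
  masks <- stats::setNames(vector("list", 6), labels)
  for (j in 1:6) {
    m <- matrix(FALSE, shape[1], shape[2])
    sel <- idx[order_lab[seg_id] == labels[j], , drop = FALSE]
    m[sel] <- TRUE
    masks[[labels[j]]] <- m
  }
  segment_set(masks, kind = "lv_auto")
}

#' Persist segmentation geometry as JSON
#'
#' @param geom an [lv_geometry()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_lv_geometry <- function(geom, path) {
  jsonlite::write_json(
    list(epicardium = unclass(geom$epicardium),
         endocardium = unclass(geom$endocardium),
         anterior_insertion = geom$anterior_insertion,
         inferior_insertion = geom$inferior_insertion),
    path, digits = NA)
  invisible(path)
}

#' Read segmentation geometry from JSON
#'
#' @param path JSON file written by [write_lv_geometry()].
#' @return an [lv_geometry()].
#' @export
read_lv_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  lv_geometry(g$epicardium, g$endocardium,
              g$anterior_insertion, g$inferior_insertion)
}
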