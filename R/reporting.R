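# Pixel filtering, display clipping, map/plot export, and the batch
# pipeline orchestrating all stages.

#' Pixel filter specification
#'
#' Sequential filters applied to contrast maps: (1) kappa outliers beyond
#' `kappa_sigma` standard deviations of the per-dataset mean, (2) absolute
#' B0 shift beyond `b0_abs_ppm`, (3) MT amplitude below `mt_min`.
#'
#' @param kappa_sigma kappa threshold in per-dataset standard deviations.
#' @param b0_abs_ppm absolute B0 shift threshold in ppm.
#' @param mt_min minimum MT amplitude (fraction of M0).
#' @param enabled named logical vector switching individual filters.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(kappa_sigma = 1.0, b0_abs_ppm = 0.25, mt_min = 0.02,
                        enabled = c(kappa = TRUE, b0 = TRUE, mt = TRUE)) {
  if (kappa_sigma <= 0 || b0_abs_ppm <= 0 || mt_min <= 0) {
    stop("filter thresholds must be > 0")
  }
  structure(list(kappa_sigma = kappa_sigma, b0_abs_ppm = b0_abs_ppm,
                 mt_min = mt_min, enabled = enabled),
            class = "filter_spec")
}

#' Sequential pixel filtering of contrast maps
#'
#' Applies the kappa, B0 and MT filters in order and reports per-step
#' attrition. Kappa statistics (mean, sd) are computed over the dataset's
#' valid pixels, i.e. per animal when one bundle holds one animal.
#'
#' @param contrasts named list of [pixel_map()]s; an `MT` entry feeds the MT
#'   filter.
#' @param fieldmaps list with `kappa` and/or `b0_ppm` [pixel_map()]s.
#' @param spec a [filter_spec()].
#' @return list with `valid_mask` (logical matrix of survivors), `table`
#'   (data frame of surviving pixel values, one column per contrast plus
#'   kappa/B0), and `attrition` (pixel counts after each step).
#' @export
filter_pixels <- function(contrasts, fieldmaps, spec = filter_spec()) {
  base <- Reduce(`&`, lapply(contrasts, function(m) m$valid_mask))
  counts <- c(initial = sum(base))
  mask <- base
  en <- spec$enabled
  if (isTRUE(en[["kappa"]]) && !is.null(fieldmaps$kappa)) {
    k <- fieldmaps$kappa$values
    sel <- mask & fieldmaps$kappa$valid_mask
    mu <- mean(k[sel]); sdev <- stats::sd(k[sel])
    mask <- sel & (abs(k - mu) <= spec$kappa_sigma * sdev)
    mask[is.na(mask)] <- FALSE
    counts <- c(counts, after_kappa = sum(mask))
  }
  if (isTRUE(en[["b0"]]) && !is.null(fieldmaps$b0_ppm)) {
    b0 <- fieldmaps$b0_ppm$values
    mask <- mask & fieldmaps$b0_ppm$valid_mask & (abs(b0) <= spec$b0_abs_ppm)
    mask[is.na(mask)] <- FALSE
    counts <- c(counts, after_b0 = sum(mask))
  }
  if (isTRUE(en[["mt"]]) && !is.null(contrasts$MT)) {
    mask <- mask & (contrasts$MT$values >= spec$mt_min)
    mask[is.na(mask)] <- FALSE
    counts <- c(counts, after_mt = sum(mask))
  }
  cols <- lapply(contrasts, function(m) m$values[mask])
  if (!is.null(fieldmaps$kappa)) cols$kappa <- fieldmaps$kappa$values[mask]
  if (!is.null(fieldmaps$b0_ppm)) cols$b0_ppm <- fieldmaps$b0_ppm$values[mask]
  idx <- which(mask, arr.ind = TRUE)
  table <- cbind(data.frame(row = idx[, 1], col = idx[, 2]),
                 as.data.frame(cols))
  list(valid_mask = mask, table = table, attrition = counts)
}

#' Percentile clipping for display
#'
#' Values below the `lo_pct` percentile or above the `hi_pct` percentile of
#' the valid pixels are set to those percentile values (clipped, not
#' discarded). Percentiles use linear interpolation between closest ranks.
#'
#' @param map a [pixel_map()].
#' @param lo_pct,hi_pct percentile bounds, `0 <= lo < hi <= 100`.
#' @return a clipped [pixel_map()].
#' @export
percentile_clip <- function(map, lo_pct = 5, hi_pct = 95) {
  if (!(lo_pct >= 0 && lo_pct < hi_pct && hi_pct <= 100)) {
    stop("need 0 <= lo < hi <= 100")
  }
  v <- map$values[map$valid_mask]
  if (!length(v)) return(map)
  q <- stats::quantile(v, c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
  out <- map$values
  out[map$valid_mask] <- pmin(pmax(v, q[1]), q[2])
  pixel_map(out, map$quantity, map$units, map$valid_mask)
}

write_map <- function(map, path_base, png_too = TRUE) {
  utils::write.csv(as.data.frame(map$values),
                   paste0(path_base, ".csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(map$valid_mask * 1L),
                   paste0(path_base, "_mask.csv"), row.names = FALSE)
  if (png_too && requireNamespace("png", quietly = TRUE)) {
    v <- map$values
    rng <- range(v[map$valid_mask], na.rm = TRUE)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    img <- (v - rng[1]) / diff(rng)
    img[!map$valid_mask] <- 0
    png::writePNG(pmin(pmax(img, 0), 1), paste0(path_base, ".png"))
  }
  invisible(path_base)
}

#' Run the batch analysis pipeline
#'
#' Executes, for the experiment roles present in the configuration, the
#' stage order load, orient, motion bin, denoise, drift, normalize, segment,
#' fit/map, filter, report. Every stage's parameters are recorded in a
#' manifest and the outputs are collected in a results directory (zipped
#' when a zip program is available). Given the same configuration and seed
#' the archive contents are bit-identical across runs.
#'
#' @param config named list (or path to a JSON/YAML file) with entries:
#'   `bundle` (path to a portable bundle, or an [experiment_bundle()]),
#'   `out_dir`, optional `seed`, `orient` (list rotations_90/flip_h/flip_v),
#'   `denoise` (logical), `pools` (requested CEST pools), `geometry` (path
#'   to LV geometry JSON or an [lv_geometry()]), `filters` (list of
#'   [filter_spec()] arguments), `pixelwise` (logical),
#'   `theta_nominal_deg`.
#' @return list with `out_dir`, `manifest`, and the computed objects
#'   (`segment_fits`, `maps`, `fieldmaps`, `filter_result` where
#'   applicable).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML configurations require the yaml package")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must name an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list(), package_version =
                     as.character(utils::packageVersion("cestkit")))
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  bundle <- config$bundle
  if (is.character(bundle)) {
    if (!dir.exists(bundle)) stop("load stage failed: no bundle at ", bundle)
    bundle <- read_bundle(bundle)
  }
  if (!inherits(bundle, "experiment_bundle")) {
    stop("load stage failed: config$bundle is not a bundle or path")
  }
  note("load", provenance = bundle$provenance)
  results <- list(out_dir = out_dir)

  maybe_orient <- function(st) {
    o <- config$orient
    if (is.null(o)) return(st)
    orient(st, o$rotations_90 %||% 0, isTRUE(o$flip_h), isTRUE(o$flip_v))
  }

  segments <- NULL
  if (!is.null(config$geometry)) {
    geom <- if (is.character(config$geometry)) read_lv_geometry(config$geometry)
            else config$geometry
    shape <- dim(bundle$members[[1]]$data)[2:3]
    segments <- lv_segments(geom, shape)
    note("segment", kind = "lv_auto", labels = names(segments$masks))
  } else if (!is.null(config$segments)) {
    segments <- config$segments
    note("segment", kind = segments$kind, labels = names(segments$masks))
  }

  fieldmaps <- list()
  if (!is.null(bundle$members$wassr)) {
    w <- normalize_zspectrum(maybe_orient(bundle$members$wassr))
    fieldmaps$b0_ppm <- wassr_b0(w)
    note("wassr", n_offsets = length(w$offsets_ppm))
    write_map(fieldmaps$b0_ppm, file.path(out_dir, "b0_map"))
  }
  if (!is.null(bundle$members$dam_theta)) {
    th <- bundle$members$truth$theta_nominal_deg %||%
      config$theta_nominal_deg %||% 60
    fieldmaps$kappa <- dam_b1(bundle$members$dam_theta[[1]],
                              bundle$members$dam_2theta[[1]], th)
    note("b1map", theta_nominal_deg = th)
    write_map(fieldmaps$kappa, file.path(out_dir, "kappa_map"))
  }
  if (!is.null(bundle$members$t1_series)) {
    ts <- bundle$members$t1_series
    fieldmaps$t1_s <- t1_map(ts$data, ts$params$tr_list_s)
    note("t1map", tr_list_s = ts$params$tr_list_s)
    write_map(fieldmaps$t1_s, file.path(out_dir, "t1_map"))
  }
  results$fieldmaps <- fieldmaps

  if (!is.null(bundle$members$cest)) {
    st <- maybe_orient(bundle$members$cest)
    if (isTRUE(config$denoise)) {
      st <- pca_denoise(st)
      note("denoise", rank = attr(st, "pca_rank"))
    }
    st <- normalize_zspectrum(st)
    note("normalize", n_offsets = length(st$offsets_ppm))
    pools <- config$pools %||% "amide"
    if (!is.null(segments)) {
      fits <- fit_segmentwise(st, segments, pools)
      tab <- segment_fit_table(fits)
      write_segment_table(tab, file.path(out_dir, "segment_fits.csv"))
      results$segment_fits <- fits
      note("fit_segmentwise", pools = pools, n_segments = length(fits))
    }
    if (isTRUE(config$pixelwise)) {
      mask <- if (!is.null(segments)) Reduce(`|`, segments$masks) else NULL
      maps <- fit_pixelwise(st, mask, pools)
      for (nm in names(maps)) {
        write_map(maps[[nm]], file.path(out_dir, paste0("contrast_", nm)))
      }
      results$maps <- maps
      note("fit_pixelwise", pools = pools, n_pixels = sum(mask %||% TRUE))
      if (length(fieldmaps)) {
        fspec <- do.call(filter_spec, config$filters %||% list())
        fr <- filter_pixels(maps[names(maps) %in% c("water", "MT", pools)],
                            fieldmaps, fspec)
        utils::write.csv(fr$table, file.path(out_dir, "surviving_pixels.csv"),
                         row.names = FALSE)
        results$filter_result <- fr
        note("filter", attrition = as.list(fr$attrition))
      }
    }
  }

  if (!is.null(segments) && length(fieldmaps)) {
    stats_out <- segment_field_stats(fieldmaps, segments)
    if (nrow(stats_out$summary)) {
      utils::write.csv(stats_out$summary,
                       file.path(out_dir, "segment_field_stats.csv"),
                       row.names = FALSE)
    }
    results$segment_field_stats <- stats_out
  }

  manifest$config <- config[setdiff(names(config), c("bundle", "segments",
                                                     "geometry"))]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  results$manifest <- manifest
  zipfile <- paste0(out_dir, ".zip")
  status <- tryCatch(utils::zip(zipfile, list.files(out_dir, full.names = TRUE),
                                flags = "-jq"),
                     error = function(e) 1L, warning = function(w) 1L)
  if (identical(status, 0L)) results$archive <- zipfile
  results
}

`%||%` <- function(a, b) if (is.null(a)) b else a
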