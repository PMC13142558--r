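# Readers and writers. Two on-disk layouts are supported:
#  * ParaVision-style experiment directories: a JCAMP-DX "method" text file
#    plus a reconstructed image block ("2dseq", float64 little-endian here);
#  * portable bundles: a JSON sidecar plus one binary array file per member,
#    so every pipeline stage can run without the Bruker layout.

#' Default ParaVision parameter key map (PV6/7 MT-module dialect)
#'
#' Maps the quantities the toolkit needs onto JCAMP-DX parameter names.
#' Only sequences based on the ParaVision 6/7 MT module are supported;
#' unknown dialects fail loudly rather than guessing. In this dialect,
#' offsets are stored in ppm, B1 amplitudes in microtesla and times in
#' seconds.
#'
#' @return named list of JCAMP-DX keys.
#' @export
pv_key_map <- function() {
  list(offsets = "PVM_SatTransFreqValues",
       b1 = "PVM_SatTransPulseAmpl",
       sat_time = "PVM_SatTransPulseTime",
       recovery = "PVM_RecoveryTime",
       flip = "PVM_ExcPulseAngle",
       freq = "PVM_FrqWork",
       matrix = "PVM_Matrix",
       tr_list = "PVM_VtrList",
       b1_list = "PVM_SatTransPowerList",
       frame_times = "PVM_FrameTimes",
       units = c(offsets = "ppm", b1 = "uT", time = "s"))
}

parse_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^##\\$?", ln)) {
      key <- sub("^##\\$?([^=]+)=.*$", "\\1", ln)
      rhs <- sub("^##\\$?[^=]+=", "", ln)
      if (grepl("^\\(", rhs)) {
        # array parameter: values on following lines until the next ##
        vals <- character()
        j <- i + 1L
        while (j <= length(lines) && !grepl("^##", lines[j])) {
          vals <- c(vals, lines[j]); j <- j + 1L
        }
        out[[key]] <- scan(text = paste(vals, collapse = " "),
                           quiet = TRUE, what = numeric())
        i <- j
      } else {
        num <- suppressWarnings(as.numeric(rhs))
        out[[key]] <- if (is.na(num)) rhs else num
        i <- i + 1L
      }
    } else i <- i + 1L
  }
  out
}

#' Read one ParaVision-style experiment directory
#'
#' Parses the JCAMP-DX `method` file through the configured key map, reads
#' the reconstructed image block, and returns an [offset_stack()] tagged with
#' the requested role. Parameter keys that are present but unused are
#' ignored; required keys that are missing raise an error.
#'
#' @param path experiment directory.
#' @param role one of `cest`, `wassr`, `dam_theta`, `dam_2theta`,
#'   `t1_series`, `quesp`, `mrf`.
#' @param key_map JCAMP-DX key map, see [pv_key_map()].
#' @return an [offset_stack()].
#' @export
read_paravision_experiment <- function(path, role = "cest",
                                       key_map = pv_key_map()) {
  method_file <- file.path(path, "method")
  if (!file.exists(method_file)) {
    stop("not a ParaVision experiment: no 'method' parameter file in ", path)
  }
  pars <- parse_jcampdx(method_file)
  need <- function(k) {
    if (is.null(pars[[key_map[[k]]]])) {
      stop("method file lacks required key '", key_map[[k]], "'")
    }
    pars[[key_map[[k]]]]
  }
  mat <- need("matrix")
  offsets <- need("offsets")
  img_file <- file.path(path, "2dseq")
  if (!file.exists(img_file)) stop("missing image block '2dseq' in ", path)
  n_vals <- file.size(img_file) / 8L
  n_frames <- n_vals / (mat[1] * mat[2])
  if (n_frames != round(n_frames)) {
    stop("image block size is not a whole number of frames")
  }
  n_frames <- as.integer(n_frames)
  if (n_frames != length(offsets)) {
    stop(sprintf(
      "offset count (%d) does not match frame count (%d) in %s",
      length(offsets), n_frames, path))
  }
  raw <- readBin(img_file, what = "double", n = n_vals, size = 8L,
                 endian = "little")
  data <- aperm(array(raw, dim = c(mat[2], mat[1], n_frames)), c(3, 2, 1))
  grab <- function(k, default) {
    v <- pars[[key_map[[k]]]]
    if (is.null(v)) default else v
  }
  params <- acquisition_params(
    offsets_ppm = offsets,
    sat_b1_uT = grab("b1", 0),
    sat_time_s = grab("sat_time", 0),
    recovery_time_s = grab("recovery", 0),
    field_MHz = grab("freq", 300.0),
    flip_angles_deg = grab("flip", 90),
    tr_list_s = pars[[key_map[["tr_list"]]]],
    b1_list_uT = pars[[key_map[["b1_list"]]]],
    frame_times_s = pars[[key_map[["frame_times"]]]])
  st <- offset_stack(data, offsets, params)
  attr(st, "role") <- role
  st
}

format_jcamp_array <- function(key, values) {
  c(sprintf("##$%s=( %d )", key, length(values)),
    paste(formatC(values, digits = 17, format = "g"), collapse = " "))
}

#' Write an offset stack as a ParaVision-style fixture directory
#'
#' Emits a JCAMP-DX `method` file and a float64 `2dseq` image block that
#' [read_paravision_experiment()] reads back bit-exactly. Used by the
#' synthetic fixture generators so the Bruker reader is exercised in tests.
#'
#' @param stack an [offset_stack()].
#' @param path directory to create.
#' @param key_map JCAMP-DX key map, see [pv_key_map()].
#' @return `path`, invisibly.
#' @export
write_fixture_experiment <- function(stack, path, key_map = pv_key_map()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  p <- stack$params
  d <- dim(stack$data)
  lines <- c("##TITLE=cestkit synthetic fixture",
             "##JCAMPDX=4.24",
             "##$Method=<User:mtModule>",
             format_jcamp_array(key_map$matrix, c(d[2], d[3])),
             format_jcamp_array(key_map$offsets, stack$offsets_ppm),
             format_jcamp_array(key_map$b1, p$sat_b1_uT),
             format_jcamp_array(key_map$sat_time, p$sat_time_s),
             format_jcamp_array(key_map$recovery, p$recovery_time_s),
             sprintf("##$%s=%s", key_map$flip,
                     formatC(p$flip_angles_deg[1], digits = 17, format = "g")),
             format_jcamp_array(key_map$freq, p$field_MHz))
  if (!is.null(p$tr_list_s)) {
    lines <- c(lines, format_jcamp_array(key_map$tr_list, p$tr_list_s))
  }
  if (!is.null(p$b1_list_uT)) {
    lines <- c(lines, format_jcamp_array(key_map$b1_list, p$b1_list_uT))
  }
  if (!is.null(p$frame_times_s)) {
    lines <- c(lines, format_jcamp_array(key_map$frame_times, p$frame_times_s))
  }
  lines <- c(lines, "##END=")
  writeLines(lines, file.path(path, "method"))
  vec <- as.vector(aperm(stack$data, c(3, 2, 1)))
  writeBin(vec, file.path(path, "2dseq"), size = 8L, endian = "little")
  invisible(path)
}

params_to_list <- function(p) unclass(p)

params_from_list <- function(l) {
  do.call(acquisition_params, l[!vapply(l, is.null, logical(1))])
}

write_array_bin <- function(x, path) {
  writeBin(as.vector(x), path, size = 8L, endian = "little")
  dim(x)
}

read_array_bin <- function(path, dims) {
  v <- readBin(path, "double", n = prod(dims), size = 8L, endian = "little")
  array(v, dim = dims)
}

#' Write an experiment bundle in the portable layout
#'
#' The portable layout is a directory holding `bundle.json` (acquisition
#' parameters, provenance and array shapes) plus one little-endian float64
#' binary file per array, so every analysis stage can run without the
#' ParaVision directory structure.
#'
#' @param bundle an [experiment_bundle()].
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  side <- list(format = "cestkit-bundle-1", members = list(),
               provenance = bundle$provenance)
  for (role in names(bundle$members)) {
    m <- bundle$members[[role]]
    if (inherits(m, "offset_stack")) {
      f <- paste0(role, ".bin")
      dims <- write_array_bin(m$data, file.path(path, f))
      entry <- list(kind = "offset_stack", file = f, dim = dims,
                    offsets_ppm = m$offsets_ppm,
                    normalized = m$normalized,
                    params = params_to_list(m$params))
      if (!is.null(m$m0)) {
        f0 <- paste0(role, "_m0.bin")
        entry$m0_file <- f0
        entry$m0_dim <- write_array_bin(m$m0, file.path(path, f0))
      }
      side$members[[role]] <- entry
    } else if (is.list(m) &&
               all(vapply(m, is.matrix, logical(1)))) {
      files <- character(length(m))
      dims <- list()
      for (i in seq_along(m)) {
        files[i] <- sprintf("%s_%02d.bin", role, i)
        dims[[i]] <- write_array_bin(as.matrix(m[[i]]),
                                     file.path(path, files[i]))
      }
      side$members[[role]] <- list(kind = "image_list", files = files,
                                   dim = dims, names = names(m))
    } else {
      # free-form list: matrices go to binary files, scalars stay in JSON
      scalars <- list(); arrays <- list()
      for (nm in names(m)) {
        if (is.matrix(m[[nm]]) || (is.numeric(m[[nm]]) && length(m[[nm]]) > 1)) {
          f <- sprintf("%s_%s.bin", role, nm)
          arrays[[nm]] <- list(file = f,
                               dim = write_array_bin(as.matrix(m[[nm]]),
                                                     file.path(path, f)))
        } else {
          scalars[[nm]] <- m[[nm]]
        }
      }
      side$members[[role]] <- list(kind = "table", data = scalars,
                                   arrays = arrays)
    }
  }
  jsonlite::write_json(side, file.path(path, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an experiment bundle from the portable layout
#'
#' @param path directory written by [write_bundle()].
#' @return an [experiment_bundle()].
#' @export
read_bundle <- function(path) {
  side_file <- file.path(path, "bundle.json")
  if (!file.exists(side_file)) stop("not a portable bundle: no bundle.json in ", path)
  side <- jsonlite::read_json(side_file, simplifyVector = FALSE)
  members <- list()
  for (role in names(side$members)) {
    e <- side$members[[role]]
    if (identical(e$kind, "offset_stack")) {
      data <- read_array_bin(file.path(path, e$file), unlist(e$dim))
      pl <- lapply(e$params, function(v) {
        if (is.list(v)) unlist(v) else v
      })
      st <- offset_stack(data, unlist(e$offsets_ppm),
                         params_from_list(pl),
                         normalized = isTRUE(e$normalized))
      if (!is.null(e$m0_file)) {
        st$m0 <- as.matrix(read_array_bin(file.path(path, e$m0_file),
                                          unlist(e$m0_dim)))
      }
      members[[role]] <- st
    } else if (identical(e$kind, "image_list")) {
      imgs <- lapply(seq_along(e$files), function(i) {
        as.matrix(read_array_bin(file.path(path, e$files[[i]]),
                                 unlist(e$dim[[i]])))
      })
      if (length(e$names)) names(imgs) <- unlist(e$names)
      members[[role]] <- imgs
    } else {
      m <- lapply(e$data, function(v) if (is.list(v)) unlist(v) else v)
      for (nm in names(e$arrays)) {
        a <- e$arrays[[nm]]
        m[[nm]] <- as.matrix(read_array_bin(file.path(path, a$file),
                                            unlist(a$dim)))
      }
      members[[role]] <- m
    }
  }
  provenance <- lapply(side$provenance %||% list(),
                       function(v) if (is.list(v)) unlist(v) else v)
  experiment_bundle(members, provenance)
}
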