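# CEST fingerprinting: dictionary generation over a parameter grid using the
# Bloch-McConnell simulator, and dot-product matching of measured signal
# trajectories.

#' Define a CEST fingerprinting scenario
#'
#' One solute pool's (fb, kb) varies over the grid together with the water
#' relaxation rates; the solute relaxation rates and chemical shift are
#' fixed. Grid rows are ordered lexicographically over (fb, kb, R1a, R2A)
#' with the last grid varying fastest.
#'
#' @param field_MHz scanner proton frequency in MHz.
#' @param fb_grid,kb_grid solute proton volume fractions and exchange rates.
#' @param r1a_grid,r2a_grid water relaxation rate grids in s^-1.
#' @param r1b,r2b fixed solute relaxation rates in s^-1.
#' @param dw_ppm solute chemical shift in ppm.
#' @param schedule an [mrf_schedule()].
#' @return an object of class `mrf_scenario`.
#' @export
mrf_scenario <- function(field_MHz, fb_grid, kb_grid, r1a_grid, r2a_grid,
                         r1b = 1, r2b = 50, dw_ppm = 2.0, schedule) {
  stopifnot(length(fb_grid) >= 1, length(kb_grid) >= 1,
            length(r1a_grid) >= 1, length(r2a_grid) >= 1)
  structure(list(field_MHz = field_MHz, fb_grid = sort(fb_grid),
                 kb_grid = sort(kb_grid), r1a_grid = sort(r1a_grid),
                 r2a_grid = sort(r2a_grid), r1b = r1b, r2b = r2b,
                 dw_ppm = dw_ppm, schedule = schedule),
            class = "mrf_scenario")
}

#' Load an MRF scenario from a YAML or JSON configuration file
#'
#' The file lists `field_MHz`, the parameter grids (`fb`, `kb`, `r1a`,
#' `r2a`), fixed solute properties (`r1b`, `r2b`, `dw_ppm`) and a schedule
#' table with per-image `b1_uT`, `offset_ppm`, `tp_s`, `recovery_s`,
#' `flip_deg`.
#'
#' @param path configuration file (`.yaml`/`.yml` needs the yaml package;
#'   `.json` uses jsonlite).
#' @return an [mrf_scenario()].
#' @export
read_mrf_scenario <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML scenarios requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sch <- cfg$schedule
  events <- lapply(seq_along(sch$b1_uT), function(i) {
    saturation_event(sch$b1_uT[i], sch$tp_s[i], sch$offset_ppm[i])
  })
  mrf_scenario(field_MHz = cfg$field_MHz, fb_grid = cfg$fb, kb_grid = cfg$kb,
               r1a_grid = cfg$r1a, r2a_grid = cfg$r2a,
               r1b = cfg$r1b, r2b = cfg$r2b, dw_ppm = cfg$dw_ppm,
               schedule = mrf_schedule(events, sch$recovery_s, sch$flip_deg))
}

#' Build an MRF dictionary
#'
#' Simulates one signal trajectory per grid point with
#' [simulate_trajectory()] and L2-normalizes every row. Row order is
#' deterministic (lexicographic over fb, kb, R1a, R2a).
#'
#' @param scenario an [mrf_scenario()].
#' @param max_entries guard against accidental desk-scale explosions.
#' @return an object of class `mrf_dictionary`: `entries` (rows x schedule
#'   length, unit L2 norm), `grid` (data frame of parameter tuples),
#'   `scenario`.
#' @export
build_dictionary <- function(scenario, max_entries = 2e6) {
  grid <- expand.grid(r2a = scenario$r2a_grid, r1a = scenario$r1a_grid,
                      kb = scenario$kb_grid, fb = scenario$fb_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("fb", "kb", "r1a", "r2a")]
  n <- nrow(grid)
  if (n > max_entries) {
    stop("grid size ", n, " exceeds the cap of ", max_entries,
         "; reduce the parameter grids")
  }
  len <- length(scenario$schedule)
  entries <- matrix(0, n, len)
  for (r in seq_len(n)) {
    water <- pool_parameters("water", fb = 1, kb = 0, dw_ppm = 0,
                             r1 = grid$r1a[r], r2 = grid$r2a[r])
    pools <- list(water)
    if (grid$fb[r] > 0) {
      pools <- c(pools, list(pool_parameters(
        "solute", fb = grid$fb[r], kb = grid$kb[r], dw_ppm = scenario$dw_ppm,
        r1 = scenario$r1b, r2 = scenario$r2b)))
    }
    traj <- simulate_trajectory(pools, scenario$schedule, scenario$field_MHz)
    nrm <- sqrt(sum(traj^2))
    entries[r, ] <- if (nrm > 0) traj / nrm else traj
  }
  structure(list(entries = entries, grid = grid, scenario = scenario),
            class = "mrf_dictionary")
}

#' Dot-product matching of measured trajectories against a dictionary
#'
#' Each measured trajectory is L2-normalized and matched to the dictionary
#' row maximizing the inner product (cosine similarity, so the matched dot
#' product lies in [0, 1] for nonnegative signals). Ties break to the lowest
#' row index; zero-norm trajectories are invalid.
#'
#' @param dictionary an [mrf_dictionary()][build_dictionary()].
#' @param measured trajectories: a vector (one pixel), a matrix (pixels x
#'   schedule length), or a 3D array (schedule length x row x col).
#' @param mask optional logical matrix for the 3D layout.
#' @return an object of class `mrf_match` with [pixel_map()]s `fb`, `kb`,
#'   `r1a`, `r2a` and `dp`, plus `index` (matched row per pixel).
#' @export
match_dictionary <- function(dictionary, measured, mask = NULL) {
  ent <- dictionary$entries
  if (is.null(dim(measured))) measured <- matrix(measured, nrow = 1)
  if (length(dim(measured)) == 3) {
    d <- dim(measured)
    if (d[1] != ncol(ent)) stop("trajectory length must equal schedule length")
    shape <- d[2:3]
    M <- t(matrix(measured, nrow = d[1]))
    sel <- if (is.null(mask)) rep(TRUE, nrow(M)) else as.vector(mask)
  } else {
    if (ncol(measured) != ncol(ent)) {
      stop("trajectory length must equal schedule length")
    }
    shape <- c(nrow(measured), 1)
    M <- measured
    sel <- rep(TRUE, nrow(M))
  }
  nrm <- sqrt(rowSums(M^2))
  ok <- sel & nrm > 0
  best <- rep(NA_integer_, nrow(M))
  dp <- rep(NA_real_, nrow(M))
  if (any(ok)) {
    sims <- (M[ok, , drop = FALSE] / nrm[ok]) %*% t(ent)
    best[ok] <- max.col(sims, ties.method = "first")
    dp[ok] <- sims[cbind(seq_len(nrow(sims)), best[ok])]
  }
  valid <- matrix(ok, shape[1], shape[2])
  g <- dictionary$grid
  as_map <- function(v, q, u) {
    vals <- matrix(NA_real_, shape[1], shape[2])
    vals[ok] <- v[best[ok]]
    pixel_map(vals, q, u, valid)
  }
  dp_m <- matrix(dp, shape[1], shape[2])
  structure(list(fb = as_map(g$fb, "fb", ""),
                 kb = as_map(g$kb, "kb", "1/s"),
                 r1a = as_map(g$r1a, "R1a", "1/s"),
                 r2a = as_map(g$r2a, "R2a", "1/s"),
                 dp = pixel_map(dp_m, "dot product", "", valid),
                 index = matrix(best, shape[1], shape[2])),
            class = "mrf_match")
}

#' Convert proton volume fraction to solute concentration
#'
#' `concentration_mM = fb * (2 * water_conc_M * 1000) / n_protons`, i.e.
#' fb times the 111 M water proton concentration, divided by the number of
#' exchangeable protons per solute molecule.
#'
#' @param fb_map a [pixel_map()] of fb (or a bare matrix/scalar).
#' @param n_protons exchangeable protons per molecule (>= 1).
#' @param water_conc_M molar water concentration (default 55.5 M; two
#'   protons per molecule are folded in).
#' @return a [pixel_map()] (or numeric, matching the input) in mM.
#' @export
to_concentration <- function(fb_map, n_protons, water_conc_M = 55.5) {
  if (n_protons < 1) stop("n_protons must be >= 1")
  fac <- 2 * water_conc_M * 1000 / n_protons
  if (inherits(fb_map, "pixel_map")) {
    pixel_map(fb_map$values * fac, "concentration", "mM", fb_map$valid_mask)
  } else {
    fb_map * fac
  }
}
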