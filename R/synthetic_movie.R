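# Ground-truth simulator for MicroED movies and reflection tables.
#
# The simulator reproduces the statistical structure the analytics assume
# -- Poisson background scaled by the detector gain, Bragg spots as Poisson
# photon counts spread over a Gaussian footprint, exponential intensity
# decay with exposure, Gaussian read noise producing negative raw pixels --
# without any physical scattering model. Random streams are split per
# component (background / spots / read noise) so that switching one off
# does not perturb the draws of the others at a fixed seed.

#' Simulation configuration
#'
#' @param geometry An [acquisition_geometry()].
#' @param cell A [unit_cell()].
#' @param laue_group Laue group used for the unique set (default `"4/mmm"`).
#' @param n_frames Number of frames to simulate.
#' @param gain ADU recorded per primary event (Falcon III-like: 1.0;
#'   CetaD-like: 14).
#' @param background_rate Mean background events per pixel per frame.
#' @param read_noise_sd Gaussian read noise sd in ADU (on the stored scale).
#' @param pedestal_truth Offset subtracted from the raw signal, so negative
#'   pixel values occur in the native data (may be 0).
#' @param pedestal Accounting pedestal used for the ground-truth clipped
#'   fractions (defaults to `pedestal_truth`).
#' @param decay_B Decay constant B in Angstrom^2 per e-; the true
#'   D50 is `ln(2)/decay_B`.
#' @param spot_profile_sd Gaussian footprint sd of a spot, in pixels.
#' @param base_intensities Data frame `h, k, l, I0` of spots to place
#'   ((h,k,0)-zone indices); `NULL` places a default grid.
#' @param rocking_width_deg Gaussian rocking width (deg); `Inf` disables
#'   rocking modulation so every frame sees the full spot intensity.
#' @param averaging_frames Subframes averaged into one stored frame
#'   (Falcon III-like readout: 40; default 1). The stored values are the
#'   subframe average, scaling the effective gain down by this factor.
#' @param d_min Resolution limit for [simulate_reflection_table()]
#'   (defaults to the detector-edge resolution of `geometry`).
#' @param amplitude_mean Mean crystal amplitude for simulated tables.
#' @param obs_per_frame Observations emitted per frame in simulated tables;
#'   default cycles the unique set twice over the movie, so the ASU is
#'   covered halfway through.
#' @param rotation_start_deg Stage angle of frame 1; the tilt ramp
#'   decreases from here (stages are rotated from high towards zero tilt).
#' @param seed Integer seed; a fixed seed makes every output reproducible.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(geometry, cell = unit_cell(20, 20, 30),
                              laue_group = "4/mmm",
                              n_frames = 10L, gain = 1.0,
                              background_rate = 20,
                              read_noise_sd = 0, pedestal_truth = 0,
                              pedestal = pedestal_truth,
                              decay_B = 0.277, spot_profile_sd = 1.5,
                              base_intensities = NULL,
                              rocking_width_deg = Inf,
                              averaging_frames = 1L,
                              d_min = NULL, amplitude_mean = 100,
                              obs_per_frame = NULL,
                              rotation_start_deg = 30,
                              seed = 1L) {
  stopifnot(inherits(geometry, "acquisition_geometry"),
            inherits(cell, "unit_cell"))
  if (any(c(background_rate, read_noise_sd, pedestal_truth, pedestal,
            spot_profile_sd) < 0))
    stop("rates, noise levels and pedestals must be >= 0", call. = FALSE)
  if (is.null(d_min)) d_min <- edge_resolution(geometry)
  structure(list(geometry = geometry, cell = cell, laue_group = laue_group,
                 n_frames = as.integer(n_frames), gain = gain,
                 background_rate = background_rate,
                 read_noise_sd = read_noise_sd,
                 pedestal_truth = pedestal_truth, pedestal = pedestal,
                 decay_B = decay_B, spot_profile_sd = spot_profile_sd,
                 base_intensities = base_intensities,
                 rocking_width_deg = rocking_width_deg,
                 averaging_frames = as.integer(averaging_frames),
                 d_min = d_min, amplitude_mean = amplitude_mean,
                 obs_per_frame = obs_per_frame,
                 rotation_start_deg = rotation_start_deg,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.default_spots <- function() {
  g <- expand.grid(h = -3:3, k = -3:3)
  g <- g[!(g$h == 0 & g$k == 0), ]
  data.frame(h = g$h, k = g$k, l = 0L, I0 = 500)
}

#' Simulate a diffraction movie with ground truth
#'
#' Each frame is
#' `gain * Poisson(background) + spots + Normal(0, read_noise_sd) - pedestal_truth`,
#' divided by `averaging_frames` for the Poisson part when subframe
#' averaging is modelled (the sum of `n` subframe Poisson draws is a single
#' Poisson draw, so only the division is needed). Each spot contributes
#' `Poisson(I_frame)` photons, placed on a Gaussian footprint centred at
#' the spot's (h,k,0)-zone position; `I_frame = I0 * exp(-B x) * rocking`,
#' with the rocking factor a Gaussian in the frame angle around a per-spot
#' centre angle (spot centres are spread evenly over the scan). Spots
#' falling outside the frame are skipped and recorded in `truth$skipped`.
#'
#' @param config A [simulation_config()].
#' @return A list with `stack` (a [frame_stack()]) and `truth` (a list:
#'   `reflection_table` of true per-frame spot intensities, `true_gain`,
#'   `true_B`, `true_D50`, `clipped_fractions`, `skipped`).
#' @export
simulate_movie <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  geom <- config$geometry
  shp <- geom$frame_shape
  nfr <- config$n_frames
  npx <- prod(shp)
  spots <- config$base_intensities
  if (is.null(spots)) spots <- .default_spots()
  ledger <- exposure_ledger(geom, nfr)
  dphi <- delta_phi_per_frame(geom)
  phis <- config$rotation_start_deg - (seq_len(nfr) - 1) * dphi
  # spot centres in pixels: (h,k,0) zone, spacing from the geometry module
  half_width <- min(shp) / 2
  spacing <- spot_separation_px(config$cell$a, config$d_min, half_width)
  row0 <- shp[1] / 2 + spots$k * spacing
  col0 <- shp[2] / 2 + spots$h * spacing
  inside <- row0 >= 1 & row0 <= shp[1] & col0 >= 1 & col0 <= shp[2]
  skipped <- spots[!inside, c("h", "k", "l")]
  # per-spot rocking centres spread evenly over the scan
  n_spots <- nrow(spots)
  centres <- seq(phis[1], phis[nfr], length.out = max(n_spots, 2))[seq_len(n_spots)]
  rock <- function(phi, ctr) {
    if (!is.finite(config$rocking_width_deg)) return(rep(1, length(phi)))
    exp(-(phi - ctr)^2 / (2 * config$rocking_width_deg^2))
  }

  bg <- with_preserved_rng(config$seed + 101L, {
    if (config$background_rate > 0)
      array(config$gain * stats::rpois(npx * nfr, config$background_rate),
            dim = c(shp, nfr))
    else array(0, dim = c(shp, nfr))
  })
  truth_rows <- vector("list", nfr)
  spot_px <- with_preserved_rng(config$seed + 202L, {
    arr <- array(0, dim = c(shp, nfr))
    for (f in seq_len(nfr)) {
      x <- ledger$cumulative_exposure[f]
      lam <- spots$I0 * exp(-config$decay_B * x) *
        vapply(centres, function(ctr) rock(phis[f], ctr), numeric(1))
      truth_rows[[f]] <- data.frame(h = spots$h, k = spots$k, l = spots$l,
                                    frame = f, intensity = lam,
                                    sigma = pmax(sqrt(lam), 1e-9),
                                    tilt_deg = phis[f])
      fm <- numeric(npx)
      for (s in which(inside)) {
        n_ph <- stats::rpois(1, lam[s])
        if (n_ph == 0) next
        rr <- pmin(pmax(round(stats::rnorm(n_ph, row0[s], config$spot_profile_sd)),
                        1), shp[1])
        cc <- pmin(pmax(round(stats::rnorm(n_ph, col0[s], config$spot_profile_sd)),
                        1), shp[2])
        idx <- (cc - 1L) * shp[1] + rr
        counts <- tabulate(idx, nbins = npx)
        fm <- fm + config$gain * counts
      }
      arr[, , f] <- fm
    }
    arr
  })
  px <- (bg + spot_px) / config$averaging_frames
  if (config$read_noise_sd > 0) {
    px <- px + with_preserved_rng(config$seed + 303L,
      array(stats::rnorm(npx * nfr, 0, config$read_noise_sd), dim = c(shp, nfr)))
  }
  px <- px - config$pedestal_truth
  clipped <- apply(px <= -config$pedestal, 3L, mean)
  truth_table <- do.call(rbind, truth_rows)
  truth_table$d <- d_spacing(truth_table$h, truth_table$k, truth_table$l,
                             config$cell)
  list(stack = frame_stack(px, source_format = "SYNTHETIC",
                           per_frame_time = geom$exposure_time_s),
       truth = list(reflection_table = truth_table,
                    true_gain = config$gain / config$averaging_frames,
                    true_B = config$decay_B,
                    true_D50 = log(2) / config$decay_B,
                    clipped_fractions = as.numeric(clipped),
                    skipped = skipped))
}

#' Simulate reflection tables for several crystals
#'
#' Emits observation tables that feed the dose analytics directly, without
#' image processing. Per crystal an amplitude `A_cryst` is drawn
#' (log-normal around `amplitude_mean`, sd 0.25 in log space); each frame
#' carries `obs_per_frame` observations whose Miller indices cycle through
#' a shuffled unique set, so completeness grows steadily with exposure.
#' Observed intensity is `A_cryst * exp(-B x) * (1 + noise_cv * z)` with
#' standard-normal `z`; the tilt column ramps down from
#' `rotation_start_deg` at the geometry's rotation speed.
#'
#' @param config A [simulation_config()].
#' @param n_crystals Number of crystals (>= 1).
#' @param noise_cv Multiplicative noise coefficient of variation (0 for
#'   noiseless tables).
#' @return A list with `tables` (one data frame per crystal, columns
#'   `h k l frame intensity sigma tilt_deg d`) and `truth`
#'   (`A` per crystal, `B`, `D50`, `unique_set`).
#' @export
simulate_reflection_table <- function(config, n_crystals = 1L, noise_cv = 0) {
  stopifnot(inherits(config, "simulation_config"))
  n_crystals <- as.integer(n_crystals)
  if (n_crystals < 1L) stop("n_crystals must be >= 1", call. = FALSE)
  geom <- config$geometry
  nfr <- config$n_frames
  ledger <- exposure_ledger(geom, nfr)
  uniq <- generate_unique_set(config$cell, config$d_min, config$laue_group)
  n_unique <- nrow(uniq)
  if (n_unique == 0) stop("unique set is empty at this resolution", call. = FALSE)
  opf <- config$obs_per_frame
  if (is.null(opf)) opf <- max(1L, ceiling(2 * n_unique / nfr))
  dphi <- delta_phi_per_frame(geom)
  tilt <- config$rotation_start_deg - (seq_len(nfr) - 1) * dphi
  dvals <- d_spacing(uniq[, 1], uniq[, 2], uniq[, 3], config$cell)
  with_preserved_rng(config$seed + 404L, {
    A <- config$amplitude_mean * exp(stats::rnorm(n_crystals, 0, 0.25))
    names(A) <- paste0("crystal", seq_len(n_crystals))
    tables <- vector("list", n_crystals)
    for (cidx in seq_len(n_crystals)) {
      ord <- sample.int(n_unique)
      ptr <- 0L
      rows <- vector("list", nfr)
      for (f in seq_len(nfr)) {
        take <- ((ptr + seq_len(opf) - 1L) %% n_unique) + 1L
        ptr <- (ptr + opf) %% n_unique
        sel <- ord[take]
        mu <- unname(A[cidx]) * exp(-config$decay_B * ledger$cumulative_exposure[f])
        noise <- if (noise_cv > 0) 1 + noise_cv * stats::rnorm(length(sel)) else 1
        inten <- mu * noise
        rows[[f]] <- data.frame(h = as.integer(uniq[sel, 1]),
                                k = as.integer(uniq[sel, 2]),
                                l = as.integer(uniq[sel, 3]), frame = f,
                                intensity = inten,
                                sigma = pmax(abs(mu) * max(noise_cv, 0.01), 1e-9),
                                tilt_deg = tilt[f], d = dvals[sel])
      }
      tables[[cidx]] <- do.call(rbind, rows)
    }
    list(tables = tables,
         truth = list(A = A, B = config$decay_B, D50 = log(2) / config$decay_B,
                      unique_set = uniq))
  })
}
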