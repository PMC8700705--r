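#' Configuration for the synthetic spectra generator
#'
#' Describes one orientation's worth of synthetic full-transmittance spectra:
#' sample counts per class, the wavelength grid, the spectral landmarks of
#' each class, the noise model, and the raw scan-block geometry (number of
#' scans per fruit, saturation of the leading/trailing scans).
#'
#' The defaults mirror the study conditions the generator emulates: 138
#' healthy and 127 watercore apples, 1185 bands over 680--1000 nm, 30--45
#' scans per fruit of which the first and last three are saturated; healthy
#' spectra rise from 680 nm to a single peak near 920 nm; watercore spectra
#' carry extra peaks near 720 and 810 nm in the equatorial orientations
#' (O1/O3) and are elevated above healthy over 680--850 nm in the axial
#' orientation (O2).
#'
#' @param n_healthy,n_watercore number of samples per class.
#' @param orientation `"O1"`, `"O2"` or `"O3"` (see [spectrum_set()]).
#' @param wavelength_start_nm,wavelength_end_nm wavelength range in nm.
#' @param n_wavelengths number of (uniformly spaced) grid points.
#' @param healthy_peak_nm location of the healthy-class intensity peak.
#' @param watercore_peak_nms locations of the watercore peaks used in the
#'   O1/O3 orientations.
#' @param o2_elevation_range_nm wavelength interval over which the O2
#'   watercore mean curve strictly exceeds the healthy one.
#' @param scatter_sigma standard deviation (log scale) of the per-sample
#'   multiplicative scatter factor.
#' @param baseline_sigma standard deviation (counts) of the per-sample
#'   additive baseline shift.
#' @param noise_sigma standard deviation (counts) of the per-scan,
#'   per-wavelength measurement noise.
#' @param scans_min,scans_max range of the per-sample scan count; must allow
#'   at least one scan to survive the fixed 3 + 3 trim.
#' @param saturation_ceiling detector ceiling (counts) applied to the three
#'   leading and three trailing scans of each block; `NULL` places it at 90%
#'   of the larger class mean-curve maximum so that saturation clipping is
#'   actually exercised.
#' @param seed integer seed; the generator is bitwise reproducible given the
#'   configuration.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_healthy = 138, n_watercore = 127,
                             orientation = "O1",
                             wavelength_start_nm = 680,
                             wavelength_end_nm = 1000,
                             n_wavelengths = 1185,
                             healthy_peak_nm = 920,
                             watercore_peak_nms = c(720, 810),
                             o2_elevation_range_nm = c(680, 850),
                             scatter_sigma = 0.08,
                             baseline_sigma = 4,
                             noise_sigma = 6,
                             scans_min = 30, scans_max = 45,
                             saturation_ceiling = NULL,
                             seed = 1) {
  orientation <- match_orientation(orientation)
  if (n_healthy < 1 || n_watercore < 1) stop("class sample counts must be positive")
  if (n_wavelengths < 2) stop("n_wavelengths must be at least 2")
  if (wavelength_start_nm >= wavelength_end_nm) {
    stop("wavelength_start_nm must be below wavelength_end_nm")
  }
  if (scans_min < 7) stop("scans_min must be at least 7: trimming removes 6 scans")
  if (scans_max < scans_min) stop("scans_max must be >= scans_min")
  if (scatter_sigma < 0 || baseline_sigma < 0 || noise_sigma < 0) {
    stop("noise standard deviations must be nonnegative")
  }
  cfg <- structure(
    list(n_healthy = as.integer(n_healthy),
         n_watercore = as.integer(n_watercore),
         orientation = orientation,
         wavelength_start_nm = wavelength_start_nm,
         wavelength_end_nm = wavelength_end_nm,
         n_wavelengths = as.integer(n_wavelengths),
         healthy_peak_nm = healthy_peak_nm,
         watercore_peak_nms = watercore_peak_nms,
         o2_elevation_range_nm = o2_elevation_range_nm,
         scatter_sigma = scatter_sigma,
         baseline_sigma = baseline_sigma,
         noise_sigma = noise_sigma,
         scans_min = as.integer(scans_min),
         scans_max = as.integer(scans_max),
         saturation_ceiling = saturation_ceiling,
         seed = as.integer(seed),
         planted_pair = NULL),
    class = "synthetic_config"
  )
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic spectra config (", x$orientation, "): ",
      x$n_healthy, " healthy + ", x$n_watercore, " watercore, ",
      x$n_wavelengths, " bands over [", x$wavelength_start_nm, ", ",
      x$wavelength_end_nm, "] nm, scans ", x$scans_min, "-", x$scans_max,
      ", seed ", x$seed, "\n", sep = "")
  if (!is.null(x$planted_pair)) {
    cat("  planted discriminative pair: ", x$planted_pair$band_i_nm, "/",
        x$planted_pair$band_k_nm, " nm (effect ", x$planted_pair$effect,
        ")\n", sep = "")
  }
  invisible(x)
}

#' Wavelength grid of a synthetic configuration
#'
#' @param config a [synthetic_config()].
#' @return Numeric vector of `n_wavelengths` uniformly spaced wavelengths.
#' @export
wavelength_grid <- function(config) {
  seq(config$wavelength_start_nm, config$wavelength_end_nm,
      length.out = config$n_wavelengths)
}

# Gaussian bump on the wavelength grid; used for spectral peaks.
gauss_bump <- function(wl, center, width) exp(-((wl - center)^2) / (2 * width^2))

#' Class-conditional mean transmittance curve
#'
#' The healthy curve is a logistic rise out of the 680 nm cut-on multiplied
#' by a broad Gaussian peak at `healthy_peak_nm`, on a positive baseline:
#' smooth, unimodal, argmax at the configured peak. The watercore curve adds
#' positive Gaussian bumps at `watercore_peak_nms` in O1/O3, and in O2 a
#' broad elevation that keeps it strictly above the healthy curve across
#' `o2_elevation_range_nm`. A planted discriminative pair (see
#' [plant_discriminative_pair()]) perturbs the watercore curve
#' multiplicatively at the two planted bands.
#'
#' @param config a [synthetic_config()].
#' @param label `1` (healthy) or `-1` (watercore).
#' @return Numeric vector of length `n_wavelengths`, strictly positive.
#' @export
#' @examples
#' cfg <- synthetic_config(n_wavelengths = 200)
#' wl <- wavelength_grid(cfg)
#' wl[which.max(mean_curve(cfg, 1))]   # ~920 nm
mean_curve <- function(config, label) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!label %in% c(1, -1)) stop("label must be 1 (healthy) or -1 (watercore)")
  wl <- wavelength_grid(config)
  base_level <- 60
  amplitude <- 1000
  rise <- stats::plogis((wl - 705) / 18)
  peak <- gauss_bump(wl, config$healthy_peak_nm, 90)
  healthy <- base_level + amplitude * rise * peak
  if (label == 1) return(healthy)
  curve <- healthy
  if (config$orientation %in% c("O1", "O3")) {
    widths <- c(13, 22)
    amps <- c(260, 300)
    for (j in seq_along(config$watercore_peak_nms)) {
      w <- if (j <= length(widths)) widths[j] else widths[length(widths)]
      a <- if (j <= length(amps)) amps[j] else amps[length(amps)]
      curve <- curve + a * gauss_bump(wl, config$watercore_peak_nms[j], w)
    }
  } else {
    lo <- config$o2_elevation_range_nm[1]
    hi <- config$o2_elevation_range_nm[2]
    center <- (lo + hi) / 2
    width <- (hi - lo) / 2.2
    curve <- curve + 320 * gauss_bump(wl, center, width)
  }
  pp <- config$planted_pair
  if (!is.null(pp) && pp$effect > 0) {
    spacing <- (config$wavelength_end_nm - config$wavelength_start_nm) /
      (config$n_wavelengths - 1)
    w <- 1.5 * spacing
    curve <- curve * (1 + pp$effect * gauss_bump(wl, pp$band_i_nm, w)) /
      (1 + pp$effect * gauss_bump(wl, pp$band_k_nm, w))
  }
  curve
}

#' Plant a known discriminative band pair into a configuration
#'
#' Perturbs the watercore mean curve multiplicatively upward at `band_i_nm`
#' and downward at `band_k_nm` (narrow bumps, 1.5 grid steps wide) so that
#' the transmittance ratio T(band_i)/T(band_k) separates the classes more
#' strongly than any other pair. The planted pair is recorded in the
#' configuration so parameter-recovery tests can assert against it.
#'
#' For the planted pair to dominate the exhaustive search it must beat the
#' generator's natural class structure in F-value terms: plant with a
#' substantial effect (0.5 or more) at bands where the two classes are
#' otherwise similar and transmittance is high (ratio noise scales with the
#' reciprocal transmittance, so low-intensity bands are noisy ratio
#' partners).
#'
#' @param config a [synthetic_config()].
#' @param band_i_nm,band_k_nm planted numerator and denominator bands (nm);
#'   must lie inside the configured wavelength range.
#' @param effect relative perturbation size (e.g. `0.5` scales the watercore
#'   curve by 1.5 at `band_i_nm`); `0` leaves the curves unchanged.
#' @return The configuration with the planted pair recorded.
#' @export
plant_discriminative_pair <- function(config, band_i_nm, band_k_nm, effect) {
  stopifnot(inherits(config, "synthetic_config"))
  rng <- c(config$wavelength_start_nm, config$wavelength_end_nm)
  if (band_i_nm < rng[1] || band_i_nm > rng[2] ||
      band_k_nm < rng[1] || band_k_nm > rng[2]) {
    stop("planted bands must lie inside the wavelength range [",
         rng[1], ", ", rng[2], "] nm")
  }
  if (effect < 0) stop("effect must be nonnegative")
  config$planted_pair <- list(band_i_nm = band_i_nm, band_k_nm = band_k_nm,
                              effect = effect)
  config
}

default_saturation_ceiling <- function(config) {
  m <- pmax(mean_curve(config, 1), mean_curve(config, -1))
  0.9 * max(m)
}

#' Simulate raw scan blocks for one orientation
#'
#' Each sample yields a block of `scans_min`--`scans_max` raw scans. A scan
#' is the class mean curve times a per-sample log-normal scatter factor,
#' plus a per-sample baseline shift and per-scan Gaussian noise; intensities
#' are kept strictly positive. The three leading and three trailing scans of
#' every block are clipped at the saturation ceiling, emulating the
#' saturated spectra recorded while the fruit enters and leaves the beam --
#' exactly the scans the preprocessing trim discards.
#'
#' @param config a [synthetic_config()]; `config$seed` drives all randomness.
#' @return A list of `scan_block` objects (fields `sample_id`,
#'   `orientation`, `label`, `wavelengths_nm`, `scans`), healthy samples
#'   first.
#' @export
#' @examples
#' blocks <- simulate_scan_blocks(synthetic_config(
#'   n_healthy = 2, n_watercore = 2, n_wavelengths = 50, seed = 1))
#' nrow(blocks[[1]]$scans) >= 30
simulate_scan_blocks <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  wl <- wavelength_grid(config)
  ceiling_val <- config$saturation_ceiling
  if (is.null(ceiling_val)) ceiling_val <- default_saturation_ceiling(config)
  curves <- list(`1` = mean_curve(config, 1), `-1` = mean_curve(config, -1))
  labels <- c(rep(1, config$n_healthy), rep(-1, config$n_watercore))
  n <- length(labels)
  blocks <- vector("list", n)
  with_local_rng(config$seed, {
    for (s in seq_len(n)) {
      lab <- labels[s]
      n_scans <- sample.int(config$scans_max - config$scans_min + 1L, 1L) +
        config$scans_min - 1L
      scatter <- exp(stats::rnorm(1, 0, config$scatter_sigma))
      baseline <- stats::rnorm(1, 0, config$baseline_sigma)
      mu <- curves[[as.character(lab)]] * scatter + baseline
      noise <- matrix(stats::rnorm(n_scans * length(wl), 0, config$noise_sigma),
                      n_scans, length(wl))
      scans <- matrix(mu, n_scans, length(wl), byrow = TRUE) + noise
      scans <- pmax(scans, 1e-6)        # transmittance counts are positive
      sat <- c(seq_len(3L), n_scans - 2:0)
      scans[sat, ] <- pmin(scans[sat, ], ceiling_val)
      blocks[[s]] <- structure(
        list(sample_id = paste0(config$orientation, "_",
                                ifelse(lab == 1, "h", "w"), "_", s),
             orientation = config$orientation,
             label = lab,
             wavelengths_nm = wl,
             scans = scans),
        class = "scan_block"
      )
    }
  })
  blocks
}

#' @export
print.scan_block <- function(x, ...) {
  cat("Scan block ", x$sample_id, " (", x$orientation, ", label ", x$label,
      "): ", nrow(x$scans), " scans x ", ncol(x$scans), " wavelengths\n",
      sep = "")
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code has no global side effects.
with_local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
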