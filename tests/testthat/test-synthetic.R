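test_that("class mean curves carry the configured spectral landmarks", {
  for (o in c("O1", "O2", "O3")) {
    cfg <- synthetic_config(orientation = o, n_wavelengths = 400)
    wl <- wavelength_grid(cfg)
    healthy <- mean_curve(cfg, 1)
    expect_true(all(healthy > 0))
    # unimodal: increases then decreases
    d <- diff(healthy)
    turn <- which(d < 0)[1]
    expect_true(all(d[seq_len(turn - 1)] > 0))
    expect_true(all(d[turn:length(d)] < 0))
    expect_lt(abs(wl[which.max(healthy)] - cfg$healthy_peak_nm), 10)
    expect_true(all(mean_curve(cfg, -1) > 0))
  }
})

test_that("O2 watercore mean strictly exceeds healthy over the elevation range", {
  cfg <- synthetic_config(orientation = "O2", n_wavelengths = 600)
  wl <- wavelength_grid(cfg)
  inside <- wl >= 680 & wl <= 850
  diff_curve <- mean_curve(cfg, -1) - mean_curve(cfg, 1)
  expect_true(all(diff_curve[inside] > 0))
})

test_that("O1/O3 watercore curves add bumps at the configured peaks", {
  cfg <- synthetic_config(orientation = "O3", n_wavelengths = 1185)
  wl <- wavelength_grid(cfg)
  excess <- mean_curve(cfg, -1) - mean_curve(cfg, 1)
  expect_true(all(excess >= 0))
  # the excess has local maxima at (close to) the watercore peak wavelengths
  for (p in cfg$watercore_peak_nms) {
    i <- which.min(abs(wl - p))
    window <- excess[max(1, i - 30):min(length(wl), i + 30)]
    expect_lt(abs(wl[max(1, i - 30) - 1 + which.max(window)] - p), 5)
  }
  expect_error(mean_curve(cfg, 0), "label")
})

test_that("generated datasets are bitwise reproducible under a fixed seed", {
  cfg <- synthetic_config(n_healthy = 5, n_watercore = 5, n_wavelengths = 60,
                          seed = 7)
  b1 <- simulate_scan_blocks(cfg)
  b2 <- simulate_scan_blocks(cfg)
  expect_identical(b1, b2)
  expect_identical(mean_curve(cfg, -1), mean_curve(cfg, -1))
  b3 <- simulate_scan_blocks(synthetic_config(n_healthy = 5, n_watercore = 5,
                                              n_wavelengths = 60, seed = 8))
  expect_false(identical(b1, b3))
})

test_that("scan counts respect the configured range and fixed counts", {
  cfg <- synthetic_config(n_healthy = 4, n_watercore = 4, n_wavelengths = 40,
                          scans_min = 35, scans_max = 35, seed = 2)
  blocks <- simulate_scan_blocks(cfg)
  expect_length(blocks, 8)
  expect_true(all(vapply(blocks, function(b) nrow(b$scans), numeric(1)) == 35))

  cfg2 <- synthetic_config(n_healthy = 30, n_watercore = 30,
                           n_wavelengths = 20, seed = 5)
  ns <- vapply(simulate_scan_blocks(cfg2), function(b) nrow(b$scans), numeric(1))
  expect_true(all(ns >= 30 & ns <= 45))
  expect_gt(length(unique(ns)), 1)
})

test_that("leading/trailing scans saturate at the ceiling, middle scans need not", {
  cfg <- synthetic_config(n_healthy = 3, n_watercore = 3, n_wavelengths = 80,
                          saturation_ceiling = 400, noise_sigma = 1, seed = 4)
  blocks <- simulate_scan_blocks(cfg)
  for (b in blocks) {
    n <- nrow(b$scans)
    edge <- b$scans[c(1:3, n - 2:0), ]
    expect_true(all(edge <= 400))
    expect_true(any(edge == 400))              # clipping actually bites
    expect_gt(max(b$scans[4:(n - 3), ]), 400)  # middle scans exceed it
    expect_true(all(b$scans > 0))
  }
})

test_that("class-conditional means converge to the configured curve as n grows", {
  dev_for_n <- function(n) {
    cfg <- synthetic_config(n_healthy = n, n_watercore = 2,
                            n_wavelengths = 60, seed = 31,
                            saturation_ceiling = Inf)
    set <- average_scans(simulate_scan_blocks(cfg))
    mu <- mean_curve(cfg, 1)
    max(abs(colMeans(set$intensities[set$labels == 1, ]) - mu) / mu)
  }
  expect_lt(dev_for_n(200), dev_for_n(8))
})

test_that("plant_discriminative_pair validates bands and records metadata", {
  cfg <- synthetic_config(n_wavelengths = 200)
  expect_error(plant_discriminative_pair(cfg, 500, 720, 0.5), "range")
  expect_error(plant_discriminative_pair(cfg, 720, 1200, 0.5), "range")
  planted <- plant_discriminative_pair(cfg, 764, 720, 0.5)
  expect_equal(planted$planted_pair,
               list(band_i_nm = 764, band_k_nm = 720, effect = 0.5))
  # null effect: curves unchanged, only metadata differs
  null_plant <- plant_discriminative_pair(cfg, 764, 720, 0)
  expect_identical(mean_curve(null_plant, -1), mean_curve(cfg, -1))
  # positive effect raises the watercore curve at band_i, lowers it at band_k
  wl <- wavelength_grid(cfg)
  delta <- mean_curve(planted, -1) - mean_curve(cfg, -1)
  expect_gt(delta[which.min(abs(wl - 764))], 0)
  expect_lt(delta[which.min(abs(wl - 720))], 0)
})
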