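test_that("two-group F matches textbook values and degenerate conventions", {
  expect_equal(f_oneway_two_groups(c(1, 2, 3), c(4, 5, 6)), 13.5)
  expect_equal(f_oneway_two_groups(c(1, 2, 3), c(3, 2, 1)), 0)
  expect_identical(f_oneway_two_groups(c(2, 2), c(5, 5)), Inf)
  expect_error(f_oneway_two_groups(1, c(2, 3)), "at least 2")
})

test_that("two-group F equals the squared pooled t statistic and the lm route", {
  set.seed(17)
  for (r in 1:50) {
    na <- sample(2:12, 1)
    nb <- sample(2:12, 1)
    a <- rnorm(na, mean = runif(1, -3, 3), sd = runif(1, 0.2, 2))
    b <- rnorm(nb, mean = runif(1, -3, 3), sd = runif(1, 0.2, 2))
    f <- f_oneway_two_groups(a, b)
    expect_equal(f, oracle_f_pooled_t2(a, b), tolerance = 1e-10)
    expect_equal(f, oracle_f_lm(a, b), tolerance = 1e-10)
  }
})

test_that("f_scan equals the scalar per-column loop and is invariant as F should be", {
  s <- toy_set(n_per_class = 6, W = 15, seed = 5)
  fs <- f_scan(s)
  scalar <- sapply(seq_len(15), function(j) {
    f_oneway_two_groups(s$intensities[s$labels == 1, j],
                        s$intensities[s$labels == -1, j])
  })
  expect_equal(fs$f_values, scalar, tolerance = 1e-10)

  # permuting samples within a class leaves the curve unchanged
  idx <- c(sample(which(s$labels == 1)), which(s$labels == -1))
  perm <- spectrum_set(s$intensities[idx, ], s$wavelengths_nm, s$labels[idx])
  expect_equal(f_scan(perm)$f_values, fs$f_values, tolerance = 1e-12)

  # common affine map of all intensities leaves the curve unchanged
  aff <- spectrum_set(3 * s$intensities + 7, s$wavelengths_nm, s$labels)
  expect_equal(f_scan(aff)$f_values, fs$f_values, tolerance = 1e-8)

  single <- spectrum_set(s$intensities[s$labels == 1, ], s$wavelengths_nm,
                         rep(1, 6))
  expect_error(f_scan(single), "both classes")
})

test_that("characteristic wavelengths sit at strict interior local maxima", {
  fake_scan <- function(f) {
    structure(list(wavelengths_nm = seq_along(f), f_values = f,
                   infinite = is.infinite(f), selected_indices = integer(0),
                   selected_wavelengths_nm = numeric(0)),
              class = "f_scan")
  }
  expect_equal(select_characteristic_wavelengths(fake_scan(c(1, 3, 2)),
                                                 1)$selected_indices, 2)
  # monotone curve: fallback to the global maximum endpoint
  expect_equal(select_characteristic_wavelengths(fake_scan(1:6),
                                                 1)$selected_indices, 6)
  # plateau takes its leftmost index
  expect_equal(select_characteristic_wavelengths(fake_scan(c(1, 4, 4, 2, 1)),
                                                 1)$selected_indices, 2)
  # infinite F values are never selected
  expect_equal(select_characteristic_wavelengths(fake_scan(c(1, Inf, 1, 2, 1)),
                                                 1)$selected_indices, 4)
  expect_error(select_characteristic_wavelengths(fake_scan(c(1, 3, 2)), 0),
               "at least 1")
})

test_that("a two-bump F curve yields both bump apices, matching a naive scan", {
  cfg <- synthetic_config(n_healthy = 40, n_watercore = 40, orientation = "O1",
                          n_wavelengths = 150, seed = 12)
  set <- average_scans(simulate_scan_blocks(cfg))
  fs <- select_characteristic_wavelengths(f_scan(set), 2)
  # naive neighbour-comparison oracle over the same curve
  f <- fs$f_values
  naive_peaks <- which(sapply(2:(length(f) - 1), function(i) {
    f[i] > f[i - 1] && f[i] > f[i + 1]
  })) + 1
  naive_top2 <- sort(naive_peaks[order(-f[naive_peaks])][1:2])
  expect_equal(fs$selected_indices, naive_top2)
  # the apices land near the watercore bump wavelengths
  expect_true(all(abs(sort(fs$selected_wavelengths_nm) -
                        c(720, 810)) < 20))
})
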