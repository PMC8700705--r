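test_that("ratio_values is the elementwise band quotient", {
  s <- spectrum_set(cbind(c(2, 4), c(1, 2)), c(700, 800), c(1, -1))
  expect_equal(ratio_values(s, 1, 2), c(2, 2))
  expect_equal(ratio_values(s, 2, 2), c(1, 1))
  s0 <- spectrum_set(cbind(c(2, 4), c(0, 2)), c(700, 800), c(1, -1),
                     sample_ids = c("apple_a", "apple_b"))
  expect_error(ratio_values(s0, 1, 2), "apple_a")
  expect_error(ratio_values(s, 1, 5), "out of range")
})

test_that("a 3-band toy search fills all ordered pairs from the scalar F", {
  set.seed(8)
  s <- spectrum_set(matrix(runif(12, 1, 10), 4, 3), c(700, 800, 900),
                    c(1, 1, -1, -1))
  rfs <- ratio_f_search(s)
  expect_equal(sum(!is.na(rfs$f_matrix)), 6)
  expect_true(all(is.na(diag(rfs$f_matrix))))
  for (i in 1:3) for (k in 1:3) {
    if (i == k) next
    expect_equal(rfs$f_matrix[i, k],
                 f_oneway_two_groups(ratio_values(s, i, k)[s$labels == 1],
                                     ratio_values(s, i, k)[s$labels == -1]),
                 tolerance = 1e-12)
  }
  expect_equal(rfs$best_f, max(rfs$f_matrix, na.rm = TRUE))
  expect_equal(rfs$f_matrix[rfs$best_pair[["i"]], rfs$best_pair[["k"]]],
               rfs$best_f)
})

test_that("blocked search equals the naive double loop on random sets", {
  for (seed in c(1, 2)) {
    set.seed(seed)
    W <- 10
    s <- spectrum_set(matrix(rexp(16 * W) + 0.5, 16, W),
                      seq(700, 900, length.out = W),
                      rep(c(1, -1), each = 8))
    naive <- oracle_ratio_f_matrix(s)
    for (bc in c(1, 3, W)) {
      rfs <- ratio_f_search(s, block_cols = bc)
      expect_equal(rfs$f_matrix, naive, tolerance = 1e-8)
    }
  }
})

test_that("identical class matrices give zero F everywhere off-diagonal", {
  X <- matrix(runif(9, 1, 5), 3, 3)
  s <- spectrum_set(rbind(X, X), c(700, 800, 900), rep(c(1, -1), each = 3))
  rfs <- ratio_f_search(s)
  expect_true(all(rfs$f_matrix[!is.na(rfs$f_matrix)] == 0))
})

test_that("the ratio F matrix is scale-free", {
  s <- toy_set(n_per_class = 5, W = 8, seed = 3)
  s2 <- spectrum_set(s$intensities * 17.3, s$wavelengths_nm, s$labels)
  expect_equal(ratio_f_search(s2)$f_matrix, ratio_f_search(s)$f_matrix,
               tolerance = 1e-9)
  neg <- spectrum_set(s$intensities - max(s$intensities), s$wavelengths_nm,
                      s$labels)
  expect_error(ratio_f_search(neg), "positive")
})

test_that("contour export round-trips and carries the maximum", {
  set.seed(4)
  s <- spectrum_set(matrix(runif(12, 1, 10), 4, 3), c(700, 800, 900),
                    c(1, 1, -1, -1))
  rfs <- ratio_f_search(s)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratio_contour(rfs, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 6)
  expect_equal(max(df$F), rfs$best_f)
  best_row <- df[df$F == max(df$F), ]
  expect_equal(best_row$wavelength_i, rfs$best_pair_nm[["i"]])
  expect_equal(best_row$wavelength_k, rfs$best_pair_nm[["k"]])
  back <- read_ratio_contour(path)
  expect_equal(back$f_matrix, rfs$f_matrix, tolerance = 1e-12)
  expect_equal(back$best_pair, rfs$best_pair)
})
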