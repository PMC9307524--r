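# Synthetic-data generators: construction guarantees, ground truth
# consistency, seed determinism.

test_that("flat-profile B-scan has the constructed band geometry", {
  scan <- generate_bscan(rep(100, 20), height_px = 120, substrate_row = 100,
                         noise_sd = 0)
  n_px <- round(100 / 4.4) # 23
  expect_equal(unique(scan$truth$profile_px_um), n_px * 4.4)
  # biofilm band spans exactly n_px rows above the substrate in every column
  biofilm <- scan$pixels == 120
  expect_true(all(biofilm[(100 - n_px):(100 - 1), ]))
  expect_false(any(biofilm[1:(100 - n_px - 1), ]))
  # empty void mask when void_fraction = 0
  expect_false(any(scan$truth$void_mask))
})

test_that("generator-reported truth matches the analytic profile mean", {
  x <- seq_len(80)
  prof <- 150 + 50 * sin(2 * pi * x / 40)
  scan <- generate_bscan(prof, height_px = 230, substrate_row = 200, noise_sd = 0)
  expect_identical(scan$truth$mean_thickness_um, mean(prof))
  expect_identical(scan$truth$profile_um, prof)
})

test_that("B-scan generation is bitwise reproducible under a seed", {
  a <- generate_bscan(rep(80, 30), height_px = 150, substrate_row = 120,
                      void_fraction = 0.2, noise_sd = 10, seed = 42)
  b <- generate_bscan(rep(80, 30), height_px = 150, substrate_row = 120,
                      void_fraction = 0.2, noise_sd = 10, seed = 42)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$truth$void_mask, b$truth$void_mask)
})

test_that("void placement hits the target fraction and stays inside the biofilm", {
  scan <- generate_bscan(rep(110, 50), height_px = 230, substrate_row = 200,
                         void_fraction = 0.25, noise_sd = 0, seed = 7)
  expect_lt(abs(scan$truth$void_fraction - 0.25), 0.02)
  # voids only where biofilm was drawn
  in_biofilm <- matrix(FALSE, 230, 50)
  n_px <- round(110 / 4.4)
  in_biofilm[(200 - n_px):(200 - 1), ] <- TRUE
  expect_true(all(in_biofilm[scan$truth$void_mask]))
})

test_that("over-tall profiles are rejected with an explanatory error", {
  expect_error(generate_bscan(rep(1000, 5), height_px = 120, substrate_row = 100),
               "exceeds image height")
})

test_that("noiseless growth curve passes through N0 and approaches K", {
  cv <- generate_growth_curve(k = 0.017, K = 0.285, N0 = 0.01,
                              times = c(0, 48, 5000), noise_sd = 0)
  expect_equal(cv$biomass[1], 0.01)
  expect_equal(cv$biomass[3], 0.285, tolerance = 1e-6)
})

test_that("logistic inflection time matches its closed form", {
  k <- 0.017; K <- 0.285; N0 <- 0.01
  t_inf <- log((K - N0) / N0) / k
  tt <- seq(0, 600, by = 0.05)
  y <- logistic_curve(tt, k, K, N0)
  # numerical argmax of the growth-rate curve vs the analytic inflection
  expect_lt(abs(tt[which.max(diff(y))] - t_inf), 0.5)
  expect_equal(logistic_curve(t_inf, k, K, N0), K / 2, tolerance = 1e-12)
})

test_that("growth-curve specs are validated", {
  expect_error(generate_growth_curve(k = -1, K = 1, N0 = 0.1), "positive")
  expect_error(generate_growth_curve(k = 1, K = 0.1, N0 = 0.5), "K > N0")
  expect_error(generate_growth_curve(k = 1, K = 1, N0 = 0.1, times = c(2, 1)),
               "increasing")
})

test_that("colonization images hit the requested coverage across many seeds", {
  for (seed in 1:100) {
    sim <- generate_colonization_image(0.3, blob_count = 10,
                                       size_px = c(64, 64), seed = seed)
    expect_lt(abs(sim$coverage - 0.3), 0.01)
    expect_identical(sim$coverage, sum(sim$mask) / length(sim$mask))
  }
})

test_that("colonization edge cases: zero coverage and infeasible requests", {
  blank <- generate_colonization_image(0, size_px = c(32, 32), seed = 1)
  expect_false(any(blank$mask))
  expect_equal(blank$coverage, 0)
  expect_error(
    generate_colonization_image(0.05, blob_count = 50, size_px = c(10, 10)),
    "infeasible")
})

test_that("the t1-level coverage request lands in the reported field band", {
  sim <- generate_colonization_image(0.096, blob_count = 25,
                                     size_px = c(256, 256), seed = 11)
  frac <- sum(sim$mask) / length(sim$mask)
  expect_gt(frac, 0.086)
  expect_lt(frac, 0.106)
})

test_that("count tables are multinomial draws with the requested depth", {
  tab <- generate_count_table(c(1, 0, 0), depths = 500, seed = 1)
  expect_equal(tab[[2]], c(500L, 0L, 0L))
  tab0 <- generate_count_table(c(0.5, 0.5), depths = 0, seed = 1)
  expect_equal(sum(tab0[[2]]), 0L)
  big <- generate_count_table(c(0.5, 0.5), depths = 1e6, seed = 2)
  expect_lt(abs(big[[2]][1] / 1e6 - 0.5), 0.01)
  # seeded determinism
  expect_identical(generate_count_table(c(0.3, 0.7), depths = 100, seed = 9),
                   generate_count_table(c(0.3, 0.7), depths = 100, seed = 9))
  expect_error(generate_count_table(c(0.6, 0.6), depths = 10), "sum to 1")
})
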