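# OCT morphometrics: substrate detection, binarisation, thickness,
# roughness, porosity, batch analysis.

test_that("substrate line is found exactly on a noiseless scan", {
  scan <- generate_bscan(rep(100, 40), height_px = 230, substrate_row = 200,
                         noise_sd = 0)
  expect_identical(detect_substrate(scan), 200L)
})

test_that("substrate detection stays within 2 px at 10% contrast noise", {
  # contrast = substrate minus background = 230 gray levels by default
  for (seed in 1:50) {
    scan <- make_flat_scan(noise_sd = 23, seed = seed)
    expect_lte(abs(detect_substrate(scan) - 200L), 2L)
  }
})

test_that("a featureless image yields a no-interface error", {
  expect_error(detect_substrate(matrix(50, 100, 20)),
               class = "periphytonr_no_interface")
})

test_that("otsu binarisation separates a two-level image like the exhaustive scan", {
  img <- matrix(c(rep(20, 600), rep(220, 400)), nrow = 25)
  mask <- binarize(img, "otsu")
  expect_equal(unname(attr(mask, "threshold")),
                   oracle_otsu(c(20, 220), c(600, 400)))
  expect_identical(sum(mask), 400L)
})

test_that("fixed threshold at 0 marks everything foreground; constant image errors", {
  img <- matrix(c(5, 10, 20, 40), 2, 2)
  expect_true(all(binarize(img, "fixed", value = 0)))
  expect_error(binarize(matrix(7, 4, 4), "otsu"),
               class = "periphytonr_degenerate")
})

test_that("noiseless binarisation recovers the generator's biofilm-minus-voids truth", {
  scan <- generate_bscan(rep(120, 40), height_px = 230, substrate_row = 200,
                         void_fraction = 0.2, noise_sd = 0, seed = 3)
  mask <- binarize(scan, "otsu")
  n_px <- round(120 / 4.4)
  truth <- matrix(FALSE, 230, 40)
  truth[(200 - n_px):(200 - 1), ] <- TRUE
  truth[scan$truth$void_mask] <- FALSE
  expect_identical(unname(mask[1:199, ]), truth[1:199, ])
})

test_that("thickness profile is forced arithmetic on constructed masks", {
  mask <- matrix(FALSE, 60, 10)
  mask[(50 - 23):(50 - 1), ] <- TRUE
  prof <- thickness_profile(mask, substrate_row = 50, axial_scale = 4.4)
  expect_equal(prof$L_F_i, rep(23 * 4.4, 10)) # 101.2 um
  empty <- thickness_profile(matrix(FALSE, 60, 10), 50, 4.4)
  expect_equal(empty$L_F_i, rep(0, 10))
})

test_that("noiseless sinusoidal biofilm is recovered within one axial pixel", {
  prof_um <- 150 + 50 * sin(seq(0, 2 * pi, length.out = 60))
  scan <- generate_bscan(prof_um, height_px = 230, substrate_row = 200,
                         noise_sd = 0)
  mask <- binarize(scan, "otsu")
  prof <- thickness_profile(mask, detect_substrate(scan), 4.4)
  expect_true(all(abs(prof$L_F_i - prof_um) <= 4.4))
})

test_that("mean thickness and roughness match naive summation and hand values", {
  expect_equal(mean_thickness(c(100, 100, 100)), 100)
  expect_equal(mean_thickness(c(50, 150)), 100)
  expect_equal(roughness(c(50, 150)), 0.5)
  expect_equal(roughness(c(80, 120, 80, 120)), 0.2)
  expect_equal(roughness(rep(77, 9)), 0)
  withr::with_seed(1, {
    for (i in 1:20) {
      v <- stats::runif(1000, 1, 300)
      expect_equal(mean_thickness(v), oracle_mean(v), tolerance = 1e-12)
      expect_equal(roughness(v), oracle_roughness(v), tolerance = 1e-12)
    }
  })
  expect_error(roughness(c(0, 0, 0)), class = "periphytonr_degenerate")
})

test_that("porosity definitions: hand values and generator recovery", {
  expect_equal(porosity(c(100, 100)), 1) # flat: mean equals max
  expect_equal(porosity(c(50, 150)), 2 / 3)
  expect_error(porosity(c(0, 0)), class = "periphytonr_degenerate")
  scan <- generate_bscan(rep(100, 60), height_px = 230, substrate_row = 200,
                         void_fraction = 0.3, noise_sd = 0, seed = 5)
  mask <- binarize(scan, "otsu")
  prof <- thickness_profile(mask, detect_substrate(scan), 4.4)
  expect_lt(abs(porosity(prof, mask, "void_fraction") - 0.3), 0.02)
})

test_that("metrics are scale-equivariant and permutation-invariant", {
  withr::with_seed(2, v <- stats::runif(200, 10, 200))
  for (c_scale in c(0.5, 3)) {
    expect_equal(mean_thickness(v * c_scale), mean_thickness(v) * c_scale)
    expect_equal(roughness(v * c_scale), roughness(v))
    expect_equal(porosity(v * c_scale), porosity(v))
  }
  perm <- sample(length(v))
  expect_equal(mean_thickness(v[perm]), mean_thickness(v))
  expect_equal(roughness(v[perm]), roughness(v))
})

test_that("roughness separates homogeneous from heterogeneous canopies", {
  withr::with_seed(3, {
    smooth <- 100 + stats::rnorm(500, sd = 5) # few, small variations
    expect_lt(roughness(smooth), 0.5)
    rough <- sample(c(rep(5, 250), rep(300, 250))) # strongly bimodal canopy
    expect_gt(roughness(rough), 0.5)
  })
})

test_that("batch analysis aggregates replicates and flags failures", {
  scans <- lapply(1:5, function(i) make_flat_scan(width = 40))
  res <- analyze_bscans(scans, groups = "t1")
  expect_equal(nrow(res$per_scan), 5)
  expect_true(all(res$aggregate$sd == 0)) # identical scans
  expect_equal(
    res$aggregate$mean[res$aggregate$metric == "mean_thickness_um"],
    23 * 4.4)
  # a featureless scan becomes a flagged record, not an abort
  scans[[3]] <- bscan(matrix(50, 230, 40), id = "flat")
  res2 <- analyze_bscans(scans)
  expect_equal(sum(!is.na(res2$per_scan$error)), 1)
  expect_equal(res2$aggregate$n[1], 4)
  expect_error(analyze_bscans(list()), "non-empty")
})
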