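test_that("sample_lai respects the trial design and its range", {
  lai <- sample_lai(140, 5, c(0.5, 6.5), seed = 1)
  expect_equal(dim(lai), c(140, 5))
  expect_length(lai, 700)
  expect_true(all(lai > 0.5 & lai < 6.5))
  # rise-and-fall phenology: date means peak mid-season
  dm <- colMeans(lai)
  peak <- which.max(dm)
  expect_true(peak > 1 && peak < 5)
  expect_true(all(diff(dm[1:peak]) > 0))
  expect_true(all(diff(dm[peak:5]) < 0))
})

test_that("sample_lai is deterministic and validates its range", {
  expect_identical(sample_lai(20, 3, c(1, 4), seed = 7),
                   sample_lai(20, 3, c(1, 4), seed = 7))
  expect_error(sample_lai(10, 2, c(2, 2), seed = 1), class = "laitex_argument_error")
  expect_error(sample_lai(10, 2, c(-1, 3), seed = 1), class = "laitex_argument_error")
})

test_that("canopy_reflectance interpolates soil to leaf monotonically", {
  p <- canopy_params(seed = 1)
  expect_equal(unname(canopy_reflectance(0, p)), p$soil_reflectance)
  expect_equal(unname(canopy_reflectance(50, p)), p$leaf_reflectance,
               tolerance = 1e-9)
  # every band stays between its endmembers and moves monotonically
  grid <- seq(0, 6, by = 0.1)
  r <- canopy_reflectance(grid, p)
  for (b in seq_along(p$wavelengths)) {
    lo <- min(p$soil_reflectance[b], p$leaf_reflectance[b])
    hi <- max(p$soil_reflectance[b], p$leaf_reflectance[b])
    expect_true(all(r[, b] >= lo - 1e-12 & r[, b] <= hi + 1e-12))
    expect_true(all(diff(r[, b]) > 0) || all(diff(r[, b]) < 0))
  }
  expect_error(canopy_reflectance(-1, p), class = "laitex_argument_error")
})

test_that("NDVI of the mixing model increases with LAI", {
  reg <- data.frame(name = c("red650", "nir842"), wavelength = c(650, 842))
  p <- canopy_params(wavelengths = reg$wavelength, band_names = reg$name,
                     soil_reflectance = c(0.20, 0.25),
                     leaf_reflectance = c(0.05, 0.50),
                     extinction = c(0.5, 0.5), seed = 1)
  r <- canopy_reflectance(seq(0, 6, by = 0.05), p)
  ndvi <- (r[, "nir842"] - r[, "red650"]) / (r[, "nir842"] + r[, "red650"])
  expect_true(all(diff(ndvi) > 0))
})

test_that("render_plot_image reproduces the endmember geometry", {
  p <- canopy_params(noise_sd = 0, plot_size = c(24, 24), seed = 1)
  bare <- render_plot_image(0, p, seed = 3)
  for (b in seq_along(p$wavelengths)) {
    expect_true(all(bare[, , b] == p$soil_reflectance[b]))
  }
  # NIR mean increases with LAI (noise off, same seed)
  m1 <- mean(render_plot_image(1, p, seed = 5)[, , "nir842"])
  m4 <- mean(render_plot_image(4, p, seed = 5)[, , "nir842"])
  expect_gt(m4, m1)
})

test_that("rendered pixels stay in [0, 1] and match the expected mean", {
  p <- canopy_params(plot_size = c(32, 32), seed = 1)
  for (lai in c(0.5, 2, 5)) {
    img <- render_plot_image(lai, p, seed = 100 + lai)
    expect_true(all(img >= 0 & img <= 1))
    exp_r <- canopy_reflectance(lai, p)
    npx <- prod(p$plot_size)
    se <- p$noise_sd / sqrt(npx)
    quant <- abs(p$soil_reflectance - p$leaf_reflectance) / npx
    got <- apply(img, 3, mean)
    expect_true(all(abs(got - exp_r) <= 3 * se + quant))
  }
})

test_that("intermediate canopy cover maximizes within-plot heterogeneity", {
  p <- canopy_params(noise_sd = 0, plot_size = c(24, 24), seed = 1)
  v0 <- vapply(1:20, function(s) var(as.vector(render_plot_image(0, p, seed = s)[, , "red650"])),
               numeric(1))
  v2 <- vapply(1:20, function(s) var(as.vector(render_plot_image(2, p, seed = s)[, , "red650"])),
               numeric(1))
  expect_true(all(v2 > v0))
})

test_that("generate_dataset writes a complete, deterministic trial", {
  p <- canopy_params(n_plots = 4, n_dates = 2, plot_size = c(16, 16), seed = 11)
  d1 <- tempfile("gen1-"); d2 <- tempfile("gen2-")
  out1 <- generate_dataset(p, d1)
  expect_equal(nrow(out1$plots), 8)
  expect_length(out1$raster_paths, 2)
  expect_true(all(file.exists(out1$raster_paths)))
  rois <- read_rois(out1$roi_path)
  expect_length(rois, 4)
  tab <- read.csv(out1$lai_path, stringsAsFactors = FALSE)
  expect_identical(names(tab), c("plot_id", "date", "lai"))
  expect_equal(nrow(tab), 8)
  # byte-identical CSV on re-run with the same seed
  generate_dataset(p, d2)
  expect_identical(readBin(file.path(d1, "plots.csv"), "raw", 1e6),
                   readBin(file.path(d2, "plots.csv"), "raw", 1e6))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generate_dataset handles the single plot/date edge case", {
  p <- canopy_params(n_plots = 1, n_dates = 1, plot_size = c(16, 16), seed = 2)
  d <- tempfile("gen-")
  out <- generate_dataset(p, d)
  expect_equal(nrow(out$plots), 1)
  expect_length(read_rois(out$roi_path), 1)
  unlink(d, recursive = TRUE)
})

test_that("canopy_params rejects inconsistent endmember spectra", {
  expect_error(canopy_params(soil_reflectance = rep(2, 10), seed = 1),
               class = "laitex_argument_error")
  # leaf NIR must exceed soil NIR
  leaf <- default_leaf_spectrum(); leaf[10] <- 0.1
  expect_error(canopy_params(leaf_reflectance = leaf, seed = 1),
               class = "laitex_argument_error")
  expect_error(canopy_params(extinction = rep(0, 10), seed = 1),
               class = "laitex_argument_error")
})
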