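#' Default band registry of the dual multispectral camera
#'
#' Ten narrow bands spanning 444-842 nm (coastal blue through near infrared),
#' the band set of the RedEdge-MX Dual camera commonly flown for crop
#' phenotyping. Band identification throughout the package is by center
#' wavelength, never by band position, so subsets (e.g. a 5-band camera)
#' work as long as red 650, red edge 705 and NIR 842 are present.
#'
#' @return A data.frame with columns `name`, `wavelength` (nm), `bandwidth` (nm).
#' @export
#' @examples
#' default_band_registry()
default_band_registry <- function() {
  data.frame(
    name = c("coastal_blue", "blue", "green531", "green560", "red650",
             "red668", "rededge705", "rededge717", "rededge740", "nir842"),
    wavelength = c(444, 475, 531, 560, 650, 668, 705, 717, 740, 842),
    bandwidth = c(28, 32, 14, 27, 16, 14, 10, 12, 18, 57),
    stringsAsFactors = FALSE
  )
}

#' Default endmember spectra
#'
#' Piecewise-linear endmember reflectance curves over the default band
#' set: a plausible dry-soil curve rising slowly with wavelength, and a
#' green-leaf curve with the green bump, red absorption trough and steep
#' red-edge rise to a bright NIR plateau. They satisfy the constraints the
#' mixing model needs: leaf > soil in the NIR and leaf < soil through the
#' red, so NDVI increases with LAI and band/LAI correlation signs flip
#' across the red edge (negative through ~717 nm, positive at 740-842 nm).
#'
#' @return Numeric vector of 10 reflectances, ordered as
#'   [default_band_registry()].
#' @export
default_soil_spectrum <- function() {
  c(0.10, 0.11, 0.13, 0.14, 0.18, 0.19, 0.20, 0.21, 0.22, 0.25)
}

#' @rdname default_soil_spectrum
#' @export
default_leaf_spectrum <- function() {
  c(0.050, 0.045, 0.100, 0.110, 0.040, 0.040, 0.150, 0.200, 0.350, 0.500)
}

#' Parameters of the synthetic canopy scene generator
#'
#' Bundles everything that defines a simulated trial: endmember spectra,
#' per-band canopy extinction coefficients, the spatial correlation length
#' of canopy gaps, sensor noise, trial dimensions (plots, dates, plot size
#' in pixels), the LAI range across varieties and growth stages, and the
#' realistic nuisance terms of a field campaign: ground-truth measurement
#' error (`lai_obs_sd`, ceptometer-style) and per-plot brightness
#' multipliers for the soil and leaf endmembers (`soil_jitter_sd`,
#' `leaf_jitter_sd`) emulating soil-background and variety effects.
#'
#' @param wavelengths Band center wavelengths in nm.
#' @param band_names Band names, same length as `wavelengths`.
#' @param soil_reflectance,leaf_reflectance Per-band endmember reflectances
#'   in \[0, 1\]. Defaults are documented piecewise-linear soil/vegetation
#'   curves. The leaf NIR reflectance must exceed the soil's, and the leaf
#'   red reflectance must be below the soil's.
#' @param extinction Per-band Beer-Lambert extinction coefficient k > 0
#'   (dimensionless); default 0.5 for every band, a typical canopy value.
#' @param gap_scale Correlation length of the canopy gap field, pixels.
#' @param noise_sd Additive Gaussian sensor noise, reflectance units.
#' @param n_plots,n_dates Number of plots (varieties) and of acquisition
#'   dates (growth stages).
#' @param plot_size Plot image size, pixels, `c(rows, cols)`.
#' @param lai_range Range `c(min, max)` of true LAI, m2/m2, with
#'   `0 <= min < max`.
#' @param lai_obs_sd Ground-truth LAI measurement error sd, m2/m2.
#' @param soil_jitter_sd,leaf_jitter_sd Sd of per-plot multiplicative
#'   brightness factors applied to the soil and leaf spectra when a dataset
#'   is generated (mean 1; 0 disables).
#' @param illum_sd Sd of a per-plot additive reflectance offset (mean 0,
#'   the same across bands) emulating residual illumination/BRDF and
#'   shadow differences left after panel calibration of a mosaicked
#'   scene. Additive offsets are the nuisance that ratio-based vegetation
#'   indices cannot cancel, while quantized co-occurrence texture is
#'   largely insensitive to them.
#' @param seed Integer RNG seed used by [generate_dataset()].
#'
#' @return An object of class `canopy_params` (a validated list).
#' @export
#' @examples
#' p <- canopy_params(seed = 1)
#' p$lai_range
canopy_params <- function(wavelengths = default_band_registry()$wavelength,
                          band_names = default_band_registry()$name,
                          soil_reflectance = default_soil_spectrum(),
                          leaf_reflectance = default_leaf_spectrum(),
                          extinction = rep(0.5, length(wavelengths)),
                          gap_scale = 4,
                          noise_sd = 0.005,
                          n_plots = 140,
                          n_dates = 5,
                          plot_size = c(64, 64),
                          lai_range = c(0.5, 6.5),
                          lai_obs_sd = 0.15,
                          soil_jitter_sd = 0.15,
                          leaf_jitter_sd = 0.08,
                          illum_sd = 0.012,
                          seed = NULL) {
  nb <- length(wavelengths)
  if (nb < 1L) abort_argument("at least one band is required")
  if (length(band_names) != nb || length(soil_reflectance) != nb ||
      length(leaf_reflectance) != nb || length(extinction) != nb) {
    abort_argument("band_names, soil_reflectance, leaf_reflectance and extinction must match wavelengths in length")
  }
  if (any(soil_reflectance < 0 | soil_reflectance > 1) ||
      any(leaf_reflectance < 0 | leaf_reflectance > 1)) {
    abort_argument("endmember reflectances must lie in [0, 1]")
  }
  if (any(extinction <= 0)) abort_argument("extinction coefficients must be strictly positive")
  has <- function(wl) any(wavelengths == wl)
  if (has(842) && has(650)) {
    i_nir <- which(wavelengths == 842)[1]
    i_red <- which(wavelengths == 650)[1]
    if (leaf_reflectance[i_nir] <= soil_reflectance[i_nir]) {
      abort_argument("leaf NIR (842 nm) reflectance must exceed soil NIR reflectance")
    }
    if (leaf_reflectance[i_red] >= soil_reflectance[i_red]) {
      abort_argument("leaf red (650 nm) reflectance must be below soil red reflectance")
    }
  }
  if (length(lai_range) != 2L || !all(is.finite(lai_range)) ||
      lai_range[1] < 0 || lai_range[1] >= lai_range[2]) {
    abort_argument("lai_range must be c(min, max) with 0 <= min < max")
  }
  if (length(plot_size) != 2L || any(plot_size < 8)) {
    abort_argument("plot_size must be c(rows, cols) with both >= 8")
  }
  if (n_plots < 1 || n_dates < 1) abort_argument("n_plots and n_dates must be >= 1")
  if (noise_sd < 0 || lai_obs_sd < 0 || soil_jitter_sd < 0 ||
      leaf_jitter_sd < 0 || illum_sd < 0) {
    abort_argument("noise and jitter standard deviations must be >= 0")
  }
  if (gap_scale <= 0) abort_argument("gap_scale must be > 0")
  structure(list(
    wavelengths = as.numeric(wavelengths), band_names = as.character(band_names),
    soil_reflectance = as.numeric(soil_reflectance),
    leaf_reflectance = as.numeric(leaf_reflectance),
    extinction = as.numeric(extinction), gap_scale = gap_scale,
    noise_sd = noise_sd, n_plots = as.integer(n_plots),
    n_dates = as.integer(n_dates), plot_size = as.integer(plot_size),
    lai_range = as.numeric(lai_range), lai_obs_sd = lai_obs_sd,
    soil_jitter_sd = soil_jitter_sd, leaf_jitter_sd = leaf_jitter_sd,
    illum_sd = illum_sd,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "canopy_params")
}

#' @export
print.canopy_params <- function(x, ...) {
  cat("Synthetic canopy scene parameters\n")
  cat(sprintf("  %d bands (%g-%g nm), %d plots x %d dates, plots %dx%d px\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$n_plots, x$n_dates, x$plot_size[1], x$plot_size[2]))
  cat(sprintf("  LAI range [%g, %g] m2/m2, obs error sd %g\n",
              x$lai_range[1], x$lai_range[2], x$lai_obs_sd))
  cat(sprintf("  sensor noise sd %g, gap scale %g px, jitter (soil %g, leaf %g), illum sd %g\n",
              x$noise_sd, x$gap_scale, x$soil_jitter_sd, x$leaf_jitter_sd, x$illum_sd))
  invisible(x)
}

#' Sample true LAI trajectories across plots and dates
#'
#' Draws a plots x dates matrix of true LAI values following a rise-and-fall
#' phenology: date means trace a sine bump across the season (tasseling
#' through milk ripening), each plot carries a persistent variety offset,
#' and a small residual varies by plot and date. Values are clamped strictly
#' inside `lai_range`.
#'
#' @param n_plots,n_dates Dimensions of the trial.
#' @param lai_range `c(min, max)` with `0 <= min < max`.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A numeric `n_plots` x `n_dates` matrix.
#' @export
#' @examples
#' lai <- sample_lai(140, 5, c(0.5, 6.5), seed = 1)
#' dim(lai)
sample_lai <- function(n_plots, n_dates, lai_range, seed) {
  if (length(lai_range) != 2L || !all(is.finite(lai_range)) ||
      lai_range[1] < 0 || lai_range[1] >= lai_range[2]) {
    abort_argument("lai_range must be c(min, max) with 0 <= min < max")
  }
  if (n_plots < 1 || n_dates < 1) abort_argument("n_plots and n_dates must be >= 1")
  rng <- diff(lai_range)
  with_seed(seed, {
    d <- seq_len(n_dates)
    profile <- sin(pi * (d - 0.5) / n_dates)          # rise and fall over the season
    date_mean <- lai_range[1] + (0.20 + 0.60 * profile) * rng
    plot_eff <- rnorm(n_plots, 0, 0.12 * rng)          # persistent variety effect
    eps <- matrix(rnorm(n_plots * n_dates, 0, 0.06 * rng), n_plots, n_dates)
    lai <- matrix(date_mean, n_plots, n_dates, byrow = TRUE) + plot_eff + eps
    margin <- 0.005 * rng
    lai <- pmin(pmax(lai, lai_range[1] + margin), lai_range[2] - margin)
    dimnames(lai) <- list(sprintf("plot_%03d", seq_len(n_plots)),
                          sprintf("date_%d", d))
    lai
  })
}

#' Expected canopy reflectance under Beer-Lambert endmember mixing
#'
#' The canopy is modelled as a two-endmember mixture: the fraction of the
#' ground seen through canopy gaps decays as `exp(-k_b * LAI)` per band, so
#' expected reflectance is
#' `R_b = soil_b * exp(-k_b * LAI) + leaf_b * (1 - exp(-k_b * LAI))`,
#' continuous and monotone in LAI, running from the soil spectrum at LAI 0
#' to the leaf spectrum asymptotically.
#'
#' @param lai Non-negative LAI value(s), m2/m2.
#' @param params A [canopy_params()] object.
#' @return A matrix `length(lai)` x bands of expected reflectances (a named
#'   vector when `lai` is scalar).
#' @export
#' @examples
#' p <- canopy_params(seed = 1)
#' canopy_reflectance(0, p)   # exactly the soil spectrum
canopy_reflectance <- function(lai, params) {
  stopifnot(inherits(params, "canopy_params"))
  if (any(!is.finite(lai)) || any(lai < 0)) abort_argument("lai must be finite and >= 0")
  gap <- exp(-outer(lai, params$extinction))           # n x bands gap fraction
  r <- gap * rep(params$soil_reflectance, each = length(lai)) +
    (1 - gap) * rep(params$leaf_reflectance, each = length(lai))
  colnames(r) <- params$band_names
  if (length(lai) == 1L) r[1, ] else r
}

# Spatially correlated standard-normal-ish field: white noise smoothed by a
# separable Gaussian kernel with sd gap_scale. Only the rank order of the
# field is used downstream, so its marginal scale is irrelevant.
smooth_gap_field <- function(rows, cols, gap_scale) {
  half <- max(1L, ceiling(3 * gap_scale))
  k <- exp(-0.5 * ((-half:half) / gap_scale)^2)
  k <- k / sum(k)
  band_mat <- function(n) {
    m <- matrix(0, n, n)
    for (o in -half:half) {
      idx <- seq_len(n)
      j <- idx + o
      ok <- j >= 1 & j <= n
      m[cbind(idx[ok], j[ok])] <- m[cbind(idx[ok], j[ok])] + k[o + half + 1]
    }
    m
  }
  z <- matrix(rnorm(rows * cols), rows, cols)
  band_mat(rows) %*% z %*% t(band_mat(cols))
}

#' Render one synthetic plot image
#'
#' Renders a multiband pixel array for a plot of given LAI: a spatially
#' correlated gap field is thresholded (by rank, so achieved gap fractions
#' are exact) at `exp(-k_b * LAI)` per band; gap pixels take the soil
#' spectrum and canopy pixels the leaf spectrum; Gaussian sensor noise is
#' added and the result clipped to \[0, 1\]. The image mean therefore
#' reproduces [canopy_reflectance()] up to noise and the 1-pixel rounding
#' of the gap count.
#'
#' @param lai Scalar LAI >= 0.
#' @param params A [canopy_params()] object.
#' @param seed Integer seed for the gap field and the noise.
#' @return A `rows x cols x bands` array with band names on the third axis.
#' @export
#' @examples
#' p <- canopy_params(noise_sd = 0, seed = 1)
#' img <- render_plot_image(2, p, seed = 7)
#' dim(img)
render_plot_image <- function(lai, params, seed) {
  stopifnot(inherits(params, "canopy_params"))
  if (length(lai) != 1L || !is.finite(lai) || lai < 0) {
    abort_argument("lai must be a single finite value >= 0")
  }
  rows <- params$plot_size[1]; cols <- params$plot_size[2]
  nb <- length(params$wavelengths)
  npx <- rows * cols
  with_seed(seed, {
    u <- smooth_gap_field(rows, cols, params$gap_scale)
    ord <- order(u, decreasing = TRUE)                 # ties broken by position
    img <- array(NA_real_, c(rows, cols, nb),
                 dimnames = list(NULL, NULL, params$band_names))
    for (b in seq_len(nb)) {
      n_gap <- round(exp(-params$extinction[b] * lai) * npx)
      px <- rep(params$leaf_reflectance[b], npx)
      if (n_gap > 0) px[ord[seq_len(n_gap)]] <- params$soil_reflectance[b]
      img[, , b] <- matrix(px, rows, cols)
    }
    if (params$noise_sd > 0) {
      img <- img + array(rnorm(npx * nb, 0, params$noise_sd), dim(img))
      img[img < 0] <- 0
      img[img > 1] <- 1
    }
    img
  })
}

#' Generate a full synthetic trial on disk
#'
#' Simulates the study design of a multi-date UAV campaign: `n_plots` plots
#' observed on `n_dates` dates. Per date, plot images are tiled (with a
#' soil-colored gutter) into one multiband scene written as a multi-page
#' 32-bit TIFF with a JSON band-registry sidecar; plot regions of interest
#' (inset from plot borders) go to a GeoJSON FeatureCollection in pixel
#' coordinates; and measured LAI (truth plus ground-measurement error) goes
#' to `plots.csv` with header `plot_id,date,lai`. Per-plot multiplicative
#' brightness jitter is applied to the soil and leaf endmember spectra,
#' emulating soil-background and variety effects.
#'
#' @param params A [canopy_params()] object; `params$seed` must be set.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `plots` (the plot table, including the
#'   latent `lai_true`), `raster_paths`, `roi_path`, `lai_path`,
#'   `registry_path`.
#' @export
#' @examples
#' p <- canopy_params(n_plots = 4, n_dates = 2, plot_size = c(16, 16), seed = 1)
#' out <- generate_dataset(p, tempfile("scene"))
#' nrow(out$plots)  # 8
generate_dataset <- function(params, out_dir) {
  stopifnot(inherits(params, "canopy_params"))
  if (is.null(params$seed)) abort_argument("params$seed must be set for generate_dataset()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_io(paste0("cannot create output directory: ", out_dir))

  np <- params$n_plots; nd <- params$n_dates
  pr <- params$plot_size[1]; pc <- params$plot_size[2]
  gutter <- 4L
  inset <- 2L
  ncol_tiles <- ceiling(sqrt(np))
  nrow_tiles <- ceiling(np / ncol_tiles)
  srows <- nrow_tiles * pr + (nrow_tiles + 1L) * gutter
  scols <- ncol_tiles * pc + (ncol_tiles + 1L) * gutter
  nb <- length(params$wavelengths)

  lai_true <- sample_lai(np, nd, params$lai_range, derive_seed(params$seed, 1))
  plot_ids <- rownames(lai_true)

  # campaign dates: five key growth stages, ~11 days apart
  dates <- format(as.Date("2021-07-24") + 11L * (seq_len(nd) - 1L), "%Y-%m-%d")

  jit <- with_seed(derive_seed(params$seed, 2), list(
    soil = matrix(pmax(0.2, rnorm(np * nd, 1, params$soil_jitter_sd)), np, nd),
    leaf = matrix(pmax(0.2, rnorm(np * nd, 1, params$leaf_jitter_sd)), np, nd),
    illum = matrix(rnorm(np * nd, 0, params$illum_sd), np, nd),
    obs = matrix(rnorm(np * nd, 0, params$lai_obs_sd), np, nd)
  ))

  registry <- data.frame(name = params$band_names,
                         wavelength = params$wavelengths,
                         bandwidth = NA_real_)
  reg_default <- default_band_registry()
  m <- match(registry$wavelength, reg_default$wavelength)
  registry$bandwidth <- reg_default$bandwidth[m]

  rois <- vector("list", np)
  raster_paths <- character(nd)
  for (d in seq_len(nd)) {
    scene <- array(0, c(srows, scols, nb))
    for (b in seq_len(nb)) scene[, , b] <- params$soil_reflectance[b]
    for (p in seq_len(np)) {
      tile_r <- (p - 1L) %/% ncol_tiles
      tile_c <- (p - 1L) %% ncol_tiles
      r0 <- gutter + tile_r * (pr + gutter)            # 0-based row of plot origin
      c0 <- gutter + tile_c * (pc + gutter)
      pp <- params
      pp$soil_reflectance <- pmin(1, pmax(0,
        params$soil_reflectance * jit$soil[p, d] + jit$illum[p, d]))
      pp$leaf_reflectance <- pmin(1, pmax(0,
        params$leaf_reflectance * jit$leaf[p, d] + jit$illum[p, d]))
      img <- render_plot_image(lai_true[p, d], pp,
                               seed = derive_seed(params$seed, 3, p, d))
      scene[(r0 + 1L):(r0 + pr), (c0 + 1L):(c0 + pc), ] <- img
      if (d == 1L) {
        rois[[p]] <- roi_rect(plot_ids[p],
                              r0 + inset, r0 + pr - inset,
                              c0 + inset, c0 + pc - inset)
      }
    }
    stack <- band_stack(scene, registry, units = "reflectance")
    raster_paths[d] <- file.path(out_dir, sprintf("scene_date%d.tif", d))
    write_stack(stack, raster_paths[d])
  }

  roi_path <- file.path(out_dir, "rois.geojson")
  write_rois_geojson(rois, roi_path)
  registry_path <- file.path(out_dir, "bands.json")
  jsonlite::write_json(registry, registry_path, digits = NA, pretty = TRUE)

  plots <- data.frame(
    plot_id = rep(plot_ids, nd),
    date = rep(dates, each = np),
    lai = pmax(0, as.vector(lai_true) + as.vector(jit$obs)),
    stringsAsFactors = FALSE
  )
  lai_path <- file.path(out_dir, "plots.csv")
  write.csv(plots[, c("plot_id", "date", "lai")], lai_path, row.names = FALSE, quote = FALSE)

  plots$lai_true <- as.vector(lai_true)
  invisible(list(plots = plots, raster_paths = raster_paths, roi_path = roi_path,
                 lai_path = lai_path, registry_path = registry_path,
                 dates = dates))
}
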