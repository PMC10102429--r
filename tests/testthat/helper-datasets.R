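# Shared synthetic datasets, generated lazily once per test run.
# Problem sizes: module-level checks use a reduced trial (60 plots x
# 3 dates, 48x48 px); the study-scale checks use the full default design
# (140 plots x 5 dates, 64x64 px).

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Generate a scene on disk, extract per-plot features and append the VIs.
generate_feature_table <- function(params) {
  out_dir <- tempfile("laitex-scene-")
  gen <- generate_dataset(params, out_dir)
  rois <- read_rois(gen$roi_path)
  lai <- utils::read.csv(gen$lai_path, stringsAsFactors = FALSE)
  feats <- extract_features(gen$raster_paths, gen$dates, rois, lai)
  feats <- vi_table(feats)
  unlink(out_dir, recursive = TRUE)
  feats
}

small_default_features <- function() {
  cached_fixture("small_features", {
    generate_feature_table(canopy_params(n_plots = 60, n_dates = 3,
                                         plot_size = c(48, 48), seed = 42))
  })
}

full_default_features <- function() {
  cached_fixture("full_features", {
    generate_feature_table(canopy_params(seed = 20210724))
  })
}

# Noise-free variant: deterministic features (no sensor noise, no
# endmember jitter, no LAI measurement error).
noise_free_features <- function() {
  cached_fixture("noise_free_features", {
    generate_feature_table(canopy_params(n_plots = 70, n_dates = 5,
                                         plot_size = c(48, 48),
                                         noise_sd = 0, lai_obs_sd = 0,
                                         soil_jitter_sd = 0, leaf_jitter_sd = 0,
                                         illum_sd = 0, seed = 99))
  })
}
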