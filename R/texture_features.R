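#' GLCM texture configuration
#'
#' Settings for windowed gray-level co-occurrence texture extraction. The
#' defaults — 64 gray levels, a 3x3 window, the four unit-direction offsets
#' (0, 45, 90, 135 degrees) averaged, symmetric co-occurrence — match the
#' common ENVI-style occurrence-texture configuration and are all
#' overridable. Quantization is linear min-max over the full raster (not
#' per window), so texture `mean`/`var` remain comparable across plots of
#' one scene.
#'
#' @param levels Integer number of gray levels L >= 2.
#' @param window Odd window size >= 3, pixels.
#' @param offsets Integer matrix of `(drow, dcol)` displacements, one per row.
#' @param symmetric Add the transposed pairs (symmetric GLCM)?
#' @param bands Center wavelengths (nm) of the bands to texture-process.
#' @return An object of class `glcm_config`.
#' @export
glcm_config <- function(levels = 64L, window = 3L,
                        offsets = rbind(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L)),
                        symmetric = TRUE,
                        bands = c(650, 705, 842)) {
  if (levels < 2L) abort_argument("levels must be >= 2")
  if (window < 3L || window %% 2L == 0L) abort_argument("window must be odd and >= 3")
  offsets <- as.matrix(offsets)
  if (nrow(offsets) < 1L || ncol(offsets) != 2L) {
    abort_argument("offsets must be a matrix of (drow, dcol) rows")
  }
  if (any(offsets[, 1] == 0 & offsets[, 2] == 0)) abort_argument("the zero offset is not allowed")
  structure(list(levels = as.integer(levels), window = as.integer(window),
                 offsets = apply(offsets, 2, as.integer), symmetric = isTRUE(symmetric),
                 bands = as.numeric(bands)),
            class = "glcm_config")
}

#' @export
print.glcm_config <- function(x, ...) {
  cat(sprintf("GLCM config: %d levels, %dx%d window, %d offsets, %s, bands %s nm\n",
              x$levels, x$window, x$window, nrow(x$offsets),
              if (x$symmetric) "symmetric" else "asymmetric",
              paste(x$bands, collapse = "/")))
  invisible(x)
}

#' Linear min-max gray-level quantization
#'
#' Bins a raster linearly into `levels` gray levels over its full-raster
#' min-max range: the minimum maps to level 0, the maximum to `levels - 1`,
#' and a constant raster maps entirely to level 0. Quantization preserves
#' value order (non-strictly).
#'
#' @param band_raster Numeric matrix.
#' @param levels Number of gray levels L >= 2.
#' @return Integer matrix with values in `0:(levels - 1)`.
#' @export
quantize <- function(band_raster, levels) {
  if (levels < 2L) abort_argument("levels must be >= 2")
  x <- as.matrix(band_raster)
  if (all(is.na(x))) abort_argument("cannot quantize an all-NA raster")
  if (any(!is.finite(x[!is.na(x)]))) abort_argument("raster must be finite")
  lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
  if (hi == lo) {
    q <- matrix(0L, nrow(x), ncol(x))
  } else {
    q <- floor((x - lo) / (hi - lo) * levels)
    q[q > levels - 1L] <- levels - 1L
    storage.mode(q) <- "integer"
  }
  q
}

#' Gray-level co-occurrence matrix of a pixel window
#'
#' Counts ordered pairs `(reference = i, neighbor = j)` of quantized values
#' at the given displacement inside the window, adds the transpose when
#' `symmetric`, and normalizes to sum 1.
#'
#' @param window_pixels Integer matrix of quantized values in `0:(levels-1)`.
#' @param offset `(drow, dcol)` displacement.
#' @param levels Number of gray levels.
#' @param symmetric Symmetrize by adding the transpose?
#' @return `levels x levels` probability matrix of class `glcm`.
#' @export
#' @examples
#' cb <- matrix(c(0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L), 4, 2)  # checkerboard cols
#' glcm(cb, c(0, 1), levels = 2)
glcm <- function(window_pixels, offset, levels, symmetric = TRUE) {
  q <- as.matrix(window_pixels)
  if (any(q < 0 | q > levels - 1L, na.rm = TRUE)) {
    abort_argument("window values must be quantized to 0:(levels-1)")
  }
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  nr <- nrow(q); nc <- ncol(q)
  rr <- seq_len(nr); cc <- seq_len(nc)
  rr <- rr[rr + dr >= 1 & rr + dr <= nr]
  cc <- cc[cc + dc >= 1 & cc + dc <= nc]
  if (length(rr) == 0L || length(cc) == 0L) {
    abort_domain("no valid pixel pair at this offset inside the window")
  }
  i <- as.vector(q[rr, cc, drop = FALSE])
  j <- as.vector(q[rr + dr, cc + dc, drop = FALSE])
  keep <- !is.na(i) & !is.na(j)
  if (!any(keep)) abort_domain("no valid pixel pair at this offset inside the window")
  i <- i[keep]; j <- j[keep]
  counts <- table(factor(i, levels = 0:(levels - 1L)),
                  factor(j, levels = 0:(levels - 1L)))
  P <- matrix(as.numeric(counts), levels, levels)
  if (symmetric) P <- P + t(P)
  P <- P / sum(P)
  structure(P, class = c("glcm", "matrix"))
}

#' Haralick-style statistics of a GLCM
#'
#' With marginal means `mu_i = sum i P(i, j)`, `mu_j`, and marginal
#' variances `sigma_i^2`, `sigma_j^2` over 0-based levels, returns
#' `mean = mu_i`, `var = sigma_i^2`,
#' `hom = sum P / (1 + (i - j)^2)`, `con = sum (i - j)^2 P`,
#' `dis = sum |i - j| P`, `ent = -sum P log P` (natural log),
#' `sm = sum P^2`, and
#' `cor = sum (i - mu_i)(j - mu_j) P / (sigma_i sigma_j)`, defined as 0
#' when either marginal variance is 0.
#'
#' @param P A GLCM probability matrix (entries >= 0, summing to 1).
#' @return Named numeric vector of the 8 statistics.
#' @export
haralick_stats <- function(P) {
  P <- unclass(as.matrix(P))
  if (any(P < 0) || abs(sum(P) - 1) > 1e-8) {
    abort_argument("P must be a probability matrix summing to 1")
  }
  L <- nrow(P)
  lev <- 0:(L - 1L)
  I <- matrix(lev, L, L)
  J <- t(I)
  mu_i <- sum(I * P); mu_j <- sum(J * P)
  var_i <- sum((I - mu_i)^2 * P); var_j <- sum((J - mu_j)^2 * P)
  D <- I - J
  pos <- P > 0
  cor <- if (var_i <= 1e-12 || var_j <= 1e-12) 0 else {
    sum((I - mu_i) * (J - mu_j) * P) / sqrt(var_i * var_j)
  }
  c(mean = mu_i,
    var = var_i,
    hom = sum(P / (1 + D^2)),
    con = sum(D^2 * P),
    dis = sum(abs(D) * P),
    ent = -sum(P[pos] * log(P[pos])),
    sm = sum(P^2),
    cor = cor)
}

#' Windowed texture maps of a band raster
#'
#' Quantizes the raster (full-raster min-max) and, for every pixel whose
#' window fits inside the raster, computes the GLCM averaged over the
#' configured offsets and its eight statistics. Border pixels (incomplete
#' windows) are NA.
#'
#' @param band_raster Numeric matrix (one band).
#' @param config A [glcm_config()].
#' @return Named list of 8 matrices (`mean`, `var`, `hom`, `con`, `dis`,
#'   `ent`, `sm`, `cor`), same dimensions as the input.
#' @export
texture_maps <- function(band_raster, config = glcm_config()) {
  stopifnot(inherits(config, "glcm_config"))
  x <- as.matrix(band_raster)
  if (nrow(x) < config$window || ncol(x) < config$window) {
    abort_argument("raster smaller than the texture window")
  }
  q <- quantize(x, config$levels)
  .glcm_texture_maps_cpp(q, config$levels, config$window,
                         config$offsets, config$symmetric)
}

texture_stat_names <- function() c("mean", "var", "hom", "con", "dis", "ent", "sm", "cor")

#' Registry of texture feature names
#'
#' @param bands Center wavelengths (nm).
#' @return Character vector `stat_band` (e.g. `mean_650`), 8 x bands long.
#' @export
texture_feature_names <- function(bands = c(650, 705, 842)) {
  as.vector(t(outer(texture_stat_names(), bands, paste, sep = "_")))
}

#' ROI means of per-band texture maps
#'
#' Averages each texture statistic map over the valid (non-border) pixels
#' of a plot ROI, yielding the `8 x n_bands` named texture feature values
#' (`mean_650`, `ent_705`, ...).
#'
#' @param texture_maps_per_band Named list (names = band wavelengths) of
#'   [texture_maps()] results.
#' @param roi An ROI object.
#' @return Named numeric vector of `8 * length(bands)` texture features.
#' @export
roi_texture_means <- function(texture_maps_per_band, roi) {
  bands <- names(texture_maps_per_band)
  if (is.null(bands)) abort_argument("texture_maps_per_band must be a named list (names = wavelengths)")
  out <- numeric(0)
  for (b in bands) {
    maps <- texture_maps_per_band[[b]]
    d <- dim(maps[[1]])
    idx <- .roi_linear_index(d[1], d[2], roi)
    if (is.null(idx)) {
      laitex_error(sprintf("ROI for plot '%s' does not intersect the raster", roi$plot_id),
                   "laitex_empty_roi_error")
    }
    for (s in texture_stat_names()) {
      v <- maps[[s]][idx]
      if (all(is.na(v))) {
        laitex_error(sprintf("ROI for plot '%s' covers only border pixels", roi$plot_id),
                     "laitex_empty_roi_error")
      }
      out[paste(s, b, sep = "_")] <- mean(v, na.rm = TRUE)
    }
  }
  out
}
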