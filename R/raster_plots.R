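#' Multiband raster stack
#'
#' A lightweight in-memory container for a multiband image: a
#' `rows x cols x bands` array plus a band registry (name, center
#' wavelength in nm, bandwidth) and a units tag, either `"reflectance"`
#' (values expected in \[0, 1.5\], tolerating calibration overshoot) or
#' `"dn"` (raw digital numbers). Bands are addressed by center wavelength.
#'
#' @param pixels `rows x cols x bands` numeric array (a matrix is promoted
#'   to a single-band array).
#' @param registry Data.frame with columns `name`, `wavelength`, and
#'   optionally `bandwidth`; one row per band.
#' @param units `"reflectance"` or `"dn"`.
#' @return An object of class `band_stack`.
#' @export
band_stack <- function(pixels, registry, units = c("reflectance", "dn")) {
  units <- match.arg(units)
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (length(dim(pixels)) != 3L) abort_argument("pixels must be a rows x cols x bands array")
  if (!is.data.frame(registry) || !all(c("name", "wavelength") %in% names(registry))) {
    abort_argument("registry must be a data.frame with columns name and wavelength")
  }
  if (dim(pixels)[3] != nrow(registry)) {
    abort_argument(sprintf("band count mismatch: %d bands in pixels, %d registry entries",
                           dim(pixels)[3], nrow(registry)))
  }
  if (units == "reflectance" && any(pixels < 0 | pixels > 1.5, na.rm = TRUE)) {
    abort_argument("reflectance-mode values must lie in [0, 1.5]")
  }
  dimnames(pixels) <- list(NULL, NULL, registry$name)
  structure(list(pixels = pixels, registry = as.data.frame(registry), units = units),
            class = "band_stack")
}

#' @export
print.band_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("band_stack: %d x %d px, %d bands (%s), units = %s\n",
              d[1], d[2], d[3],
              paste(x$registry$wavelength, collapse = ", "), x$units))
  invisible(x)
}

# Index of the band closest to the requested center wavelength (exact match
# required within 1 nm; identification is by wavelength, not position).
band_index <- function(stack, wavelength) {
  i <- which(abs(stack$registry$wavelength - wavelength) < 1)
  if (length(i) == 0L) {
    laitex_error(sprintf("band with center wavelength %g nm not found in registry", wavelength),
                 "laitex_key_error")
  }
  i[1]
}

# The tiff codec stores 32-bit samples as truncated integer * (2^32 - 1);
# readTIFF returns k / 2^32. Snapping input to the readable grid
# {k / 2^32} and padding by half a step before writing makes
# read -> write -> read exactly lossless (first-write error <= 2^-33).
.tiff_snap_write <- function(pages, path) {
  s <- 2^32
  pages <- lapply(pages, function(m) {
    k <- pmin(round(m * s), s - 1)
    (k + 0.5) / (s - 1)
  })
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32))
}

registry_sidecar_path <- function(path) paste0(path, ".bands.json")

#' Write a reflectance stack to a multi-page TIFF
#'
#' One page per band, 32-bit samples, with the band registry written to a
#' JSON sidecar (`<path>.bands.json`). Values must be reflectances in
#' \[0, 1\]; they are snapped to the codec's representable grid so that a
#' read-back, re-written file round-trips exactly.
#'
#' @param stack A [band_stack()] in reflectance units.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "band_stack"))
  if (stack$units != "reflectance") abort_argument("write_stack() requires reflectance units")
  if (any(stack$pixels < 0 | stack$pixels > 1)) {
    abort_argument("write_stack() requires reflectances in [0, 1]")
  }
  nb <- dim(stack$pixels)[3]
  pages <- lapply(seq_len(nb), function(b) stack$pixels[, , b])
  ok <- tryCatch(.tiff_snap_write(pages, path), error = function(e) NA)
  if (!file.exists(path)) abort_io(paste0("failed to write raster: ", path))
  jsonlite::write_json(stack$registry, registry_sidecar_path(path),
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a multiband TIFF into a band stack
#'
#' Band metadata comes from the JSON sidecar written by [write_stack()],
#' or from an explicit `registry` argument which overrides (and is checked
#' against) the file's band count.
#'
#' @param path TIFF path.
#' @param registry Optional band registry data.frame override.
#' @param units Units tag of the stored values.
#' @return A [band_stack()].
#' @export
read_stack <- function(path, registry = NULL, units = "reflectance") {
  if (!file.exists(path)) abort_io(paste0("raster file not found: ", path))
  pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  if (is.null(registry)) {
    sc <- registry_sidecar_path(path)
    if (file.exists(sc)) {
      registry <- as.data.frame(jsonlite::read_json(sc, simplifyVector = TRUE))
    } else {
      registry <- data.frame(name = sprintf("band_%d", seq_along(pages)),
                             wavelength = NA_real_)
    }
  }
  if (nrow(registry) != length(pages)) {
    abort_argument(sprintf("band count mismatch: file has %d bands, registry declares %d",
                           length(pages), nrow(registry)))
  }
  px <- array(unlist(pages, use.names = FALSE),
              c(dim(pages[[1]]), length(pages)))
  band_stack(px, registry, units = units)
}

#' Radiometric calibration from a reference panel
#'
#' Single-panel, zero-intercept linear calibration (the standard MicaSense
#' panel procedure): per band, `reflectance = DN * panel_reflectance / panel_DN`.
#'
#' @param dn_stack A [band_stack()] with `units = "dn"`.
#' @param panel_dn Per-band mean DN of the calibration panel (> 0).
#' @param panel_reflectance Per-band known panel reflectance.
#' @return A reflectance-mode [band_stack()].
#' @export
#' @examples
#' reg <- data.frame(name = "nir842", wavelength = 842)
#' dn <- band_stack(matrix(12500, 2, 2), reg, units = "dn")
#' calibrate(dn, panel_dn = 25000, panel_reflectance = 0.5)$pixels[1, 1, 1]  # 0.25
calibrate <- function(dn_stack, panel_dn, panel_reflectance) {
  stopifnot(inherits(dn_stack, "band_stack"))
  if (dn_stack$units != "dn") abort_argument("calibrate() expects a stack in DN units")
  nb <- dim(dn_stack$pixels)[3]
  if (length(panel_dn) == 1L) panel_dn <- rep(panel_dn, nb)
  if (length(panel_reflectance) == 1L) panel_reflectance <- rep(panel_reflectance, nb)
  if (length(panel_dn) != nb || length(panel_reflectance) != nb) {
    abort_argument("panel_dn and panel_reflectance must have one value per band")
  }
  if (any(!is.finite(panel_dn)) || any(panel_dn <= 0)) {
    abort_argument("panel_dn must be strictly positive")
  }
  gain <- panel_reflectance / panel_dn
  px <- dn_stack$pixels
  for (b in seq_len(nb)) px[, , b] <- px[, , b] * gain[b]
  band_stack(px, dn_stack$registry, units = "reflectance")
}

# Regions of interest ------------------------------------------------------

#' Rectangular and polygonal plot regions of interest
#'
#' ROIs live in 0-based pixel coordinates, row-major. A rectangle is
#' half-open: it contains pixels with `row_min <= row < row_max` and
#' `col_min <= col < col_max`. A polygon contains the pixels whose centers
#' `(col + 0.5, row + 0.5)` fall inside it (x = column, y = row).
#'
#' @param plot_id Plot identifier.
#' @param row_min,row_max,col_min,col_max Half-open pixel bounds.
#' @return An object of class `roi_rect` / `roi_polygon`.
#' @export
roi_rect <- function(plot_id, row_min, row_max, col_min, col_max) {
  if (row_max <= row_min || col_max <= col_min) {
    abort_argument(sprintf("empty ROI for plot '%s' (non-positive extent)", plot_id))
  }
  structure(list(plot_id = as.character(plot_id),
                 row_min = as.integer(row_min), row_max = as.integer(row_max),
                 col_min = as.integer(col_min), col_max = as.integer(col_max)),
            class = c("roi_rect", "roi"))
}

#' @param coords Two-column matrix of polygon vertices, columns `(x = col, y = row)`.
#' @rdname roi_rect
#' @export
roi_polygon <- function(plot_id, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L) abort_argument(sprintf("polygon ROI for plot '%s' needs >= 3 vertices", plot_id))
  structure(list(plot_id = as.character(plot_id), coords = coords),
            class = c("roi_polygon", "roi"))
}

#' Write ROIs as a GeoJSON FeatureCollection (pixel coordinates)
#'
#' @param rois List of ROI objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rois_geojson <- function(rois, path) {
  feat <- lapply(rois, function(r) {
    if (inherits(r, "roi_rect")) {
      ring <- cbind(c(r$col_min, r$col_max, r$col_max, r$col_min, r$col_min),
                    c(r$row_min, r$row_min, r$row_max, r$row_max, r$row_min))
    } else {
      ring <- r$coords
      if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    }
    list(type = "Feature",
         properties = list(plot_id = r$plot_id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read plot ROIs from GeoJSON polygons or a CSV rectangle table
#'
#' The CSV form has header `plot_id,row_min,row_max,col_min,col_max`
#' (half-open pixel bounds). GeoJSON polygons are interpreted in pixel
#' coordinates (x = column, y = row); axis-aligned 5-vertex rectangles
#' whose corners sit on integer pixel edges are recognized and read back
#' as rectangles.
#'
#' @param path ROI file (`.geojson`/`.json` or `.csv`).
#' @return A named list of ROI objects (names = plot ids).
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) abort_io(paste0("ROI file not found: ", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("plot_id", "row_min", "row_max", "col_min", "col_max")
    if (!all(need %in% names(tab))) {
      abort_argument(paste0("ROI CSV must have columns ", paste(need, collapse = ",")))
    }
    rois <- lapply(seq_len(nrow(tab)), function(i) {
      roi_rect(tab$plot_id[i], tab$row_min[i], tab$row_max[i],
               tab$col_min[i], tab$col_max[i])
    })
  } else {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(gj$features)) abort_argument("GeoJSON must be a FeatureCollection")
    rois <- lapply(gj$features, function(f) {
      pid <- f$properties$plot_id
      ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                    function(xy) as.numeric(unlist(xy))))
      is_rect <- nrow(ring) == 5L &&
        length(unique(ring[, 1])) == 2L && length(unique(ring[, 2])) == 2L &&
        all(ring == round(ring))
      if (is_rect) {
        roi_rect(pid, min(ring[, 2]), max(ring[, 2]), min(ring[, 1]), max(ring[, 1]))
      } else {
        roi_polygon(pid, ring[-nrow(ring), , drop = FALSE])
      }
    })
  }
  names(rois) <- vapply(rois, `[[`, "", "plot_id")
  rois
}

# Linear (column-major) indices of the pixels belonging to an ROI on a
# rows x cols grid; NULL when the intersection is empty.
.roi_linear_index <- function(rows, cols, roi) {
  if (inherits(roi, "roi_rect")) {
    r0 <- max(roi$row_min, 0L); r1 <- min(roi$row_max, rows)
    c0 <- max(roi$col_min, 0L); c1 <- min(roi$col_max, cols)
    if (r1 <= r0 || c1 <= c0) return(NULL)
    idx <- as.vector(outer((r0 + 1L):r1, ((c0 + 1L):c1 - 1L) * rows, `+`))
  } else {
    grid <- expand.grid(row = seq_len(rows) - 0.5, col = seq_len(cols) - 0.5)
    inside <- mgcv::in.out(rbind(roi$coords, roi$coords[1, ]),
                           cbind(grid$col, grid$row))
    if (!any(inside)) return(NULL)
    idx <- which(inside)
  }
  idx
}

#' Extract the pixels of a plot ROI
#'
#' Returns the `n_pixels x bands` matrix of stack values whose pixel
#' centers fall inside the ROI (half-open bounds for rectangles,
#' center-in-polygon for polygons).
#'
#' @param stack A [band_stack()].
#' @param roi An ROI object.
#' @return Numeric matrix with one column per band (named by band).
#' @export
extract_plot_pixels <- function(stack, roi) {
  stopifnot(inherits(stack, "band_stack"), inherits(roi, "roi"))
  d <- dim(stack$pixels)
  idx <- .roi_linear_index(d[1], d[2], roi)
  if (is.null(idx)) {
    laitex_error(sprintf("ROI for plot '%s' does not intersect the raster", roi$plot_id),
                 "laitex_empty_roi_error")
  }
  flat <- matrix(stack$pixels, ncol = d[3])
  px <- flat[idx, , drop = FALSE]
  colnames(px) <- stack$registry$name
  px
}

#' Per-band mean reflectance of a pixel matrix
#'
#' @param pixel_matrix `n_pixels x bands` matrix from [extract_plot_pixels()].
#' @return Named per-band mean vector.
#' @export
plot_mean_reflectance <- function(pixel_matrix) {
  if (is.null(dim(pixel_matrix)) || nrow(pixel_matrix) < 1L) {
    abort_argument("pixel matrix must have at least one pixel")
  }
  colMeans(pixel_matrix)
}
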