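#' Registry of the eight vegetation indices
#'
#' The eight indices computed by the pipeline, each an algebraic
#' combination of the blue (475 nm), red (650 nm), red-edge (705 nm) and
#' NIR (842 nm) reflectances:
#' \itemize{
#'   \item NDVI  = (NIR - R) / (NIR + R)
#'   \item NDRE  = (NIR - RE) / (NIR + RE)
#'   \item MTCI  = (NIR - RE) / (RE + R)
#'   \item DVI   = NIR - R
#'   \item RVI   = NIR / R
#'   \item CIrededge = NIR / RE - 1
#'   \item EVI   = 2.5 (NIR - R) / (NIR + 6 R - 7.5 B + 1)
#'   \item OSAVI = (1 + 0.16) (NIR - R) / (NIR + R + 0.16)
#' }
#' The MTCI and OSAVI forms are implemented exactly as used in this
#' analysis dialect (MTCI with the red band in the denominator; OSAVI in
#' its (1 + 0.16) normalization), which differs from some literature
#' variants.
#'
#' @return Data.frame with columns `name` and `bands` (comma-separated
#'   required center wavelengths, nm).
#' @export
vi_registry <- function() {
  data.frame(
    name = c("NDVI", "NDRE", "MTCI", "DVI", "RVI", "CIrededge", "EVI", "OSAVI"),
    bands = c("650,842", "705,842", "650,705,842", "650,842", "650,842",
              "705,842", "475,650,842", "650,842"),
    stringsAsFactors = FALSE
  )
}

.vi_band <- function(bands, wl) {
  nm <- as.character(wl)
  if (!nm %in% names(bands) || !is.finite(bands[[nm]])) {
    laitex_error(sprintf("missing band: reflectance at %g nm is required", wl),
                 "laitex_key_error")
  }
  unname(bands[[nm]])
}

.vi_ratio <- function(num, den, name) {
  if (den == 0) abort_domain(sprintf("zero denominator in %s", name))
  num / den
}

#' Compute one vegetation index
#'
#' @param name Index name from [vi_registry()].
#' @param reflectance_by_band Named numeric vector of band reflectances;
#'   names are center wavelengths in nm (e.g. `c("650" = 0.1, "842" = 0.5)`).
#' @return The index value. A denominator of exactly zero raises a domain
#'   error (class `laitex_domain_error`) rather than returning Inf/NaN.
#' @export
#' @examples
#' compute_vi("NDVI", c("650" = 0.1, "842" = 0.5))
compute_vi <- function(name, reflectance_by_band) {
  b <- reflectance_by_band
  switch(name,
    NDVI = {
      nir <- .vi_band(b, 842); r <- .vi_band(b, 650)
      .vi_ratio(nir - r, nir + r, "NDVI")
    },
    NDRE = {
      nir <- .vi_band(b, 842); re <- .vi_band(b, 705)
      .vi_ratio(nir - re, nir + re, "NDRE")
    },
    MTCI = {
      nir <- .vi_band(b, 842); re <- .vi_band(b, 705); r <- .vi_band(b, 650)
      .vi_ratio(nir - re, re + r, "MTCI")
    },
    DVI = .vi_band(b, 842) - .vi_band(b, 650),
    RVI = .vi_ratio(.vi_band(b, 842), .vi_band(b, 650), "RVI"),
    CIrededge = .vi_ratio(.vi_band(b, 842), .vi_band(b, 705), "CIrededge") - 1,
    EVI = {
      nir <- .vi_band(b, 842); r <- .vi_band(b, 650); blue <- .vi_band(b, 475)
      2.5 * .vi_ratio(nir - r, nir + 6 * r - 7.5 * blue + 1, "EVI")
    },
    OSAVI = {
      nir <- .vi_band(b, 842); r <- .vi_band(b, 650)
      (1 + 0.16) * .vi_ratio(nir - r, nir + r + 0.16, "OSAVI")
    },
    laitex_error(sprintf("unknown vegetation index '%s'", name), "laitex_key_error")
  )
}

#' Append the eight vegetation index columns to a feature table
#'
#' Band-mean columns are expected as `b<wavelength>` (e.g. `b650`); the
#' eight VI columns are appended, with row count unchanged. A domain or
#' missing-band error on any row is re-raised with the row's `plot_id`
#' for context.
#'
#' @param feature_table Data.frame with band-mean columns `b475`, `b650`,
#'   `b705`, `b842` (others allowed).
#' @return The table with 8 added columns named as in [vi_registry()].
#' @export
vi_table <- function(feature_table) {
  reg <- vi_registry()
  need <- c(475, 650, 705, 842)
  cols <- paste0("b", need)
  missing_cols <- setdiff(cols, names(feature_table))
  if (length(missing_cols)) {
    laitex_error(paste0("missing band-mean columns: ", paste(missing_cols, collapse = ", ")),
                 "laitex_key_error")
  }
  n <- nrow(feature_table)
  out <- feature_table
  for (v in reg$name) out[[v]] <- numeric(n)
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    bands <- setNames(as.numeric(feature_table[i, cols]), as.character(need))
    for (v in reg$name) {
      out[i, v] <- tryCatch(compute_vi(v, bands), laitex_error = function(e) {
        ctx <- if ("plot_id" %in% names(feature_table)) {
          sprintf(" (plot_id %s, row %d)", feature_table$plot_id[i], i)
        } else sprintf(" (row %d)", i)
        laitex_error(paste0(conditionMessage(e), ctx), class(e)[1])
      })
    }
  }
  out
}
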