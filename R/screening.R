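#' Pearson product-moment correlation
#'
#' A validated wrapper: requires n >= 3 complete pairs and positive
#' variance in both variables (zero variance raises an
#' undefined-correlation error rather than returning NA).
#'
#' @param x,y Numeric vectors of equal length.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort_argument("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort_argument("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    laitex_error("correlation undefined: zero variance", "laitex_domain_error")
  }
  cor(x, y)
}

#' Two-sided significance of a Pearson correlation
#'
#' p-value from `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. `|r| = 1` returns an exact p of 0 (flagged via attribute
#' `exact`).
#'
#' @param r Correlation coefficient.
#' @param n Sample size (>= 3).
#' @return The two-sided p-value.
#' @export
#' @examples
#' r_significance(0.9, 5)  # ~0.037
r_significance <- function(r, n) {
  if (n < 3) abort_argument("n must be >= 3")
  if (abs(r) > 1) abort_argument("|r| must be <= 1")
  if (abs(r) == 1) return(structure(0, exact = TRUE))
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Correlation screening of image features against LAI
#'
#' Computes the Pearson correlation, two-sided p-value and significance
#' stars (* p < 0.05, ** p < 0.01, uncorrected for multiplicity — the
#' conventional raw-star reporting) of every spectral parameter (band
#' means + vegetation indices) and texture feature against LAI, and
#' assembles the three model input sets: `VIs` (vegetation indices with
#' `|r| >= vi_threshold`, ordered by descending |r| then name), `TIs`
#' (the selected texture index columns), and `VIs+TIs` (their union).
#'
#' @param feature_table Data.frame joined with the LAI column.
#' @param lai_col Name of the LAI column.
#' @param band_cols Band-mean column names (default all `b<wavelength>`).
#' @param vi_cols Vegetation index columns (default the 8-VI registry).
#' @param texture_cols Texture feature columns (default the 24-feature
#'   registry).
#' @param ti_cols Selected texture index columns (e.g. from
#'   [append_texture_indices()]); screened and placed in the `TIs` set.
#' @param vi_threshold Absolute-correlation selection threshold for VIs.
#' @return A list of class `lai_screening`: `reports` (data.frame
#'   `feature`, `group`, `r`, `n`, `p`, `stars`) and `sets` (named list of
#'   feature-name vectors `VIs`, `TIs`, `VIs+TIs`).
#' @export
screen_features <- function(feature_table, lai_col = "lai",
                            band_cols = grep("^b\\d+$", names(feature_table), value = TRUE),
                            vi_cols = intersect(vi_registry()$name, names(feature_table)),
                            texture_cols = intersect(texture_feature_names(), names(feature_table)),
                            ti_cols = character(),
                            vi_threshold = 0.700) {
  if (!lai_col %in% names(feature_table)) {
    laitex_error(sprintf("LAI column '%s' not found in the feature table", lai_col),
                 "laitex_key_error")
  }
  lai <- feature_table[[lai_col]]
  groups <- c(setNames(rep("band", length(band_cols)), band_cols),
              setNames(rep("vi", length(vi_cols)), vi_cols),
              setNames(rep("texture", length(texture_cols)), texture_cols),
              setNames(rep("texture_index", length(ti_cols)), ti_cols))
  reports <- do.call(rbind, lapply(names(groups), function(f) {
    x <- feature_table[[f]]
    ok <- is.finite(x) & is.finite(lai)
    r <- tryCatch(pearson_r(x[ok], lai[ok]), laitex_error = function(e) NA_real_)
    n <- sum(ok)
    p <- if (is.na(r)) NA_real_ else as.numeric(r_significance(r, n))
    data.frame(feature = f, group = unname(groups[f]), r = r, n = n, p = p,
               stars = if (is.na(p)) "" else significance_stars(p),
               stringsAsFactors = FALSE)
  }))
  vi_rep <- reports[reports$group == "vi" & !is.na(reports$r), ]
  vi_rep <- vi_rep[abs(vi_rep$r) >= vi_threshold, ]
  vi_rep <- vi_rep[order(-abs(vi_rep$r), vi_rep$feature), ]
  sets <- list(
    VIs = vi_rep$feature,
    TIs = ti_cols,
    `VIs+TIs` = c(vi_rep$feature, ti_cols)
  )
  structure(list(reports = reports, sets = sets, vi_threshold = vi_threshold),
            class = "lai_screening")
}

#' @export
print.lai_screening <- function(x, ...) {
  cat(sprintf("LAI correlation screening: %d features (threshold |r| >= %.3f)\n",
              nrow(x$reports), x$vi_threshold))
  cat("Selected input sets:\n")
  for (s in names(x$sets)) {
    cat(sprintf("  %-8s %s\n", s,
                if (length(x$sets[[s]])) paste(x$sets[[s]], collapse = ", ") else "(empty)"))
  }
  cat("Note: p-values are raw (no multiple-testing correction).\n")
  invisible(x)
}
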