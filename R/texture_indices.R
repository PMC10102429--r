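#' Pairwise texture indices
#'
#' Combines two texture feature values T1, T2 into a texture index:
#' normalized difference `NDTI = (T1 - T2) / (T1 + T2)`, ratio
#' `RTI = T1 / T2`, or difference `DTI = T1 - T2`. A denominator of
#' exactly zero raises a domain error (vectorized callers treat such rows
#' as missing).
#'
#' @param kind One of `"NDTI"`, `"RTI"`, `"DTI"`.
#' @param t1,t2 Texture feature values (scalars or vectors).
#' @return The index value(s).
#' @export
#' @examples
#' texture_index("NDTI", 3, 1)  # 0.5
texture_index <- function(kind, t1, t2) {
  kind <- match.arg(kind, c("NDTI", "RTI", "DTI"))
  if (any(!is.finite(t1)) || any(!is.finite(t2))) abort_argument("t1 and t2 must be finite")
  switch(kind,
    NDTI = {
      if (any(t1 + t2 == 0)) abort_domain("zero denominator in NDTI (t1 + t2 = 0)")
      (t1 - t2) / (t1 + t2)
    },
    RTI = {
      if (any(t2 == 0)) abort_domain("zero denominator in RTI (t2 = 0)")
      t1 / t2
    },
    DTI = t1 - t2
  )
}

# Vectorized, NA-tolerant variant used by traverse_pairs: domain errors
# become NA instead of raising.
.texture_index_na <- function(kind, t1, t2) {
  switch(kind,
    NDTI = ifelse(t1 + t2 == 0, NA_real_, (t1 - t2) / (t1 + t2)),
    RTI = ifelse(t2 == 0, NA_real_, t1 / t2),
    DTI = t1 - t2
  )
}

#' Texture index values over all ordered feature pairs
#'
#' For each index kind, evaluates the index on every ordered pair of the
#' texture feature columns (24 features -> 576 ordered pairs, diagonal
#' included but degenerate by construction). Ordered pairs matter: RTI is
#' not order-invariant in |r|, and published selections name specific
#' ordered pairs. Cross-band pairs are included. Rows where a denominator
#' is exactly zero are missing (NA).
#'
#' @param feature_table Data.frame containing the texture feature columns.
#' @param kinds Index kinds to compute.
#' @param features Texture feature column names (default the 24-feature
#'   registry from [texture_feature_names()]).
#' @return Named list (per kind) of `n x (p^2)` matrices; columns named
#'   `"t1:t2"`.
#' @export
traverse_pairs <- function(feature_table, kinds = c("NDTI", "RTI", "DTI"),
                           features = texture_feature_names()) {
  kinds <- match.arg(kinds, c("NDTI", "RTI", "DTI"), several.ok = TRUE)
  missing_cols <- setdiff(features, names(feature_table))
  if (length(missing_cols)) {
    laitex_error(paste0("missing texture feature columns: ",
                        paste(missing_cols, collapse = ", ")),
                 "laitex_key_error")
  }
  X <- as.matrix(feature_table[, features, drop = FALSE])
  p <- length(features)
  pairs <- expand.grid(t2 = seq_len(p), t1 = seq_len(p))[, c("t1", "t2")]
  cn <- paste(features[pairs$t1], features[pairs$t2], sep = ":")
  out <- lapply(kinds, function(k) {
    M <- .texture_index_na(k, X[, pairs$t1, drop = FALSE], X[, pairs$t2, drop = FALSE])
    M <- matrix(M, nrow = nrow(X), dimnames = list(NULL, cn))
    M
  })
  names(out) <- kinds
  out
}

#' Correlation of every texture index with LAI
#'
#' Pairwise-complete Pearson correlation of each ordered-pair index column
#' with LAI, reshaped to a `p x p` matrix per kind (rows = T1, cols = T2).
#' Cells with fewer than 3 complete samples or zero variance are NA. The
#' per-kind arg-max |r| pair is attached as attribute `best`.
#'
#' @param index_tables Output of [traverse_pairs()].
#' @param lai Numeric LAI vector, same length as the table rows.
#' @return Named list of correlation matrices with feature-named axes.
#' @export
index_lai_correlation <- function(index_tables, lai) {
  lapply(index_tables, function(M) {
    if (nrow(M) != length(lai)) abort_argument("lai length must match index table rows")
    r <- suppressWarnings(as.vector(cor(M, lai, use = "pairwise.complete.obs")))
    nok <- colSums(!is.na(M) & !is.na(lai))
    r[nok < 3] <- NA_real_
    feats <- unique(vapply(strsplit(colnames(M), ":", fixed = TRUE), `[[`, "", 1))
    p <- length(feats)
    cm <- matrix(r, p, p, byrow = TRUE, dimnames = list(t1 = feats, t2 = feats))
    best <- if (all(is.na(cm))) NULL else {
      ij <- which(abs(cm) == max(abs(cm), na.rm = TRUE), arr.ind = TRUE)
      ij <- ij[order(rownames(cm)[ij[, 1]], colnames(cm)[ij[, 2]]), , drop = FALSE]
      list(t1 = rownames(cm)[ij[1, 1]], t2 = colnames(cm)[ij[1, 2]],
           r = cm[ij[1, 1], ij[1, 2]])
    }
    attr(cm, "best") <- best
    cm
  })
}

#' Select the strongest texture index per kind
#'
#' Per index kind, returns the `k_per_kind` ordered pairs with maximal
#' absolute correlation with LAI; ties are broken lexicographically by
#' `(t1, t2)`.
#'
#' @param correlation_matrices Output of [index_lai_correlation()].
#' @param k_per_kind Pairs to keep per kind.
#' @return Data.frame with columns `kind`, `t1`, `t2`, `r`, and a `name`
#'   column `kind(t1,t2)` usable as a feature column id.
#' @export
select_best_indices <- function(correlation_matrices, k_per_kind = 1L) {
  if (length(correlation_matrices) == 0L) abort_argument("no correlation matrices supplied")
  rows <- lapply(names(correlation_matrices), function(kind) {
    cm <- correlation_matrices[[kind]]
    if (all(is.na(cm))) abort_argument(sprintf("correlation matrix for %s is all-missing", kind))
    df <- data.frame(kind = kind,
                     t1 = rep(rownames(cm), each = ncol(cm)),
                     t2 = rep(colnames(cm), times = nrow(cm)),
                     r = as.vector(t(cm)),
                     stringsAsFactors = FALSE)
    df <- df[!is.na(df$r), ]
    df <- df[order(-abs(df$r), df$t1, df$t2), ]
    head(df, k_per_kind)
  })
  out <- do.call(rbind, rows)
  out$name <- sprintf("%s(%s,%s)", out$kind, out$t1, out$t2)
  rownames(out) <- NULL
  out
}

#' Append selected texture index columns to a feature table
#'
#' @param feature_table Data.frame with the texture feature columns.
#' @param selected Data.frame from [select_best_indices()].
#' @return The table with one added column per selected index, named
#'   `kind(t1,t2)`.
#' @export
append_texture_indices <- function(feature_table, selected) {
  for (i in seq_len(nrow(selected))) {
    t1 <- feature_table[[selected$t1[i]]]
    t2 <- feature_table[[selected$t2[i]]]
    if (is.null(t1) || is.null(t2)) {
      laitex_error(sprintf("texture feature column missing for index %s", selected$name[i]),
                   "laitex_key_error")
    }
    feature_table[[selected$name[i]]] <- .texture_index_na(selected$kind[i], t1, t2)
  }
  feature_table
}
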