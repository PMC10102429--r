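# Independent brute-force oracles, deliberately written from first
# principles (naive loops, no shared code with the package internals).

# Naive co-occurrence probability matrix of a quantized window at one
# offset: enumerate every pixel pair explicitly.
oracle_glcm <- function(win, offset, levels, symmetric = TRUE) {
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(win))) {
    for (c in seq_len(ncol(win))) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 >= 1 && r2 <= nrow(win) && c2 >= 1 && c2 <= ncol(win)) {
        i <- win[r, c] + 1L; j <- win[r2, c2] + 1L
        P[i, j] <- P[i, j] + 1
        if (symmetric) P[j, i] <- P[j, i] + 1
      }
    }
  }
  if (sum(P) == 0) return(NULL)
  P / sum(P)
}

# The eight statistics from the definitions, computed with explicit sums.
oracle_stats <- function(P) {
  L <- nrow(P)
  s <- c(mean = 0, var = 0, hom = 0, con = 0, dis = 0, ent = 0, sm = 0, cor = 0)
  mu_i <- 0; mu_j <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    mu_i <- mu_i + i * P[i + 1, j + 1]
    mu_j <- mu_j + j * P[i + 1, j + 1]
  }
  v_i <- 0; v_j <- 0; cov <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    p <- P[i + 1, j + 1]
    v_i <- v_i + (i - mu_i)^2 * p
    v_j <- v_j + (j - mu_j)^2 * p
    cov <- cov + (i - mu_i) * (j - mu_j) * p
    s["hom"] <- s["hom"] + p / (1 + (i - j)^2)
    s["con"] <- s["con"] + (i - j)^2 * p
    s["dis"] <- s["dis"] + abs(i - j) * p
    if (p > 0) s["ent"] <- s["ent"] - p * log(p)
    s["sm"] <- s["sm"] + p^2
  }
  s["mean"] <- mu_i
  s["var"] <- v_i
  s["cor"] <- if (v_i <= 1e-12 || v_j <= 1e-12) 0 else cov / sqrt(v_i * v_j)
  s
}

# Offset-averaged window statistics: average the per-offset normalized
# GLCMs, then the statistics.
oracle_window_stats <- function(win, offsets, levels, symmetric = TRUE) {
  Ps <- list()
  for (o in seq_len(nrow(offsets))) {
    P <- oracle_glcm(win, offsets[o, ], levels, symmetric)
    if (!is.null(P)) Ps[[length(Ps) + 1L]] <- P
  }
  oracle_stats(Reduce(`+`, Ps) / length(Ps))
}

# Full texture-map oracle on a small raster (interior pixels only).
oracle_texture_maps <- function(raster, levels, window, offsets, symmetric = TRUE) {
  q <- quantize(raster, levels)
  h <- window %/% 2
  nr <- nrow(q); nc <- ncol(q)
  maps <- lapply(1:8, function(i) matrix(NA_real_, nr, nc))
  names(maps) <- c("mean", "var", "hom", "con", "dis", "ent", "sm", "cor")
  for (r in (h + 1):(nr - h)) {
    for (c in (h + 1):(nc - h)) {
      win <- q[(r - h):(r + h), (c - h):(c + h)]
      s <- oracle_window_stats(win, offsets, levels, symmetric)
      for (nm in names(maps)) maps[[nm]][r, c] <- s[[nm]]
    }
  }
  maps
}

default_offsets <- function() rbind(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
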