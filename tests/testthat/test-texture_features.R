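test_that("quantize maps min-max linearly onto 0..L-1", {
  expect_true(all(quantize(matrix(0.4, 5, 5), 64) == 0))
  expect_equal(as.vector(quantize(matrix(c(0, 1, 0, 1), 2), 2)), c(0L, 1L, 0L, 1L))
  set.seed(9)
  x <- matrix(runif(100), 10)
  q <- quantize(x, 8)
  expect_true(all(q >= 0 & q <= 7))
  expect_equal(q[which.max(x)], 7L)
  expect_equal(q[which.min(x)], 0L)
  # order preservation (non-strict): sorting values sorts levels
  o <- order(x)
  expect_true(all(diff(q[o]) >= 0))
  expect_error(quantize(matrix(NA_real_, 3, 3), 8), class = "laitex_argument_error")
})

test_that("glcm counts pairs and normalizes as the brute-force oracle", {
  # constant window: single entry
  P <- glcm(matrix(0L, 3, 3), c(0, 1), levels = 4)
  expect_equal(sum(P), 1)
  expect_equal(P[1, 1], 1)
  # two-level checkerboard, horizontal offset, symmetric
  cb <- outer(0:3, 0:3, function(i, j) (i + j) %% 2L)
  P <- glcm(cb, c(0, 1), levels = 2, symmetric = TRUE)
  expect_equal(unclass(P), matrix(c(0, 0.5, 0.5, 0), 2), ignore_attr = TRUE)
  # random rasters: match oracle, symmetric
  set.seed(11)
  for (i in 1:10) {
    w <- matrix(sample(0:5, 36, replace = TRUE), 6)
    off <- rbind(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))[sample(4, 1), ]
    P <- glcm(w, off, levels = 6, symmetric = TRUE)
    expect_equal(unclass(P), oracle_glcm(w, off, 6, TRUE), ignore_attr = TRUE)
    expect_equal(unclass(P), t(unclass(P)))
    expect_equal(sum(P), 1, tolerance = 1e-12)
  }
  expect_error(glcm(matrix(0L, 1, 1), c(0, 1), 2), class = "laitex_domain_error")
})

test_that("haralick_stats matches closed forms", {
  # degenerate single-entry GLCM
  P1 <- matrix(0, 4, 4); P1[1, 1] <- 1
  s <- haralick_stats(P1)
  expect_equal(unname(s[c("con", "dis", "var", "ent")]), c(0, 0, 0, 0))
  expect_equal(unname(s[c("hom", "sm")]), c(1, 1))
  expect_equal(unname(s["cor"]), 0)  # zero marginal variance convention
  # checkerboard GLCM
  s <- haralick_stats(matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(unname(s["mean"]), 0.5)
  expect_equal(unname(s["var"]), 0.25)
  expect_equal(unname(s["con"]), 1)
  expect_equal(unname(s["dis"]), 1)
  expect_equal(unname(s["hom"]), 0.5)
  expect_equal(unname(s["ent"]), log(2))
  expect_equal(unname(s["sm"]), 0.5)
  expect_equal(unname(s["cor"]), -1)
  # uniform GLCM closed forms
  for (L in c(2, 4, 8)) {
    s <- haralick_stats(matrix(1 / L^2, L, L))
    expect_equal(unname(s["sm"]), 1 / L^2)
    expect_equal(unname(s["ent"]), 2 * log(L))
  }
})

test_that("haralick statistics respect their bounds on random GLCMs", {
  set.seed(21)
  for (i in 1:50) {
    L <- sample(2:8, 1)
    C <- matrix(rexp(L^2), L)
    C <- C + t(C)
    s <- haralick_stats(C / sum(C))
    expect_true(s["hom"] > 0 && s["hom"] <= 1)
    expect_true(s["sm"] > 0 && s["sm"] <= 1)
    expect_gte(unname(s["ent"]), 0)
    expect_gte(unname(s["con"]), 0)
    expect_true(abs(s["cor"]) <= 1 + 1e-12)
  }
})

test_that("windowed texture maps equal per-window brute force exactly", {
  set.seed(31)
  x <- matrix(runif(144), 12, 12)
  cfg <- glcm_config(levels = 8, window = 3)
  maps <- texture_maps(x, cfg)
  oracle <- oracle_texture_maps(x, 8, 3, default_offsets())
  for (nm in names(oracle)) {
    expect_equal(maps[[nm]], oracle[[nm]], tolerance = 1e-12)
  }
  # border pixels are NA
  expect_true(all(is.na(maps$con[1, ])))
  expect_true(all(is.na(maps$con[, 12])))
})

test_that("texture maps handle constant rasters and window asymmetries", {
  cfg <- glcm_config(levels = 16, window = 3)
  maps <- texture_maps(matrix(0.7, 10, 10), cfg)
  interior <- maps$con[2:9, 2:9]
  expect_true(all(interior == 0))
  expect_equal(maps$hom[2:9, 2:9], matrix(1, 8, 8), tolerance = 1e-12)
  # contrast is zero iff the quantized window is constant
  x <- matrix(0, 10, 10); x[5, 5] <- 1
  maps <- texture_maps(x, cfg)
  expect_gt(maps$con[5, 5], 0)
  expect_equal(unname(maps$con[2, 2]), 0)
  expect_error(texture_maps(matrix(0, 2, 2), cfg), class = "laitex_argument_error")
})

test_that("a larger window smooths the contrast map", {
  set.seed(41)
  ratio <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(runif(400), 20, 20)
    v3 <- var(as.vector(texture_maps(x, glcm_config(levels = 8, window = 3))$con),
              na.rm = TRUE)
    v7 <- var(as.vector(texture_maps(x, glcm_config(levels = 8, window = 7))$con),
              na.rm = TRUE)
    v7 / v3
  }, numeric(1))
  expect_true(all(ratio < 1))
})

test_that("roi_texture_means yields 8 stats x bands with masked-mean values", {
  set.seed(51)
  cfg <- glcm_config(levels = 8, window = 3)
  maps <- list(`650` = texture_maps(matrix(runif(196), 14, 14), cfg),
               `705` = texture_maps(matrix(runif(196), 14, 14), cfg),
               `842` = texture_maps(matrix(0.5, 14, 14), cfg))
  roi <- roi_rect("p1", 3, 10, 3, 10)
  v <- roi_texture_means(maps, roi)
  expect_length(v, 24)
  expect_named(v, texture_feature_names(), ignore.order = TRUE)
  expect_equal(unname(v["con_842"]), 0)
  # brute-force masked mean
  mask <- matrix(FALSE, 14, 14); mask[4:10, 4:10] <- TRUE
  expect_equal(unname(v["ent_650"]),
               mean(maps$`650`$ent[mask], na.rm = TRUE), tolerance = 1e-12)
  # ROI covering only border pixels errors
  expect_error(roi_texture_means(maps, roi_rect("p2", 0, 1, 0, 14)),
               class = "laitex_empty_roi_error")
})

test_that("glcm_config validates its fields", {
  expect_error(glcm_config(levels = 1), class = "laitex_argument_error")
  expect_error(glcm_config(window = 4), class = "laitex_argument_error")
  expect_error(glcm_config(offsets = rbind(c(0, 0))), class = "laitex_argument_error")
})
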