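test_that("tenfold_split partitions with balanced fold sizes", {
  f <- tenfold_split(700, seed = 1)
  expect_length(f, 700)
  expect_true(all(table(f) == 70))           # 630 train / 70 validation
  f2 <- tenfold_split(703, seed = 2)
  expect_true(all(table(f2) %in% c(70, 71)))
  expect_identical(tenfold_split(50, seed = 3), tenfold_split(50, seed = 3))
  f3 <- tenfold_split(10, seed = 4)
  expect_true(all(table(f3) == 1))
  expect_setequal(unique(f3), 1:10)
  expect_error(tenfold_split(9, seed = 1), class = "laitex_argument_error")
})

test_that("standardize_features uses training parameters only", {
  set.seed(131)
  X <- matrix(rnorm(60, 5, 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  sc <- standardize_features(X)
  expect_equal(unname(colMeans(sc$train)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(sc$train, 2, sd)), c(1, 1, 1), tolerance = 1e-12)
  shifted <- X + 10
  sc2 <- standardize_features(X, shifted)
  expect_equal(unname(colMeans(sc2$apply)), unname(10 / sc2$scale), tolerance = 1e-10)
  # round trip
  back <- sweep(sweep(sc$train, 2, sc$scale, `*`), 2, sc$center, `+`)
  expect_equal(unclass(back), unclass(X), ignore_attr = TRUE, tolerance = 1e-12)
  X[, 2] <- 7
  err <- tryCatch(standardize_features(X), condition = identity)
  expect_s3_class(err, "laitex_argument_error")
  expect_match(conditionMessage(err), "b")
})

test_that("metrics reproduce their identities and hand values", {
  y <- c(1, 2, 3, 4)
  m <- metrics(y, y)
  expect_equal(unname(m["R2"]), 1)
  expect_equal(unname(m["RMSE"]), 0)
  expect_true(is.infinite(m["RPD"]))
  # constant mean predictor: R2 = 0, RPD = 1 under population sd
  m <- metrics(y, rep(mean(y), 4))
  expect_equal(unname(m["R2"]), 0)
  expect_equal(unname(m["RPD"]), 1)
  # hand computation
  m <- metrics(y, c(1.1, 1.9, 3.2, 3.8))
  expect_equal(unname(m["RMSE"]), sqrt(0.1 / 4), tolerance = 1e-12)
  expect_equal(unname(m["RMSE"]), 0.1581139, tolerance = 1e-6)
  expect_equal(unname(m["RPD"]), sqrt(1.25) / sqrt(0.025), tolerance = 1e-12)
  expect_equal(unname(m["RPD"]), 7.071068, tolerance = 1e-6)
  expect_equal(unname(m["RPD"]), unname(sqrt(mean((y - mean(y))^2)) / m["RMSE"]))
  # order invariance
  set.seed(141)
  yy <- runif(30); pp <- yy + rnorm(30, 0, 0.1)
  o <- sample(30)
  expect_equal(metrics(yy, pp), metrics(yy[o], pp[o]))
  expect_error(metrics(rep(1, 5), rnorm(5)), class = "laitex_domain_error")
})

test_that("PLSR recovers a perfectly linear response", {
  set.seed(151)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- 2 + 1.5 * X[, 1] + 6
  y <- y - min(y) + 0.1                      # keep LAI-like non-negative
  folds <- tenfold_split(n, seed = 5)
  res <- fit_predict(model_spec("PLSR", seed = 1), X, y, folds)
  expect_equal(unname(res$summary["val_R2"]), 1, tolerance = 1e-6)
  expect_lt(res$summary[["val_RMSE"]], 1e-6)
  # out-of-fold predictions cover every sample exactly once
  expect_equal(sum(!is.na(res$predictions$yhat)), n)
})

test_that("cross-validation results are deterministic given seeds", {
  set.seed(161)
  n <- 80
  X <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- X[, 1] * 3 + rnorm(n, 0, 0.2) + 2
  folds <- tenfold_split(n, seed = 9)
  for (fam in c("SVM", "RF", "BPNN", "PLSR")) {
    r1 <- fit_predict(model_spec(fam, seed = 77), X, y, folds)
    r2 <- fit_predict(model_spec(fam, seed = 77), X, y, folds)
    expect_identical(r1$fold_metrics, r2$fold_metrics)
  }
})

test_that("permuted responses give near-zero validation R2 (no leakage)", {
  set.seed(171)
  n <- 150
  X <- matrix(runif(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  r2s <- vapply(1:5, function(s) {
    y <- sample(runif(n, 0.5, 6.5))
    folds <- tenfold_split(n, seed = s)
    res <- fit_predict(model_spec("PLSR", seed = s), X, y, folds)
    res$summary[["val_R2"]]
  }, numeric(1))
  expect_lt(abs(mean(r2s)), 0.15)
})

test_that("stochastic families require a seed; rows with NA are dropped", {
  expect_error(model_spec("RF"), class = "laitex_argument_error")
  expect_error(model_spec("BPNN"), class = "laitex_argument_error")
  set.seed(181)
  n <- 60
  X <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- X[, 1] + 1
  X[3, 2] <- NA
  folds <- tenfold_split(n, seed = 1)
  expect_message(res <- fit_predict(model_spec("PLSR", seed = 1), X, y, folds),
                 "dropping 1")
  expect_equal(nrow(res$predictions), n - 1)
})

test_that("run_experiment produces the full comparison layout", {
  feats <- small_default_features()
  sets <- list(VIs = c("NDVI", "RVI", "OSAVI"),
               TIs = c("mean_705", "ent_705"),
               `VIs+TIs` = c("NDVI", "RVI", "OSAVI", "mean_705", "ent_705"))
  exp1 <- run_experiment(feats, sets, families = c("SVM", "PLSR"), seed = 4)
  expect_s3_class(exp1, "lai_experiment")
  expect_equal(nrow(exp1$results), 2 * 3 * 2)
  expect_true(all(exp1$results$RMSE >= 0))
  expect_true(all(exp1$results$RPD > 0))
  # identical seed -> identical table
  exp2 <- run_experiment(feats, sets, families = c("SVM", "PLSR"), seed = 4)
  expect_identical(exp1$results, exp2$results)
  # predictions long table: one block per model
  preds <- experiment_predictions(exp1)
  expect_equal(nrow(preds), 2 * 3 * nrow(feats))
  expect_error(run_experiment(feats, list(VIs = character()), seed = 1),
               class = "laitex_argument_error")
})

test_that("noise-free canopies are recovered by every family", {
  feats <- noise_free_features()
  sets <- list(VIs = intersect(vi_registry()$name, names(feats)))
  res <- run_experiment(feats, sets, seed = 13)
  val <- res$results[res$results$split == "Val", ]
  for (fam in c("SVM", "RF", "BPNN", "PLSR")) {
    expect_gt(val$R2[val$family == fam], 0.95)
  }
})
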