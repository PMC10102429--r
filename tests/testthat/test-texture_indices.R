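test_that("texture index identities and sign symmetry hold", {
  expect_equal(texture_index("DTI", 0.7, 0.7), 0)
  expect_equal(texture_index("RTI", 0.7, 0.7), 1)
  expect_equal(texture_index("NDTI", 0.7, 0.7), 0)
  expect_equal(texture_index("NDTI", 3, 1), 0.5)
  expect_equal(texture_index("NDTI", 1, 3), -0.5)
  expect_error(texture_index("NDTI", 1, -1), class = "laitex_domain_error")
  expect_error(texture_index("RTI", 1, 0), class = "laitex_domain_error")
})

test_that("index algebra holds over randomized pairs", {
  set.seed(61)
  t1 <- runif(1000, 0.01, 10)
  t2 <- runif(1000, 0.01, 10)
  expect_equal(texture_index("RTI", t1, t2) * texture_index("RTI", t2, t1),
               rep(1, 1000), tolerance = 1e-12)
  nd <- texture_index("NDTI", t1, t2)
  expect_true(all(nd >= -1 & nd <= 1))
  expect_equal(nd, -texture_index("NDTI", t2, t1), tolerance = 1e-12)
  expect_equal(texture_index("DTI", t1, t1), rep(0, 1000))
})

fake_texture_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  cols <- texture_feature_names()
  tab <- as.data.frame(setNames(lapply(cols, function(x) runif(n, 0.1, 2)), cols))
  tab
}

test_that("traverse_pairs spans all 576 ordered pairs per kind", {
  tab <- fake_texture_table()
  out <- traverse_pairs(tab)
  expect_named(out, c("NDTI", "RTI", "DTI"))
  for (k in names(out)) expect_equal(ncol(out[[k]]), 24^2)
  # diagonal DTI columns are identically zero
  diag_cols <- paste(texture_feature_names(), texture_feature_names(), sep = ":")
  expect_true(all(out$DTI[, diag_cols] == 0))
  # NDTI is antisymmetric under pair transposition
  expect_equal(out$NDTI[, "mean_650:ent_705"], -out$NDTI[, "ent_705:mean_650"],
               tolerance = 1e-12)
  expect_error(traverse_pairs(tab[, -1]), class = "laitex_key_error")
})

test_that("zero denominators become missing values, not crashes", {
  tab <- fake_texture_table()
  tab$mean_650[3] <- -tab$ent_705[3]  # NDTI denominator 0
  tab$con_842[5] <- 0                 # RTI denominator 0
  out <- traverse_pairs(tab)
  expect_true(is.na(out$NDTI[3, "mean_650:ent_705"]))
  expect_true(is.na(out$RTI[5, "mean_650:con_842"]))
  expect_false(anyNA(out$DTI))
})

test_that("planted proportional signals are recovered exactly", {
  n <- 120
  set.seed(71)
  lai <- runif(n, 0.5, 6.5)
  tab <- fake_texture_table(n, seed = 72)
  # make NDTI(mean_705, ent_705) = 0.1 * lai by construction
  a <- 0.1 * lai
  tab$ent_705 <- runif(n, 0.5, 1.5)
  tab$mean_705 <- tab$ent_705 * (1 + a) / (1 - a)
  idx <- traverse_pairs(tab)
  cors <- index_lai_correlation(idx, lai)
  expect_equal(cors$NDTI["mean_705", "ent_705"], 1, tolerance = 1e-9)
  best <- select_best_indices(cors["NDTI"])
  # NDTI always ties with its pair-transpose (r vs -r); the lexicographic
  # tie-break picks one ordering of the planted pair deterministically
  expect_setequal(c(best$t1, best$t2), c("mean_705", "ent_705"))
  expect_equal(abs(best$r), 1, tolerance = 1e-9)
  expect_identical(best$t1, "ent_705")  # tie-break contract
})

test_that("shuffled LAI yields only weak correlations", {
  tab <- fake_texture_table(200, seed = 81)
  set.seed(82)
  lai <- sample(runif(200, 0.5, 6.5))
  cors <- index_lai_correlation(traverse_pairs(tab), lai)
  expect_lt(max(abs(cors$NDTI), na.rm = TRUE), 0.35)
})

test_that("constant index columns yield missing cells", {
  tab <- fake_texture_table(30, seed = 91)
  tab$mean_650 <- 1; tab$ent_650 <- 1
  cors <- index_lai_correlation(traverse_pairs(tab), runif(30, 1, 5))
  expect_true(is.na(cors$DTI["mean_650", "ent_650"]))
  expect_true(is.na(cors$NDTI["mean_650", "mean_650"]))
})

test_that("select_best_indices breaks ties lexicographically and counts k", {
  feats <- texture_feature_names()[1:3]
  cm <- matrix(0.5, 3, 3, dimnames = list(feats, feats))
  out <- select_best_indices(list(NDTI = cm, RTI = cm, DTI = cm), k_per_kind = 1)
  expect_equal(nrow(out), 3)
  expect_true(all(out$t1 == sort(feats)[1]))
  expect_true(all(out$t2 == sort(feats)[1]))
  out2 <- select_best_indices(list(NDTI = cm, RTI = cm, DTI = cm), k_per_kind = 2)
  expect_equal(nrow(out2), 6)
})

test_that("the top pair by |Spearman| is invariant to monotone LAI transforms", {
  feats <- small_default_features()
  tex <- texture_feature_names()
  idx <- traverse_pairs(feats, kinds = "NDTI", features = tex)
  sp_best <- function(lai) {
    r <- suppressWarnings(cor(idx$NDTI, lai, method = "spearman",
                              use = "pairwise.complete.obs"))
    colnames(idx$NDTI)[which.max(abs(r))]
  }
  base <- sp_best(feats$lai)
  expect_identical(sp_best(exp(feats$lai)), base)
  expect_identical(sp_best(feats$lai^3), base)
})

test_that("append_texture_indices adds named index columns", {
  tab <- fake_texture_table(20, seed = 5)
  sel <- data.frame(kind = c("RTI", "DTI"), t1 = c("mean_705", "mean_705"),
                    t2 = c("ent_705", "con_705"), r = c(0.9, 0.8),
                    name = c("RTI(mean_705,ent_705)", "DTI(mean_705,con_705)"))
  out <- append_texture_indices(tab, sel)
  expect_equal(out[["RTI(mean_705,ent_705)"]], tab$mean_705 / tab$ent_705)
  expect_equal(out[["DTI(mean_705,con_705)"]], tab$mean_705 - tab$con_705)
})
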