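separableTable <- function(n = 30, seed = 1) {
  set.seed(seed)
  lab <- rep(c("dba", "neutral"), each = n)
  shift <- ifelse(lab == "dba", 5, 0)
  data.frame(f1 = rnorm(2 * n) + shift, f2 = rnorm(2 * n) + shift,
             f3 = rnorm(2 * n), label = lab)
}

test_that("cross-validation is deterministic and perfect on separable data", {
  tab <- separableTable()
  cv1 <- crossValidate(tab, c("f1", "f2"), C = 1, gamma = 0.5, seed = 4)
  cv2 <- crossValidate(tab, c("f1", "f2"), C = 1, gamma = 0.5, seed = 4)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$cv_mcc, cv2$cv_mcc)
  expect_equal(cv1$cv_mcc, 1.0)
  # different seed reshuffles folds
  cv3 <- crossValidate(tab, c("f1", "f2"), C = 1, gamma = 0.5, seed = 5)
  expect_false(identical(cv1$fold, cv3$fold))
})

test_that("folds are stratified and class absence errors", {
  tab <- separableTable(n = 13)
  fold <- makeStratifiedFolds(tab$label, k = 5, seed = 2)
  for (f in 1:5) {
    expect_gte(sum(fold == f & tab$label == "dba"), 2)
    expect_gte(sum(fold == f & tab$label == "neutral"), 2)
  }
  tabOne <- tab
  tabOne$label <- "dba"
  expect_error(crossValidate(tabOne, "f1", 1, 0.1), "class")
})

test_that("permuted labels drive the cross-validated MCC toward zero", {
  tab <- separableTable(n = 30)
  for (s in 1:3) {
    permuted <- tab
    set.seed(100 + s)
    permuted$label <- sample(permuted$label)
    cv <- crossValidate(permuted, c("f1", "f2", "f3"), C = 1,
                        gamma = 0.1, seed = s)
    expect_lt(abs(cv$cv_mcc), 0.35)
  }
})

test_that("cross-validation does not leak resubstitution performance", {
  # pure-noise features: honest CV stays near 0 while the leaked
  # train-equals-test evaluation can reach a high MCC
  set.seed(77)
  noise <- data.frame(matrix(rnorm(60 * 4), 60, 4))
  names(noise) <- paste0("f", 1:4)
  noise$label <- rep(c("dba", "neutral"), each = 30)
  cv <- crossValidate(noise, paste0("f", 1:4), C = 100, gamma = 1,
                      seed = 3)
  x <- scale(as.matrix(noise[, 1:4]))
  leakFit <- e1071::svm(x, factor(noise$label), kernel = "radial",
                        cost = 100, gamma = 1, scale = FALSE)
  pred <- predict(leakFit, x)
  leakMcc <- confusionMetrics(
    sum(pred == "dba" & noise$label == "dba"),
    sum(pred == "dba" & noise$label == "neutral"),
    sum(pred == "neutral" & noise$label == "neutral"),
    sum(pred == "neutral" & noise$label == "dba"))$mcc
  expect_lt(abs(cv$cv_mcc), 0.4)
  expect_gt(leakMcc, 0.9)
  expect_gt(leakMcc - cv$cv_mcc, 0.5)
})

test_that("exhaustive selection honours subset size, budget and tie rules", {
  tab <- separableTable()
  # min_features = all candidates: a single combination
  cfg <- trainingConfig(c("f1", "f2", "f3"), min_features = 3,
                        c_grid = c(0.1, 1), gamma_grid = c(0.1, 1),
                        seed = 2)
  sel <- selectFeaturesAndHyperparams(tab, cfg)
  expect_equal(sel$n_evaluated, 4)
  expect_setequal(sel$features, c("f1", "f2", "f3"))
  # equal-MCC optima resolve to fewer features, then smaller C and gamma
  cfg2 <- trainingConfig(c("f1", "f2", "f3"), min_features = 2,
                         c_grid = c(0.1, 1, 10),
                         gamma_grid = c(0.1, 1), seed = 2)
  sel2 <- selectFeaturesAndHyperparams(tab, cfg2)
  expect_length(sel2$features, 2)
  # budget gate
  cfgBig <- trainingConfig(names(tab)[1:3], min_features = 2,
                           budget = 10)
  expect_error(selectFeaturesAndHyperparams(tab, cfgBig), "budget")
})

test_that("the final model calibrates scores into [0, 1] monotonically", {
  tab <- separableTable()
  fit <- trainFinal(tab, c("f1", "f2"), C = 1, gamma = 0.5)
  sc <- predictScore(fit, tab)
  expect_true(all(sc >= 0 & sc <= 1))
  # separable fit: no training errors at the 0.5 threshold
  expect_equal(unname(sc > 0.5), tab$label == "dba")
  # points at the class centres sit near the score extremes
  deep <- data.frame(f1 = c(5, 0), f2 = c(5, 0))
  dsc <- predictScore(fit, deep)
  expect_gt(dsc[1], 0.9)
  expect_lt(dsc[2], 0.1)
  # serialisation round-trip preserves scores exactly
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(fit, path)
  expect_identical(predictScore(readRDS(path), tab), sc)
})

test_that("the saturation scan covers length x 19 cells in [0, 1]", {
  tab <- separableTable()
  fit <- trainFinal(tab, c("f1", "f2"), C = 1, gamma = 0.5)
  fz <- function(p, wt, mut) {
    c(f1 = as.numeric(mut == "P") * 4, f2 = as.numeric(mut == "P") * 4)
  }
  scan <- saturationScan(fit, fz, "MKLVAGHTWD")
  expect_equal(dim(scan), c(10, 20))
  expect_equal(sum(!is.na(scan)), 190)
  expect_true(all(scan >= 0 & scan <= 1, na.rm = TRUE))
  # wild-type cells absent
  for (p in 1:10) expect_true(is.na(scan[p, substr("MKLVAGHTWD", p, p)]))
  # the planted proline-deleterious model scores Pro columns highest
  proScores <- scan[, "P"]
  otherMax <- apply(scan[, colnames(scan) != "P"], 1, max, na.rm = TRUE)
  expect_true(all(proScores > otherMax, na.rm = TRUE))
})

test_that("the full protocol is reproducible from table, config and seed", {
  tab <- makeFeatureTable(nPositive = 20, nNegative = 20, seed = 9)
  cfg <- trainingConfig(c("ddg", "rsasa", "conservation", "d_helix"),
                        min_features = 3, c_grid = c(0.1, 1),
                        gamma_grid = c(0.1, 1), seed = 6)
  s1 <- selectFeaturesAndHyperparams(tab, cfg)
  s2 <- selectFeaturesAndHyperparams(tab, cfg)
  expect_identical(s1, s2)
})
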