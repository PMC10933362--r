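test_that("regression learns a deterministic target and reports sane metrics", {
  set.seed(801)
  x <- cbind(x1 = runif(600, 0, 10))
  fm <- make_fm(x, 5 * x[, 1])
  rep_ <- evaluate_regression(fm, model_config(seed = 802, repeats = 5))
  expect_gt(rep_$r2, 0.99)
  expect_true(all(rep_$per_repeat$rmse >= rep_$per_repeat$mae))
  expect_true(all(rep_$per_repeat$r2 <= 1))
  expect_equal(nrow(rep_$per_repeat), 5)

  # bit-identical under the same seed
  rep2 <- evaluate_regression(fm, model_config(seed = 802, repeats = 5))
  expect_identical(rep_$per_repeat, rep2$per_repeat)
  expect_identical(rep_$predictions, rep2$predictions)
})

test_that("gradient boosting is available behind the same protocol", {
  set.seed(805)
  x <- cbind(a = runif(300), b = runif(300))
  fm <- make_fm(x, 10 * x[, 1] - 4 * x[, 2] + rnorm(300, 0, 0.05))
  rep_ <- evaluate_regression(fm, model_config("gradient_boosting",
                                               seed = 806, repeats = 3))
  expect_gt(rep_$r2, 0.95)
})

test_that("a permuted target yields no explanatory power", {
  set.seed(803)
  x <- matrix(rnorm(500 * 5), 500, dimnames = list(NULL, paste0("f", 1:5)))
  fm <- make_fm(x, rnorm(500))
  rep_ <- evaluate_regression(fm, model_config(seed = 804, repeats = 10,
                                               trees_per_bag = 100))
  expect_lt(abs(rep_$r2), 0.1)
})

test_that("classification handles separable data and degenerate labels", {
  set.seed(810)
  n <- 200
  y <- c(runif(n / 2, 55000, 70000), runif(n / 2, 20000, 45000))
  x <- cbind(marker = c(rnorm(n / 2, 3, 0.2), rnorm(n / 2, -3, 0.2)))
  fm <- make_fm(x, y)
  cl <- suppressWarnings(classify_balance(fm, model_config(seed = 811,
                                                           repeats = 30)))
  expect_equal(cl$auc, 1)
  expect_equal(cl$ca, 1)
  expect_true(all(cl$quadrant %in% c("TN", "TP")))

  # quadrant bookkeeping partitions the specimens
  tab <- table(factor(cl$quadrant, levels = c("TN", "FN", "FP", "TP")))
  expect_equal(sum(tab), n)
  expect_setequal(which(cl$quadrant %in% c("TN", "FP")), which(cl$actual_high))

  expect_error(classify_balance(fm, model_config(seed = 1, yield_cutoff = 5)),
               "degenerate labels")
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(812)
  n <- 500
  x <- cbind(m = rnorm(n), m2 = rnorm(n))
  y <- sample(c(runif(n / 2, 55000, 70000), runif(n / 2, 30000, 45000)))
  cl <- classify_balance(make_fm(x, y), model_config(seed = 813, repeats = 15))
  expect_lt(abs(cl$auc - 0.5), 0.05)
})

test_that("out-of-fold predictions never come from a training fold", {
  obs <- small_trials()$observations
  fm <- assemble_features(obs)
  rep_ <- evaluate_regression(fm, model_config(seed = 820, repeats = 8))
  for (r in seq_along(rep_$splits)) {
    test_rows <- rep_$predictions$row[rep_$predictions$repeat_ == r]
    expect_length(intersect(test_rows, rep_$splits[[r]]), 0)
    expect_setequal(c(test_rows, rep_$splits[[r]]), seq_len(nrow(fm$x)))
  }
  fmc <- select_features(fm, c("cultivar",
                               grep("^tissue_", colnames(fm$x), value = TRUE)))
  cl <- suppressWarnings(classify_balance(fmc, model_config(seed = 821,
                                                            repeats = 8)))
  for (r in seq_along(cl$splits))
    expect_length(intersect(cl$splits[[r]],
                            setdiff(seq_len(nrow(fmc$x)), cl$splits[[r]])), 0)
})

test_that("true-negative selection returns the TN subset", {
  obs <- small_trials()$observations
  fm <- assemble_features(obs)
  fmc <- select_features(fm, c("cultivar",
                               grep("^tissue_", colnames(fm$x), value = TRUE)))
  cl <- suppressWarnings(classify_balance(fmc, model_config(seed = 830,
                                                            repeats = 10)))
  tn <- select_true_negatives(cl, obs)
  expect_equal(nrow(tn), sum(cl$quadrant == "TN"))
  expect_true(all(tn$yield > 50000))
  expect_identical(attr(tn, "rows"), which(cl$quadrant == "TN"))

  # all high and correctly predicted -> everything selected
  cl_all <- cl
  cl_all$quadrant <- rep("TN", nrow(obs))
  expect_equal(nrow(select_true_negatives(cl_all, obs)), nrow(obs))
  # none above cutoff -> empty with warning
  cl_none <- cl
  cl_none$quadrant <- rep("TP", nrow(obs))
  expect_warning(empty <- select_true_negatives(cl_none, obs), "empty selection")
  expect_equal(nrow(empty), 0)
})
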