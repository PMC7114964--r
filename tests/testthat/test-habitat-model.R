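test_that("evaluate_confusion computes row errors and the overall error", {
  cm <- matrix(c(8, 2,
                 1, 9), 2, byrow = TRUE,
               dimnames = list(c("a", "p"), c("a", "p")))
  ev <- evaluate_confusion(cm)
  expect_equal(unname(ev$class_errors), c(2 / 10, 1 / 10))
  expect_equal(ev$overall_error, 3 / 20)
  expect_length(ev$undefined_classes, 0L)
  # empty true class -> NA error, listed as undefined
  cm2 <- matrix(c(5, 1, 0, 0), 2, byrow = TRUE,
                dimnames = list(c("x", "y"), c("x", "y")))
  ev2 <- evaluate_confusion(cm2)
  expect_true(is.na(ev2$class_errors[["y"]]))
  expect_equal(ev2$undefined_classes, "y")
  expect_error(evaluate_confusion(matrix(1, 2, 3)), "square")
  expect_error(evaluate_confusion(matrix(c(1, -1, 0, 2), 2)), "non-negative")
  expect_error(evaluate_confusion(matrix(0, 2, 2)), "all zeros")
})

test_that("evaluate_binary matches the pairwise-concordance AUC oracle", {
  set.seed(21)
  scores <- round(runif(60), 1)          # coarse grid forces ties
  labels <- runif(60) < plogis(4 * (scores - 0.5))
  if (!any(labels)) labels[1] <- TRUE
  if (all(labels)) labels[1] <- FALSE
  ev <- evaluate_binary(scores, labels)
  expect_equal(ev$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  expect_equal(ev$sensitivity, mean(scores[labels] >= 0.5))
  expect_equal(ev$specificity, mean(scores[!labels] < 0.5))
  # perfect separation
  expect_equal(evaluate_binary(c(0.1, 0.2, 0.8, 0.9),
                               c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_error(evaluate_binary(1:3 / 4, c(TRUE, TRUE, TRUE)), "both classes")
  expect_error(evaluate_binary(c(NA, 1), c(TRUE, FALSE)), "NA")
})

test_that("select_predictors collapses collinear groups toward the response", {
  tbl <- synthetic_attribute_table(150, seed = 4)
  set.seed(5)
  tbl$MeanWD <- tbl$MaxWD + rnorm(150, 0, 0.01)     # r^2 > 0.95 with MaxWD
  tbl$Const <- 7
  y <- factor(as.integer(tbl$MaxWD > median(tbl$MaxWD)))
  expect_warning(
    keep <- select_predictors(tbl, y, model_config(),
                              candidates = c("MaxWD", "MeanWD", "Max_Rug",
                                             "Index", "Const")),
    "constant predictor")
  expect_false("Const" %in% keep)
  # of the collinear depth pair, the one explaining the response survives
  expect_true("MaxWD" %in% keep)
  expect_false("MeanWD" %in% keep)
  expect_true(all(c("Max_Rug", "Index") %in% keep))
  # default candidates come from the standard attribute columns
  expect_true(all(select_predictors(tbl, y) %in% model_predictor_columns()))
})

test_that("train_rf is deterministic under a fixed seed", {
  tbl <- synthetic_attribute_table(120, seed = 8)
  y <- factor(as.integer(tbl$Max_Rug > median(tbl$Max_Rug)), levels = 0:1)
  preds <- c("MaxWD", "Max_Rug", "Index", "MaxCurrent")
  cfg <- model_config(n_trees = 100L, seed = 99L)
  f1 <- train_rf(tbl, y, preds, cfg)
  f2 <- train_rf(tbl, y, preds, cfg)
  expect_identical(f1$train_idx, f2$train_idx)
  expect_identical(f1$report$oob_error, f2$report$oob_error)
  expect_identical(f1$report$holdout$auc, f2$report$holdout$auc)
  expect_identical(f1$report$importance, f2$report$importance)
  # the split is stratified and roughly one third
  expect_equal(length(f1$test_idx), 40L, tolerance = 0.05)
  expect_equal(nlevels(droplevels(y[f1$test_idx])), 2L)
  expect_error(train_rf(tbl, factor(rep(1, 120)), preds, cfg), "single class")
  expect_error(train_rf(tbl, y, c("MaxWD", "NoSuch"), cfg), "NoSuch")
})

test_that("predict_map scores every record and validates columns", {
  tbl <- synthetic_attribute_table(90, seed = 2)
  y <- factor(as.integer(tbl$MaxWD > median(tbl$MaxWD)), levels = 0:1)
  fit <- train_rf(tbl, y, c("MaxWD", "Max_Rug", "Index"),
                  model_config(n_trees = 100L, seed = 1L))
  pm <- predict_map(fit, tbl)
  expect_equal(nrow(pm), 90L)
  expect_true(all(pm$presence_prob >= 0 & pm$presence_prob <= 1))
  expect_identical(pm$predicted, pm$presence_prob >= 0.5)
  expect_identical(pm$feature_id, tbl$feature_id)
  expect_error(predict_map(fit, tbl[c("MaxWD", "Max_Rug")]), "Index")
  tbl$MaxWD[3] <- NA
  expect_error(predict_map(fit, tbl), "missing predictor values")
  expect_error(predict_map(list(), tbl), "mound_rf")
})

test_that("response curves profile the vote-fraction scale", {
  tbl <- synthetic_attribute_table(90, seed = 6)
  y <- factor(as.integer(tbl$MaxWD > median(tbl$MaxWD)), levels = 0:1)
  fit <- train_rf(tbl, y, c("MaxWD", "Max_Rug"),
                  model_config(n_trees = 150L, seed = 1L))
  rc <- response_curves(fit, tbl, n_grid = 15L)
  expect_named(rc, c("MaxWD", "Max_Rug"))
  expect_equal(nrow(rc$MaxWD), 15L)
  expect_true(all(rc$MaxWD$partial_prob >= 0 & rc$MaxWD$partial_prob <= 1))
  expect_equal(range(rc$MaxWD$value), range(tbl$MaxWD))
  # the planted rule makes the MaxWD profile rise end-to-end
  expect_gt(rc$MaxWD$partial_prob[15] - rc$MaxWD$partial_prob[1], 0.5)
  expect_error(response_curves(fit, tbl, predictors = "Index"), "not in model")
})

test_that("planted logistic drivers lead the importance ranking", {
  # presence ~ logistic(MaxWD, Max_Rug, Index): those three take the top
  # three importance ranks in >= 80% of seeded runs
  preds <- c("MaxWD", "Max_Rug", "Mean_Rug", "Index", "MBG_Orient",
             "MaxCurrent", "Area", "InitialSlp")
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  hits <- 0L
  for (s in 1:20) {
    t2 <- synthetic_attribute_table(250, seed = 100 + s)
    lin <- 1.5 * zs(t2$MaxWD) + 1.2 * zs(t2$Max_Rug) + 1.2 * zs(t2$Index) -
      0.5 * zs(t2$MaxCurrent)
    set.seed(200 + s)
    yy <- factor(stats::rbinom(nrow(t2), 1, stats::plogis(lin)), levels = 0:1)
    f <- train_rf(t2, yy, preds, model_config(n_trees = 300L, seed = s))
    if (all(c("MaxWD", "Max_Rug", "Index") %in%
            names(f$report$importance)[1:3])) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.8)
})
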