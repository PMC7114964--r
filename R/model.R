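#' Random-forest model configuration
#'
#' Settings for the coral presence / cover-class classifier: forest size and
#' variables per split (defaults 1500 and 6, the published settings), the
#' holdout fraction (one third of the mounds, stratified by class), the
#' predictor-collinearity cutoff (r^2 > 0.95 drops all but one of a
#' correlated group) and the RNG seed that fixes the split and the forest.
#'
#' @param n_trees number of trees (default 1500).
#' @param vars_per_split candidate variables per split (default 6; capped at
#'   the number of predictors at fit time).
#' @param test_fraction fraction held out for validation (default 1/3).
#' @param correlation_cutoff r^2 above which predictors count as collinear.
#' @param seed integer RNG seed.
#' @param target `"presence_absence"` or `"cover_class_5"`.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_trees = 1500L, vars_per_split = 6L,
                         test_fraction = 1 / 3, correlation_cutoff = 0.95,
                         seed = 1L,
                         target = c("presence_absence", "cover_class_5")) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  structure(list(n_trees = as.integer(n_trees),
                 vars_per_split = as.integer(vars_per_split),
                 test_fraction = test_fraction,
                 correlation_cutoff = correlation_cutoff,
                 seed = as.integer(seed), target = match.arg(target)),
            class = "model_config")
}

# the attribute columns offered to the model (description-tool variables used
# in the published models, plus the joined current speed)
model_predictor_columns <- function() {
  c("Area", "Index", "MBG_Width", "MBG_Length", "MBG_W_L", "MBG_Orient",
    "MinWD", "MaxWD", "MeanWD", "ConfCL_WD", "MinVRelief", "MaxVRelief",
    "Min_Rug", "Max_Rug", "Mean_Rug", "Min_BS", "Max_BS", "Mean_BS",
    "InitialSlp", "MaxCurrent")
}

#' Drop collinear predictors
#'
#' Groups predictors whose pairwise squared Pearson correlation exceeds
#' `config$correlation_cutoff` (transitively, via graph components) and keeps
#' from each group only the predictor that explains the most variance against
#' the response (largest R^2 of `predictor ~ class`). Constant predictors are
#' dropped with a warning. This mirrors the published treatment of the four
#' mutually correlated water-depth variables, of which only maximum water
#' depth was retained.
#'
#' @param table data.frame of attribute records.
#' @param response factor (or coercible) response, one element per row.
#' @param config a [model_config()].
#' @param candidates candidate predictor column names; default: the columns of
#'   [model_predictor_columns()] present in `table`, plus nothing else.
#' @return character vector of surviving predictor names.
#' @export
select_predictors <- function(table, response, config = model_config(),
                              candidates = NULL) {
  response <- as.factor(response)
  if (is.null(candidates))
    candidates <- intersect(model_predictor_columns(), names(table))
  candidates <- candidates[vapply(table[candidates], is.numeric, logical(1))]
  keep_nonconst <- vapply(candidates, function(nm) {
    v <- table[[nm]]
    length(unique(v[!is.na(v)])) > 1L
  }, logical(1))
  if (any(!keep_nonconst))
    warning("dropping constant predictor(s): ",
            paste(candidates[!keep_nonconst], collapse = ", "))
  candidates <- candidates[keep_nonconst]
  if (length(candidates) < 2L) return(candidates)
  x <- as.matrix(table[candidates])
  r2 <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))^2
  r2[is.na(r2)] <- 0
  adj <- r2 > config$correlation_cutoff
  # connected components of the collinearity graph
  comp <- rep(NA_integer_, length(candidates))
  cid <- 0L
  for (i in seq_along(candidates)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier)) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  # variance explained against the response, per predictor
  expl <- vapply(candidates, function(nm) {
    v <- table[[nm]]
    ok <- !is.na(v)
    if (length(unique(response[ok])) < 2L) return(0)
    summary(stats::lm(v[ok] ~ response[ok]))$r.squared
  }, numeric(1))
  keep <- vapply(split(seq_along(candidates), comp), function(grp) {
    grp[which.max(expl[grp])]
  }, integer(1))
  candidates[sort(keep)]
}

#' Confusion-matrix error rates
#'
#' Per-class and overall misclassification from a square count matrix with
#' rows = true class and columns = predicted class: each class error is
#' (row sum - diagonal) / row sum and the overall error is
#' (total - trace) / total. Classes with an empty row have an undefined error
#' and are reported as `NA` (and listed in `undefined_classes`).
#'
#' @param confusion square non-negative count matrix.
#' @return list with `class_errors`, `overall_error`, `undefined_classes`.
#' @export
evaluate_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  if (any(confusion < 0) || any(is.na(confusion)))
    stop("confusion matrix must be non-negative counts")
  rs <- rowSums(confusion)
  if (all(rs == 0)) stop("confusion matrix is all zeros")
  ce <- (rs - diag(confusion)) / rs
  ce[rs == 0] <- NA_real_
  tot <- sum(confusion)
  list(class_errors = ce,
       overall_error = (tot - sum(diag(confusion))) / tot,
       undefined_classes = names(ce)[is.na(ce)] %||% which(is.na(ce)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binary classification metrics
#'
#' Sensitivity and specificity at a vote threshold (default 0.5) and the area
#' under the ROC curve computed from the rank statistic (Mann-Whitney; tied
#' scores count one half), so it needs no curve construction.
#'
#' @param scores numeric vector of presence probabilities.
#' @param labels logical, 0/1 or two-level factor; `TRUE`/`1`/second level =
#'   presence. Both classes must occur.
#' @param threshold vote threshold for the point metrics.
#' @return list with `sensitivity`, `specificity`, `auc`.
#' @export
evaluate_binary <- function(scores, labels, threshold = 0.5) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(as.numeric(labels))
  if (any(is.na(labels)) || any(is.na(scores)))
    stop("scores/labels must not contain NA")
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present in `labels`")
  pred <- scores >= threshold
  r <- rank(scores, ties.method = "average")
  list(sensitivity = sum(pred & labels) / npos,
       specificity = sum(!pred & !labels) / nneg,
       auc = (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg))
}

#' Fit the coral presence / cover random forest
#'
#' Splits the records into a stratified training partition (1 -
#' `test_fraction`) and a holdout, fits a random forest with permutation
#' importance, and reports the out-of-bag confusion matrix and error of the
#' training partition plus holdout metrics (sensitivity, specificity and rank
#' AUC for a binary target; confusion and overall error otherwise). Fixing
#' `config$seed` fixes the split, the forest and every reported number.
#'
#' @param table data.frame of attribute records.
#' @param response response vector (factor or coercible), one per row; for
#'   presence/absence use levels ordered absence, presence (e.g. 0/1).
#' @param predictors character vector of predictor columns (e.g. from
#'   [select_predictors()]).
#' @param config a [model_config()].
#' @return an object of class `mound_rf`: list with `model` (the randomForest
#'   fit), `report` (training OOB confusion/class errors/overall error,
#'   holdout metrics, permutation importance), `predictors`, `positive_class`,
#'   `train_idx`, `test_idx`, `config`.
#' @export
train_rf <- function(table, response, predictors, config = model_config()) {
  response <- droplevels(as.factor(response))
  if (nlevels(response) < 2L)
    stop("response has a single class; cannot train a classifier")
  missing_cols <- setdiff(predictors, names(table))
  if (length(missing_cols))
    stop("predictor column(s) not in table: ", paste(missing_cols, collapse = ", "))
  x <- table[predictors]
  ok <- stats::complete.cases(x)
  if (!all(ok)) {
    warning(sprintf("dropping %d record(s) with missing predictors", sum(!ok)))
    x <- x[ok, , drop = FALSE]; response <- droplevels(response[ok])
  }
  n <- nrow(x)
  set.seed(config$seed)
  for (attempt in seq_len(20L)) {
    test_idx <- unlist(lapply(split(seq_len(n), response), function(ix) {
      k <- max(1L, round(length(ix) * config$test_fraction))
      sample(ix, k)
    }), use.names = FALSE)
    train_idx <- setdiff(seq_len(n), test_idx)
    if (nlevels(droplevels(response[train_idx])) == nlevels(response) &&
        nlevels(droplevels(response[test_idx])) == nlevels(response)) break
    warning("a partition lost a class; re-drawing the stratified split")
  }
  mtry <- min(config$vars_per_split, length(predictors))
  fit <- randomForest::randomForest(
    x = x[train_idx, , drop = FALSE], y = response[train_idx],
    ntree = config$n_trees, mtry = mtry, importance = TRUE)
  oob_conf <- fit$confusion[, seq_len(nlevels(response)), drop = FALSE]
  oob <- evaluate_confusion(oob_conf)
  imp <- randomForest::importance(fit, type = 1)[, 1]
  report <- list(oob_confusion = oob_conf,
                 oob_class_errors = oob$class_errors,
                 oob_error = oob$overall_error,
                 importance = sort(imp, decreasing = TRUE))
  positive <- levels(response)[nlevels(response)]
  hold_y <- response[test_idx]
  if (nlevels(response) == 2L) {
    p <- predict(fit, x[test_idx, , drop = FALSE], type = "prob")[, positive]
    report$holdout <- evaluate_binary(p, hold_y == positive)
    report$holdout$n <- length(test_idx)
  } else {
    pred <- predict(fit, x[test_idx, , drop = FALSE])
    conf <- table(true = hold_y, predicted = pred)
    ev <- evaluate_confusion(conf)
    report$holdout <- list(confusion = conf, class_errors = ev$class_errors,
                           overall_error = ev$overall_error, n = length(test_idx))
  }
  structure(list(model = fit, report = report, predictors = predictors,
                 positive_class = positive, train_idx = train_idx,
                 test_idx = test_idx, config = config),
            class = "mound_rf")
}

#' @method print mound_rf
#' @export
print.mound_rf <- function(x, ...) {
  cat(sprintf("<mound_rf> %d trees, mtry %d, %d predictors\n",
              x$model$ntree, x$model$mtry, length(x$predictors)))
  cat(sprintf("  training OOB error: %.4f\n", x$report$oob_error))
  if (!is.null(x$report$holdout$auc))
    cat(sprintf("  holdout: sensitivity %.3f, specificity %.3f, AUC %.3f\n",
                x$report$holdout$sensitivity, x$report$holdout$specificity,
                x$report$holdout$auc))
  invisible(x)
}

#' Predict live-coral presence probability per feature
#'
#' Probability = fraction of tree votes for the presence class, evaluated on
#' every record of `table` (typically all delineated features, not just the
#' labelled ones). Deterministic given the fitted forest.
#'
#' @param model a `mound_rf` from [train_rf()].
#' @param table data.frame containing every training predictor column.
#' @return data.frame with `feature_id` (if present in `table`),
#'   `presence_prob` and `predicted` (vote >= 0.5).
#' @export
predict_map <- function(model, table) {
  if (!inherits(model, "mound_rf")) stop("`model` must be a mound_rf")
  missing_cols <- setdiff(model$predictors, names(table))
  if (length(missing_cols))
    stop("missing predictor column(s): ", paste(missing_cols, collapse = ", "))
  x <- table[model$predictors]
  bad <- !stats::complete.cases(x)
  if (any(bad))
    stop("record(s) with missing predictor values: rows ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  p <- predict(model$model, x, type = "prob")[, model$positive_class]
  out <- data.frame(presence_prob = as.numeric(p),
                    predicted = as.numeric(p) >= 0.5)
  if ("feature_id" %in% names(table))
    out <- cbind(feature_id = table$feature_id, out)
  out
}

#' Partial-dependence response curves
#'
#' For each requested predictor, the average predicted presence probability
#' over the table while that predictor is clamped to each point of a grid
#' spanning its observed range (25 points by default) — the probability-scale
#' partial dependence that relates a predictor's values to the chance of live
#' coral.
#'
#' @param model a `mound_rf` (binary target).
#' @param table data.frame with the training predictor columns.
#' @param predictors predictors to profile (default: all in the model).
#' @param n_grid grid resolution (default 25).
#' @return named list of data.frames with columns `value` and `partial_prob`.
#' @export
response_curves <- function(model, table, predictors = NULL, n_grid = 25L) {
  if (!inherits(model, "mound_rf")) stop("`model` must be a mound_rf")
  if (is.null(predictors)) predictors <- model$predictors
  unknown <- setdiff(predictors, model$predictors)
  if (length(unknown))
    stop("predictor(s) not in model: ", paste(unknown, collapse = ", "))
  x <- table[model$predictors]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  out <- lapply(predictors, function(nm) {
    grid <- seq(min(x[[nm]]), max(x[[nm]]), length.out = n_grid)
    pp <- vapply(grid, function(v) {
      xc <- x
      xc[[nm]] <- v
      mean(predict(model$model, xc, type = "prob")[, model$positive_class])
    }, numeric(1))
    data.frame(value = grid, partial_prob = pp)
  })
  names(out) <- predictors
  out
}
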