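#' ROC curve and AUC
#'
#' Sweeps a decision threshold over all distinct scores (plus the 0/1
#' endpoints); at each threshold the point is
#' `X = 1 - TN / (TN + FP)` (false-positive rate) and
#' `Y = TP / (TP + FN)` (true-positive rate), a point being called
#' positive when its score is >= the threshold. AUC is the trapezoidal
#' area under the (X, Y) polyline and equals the Mann-Whitney
#' probability that a random positive outranks a random negative
#' (ties counted half).
#'
#' @param labels observed 0/1 labels (both classes required).
#' @param scores predicted scores in \[0, 1\].
#' @return list with `points` (data.frame `threshold`, `X`, `Y`) and `auc`.
#' @export
roc_curve <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop_spatrisk("input", "labels and scores must have equal length")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_spatrisk("roc_undefined", "ROC needs both classes present (got %d/%d)", n1, n0)
  thr <- sort(unique(c(0, scores, 1, 1 + .Machine$double.eps)), decreasing = TRUE)
  pts <- vapply(thr, function(t) {
    pred <- scores >= t
    c(X = sum(pred & labels == 0) / n0, Y = sum(pred & labels == 1) / n1)
  }, numeric(2))
  X <- pts["X", ]; Y <- pts["Y", ]
  auc <- sum(diff(X) * (utils::head(Y, -1) + utils::tail(Y, -1)) / 2)
  list(points = data.frame(threshold = thr, X = X, Y = Y), auc = auc)
}

#' Confusion counts at a threshold
#'
#' @param labels observed 0/1 labels.
#' @param scores predicted scores.
#' @param threshold decision threshold (score >= threshold is positive).
#' @return list with `TP`, `TN`, `FP`, `FN` counts and the `tp_rate` /
#'   `fp_rate` they imply.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- scores >= threshold
  TP <- sum(pred & labels == 1); FN <- sum(!pred & labels == 1)
  FP <- sum(pred & labels == 0); TN <- sum(!pred & labels == 0)
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       tp_rate = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       fp_rate = if (TN + FP > 0) FP / (TN + FP) else NA_real_)
}

#' RMSE and MAE of predictions
#'
#' `RMSE = sqrt(mean((y - yhat)^2))`, `MAE = mean(|y - yhat|)`;
#' RMSE >= MAE always.
#'
#' @param observed observed values.
#' @param predicted predicted values (same length).
#' @return named numeric vector `c(rmse, mae)`.
#' @export
error_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1L)
    stop_spatrisk("input", "observed and predicted must be equal-length, non-empty")
  e <- observed - predicted
  c(rmse = sqrt(mean(e^2)), mae = mean(abs(e)))
}

#' Relative decrease (RD) of AUC on excluding a factor
#'
#' `RD = 100 * (AUC_all - AUC_i) / AUC_all`, in percent of the all-factor
#' training AUC; negative when exclusion helps.
#'
#' @param auc_all all-factor AUC (percent or proportion, > 0).
#' @param auc_excluded AUC with the factor excluded (same scale).
#' @return RD in percent.
#' @export
sensitivity_rd <- function(auc_all, auc_excluded) {
  if (any(auc_all <= 0))
    stop_spatrisk("parameter", "auc_all must be > 0")
  100 * (auc_all - auc_excluded) / auc_all
}

#' Leave-one-factor-out sensitivity analysis
#'
#' Retrains the classifier once per excluded criterion on the identical
#' training rows and seed, and reports each factor's training-data AUC and
#' its RD against the all-criteria AUC. Training-data AUC is computed from
#' out-of-bag votes: trees grown to purity reproduce their own training
#' labels almost perfectly, so resubstitution AUC saturates at 1 for every
#' subset and carries no ranking information, whereas the OOB estimate is
#' the standard unsaturated training-data accuracy of a bagged forest. A
#' `use_test_auc` flag switches the comparison to held-out rows instead.
#'
#' @param features a [extract_features()] matrix with both labels (and a
#'   partition, if train/test are distinguished).
#' @param n_trees,mtry,min_node,seed forwarded to [train_random_forest()].
#' @param use_test_auc compute the AUCs on the test partition instead of
#'   the training data.
#' @return An object of class `sensitivity_report`: data.frame with
#'   `excluded`, `auc_i` (percent) and `rd` (percent); the attribute
#'   `auc_all` holds the all-factor AUC in percent.
#' @export
run_sensitivity <- function(features, n_trees = 100L, mtry = NULL,
                            min_node = 1L, seed = 1L, use_test_auc = FALSE) {
  stopifnot(inherits(features, "feature_matrix"))
  p <- ncol(features$X)
  if (p < 2L) stop_spatrisk("parameter", "sensitivity needs >= 2 criteria")
  has_part <- any(!is.na(features$partition) & features$partition == "train")
  auc_of <- function(fm) {
    model <- train_random_forest(fm, n_trees = n_trees, mtry = mtry,
                                 min_node = min_node, seed = seed)
    if (use_test_auc) {
      if (!has_part) stop_spatrisk("parameter", "no test partition available")
      te <- fm_subset(fm, "test")
      100 * roc_curve(te$label, predict(model, te))$auc
    } else {
      keep <- !is.na(model$oob_prob)
      100 * roc_curve(model$train_label[keep], model$oob_prob[keep])$auc
    }
  }
  drop_col <- function(fm, j) {
    structure(list(X = fm$X[, -j, drop = FALSE], label = fm$label,
                   partition = fm$partition, dropped = fm$dropped),
              class = "feature_matrix")
  }
  auc_all <- auc_of(features)
  rows <- lapply(seq_len(p), function(j) {
    res <- tryCatch(auc_of(drop_col(features, j)),
                    error = function(e) NA_real_)
    data.frame(excluded = colnames(features$X)[j], auc_i = res,
               rd = if (is.na(res)) NA_real_ else sensitivity_rd(auc_all, res),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$auc_i))
    stop_spatrisk("partial_report", "training failed for excluded factor(s): %s",
                  paste(out$excluded[is.na(out$auc_i)], collapse = ", "))
  structure(out, auc_all = auc_all, class = c("sensitivity_report", "data.frame"))
}

#' Train/validation performance report
#'
#' The standard two-column performance table of a susceptibility model:
#' RMSE, MAE, true/false-positive rates at threshold 0.5, and AUC for the
#' training and test partitions. Training metrics use the model's
#' out-of-bag predictions (see [run_sensitivity()]); set
#' `resubstitution = TRUE` for in-bag training predictions instead.
#'
#' @param model an `rf_model`.
#' @param features a [extract_features()] matrix with a train/test
#'   partition.
#' @param resubstitution evaluate training rows with the full forest
#'   instead of out-of-bag votes.
#' @return data.frame with `metric`, `train`, `validation`.
#' @export
validation_report <- function(model, features, resubstitution = FALSE) {
  one <- function(part) {
    fm <- fm_subset(features, part)
    if (!nrow(fm$X)) return(rep(NA_real_, 5))
    if (part == "train" && !resubstitution &&
        length(model$oob_prob) == nrow(fm$X)) {
      keep <- !is.na(model$oob_prob)
      pr <- model$oob_prob[keep]
      lab <- model$train_label[keep]
    } else {
      pr <- predict(model, fm)
      lab <- fm$label
    }
    em <- error_metrics(lab, pr)
    cm <- confusion_counts(lab, pr)
    auc <- roc_curve(lab, pr)$auc
    c(em["rmse"], em["mae"], cm$tp_rate, cm$fp_rate, auc)
  }
  tr <- one("train"); te <- one("test")
  data.frame(metric = c("RMSE", "MAE", "TP", "FP", "AUC"),
             train = as.numeric(tr), validation = as.numeric(te),
             stringsAsFactors = FALSE)
}
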