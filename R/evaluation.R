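#' Confusion-matrix metrics for outcome predictions
#'
#' The positive class is "poor": a true positive is a poor-outcome patient
#' predicted poor, a true negative a good-outcome patient predicted good.
#' Accuracy = (TP+TN)/(TP+FP+TN+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP). A ratio with an empty denominator (e.g.
#' sensitivity when no poor patients exist) is reported as `NA`, not 0.
#'
#' @param predictions data.frame with columns `patient` and `predicted`
#'   (from [nb_predict()]).
#' @param labels named character vector patient -> "good"/"poor".
#' @return A list of class `caerus_confusion`: `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion <- function(predictions, labels) {
  if (!nrow(predictions)) stop("no predictions")
  truth <- labels[predictions$patient]
  if (any(is.na(truth))) stop("every prediction needs a label")
  pred <- predictions$predicted
  tp <- sum(truth == "poor" & pred == "poor")
  fn <- sum(truth == "poor" & pred == "good")
  tn <- sum(truth == "good" & pred == "good")
  fp <- sum(truth == "good" & pred == "poor")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(
      tp = tp, fp = fp, tn = tn, fn = fn,
      accuracy = ratio(tp + tn, tp + fp + tn + fn),
      sensitivity = ratio(tp, tp + fn),
      specificity = ratio(tn, tn + fp)
    ),
    class = "caerus_confusion"
  )
}

#' @export
print.caerus_confusion <- function(x, ...) {
  cat(sprintf(
    "<caerus_confusion> TP=%d FP=%d TN=%d FN=%d | acc=%.3f sens=%s spec=%s\n",
    x$tp, x$fp, x$tn, x$fn, x$accuracy,
    format(x$sensitivity, digits = 3), format(x$specificity, digits = 3)
  ))
  invisible(x)
}

#' ROC curve and AUC for poor-outcome posteriors
#'
#' Sweeps a decision threshold over the unique posterior values (patients
#' with equal scores move across the threshold together), accumulating the
#' true- and false-positive rates for the positive class "poor"; the AUC is
#' the trapezoidal area under the resulting curve.
#'
#' @param posterior_poor named numeric vector, patient -> posterior
#'   probability of poor outcome.
#' @param labels named character vector patient -> "good"/"poor".
#' @return A list with `roc` (data.frame of `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(posterior_poor, labels) {
  truth <- labels[names(posterior_poor)]
  if (any(is.na(truth))) stop("every scored patient needs a label")
  n_pos <- sum(truth == "poor")
  n_neg <- sum(truth == "good")
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  thr <- sort(unique(posterior_poor), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(posterior_poor >= t & truth == "poor") / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(posterior_poor >= t & truth == "good") / n_neg,
                numeric(1))
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr), threshold = c(Inf, thr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

# Deterministic stratified fold assignment: within each class, patients are
# shuffled by the seeded RNG and dealt round-robin into k folds.
stratified_folds <- function(labels, k, seed) {
  folds <- stats::setNames(integer(length(labels)), names(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      ids <- names(labels)[labels == cl]
      ids <- sample(ids)
      folds[ids] <- rep_len(seq_len(k), length(ids))
    }
  })
  folds
}

# Evaluate LOOCV accuracy of a fixed signature set on a feature submatrix.
loocv_accuracy <- function(features, labels, alpha, n_bins) {
  patients <- rownames(features)
  correct <- 0L
  for (p in patients) {
    train <- features[setdiff(patients, p), , drop = FALSE]
    lab_train <- labels[rownames(train)]
    if (length(unique(lab_train)) < 2) next
    model <- nb_fit(train, labels, alpha = alpha, n_bins = n_bins)
    pred <- nb_predict(model, features[p, , drop = FALSE])
    correct <- correct + (pred$predicted == labels[[p]])
  }
  correct / length(patients)
}

# Shared engine: tune c on a training patient set by LOOCV, then fit on the
# full training set and predict the test patients. `sig_by_c` maps each c
# to its signature set; `features` is the precomputed per-patient feature
# matrix over the union of signatures (per-patient transform, label-free).
tune_and_predict <- function(features, labels, train_ids, test_ids,
                             sig_by_c, c_grid, alpha, n_bins) {
  usable_sigs <- colnames(features)
  acc_cache <- new.env(parent = emptyenv())
  best_c <- NA_real_
  best_acc <- -Inf
  for (ci in sort(c_grid)) {
    sigs <- intersect(sig_by_c[[as.character(ci)]], usable_sigs)
    if (!length(sigs)) {
      message(sprintf("threshold c=%g yields no usable signature; skipped", ci))
      next
    }
    key <- paste(sigs, collapse = "\r")
    acc <- get0(key, envir = acc_cache)
    if (is.null(acc)) {
      acc <- loocv_accuracy(features[train_ids, sigs, drop = FALSE],
                            labels, alpha, n_bins)
      assign(key, acc, envir = acc_cache)
    }
    if (acc > best_acc) {  # ties keep the smallest c (first seen)
      best_acc <- acc
      best_c <- ci
    }
  }
  if (is.na(best_c)) stop("no threshold in c_grid yields a usable signature set")
  sigs <- intersect(sig_by_c[[as.character(best_c)]], usable_sigs)
  model <- nb_fit(features[train_ids, sigs, drop = FALSE], labels,
                  alpha = alpha, n_bins = n_bins)
  pred <- nb_predict(model, features[test_ids, , drop = FALSE])
  list(chosen_c = best_c, predictions = pred)
}

# Signature sets for every c in the grid, from label-free bundle scoring.
signatures_by_c <- function(bundle, c_grid, use_mutations, cfg) {
  reports <- score_all(bundle, cfg)
  out <- lapply(c_grid, function(ci) {
    cfg_c <- cfg
    cfg_c$threshold_c <- ci
    select_signatures(reports, cfg_c, use_mutations)
  })
  names(out) <- as.character(c_grid)
  out
}

cv_result <- function(folds, predictions, labels, seed) {
  pooled <- confusion(predictions, labels)
  post_poor <- stats::setNames(1 - predictions$posterior_good,
                               predictions$patient)
  roc <- roc_auc(post_poor, labels)
  structure(
    list(
      folds = folds, pooled = pooled, predictions = predictions,
      roc = roc$roc, auc = roc$auc, seed = seed
    ),
    class = "caerus_cv"
  )
}

#' @export
print.caerus_cv <- function(x, ...) {
  cat(sprintf(
    "<caerus_cv> %d folds | pooled acc=%.3f sens=%s spec=%s AUC=%.3f (seed %d)\n",
    length(x$folds), x$pooled$accuracy,
    format(x$pooled$sensitivity, digits = 3),
    format(x$pooled$specificity, digits = 3), x$auc, x$seed
  ))
  invisible(x)
}

#' Nested five-fold cross-validation with inner threshold tuning
#'
#' The cohort is split into 5 stratified outer folds by a seeded shuffle.
#' Within each 80% training portion, every candidate threshold c is scored
#' by leave-one-out cross-validation (signatures are selected from the
#' interactome bundle at c -- a label-free step -- features built, a naive
#' Bayes model fitted on the remaining training patients and the held-out
#' patient predicted); the c maximizing LOOCV accuracy (smallest c on ties)
#' is used to train on the full 80% and predict the held-out 20%. Out-of-
#' fold predictions are pooled into confusion metrics and a ROC curve.
#'
#' @param bundle a `caerus_bundle`.
#' @param cohort a `caerus_cohort` with >= 10 patients and both classes.
#' @param c_grid candidate thresholds (default 10, 20, ..., 150).
#' @param use_mutations tune/select on the mutation-weighted score.
#' @param seed integer seed controlling the fold shuffle.
#' @param cfg a [score_config()] (its `threshold_c` is overridden by the
#'   grid).
#' @param alpha,n_bins classifier smoothing and bin count.
#' @param feature_mode passed to [patient_features()].
#' @return A `caerus_cv` result: per-fold chosen c and metrics, pooled
#'   metrics, per-patient out-of-fold predictions, ROC points and AUC.
#' @export
nested_cv <- function(bundle, cohort, c_grid = seq(10, 150, by = 10),
                      use_mutations = FALSE, seed = 1L,
                      cfg = score_config(), alpha = 1, n_bins = 20L,
                      feature_mode = "rank") {
  if (length(cohort$patients) < 10) stop("nested_cv needs at least 10 patients")
  sig_by_c <- signatures_by_c(bundle, c_grid, use_mutations, cfg)
  union_sigs <- sort(unique(unlist(sig_by_c, use.names = FALSE)))
  if (!length(union_sigs)) stop("no threshold in c_grid selects any signature")
  features <- suppressWarnings(
    patient_features(union_sigs, bundle, cohort, mode = feature_mode)
  )
  labels <- cohort$labels
  fold_of <- stratified_folds(labels, 5L, seed)
  folds <- list()
  preds <- list()
  for (k in 1:5) {
    test_ids <- names(fold_of)[fold_of == k]
    train_ids <- names(fold_of)[fold_of != k]
    if (length(unique(labels[test_ids])) < 2 ||
        length(unique(labels[train_ids])) < 2) {
      stop("both classes must be present in every outer fold")
    }
    res <- tune_and_predict(features, labels, train_ids, test_ids,
                            sig_by_c, c_grid, alpha, n_bins)
    folds[[k]] <- list(chosen_c = res$chosen_c,
                       metrics = confusion(res$predictions, labels))
    preds[[k]] <- res$predictions
  }
  cv_result(folds, do.call(rbind, preds), labels, seed)
}

#' Leave-one-out cross-validation with inner threshold tuning
#'
#' Outer leave-one-out protocol for small cohorts: each patient in turn is
#' held out, the threshold c is tuned by LOOCV on the remaining n-1
#' patients (same rule as [nested_cv()]), a model is fitted on those n-1
#' and the held-out patient predicted. Metrics are pooled over all n
#' held-out predictions.
#'
#' @inheritParams nested_cv
#' @return A `caerus_cv` result (one fold entry per patient).
#' @export
loocv <- function(bundle, cohort, c_grid = seq(10, 150, by = 10),
                  use_mutations = FALSE, seed = 1L,
                  cfg = score_config(), alpha = 1, n_bins = 20L,
                  feature_mode = "rank") {
  labels <- cohort$labels
  if (min(table(labels)) < 2) stop("loocv needs at least 2 patients per class")
  sig_by_c <- signatures_by_c(bundle, c_grid, use_mutations, cfg)
  union_sigs <- sort(unique(unlist(sig_by_c, use.names = FALSE)))
  if (!length(union_sigs)) stop("no threshold in c_grid selects any signature")
  features <- suppressWarnings(
    patient_features(union_sigs, bundle, cohort, mode = feature_mode)
  )
  folds <- list()
  preds <- list()
  for (p in cohort$patients) {
    train_ids <- setdiff(cohort$patients, p)
    res <- tune_and_predict(features, labels, train_ids, p,
                            sig_by_c, c_grid, alpha, n_bins)
    folds[[p]] <- list(chosen_c = res$chosen_c,
                       metrics = NULL)  # single-patient fold: no per-fold matrix
    preds[[p]] <- res$predictions
  }
  cv_result(folds, do.call(rbind, preds), labels, seed)
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
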