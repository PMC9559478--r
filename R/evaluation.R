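#' Stratified k-fold assignment
#'
#' Assigns each record to one of `k` cross-validation folds, stratified on
#' the binary modality: within each class, shuffled indices are dealt
#' round-robin, so per-fold class counts differ by at most one from exact
#' proportionality.
#'
#' @param labels binary label vector (0/1, logical, or GRASS/NOGRASS).
#' @param k number of folds (default 10).
#' @param seed integer RNG seed.
#' @return integer vector of fold ids in 1..k, one per record.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1) {
  y <- encode_response(labels)
  k <- check_count(k, "k", min = 2L)
  counts <- table(y)
  if (any(counts < k)) {
    stop(sprintf("each class needs at least k = %d members (got %s)",
                 k, paste(counts, collapse = "/")), call. = FALSE)
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' ROC area under the curve by rank concordance
#'
#' AUC computed as the Mann-Whitney concordance probability: the chance
#' that a random positive (GRASS) record scores above a random negative
#' one, with ties counting one half. This equals the trapezoidal area
#' under the empirical ROC curve.
#'
#' @param scores numeric score vector (higher = more GRASS-like).
#' @param labels binary labels as in [stratified_folds()].
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  y <- encode_response(labels)
  if (length(scores) != length(y)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  r <- rank(scores)  # average ranks: ties count 1/2
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Sensitivity, specificity and accuracy of binary predictions
#'
#' Sensitivity is recall of the GRASS (positive) class, specificity of
#' the NOGRASS class, accuracy the overall fraction correct.
#'
#' @param predicted,actual binary vectors (0/1, logical, or
#'   GRASS/NOGRASS) of equal length.
#' @return named numeric vector `c(sensitivity, specificity, accuracy)`.
#' @export
confusion_metrics <- function(predicted, actual) {
  if (length(predicted) == 0L) stop("empty input", call. = FALSE)
  if (length(predicted) != length(actual)) {
    stop("`predicted` and `actual` must have equal length", call. = FALSE)
  }
  pred <- encode_binary(predicted)
  act <- encode_binary(actual)
  tp <- sum(pred == 1 & act == 1)
  fn <- sum(pred == 0 & act == 1)
  tn <- sum(pred == 0 & act == 0)
  fp <- sum(pred == 1 & act == 0)
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(act))
}

# Like encode_response() but tolerates single-class vectors (a constant
# classifier is a legitimate, if degenerate, prediction).
encode_binary <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("GRASS", "NOGRASS"))
    if (length(bad)) {
      stop("labels must be GRASS/NOGRASS; found: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    y <- as.integer(y == "GRASS")
  }
  y <- as.numeric(y)
  if (any(!y %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  y
}

#' Cross-validated performance of a PLS-DA configuration
#'
#' Runs stratified k-fold cross-validation at a fixed (or CV-selected)
#' component count and reports per-fold AUC, sensitivity and specificity
#' with their means and standard deviations, in the "mean +/- SD across
#' folds" style customary for such models. Classes within each fold are
#' assigned by the 0.5 probability threshold of a calibration fitted on
#' that fold's training part.
#'
#' @param X predictors (n x p).
#' @param y binary response.
#' @param A component count; if `NULL`, selected by
#'   [select_n_components()] on the same folds.
#' @param max_A cap for component selection (default 30).
#' @param k folds (default 10).
#' @param seed integer RNG seed.
#' @return object of class `cv_result`: list with `A`, `fold_metrics`
#'   (data.frame of per-fold AUC/sensitivity/specificity), `mean`, `sd`,
#'   and (when selected) `cv_auc_by_ncomp`.
#' @export
cross_validate_plsda <- function(X, y, A = NULL, max_A = 30, k = 10,
                                 seed = 1) {
  X <- as.matrix(X)
  y <- encode_response(y)
  cv_auc_by_ncomp <- NULL
  if (is.null(A)) {
    sel <- select_n_components(X, y, max_A = max_A, k = k, seed = seed)
    A <- sel$A_star
    folds <- sel$folds
    cv_auc_by_ncomp <- sel$cv_auc
  } else {
    folds <- stratified_folds(y, k = k, seed = seed)
  }
  k <- max(folds)
  fm <- data.frame(fold = seq_len(k), auc = NA_real_,
                   sensitivity = NA_real_, specificity = NA_real_)
  for (f in seq_len(k)) {
    tr <- folds != f
    A_fit <- min(A, sum(tr) - 1L, ncol(X))
    fit <- fit_pls(X[tr, , drop = FALSE], y[tr], A = A_fit)
    prob <- predict_grass_probability(fit, as.data.frame(X[!tr, , drop = FALSE]))
    fm$auc[f] <- roc_auc(prob, y[!tr])
    cm <- confusion_metrics(as.integer(prob > 0.5), y[!tr])
    fm$sensitivity[f] <- cm[["sensitivity"]]
    fm$specificity[f] <- cm[["specificity"]]
  }
  structure(
    list(A = A, fold_metrics = fm,
         mean = colMeans(fm[, c("auc", "sensitivity", "specificity")]),
         sd = apply(fm[, c("auc", "sensitivity", "specificity")], 2,
                    stats::sd),
         cv_auc_by_ncomp = cv_auc_by_ncomp),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Stratified %d-fold cross-validation, %d latent variable(s)\n",
              nrow(x$fold_metrics), x$A))
  for (m in c("auc", "sensitivity", "specificity")) {
    cat(sprintf("  %-12s %.2f +/- %.2f %%\n", m,
                100 * x$mean[[m]], 100 * x$sd[[m]]))
  }
  invisible(x)
}

#' Month-restricted external validation accuracy
#'
#' Validates a model on the months whose feeding regime is least
#' ambiguous, identically for every labeling scheme: only December and
#' January records (taken as NOGRASS ground truth) and July and August
#' records (taken as GRASS) enter; all other months are excluded. This is
#' the common protocol that makes validation accuracies comparable across
#' schemes.
#'
#' @param model fitted `plsda` model.
#' @param records validation data.frame with `month` and the model's
#'   predictor columns.
#' @return list with `accuracy`, `n_used` (records in the four-month
#'   protocol window), `n_total`, and the `confusion` metrics vector.
#' @export
external_validation_accuracy <- function(model, records) {
  if (!"month" %in% names(records)) {
    stop("validation records must have a `month` column", call. = FALSE)
  }
  keep <- records$month %in% c(12L, 1L, 7L, 8L)
  if (!any(keep)) {
    stop("no validation records in the protocol months (Dec, Jan, Jul, Aug)",
         call. = FALSE)
  }
  sub <- records[keep, , drop = FALSE]
  truth <- ifelse(sub$month %in% c(7L, 8L), "GRASS", "NOGRASS")
  pred <- predict(model, sub, type = "class")
  cm <- confusion_metrics(pred, truth)
  list(accuracy = cm[["accuracy"]], n_used = nrow(sub),
       n_total = nrow(records), confusion = cm)
}

#' Mean GRASS probability per year and month
#'
#' Averages per-record GRASS probabilities over every (year, month) cell,
#' including transition (OTHERS) months the model never saw in training —
#' the curve is how the model's view of the grazing season is inspected.
#'
#' @param records data.frame with `year` and `month` columns.
#' @param probability numeric vector of GRASS probabilities, one per row
#'   of `records` (or the name of a column of `records` holding them).
#' @return data.frame with columns `year`, `month`, `probability` (cell
#'   mean), `se` (standard error of the cell mean), `n` (records in the
#'   cell), ordered by year then month.
#' @export
monthly_probability_curve <- function(records, probability = "probability") {
  if (is.character(probability) && length(probability) == 1L) {
    if (!probability %in% names(records)) {
      stop("column `", probability, "` not found in records", call. = FALSE)
    }
    probability <- records[[probability]]
  }
  if (length(probability) != nrow(records)) {
    stop("`probability` must have one value per record", call. = FALSE)
  }
  if (any(probability < 0 | probability > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  key <- interaction(records$year, records$month, drop = TRUE)
  agg <- data.frame(
    year = as.integer(tapply(records$year, key, `[`, 1)),
    month = as.integer(tapply(records$month, key, `[`, 1)),
    probability = as.numeric(tapply(probability, key, mean)),
    se = as.numeric(tapply(probability, key,
                           function(v) stats::sd(v) / sqrt(length(v)))),
    n = as.integer(tapply(probability, key, length)))
  agg <- agg[order(agg$year, agg$month), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Pearson correlations between the GRASS probabilities of several models
#'
#' @param ... two or more aligned numeric probability vectors (same
#'   records, same order), optionally named.
#' @return symmetric Pearson correlation matrix with unit diagonal.
#' @export
intermodel_probability_correlation <- function(...) {
  probs <- list(...)
  if (length(probs) == 1L && is.list(probs[[1]])) probs <- probs[[1]]
  if (length(probs) < 2L) {
    stop("need at least two probability vectors", call. = FALSE)
  }
  n <- lengths(probs)
  if (length(unique(n)) != 1L) {
    stop("probability vectors must have equal length (aligned records)",
         call. = FALSE)
  }
  if (is.null(names(probs)) || any(names(probs) == "")) {
    names(probs) <- paste0("GRASS", seq_along(probs))
  }
  stats::cor(do.call(cbind, probs))
}
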