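#' Fit a two-class PLS discriminant model (NIPALS)
#'
#' Partial least squares regression of a 0/1 class response on
#' mean-centered, unit-variance-scaled predictors, extracted component by
#' component with the NIPALS recursion (for a single response the inner
#' loop is closed-form: the weight vector is the predictor-response
#' covariance, normalized). Two-class discriminant analysis on a 0/1
#' response is equivalent to two-column dummy coding up to an affine map,
#' so GRASS is coded 1 (the positive class) and NOGRASS 0.
#'
#' Zero-variance predictors cannot be scaled and are dropped with a
#' warning. Extraction stops early, recording the effective number of
#' components, if the residual predictor matrix or the weight vector
#' becomes numerically zero (tolerance 1e-12).
#'
#' Class probabilities use a logistic (Platt-style) calibration of the
#' continuous PLS prediction. Following the standard Platt procedure the
#' calibration is fitted on out-of-fold scores from an internal
#' cross-validation (5 folds), not on the training scores themselves,
#' which would be overconfident whenever the classes separate well. Any
#' strictly monotone map leaves ROC/AUC unchanged, so the calibration
#' affects only the probability scale, not model selection.
#'
#' @param X numeric matrix or data.frame of predictors (n x p).
#' @param y response: 0/1 numeric, logical, or a factor/character vector
#'   with levels GRASS/NOGRASS (GRASS is coded 1).
#' @param A number of latent variables; must satisfy
#'   `A <= min(p, n - 1)`.
#' @param tol numerical tolerance for early stopping (default 1e-12).
#' @param calibrate fit the out-of-fold probability calibration (default
#'   `TRUE`); internal refits set this to `FALSE` and calibrate on
#'   training scores instead.
#' @return object of class `plsda`: list with predictor `means`, `scales`,
#'   weight matrix `W` (p x A, unit-norm columns), predictor loadings `P`,
#'   response loadings `q`, regression coefficients `b` (scaled-predictor
#'   scale), `intercept`, per-component explained response sum of squares
#'   `ss`, score norms `tss`, requested `A`, effective `A_eff`,
#'   calibration coefficients `calibration`, and the retained predictor
#'   names `predictors`.
#' @examples
#' d <- generate_dataset(10, 1, seed = 1)
#' d <- build_modeling_subset(label_records(d, 1))
#' fit <- fit_pls(d[, trait_names()], d$y, A = 5)
#' fit$A_eff
#' @export
fit_pls <- function(X, y, A, tol = 1e-12, calibrate = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- encode_response(y)
  n <- nrow(X)
  p <- ncol(X)
  A <- check_count(A, "A")
  if (length(y) != n) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (A > min(p, n - 1L)) {
    stop(sprintf("A = %d exceeds min(p, n - 1) = %d", A, min(p, n - 1L)),
         call. = FALSE)
  }
  X <- ensure_colnames(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 1e-12
  if (!all(keep)) {
    warning("dropping zero-variance predictor(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
    mu <- mu[keep]
    sdv <- sdv[keep]
    p <- ncol(X)
    if (p == 0L) stop("no usable predictors left", call. = FALSE)
    A <- min(A, min(p, n - 1L))
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  ybar <- mean(y)
  yc <- y - ybar

  W <- P <- matrix(0, p, A)
  q <- ss <- tss <- numeric(A)
  Xr <- Xs
  yr <- yc
  A_eff <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xr, yr)[, 1]
    wn <- sqrt(sum(w^2))
    if (wn < tol) break
    w <- w / wn
    t_a <- drop(Xr %*% w)
    tt <- sum(t_a^2)
    if (tt < tol) break
    p_a <- crossprod(Xr, t_a)[, 1] / tt
    q_a <- sum(yr * t_a) / tt
    Xr <- Xr - tcrossprod(t_a, p_a)
    yr <- yr - q_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    q[a] <- q_a
    tss[a] <- tt
    ss[a] <- q_a^2 * tt  # response SS explained by component a
    A_eff <- a
  }
  if (A_eff == 0L) {
    stop("no PLS component could be extracted (predictors uncorrelated ",
         "with the response at machine precision)", call. = FALSE)
  }
  W <- W[, seq_len(A_eff), drop = FALSE]
  P <- P[, seq_len(A_eff), drop = FALSE]
  q <- q[seq_len(A_eff)]
  ss <- ss[seq_len(A_eff)]
  tss <- tss[seq_len(A_eff)]
  b <- drop(W %*% solve(crossprod(P, W), q))

  model <- structure(
    list(predictors = colnames(X), means = mu, scales = sdv,
         W = W, P = P, q = q, b = b, intercept = ybar,
         ss = ss, tss = tss, A = A, A_eff = A_eff,
         labels = c(negative = "NOGRASS", positive = "GRASS"),
         calibration = c(a0 = 0, a1 = 1)),
    class = "plsda")
  if (calibrate) {
    model$calibration <- platt_calibration(cv_scores(X, y, A_eff, tol), y)
  } else {
    score <- drop(Xs %*% b) + ybar
    model$calibration <- platt_calibration(score, y)
  }
  model
}

# Out-of-fold continuous PLS predictions used to fit the probability
# calibration (5 inner folds, deterministic). Falls back to the training
# scores when a class is too small to stratify.
cv_scores <- function(X, y, A, tol, k = 5L) {
  if (min(table(y)) < k) {
    fit <- fit_pls(X, y, A = A, tol = tol, calibrate = FALSE)
    return(predict(fit, as.data.frame(X), type = "score"))
  }
  folds <- stratified_folds(y, k = k, seed = 1L)
  score <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    A_fit <- min(A, sum(tr) - 1L)
    fit <- suppressWarnings(
      fit_pls(X[tr, , drop = FALSE], y[tr], A = A_fit, tol = tol,
              calibrate = FALSE))
    score[!tr] <- predict(fit, as.data.frame(X[!tr, , drop = FALSE]),
                          type = "score")
  }
  score
}

# Give anonymous predictor columns stable names so that training and
# prediction agree on the schema.
ensure_colnames <- function(X) {
  cn <- colnames(X)
  if (is.null(cn)) cn <- rep("", ncol(X))
  blank <- !nzchar(cn)
  cn[blank] <- paste0("x", which(blank))
  colnames(X) <- cn
  X
}

# Map factor/character/logical responses onto the 0/1 coding (GRASS = 1).
encode_response <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("GRASS", "NOGRASS"))
    if (length(bad)) {
      stop("response labels must be GRASS/NOGRASS; found: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    y <- as.integer(y == "GRASS")
  }
  y <- as.numeric(y)
  if (any(!y %in% c(0, 1))) {
    stop("numeric response must be 0/1", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("degenerate labels: both classes must be present", call. = FALSE)
  }
  y
}

# Logistic calibration of the continuous PLS prediction: fit
# P(GRASS | score) = plogis(a0 + a1 * score) on training data. Under
# complete separation glm()'s coefficients diverge; they are then capped
# so probabilities stay finite and strictly monotone in the score.
platt_calibration <- function(score, y) {
  fit <- suppressWarnings(
    stats::glm(y ~ score, family = stats::binomial(),
               control = list(maxit = 50)))
  co <- stats::coef(fit)
  if (any(!is.finite(co)) || abs(co[2]) > 1e6) {
    # complete separation: steep but finite slope through the midpoint
    # between class score means
    m1 <- mean(score[y == 1])
    m0 <- mean(score[y == 0])
    a1 <- 50 / max(abs(m1 - m0), 1e-8)
    co <- c(-a1 * (m0 + m1) / 2, a1)
  }
  c(a0 = unname(co[1]), a1 = unname(co[2]))
}

# Coefficient path: column a holds the regression coefficients of the
# model truncated to the first a components. R = P'W is unit upper
# triangular for NIPALS, so each solve is a cheap back-substitution.
pls_coef_path <- function(W, P, q) {
  A <- ncol(W)
  R <- crossprod(P, W)
  B <- matrix(0, nrow(W), A, dimnames = list(rownames(W), NULL))
  for (a in seq_len(A)) {
    idx <- seq_len(a)
    B[, a] <- W[, idx, drop = FALSE] %*%
      solve(R[idx, idx, drop = FALSE], q[idx])
  }
  B
}

#' @export
print.plsda <- function(x, ...) {
  cat("Two-class PLS-DA model (NIPALS)\n")
  cat(sprintf("  predictors: %d   components: %d (requested %d)\n",
              length(x$predictors), x$A_eff, x$A))
  cat(sprintf("  positive class: %s   calibration: plogis(%.3g + %.3g * score)\n",
              x$labels[["positive"]], x$calibration[["a0"]],
              x$calibration[["a1"]]))
  invisible(x)
}

#' Predict from a fitted PLS-DA model
#'
#' @param object fitted `plsda` model.
#' @param newdata matrix or data.frame holding at least the model's
#'   predictor columns.
#' @param type `"score"` for the continuous PLS prediction (on the 0/1
#'   response scale), `"probability"` for the calibrated GRASS
#'   probability, `"class"` for the 0.5-thresholded modality.
#' @param ncomp optional truncation to the first `ncomp` components.
#' @param ... unused.
#' @return numeric vector (`score`/`probability`) or character vector
#'   (`class`).
#' @export
predict.plsda <- function(object, newdata,
                          type = c("score", "probability", "class"),
                          ncomp = NULL, ...) {
  type <- match.arg(type)
  Xs <- scale_newdata(object, newdata)
  if (is.null(ncomp) || ncomp >= object$A_eff) {
    b <- object$b
  } else {
    stopifnot(ncomp >= 1)
    B <- pls_coef_path(object$W, object$P, object$q)
    b <- B[, ncomp]
  }
  score <- unname(drop(Xs %*% b)) + object$intercept
  if (type == "score") return(score)
  prob <- stats::plogis(object$calibration[["a0"]] +
                          object$calibration[["a1"]] * score)
  if (type == "probability") return(prob)
  ifelse(prob > 0.5, object$labels[["positive"]], object$labels[["negative"]])
}

# Align, check and scale new data against the training schema.
scale_newdata <- function(object, newdata) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$predictors, names(newdata))
  if (length(missing)) {
    stop("newdata is missing predictor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(newdata[object$predictors])
  storage.mode(X) <- "double"
  sweep(sweep(X, 2, object$means), 2, object$scales, "/")
}

#' Probability of the GRASS modality
#'
#' Convenience wrapper around `predict(model, X, type = "probability")`.
#' The NOGRASS probability is its complement, so the two modalities'
#' probabilities sum to 1 per record.
#'
#' @param model fitted `plsda` model.
#' @param X new data with the model's predictor columns.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_grass_probability <- function(model, X) {
  predict(model, X, type = "probability")
}

#' Select the number of PLS latent variables by cross-validated AUC
#'
#' Evaluates every component count from 1 to `max_A` by k-fold
#' cross-validation stratified on the two modalities, scoring each count
#' by mean held-out AUC of the continuous PLS prediction. Ties break
#' toward the smaller count. The cap of 30 components limits overfitting
#' risk.
#'
#' Each fold is fitted once at the maximal count and all truncated models
#' are read off the same fit, so the search costs k fits, not k * max_A.
#'
#' @param X predictors (n x p).
#' @param y binary response as in [fit_pls()].
#' @param max_A maximum number of components (default and cap 30).
#' @param k number of CV folds (default 10).
#' @param seed integer RNG seed for the folds.
#' @return list with `A_star` (selected count), `cv_auc` (mean held-out
#'   AUC per candidate count), and `folds` (the fold assignment used).
#' @export
select_n_components <- function(X, y, max_A = 30, k = 10, seed = 1) {
  X <- ensure_colnames(as.matrix(X))
  y <- encode_response(y)
  max_A <- min(check_count(max_A, "max_A"), 30L)
  folds <- stratified_folds(y, k = k, seed = seed)
  k <- max(folds)
  A_cap <- min(max_A, ncol(X))
  auc_mat <- matrix(NA_real_, k, A_cap)
  for (f in seq_len(k)) {
    tr <- folds != f
    A_fit <- min(A_cap, sum(tr) - 1L)
    fit <- fit_pls(X[tr, , drop = FALSE], y[tr], A = A_fit)
    B <- pls_coef_path(fit$W, fit$P, fit$q)
    Xs <- scale_newdata(fit, as.data.frame(X[!tr, , drop = FALSE]))
    scores <- Xs %*% B + fit$intercept
    a_avail <- ncol(B)
    for (a in seq_len(A_cap)) {
      auc_mat[f, a] <- roc_auc(scores[, min(a, a_avail)], y[!tr])
    }
  }
  cv_auc <- colMeans(auc_mat)
  A_star <- which.max(cv_auc)  # first maximum = smallest A on ties
  list(A_star = as.integer(A_star), cv_auc = cv_auc, folds = folds)
}

#' Variable Importance in Projection (VIP) scores
#'
#' For predictor j, the raw VIP aggregates the squared normalized weights
#' over components, weighted by each component's explained response sum
#' of squares SS_a:
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a (w_{ja}/\|w_a\|)^2 / \sum_a SS_a}}
#' so the mean of the squared raw VIPs over the p retained predictors is
#' exactly 1. The scaled VIP rescales the raw score to a 0-100 range
#' (100 = most important predictor), the scale on which thresholds such
#' as 50 are interpreted.
#'
#' @param model fitted `plsda` model.
#' @return data.frame of class `vip_table` with columns `predictor`,
#'   `vip` (raw), `vip_scaled` (0-100).
#' @export
compute_vip <- function(model) {
  stopifnot(inherits(model, "plsda"))
  W <- model$W
  ss <- model$ss
  w2 <- sweep(W^2, 2, colSums(W^2), "/")  # weights are unit-norm already
  p <- nrow(W)
  raw <- sqrt(p * drop(w2 %*% ss) / sum(ss))
  out <- data.frame(predictor = model$predictors, vip = raw,
                    vip_scaled = 100 * raw / max(raw),
                    stringsAsFactors = FALSE)
  class(out) <- c("vip_table", "data.frame")
  out
}

#' Reduce the predictor set by a scaled-VIP threshold
#'
#' Retains every predictor whose scaled VIP (0-100) is at least
#' `threshold`. Refitting the model on the retained subset is the
#' caller's task.
#'
#' @param vip a `vip_table` from [compute_vip()].
#' @param threshold scaled-VIP threshold in \[0, 100\] (the study used 50).
#' @return character vector of retained predictor names.
#' @export
reduce_by_vip <- function(vip, threshold) {
  stopifnot(inherits(vip, "vip_table"))
  if (threshold < 0 || threshold > 100) {
    stop("`threshold` must be in [0, 100]", call. = FALSE)
  }
  kept <- vip$predictor[vip$vip_scaled >= threshold]
  if (length(kept) == 0L) {
    stop("VIP threshold removed every predictor", call. = FALSE)
  }
  kept
}
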