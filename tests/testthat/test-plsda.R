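test_that("full-rank PLS reproduces the least-squares solution", {
  set.seed(1)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- rep(c(0L, 1L), each = 10)
  fit <- fit_pls(X, y, A = 5)
  expect_equal(unname(fit$b), unname(bf_ols(X, y)), tolerance = 1e-8)
})

test_that("the first weight vector is the predictor-response covariance", {
  set.seed(2)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- rep(c(0L, 1L), 15)
  fit <- fit_pls(X, y, A = 1)
  w_expected <- drop(crossprod(scale(X), y - mean(y)))
  w_expected <- w_expected / sqrt(sum(w_expected^2))
  expect_equal(unname(fit$W[, 1]), unname(w_expected), tolerance = 1e-10)
})

test_that("score vectors are mutually orthogonal and b matches (W, P, q)", {
  lab <- sim_modeling_data(15, 2, scheme = 1, seed = 3)
  X <- as.matrix(lab[, trait_names()])
  fit <- fit_pls(X, lab$y, A = 8)
  Xs <- sweep(sweep(X, 2, fit$means), 2, fit$scales, "/")
  Tm <- Xs %*% fit$W %*% solve(crossprod(fit$P, fit$W))
  gram <- crossprod(Tm)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8 * max(diag(gram)))
  # predictions through the score route equal the coefficient route
  yhat_scores <- unname(drop(Tm %*% fit$q)) + fit$intercept
  yhat_b <- predict(fit, lab, type = "score")
  expect_equal(yhat_scores, yhat_b, tolerance = 1e-8)
})

test_that("a duplicated column leaves full-rank predictions unchanged", {
  set.seed(4)
  X <- matrix(rnorm(25 * 4), 25, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- rep(c(0L, 1L), length.out = 25)
  Xdup <- cbind(X, x4b = X[, 4])
  fit <- fit_pls(X, y, A = 4)
  fit_dup <- fit_pls(Xdup, y, A = 5)  # rank is still 4; early stop allowed
  expect_equal(predict(fit_dup, as.data.frame(Xdup), type = "score"),
               predict(fit, as.data.frame(X), type = "score"),
               tolerance = 1e-6)
})

test_that("component count is validated and zero-variance columns dropped", {
  set.seed(5)
  X <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- rep(c(0L, 1L), 5)
  expect_error(fit_pls(X, y, A = 10), "exceeds")
  Xz <- cbind(X, const = 1)
  expect_warning(fit2 <- fit_pls(Xz, y, A = 3), "zero-variance")
  expect_equal(fit2$predictors, paste0("x", 1:4))
  expect_error(fit_pls(X, rep(1L, 10), A = 2), "degenerate")
})

test_that("probabilities are calibrated, complementary and separating", {
  lab <- sim_modeling_data(30, 2, scheme = 1, seed = 6)
  X <- lab[, trait_names()]
  fit <- fit_pls(X, lab$y, A = 5)
  prob <- predict_grass_probability(fit, lab)
  expect_true(all(prob >= 0 & prob <= 1))
  # top-scoring training record is confidently GRASS
  top <- which.max(predict(fit, lab, type = "score"))
  expect_gt(prob[top], 0.5)
  expect_equal(predict(fit, lab, type = "class")[top], "GRASS")
  # two-class normalization: P(NOGRASS) = 1 - P(GRASS) by construction
  expect_equal(prob + (1 - prob), rep(1, length(prob)))
  # strong simulated effects separate full-grass from housed records
  d <- generate_dataset(30, 2, seed = 6)
  p_all <- predict_grass_probability(fit, d)
  expect_gt(mean(p_all[d$latent_g > 0.95]) - mean(p_all[d$latent_g == 0]), 0.5)
  expect_error(predict(fit, d[, 1:10]), "missing predictor")
})

test_that("component selection is capped and favors small models on ties", {
  # one perfectly separating predictor: AUC is 1 from the first component
  set.seed(7)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(sep = y * 10 + rnorm(n, sd = 0.01),
             matrix(rnorm(n * 5), n, 5))
  sel <- select_n_components(X, y, max_A = 6, k = 5, seed = 1)
  expect_equal(sel$A_star, 1L)
  expect_equal(max(sel$cv_auc), 1)
  # the cap of 30 components is enforced even if more are requested
  lab <- sim_modeling_data(25, 2, scheme = 1, seed = 8)
  sel2 <- select_n_components(lab[, trait_names()], lab$y,
                              max_A = 50, k = 5, seed = 1)
  expect_lte(sel2$A_star, 30L)
  expect_lte(length(sel2$cv_auc), 30L)
})

test_that("pure-noise predictors give chance-level cross-validated AUC", {
  set.seed(8)
  n <- 500
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rep(c(0L, 1L), each = n / 2)
  sel <- select_n_components(X, y, max_A = 10, k = 10, seed = 2)
  # held-out AUC under the null centers slightly below 0.5 (the usual
  # cross-validation pessimism), so the chance band is symmetric
  expect_gte(sel$cv_auc[sel$A_star], 0.40)
  expect_lte(sel$cv_auc[sel$A_star], 0.60)
})

test_that("VIP closed forms, normalization and permutation equivariance hold", {
  dsg <- make_vip_designs()
  fit_e1 <- fit_pls(dsg$X_e1, dsg$y, A = 1)
  vip_e1 <- compute_vip(fit_e1)
  expect_equal(vip_e1$vip, c(2, 0, 0, 0), tolerance = 1e-10)
  fit_sym <- fit_pls(dsg$X_sym, dsg$y, A = 1)
  vip_sym <- compute_vip(fit_sym)
  expect_equal(vip_sym$vip, rep(1, 4), tolerance = 1e-10)
  # normalization identity on an arbitrary multi-component fit
  lab <- sim_modeling_data(20, 2, scheme = 2, seed = 9)
  fit <- fit_pls(lab[, trait_names()], lab$y, A = 6)
  vip <- compute_vip(fit)
  expect_equal(mean(vip$vip^2), 1, tolerance = 1e-8)
  expect_equal(max(vip$vip_scaled), 100)
  # permuting predictor columns permutes the scores identically
  perm <- sample(trait_names())
  fit_p <- fit_pls(lab[, perm], lab$y, A = 6)
  vip_p <- compute_vip(fit_p)
  expect_equal(vip_p$vip[match(vip$predictor, vip_p$predictor)],
               vip$vip, tolerance = 1e-10)
})

test_that("VIP thresholding keeps boundaries and recovers signal traits", {
  lab <- sim_modeling_data(20, 2, scheme = 2, seed = 9)
  fit <- fit_pls(lab[, trait_names()], lab$y, A = 6)
  vip <- compute_vip(fit)
  expect_length(reduce_by_vip(vip, 0), 48L)
  at_max <- reduce_by_vip(vip, 100)
  expect_true(all(vip$vip_scaled[vip$predictor %in% at_max] == 100))
  expect_error(reduce_by_vip(vip, 101), "threshold")
  # schema with signal confined to 10 named traits
  schema <- null_trait_schema()
  signal <- c("c18_3_cis9_cis12_cis15", "c18_2_cis9_trans11", "omega3",
              "mcfa", "lcfa", "scfa", "milk_yield", "trans_fa",
              "c18_1_trans", "c17_0")
  schema$grass_multiplier[match(signal, schema$name)] <-
    default_trait_schema()$grass_multiplier[match(signal,
                                                  schema$name)]
  lab_s <- sim_modeling_data(40, 2, scheme = 1, seed = 10, schema = schema)
  fit_s <- fit_pls(lab_s[, trait_names()], lab_s$y, A = 5)
  kept <- reduce_by_vip(compute_vip(fit_s), 50)
  expect_true(all(signal %in% kept))
})

test_that("VIP-reduced refits do not beat the full predictor set on CV AUC", {
  # both fits saturate near AUC 1 on the default generator, so the loss
  # from discarding predictors is asserted pairwise per fold (same fold
  # assignment) within one standard error of the paired difference
  lab <- sim_modeling_data(100, 2, scheme = 1, seed = 12)
  X <- lab[, trait_names()]
  cv_full <- cross_validate_plsda(X, lab$y, A = 10, k = 10, seed = 3)
  fit <- fit_pls(X, lab$y, A = 10)
  kept <- reduce_by_vip(compute_vip(fit), 50)
  expect_lt(length(kept), 48L)
  cv_red <- cross_validate_plsda(X[, kept], lab$y, A = min(10, length(kept)),
                                 k = 10, seed = 3)
  delta <- cv_full$fold_metrics$auc - cv_red$fold_metrics$auc
  se <- stats::sd(delta) / sqrt(length(delta))
  expect_gte(mean(delta), -se)
})
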