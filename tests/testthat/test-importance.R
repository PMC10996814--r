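# Importance methods are validated on hand-constructed networks whose
# true attributions are known exactly (a feature the network provably
# ignores must score 0; a purely linear network makes integrated
# gradients analytic), plus integrity checks on a real trained model.

# A deterministic two-feature network that ignores its second feature:
# the second row of W1 is zeroed, batch-norm and dropout disabled.
make_lopsided_model <- function(k = 3) {
  cfg <- network_config(2, k, hidden_nodes = 4, dropout = 0,
                        batch_norm = FALSE, seed = 3)
  m <- build_network(cfg)
  m$W1[2, ] <- 0
  m
}

wrap_fm <- function(x, groups = NULL) {
  if (is.null(groups)) {
    groups <- stats::setNames(as.list(colnames(x)), colnames(x))
  }
  structure(list(x = x,
                 kind = stats::setNames(rep("continuous", ncol(x)),
                                        colnames(x)),
                 groups = groups, feature_set = "custom"),
            class = "feature_matrix")
}

test_that("permutation importance of an ignored feature is exactly zero", {
  set.seed(17)
  n <- 40
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("f1", "f2")))
  fm <- wrap_fm(x)
  m <- make_lopsided_model()
  grid <- make_time_grid(100, 3)
  d <- runif(n, 1, 99); e <- rbinom(n, 1, 0.7)
  for (metric in c("ibs", "c_index_td")) {
    imp <- suppressWarnings(permutation_importance(
      m, fm, d, e, grid, metric = metric, n_repeats = 5, seed = 1))
    expect_equal(imp$mean[imp$feature == "f2"], 0)
    expect_equal(imp$min[imp$feature == "f2"], 0)
    expect_equal(imp$max[imp$feature == "f2"], 0)
    # the active feature moves the metric on at least one shuffle
    expect_gt(abs(imp$mean[imp$feature == "f1"]) +
                abs(imp$max[imp$feature == "f1"]), 0)
  }
})

test_that("permutation importance shuffles one-hot blocks jointly", {
  toy <- train_toy_model(n = 60, seed = 51, max_epochs = 5, n_bins = 5)
  arm <- toy$arm
  imp <- suppressWarnings(permutation_importance(
    toy$model, arm$x_test, arm$durations_test, arm$events_test,
    arm$grid, metric = "ibs", n_repeats = 3, seed = 2))
  # one row per original feature, not per encoded column
  expect_setequal(imp$feature, names(arm$x_test$groups))
  expect_lt(nrow(imp), ncol(arm$x_test$x))
  # an all-zero encoded column contributes exactly nothing
  zero_grp <- list(`histology=Small Cell` = "histology=Small Cell")
  imp0 <- suppressWarnings(permutation_importance(
    toy$model, arm$x_test, arm$durations_test, arm$events_test,
    arm$grid, metric = "ibs", n_repeats = 3, seed = 2,
    groups = zero_grp))
  expect_equal(imp0$mean, 0)
  expect_equal(imp0$min, 0)
  expect_equal(attr(imp0, "metric"), "ibs")
  expect_true(is.finite(attr(imp0, "baseline")))
})

test_that("ablation is exact for ignored features and sums over bins", {
  set.seed(23)
  n <- 25
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("f1", "f2")))
  fm <- wrap_fm(x)
  m <- make_lopsided_model()
  lab <- data.frame(bin_index = sample(0:2, n, TRUE),
                    event = rbinom(n, 1, 0.6))
  ab <- feature_ablation(m, fm, labels = lab)
  expect_equal(ab$global[ab$feature == "f2"], 0)
  expect_equal(unname(attr(ab, "loss_delta")["f2"]), 0)
  loc <- attr(ab, "local")
  expect_equal(dim(loc), c(2, 3))
  expect_equal(ab$global, unname(rowSums(loc)), tolerance = 1e-12)
  # inputs already at the baseline value produce zero change everywhere
  fm0 <- wrap_fm(matrix(0, 5, 2, dimnames = list(NULL, c("f1", "f2"))))
  ab0 <- feature_ablation(m, fm0)
  expect_equal(ab0$global, c(0, 0))
})

test_that("integrated gradients are analytic for a linear network", {
  cfg <- network_config(3, 2, hidden_nodes = 4, dropout = 0,
                        batch_norm = FALSE, activation = "identity",
                        seed = 7)
  m <- build_network(cfg)
  # logit_o(x) = sum_f x_f * (W1 W2)[f, o] + const  =>  IG is exact
  W <- m$W1 %*% m$W2
  set.seed(41)
  x <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  fm <- wrap_fm(x)
  ig <- integrated_gradients(m, fm, baseline = 0, n_steps = 8)
  expect_lt(attr(ig, "completeness_error"), 1e-10)
  expected_local <- t(vapply(seq_len(3), function(f) {
    colMeans(x[, f] %o% W[f, ])
  }, numeric(2)))
  expect_equal(unname(attr(ig, "local")), unname(expected_local),
               tolerance = 1e-10)
  expect_equal(ig$global, unname(rowSums(expected_local)),
               tolerance = 1e-10)
  # inputs equal to the baseline get zero attribution
  fmb <- wrap_fm(matrix(0, 2, 3, dimnames = list(NULL, c("a", "b", "c"))))
  ig0 <- integrated_gradients(m, fmb, baseline = 0, n_steps = 4)
  expect_equal(ig0$global, c(0, 0, 0))
  expect_equal(ig0$global_abs, c(0, 0, 0))
})

test_that("integrated gradients satisfy completeness on a trained model", {
  toy <- train_toy_model(n = 60, seed = 52, max_epochs = 5, n_bins = 5)
  arm <- toy$arm
  sub <- arm$x_train
  sub$x <- sub$x[1:6, , drop = FALSE]
  # the midpoint Riemann sum converges at first order in n_steps (ReLU
  # kinks cap the rate), so the residual must shrink as steps increase
  ig_coarse <- suppressWarnings(integrated_gradients(toy$model, sub,
                                                     n_steps = 16))
  ig <- suppressWarnings(integrated_gradients(toy$model, sub,
                                              n_steps = 512))
  expect_lt(attr(ig, "completeness_error"),
            attr(ig_coarse, "completeness_error") + 1e-12)
  expect_lt(attr(ig, "completeness_error"), 0.02)
  expect_true(all(ig$global_abs >= abs(ig$global) - 1e-12))
  expect_equal(ig$global, unname(rowSums(attr(ig, "local"))),
               tolerance = 1e-10)
})

test_that("importance analyses leave the model and predictions untouched", {
  toy <- train_toy_model(n = 60, seed = 53, max_epochs = 5, n_bins = 5)
  arm <- toy$arm
  before <- predict_survival(toy$model, arm$x_test, arm$grid)
  invisible(suppressWarnings(permutation_importance(
    toy$model, arm$x_test, arm$durations_test, arm$events_test,
    arm$grid, metric = "inbll", n_repeats = 2, seed = 1)))
  invisible(feature_ablation(toy$model, arm$x_train, arm$labels_train))
  invisible(suppressWarnings(
    integrated_gradients(toy$model, arm$x_test, n_steps = 16)))
  after <- predict_survival(toy$model, arm$x_test, arm$grid)
  expect_identical(before$survival, after$survival)
})

test_that("rank_report orders features and measures method agreement", {
  t1 <- data.frame(feature = c("a", "b", "c"), global = c(3, -2, 0.5))
  t2 <- data.frame(feature = c("a", "b", "c"), global = c(0.1, 1, 9))
  class(t1) <- class(t2) <- c("importance_table", "data.frame")
  rr <- rank_report(list(m1 = t1, m2 = t2))
  expect_equal(rr$ranks["a", "m1"], 1)
  expect_equal(rr$ranks["b", "m1"], 2)
  expect_equal(rr$ranks["c", "m2"], 1)
  expect_equal(unname(rr$agreement["m1", "m1"]), 1)
  # perfectly reversed orders give Spearman -1
  expect_equal(unname(rr$agreement["m1", "m2"]), -1)
  same <- rank_report(list(x = t1, y = t1))
  expect_equal(unname(same$agreement["x", "y"]), 1)
  expect_error(rank_report(list()), "at least one")
})
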