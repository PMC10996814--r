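test_that("hidden-layer width defaults to the floored mean of in/out widths", {
  expect_equal(network_config(31, 20)$hidden_nodes, 25L)
  expect_equal(network_config(3, 20)$hidden_nodes, 11L)
  expect_equal(network_config(28, 20)$hidden_nodes, 24L)
})

test_that("loss matches hand-computed single-patient cases", {
  g <- list(bin_index = 0L, event = 1L)
  lab1 <- data.frame(bin_index = 0L, event = 1L)
  expect_equal(logistic_hazard_loss(matrix(0.5, 1, 1), lab1), -log(0.5))
  lab2 <- data.frame(bin_index = 1L, event = 0L)
  expect_equal(logistic_hazard_loss(matrix(0.5, 1, 2), lab2),
               -2 * log(0.5))
})

test_that("loss equals the expanded binary cross-entropy oracle", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(2:10, 1); k <- sample(2:5, 1)
    h <- matrix(runif(n * k, 0.01, 0.99), n, k)
    lab <- data.frame(bin_index = sample(0:(k - 1), n, TRUE),
                      event = rbinom(n, 1, 0.6))
    expect_equal(logistic_hazard_loss(h, lab), loss_oracle(h, lab),
                 tolerance = 1e-12)
  }
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(5)
  n <- 6; p <- 4; k <- 4
  cfg <- network_config(p, k, hidden_nodes = 3, dropout = 0,
                        batch_norm = TRUE, seed = 2)
  model <- build_network(cfg)
  x <- matrix(rnorm(n * p), n, p)
  lab <- data.frame(bin_index = sample(0:(k - 1), n, TRUE),
                    event = rbinom(n, 1, 0.7))
  fw <- hybridsurv:::.forward(model, x, training = TRUE)
  dlog <- hybridsurv:::.loss_grad_logits(fw$hazards, lab)
  grads <- hybridsurv:::.backward(model, x, fw, dlog)
  loss_at <- function(m) {
    f <- hybridsurv:::.forward(m, x, training = TRUE)
    logistic_hazard_loss(f$hazards, lab)
  }
  eps <- 1e-6
  for (nm in c("W1", "b1", "gamma", "beta", "W2", "b2")) {
    par <- model[[nm]]
    idx <- seq_len(min(length(par), 5))
    for (ii in idx) {
      mp <- model; mp[[nm]][ii] <- par[ii] + eps
      mm <- model; mm[[nm]][ii] <- par[ii] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(grads[[nm]][ii], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, ii))
    }
  }
})

test_that("initialization and training are deterministic under a seed", {
  cfg <- network_config(5, 4, seed = 9)
  m1 <- build_network(cfg); m2 <- build_network(cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  m3 <- build_network(network_config(5, 4, seed = 10))
  expect_false(identical(m1$W1, m3$W1))

  set.seed(77)
  n <- 40; p <- 5; k <- 4
  x <- matrix(rnorm(n * p), n, p)
  lab <- data.frame(bin_index = sample(0:(k - 1), n, TRUE),
                    event = rbinom(n, 1, 0.7))
  cfg <- network_config(p, k, max_epochs = 15, seed = 3, batch_size = 16)
  t1 <- train_hazard_net(build_network(cfg), x[1:30, ], lab[1:30, ],
                         x[31:40, ], lab[31:40, ])
  t2 <- train_hazard_net(build_network(cfg), x[1:30, ], lab[1:30, ],
                         x[31:40, ], lab[31:40, ])
  expect_identical(t1$log, t2$log)
  expect_identical(t1$W1, t2$W1)
})

test_that("early stopping restores the best epoch and honors patience 0", {
  set.seed(12)
  n <- 30; p <- 4; k <- 3
  x <- matrix(rnorm(n * p), n, p)
  lab <- data.frame(bin_index = sample(0:(k - 1), n, TRUE),
                    event = rbinom(n, 1, 0.7))
  cfg <- network_config(p, k, max_epochs = 100, patience = 0, seed = 4,
                        batch_size = 10)
  m <- train_hazard_net(build_network(cfg), x[1:20, ], lab[1:20, ],
                        x[21:30, ], lab[21:30, ])
  lg <- m$log
  # stopped at the first epoch whose validation loss failed to improve
  expect_equal(nrow(lg), m$best_epoch + 1)
  expect_equal(which.min(lg$val_loss), m$best_epoch)
  # restored weights reproduce the best-epoch validation loss
  val_pred <- hybridsurv:::.forward(m, x[21:30, ], training = FALSE)$hazards
  expect_equal(logistic_hazard_loss(val_pred, lab[21:30, ]),
               min(lg$val_loss), tolerance = 1e-12)
})

test_that("a separable toy problem trains to near the entropy floor", {
  # one binary feature fully determines an event in bin 0 vs censoring
  # in the last bin; the achievable validation loss is ~0
  set.seed(8)
  n <- 80
  xf <- rep(c(0, 1), each = n / 2)
  x <- cbind(xf, rnorm(n, 0, 0.01))
  lab <- data.frame(bin_index = ifelse(xf == 1, 0L, 2L),
                    event = as.integer(xf == 1))
  idx_tr <- c(1:30, 41:70); idx_va <- c(31:40, 71:80)
  cfg <- network_config(2, 3, max_epochs = 300, patience = 30,
                        learning_rate = 0.05, dropout = 0, seed = 6,
                        batch_size = 20)
  m <- train_hazard_net(build_network(cfg), x[idx_tr, ], lab[idx_tr, ],
                        x[idx_va, ], lab[idx_va, ])
  expect_lt(m$best_val_loss, 0.05)
})

test_that("survival assembly is a cumulative product with S(0) = 1", {
  grid <- make_time_grid(100, 2)
  pred <- make_prediction(matrix(c(0.1, 0.2), 1, 2), grid$edges)
  expect_equal(as.numeric(pred$survival), c(0.9, 0.72))
  pred0 <- make_prediction(matrix(0, 2, 2), grid$edges)
  expect_true(all(pred0$survival == 1))
  expect_equal(as.numeric(surv_at(pred, 0)), 1)
  # right-continuous step evaluation with (left-open, right-closed] bins
  expect_equal(as.numeric(surv_at(pred, 50)), 0.9)
  expect_equal(as.numeric(surv_at(pred, 50.1)), 0.72)
  expect_equal(as.numeric(surv_at(pred, 1e4)), 0.72)
})

test_that("predicted survival is monotone non-increasing on a real run", {
  toy <- train_toy_model(n = 80, seed = 21, max_epochs = 20)
  pred <- predict_survival(toy$model, toy$arm$x_test, toy$arm$grid)
  expect_true(all(pred$hazards > 0 & pred$hazards < 1))
  expect_true(all(apply(pred$survival, 1, function(s) all(diff(s) <= 0))))
  expect_true(all(pred$survival > 0 & pred$survival <= 1))
  # S consistent with h
  recon <- t(apply(1 - pred$hazards, 1, cumprod))
  expect_equal(pred$survival, recon, tolerance = 1e-12)
  expect_error(predict_survival(toy$model, toy$arm$x_test$x[, 1:3],
                                toy$arm$grid), "mismatch")
})

test_that("checkpoints round-trip to bit-identical predictions", {
  toy <- train_toy_model(n = 60, seed = 33, max_epochs = 10)
  path <- tempfile(fileext = ".json")
  save_checkpoint(toy$model, path, scaler = toy$arm$scaler,
                  grid = toy$arm$grid)
  loaded <- load_checkpoint(path)
  p1 <- predict_survival(toy$model, toy$arm$x_test, toy$arm$grid)
  p2 <- predict_survival(loaded$model, toy$arm$x_test, loaded$grid)
  expect_identical(p1$survival, p2$survival)
  expect_identical(loaded$scaler$center, toy$arm$scaler$center)
  unlink(path)
})

test_that("random search is seeded, respects the budget and picks the argmin", {
  toy <- train_toy_model(n = 60, seed = 44, max_epochs = 8, n_bins = 5)
  arm <- toy$arm
  fd <- list(list(x_train = arm$x_train, labels_train = arm$labels_train,
                  x_val = arm$x_val, labels_val = arm$labels_val,
                  durations_val = arm$durations_val,
                  events_val = arm$events_val, grid = arm$grid))
  base <- network_config(ncol(arm$x_train$x), 5, max_epochs = 8,
                         seed = 1, batch_size = 30)
  space <- list(learning_rate = c(0.01, 0.1), dropout = c(0, 0.4))
  r1 <- random_search_hyperparameters(space, fd, base, budget = 3, seed = 2)
  r2 <- random_search_hyperparameters(space, fd, base, budget = 3, seed = 2)
  expect_identical(r1$trials, r2$trials)
  expect_equal(nrow(r1$trials), 3)
  expect_equal(r1$best_score, min(r1$trials$score))
  one <- random_search_hyperparameters(space, fd, base, budget = 1, seed = 5)
  expect_equal(nrow(one$trials), 1)
  expect_equal(one$best_score, one$trials$score)
})
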