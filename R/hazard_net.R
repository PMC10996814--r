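# Discrete-time logistic-hazard survival network.
#
# A single-hidden-layer multilayer perceptron maps the encoded feature
# vector to one conditional event probability (hazard) per time bin:
#   x -> affine -> batch-norm -> ReLU -> dropout -> affine -> sigmoid
# Training minimizes the right-censored discrete-hazard negative
# log-likelihood by Adam with early stopping on the validation loss.
# The forward pass, backpropagation and optimizer are implemented in
# base R matrix code so the whole pipeline is dependency-free and
# deterministic under a seed.

.HAZ_EPS <- 1e-7

#' Network configuration
#'
#' Defaults follow the study settings: a single hidden layer whose width
#' is the floor of the arithmetic mean of input and output widths,
#' dropout 0.2, learning rate 0.07, batch size 50 (capped at the
#' training-set size), at most 512 epochs, batch normalization on.
#'
#' @param n_features Number of encoded input features.
#' @param n_bins Number of discrete time bins (default 20).
#' @param hidden_nodes Hidden-layer width; default
#'   `floor((n_features + n_bins) / 2)`.
#' @param dropout Dropout fraction in `[0, 1)`.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size (effective size is
#'   `min(batch_size, n_train)`).
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience in epochs; training stops
#'   once the validation loss has not improved for more than `patience`
#'   consecutive epochs, and the best-epoch weights are restored.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @param batch_norm Use batch normalization after the first affine map.
#' @param activation Hidden activation; `"relu"` (default) or
#'   `"identity"` (useful for analytical checks).
#' @return A `network_config` list.
#' @export
network_config <- function(n_features, n_bins = 20L, hidden_nodes = NULL,
                           dropout = 0.2, learning_rate = 0.07,
                           batch_size = 50L, max_epochs = 512L,
                           patience = 10L, seed = 1L, batch_norm = TRUE,
                           activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (is.null(hidden_nodes)) {
    hidden_nodes <- floor((n_features + n_bins) / 2)
  }
  stopifnot(dropout >= 0, dropout < 1, n_bins >= 1, hidden_nodes >= 1)
  structure(list(
    n_features = as.integer(n_features), n_bins = as.integer(n_bins),
    hidden_nodes = as.integer(hidden_nodes), dropout = dropout,
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    seed = as.integer(seed), batch_norm = isTRUE(batch_norm),
    activation = activation
  ), class = "network_config")
}

#' Build an untrained hazard network
#'
#' Weights use Glorot-uniform initialization seeded deterministically
#' from the config.
#'
#' @param config A [network_config()].
#' @return A `hazard_net` model state.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  p <- config$n_features; h <- config$hidden_nodes; k <- config$n_bins
  lim1 <- sqrt(6 / (p + h)); lim2 <- sqrt(6 / (h + k))
  w <- with_seed(derive_seed(config$seed, "init"), {
    list(W1 = matrix(stats::runif(p * h, -lim1, lim1), p, h),
         W2 = matrix(stats::runif(h * k, -lim2, lim2), h, k))
  })
  structure(list(
    config = config,
    W1 = w$W1, b1 = rep(0, h),
    gamma = rep(1, h), beta = rep(0, h),
    running_mean = rep(0, h), running_var = rep(1, h),
    W2 = w$W2, b2 = rep(0, k),
    trained = FALSE, log = NULL
  ), class = "hazard_net")
}

# Forward pass. training = TRUE uses batch statistics and dropout and
# returns the intermediates needed for backprop; training = FALSE uses
# the running batch-norm statistics with dropout off.
.forward <- function(model, x, training = FALSE, dropout_mask = NULL) {
  cfg <- model$config
  z1 <- sweep(x %*% model$W1, 2, model$b1, "+")
  eps <- 1e-5
  if (cfg$batch_norm) {
    if (training) {
      bm <- colMeans(z1)
      bv <- colMeans(sweep(z1, 2, bm)^2)
    } else {
      bm <- model$running_mean
      bv <- model$running_var
    }
    inv_std <- 1 / sqrt(bv + eps)
    z1h <- sweep(sweep(z1, 2, bm), 2, inv_std, "*")
    z1b <- sweep(sweep(z1h, 2, model$gamma, "*"), 2, model$beta, "+")
  } else {
    bm <- bv <- inv_std <- NULL
    z1h <- NULL
    z1b <- z1
  }
  a <- if (cfg$activation == "relu") pmax(z1b, 0) else z1b
  if (training && cfg$dropout > 0) {
    if (is.null(dropout_mask)) {
      keep <- 1 - cfg$dropout
      dropout_mask <- matrix(
        stats::rbinom(length(a), 1, keep) / keep, nrow(a), ncol(a))
    }
    ad <- a * dropout_mask
  } else {
    dropout_mask <- NULL
    ad <- a
  }
  logits <- sweep(ad %*% model$W2, 2, model$b2, "+")
  hazards <- stats::plogis(logits)
  list(hazards = hazards, logits = logits, z1 = z1, z1h = z1h, z1b = z1b,
       a = a, ad = ad, bm = bm, bv = bv, inv_std = inv_std,
       dropout_mask = dropout_mask)
}

# Expand discrete labels into the (target, mask) matrices of the
# likelihood: mask[i, j] = 1 for bins j <= k_i (0-based k_i), target is
# 1 only at (i, k_i) when the event occurred.
.label_matrices <- function(labels, n_bins) {
  n <- nrow(labels)
  k1 <- labels$bin_index + 1L
  mask <- matrix(0, n, n_bins)
  target <- matrix(0, n, n_bins)
  for (i in seq_len(n)) mask[i, seq_len(k1[i])] <- 1
  target[cbind(seq_len(n), k1)] <- labels$event
  list(mask = mask, target = target)
}

#' Negative log-likelihood of the discrete hazard model
#'
#' For patient `i` with event/censoring bin `k_i` and event indicator
#' `delta_i`, the contribution is
#' `-[ sum_{j<k_i} log(1 - h_ij) + delta_i log h_{i k_i} +
#'     (1 - delta_i) log(1 - h_{i k_i}) ]`;
#' the loss is the mean over patients. This equals binary cross-entropy
#' over per-interval expanded (patient, bin) rows up to and including
#' bin `k_i`. Hazards are clipped to `[1e-7, 1 - 1e-7]` before logs.
#'
#' @param hazards Matrix (patients x bins) of per-bin hazards.
#' @param labels Data frame with 0-based `bin_index` and `event`
#'   (from [discretize()]).
#' @return Non-negative scalar loss.
#' @export
logistic_hazard_loss <- function(hazards, labels) {
  h <- pmin(pmax(hazards, .HAZ_EPS), 1 - .HAZ_EPS)
  lm_ <- .label_matrices(labels, ncol(h))
  ll <- lm_$mask * (lm_$target * log(h) + (1 - lm_$target) * log(1 - h))
  -mean(rowSums(ll))
}

# Gradient of the mean NLL with respect to the logits.
.loss_grad_logits <- function(hazards, labels) {
  lm_ <- .label_matrices(labels, ncol(hazards))
  lm_$mask * (hazards - lm_$target) / nrow(hazards)
}

# One backward pass; returns gradients for all trainable parameters.
.backward <- function(model, x, fw, dlogits) {
  cfg <- model$config
  g <- list()
  g$W2 <- t(fw$ad) %*% dlogits
  g$b2 <- colSums(dlogits)
  dad <- dlogits %*% t(model$W2)
  da <- if (!is.null(fw$dropout_mask)) dad * fw$dropout_mask else dad
  dz1b <- if (cfg$activation == "relu") da * (fw$z1b > 0) else da
  if (cfg$batch_norm) {
    n <- nrow(x)
    g$gamma <- colSums(dz1b * fw$z1h)
    g$beta <- colSums(dz1b)
    dz1h <- sweep(dz1b, 2, model$gamma, "*")
    s1 <- colSums(dz1h)
    s2 <- colSums(dz1h * fw$z1h)
    dz1 <- sweep(
      n * dz1h - matrix(s1, n, length(s1), byrow = TRUE) -
        fw$z1h * matrix(s2, n, length(s2), byrow = TRUE),
      2, fw$inv_std / n, "*")
  } else {
    g$gamma <- NULL; g$beta <- NULL
    dz1 <- dz1b
  }
  g$W1 <- t(x) %*% dz1
  g$b1 <- colSums(dz1)
  g
}

.adam_init <- function(model) {
  par_names <- c("W1", "b1", "W2", "b2",
                 if (model$config$batch_norm) c("gamma", "beta"))
  st <- list(t = 0, m = list(), v = list(), names = par_names)
  for (nm in par_names) {
    st$m[[nm]] <- model[[nm]] * 0
    st$v[[nm]] <- model[[nm]] * 0
  }
  st
}

.adam_step <- function(model, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in st$names) {
    gg <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gg
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gg^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    model[[nm]] <- model[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(model = model, state = st)
}

#' Train a hazard network
#'
#' Adam on mini-batches with per-epoch validation-loss early stopping;
#' the weights from the best validation epoch are restored. All random
#' draws (shuffling, dropout) come from a stream derived from the
#' config seed, so identical seeds and data give identical training
#' logs.
#'
#' @param model An untrained `hazard_net` from [build_network()].
#' @param x_train,x_val Scaled feature matrices (plain numeric matrices
#'   or `feature_matrix` objects).
#' @param labels_train,labels_val Discrete labels from [discretize()].
#' @return The trained model; `model$log` holds a data frame of
#'   per-epoch train/validation loss, `model$best_epoch` the restored
#'   epoch.
#' @export
train_hazard_net <- function(model, x_train, labels_train, x_val,
                             labels_val) {
  stopifnot(inherits(model, "hazard_net"))
  x_train <- .as_matrix(x_train); x_val <- .as_matrix(x_val)
  cfg <- model$config
  if (ncol(x_train) != cfg$n_features) {
    stop("feature count mismatch with network config", call. = FALSE)
  }
  n <- nrow(x_train)
  bs <- min(cfg$batch_size, n)
  adam <- .adam_init(model)
  bn_momentum <- 0.1

  best_val <- Inf; best_model <- model; best_epoch <- 0L
  epochs_since <- 0L
  log_rows <- vector("list", cfg$max_epochs)

  with_seed(derive_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      n_batches <- ceiling(n / bs)
      for (b in seq_len(n_batches)) {
        idx <- perm[((b - 1) * bs + 1):min(b * bs, n)]
        if (length(idx) < 2 && cfg$batch_norm) next  # BN needs >= 2 rows
        xb <- x_train[idx, , drop = FALSE]
        lb <- labels_train[idx, , drop = FALSE]
        fw <- .forward(model, xb, training = TRUE)
        if (any(!is.finite(fw$logits))) {
          stop("training diverged: non-finite logits", call. = FALSE)
        }
        if (cfg$batch_norm) {
          model$running_mean <- (1 - bn_momentum) * model$running_mean +
            bn_momentum * fw$bm
          model$running_var <- (1 - bn_momentum) * model$running_var +
            bn_momentum * fw$bv
        }
        dlog <- .loss_grad_logits(fw$hazards, lb)
        grads <- .backward(model, xb, fw, dlog)
        upd <- .adam_step(model, grads, adam, cfg$learning_rate)
        model <- upd$model; adam <- upd$state
      }
      train_loss <- logistic_hazard_loss(
        .forward(model, x_train, training = FALSE)$hazards, labels_train)
      val_loss <- logistic_hazard_loss(
        .forward(model, x_val, training = FALSE)$hazards, labels_val)
      if (!is.finite(train_loss) || !is.finite(val_loss)) {
        stop("training diverged: non-finite loss", call. = FALSE)
      }
      log_rows[[epoch]] <- data.frame(epoch = epoch,
                                      train_loss = train_loss,
                                      val_loss = val_loss)
      if (val_loss < best_val) {
        best_val <- val_loss; best_model <- model; best_epoch <- epoch
        epochs_since <- 0L
      } else {
        epochs_since <- epochs_since + 1L
        if (epochs_since > cfg$patience) break
      }
    }
  })

  out <- best_model
  out$trained <- TRUE
  out$log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  out$best_epoch <- best_epoch
  out$best_val_loss <- best_val
  out
}

.as_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) x$x else as.matrix(x)
}

#' Predict per-bin hazards and survival curves
#'
#' Runs the network in evaluation mode (running batch-norm statistics,
#' dropout off) and assembles step survival curves as the cumulative
#' product of one minus the hazards; `S(0) = 1`.
#'
#' @param model A trained `hazard_net`.
#' @param x Feature matrix scaled with the training scaler.
#' @param grid The `time_grid` used for training labels.
#' @return A `discrete_survival_prediction`: list with `grid`, `hazards`
#'   (patients x bins) and `survival` (patients x bins,
#'   `S[i,k] = prod_{j<=k} (1 - h[i,j])`).
#' @export
predict_survival <- function(model, x, grid) {
  stopifnot(inherits(model, "hazard_net"), inherits(grid, "time_grid"))
  x <- .as_matrix(x)
  if (ncol(x) != model$config$n_features) {
    stop("feature count mismatch with network config", call. = FALSE)
  }
  if (grid$n_bins != model$config$n_bins) {
    stop("grid bin count mismatch with network config", call. = FALSE)
  }
  h <- .forward(model, x, training = FALSE)$hazards
  s <- t(apply(1 - h, 1, cumprod))
  if (nrow(h) == 1) s <- matrix(s, nrow = 1)
  structure(list(grid = grid, hazards = h, survival = s),
            class = "discrete_survival_prediction")
}

#' Evaluate step survival curves at arbitrary times
#'
#' The curve is right-continuous between grid edges with the same
#' left-open, right-closed bin convention as [discretize()]:
#' `S(t) = S[, k]` for `t` in `(edges[k], edges[k+1]]`, `S(0) = 1`, and
#' times past the grid take the final value.
#'
#' @param prediction A `discrete_survival_prediction`.
#' @param times Evaluation times (days).
#' @return Matrix (patients x times) of survival probabilities.
#' @export
surv_at <- function(prediction, times) {
  stopifnot(inherits(prediction, "discrete_survival_prediction"))
  edges <- prediction$grid$edges
  s <- prediction$survival
  sapply(times, function(t) {
    if (t <= edges[1]) return(rep(1, nrow(s)))
    k <- sum(edges[-1] < t) + 1L   # 1-based bin containing t
    k <- min(k, ncol(s))
    s[, k]
  })
}

#' Save a trained network checkpoint
#'
#' Writes a self-describing JSON archive of the weights, configuration,
#' and (optionally) scaler state, time grid and feature schema. Doubles
#' are serialized with 17 significant digits so a load reproduces
#' bit-identical predictions.
#'
#' @param model A `hazard_net`.
#' @param path Output file path.
#' @param scaler,grid,feature_names Optional companions to embed.
#' @export
save_checkpoint <- function(model, path, scaler = NULL, grid = NULL,
                            feature_names = NULL) {
  stopifnot(inherits(model, "hazard_net"))
  num <- function(x) .num_to_chr(as.numeric(x))
  payload <- list(
    format = "hybridsurv-checkpoint-1",
    config = model$config[setdiff(names(model$config), NULL)],
    dims = list(W1 = dim(model$W1), W2 = dim(model$W2)),
    weights = list(
      W1 = num(model$W1), b1 = num(model$b1),
      gamma = num(model$gamma), beta = num(model$beta),
      running_mean = num(model$running_mean),
      running_var = num(model$running_var),
      W2 = num(model$W2), b2 = num(model$b2)
    ),
    trained = model$trained,
    best_epoch = model$best_epoch
  )
  if (!is.null(scaler)) {
    payload$scaler <- list(columns = scaler$columns,
                           center = num(scaler$center),
                           scale = num(scaler$scale))
  }
  if (!is.null(grid)) {
    payload$grid <- list(n_bins = grid$n_bins, edges = num(grid$edges))
  }
  if (!is.null(feature_names)) payload$feature_names <- feature_names
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return List with `model` and, when present, `scaler`, `grid`,
#'   `feature_names`.
#' @export
load_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "hybridsurv-checkpoint-1")) {
    stop("not a hybridsurv checkpoint", call. = FALSE)
  }
  cfg <- do.call(network_config, p$config[c(
    "n_features", "n_bins", "hidden_nodes", "dropout", "learning_rate",
    "batch_size", "max_epochs", "patience", "seed", "batch_norm",
    "activation")])
  num <- function(x) as.numeric(x)
  model <- structure(list(
    config = cfg,
    W1 = matrix(num(p$weights$W1), p$dims$W1[1], p$dims$W1[2]),
    b1 = num(p$weights$b1),
    gamma = num(p$weights$gamma), beta = num(p$weights$beta),
    running_mean = num(p$weights$running_mean),
    running_var = num(p$weights$running_var),
    W2 = matrix(num(p$weights$W2), p$dims$W2[1], p$dims$W2[2]),
    b2 = num(p$weights$b2),
    trained = isTRUE(p$trained),
    best_epoch = p$best_epoch, log = NULL
  ), class = "hazard_net")
  out <- list(model = model)
  if (!is.null(p$scaler)) {
    out$scaler <- structure(list(
      columns = p$scaler$columns,
      center = stats::setNames(num(p$scaler$center), p$scaler$columns),
      scale = stats::setNames(num(p$scaler$scale), p$scaler$columns)
    ), class = "feature_scaler")
  }
  if (!is.null(p$grid)) {
    out$grid <- structure(list(n_bins = as.integer(p$grid$n_bins),
                               edges = num(p$grid$edges)),
                          class = "time_grid")
  }
  if (!is.null(p$feature_names)) out$feature_names <- p$feature_names
  out
}

#' Randomized hyperparameter search over cross-validation folds
#'
#' Samples configurations uniformly from the declared space, trains on
#' each supplied fold, and returns the configuration minimizing the
#' mean metric (default the integrated IPCW Brier score on the fold's
#' validation set).
#'
#' @param space Named list of ranges: `learning_rate`, `dropout`
#'   (continuous `c(lo, hi)`), `batch_size`, `patience` (integer
#'   `c(lo, hi)`). Omitted entries keep the base config value.
#' @param fold_data List of folds, each a list with `x_train`,
#'   `labels_train`, `x_val`, `labels_val`, `durations_val`,
#'   `events_val`, `grid`.
#' @param base_config A [network_config()] supplying fixed fields.
#' @param metric `"ibs"`, `"inbll"` or `"val_loss"` (minimized).
#' @param budget Number of sampled configurations (>= 1).
#' @param seed Seed for the sampling sequence.
#' @return List with `best_config`, `best_score` and the full `trials`
#'   data frame.
#' @export
random_search_hyperparameters <- function(space, fold_data, base_config,
                                          metric = c("ibs", "inbll",
                                                     "val_loss"),
                                          budget = 10L, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(budget >= 1)
  draws <- with_seed(derive_seed(seed, "hpsearch"), {
    lapply(seq_len(budget), function(i) {
      d <- list()
      if (!is.null(space$learning_rate)) {
        d$learning_rate <- stats::runif(1, space$learning_rate[1],
                                        space$learning_rate[2])
      }
      if (!is.null(space$dropout)) {
        d$dropout <- stats::runif(1, space$dropout[1], space$dropout[2])
      }
      if (!is.null(space$batch_size)) {
        d$batch_size <- sample(space$batch_size[1]:space$batch_size[2], 1)
      }
      if (!is.null(space$patience)) {
        d$patience <- sample(space$patience[1]:space$patience[2], 1)
      }
      d
    })
  })
  trials <- vector("list", budget)
  scores <- numeric(budget)
  for (i in seq_len(budget)) {
    cfg <- base_config
    for (nm in names(draws[[i]])) cfg[[nm]] <- draws[[i]][[nm]]
    fold_scores <- vapply(fold_data, function(fd) {
      m <- train_hazard_net(build_network(cfg), fd$x_train,
                            fd$labels_train, fd$x_val, fd$labels_val)
      if (metric == "val_loss") return(m$best_val_loss)
      pred <- predict_survival(m, fd$x_val, fd$grid)
      rep_ <- metric_report(pred, fd$durations_val, fd$events_val)
      if (metric == "ibs") rep_$ibs else rep_$inbll
    }, numeric(1))
    scores[i] <- mean(fold_scores)
    trials[[i]] <- data.frame(
      trial = i,
      learning_rate = cfg$learning_rate, dropout = cfg$dropout,
      batch_size = cfg$batch_size, patience = cfg$patience,
      score = scores[i]
    )
  }
  best <- which.min(scores)
  cfg <- base_config
  for (nm in names(draws[[best]])) cfg[[nm]] <- draws[[best]][[nm]]
  list(best_config = cfg, best_score = scores[best],
       trials = do.call(rbind, trials))
}
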