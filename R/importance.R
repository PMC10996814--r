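# Feature-importance analysis of a trained hazard network:
# permutation importance against the accuracy metrics (test set),
# feature ablation, and integrated gradients on the pre-sigmoid logits
# (training set). One-hot groups are treated as blocks so each original
# feature gets one importance; the per-level view remains available by
# passing per-column groups.

#' Permutation feature importance against an accuracy metric
#'
#' For each feature group, the group's rows are shuffled (jointly for
#' one-hot blocks) and the chosen metric recomputed; importance is the
#' signed metric change oriented so that larger means more important
#' (`permuted - baseline` for the error metrics IBS/INBLL,
#' `baseline - permuted` for the concordance index).
#'
#' @param model Trained `hazard_net`.
#' @param x Scaled `feature_matrix` of the evaluation (test) set.
#' @param durations,events Observed outcomes for the same rows.
#' @param grid The training `time_grid`.
#' @param metric One of `"ibs"`, `"inbll"`, `"c_index_td"`.
#' @param n_repeats Shuffles per feature (default 20; fewer than 2
#'   leaves the spread undefined, with a warning).
#' @param seed Seed for the shuffles.
#' @param groups Named list mapping feature names to column names;
#'   default: the encoding groups stored in `x`.
#' @return An `importance_table` data frame with one row per feature:
#'   `mean`, `q1`, `q3`, `min`, `max`, `n_repeats`, plus attributes
#'   `method`, `metric`, `baseline`.
#' @export
permutation_importance <- function(model, x, durations, events, grid,
                                   metric = c("ibs", "inbll",
                                              "c_index_td"),
                                   n_repeats = 20L, seed = 1L,
                                   groups = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(x, "feature_matrix"))
  if (n_repeats < 2) {
    warning("n_repeats < 2: importance spread is undefined", call. = FALSE)
  }
  if (is.null(groups)) groups <- x$groups
  xm <- x$x
  score <- function(mat) {
    pred <- predict_survival(model, mat, grid)
    switch(metric,
           ibs = integrate_over_time(
             as.numeric(suppressWarnings(
               brier_ipcw(pred, durations, events))), eval_grid(grid)),
           inbll = integrate_over_time(
             as.numeric(suppressWarnings(
               nbll_ipcw(pred, durations, events))), eval_grid(grid)),
           c_index_td = concordance_td(pred, durations, events))
  }
  baseline <- score(xm)
  n <- nrow(xm)
  perms <- with_seed(derive_seed(seed, "perm_importance"), {
    lapply(seq_len(max(n_repeats, 1)), function(r) sample.int(n))
  })
  rows <- lapply(names(groups), function(g) {
    cols <- groups[[g]]
    deltas <- vapply(perms, function(p) {
      xp <- xm
      xp[, cols] <- xm[p, cols, drop = FALSE]
      s <- score(xp)
      if (metric == "c_index_td") baseline - s else s - baseline
    }, numeric(1))
    qs <- stats::quantile(deltas, c(0.25, 0.75), names = FALSE)
    data.frame(feature = g, mean = mean(deltas), q1 = qs[1], q2 = qs[2],
               min = min(deltas), max = max(deltas),
               n_repeats = length(deltas), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "q2"] <- "q3"
  attr(out, "method") <- "permutation"
  attr(out, "metric") <- metric
  attr(out, "baseline") <- baseline
  class(out) <- c("importance_table", class(out))
  out
}

#' Feature ablation importance
#'
#' Replaces each feature group with a baseline value (0 = the training
#' mean for scaled continuous columns) and records, per output bin, the
#' change in the model's mean predicted hazard; the global importance
#' is the sum over bins. The change in training loss is recorded as
#' well when labels are supplied.
#'
#' @param model Trained `hazard_net`.
#' @param x Scaled `feature_matrix`.
#' @param labels Optional discrete labels for the loss change.
#' @param baseline_value Replacement value (default 0).
#' @param groups Feature-to-column mapping; default from `x`.
#' @return An `importance_table` with `global` per feature and
#'   attributes `local` (feature x bin matrix of mean-hazard changes),
#'   `loss_delta`, `method`.
#' @export
feature_ablation <- function(model, x, labels = NULL, baseline_value = 0,
                             groups = NULL) {
  stopifnot(inherits(x, "feature_matrix"))
  if (is.null(groups)) groups <- x$groups
  xm <- x$x
  h0 <- .forward(model, xm, training = FALSE)$hazards
  base_mean <- colMeans(h0)
  base_loss <- if (!is.null(labels)) logistic_hazard_loss(h0, labels) else NA
  local <- matrix(NA_real_, length(groups), model$config$n_bins,
                  dimnames = list(names(groups), NULL))
  loss_delta <- stats::setNames(rep(NA_real_, length(groups)),
                                names(groups))
  for (g in names(groups)) {
    xa <- xm
    xa[, groups[[g]]] <- baseline_value
    ha <- .forward(model, xa, training = FALSE)$hazards
    local[g, ] <- base_mean - colMeans(ha)
    if (!is.null(labels)) {
      loss_delta[g] <- logistic_hazard_loss(ha, labels) - base_loss
    }
  }
  out <- data.frame(feature = names(groups), global = rowSums(local),
                    stringsAsFactors = FALSE)
  attr(out, "local") <- local
  attr(out, "loss_delta") <- loss_delta
  attr(out, "method") <- "ablation"
  class(out) <- c("importance_table", class(out))
  out
}

# Gradient of each pre-sigmoid output logit with respect to the inputs,
# in evaluation mode (dropout off, batch-norm frozen at the running
# statistics). Returns an n_features x n_bins matrix per sample.
.logit_input_grad <- function(model, x_row) {
  cfg <- model$config
  z1 <- as.numeric(x_row %*% model$W1) + model$b1
  if (cfg$batch_norm) {
    inv_std <- 1 / sqrt(model$running_var + 1e-5)
    scale <- model$gamma * inv_std
    z1b <- scale * (z1 - model$running_mean) + model$beta
  } else {
    scale <- rep(1, length(z1))
    z1b <- z1
  }
  act_grad <- if (cfg$activation == "relu") as.numeric(z1b > 0) else
    rep(1, length(z1b))
  # d logit_o / d x_f = sum_h W1[f,h] * scale[h] * act'[h] * W2[h,o]
  model$W1 %*% (model$W2 * (scale * act_grad))
}

#' Integrated gradients attribution
#'
#' Path-integral attribution of each pre-sigmoid bin logit from a
#' baseline input (zero vector by default, i.e. the training mean for
#' scaled continuous features) to each observed input, approximated by
#' a midpoint Riemann sum over `n_steps` interpolation points. The
#' completeness residual `|sum_f IG_f - (f(x) - f(baseline))|` is
#' reported per sample and bin.
#'
#' @param model Trained `hazard_net`.
#' @param x Scaled `feature_matrix` (typically the training set).
#' @param baseline Baseline input: scalar or vector of length
#'   `n_features` (default 0).
#' @param n_steps Riemann-sum resolution (default 64).
#' @param groups Feature-to-column mapping; default from `x`.
#' @return An `importance_table` with signed-sum and absolute-sum
#'   global aggregations per feature, and attributes `local`
#'   (feature x bin, mean signed attribution over samples),
#'   `completeness_error` (max over samples and bins), `method`.
#' @export
integrated_gradients <- function(model, x, baseline = 0, n_steps = 64L,
                                 groups = NULL) {
  stopifnot(inherits(x, "feature_matrix"))
  if (is.null(groups)) groups <- x$groups
  xm <- x$x
  p <- ncol(xm); k <- model$config$n_bins; n <- nrow(xm)
  if (length(baseline) == 1) baseline <- rep(baseline, p)
  logit_of <- function(row) {
    as.numeric(.forward(model, matrix(row, 1), training = FALSE)$logits)
  }
  f_base <- logit_of(baseline)
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  attr_sum <- matrix(0, p, k)          # signed, summed over samples
  attr_abs <- matrix(0, p, k)          # |per-sample|, summed
  max_comp_err <- 0
  for (i in seq_len(n)) {
    xi <- xm[i, ]
    diff_ <- xi - baseline
    grad_acc <- matrix(0, p, k)
    for (al in alphas) {
      grad_acc <- grad_acc +
        .logit_input_grad(model, matrix(baseline + al * diff_, 1))
    }
    ig <- diff_ * grad_acc / n_steps   # p x k
    comp <- abs(colSums(ig) - (logit_of(xi) - f_base))
    max_comp_err <- max(max_comp_err, comp)
    rel <- abs(logit_of(xi) - f_base)
    if (any(comp > 0.01 * pmax(rel, 1e-8))) {
      warning("integrated-gradients completeness error above 1% of the ",
              "logit change; consider larger n_steps", call. = FALSE)
    }
    attr_sum <- attr_sum + ig
    attr_abs <- attr_abs + abs(ig)
  }
  rownames(attr_sum) <- rownames(attr_abs) <- colnames(xm)
  # collapse encoded columns to feature groups and average over samples
  local <- t(vapply(groups, function(cols) {
    colSums(attr_sum[cols, , drop = FALSE]) / n
  }, numeric(k)))
  local_abs <- t(vapply(groups, function(cols) {
    colSums(attr_abs[cols, , drop = FALSE]) / n
  }, numeric(k)))
  out <- data.frame(feature = names(groups),
                    global = rowSums(local),
                    global_abs = rowSums(local_abs),
                    stringsAsFactors = FALSE)
  attr(out, "local") <- local
  attr(out, "completeness_error") <- max_comp_err
  attr(out, "method") <- "integrated_gradients"
  attr(out, "target") <- "pre-sigmoid logit per bin"
  class(out) <- c("importance_table", class(out))
  out
}

#' Cross-method importance ranking
#'
#' Merges importance tables, ranks features per method by the absolute
#' global importance (or mean, for permutation tables), and reports
#' Spearman rank agreement between method pairs.
#'
#' @param tables Named list of `importance_table` objects (>= 1).
#' @return List with `ranks` (feature x method data frame of ranks,
#'   1 = most important) and `agreement` (Spearman correlation matrix).
#' @export
rank_report <- function(tables) {
  if (!length(tables)) stop("need at least one importance table",
                            call. = FALSE)
  if (is.null(names(tables))) {
    names(tables) <- vapply(tables, function(t)
      attr(t, "method") %||% "method", character(1))
    names(tables) <- make.unique(names(tables))
  }
  scores <- lapply(tables, function(t) {
    v <- if ("global" %in% names(t)) abs(t$global) else abs(t$mean)
    stats::setNames(v, t$feature)
  })
  feats <- Reduce(intersect, lapply(scores, names))
  ranks <- vapply(scores, function(s) rank(-s[feats]), numeric(length(feats)))
  ranks <- matrix(ranks, nrow = length(feats),
                  dimnames = list(feats, names(tables)))
  agreement <- stats::cor(ranks, method = "spearman")
  list(ranks = as.data.frame(ranks), agreement = agreement)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
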