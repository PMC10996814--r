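# End-to-end orchestration: encode -> split -> scale -> discretize ->
# train -> predict -> evaluate (-> importance), once per feature set,
# plus the k-fold stability analysis. These are the functions the
# numbered analysis scripts drive.

# Encode, subset, scale (train statistics only) and discretize one
# arm's data for a given split.
prepare_arm_data <- function(cohort, feature_set, split, n_bins = 20L) {
  fm_all <- encode_features(cohort, feature_set)
  idx <- function(ids) match(ids, cohort$patient_id)
  subset_fm <- function(fm, rows) {
    fm$x <- fm$x[rows, , drop = FALSE]
    fm
  }
  tr <- idx(split$train); va <- idx(split$validation); te <- idx(split$test)
  fm_tr <- subset_fm(fm_all, tr)
  scaler <- suppressWarnings(fit_scaler(fm_tr))
  grid <- make_time_grid(cohort$duration_days[tr], n_bins)
  lab <- function(rows) suppressWarnings(
    discretize(cohort$duration_days[rows], cohort$event[rows], grid))
  list(
    feature_set = feature_set, split = split, scaler = scaler, grid = grid,
    x_train = apply_scaler(scaler, fm_tr),
    x_val = apply_scaler(scaler, subset_fm(fm_all, va)),
    x_test = apply_scaler(scaler, subset_fm(fm_all, te)),
    labels_train = lab(tr), labels_val = lab(va), labels_test = lab(te),
    durations_test = cohort$duration_days[te],
    events_test = cohort$event[te],
    durations_val = cohort$duration_days[va],
    events_val = cohort$event[va]
  )
}

#' Run the study pipeline on a cohort
#'
#' Splits the cohort once, then for each requested feature set encodes,
#' scales (training statistics only), discretizes, trains the hazard
#' network, predicts test-set survival curves and computes the metric
#' report. The same split is used for every arm so the comparison is
#' like-for-like.
#'
#' @param cohort Cohort data frame (columns as produced by
#'   [generate_cohort()], including `duration_days` and `event`).
#' @param feature_sets Character vector of arms to run.
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_bins Number of discrete time bins (default 20).
#' @param net_overrides Named list of [network_config()] fields to
#'   override (e.g. `list(max_epochs = 100)`).
#' @param importance Compute permutation importance (test set, IPCW
#'   Brier), feature ablation and integrated gradients (training set)
#'   for each arm.
#' @param outdir Optional directory: writes survival-curve CSVs, metric
#'   JSONs, importance CSVs, checkpoints and a manifest.
#' @return An `experiment_report`: named list of arm reports (each with
#'   `metrics`, `model`, `prediction`, `split`, ...) plus attributes.
#' @export
run_experiment <- function(cohort,
                           feature_sets = c("hybrid", "clinical_only",
                                            "mb_only"),
                           seed = 1L, n_bins = 20L,
                           net_overrides = list(),
                           importance = FALSE, outdir = NULL) {
  split <- split_cohort(cohort$patient_id, derive_seed(seed, "split"))
  arms <- list()
  for (fs in feature_sets) {
    arm <- prepare_arm_data(cohort, fs, split, n_bins)
    cfg <- network_config(n_features = ncol(arm$x_train$x),
                          n_bins = n_bins,
                          seed = derive_seed(seed, paste0("net_", fs)))
    for (nm in names(net_overrides)) cfg[[nm]] <- net_overrides[[nm]]
    cfg$batch_size <- min(cfg$batch_size, nrow(arm$x_train$x))
    model <- train_hazard_net(build_network(cfg), arm$x_train,
                              arm$labels_train, arm$x_val, arm$labels_val)
    pred <- predict_survival(model, arm$x_test, arm$grid)
    metrics <- suppressWarnings(
      metric_report(pred, arm$durations_test, arm$events_test))
    rep_ <- list(feature_set = fs, split = split, config = cfg,
                 model = model, prediction = pred, metrics = metrics,
                 scaler = arm$scaler, grid = arm$grid,
                 durations_test = arm$durations_test,
                 events_test = arm$events_test)
    if (importance) {
      rep_$importance <- list(
        permutation = suppressWarnings(permutation_importance(
          model, arm$x_test, arm$durations_test, arm$events_test,
          arm$grid, metric = "ibs",
          seed = derive_seed(seed, paste0("perm_", fs)))),
        ablation = feature_ablation(model, arm$x_train,
                                    arm$labels_train),
        integrated_gradients = suppressWarnings(
          integrated_gradients(model, arm$x_train))
      )
    }
    arms[[fs]] <- rep_
  }
  out <- structure(arms, class = "experiment_report",
                   seed = seed, n_bins = n_bins)
  if (!is.null(outdir)) write_experiment(out, outdir)
  out
}

#' Compare metric reports across feature-set arms
#'
#' Requires at least two arms run on identical splits (constant random
#' seeding across arms, so train/validation/test membership matches).
#'
#' @param reports An `experiment_report` or named list of arm reports.
#' @return Data frame with one row per arm (`c_index_td`, `ibs`,
#'   `inbll`) plus attribute `hybrid_dominates` (named logical per
#'   metric when a hybrid arm is present).
#' @export
compare_feature_sets <- function(reports) {
  if (length(reports) < 2) {
    stop("need at least two arm reports to compare", call. = FALSE)
  }
  test_sets <- lapply(reports, function(r) r$split$test)
  if (!all(vapply(test_sets[-1], identical, logical(1), test_sets[[1]]))) {
    stop("arms were run on different splits; hold the seed constant",
         call. = FALSE)
  }
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(feature_set = r$feature_set,
               c_index_td = r$metrics$c_index_td,
               ibs = r$metrics$ibs, inbll = r$metrics$inbll,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  if ("hybrid" %in% tab$feature_set) {
    hy <- tab[tab$feature_set == "hybrid", ]
    others <- tab[tab$feature_set != "hybrid", ]
    attr(tab, "hybrid_dominates") <- c(
      c_index_td = all(hy$c_index_td > others$c_index_td),
      ibs = all(hy$ibs < others$ibs),
      inbll = all(hy$inbll < others$inbll)
    )
  }
  tab
}

#' k-fold stability analysis
#'
#' Partitions the cohort into `n_groups` groups and trains one model
#' per ordered (test, validation) group pair — 20 folds for 5 groups —
#' with all hyperparameters held constant. Stability is summarized by
#' the distribution of the best validation loss across folds, plus the
#' per-fold test concordance.
#'
#' @param cohort Cohort data frame.
#' @param feature_set Arm to run.
#' @param n_groups Number of groups (default 5).
#' @param seed Master seed.
#' @param n_bins Time bins.
#' @param net_overrides Named [network_config()] overrides.
#' @return List with `folds` (data frame: fold, val_loss, c_index_td)
#'   and `summary` (median/mean/range of validation loss).
#' @export
run_kfold <- function(cohort, feature_set = "hybrid", n_groups = 5L,
                      seed = 1L, n_bins = 20L, net_overrides = list()) {
  folds <- enumerate_folds(cohort$patient_id, n_groups,
                           derive_seed(seed, "kfold"))
  rows <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    arm <- prepare_arm_data(cohort, feature_set, folds[[i]], n_bins)
    cfg <- network_config(n_features = ncol(arm$x_train$x),
                          n_bins = n_bins,
                          seed = derive_seed(seed, "kfold_net"))
    for (nm in names(net_overrides)) cfg[[nm]] <- net_overrides[[nm]]
    cfg$batch_size <- min(cfg$batch_size, nrow(arm$x_train$x))
    model <- train_hazard_net(build_network(cfg), arm$x_train,
                              arm$labels_train, arm$x_val, arm$labels_val)
    pred <- predict_survival(model, arm$x_test, arm$grid)
    ci <- tryCatch(concordance_td(pred, arm$durations_test,
                                  arm$events_test),
                   error = function(e) NA_real_)
    rows[[i]] <- data.frame(fold = i,
                            test_group = folds[[i]]$test_group,
                            validation_group = folds[[i]]$validation_group,
                            val_loss = model$best_val_loss,
                            c_index_td = ci)
  }
  tab <- do.call(rbind, rows)
  list(folds = tab,
       summary = c(median = stats::median(tab$val_loss),
                   mean = mean(tab$val_loss),
                   min = min(tab$val_loss), max = max(tab$val_loss)))
}

#' Write experiment artifacts to disk
#'
#' Emits, per arm: long-form survival-curve CSV
#' (`patient_id,time_days,survival_probability`), metric JSON, a model
#' checkpoint; plus a manifest JSON for the run.
#'
#' @param report An `experiment_report`.
#' @param outdir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_experiment <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (fs in names(report)) {
    r <- report[[fs]]
    # survival curves in long form, with the S(0) = 1 step prepended
    s <- r$prediction$survival
    edges <- r$grid$edges
    ids <- r$split$test
    curves <- do.call(rbind, lapply(seq_along(ids), function(i) {
      data.frame(patient_id = ids[i], time_days = edges,
                 survival_probability = c(1, s[i, ]))
    }))
    utils::write.csv(curves,
                     file.path(outdir, sprintf("survival_%s.csv", fs)),
                     row.names = FALSE)
    m <- r$metrics
    jsonlite::write_json(
      list(feature_set = fs, c_index_td = m$c_index_td, ibs = m$ibs,
           inbll = m$inbll, n_test = m$n_test,
           per_time = m$per_time),
      file.path(outdir, sprintf("metrics_%s.json", fs)),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
    save_checkpoint(r$model,
                    file.path(outdir, sprintf("checkpoint_%s.json", fs)),
                    scaler = r$scaler, grid = r$grid)
    if (!is.null(r$importance)) {
      utils::write.csv(r$importance$permutation,
                       file.path(outdir, sprintf("perm_importance_%s.csv",
                                                 fs)),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(r$importance$ablation),
                       file.path(outdir, sprintf("ablation_%s.csv", fs)),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(r$importance$integrated_gradients),
                       file.path(outdir, sprintf("intgrad_%s.csv", fs)),
                       row.names = FALSE)
    }
  }
  manifest <- list(
    seed = attr(report, "seed"), n_bins = attr(report, "n_bins"),
    arms = names(report),
    test_ids = report[[1]]$split$test,
    package_version = as.character(utils::packageVersion("hybridsurv")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
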