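# Leakage-safe feature encoding/scaling, equidistant time
# discretization, and the train/validation/test splitting schemes.

# Declared feature schema. Multi-level categoricals are fully one-hot
# encoded (no reference-level drop; absent levels still get a column of
# zeros), binaries stay as single 0/1 columns, and the
# neutrophil-to-lymphocyte ratio is never constructed, to avoid
# collinearity with its components.
.mb_features <- c("mu", "Lambda", "alpha1")
.clinical_continuous <- c("age", "neutrophil_bsl", "lymphocyte_bsl", "kps")
.binary_features <- c("sex_male" = "sex", "ever_smoker" = "ever_smoker",
                      "prior_systemic" = "prior_systemic",
                      "prior_radiation" = "prior_radiation")

#' Declared levels of each categorical feature
#'
#' Histology keeps the Small Cell and Purely Undifferentiated codes even
#' though the study cohort contains no such patients, so encoded
#' matrices always have a fixed schema.
#'
#' @return Named list of level vectors.
#' @export
feature_levels <- function() {
  list(
    race = c("African American", "Asian", "White", "Hispanic"),
    histology = c("Adenocarcinoma", "Squamous Cell", "Neuroendocrine",
                  "Small Cell", "Purely Undifferentiated", "Other"),
    treatment_arm = as.character(1:5),
    max_ae_grade = as.character(1:5)
  )
}

.one_hot <- function(x, levels, prefix) {
  x <- as.character(x)
  bad <- setdiff(unique(x), levels)
  if (length(bad)) {
    stop(sprintf("unknown level(s) for %s: %s", prefix,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  m <- vapply(levels, function(l) as.numeric(x == l), numeric(length(x)))
  m <- matrix(m, nrow = length(x))
  colnames(m) <- paste0(prefix, "=", levels)
  m
}

#' Encode a cohort into a numeric feature matrix
#'
#' Builds the model design matrix for one of the three feature sets:
#' `"hybrid"` (mathematical biomarkers mu, Lambda, alpha1 plus all
#' clinical features), `"clinical_only"`, or `"mb_only"` (the three
#' biomarkers alone).
#'
#' @param cohort Data frame of patient records (see
#'   [generate_cohort()] for the schema).
#' @param feature_set One of `"hybrid"`, `"clinical_only"`, `"mb_only"`.
#' @return A `feature_matrix` object: list with `x` (numeric matrix),
#'   `kind` (per-column `"continuous"` or `"one_hot"`), and `groups`
#'   (named list mapping each original feature to its column names).
#' @export
encode_features <- function(cohort,
                            feature_set = c("hybrid", "clinical_only",
                                            "mb_only")) {
  feature_set <- match.arg(feature_set)
  if (!nrow(cohort)) stop("cohort is empty", call. = FALSE)

  cols <- list(); kinds <- character(); groups <- list()
  add_cont <- function(name) {
    v <- cohort[[name]]
    if (is.null(v)) stop(sprintf("missing column `%s`", name), call. = FALSE)
    if (any(is.na(v))) stop(sprintf("column `%s` has missing values", name),
                            call. = FALSE)
    cols[[name]] <<- matrix(as.numeric(v), ncol = 1,
                            dimnames = list(NULL, name))
    kinds <<- c(kinds, stats::setNames("continuous", name))
    groups[[name]] <<- name
  }
  add_binary <- function(colname, source) {
    v <- cohort[[source]]
    if (is.null(v)) stop(sprintf("missing column `%s`", source), call. = FALSE)
    if (source == "sex") {
      bad <- setdiff(unique(as.character(v)), c("male", "female"))
      if (length(bad)) stop(sprintf("unknown level(s) for sex: %s",
                                    paste(bad, collapse = ", ")),
                            call. = FALSE)
      v <- as.numeric(v == "male")
    } else {
      v <- as.numeric(v)
      if (!all(v %in% c(0, 1))) {
        stop(sprintf("column `%s` must be binary 0/1", source), call. = FALSE)
      }
    }
    cols[[colname]] <<- matrix(v, ncol = 1, dimnames = list(NULL, colname))
    kinds <<- c(kinds, stats::setNames("one_hot", colname))
    groups[[colname]] <<- colname
  }
  add_cat <- function(name) {
    lv <- feature_levels()[[name]]
    m <- .one_hot(cohort[[name]], lv, name)
    cols[[name]] <<- m
    kinds <<- c(kinds, stats::setNames(rep("one_hot", ncol(m)), colnames(m)))
    groups[[name]] <<- colnames(m)
  }

  if (feature_set %in% c("hybrid", "mb_only")) {
    for (f in .mb_features) add_cont(f)
  }
  if (feature_set %in% c("hybrid", "clinical_only")) {
    for (f in .clinical_continuous) add_cont(f)
    add_cat("race")
    add_binary("sex_male", "sex")
    add_cat("histology")
    add_binary("ever_smoker", "ever_smoker")
    add_binary("prior_systemic", "prior_systemic")
    add_binary("prior_radiation", "prior_radiation")
    add_cat("treatment_arm")
    add_cat("max_ae_grade")
  }

  x <- do.call(cbind, unname(cols))
  structure(list(x = x, kind = kinds, groups = groups,
                 feature_set = feature_set),
            class = "feature_matrix")
}

#' Fit a standardizing scaler on training rows
#'
#' Computes per-column mean and standard deviation of the continuous
#' columns of a training feature matrix. One-hot columns are left
#' untouched by [apply_scaler()]. Fitting on training rows only — and
#' refitting per fold — keeps validation/test statistics out of the
#' transform (no data leakage).
#'
#' @param train A `feature_matrix` of training rows.
#' @return A `feature_scaler` object.
#' @export
fit_scaler <- function(train) {
  stopifnot(inherits(train, "feature_matrix"))
  cont <- names(train$kind)[train$kind == "continuous"]
  mu <- vapply(cont, function(cn) mean(train$x[, cn]), numeric(1))
  # population standard deviation, as in the usual ML standard scaler
  sd_ <- vapply(cont, function(cn) {
    v <- train$x[, cn]
    sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  zero_var <- !is.finite(sd_) | sd_ == 0
  if (any(zero_var)) {
    warning(sprintf("zero-variance continuous column(s): %s; scaling by 1",
                    paste(cont[zero_var], collapse = ", ")), call. = FALSE)
    sd_[zero_var] <- 1
  }
  structure(list(columns = cont, center = mu, scale = sd_),
            class = "feature_scaler")
}

#' Apply a fitted scaler to a feature matrix
#'
#' @param state A `feature_scaler` from [fit_scaler()].
#' @param fm A `feature_matrix` with the same columns.
#' @return The `feature_matrix` with continuous columns standardized
#'   under the training statistics.
#' @export
apply_scaler <- function(state, fm) {
  stopifnot(inherits(state, "feature_scaler"), inherits(fm, "feature_matrix"))
  if (!all(state$columns %in% colnames(fm$x))) {
    stop("feature matrix lacks columns the scaler was fit on", call. = FALSE)
  }
  for (cn in state$columns) {
    fm$x[, cn] <- (fm$x[, cn] - state$center[[cn]]) / state$scale[[cn]]
  }
  fm
}

#' Equidistant time grid over the training durations
#'
#' @param train_durations Positive durations (days) of the training set.
#' @param n_bins Number of bins; the study default is 20.
#' @return A `time_grid`: list with `n_bins` and `edges`
#'   (length `n_bins + 1`, starting at 0).
#' @export
make_time_grid <- function(train_durations, n_bins = 20L) {
  if (n_bins < 2) stop("n_bins must be at least 2", call. = FALSE)
  if (any(train_durations <= 0)) stop("durations must be positive",
                                      call. = FALSE)
  edges <- seq(0, max(train_durations), length.out = n_bins + 1)
  structure(list(n_bins = as.integer(n_bins), edges = edges),
            class = "time_grid")
}

#' Map a duration to a discrete time bin
#'
#' Bins are left-open, right-closed: a duration exactly on an edge falls
#' in the earlier bin. Durations beyond the grid clamp to the last bin
#' with a warning (test patients may outlive the training horizon).
#'
#' @param duration Positive duration(s) in days.
#' @param event 0/1 event indicator(s), recycled to match.
#' @param grid A `time_grid`.
#' @return Data frame with `bin_index` (0-based, in `0..n_bins-1`) and
#'   `event`.
#' @export
discretize <- function(duration, event, grid) {
  stopifnot(inherits(grid, "time_grid"))
  if (any(duration <= 0)) stop("durations must be positive", call. = FALSE)
  interior <- grid$edges[-1]
  k <- vapply(duration, function(d) sum(interior < d), numeric(1))
  over <- k > grid$n_bins - 1
  if (any(over)) {
    warning(sprintf("%d duration(s) beyond the grid clamped to the last bin",
                    sum(over)), call. = FALSE)
    k[over] <- grid$n_bins - 1
  }
  data.frame(bin_index = as.integer(k), event = as.integer(event))
}

#' Random train/validation/test split
#'
#' By default the test set is `ceiling(0.2 n)` patients and the
#' validation set is ~20% of the remainder, mirroring a 93-patient
#' cohort splitting into 59 train / 15 validation / 19 test.
#'
#' @param ids Vector of patient identifiers.
#' @param seed Integer seed.
#' @param fractions Length-3 numeric `(train, val, test)` summing to 1.
#' @return A list with `train`, `validation`, `test` id vectors.
#' @export
split_cohort <- function(ids, seed, fractions = c(0.6, 0.2, 0.2)) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  n <- length(ids)
  n_test <- ceiling(fractions[3] * n)
  # validation share is taken of the non-test patients (93 -> 59/15/19)
  n_val <- round(fractions[2] * (n - n_test))
  n_train <- n - n_test - n_val
  if (min(n_train, n_val, n_test) < 1) {
    stop("split produces an empty part", call. = FALSE)
  }
  perm <- with_seed(seed, sample(ids))
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

#' Enumerate all ordered k-fold splits
#'
#' Partitions the ids into `n_groups` near-equal groups and forms one
#' fold for every ordered pair (test group, validation group) with test
#' != validation; the remaining groups are the training set. With 5
#' groups this yields the study's 20 folds.
#'
#' @param ids Vector of patient identifiers.
#' @param n_groups Number of groups (>= 3).
#' @param seed Integer seed for the group assignment.
#' @return List of `n_groups * (n_groups - 1)` split lists, each with
#'   `train`, `validation`, `test`, plus attribute `groups`.
#' @export
enumerate_folds <- function(ids, n_groups = 5L, seed = 1L) {
  if (n_groups < 3) stop("n_groups must be at least 3", call. = FALSE)
  n <- length(ids)
  perm <- with_seed(seed, sample(ids))
  # assign contiguous chunks of the permuted ids to near-equal groups
  sizes <- tabulate(rep(seq_len(n_groups), length.out = n), n_groups)
  grp <- rep(seq_len(n_groups), times = sizes)
  groups <- split(perm, grp)
  if (any(lengths(groups) < 2)) {
    warning("some groups have fewer than 2 patients", call. = FALSE)
  }
  folds <- list()
  for (te in seq_len(n_groups)) {
    for (va in seq_len(n_groups)) {
      if (te == va) next
      folds[[length(folds) + 1]] <- list(
        train = sort(unlist(groups[-c(te, va)], use.names = FALSE)),
        validation = sort(groups[[va]]),
        test = sort(groups[[te]]),
        test_group = te, validation_group = va
      )
    }
  }
  attr(folds, "groups") <- groups
  folds
}
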