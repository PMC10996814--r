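# Independent oracles used across the suite. Each is a deliberately
# naive implementation (numerical integration, exhaustive enumeration,
# term-by-term summation) kept separate from the package's own code
# paths.

# Adaptive numerical integration of the tumor-burden ODE.
ode_oracle <- function(alpha0, mu, Lambda, times) {
  a <- alpha0 - mu + Lambda * mu
  b <- Lambda * mu
  rhs <- function(t, state, parms) list(a * state - b * state^2)
  out <- deSolve::ode(y = c(rho = 1), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-12)
  as.numeric(out[, "rho"])
}

# Expanded-target binary cross-entropy: one (patient, bin) row per bin
# up to and including the label bin.
loss_oracle <- function(hazards, labels) {
  eps <- 1e-7
  h <- pmin(pmax(hazards, eps), 1 - eps)
  total <- 0
  for (i in seq_len(nrow(h))) {
    k <- labels$bin_index[i] + 1L
    for (j in seq_len(k)) {
      y <- as.numeric(j == k && labels$event[i] == 1)
      total <- total - (y * log(h[i, j]) + (1 - y) * log(1 - h[i, j]))
    }
  }
  total / nrow(h)
}

# Hand Kaplan-Meier on the censoring indicator; returns an evaluator
# with a left-limit option.
hand_km_censoring <- function(durations, events) {
  cens_times <- sort(unique(durations[events == 0]))
  function(t, left = FALSE) {
    g <- 1
    for (tc in cens_times) {
      ok <- if (left) tc < t else tc <= t
      if (!ok) break
      at_risk <- sum(durations >= tc)
      d <- sum(durations == tc & events == 0)
      g <- g * (1 - d / at_risk)
    }
    g
  }
}

# Step-function survival evaluation matching the left-open,
# right-closed bin convention (independent re-implementation).
step_surv <- function(surv_row, edges, t) {
  if (t <= edges[1]) return(1)
  k <- 0
  for (j in seq_along(edges)[-1]) if (edges[j] < t) k <- k + 1
  surv_row[min(k + 1, length(surv_row))]
}

# Term-by-term IPCW Brier score at one time.
brier_oracle_at <- function(surv_mat, edges, durations, events, t,
                            g_floor = 1e-4) {
  G <- hand_km_censoring(durations, events)
  n <- length(durations)
  total <- 0
  for (i in seq_len(n)) {
    s <- step_surv(surv_mat[i, ], edges, t)
    if (durations[i] <= t && events[i] == 1) {
      total <- total + s^2 / max(G(durations[i], left = TRUE), g_floor)
    } else if (durations[i] > t) {
      total <- total + (1 - s)^2 / max(G(t), g_floor)
    }
  }
  total / n
}

# Term-by-term IPCW negative binomial log-likelihood at one time.
nbll_oracle_at <- function(surv_mat, edges, durations, events, t,
                           g_floor = 1e-4) {
  G <- hand_km_censoring(durations, events)
  eps <- 1e-7
  n <- length(durations)
  total <- 0
  for (i in seq_len(n)) {
    s <- min(max(step_surv(surv_mat[i, ], edges, t), eps), 1 - eps)
    if (durations[i] <= t && events[i] == 1) {
      total <- total + log(1 - s) / max(G(durations[i], left = TRUE),
                                        g_floor)
    } else if (durations[i] > t) {
      total <- total + log(s) / max(G(t), g_floor)
    }
  }
  -total / n
}

# Exhaustive all-pairs event-time concordance.
concordance_oracle <- function(surv_mat, edges, durations, events) {
  n <- length(durations)
  conc <- 0; total <- 0
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    for (j in seq_len(n)) {
      if (durations[j] <= durations[i]) next
      si <- round(step_surv(surv_mat[i, ], edges, durations[i]), 12)
      sj <- round(step_surv(surv_mat[j, ], edges, durations[i]), 12)
      if (si < sj) conc <- conc + 1
      if (si == sj) conc <- conc + 0.5
      total <- total + 1
    }
  }
  conc / total
}

# Build a prediction object directly from a hazard matrix (bypasses the
# network) for metric tests.
make_prediction <- function(hazards, edges) {
  grid <- structure(list(n_bins = ncol(hazards), edges = edges),
                    class = "time_grid")
  s <- t(apply(1 - hazards, 1, cumprod))
  if (nrow(hazards) == 1) s <- matrix(s, nrow = 1)
  structure(list(grid = grid, hazards = hazards, survival = s),
            class = "discrete_survival_prediction")
}

# Small trained model on a generated cohort, shared by importance and
# network tests.
train_toy_model <- function(n = 120, seed = 11, feature_set = "hybrid",
                            max_epochs = 40, n_bins = 10) {
  gen <- generate_cohort(cohort_spec(n_patients = n, seed = seed))
  split <- split_cohort(gen$cohort$patient_id, seed = seed + 1)
  arm <- hybridsurv:::prepare_arm_data(gen$cohort, feature_set, split,
                                       n_bins)
  cfg <- network_config(n_features = ncol(arm$x_train$x), n_bins = n_bins,
                        max_epochs = max_epochs, seed = seed)
  cfg$batch_size <- min(cfg$batch_size, nrow(arm$x_train$x))
  model <- train_hazard_net(build_network(cfg), arm$x_train,
                            arm$labels_train, arm$x_val, arm$labels_val)
  list(model = model, arm = arm, gen = gen, cfg = cfg)
}
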