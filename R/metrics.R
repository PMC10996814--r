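# Evaluation statistics for step-function survival predictions:
# event-time concordance, IPCW Brier score and IPCW negative binomial
# log-likelihood, with a Kaplan-Meier estimate of the censoring
# distribution supplying the inverse-probability weights.

.G_FLOOR <- 1e-4

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Applies the Kaplan-Meier estimator to the flipped indicator
#' `1 - delta`, giving the probability G(t) of remaining uncensored
#' through time t. Used to build inverse-probability-of-censoring
#' weights.
#'
#' @param durations Positive follow-up times.
#' @param events 0/1 event indicators (1 = death).
#' @return A `censoring_estimate`: right-continuous step function with
#'   evaluators `$at(t)` and `$at_left(t)` (the left limit G(t-)).
#' @export
km_censoring <- function(durations, events) {
  if (any(durations <= 0)) stop("durations must be positive", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(durations, 1 - events) ~ 1, se.fit = FALSE)
  times <- fit$time
  surv <- fit$surv
  step_at <- function(t, left = FALSE) {
    vapply(t, function(ti) {
      idx <- if (left) sum(times < ti) else sum(times <= ti)
      if (idx == 0) 1 else surv[idx]
    }, numeric(1))
  }
  structure(list(
    times = times, surv = surv,
    at = function(t) step_at(t, left = FALSE),
    at_left = function(t) step_at(t, left = TRUE)
  ), class = "censoring_estimate")
}

# Shared IPCW machinery: for each (patient, eval time) pair classify the
# term and produce its weight. Returns, per eval time, the two index
# sets and their floored weights plus the count of floored terms.
.ipcw_terms <- function(durations, events, t, G) {
  died <- durations <= t & events == 1
  alive <- durations > t
  w_died <- G$at_left(durations[died])
  w_alive <- rep(G$at(t), sum(alive))
  n_floored <- sum(w_died < .G_FLOOR) + sum(w_alive < .G_FLOOR)
  list(died = died, alive = alive,
       w_died = pmax(w_died, .G_FLOOR),
       w_alive = pmax(w_alive, .G_FLOOR),
       n_floored = n_floored)
}

#' IPCW Brier score curve
#'
#' The inverse-probability-of-censoring-weighted Brier score at each
#' evaluation time t:
#' `BS(t) = (1/N) sum_i [ S(t|x_i)^2 1{T_i <= t, d_i = 1} / G(T_i-) +
#'                        (1 - S(t|x_i))^2 1{T_i > t} / G(t) ]`
#' with S evaluated as a right-continuous step function and G the
#' Kaplan-Meier censoring survival. Weights below `1e-4` are floored
#' and counted (attribute `n_floored`).
#'
#' @param prediction A `discrete_survival_prediction`.
#' @param durations,events Observed follow-up and event indicators for
#'   the same patients (rows).
#' @param eval_times Evaluation times inside the grid span; default is
#'   the interior grid from [eval_grid()].
#' @return Numeric vector of per-time Brier scores.
#' @export
brier_ipcw <- function(prediction, durations, events, eval_times = NULL) {
  if (is.null(eval_times)) eval_times <- eval_grid(prediction$grid)
  G <- km_censoring(durations, events)
  s_mat <- surv_at(prediction, eval_times)
  n <- length(durations)
  floored <- 0L
  out <- vapply(seq_along(eval_times), function(j) {
    t <- eval_times[j]
    tm <- .ipcw_terms(durations, events, t, G)
    floored <<- floored + tm$n_floored
    s <- s_mat[, j]
    (sum(s[tm$died]^2 / tm$w_died) +
       sum((1 - s[tm$alive])^2 / tm$w_alive)) / n
  }, numeric(1))
  if (floored > 0) {
    warning(sprintf("%d IPCW weight(s) floored at %g", floored, .G_FLOOR),
            call. = FALSE)
  }
  attr(out, "n_floored") <- floored
  out
}

#' IPCW negative binomial log-likelihood curve
#'
#' `NBLL(t) = -(1/N) sum_i [ log(1 - S(t|x_i)) 1{T_i <= t, d_i = 1} /
#'            G(T_i-) + log S(t|x_i) 1{T_i > t} / G(t) ]`,
#' with S clipped away from 0 and 1 before logs.
#'
#' @inheritParams brier_ipcw
#' @return Numeric vector of per-time NBLL values.
#' @export
nbll_ipcw <- function(prediction, durations, events, eval_times = NULL) {
  if (is.null(eval_times)) eval_times <- eval_grid(prediction$grid)
  G <- km_censoring(durations, events)
  s_mat <- pmin(pmax(surv_at(prediction, eval_times), .HAZ_EPS),
                1 - .HAZ_EPS)
  n <- length(durations)
  floored <- 0L
  out <- vapply(seq_along(eval_times), function(j) {
    t <- eval_times[j]
    tm <- .ipcw_terms(durations, events, t, G)
    floored <<- floored + tm$n_floored
    s <- s_mat[, j]
    -(sum(log(1 - s[tm$died]) / tm$w_died) +
        sum(log(s[tm$alive]) / tm$w_alive)) / n
  }, numeric(1))
  if (floored > 0) {
    warning(sprintf("%d IPCW weight(s) floored at %g", floored, .G_FLOOR),
            call. = FALSE)
  }
  attr(out, "n_floored") <- floored
  out
}

#' Time-average a per-time metric curve
#'
#' Trapezoidal integral of the curve divided by the evaluated span —
#' the integrated Brier score / integrated NBLL reported as a single
#' number.
#'
#' @param values Per-time metric values.
#' @param eval_times Matching evaluation times (>= 2).
#' @return Scalar time average.
#' @export
integrate_over_time <- function(values, eval_times) {
  if (length(eval_times) < 2) stop("need at least 2 eval times",
                                   call. = FALSE)
  dt <- diff(eval_times)
  area <- sum(dt * (values[-1] + values[-length(values)]) / 2)
  area / (eval_times[length(eval_times)] - eval_times[1])
}

#' Interior evaluation grid for metric curves
#'
#' 100 equidistant points strictly inside the discretization span. The
#' extreme tails are excluded: at t = 0 every patient is trivially
#' predicted alive, and at the final edge trivially dead.
#'
#' @param grid A `time_grid`.
#' @param n_points Number of interior points (default 100).
#' @return Numeric vector of evaluation times.
#' @export
eval_grid <- function(grid, n_points = 100L) {
  span <- range(grid$edges)
  seq(span[1], span[2], length.out = n_points + 2L)[2:(n_points + 1L)]
}

#' Event-time concordance index
#'
#' Over comparable pairs (i, j) with `T_i < T_j` and `delta_i = 1`, a
#' pair is concordant when the patient with the earlier event has the
#' lower predicted survival at that event time:
#' `S(T_i | x_i) < S(T_i | x_j)`. Ties in the predicted survival
#' (after rounding to 12 decimals) credit 0.5.
#'
#' @inheritParams brier_ipcw
#' @return Concordant fraction in `[0, 1]`.
#' @export
concordance_td <- function(prediction, durations, events) {
  n <- length(durations)
  conc <- 0; total <- 0
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    s_at_ti <- round(as.numeric(surv_at(prediction, durations[i])), 12)
    comparable <- which(durations > durations[i])
    if (!length(comparable)) next
    si <- s_at_ti[i]; sj <- s_at_ti[comparable]
    conc <- conc + sum(si < sj) + 0.5 * sum(si == sj)
    total <- total + length(comparable)
  }
  if (total == 0) {
    stop("no comparable pairs; concordance undefined", call. = FALSE)
  }
  conc / total
}

#' Full metric report for a prediction set
#'
#' @inheritParams brier_ipcw
#' @return A `metric_report`: list with `c_index_td`, `ibs`, `inbll`,
#'   `n_test` and the per-time curves.
#' @export
metric_report <- function(prediction, durations, events,
                          eval_times = NULL) {
  if (is.null(eval_times)) eval_times <- eval_grid(prediction$grid)
  bs <- brier_ipcw(prediction, durations, events, eval_times)
  nb <- nbll_ipcw(prediction, durations, events, eval_times)
  structure(list(
    c_index_td = concordance_td(prediction, durations, events),
    ibs = integrate_over_time(as.numeric(bs), eval_times),
    inbll = integrate_over_time(as.numeric(nb), eval_times),
    n_test = length(durations),
    per_time = data.frame(times = eval_times, brier = as.numeric(bs),
                          nbll = as.numeric(nb))
  ), class = "metric_report")
}
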