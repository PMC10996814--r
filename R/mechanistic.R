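# Mechanistic tumor-burden model: logistic-form ODE for normalized burden
# rho(t) (burden divided by burden at treatment start, so rho(0) = 1),
#   d rho / dt = rho * (alpha0 - mu + Lambda*mu) + rho^2 * (-Lambda*mu)
# with alpha0 the intrinsic pre-treatment growth rate (day^-1), mu the
# tumor kill rate under checkpoint-inhibitor therapy (day^-1), and Lambda
# the dimensionless anti-tumor immune state. Writing a = alpha0 - mu +
# Lambda*mu and b = Lambda*mu this is the logistic ODE
# d rho/dt = a*rho - b*rho^2, which has a closed-form solution.

#' Construct a tumor-burden series
#'
#' A longitudinal series of normalized tumor burden for one patient.
#' Burden is normalized by the value at treatment start, so the series
#' begins at `(0, 1)`.
#'
#' @param patient_id Identifier (any scalar).
#' @param times Observation times in days, strictly increasing, first
#'   element 0.
#' @param burdens Normalized burden at each time; `burdens[1]` must be 1
#'   (within `1e-9`), all values positive.
#' @return An object of class `tumor_burden_series`.
#' @export
tumor_burden_series <- function(patient_id, times, burdens) {
  times <- as.numeric(times)
  burdens <- as.numeric(burdens)
  if (length(times) != length(burdens)) {
    stop("`times` and `burdens` must have the same length", call. = FALSE)
  }
  if (length(times) < 2) {
    stop("a tumor burden series needs at least 2 observations", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(burdens))) {
    stop("times and burdens must be finite", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (times[1] != 0) {
    stop("first observation must be at time 0", call. = FALSE)
  }
  if (abs(burdens[1] - 1) > 1e-9) {
    stop("burden at time 0 must be 1 (normalized series)", call. = FALSE)
  }
  if (any(burdens <= 0)) {
    stop("burdens must be positive", call. = FALSE)
  }
  structure(
    list(patient_id = patient_id, times = times, burdens = burdens),
    class = "tumor_burden_series"
  )
}

#' Construct a set of mechanistic model parameters
#'
#' The mathematical biomarkers of the tumor-burden model. Negative `mu`
#' and `Lambda` are permitted: they arise when the tumor grows faster
#' after treatment than before.
#'
#' @param alpha0 Intrinsic pre-treatment growth rate (day^-1).
#' @param mu Tumor kill rate (day^-1).
#' @param Lambda Anti-tumor immune state (dimensionless).
#' @param alpha1 Growth rate at first restaging (day^-1), or `NA` if not
#'   yet computed.
#' @return An object of class `mechanistic_params`.
#' @export
mechanistic_params <- function(alpha0, mu, Lambda, alpha1 = NA_real_) {
  vals <- c(alpha0 = alpha0, mu = mu, Lambda = Lambda, alpha1 = alpha1)
  if (any(!is.finite(vals[1:3]))) {
    stop("alpha0, mu and Lambda must be finite", call. = FALSE)
  }
  structure(as.list(vals), class = "mechanistic_params")
}

# Growth/saturation coefficients of the logistic form.
.ode_coefs <- function(params) {
  a <- params$alpha0 - params$mu + params$Lambda * params$mu
  b <- params$Lambda * params$mu
  c(a = a, b = b)
}

# Time at which the closed-form denominator crosses zero (finite-time
# blow-up), or Inf if the solution exists for all t >= 0.
.blowup_time <- function(a, b) {
  if (a == 0) {
    if (b < 0) return(-1 / b)
    return(Inf)
  }
  ratio <- 1 - a / b # e^{a t*} at the crossing; only defined for b != 0
  if (b == 0 || !is.finite(ratio) || ratio <= 0) return(Inf)
  t_star <- log(ratio) / a
  if (t_star > 0) t_star else Inf
}

#' Solve the tumor-burden ODE in closed form
#'
#' Evaluates the normalized burden trajectory rho(t) with rho(0) = 1 for
#' the logistic-form model `d rho/dt = a rho - b rho^2`, where
#' `a = alpha0 - mu + Lambda*mu` and `b = Lambda*mu`:
#' `rho(t) = a e^{at} / (a + b (e^{at} - 1))` for `a != 0` and
#' `rho(t) = 1 / (1 + b t)` for `a = 0`.
#'
#' @param params A [mechanistic_params()] object (alpha1 is ignored).
#' @param times Numeric vector of times in days, all finite and >= 0.
#' @return Numeric vector of normalized burden values.
#' @examples
#' p <- mechanistic_params(alpha0 = 0.01, mu = 0.02, Lambda = 2)
#' solve_tumor_burden(p, c(0, 30, 60))
#' @export
solve_tumor_burden <- function(params, times) {
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and non-negative", call. = FALSE)
  }
  co <- .ode_coefs(params)
  a <- co[["a"]]; b <- co[["b"]]
  t_star <- .blowup_time(a, b)
  if (length(times) && max(times) >= t_star) {
    stop(sprintf(
      "tumor-burden solution blows up at t = %.4g days, before requested t = %.4g",
      t_star, max(times)
    ), call. = FALSE)
  }
  if (a == 0) {
    rho <- 1 / (1 + b * times)
  } else if (a > 0) {
    # exp(-a t) <= 1 keeps this form finite for arbitrarily large a t
    rho <- a / ((a - b) * exp(-a * times) + b)
  } else {
    eat <- exp(a * times)
    rho <- a * eat / ((a - b) + b * eat)
  }
  rho
}

#' Fit the mechanistic model to a burden series
#'
#' Estimates the tumor kill rate `mu` and anti-tumor immune state
#' `Lambda` from one patient's normalized burden series, with the
#' intrinsic growth rate `alpha0` supplied externally (in the original
#' study it is the average pre-treatment growth rate across measured
#' tumors). The fit minimizes the sum of squared residuals on the log
#' burden scale, the natural scale for a multiplicative error model on
#' volumes.
#'
#' Only the combination `(a, b) = (alpha0 - mu + Lambda*mu, Lambda*mu)`
#' is identified by the trajectory, so the optimizer works in `(a, b)`
#' and the canonical `(mu, Lambda)` pair is recovered as
#' `mu = alpha0 - a + b` and `Lambda = b / mu` (with `Lambda = 0` when
#' `mu = 0`). Multi-start local optimization (Nelder-Mead then BFGS
#' polish) with deterministically seeded restarts guards against local
#' minima.
#'
#' @param series A [tumor_burden_series()].
#' @param alpha0 Intrinsic growth rate in day^-1. Defaults to 0 with a
#'   warning when not supplied.
#' @param n_starts Number of random restarts (>= 1); the first start is
#'   a deterministic log-linear initial guess.
#' @param seed Integer seed for the restart draws.
#' @return A [mechanistic_params()] with attributes `rss` (residual sum
#'   of squares on the log scale) and `convergence` (0 for success).
#' @export
fit_mechanistic_params <- function(series, alpha0 = NULL, n_starts = 8L,
                                   seed = 1L) {
  stopifnot(inherits(series, "tumor_burden_series"))
  if (is.null(alpha0)) {
    warning("alpha0 not supplied; defaulting to 0", call. = FALSE)
    alpha0 <- 0
  }
  tt <- series$times
  yy <- series$burdens
  if (sum(tt > 0) < 2) {
    stop("insufficient data: need at least 2 post-baseline observations",
         call. = FALSE)
  }
  log_y <- log(yy)

  obj <- function(par) {
    a <- par[1]; b <- par[2]
    if (!all(is.finite(par))) return(1e12)
    if (max(tt) >= .blowup_time(a, b)) return(1e12)
    if (a == 0) {
      pred <- 1 / (1 + b * tt)
    } else {
      eat <- exp(a * tt)
      pred <- a * eat / (a + b * (eat - 1))
    }
    if (any(!is.finite(pred)) || any(pred <= 0)) return(1e12)
    sum((log(pred) - log_y)^2)
  }

  # Deterministic start: slope of log burden gives a; b = 0.
  a0 <- stats::coef(stats::lm(log_y ~ tt + 0))[[1]]
  starts <- list(c(a0, 0))
  if (n_starts > 1) {
    jitter <- with_seed(seed, matrix(stats::rnorm(2 * (n_starts - 1), 0, 0.02),
                                     ncol = 2))
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- c(a0 + jitter[i, 1], jitter[i, 2])
    }
  }

  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    fit2 <- suppressWarnings(
      stats::optim(fit$par, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
    )
    cand <- if (fit2$value <= fit$value) fit2 else fit
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best) || best$value >= 1e12) {
    stop("mechanistic fit failed to converge from all starts", call. = FALSE)
  }

  a <- best$par[1]; b <- best$par[2]
  # Canonicalize the degenerate flat trajectory (a = b = 0 within
  # optimizer tolerance and alpha0 = 0) to mu = 0, Lambda = 0.
  tol <- 1e-8
  if (abs(a) < tol && abs(b) < tol) {
    a <- 0; b <- 0
  }
  mu <- alpha0 - a + b
  Lambda <- if (mu == 0) 0 else b / mu
  out <- mechanistic_params(alpha0 = alpha0, mu = mu, Lambda = Lambda)
  attr(out, "rss") <- best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Growth rate at first restaging
#'
#' The effective exponential growth rate between treatment start and the
#' first restaging scan at `t1`, from the short-term model solution
#' `rho(t) ~ exp(alpha1 t)`: `alpha1 = ln(rho(t1)) / t1`.
#'
#' @param burden_at_t1 Normalized burden at `t1`; must be positive.
#' @param t1 Time of first restaging in days; must be positive.
#' @return alpha1 in day^-1.
#' @examples
#' compute_alpha1(2, 60) # ln(2)/60
#' @export
compute_alpha1 <- function(burden_at_t1, t1) {
  if (any(burden_at_t1 <= 0) || any(t1 <= 0)) {
    stop("burden_at_t1 and t1 must be positive", call. = FALSE)
  }
  log(burden_at_t1) / t1
}

#' Prognostic group from the first-restaging growth rate
#'
#' Patients with `alpha1 <= 0.002` per day (relatively slower-growing
#' lesions) are labelled `"favorable"`; faster growth is
#' `"unfavorable"`. The boundary is inclusive.
#'
#' @param alpha1 Growth rate(s) in day^-1, finite.
#' @return Character vector of `"favorable"` / `"unfavorable"`.
#' @export
classify_alpha1 <- function(alpha1) {
  if (any(!is.finite(alpha1))) stop("alpha1 must be finite", call. = FALSE)
  ifelse(alpha1 <= 0.002, "favorable", "unfavorable")
}

#' Estimate biomarkers for every patient in a burden table
#'
#' Convenience wrapper mapping [fit_mechanistic_params()] and
#' [compute_alpha1()] over a long-format burden table.
#'
#' @param burden_df Data frame with columns `patient_id`, `time_days`,
#'   `normalized_burden`; each patient must include a `time_days == 0`
#'   row with burden 1.
#' @param alpha0 Named vector of per-patient intrinsic growth rates, a
#'   single value recycled to all patients, or `NULL` (0 with warning).
#' @param seed Seed passed to the per-patient fits.
#' @return Data frame `patient_id, alpha0, mu, Lambda, alpha1, rss,
#'   prognostic_group`.
#' @export
fit_biomarkers <- function(burden_df, alpha0 = NULL, seed = 1L) {
  stopifnot(all(c("patient_id", "time_days", "normalized_burden") %in%
                  names(burden_df)))
  ids <- unique(burden_df$patient_id)
  if (is.null(alpha0)) {
    warning("alpha0 not supplied; defaulting to 0 for all patients",
            call. = FALSE)
    alpha0 <- stats::setNames(rep(0, length(ids)), ids)
  } else if (length(alpha0) == 1 && is.null(names(alpha0))) {
    alpha0 <- stats::setNames(rep(alpha0, length(ids)), ids)
  }
  rows <- lapply(ids, function(id) {
    sub <- burden_df[burden_df$patient_id == id, ]
    sub <- sub[order(sub$time_days), ]
    ser <- tumor_burden_series(id, sub$time_days, sub$normalized_burden)
    a0 <- alpha0[[as.character(id)]]
    fit <- fit_mechanistic_params(ser, alpha0 = a0, seed = seed)
    post <- sub[sub$time_days > 0, ]
    a1 <- compute_alpha1(post$normalized_burden[1], post$time_days[1])
    data.frame(
      patient_id = id, alpha0 = a0, mu = fit$mu, Lambda = fit$Lambda,
      alpha1 = a1, rss = attr(fit, "rss"),
      prognostic_group = classify_alpha1(a1),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
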