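#' Labeling schedule of a pulsed heavy-lysine experiment
#'
#' Describes the K6 feeding window and the kinetics of the free heavy-lysine
#' precursor pool. `precursor_plateau` is the asymptotic heavy fraction of the
#' free lysine pool (dietary lysine is never 100% of the pool because of
#' recycling of pre-existing light protein); `precursor_rise_time` is the time
#' constant, in days, with which the pool equilibrates after the diet switch.
#' `precursor_rise_time = 0` means the pool jumps to its plateau instantly.
#'
#' @param label_days Duration of K6 feeding in days. The reference designs use
#'   6 days (disease cohorts) or 8 days (aged cohorts).
#' @param precursor_plateau Asymptotic heavy fraction of the precursor pool,
#'   in (0, 1].
#' @param precursor_rise_time Pool equilibration time constant in days
#'   (>= 0; 0 = instantaneous).
#' @return An object of class `"labeling_schedule"`.
#' @examples
#' labeling_schedule(label_days = 6)
#' @export
labeling_schedule <- function(label_days = 6, precursor_plateau = 1,
                              precursor_rise_time = 0) {
  if (!is.numeric(label_days) || length(label_days) != 1L ||
      !is.finite(label_days) || label_days <= 0) {
    abort("`label_days` must be a single positive number.")
  }
  if (!is.numeric(precursor_plateau) || length(precursor_plateau) != 1L ||
      !is.finite(precursor_plateau) ||
      precursor_plateau <= 0 || precursor_plateau > 1) {
    abort("`precursor_plateau` must be in (0, 1].")
  }
  if (!is.numeric(precursor_rise_time) || length(precursor_rise_time) != 1L ||
      !is.finite(precursor_rise_time) || precursor_rise_time < 0) {
    abort("`precursor_rise_time` must be a nonnegative number of days.")
  }
  structure(
    list(label_days = label_days,
         precursor_plateau = precursor_plateau,
         precursor_rise_time = precursor_rise_time),
    class = "labeling_schedule"
  )
}

#' @export
print.labeling_schedule <- function(x, ...) {
  cat(sprintf(
    "<labeling_schedule> %g d label, precursor plateau %g, rise time %g d\n",
    x$label_days, x$precursor_plateau, x$precursor_rise_time))
  invisible(x)
}

check_schedule <- function(schedule) {
  if (!inherits(schedule, "labeling_schedule")) {
    abort("`schedule` must be created with `labeling_schedule()`.")
  }
  schedule
}

#' Expected heavy-lysine incorporation under first-order turnover
#'
#' For a protein degraded (and resynthesized at steady state) with rate
#' constant `k`, the fraction of its lysine sites carrying the heavy label
#' after the feeding window is, with an instantaneously labeled precursor
#' pool, `I = plateau * (1 - exp(-k * t))`. With a pool that itself
#' equilibrates exponentially with time constant `tau`, the incorporation is
#' the convolution of the two first-order systems:
#' `I = plateau * (1 - (k * exp(-t/tau) - (1/tau) * exp(-k*t)) / (k - 1/tau))`,
#' with the `k = 1/tau` degeneracy handled by its analytic limit
#' `1 - exp(-k*t) * (1 + k*t)`.
#'
#' @param k Degradation rate constant(s), 1/day; strictly positive.
#' @param schedule A [labeling_schedule()].
#' @return Incorporation fraction(s) in `[0, precursor_plateau)`.
#' @examples
#' expected_incorporation(log(2) / 6, labeling_schedule(6))  # one half-life: 0.5
#' @seealso [fit_rate_constant()] for the inverse.
#' @export
expected_incorporation <- function(k, schedule) {
  check_schedule(schedule)
  if (!is.numeric(k) || length(k) == 0L || any(!is.finite(k)) || any(k <= 0)) {
    abort("`k` must be strictly positive and finite (1/day).")
  }
  t <- schedule$label_days
  q <- schedule$precursor_plateau
  tau <- schedule$precursor_rise_time
  if (tau == 0) {
    return(q * -expm1(-k * t))
  }
  r <- 1 / tau
  out <- numeric(length(k))
  near <- abs(k - r) < 1e-8 * r
  kk <- k[!near]
  out[!near] <- 1 - (kk * exp(-r * t) - r * exp(-kk * t)) / (kk - r)
  out[near] <- -expm1(-k[near] * t) - exp(-k[near] * t) * k[near] * t
  q * out
}

#' Steady-state abundance of a first-order turnover system
#'
#' Solves `dP/dt = s - k * P = 0`, i.e. the abundance at which synthesis and
#' degradation balance.
#'
#' @param s Synthesis rate(s), abundance-units/day; strictly positive.
#' @param k Degradation rate constant(s), 1/day; strictly positive.
#' @return Steady-state abundance `s / k`.
#' @examples
#' steady_state_abundance(2, 0.5)  # 4
#' @export
steady_state_abundance <- function(s, k) {
  if (!is.numeric(s) || any(!is.finite(s)) || any(s <= 0)) {
    abort("`s` must be strictly positive and finite.")
  }
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0)) {
    abort("`k` must be strictly positive and finite.")
  }
  s / k
}

#' Invert incorporation to a degradation rate constant
#'
#' One-pool inversion of [expected_incorporation()]:
#' `k = -log(1 - I / q) / label_days`, where `q` is the heavy fraction of the
#' precursor pool. The inversion assumes instantaneous pool equilibration
#' (`precursor_rise_time = 0`); with a slowly rising pool it underestimates
#' `k`, which is why the pool estimate enters as an explicit argument rather
#' than a hidden constant.
#'
#' @param incorporation Observed incorporation fraction(s) in `[0, 1)`.
#' @param schedule A [labeling_schedule()]; only `label_days` and (as the
#'   default pool) `precursor_plateau` are used.
#' @param pool Heavy fraction of the precursor pool: a single number, or a
#'   [estimate_precursor_pool()] result (its median `q_hat` is used). Defaults
#'   to `schedule$precursor_plateau`.
#' @return Rate constant(s) in 1/day. Saturated values
#'   (`incorporation >= pool`) are not invertible and return `NA` with a
#'   warning.
#' @examples
#' fit_rate_constant(0.5, labeling_schedule(6))  # log(2)/6
#' @export
fit_rate_constant <- function(incorporation, schedule, pool = NULL) {
  check_schedule(schedule)
  if (!is.numeric(incorporation) || any(!is.finite(incorporation)) ||
      any(incorporation < 0)) {
    abort("`incorporation` must be finite and nonnegative.")
  }
  q <- resolve_pool(pool, schedule)
  saturated <- incorporation >= q
  if (any(saturated)) {
    warn(sprintf(
      "%d incorporation value(s) at or above the precursor pool (%.4g); not invertible, returning NA.",
      sum(saturated), q))
  }
  frac <- ifelse(saturated, 0, incorporation / q)
  k <- -log1p(-frac) / schedule$label_days
  k[saturated] <- NA_real_
  k
}

resolve_pool <- function(pool, schedule) {
  if (is.null(pool)) return(schedule$precursor_plateau)
  if (is.numeric(pool) && length(pool) == 1L) {
    if (!is.finite(pool) || pool <= 0 || pool > 1) {
      abort("`pool` must be in (0, 1].")
    }
    return(pool)
  }
  if (is.data.frame(pool) && "q_hat" %in% names(pool)) {
    q <- median(pool$q_hat, na.rm = TRUE)
    if (!is.finite(q) || q <= 0) abort("Precursor pool estimate is not usable.")
    return(q)
  }
  abort("`pool` must be a single number or an `estimate_precursor_pool()` result.")
}

#' Rate constant that yields a target incorporation
#'
#' Inverse of [expected_incorporation()] for any schedule. With an
#' instantaneous precursor pool the closed form is used; otherwise the rate is
#' found numerically. Used by the simulator to construct cohorts whose
#' incorporation is a prescribed multiple of the control (e.g. a uniform
#' global slowdown).
#'
#' @param target Target incorporation fraction(s), each in
#'   `(0, precursor_plateau)`.
#' @param schedule A [labeling_schedule()].
#' @return Rate constant(s) in 1/day.
#' @export
k_for_incorporation <- function(target, schedule) {
  check_schedule(schedule)
  q <- schedule$precursor_plateau
  if (!is.numeric(target) || any(!is.finite(target)) ||
      any(target <= 0) || any(target >= q)) {
    abort("`target` incorporation must lie strictly between 0 and the precursor plateau.")
  }
  if (schedule$precursor_rise_time == 0) {
    return(-log1p(-(target / q)) / schedule$label_days)
  }
  vapply(target, function(ti) {
    stats::uniroot(function(k) expected_incorporation(k, schedule) - ti,
                   interval = c(1e-10, 1e4), tol = 1e-12)$root
  }, numeric(1))
}
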