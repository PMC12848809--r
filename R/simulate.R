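#' Ground truth for a synthetic trial arm
#'
#' Describes the latent event-time distribution of one arm/endpoint together
#' with its observation scheme: administrative censoring at `max_follow_up`
#' and optional independent exponential dropout.
#'
#' @param family event-time family, see [surv_families()].
#' @param params named parameters for `family`.
#' @param n_patients arm size.
#' @param max_follow_up administrative censoring time (months); `Inf` for
#'   complete follow-up.
#' @param seed integer seed making [simulate_arm()] deterministic.
#' @param dropout_rate rate (per month) of an independent exponential
#'   censoring process; 0 (default) for administrative censoring only.
#' @return an object of class `trial_arm_truth`.
#' @export
trial_arm_truth <- function(family, params, n_patients, max_follow_up = Inf,
                            seed = 1L, dropout_rate = 0) {
  family <- match_family(family)
  params <- check_family_params(family, params)
  stopifnot(n_patients >= 1, max_follow_up >= 0, dropout_rate >= 0,
            length(seed) == 1L, is.finite(seed))
  structure(list(family = family, params = params,
                 n_patients = as.integer(n_patients),
                 max_follow_up = max_follow_up, seed = as.integer(seed),
                 dropout_rate = dropout_rate),
            class = "trial_arm_truth")
}

#' Simulate survival records for one arm
#'
#' Draws latent event times from the arm's family and censors them at
#' `max_follow_up` (and at dropout times when a dropout rate is set).
#' Deterministic given `truth$seed`; the caller's RNG state is restored.
#'
#' @param truth a [trial_arm_truth()].
#' @return data.frame with columns `time` (months) and `event` (1/0).
#' @export
simulate_arm <- function(truth) {
  stopifnot(inherits(truth, "trial_arm_truth"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(truth$seed)
  latent <- family_rand(truth$family, truth$params, truth$n_patients)
  censor <- rep(truth$max_follow_up, truth$n_patients)
  if (truth$dropout_rate > 0)
    censor <- pmin(censor, stats::rexp(truth$n_patients, truth$dropout_rate))
  data.frame(time = pmin(latent, censor), event = as.integer(latent <= censor))
}

#' Kaplan-Meier estimate as a digitized curve
#'
#' Product-limit estimator of the records, returned in the same container a
#' figure digitization would produce: exact step coordinates (prefixed with
#' (0, 1) and closed with a final coordinate at maximum follow-up) plus a
#' numbers-at-risk table on a time grid. `n_at_risk` at time t is the count
#' of records with `time >= t`.
#'
#' @param records data.frame with columns `time`, `event`.
#' @param risk_times grid for the risk table; default every 3 months from 0
#'   to the last observed time (typical spacing of published KM figures).
#' @inheritParams digitized_curve
#' @return a [digitized_curve()] with `total_events` filled in.
#' @export
km_estimate <- function(records, risk_times = NULL, endpoint = "PFS",
                        strategy_id = "arm") {
  records <- validate_ipd(records)
  if (nrow(records) == 0L) stop("no survival records", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  keep <- fit$n.event > 0
  coords <- data.frame(time = c(0, fit$time[keep]), survival = c(1, fit$surv[keep]))
  t_max <- max(records$time)
  if (t_max > max(coords$time))  # close the step function at end of follow-up
    coords <- rbind(coords, data.frame(time = t_max,
                                       survival = coords$survival[nrow(coords)]))
  if (is.null(risk_times))
    risk_times <- seq(0, max(coords$time), by = 3)
  risk_times <- risk_times[risk_times <= max(coords$time) + 1e-9]
  risk <- data.frame(time = risk_times,
                     n_at_risk = vapply(risk_times,
                                        function(t) sum(records$time >= t), 0L))
  digitized_curve(coords, risk, endpoint = endpoint, strategy_id = strategy_id,
                  total_events = sum(records$event))
}

#' Emulate figure digitization of a KM curve
#'
#' Published curves are read off a plot at limited resolution and with
#' measurement error. Curve-following extraction (automeris-style) samples
#' points along the plotted path, so this thins the step function to at most
#' `n_points` of its own corner coordinates chosen at equal arc-length
#' spacing along the (normalized) step path — segments where the curve drops
#' steeply receive proportionally more points, and retained drops stay at
#' their true step times. Optionally the survival values are then perturbed
#' with Gaussian noise (sd `jitter_sd`), clipped to \[0, 1\] and
#' re-monotonized by cumulative minimum. The risk table and any reported
#' event total pass through unchanged. With `n_points` at least the number
#' of steps and no jitter, the operation is lossless.
#'
#' @param curve a [digitized_curve()].
#' @param n_points maximum number of output coordinates (>= 2).
#' @param jitter_sd standard deviation of the y measurement error; 0 for
#'   lossless thinning.
#' @param seed optional seed for the jitter draw (caller RNG restored).
#' @export
emit_digitized <- function(curve, n_points = 100L, jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(curve, "digitized_curve"))
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be non-negative", call. = FALSE)
  ct <- curve$coords$time
  cs <- curve$coords$survival
  if (length(ct) > n_points) {
    # normalized arc length of the step path: horizontal run + vertical drop
    span <- max(ct) - min(ct)
    drop <- max(cs[1] - cs[length(cs)], .Machine$double.eps)
    arc <- c(0, cumsum(diff(ct) / max(span, .Machine$double.eps) - diff(cs) / drop))
    targets <- seq(0, arc[length(arc)], length.out = n_points)
    keep <- findInterval(targets, arc, all.inside = TRUE)
    keep <- sort(unique(c(1L, keep, length(ct))))
    grid <- ct[keep]
    s <- cs[keep]
  } else {
    grid <- ct
    s <- cs
  }
  if (jitter_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (!is.null(seed)) {
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    s[-1] <- s[-1] + stats::rnorm(length(s) - 1L, sd = jitter_sd)  # keep (0,1) exact
    s <- cummin(pmin(pmax(s, 0), 1))
  }
  digitized_curve(data.frame(time = grid, survival = s), curve$risk_table,
                  endpoint = curve$endpoint, strategy_id = curve$strategy_id,
                  total_events = curve$total_events)
}
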