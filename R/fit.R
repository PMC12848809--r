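flexsurv_dist <- function(family) {
  switch(match_family(family),
    exponential = "exp", weibull = "weibull", lognormal = "lnorm",
    loglogistic = "llogis", gompertz = "gompertz")
}

# flexsurv native parameters -> the package's canonical parameterization
canonical_params <- function(family, native) {
  switch(match_family(family),
    exponential = c(rate = unname(native[["rate"]])),
    weibull     = c(shape = unname(native[["shape"]]), scale = unname(native[["scale"]])),
    lognormal   = c(meanlog = unname(native[["meanlog"]]), sdlog = unname(native[["sdlog"]])),
    loglogistic = c(logloc = log(unname(native[["scale"]])),
                    logscale = 1 / unname(native[["shape"]])),
    gompertz    = c(shape = unname(native[["shape"]]), rate = unname(native[["rate"]])))
}

#' Fit a parametric survival family to right-censored records
#'
#' Maximum-likelihood fit via [flexsurv::flexsurvreg()], with up to three
#' starts (default initials, then perturbed) to guard against local optima.
#' AIC and BIC are recomputed from the censored-data log-likelihood as
#' `2k - 2*logLik` and `k*log(n) - 2*logLik` with `k` the number of free
#' parameters (1 for exponential, 2 otherwise). A fit that fails to converge
#' is returned with `converged = FALSE` rather than an error, so the
#' selection step can skip it.
#'
#' @param ipd data.frame with columns `time`, `event`; needs >= 2 records
#'   and >= 1 event (the likelihood is unbounded otherwise).
#' @param family one of [surv_families()].
#' @return an object of class `parametric_fit`: family, canonical `params`
#'   (see [surv_families()]), `log_likelihood`, `aic`, `bic`, `n_obs`,
#'   `n_events`, `converged`, and `est_table` (estimates and standard errors
#'   on the optimizer's scale, for Wald-type checks).
#' @export
fit_parametric <- function(ipd, family) {
  family <- match_family(family)
  ipd <- validate_ipd(ipd)
  if (nrow(ipd) < 2L) stop("need at least 2 records", call. = FALSE)
  if (sum(ipd$event) < 1L)
    stop("no events: censored-only data leave the scale unidentified", call. = FALSE)
  dist <- flexsurv_dist(family)
  # flexsurv rejects exact zeros under log-time families
  ipd$time <- pmax(ipd$time, 1e-8)

  fit <- NULL
  for (attempt in 1:3) {
    inits <- NULL
    if (attempt > 1L && !is.null(fit)) {
      inits <- fit$res[, "est"] * exp(stats::runif(nrow(fit$res), -0.3, 0.3))
    }
    args <- list(formula = survival::Surv(time, event) ~ 1, data = ipd, dist = dist)
    if (!is.null(inits)) args$inits <- inits
    cand <- tryCatch(do.call(flexsurv::flexsurvreg, args), error = function(e) NULL)
    ok <- !is.null(cand) && is.finite(cand$loglik) &&
      (is.null(cand$opt$convergence) || cand$opt$convergence == 0)
    if (ok && (is.null(fit) || cand$loglik > fit$loglik + 1e-9)) fit <- cand
    if (ok && attempt == 1L) break   # default start converged; accept
  }
  n <- nrow(ipd)
  if (is.null(fit)) {
    return(structure(list(family = family, params = NULL,
                          log_likelihood = NA_real_, aic = NA_real_,
                          bic = NA_real_, n_obs = n, n_events = sum(ipd$event),
                          converged = FALSE, est_table = NULL),
                     class = "parametric_fit"))
  }
  k <- nrow(fit$res)
  ll <- fit$loglik
  native <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  structure(list(family = family,
                 params = canonical_params(family, native),
                 log_likelihood = ll,
                 aic = 2 * k - 2 * ll,
                 bic = k * log(n) - 2 * ll,
                 n_obs = n, n_events = sum(ipd$event),
                 converged = TRUE,
                 est_table = fit$res.t[, c("est", "se"), drop = FALSE]),
            class = "parametric_fit")
}

#' @export
print.parametric_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<parametric_fit> %s: did not converge (n = %d)\n", x$family, x$n_obs))
    return(invisible(x))
  }
  cat(sprintf("<parametric_fit> %s: %s | logLik %.3f, AIC %.2f, BIC %.2f (n = %d, events = %d)\n",
              x$family,
              paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", "),
              x$log_likelihood, x$aic, x$bic, x$n_obs, x$n_events))
  invisible(x)
}

#' Select the extrapolation model by information criteria
#'
#' @param fits list of [fit_parametric()] results (converged fits only are
#'   eligible).
#' @param policy `"aic"` or `"bic"` pick the minimizer of that criterion;
#'   `"aic_then_bic"` (default) ranks by AIC and breaks near-ties
#'   (delta-AIC < 2) by BIC, which favours the more parsimonious family when
#'   AIC cannot separate them.
#' @return the selected `parametric_fit`.
#' @export
select_best <- function(fits, policy = c("aic_then_bic", "aic", "bic")) {
  policy <- match.arg(policy)
  if (inherits(fits, "parametric_fit")) fits <- list(fits)
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0L) stop("no converged fits to select from", call. = FALSE)
  aic <- vapply(fits, `[[`, 0, "aic")
  bic <- vapply(fits, `[[`, 0, "bic")
  idx <- switch(policy,
    aic = which.min(aic),
    bic = which.min(bic),
    aic_then_bic = {
      near <- which(aic - min(aic) < 2)
      near[which.min(bic[near])]
    })
  fits[[idx]]
}

#' Fitted survival function
#'
#' Evaluates S(t) of a converged fit using the family's closed form.
#'
#' @param fit a converged [fit_parametric()] result (or any
#'   `parametric_fit`-shaped list with `family` and `params`).
#' @param t non-negative times (months); vectorized.
#' @export
survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "parametric_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  family_survival(fit$family, fit$params, t)
}

#' Construct a parametric_fit from known parameters
#'
#' Convenience for tests and for driving the cohort model directly from
#' ground-truth parameters (no data involved; information criteria are NA).
#'
#' @inheritParams family_survival
#' @export
parametric_fit_from_params <- function(family, params) {
  family <- match_family(family)
  params <- check_family_params(family, params)
  structure(list(family = family, params = params,
                 log_likelihood = NA_real_, aic = NA_real_, bic = NA_real_,
                 n_obs = NA_integer_, n_events = NA_integer_,
                 converged = TRUE, est_table = NULL),
            class = "parametric_fit")
}

#' Cycle-specific transition probabilities from fitted survival curves
#'
#' With cycle boundaries `t0 = cycle_index * cycle_len` and
#' `t1 = t0 + cycle_len`, the conditional exit probability from
#' progression-free is `q_pf = 1 - S_PFS(t1)/S_PFS(t0)` and the conditional
#' death probability is `q_os = 1 - S_OS(t1)/S_OS(t0)`. The split of the PF
#' exit is the package's convention (the split is not identified by PFS and
#' OS marginals alone): OS-derived mortality bounds PF deaths,
#' `p_pf_to_death = min(q_os, q_pf)`; the remainder progresses; patients in
#' progressive disease face the same OS conditional mortality,
#' `p_pd_to_death = q_os`. All probabilities are clipped to \[0, 1\]. When a
#' survival function has already hit zero at `t0`, the state is treated as
#' absorbing into death and `absorbing = TRUE` is flagged.
#'
#' @param pfs_fit,os_fit converged [fit_parametric()] results.
#' @param cycle_index non-negative integer cycle number.
#' @param cycle_len cycle length in months (default 3 weeks).
#' @return list with `cycle_index`, `p_pf_to_pd`, `p_pf_to_death`,
#'   `p_pd_to_death`, `absorbing`.
#' @export
cycle_transition_probs <- function(pfs_fit, os_fit, cycle_index,
                                   cycle_len = cycle_length_months()) {
  stopifnot(cycle_index >= 0, cycle_len > 0)
  t0 <- cycle_index * cycle_len
  t1 <- t0 + cycle_len
  s_pf <- survival_at(pfs_fit, c(t0, t1))
  s_os <- survival_at(os_fit, c(t0, t1))
  transition_from_conditionals(s_pf[1], s_pf[2], s_os[1], s_os[2], cycle_index)
}

transition_from_conditionals <- function(spf0, spf1, sos0, sos1, cycle_index) {
  eps <- .Machine$double.xmin
  absorbing <- spf0 <= eps || sos0 <= eps
  q_pf <- if (spf0 <= eps) 1 else 1 - spf1 / spf0
  q_os <- if (sos0 <= eps) 1 else 1 - sos1 / sos0
  if (absorbing) { q_pf <- 1; q_os <- 1 }
  clip <- function(p) min(max(p, 0), 1)
  q_pf <- clip(q_pf); q_os <- clip(q_os)
  p_death <- min(q_os, q_pf)
  list(cycle_index = as.integer(cycle_index),
       p_pf_to_pd = clip(q_pf - p_death),
       p_pf_to_death = p_death,
       p_pd_to_death = q_os,
       absorbing = absorbing)
}

# vectorized transition grid over cycles 0..(n_cycles-1)
transition_grid <- function(pfs_fit, os_fit, n_cycles, cycle_len) {
  t_grid <- (0:n_cycles) * cycle_len
  s_pf <- survival_at(pfs_fit, t_grid)
  s_os <- survival_at(os_fit, t_grid)
  out <- lapply(seq_len(n_cycles), function(k)
    transition_from_conditionals(s_pf[k], s_pf[k + 1], s_os[k], s_os[k + 1], k - 1L))
  data.frame(cycle_index = vapply(out, `[[`, 0L, "cycle_index"),
             p_pf_to_pd = vapply(out, `[[`, 0, "p_pf_to_pd"),
             p_pf_to_death = vapply(out, `[[`, 0, "p_pf_to_death"),
             p_pd_to_death = vapply(out, `[[`, 0, "p_pd_to_death"),
             absorbing = vapply(out, `[[`, NA, "absorbing"))
}
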