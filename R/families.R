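#' Parametric survival families
#'
#' The five families used for extrapolation. Parameterizations:
#' \describe{
#'   \item{exponential}{`rate` (\eqn{\lambda > 0}); \eqn{S(t) = e^{-\lambda t}}.}
#'   \item{weibull}{`shape` (\eqn{k > 0}), `scale` (\eqn{\sigma > 0});
#'     \eqn{S(t) = e^{-(t/\sigma)^k}}.}
#'   \item{lognormal}{`meanlog`, `sdlog` (\eqn{> 0}): location and scale of
#'     log event time.}
#'   \item{loglogistic}{`logloc` (\eqn{\mu}), `logscale` (\eqn{\sigma > 0}):
#'     location and scale of log event time;
#'     \eqn{S(t) = 1/(1 + e^{(\log t - \mu)/\sigma})}.}
#'   \item{gompertz}{`shape` (\eqn{a}, unrestricted), `rate` (\eqn{b > 0});
#'     hazard \eqn{h(t) = b e^{a t}}, so
#'     \eqn{S(t) = \exp\{-(b/a)(e^{a t} - 1)\}}. With \eqn{a < 0} the
#'     distribution is defective (a fraction \eqn{e^{b/a}} never experiences
#'     the event). The \eqn{a \to 0} limit is exponential with rate \eqn{b}.}
#' }
#'
#' @return `surv_families()` returns the character vector of family names.
#' @export
surv_families <- function() {
  c("exponential", "weibull", "lognormal", "loglogistic", "gompertz")
}

match_family <- function(family) {
  if (!is.character(family) || length(family) != 1L || !family %in% surv_families())
    stop("unknown survival family: ", paste(family, collapse = ", "),
         " (must be one of ", paste(surv_families(), collapse = ", "), ")",
         call. = FALSE)
  family
}

family_param_names <- function(family) {
  switch(match_family(family),
    exponential = "rate",
    weibull     = c("shape", "scale"),
    lognormal   = c("meanlog", "sdlog"),
    loglogistic = c("logloc", "logscale"),
    gompertz    = c("shape", "rate"))
}

#' @rdname surv_families
#' @param family one of `surv_families()`.
#' @param params named numeric vector of family parameters (see Details).
#' @export
check_family_params <- function(family, params) {
  family <- match_family(family)
  wanted <- family_param_names(family)
  if (is.null(names(params)) || !all(wanted %in% names(params)))
    stop(sprintf("'%s' needs parameters: %s", family,
                 paste(wanted, collapse = ", ")), call. = FALSE)
  params <- params[wanted]
  if (any(!is.finite(params))) stop("non-finite family parameters", call. = FALSE)
  pos <- switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    lognormal   = "sdlog",
    loglogistic = "logscale",
    gompertz    = "rate")
  if (any(params[pos] <= 0))
    stop(sprintf("'%s': parameters %s must be positive", family,
                 paste(pos, collapse = ", ")), call. = FALSE)
  params
}

#' Survival function of a parametric family
#'
#' @inheritParams check_family_params
#' @param t non-negative times (months).
#' @return S(t), a vector the length of `t`.
#' @export
family_survival <- function(family, params, t) {
  family <- match_family(family)
  params <- check_family_params(family, params)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  out <- switch(family,
    exponential = exp(-params[["rate"]] * t),
    weibull     = exp(-(t / params[["scale"]])^params[["shape"]]),
    lognormal   = ifelse(t == 0, 1,
      stats::pnorm((log(pmax(t, .Machine$double.xmin)) - params[["meanlog"]]) /
                     params[["sdlog"]], lower.tail = FALSE)),
    loglogistic = ifelse(t == 0, 1,
      1 / (1 + exp((log(pmax(t, .Machine$double.xmin)) - params[["logloc"]]) /
                     params[["logscale"]]))),
    gompertz    = gompertz_survival(params[["shape"]], params[["rate"]], t))
  as.numeric(out)
}

# exp(-(b/a)(e^{at}-1)); uses expm1 and falls back to the exponential
# limit when |a t| is numerically negligible
gompertz_survival <- function(a, b, t) {
  if (abs(a) < 1e-12) return(exp(-b * t))
  exp(-(b / a) * expm1(a * t))
}

#' Random event times from a parametric family
#'
#' Draws from the current RNG stream (seed management is the caller's job;
#' [simulate_arm()] seeds from its `TrialArmTruth`). Gompertz draws with
#' negative shape can be `Inf` (the defective fraction never progresses/dies).
#'
#' @inheritParams family_survival
#' @param n number of draws.
#' @export
family_rand <- function(family, params, n) {
  family <- match_family(family)
  params <- check_family_params(family, params)
  switch(family,
    exponential = stats::rexp(n, rate = params[["rate"]]),
    weibull     = stats::rweibull(n, shape = params[["shape"]], scale = params[["scale"]]),
    lognormal   = stats::rlnorm(n, meanlog = params[["meanlog"]], sdlog = params[["sdlog"]]),
    loglogistic = {
      u <- stats::runif(n)  # inversion of S(t) = 1/(1+exp((log t - mu)/sigma))
      exp(params[["logloc"]] + params[["logscale"]] * log((1 - u) / u))
    },
    gompertz    = flexsurv::rgompertz(n, shape = params[["shape"]], rate = params[["rate"]]))
}

#' Median event time of a parametric family
#' @inheritParams family_survival
#' @export
family_median <- function(family, params) {
  family <- match_family(family)
  params <- check_family_params(family, params)
  switch(family,
    exponential = log(2) / params[["rate"]],
    weibull     = params[["scale"]] * log(2)^(1 / params[["shape"]]),
    lognormal   = exp(params[["meanlog"]]),
    loglogistic = exp(params[["logloc"]]),
    gompertz    = {
      a <- params[["shape"]]; b <- params[["rate"]]
      if (abs(a) < 1e-12) log(2) / b
      else if (a < 0 && exp(b / a) > 0.5) Inf   # defective: S never reaches 1/2
      else log1p(a * log(2) / b) / a
    })
}
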