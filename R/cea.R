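#' Incremental cost-effectiveness table with dominance classification
#'
#' The reference is the least costly non-dominated strategy. A strategy is
#' strictly dominated when some other strategy costs no more and yields no
#' fewer QALYs (with at least one strict inequality). Extended dominance is
#' then applied on the remaining frontier: a strategy whose incremental
#' ICER exceeds that of a more effective alternative is removed, so frontier
#' ICERs are strictly increasing in effectiveness. Deltas and ICERs versus
#' the reference are reported for every strategy (ICER only where the QALY
#' gain is positive); `frontier_icer` is the sequential ICER along the
#' efficiency frontier.
#'
#' @param results list of [accumulate_econ()] results (or a data.frame with
#'   columns `strategy`, `cost`, `qalys`); strategy names must be unique.
#' @return a data.frame of class `cea_table` with columns `strategy`,
#'   `cost`, `qalys`, `delta_cost`, `delta_qalys`, `icer`, `dominance`
#'   (none/strict/extended), `on_frontier`, `frontier_icer`.
#' @export
icer_table <- function(results) {
  df <- if (is.data.frame(results)) results
        else data.frame(strategy = vapply(results, `[[`, "", "strategy"),
                        cost = vapply(results, `[[`, 0, "total_cost"),
                        qalys = vapply(results, `[[`, 0, "total_qalys"))
  stopifnot(all(c("strategy", "cost", "qalys") %in% names(df)), nrow(df) >= 2)
  if (anyDuplicated(df$strategy))
    stop("duplicate strategy names", call. = FALSE)
  n <- nrow(df)
  dominance <- rep("none", n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    strict <- any(df$cost[others] <= df$cost[i] & df$qalys[others] >= df$qalys[i] &
                  (df$cost[others] < df$cost[i] | df$qalys[others] > df$qalys[i]))
    if (strict) dominance[i] <- "strict"
  }
  # extended dominance on the surviving candidates, ordered by effectiveness
  frontier <- order(df$qalys, df$cost)
  frontier <- frontier[dominance[frontier] == "none"]
  repeat {
    if (length(frontier) < 3L) break
    dc <- diff(df$cost[frontier]); dq <- diff(df$qalys[frontier])
    icer_seq <- ifelse(dq > 0, dc / dq, Inf)
    drop <- which(diff(icer_seq) < 0)   # ICER exceeds that of next step up
    if (!length(drop)) break
    dominance[frontier[drop[1] + 1L]] <- "extended"
    frontier <- frontier[-(drop[1] + 1L)]
  }
  ref <- frontier[which.min(df$cost[frontier])]
  delta_cost <- df$cost - df$cost[ref]
  delta_qalys <- df$qalys - df$qalys[ref]
  icer <- ifelse(delta_qalys > 0, delta_cost / delta_qalys, NA_real_)
  icer[ref] <- NA_real_
  delta_cost[ref] <- NA_real_; delta_qalys[ref] <- NA_real_
  frontier_icer <- rep(NA_real_, n)
  if (length(frontier) > 1L) {
    fi <- diff(df$cost[frontier]) / diff(df$qalys[frontier])
    frontier_icer[frontier[-1]] <- fi
  }
  out <- data.frame(strategy = df$strategy, cost = df$cost, qalys = df$qalys,
                    delta_cost = delta_cost, delta_qalys = delta_qalys,
                    icer = icer, dominance = dominance,
                    on_frontier = seq_len(n) %in% frontier,
                    frontier_icer = frontier_icer)
  attr(out, "reference") <- df$strategy[ref]
  class(out) <- c("cea_table", "data.frame")
  out
}

#' Preferred strategy at a willingness-to-pay threshold
#'
#' Walks the efficiency frontier from the reference upward and returns the
#' most effective strategy whose sequential ICER does not exceed `wtp`
#' (equivalent to maximizing deterministic net monetary benefit over the
#' frontier).
#'
#' @param table an [icer_table()].
#' @param wtp willingness-to-pay threshold, CNY/QALY.
#' @return the preferred strategy name.
#' @export
check_wtp_decision <- function(table, wtp) {
  stopifnot(inherits(table, "cea_table"), wtp >= 0)
  f <- table[table$on_frontier, , drop = FALSE]
  f <- f[order(f$qalys, f$cost), , drop = FALSE]
  preferred <- f$strategy[1]
  for (j in seq_len(nrow(f))[-1]) {
    if (!is.na(f$frontier_icer[j]) && f$frontier_icer[j] <= wtp)
      preferred <- f$strategy[j]
    else break
  }
  preferred
}

#' Distribution specification for a model parameter
#'
#' @param name parameter name (see [econ_param_names()] for the parameters
#'   the packaged model understands).
#' @param family `"gamma"` (costs), `"beta"` (utilities/probabilities) or
#'   `"fixed"`.
#' @param base,low,high base-case value and plausible range
#'   (`low <= base <= high`). The range is used both as the one-way
#'   sensitivity interval and, read as a 95\% interval, to set the spread of
#'   the PSA distribution: `se = (high - low)/(2 * 1.96)`.
#' @export
distribution_spec <- function(name, family = c("gamma", "beta", "fixed"),
                              base, low = base, high = base) {
  family <- match.arg(family)
  stopifnot(low <= base + 1e-12, base <= high + 1e-12)
  if (family == "beta" && (low < 0 || high > 1))
    stop("beta parameters must lie in [0, 1]", call. = FALSE)
  structure(list(name = name, family = family, base = base,
                 low = low, high = high),
            class = "distribution_spec")
}

#' Moment-matched sampler for a distribution specification
#'
#' Gamma: `shape = base^2/se^2`, `scale = se^2/base`. Beta: method-of-moments
#' alpha/beta with mean `base` and the same `se`. A zero `se` with a
#' non-fixed family degenerates to fixed with a warning. The sampler draws
#' from the current RNG stream.
#'
#' @param spec a [distribution_spec()].
#' @return function of `n` returning `n` draws.
#' @export
parameterize_distribution <- function(spec) {
  stopifnot(inherits(spec, "distribution_spec"))
  se <- (spec$high - spec$low) / (2 * 1.96)
  base <- spec$base
  if (spec$family == "fixed") return(function(n) rep(base, n))
  if (se == 0) {
    warning(sprintf("parameter '%s': zero range, treated as fixed", spec$name),
            call. = FALSE)
    return(function(n) rep(base, n))
  }
  if (spec$family == "gamma") {
    shape <- base^2 / se^2
    scale <- se^2 / base
    return(function(n) stats::rgamma(n, shape = shape, scale = scale))
  }
  # beta by method of moments; requires var < mean(1-mean)
  v <- se^2
  if (v >= base * (1 - base)) {
    warning(sprintf("parameter '%s': range too wide for a beta with this mean, treated as fixed",
                    spec$name), call. = FALSE)
    return(function(n) rep(base, n))
  }
  nu <- base * (1 - base) / v - 1
  function(n) stats::rbeta(n, shape1 = base * nu, shape2 = (1 - base) * nu)
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the pairwise ICER of `comparator[1]` versus `comparator[2]`
#' with each parameter set to its low and high bound while all others stay
#' at base. Entries are sorted by descending ICER width. A bound at which
#' the QALY difference is not positive yields an undefined ICER and is
#' flagged rather than dropped; parameters without a handle in the model
#' get width 0.
#'
#' @param context a model context from [build_context()].
#' @param dist_specs list of [distribution_spec()]s.
#' @param comparator length-2 character: (intervention, reference).
#' @return data.frame of class `tornado`: `parameter`, `base`, `low`,
#'   `high`, `icer_base`, `icer_low`, `icer_high`, `width`, `flagged`.
#' @export
one_way_sa <- function(context, dist_specs,
                       comparator = c("camrelizumab", "sintilimab")) {
  stopifnot(length(comparator) == 2L)
  pair_icer <- function(overrides = NULL) {
    res <- evaluate_strategies(context, overrides)
    a <- res[res$strategy == comparator[1], ]
    b <- res[res$strategy == comparator[2], ]
    if (nrow(a) != 1L || nrow(b) != 1L)
      stop("comparator strategies not found in context", call. = FALSE)
    dq <- a$qalys - b$qalys
    if (dq <= 0) return(NA_real_)
    (a$cost - b$cost) / dq
  }
  base_icer <- pair_icer()
  rows <- lapply(dist_specs, function(sp) {
    known <- sp$name %in% econ_param_names()
    il <- if (known) pair_icer(stats::setNames(sp$low, sp$name)) else base_icer
    ih <- if (known) pair_icer(stats::setNames(sp$high, sp$name)) else base_icer
    data.frame(parameter = sp$name, base = sp$base, low = sp$low, high = sp$high,
               icer_base = base_icer, icer_low = il, icer_high = ih,
               width = if (is.na(il) || is.na(ih)) NA_real_ else abs(ih - il),
               flagged = is.na(il) || is.na(ih) || !known)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$width), Inf, out$width)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws all parameters jointly per iteration (one draw per
#' [distribution_spec()], shared across strategies) and re-evaluates
#' discounted costs and QALYs for every strategy through the cohort model.
#' Survival-model parameters are not resampled: the fitted traces are the
#' conditional backbone, and parameter uncertainty enters through costs and
#' utilities (the distributions the source tables specify). Iterations that
#' error are recorded; more than 1\% failures aborts.
#'
#' @param context a model context from [build_context()].
#' @param dist_specs list of [distribution_spec()]s.
#' @param n_iterations number of Monte Carlo draws (default 10,000).
#' @param seed RNG seed; the result is reproducible given the seed.
#' @return object of class `psa_result`: list with `cost` and `qalys`
#'   (n x strategies matrices), `draws`, `strategies`, `n_iterations`,
#'   `seed`, `failures`.
#' @export
run_psa <- function(context, dist_specs, n_iterations = 10000L, seed = 1L) {
  stopifnot(n_iterations >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  samplers <- lapply(dist_specs, parameterize_distribution)
  names(samplers) <- vapply(dist_specs, `[[`, "", "name")
  draws <- vapply(samplers, function(f) f(n_iterations), numeric(n_iterations))
  if (n_iterations == 1L) draws <- matrix(draws, nrow = 1,
                                          dimnames = list(NULL, names(samplers)))
  strategies <- vapply(context$strategies, `[[`, "", "name")
  cost <- matrix(NA_real_, n_iterations, length(strategies),
                 dimnames = list(NULL, strategies))
  qalys <- cost
  failures <- integer(0)
  for (i in seq_len(n_iterations)) {
    res <- tryCatch(evaluate_strategies(context, draws[i, ]),
                    error = function(e) NULL)
    if (is.null(res)) { failures <- c(failures, i); next }
    cost[i, res$strategy] <- res$cost
    qalys[i, res$strategy] <- res$qalys
  }
  if (length(failures) > 0.01 * n_iterations)
    stop(sprintf("PSA aborted: %d/%d iterations failed", length(failures),
                 n_iterations), call. = FALSE)
  structure(list(cost = cost, qalys = qalys, draws = draws,
                 strategies = strategies, n_iterations = n_iterations,
                 seed = seed, failures = failures),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations x %d strategies (seed %d, %d failures)\n",
              x$n_iterations, length(x$strategies), x$seed, length(x$failures)))
  for (s in x$strategies)
    cat(sprintf("  %s: mean cost %.0f, mean QALYs %.3f\n",
                s, mean(x$cost[, s], na.rm = TRUE), mean(x$qalys[, s], na.rm = TRUE)))
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, the probability that a strategy is
#' cost-effective is the fraction of PSA iterations in which it attains the
#' highest net monetary benefit `wtp * qalys - cost`; exact ties split
#' equally, so the probabilities always partition to 1.
#'
#' @param psa a [run_psa()] result.
#' @param wtp_grid vector of thresholds (CNY/QALY); default 0 to 400,000 in
#'   steps of 10,000, plus the 287,247 decision threshold.
#' @return data.frame of class `ceac`: column `wtp` plus one probability
#'   column per strategy.
#' @export
ceac <- function(psa, wtp_grid = default_wtp_grid()) {
  stopifnot(inherits(psa, "psa_result"))
  if (length(wtp_grid) == 0L) stop("empty WTP grid", call. = FALSE)
  keep <- setdiff(seq_len(psa$n_iterations), psa$failures)
  q <- psa$qalys[keep, , drop = FALSE]
  cst <- psa$cost[keep, , drop = FALSE]
  probs <- t(vapply(wtp_grid, function(w) {
    nmb <- w * q - cst
    best <- nmb == apply(nmb, 1, max)
    colMeans(best / rowSums(best))
  }, numeric(ncol(q))))
  out <- data.frame(wtp = wtp_grid, probs)
  names(out) <- c("wtp", colnames(q))
  class(out) <- c("ceac", "data.frame")
  out
}

#' @rdname ceac
#' @export
default_wtp_grid <- function() sort(unique(c(seq(0, 400000, by = 10000), 3 * 95749)))
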