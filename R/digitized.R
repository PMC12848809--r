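#' Digitized Kaplan-Meier curve
#'
#' The unit of survival evidence entering the pipeline: (time, survival)
#' coordinates of a published KM step function together with its
#' numbers-at-risk table, as produced by figure digitization (or by
#' [km_estimate()] / [emit_digitized()] on synthetic data).
#'
#' Invariants enforced by the constructor: coordinates start at (0, 1);
#' survival is non-increasing and in \[0, 1\]; risk-table times are
#' non-decreasing with non-increasing counts; every risk-table time lies
#' within the coordinate time span.
#'
#' @param coords data.frame with columns `time` (months) and `survival`.
#' @param risk_table data.frame with columns `time` and `n_at_risk`.
#' @param endpoint "PFS" or "OS".
#' @param strategy_id identifier of the treatment arm.
#' @param total_events optional total number of events (used by
#'   [reconstruct_ipd()] when available; `NULL` when the publication does not
#'   report it, e.g. median OS not reached).
#' @return an object of class `digitized_curve`.
#' @export
digitized_curve <- function(coords, risk_table, endpoint = c("PFS", "OS"),
                            strategy_id = "arm", total_events = NULL) {
  endpoint <- match.arg(endpoint)
  coords <- as.data.frame(coords)
  risk_table <- as.data.frame(risk_table)
  stopifnot(all(c("time", "survival") %in% names(coords)),
            all(c("time", "n_at_risk") %in% names(risk_table)))
  if (nrow(coords) < 1L || coords$time[1] != 0 || coords$survival[1] != 1)
    stop("coords must begin at (0, 1.0)", call. = FALSE)
  if (is.unsorted(coords$time))
    stop("coord times must be non-decreasing", call. = FALSE)
  if (any(diff(coords$survival) > 1e-12))
    stop("survival must be non-increasing in time", call. = FALSE)
  if (any(coords$survival < -1e-12 | coords$survival > 1 + 1e-12))
    stop("survival values must lie in [0, 1]", call. = FALSE)
  coords$survival <- pmin(pmax(coords$survival, 0), 1)
  if (nrow(risk_table) < 1L)
    stop("risk_table must have at least one entry", call. = FALSE)
  if (is.unsorted(risk_table$time))
    stop("risk_table times must be non-decreasing", call. = FALSE)
  if (any(diff(risk_table$n_at_risk) > 0))
    stop("n_at_risk must be non-increasing", call. = FALSE)
  if (any(risk_table$n_at_risk < 0))
    stop("n_at_risk must be non-negative", call. = FALSE)
  span <- range(coords$time)
  if (any(risk_table$time < span[1] - 1e-9 | risk_table$time > span[2] + 1e-9))
    stop("every risk_table time must lie within the coordinate time span",
         call. = FALSE)
  if (!is.null(total_events)) {
    stopifnot(length(total_events) == 1L, total_events >= 0)
    total_events <- as.integer(round(total_events))
  }
  structure(list(endpoint = endpoint, strategy_id = strategy_id,
                 coords = coords[, c("time", "survival")],
                 risk_table = risk_table[, c("time", "n_at_risk")],
                 total_events = total_events),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("<digitized_curve> %s / %s: %d coordinates over [%g, %g] months, %d risk times%s\n",
              x$strategy_id, x$endpoint, nrow(x$coords),
              min(x$coords$time), max(x$coords$time), nrow(x$risk_table),
              if (is.null(x$total_events)) ""
              else sprintf(", %d events reported", x$total_events)))
  invisible(x)
}

#' Step-function evaluation of a digitized curve
#'
#' Right-continuous interpolation of the KM step function at arbitrary times.
#'
#' @param curve a [digitized_curve()].
#' @param t times (months) within or beyond the coordinate span (constant
#'   extrapolation of the last value beyond it).
#' @export
curve_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "digitized_curve"))
  f <- stats::stepfun(curve$coords$time[-1], curve$coords$survival, right = FALSE)
  f(t)
}

curve_paths <- function(dir, strategy_id, endpoint) {
  base <- sprintf("%s_%s", strategy_id, endpoint)
  list(curve = file.path(dir, paste0(base, "_curve.csv")),
       risk  = file.path(dir, paste0(base, "_risk.csv")))
}

#' Read and write digitized curves
#'
#' The on-disk dialect is a pair of CSVs named
#' `{strategy}_{endpoint}_curve.csv` (columns `time,survival`) and
#' `{strategy}_{endpoint}_risk.csv` (columns `time,n_at_risk`).
#'
#' @param curve a [digitized_curve()].
#' @param dir directory holding the CSV pair.
#' @return `write_digitized_curve` returns the two file paths invisibly;
#'   `read_digitized_curve` returns a [digitized_curve()].
#' @export
write_digitized_curve <- function(curve, dir) {
  stopifnot(inherits(curve, "digitized_curve"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- curve_paths(dir, curve$strategy_id, curve$endpoint)
  utils::write.csv(curve$coords, p$curve, row.names = FALSE)
  utils::write.csv(curve$risk_table, p$risk, row.names = FALSE)
  invisible(unlist(p))
}

#' @rdname write_digitized_curve
#' @param strategy_id,endpoint identify the CSV pair to read.
#' @param total_events optional event count to attach (the CSV dialect does
#'   not carry it).
#' @export
read_digitized_curve <- function(dir, strategy_id, endpoint,
                                 total_events = NULL) {
  p <- curve_paths(dir, strategy_id, endpoint)
  for (f in unlist(p)) if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  digitized_curve(utils::read.csv(p$curve), utils::read.csv(p$risk),
                  endpoint = endpoint, strategy_id = strategy_id,
                  total_events = total_events)
}

#' Read and write individual-patient survival records
#'
#' CSV with header `time,event` (`event` 1 = event, 0 = censored).
#'
#' @param ipd data.frame with columns `time`, `event`.
#' @param path CSV path.
#' @export
write_ipd <- function(ipd, path) {
  ipd <- validate_ipd(ipd)
  utils::write.csv(ipd, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ipd
#' @export
read_ipd <- function(path) {
  validate_ipd(utils::read.csv(path))
}

validate_ipd <- function(ipd) {
  ipd <- as.data.frame(ipd)
  stopifnot(all(c("time", "event") %in% names(ipd)))
  if (any(ipd$time < 0)) stop("survival times must be non-negative", call. = FALSE)
  if (!all(ipd$event %in% c(0, 1))) stop("event must be 0 or 1", call. = FALSE)
  ipd[, c("time", "event")]
}
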