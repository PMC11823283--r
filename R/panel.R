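#' Construct a unit-time-outcome count panel
#'
#' Bundles observed counts over areal units, time points and outcomes with
#' the matching censor flags and populations.  Cells flagged as censored are
#' only known to lie in the suppression interval \[1, 5\]; the stored count
#' value at such cells is ignored by all likelihood code (and may be `NA`).
#'
#' @param counts integer array of dimension `I x J x K` (unit, time, outcome);
#'   `NA` allowed only where `censored` is `TRUE`.
#' @param censored logical array of the same dimension (default: none).
#' @param populations positive numeric matrix `I x J`.
#' @param unit_labels,time_labels,outcome_labels optional character vectors.
#' @return An object of class `count_panel`.
#' @export
count_panel <- function(counts, censored = NULL, populations,
                        unit_labels = NULL, time_labels = NULL,
                        outcome_labels = NULL) {
  counts <- as.array(counts)
  if (length(dim(counts)) != 3L)
    stop("`counts` must be a 3-d array (unit x time x outcome)")
  d <- dim(counts)
  if (is.null(censored)) censored <- array(FALSE, d)
  censored <- array(as.logical(censored), dim(as.array(censored)))
  if (!identical(dim(censored), d))
    stop("`censored` must have the same dimensions as `counts`")
  populations <- as.matrix(populations)
  if (!identical(dim(populations), d[1:2]))
    stop("`populations` must be an I x J matrix matching `counts`")
  if (any(!is.finite(populations)) || any(populations <= 0))
    stop("populations must be strictly positive")
  obs <- counts[!censored]
  if (any(is.na(obs)))
    stop("observed (uncensored) counts must not be NA")
  if (any(obs < 0) || any(obs != round(obs)))
    stop("observed counts must be nonnegative integers")
  lab <- function(x, n, pre) if (is.null(x)) paste0(pre, seq_len(n)) else {
    if (length(x) != n) stop("label length does not match dimension")
    as.character(x)
  }
  structure(list(
    counts = counts, censored = censored, populations = populations,
    unit_labels = lab(unit_labels, d[1], "unit"),
    time_labels = lab(time_labels, d[2], "time"),
    outcome_labels = lab(outcome_labels, d[3], "outcome")
  ), class = "count_panel")
}

#' @export
print.count_panel <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("count_panel: %d units x %d times x %d outcomes (%d censored cells)\n",
              d[1], d[2], d[3], sum(x$censored)))
  invisible(x)
}

#' @export
dim.count_panel <- function(x) dim(x$counts)

#' Baseline statewide rates per outcome
#'
#' The rate of outcome k is the total count over all units at the baseline
#' time divided by the total population at that time.  Censored cells enter
#' the totals at the midpoint of the suppression interval \[1, 5\].
#'
#' @param panel a [count_panel].
#' @param baseline_time time index of the baseline (default 1, the first
#'   time point).
#' @param censored_value value imputed for censored cells (default 3, the
#'   integer centre of the suppression interval).
#' @return numeric vector of positive rates, one per outcome.
#' @export
baseline_rates <- function(panel, baseline_time = 1L, censored_value = 3) {
  stopifnot(inherits(panel, "count_panel"))
  d <- dim(panel$counts)
  if (length(baseline_time) != 1L || is.na(baseline_time) ||
      baseline_time < 1L || baseline_time > d[2])
    stop("invalid baseline time index")
  ptot <- sum(panel$populations[, baseline_time])
  r <- numeric(d[3])
  for (k in seq_len(d[3])) {
    y <- panel$counts[, baseline_time, k]
    cns <- panel$censored[, baseline_time, k]
    y[cns] <- censored_value
    r[k] <- sum(y) / ptot
    if (r[k] <= 0)
      stop(sprintf("zero baseline rate for outcome '%s'",
                   panel$outcome_labels[k]))
  }
  names(r) <- panel$outcome_labels
  r
}

#' Expected counts under the baseline rates
#'
#' `E[i,j,k] = P[i,j] * r[k]`: the Poisson offset of the model.
#'
#' @param panel a [count_panel].
#' @param rates positive numeric vector, one rate per outcome.
#' @return An object of class `expected_counts` with elements `rates` and
#'   `expected` (an `I x J x K` array).
#' @export
expected_counts <- function(panel, rates) {
  stopifnot(inherits(panel, "count_panel"))
  d <- dim(panel$counts)
  if (length(rates) != d[3]) stop("one rate per outcome required")
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("rates must be strictly positive")
  E <- outer(panel$populations, rates)
  dimnames(E) <- NULL
  structure(list(rates = rates, expected = E), class = "expected_counts")
}
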