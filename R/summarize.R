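#' Posterior summary table
#'
#' One row per scalar parameter with posterior mean and equal-tailed 95%
#' credible interval (2.5th / 97.5th percentiles).  Structural zeros of the
#' loadings (and of the identified matrix `L`) are reported as exact 0.
#'
#' @param samples a `dsfm_samples` object.
#' @return data.frame with columns `parameter`, `mean`, `lo95`, `hi95`.
#' @export
summarize_samples <- function(samples) {
  stopifnot(inherits(samples, "dsfm_samples"))
  if (samples$n_retained < 2L)
    stop("at least 2 retained draws are required to summarize")
  dm <- samples$dims
  pat <- samples$pattern
  lab <- samples$outcome_labels
  qfun <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  rows <- list()
  add <- function(name, x, structural_zero = FALSE) {
    if (structural_zero) {
      rows[[length(rows) + 1L]] <<- data.frame(
        parameter = name, mean = 0, lo95 = 0, hi95 = 0)
    } else {
      q <- qfun(x)
      rows[[length(rows) + 1L]] <<- data.frame(
        parameter = name, mean = mean(x), lo95 = q[1], hi95 = q[2])
    }
  }
  for (mm in seq_len(dm$m)) for (k in seq_len(dm$K)) {
    col <- (mm - 1L) * dm$K + k
    add(sprintf("gamma[%s,%d]", lab[k], mm), samples$draws$gamma[, col],
        structural_zero = !pat$mask[k, mm])
  }
  ord <- pat$outcome_order
  for (mm in seq_len(dm$m)) for (k in seq_len(dm$K)) {
    col <- (mm - 1L) * dm$K + k
    add(sprintf("L[%s,%d]", lab[ord[k]], mm), samples$draws$L[, col],
        structural_zero = k <= dm$m && mm > k)
  }
  for (mm in seq_len(dm$m)) for (j in seq_len(dm$J))
    add(sprintf("mu[%d,%d]", j, mm),
        samples$draws$mu[, (mm - 1L) * dm$J + j])
  for (mm in seq_len(dm$m)) add(sprintf("eta[%d]", mm),
                                samples$draws$eta[, mm])
  for (k in seq_len(dm$K)) add(sprintf("sigma2[%s]", lab[k]),
                               samples$draws$sigma2[, k])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
summary.dsfm_samples <- function(object, ...) summarize_samples(object)

#' Split-chain potential scale reduction factor
#'
#' Split-R-hat of a single chain: the chain is halved and the usual
#' between/within variance ratio computed.  A convergence diagnostic, not a
#' gate.
#'
#' @param x numeric vector of draws.
#' @return scalar R-hat (NA for degenerate chains).
#' @export
split_rhat <- function(x) {
  n <- length(x) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(x[seq_len(n)], x[seq_len(n) + n])
  W <- mean(apply(halves, 2, stats::var))
  B <- n * stats::var(colMeans(halves))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of a chain
#'
#' Initial-positive-sequence estimator based on the sample
#' autocorrelations.
#'
#' @param x numeric vector of draws.
#' @return scalar effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 2L, 200L), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r < 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}
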