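#' Log relative risk implied by loadings, factors and heterogeneity
#'
#' `log lambda[i,j,k] = Gamma[k, ] . F[i,j, ] + eps[i,j,k]`.
#'
#' @param loadings `K x m` loadings matrix.
#' @param factors `I x J x m` array of latent factor values.
#' @param noise optional list with element `epsilon` (`I x J x K` array);
#'   `NULL` means no heterogeneity term.
#' @return `I x J x K` array of log relative risks.
#' @export
linear_predictor <- function(loadings, factors, noise = NULL) {
  loadings <- as.matrix(loadings)
  factors <- as.array(factors)
  if (length(dim(factors)) != 3L)
    stop("`factors` must be a 3-d array (unit x time x factor)")
  d <- dim(factors)
  if (ncol(loadings) != d[3])
    stop("dimension mismatch: ncol(loadings) != number of factors")
  K <- nrow(loadings)
  fmat <- matrix(factors, nrow = d[1] * d[2], ncol = d[3])
  lp <- array(fmat %*% t(loadings), dim = c(d[1], d[2], K))
  if (!is.null(noise) && !is.null(noise$epsilon)) {
    eps <- as.array(noise$epsilon)
    if (!identical(dim(eps), dim(lp)))
      stop("dimension mismatch: epsilon vs linear predictor")
    lp <- lp + eps
  }
  lp
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Interval-censored Poisson log-likelihood contribution
#'
#' Log of the Poisson pmf summed over the suppression interval,
#' `log sum_{y=lower}^{upper} Poisson(y; mu)`, vectorised over `mu`.
#'
#' @param mu positive Poisson means.
#' @param lower,upper integer interval bounds (default the suppression
#'   interval 1..5, inclusive).
#' @return numeric vector of log-probabilities.
#' @export
pois_interval_loglik <- function(mu, lower = 1L, upper = 5L) {
  ys <- seq.int(lower, upper)
  lp <- vapply(mu, function(m) log_sum_exp(stats::dpois(ys, m, log = TRUE)),
               numeric(1))
  lp
}

#' Observation-level log-likelihood of a count panel
#'
#' Sum over all cells of the Poisson log-pmf at mean `E * lambda`; censored
#' cells contribute the interval probability over counts 1..5.
#'
#' @param panel a [count_panel].
#' @param expected an [expected_counts] object (or an `I x J x K` array).
#' @param loglambda `I x J x K` array of log relative risks.
#' @return scalar log-likelihood.
#' @export
obs_loglik <- function(panel, expected, loglambda) {
  stopifnot(inherits(panel, "count_panel"))
  E <- if (inherits(expected, "expected_counts")) expected$expected else
    as.array(expected)
  if (!identical(dim(E), dim(panel$counts)) ||
      !identical(dim(as.array(loglambda)), dim(panel$counts)))
    stop("shape mismatch between panel, expected counts and log-lambda")
  mu <- E * exp(loglambda)
  cns <- panel$censored
  ll <- 0
  if (any(!cns))
    ll <- ll + sum(stats::dpois(panel$counts[!cns], mu[!cns], log = TRUE))
  if (any(cns))
    ll <- ll + sum(pois_interval_loglik(mu[cns]))
  ll
}

#' Proportion of outcome variability explained by the factors
#'
#' For outcome k, `v_k = Var(Gamma_k . F) / (Var(Gamma_k . F) + sigma2_k)`,
#' with the variance taken empirically over all unit-time cells.
#'
#' @param loadings `K x m` loadings matrix.
#' @param factors `I x J x m` array (or `(I*J) x m` matrix) of factor values.
#' @param sigma2 positive variance per outcome.
#' @return numeric vector in \[0, 1\], one value per outcome.
#' @export
variance_explained <- function(loadings, factors, sigma2) {
  loadings <- as.matrix(loadings)
  if (length(dim(factors)) == 3L)
    factors <- matrix(factors, nrow = dim(factors)[1] * dim(factors)[2])
  factors <- as.matrix(factors)
  if (nrow(factors) < 2L)
    stop("at least 2 unit-time cells are required")
  if (length(sigma2) != nrow(loadings))
    stop("one sigma2 per outcome required")
  fit <- factors %*% t(loadings)
  v <- apply(fit, 2, stats::var)
  out <- ifelse(v + sigma2 > 0, v / (v + sigma2), 0)
  names(out) <- rownames(loadings)
  out
}
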