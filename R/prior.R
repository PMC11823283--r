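#' Factor hyperparameters
#'
#' Statewide means `mu[j, m]` per time and factor, and temporal AR(1)
#' coefficients `eta[m]` in (0, 1).
#'
#' @param mu `J x m` numeric matrix.
#' @param eta numeric vector of length `m`, each in (0, 1).
#' @return An object of class `factor_hyper`.
#' @export
factor_hyper <- function(mu, eta) {
  mu <- as.matrix(mu)
  if (length(eta) != ncol(mu))
    stop("one eta per factor (column of mu) required")
  if (any(eta <= 0) || any(eta >= 1))
    stop("eta must lie strictly inside (0, 1)")
  structure(list(mu = mu, eta = as.numeric(eta)), class = "factor_hyper")
}

#' ICAR full-conditional mean and variance of one unit
#'
#' Conditional on all other units' current values, a unit's value is normal
#' with mean `center + sum_l (w_il / w_i+)(values_l - center)` and variance
#' `1 / w_i+`.
#'
#' @param values numeric vector of per-unit values.
#' @param center the common centering level (e.g. the statewide mean).
#' @param unit unit index.
#' @param graph an [adjacency_graph].
#' @return list with `mean` and `variance`.
#' @export
icar_conditional <- function(values, center, unit, graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (unit < 1L || unit > graph$n) stop("invalid unit index")
  d <- graph$degrees[unit]
  if (d < 1L) stop("isolated unit: graph invariant violated")
  nb <- graph$nbr[[unit]]
  list(mean = center + sum(values[nb] - center) / d, variance = 1 / d)
}

#' AR(1)-shifted conditional centering level
#'
#' `mu_jm + eta * (f_prev - mu_(j-1)m)`: the temporal shift of the ICAR
#' centering level for years after the first.
#'
#' @param mu_j,mu_jprev statewide means at the current and previous year.
#' @param eta temporal autoregressive coefficient.
#' @param f_prev the unit's factor value at the previous year.
#' @return numeric.
#' @export
ar1_shifted_mean <- function(mu_j, mu_jprev, eta, f_prev) {
  mu_j + eta * (f_prev - mu_jprev)
}

factor_innovations <- function(f, hyper) {
  d <- dim(f)
  e <- f
  for (mm in seq_len(d[3])) {
    e[, 1, mm] <- f[, 1, mm] - hyper$mu[1, mm]
    if (d[2] > 1L) for (j in 2:d[2])
      e[, j, mm] <- (f[, j, mm] - hyper$mu[j, mm]) -
        hyper$eta[mm] * (f[, j - 1, mm] - hyper$mu[j - 1, mm])
  }
  e
}

#' Joint log-density of the latent factor field (up to a constant)
#'
#' With innovations `e_i1m = f_i1m - mu_1m` and, for later years,
#' `e_ijm = (f_ijm - mu_jm) - eta_m (f_i(j-1)m - mu_(j-1)m)`, returns the
#' pairwise-difference ICAR log-density
#' `sum_m sum_j ( -1/2 sum_(i,l) in edges (e_ijm - e_ljm)^2 )`.
#' This density is flat along the constant vector within each (year,
#' factor); the sampler completes it with a proper statewide-mean component
#' (see the package vignette) and the per-year centering constraint.
#'
#' @param f `I x J x m` factor array.
#' @param hyper a [factor_hyper].
#' @param graph an [adjacency_graph].
#' @param check_centered error when the field is not centered (per-year,
#'   per-factor mean of `f - mu` above `1e-8`); disable to evaluate
#'   perturbed fields.
#' @return scalar log-density up to an additive constant.
#' @export
joint_logprior <- function(f, hyper, graph, check_centered = TRUE) {
  stopifnot(inherits(hyper, "factor_hyper"), inherits(graph, "adjacency_graph"))
  f <- as.array(f)
  d <- dim(f)
  if (length(d) != 3L || d[1] != graph$n ||
      !identical(d[2:3], dim(hyper$mu)))
    stop("factor field dimensions do not match graph / hyperparameters")
  if (check_centered) {
    dev <- matrix(apply(f, c(2, 3), mean), d[2], d[3]) - hyper$mu
    if (max(abs(dev)) > 1e-8)
      stop("factor field is not centered (per-year, per-factor mean of f - mu)")
  }
  e <- factor_innovations(f, hyper)
  a <- graph$edges[, 1]; b <- graph$edges[, 2]
  tot <- 0
  for (mm in seq_len(d[3])) for (j in seq_len(d[2]))
    tot <- tot + sum((e[a, j, mm] - e[b, j, mm])^2)
  -0.5 * tot
}

# statewide-mean completion of the improper pairwise density: each year's
# mean innovation gets precision I (see vignette)
level_logprior <- function(f, hyper, level_prec = dim(f)[1]) {
  e <- factor_innovations(f, hyper)
  ebar <- matrix(apply(e, c(2, 3), mean), dim(f)[2], dim(f)[3])
  -0.5 * level_prec * sum(ebar^2)
}

#' Center a factor field
#'
#' Subtracts, for each year and factor, the cross-unit mean of `f - mu`
#' from the field, enforcing the per-year, per-factor centering constraint.
#' Idempotent.
#'
#' @param f `I x J x m` factor array.
#' @param mu `J x m` matrix of statewide means.
#' @return The centered array.
#' @export
center_factors <- function(f, mu) {
  f <- as.array(f)
  d <- dim(f)
  s <- matrix(apply(f, c(2, 3), mean), d[2], d[3]) - as.matrix(mu)
  f - aperm(array(s, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
}

#' Simulate a factor field from the ICAR + AR(1) prior
#'
#' Draws exactly centered ICAR innovations for each year and factor through
#' the eigendecomposition of the graph Laplacian (covariance equal to the
#' Laplacian pseudo-inverse on the sum-to-zero subspace), accumulates them
#' with the AR(1) recursion `delta_j = eta delta_(j-1) + e_j`, and returns
#' `f = mu + delta`.
#'
#' @param graph a connected [adjacency_graph].
#' @param hyper a [factor_hyper] (its `mu` fixes `J` and `m`).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return `I x J x m` centered factor array.
#' @export
sample_factor_prior <- function(graph, hyper, seed = NULL) {
  stopifnot(inherits(graph, "adjacency_graph"), inherits(hyper, "factor_hyper"))
  if (!is.null(seed)) set.seed(seed)
  I <- graph$n; J <- nrow(hyper$mu); m <- ncol(hyper$mu)
  eg <- eigen(graph_laplacian(graph), symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  if (sum(!pos) != 1L)
    stop("graph Laplacian must have a single null eigenvalue (connected graph)")
  V <- eg$vectors[, pos, drop = FALSE]
  isq <- 1 / sqrt(eg$values[pos])
  f <- array(0, dim = c(I, J, m))
  for (mm in seq_len(m)) {
    delta_prev <- numeric(I)
    for (j in seq_len(J)) {
      e <- as.vector(V %*% (isq * stats::rnorm(ncol(V))))
      delta <- if (j == 1L) e else hyper$eta[mm] * delta_prev + e
      f[, j, mm] <- hyper$mu[j, mm] + delta
      delta_prev <- delta
    }
  }
  f
}
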