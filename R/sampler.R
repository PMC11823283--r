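#' Sampler configuration
#'
#' Defaults mirror a production-scale run (500,000 iterations, half
#' discarded as burn-in, every 50th draw retained); tests and examples use
#' much smaller settings.
#'
#' @param n_iter total MCMC iterations.
#' @param burn_in iterations discarded before retention (`< n_iter`).
#' @param thin retain every `thin`-th post-burn-in draw.
#' @param proposal_sd named list of random-walk standard deviations for the
#'   `loadings`, `factors`, `epsilon` and `eta` blocks and for `log c` of
#'   the `scale` interweaving move.
#' @param adapt tune proposal scales toward 44% acceptance during burn-in
#'   (frozen afterwards).
#' @param seed integer seed; the whole run is reproducible from it.
#' @param prior_only switch the likelihood off (prior-sampling mode, used
#'   for validating the chain against known marginals).
#' @param store_epsilon,store_factors retain draws of the heterogeneity and
#'   factor fields (memory permitting).
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_iter = 500000L, burn_in = 250000L, thin = 50L,
                           proposal_sd = list(loadings = 0.1, factors = 0.5,
                                              epsilon = 0.5, eta = 0.1,
                                              scale = 0.02),
                           adapt = TRUE, seed = 1L, prior_only = FALSE,
                           store_epsilon = TRUE, store_factors = TRUE) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (n_iter < 1L || burn_in < 0L || burn_in >= n_iter || thin < 1L)
    stop("need 0 <= burn_in < n_iter and thin >= 1")
  if (is.null(proposal_sd$scale)) proposal_sd$scale <- 0.02
  for (b in c("loadings", "factors", "epsilon", "eta", "scale"))
    if (is.null(proposal_sd[[b]]) || proposal_sd[[b]] <= 0)
      stop("proposal_sd$", b, " must be positive")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 proposal_sd = proposal_sd, adapt = isTRUE(adapt),
                 seed = as.integer(seed), prior_only = isTRUE(prior_only),
                 store_epsilon = isTRUE(store_epsilon),
                 store_factors = isTRUE(store_factors)),
            class = "sampler_config")
}

# fast LQ used inside the sampler (pattern validated once, up front)
lq_fast <- function(values, ord, m, tol = 1e-12) {
  g <- values[ord, , drop = FALSE]
  gs <- gram_schmidt_qr(t(g[seq_len(m), , drop = FALSE]), tol = tol)
  A2 <- t(g[-seq_len(m), , drop = FALSE])
  R <- cbind(gs$R, if (ncol(A2) > 0) t(gs$Q) %*% A2)
  list(L = t(R), Q = t(gs$Q))
}

#' Assemble the model bundle used by the sampler blocks
#'
#' Validates the pattern and graph against the panel, computes baseline
#' rates and expected counts, and packs the flat data arrays the update
#' blocks and C++ kernels consume.
#'
#' @inheritParams dsfm_fit
#' @param prior_only switch the likelihood off for all blocks.
#' @return A list of class `dsfm_model`.
#' @export
dsfm_model <- function(panel, graph, pattern = default_pattern(),
                       baseline_time = 1L, prior_only = FALSE) {
  stopifnot(inherits(panel, "count_panel"), inherits(graph, "adjacency_graph"))
  chk <- validate_pattern(pattern)
  if (!chk$ok)
    stop("invalid loadings pattern: ", paste(chk$problems, collapse = "; "))
  d <- dim(panel$counts)
  if (graph$n != d[1]) stop("graph size does not match the panel's units")
  if (nrow(pattern$mask) != d[3])
    stop("pattern rows do not match the panel's outcomes")
  rates <- baseline_rates(panel, baseline_time)
  model <- build_model(panel, graph, pattern, rates)
  model$prior_only <- isTRUE(prior_only)
  class(model) <- "dsfm_model"
  model
}

#' Initial sampler state
#'
#' Deterministic, reproducible start.  The default seeds the chain from a
#' confirmatory alternating-least-squares fit to the empirical log relative
#' risks (censored cells at the interval midpoint), so that desk-scale
#' chains begin inside the basin of the data-supported mode; the
#' `"neutral"` method instead uses anchors at 1, other free loadings at 0,
#' factors at the statewide means (0), `eta = 0.5`, `sigma2 = 1` and
#' heterogeneity at 0.  Either way the LQ pair is computed from the
#' initial loadings.
#'
#' @param model a [dsfm_model].
#' @param method `"empirical"` (default): confirmatory alternating least
#'   squares on the empirical log relative risks seeds the loadings,
#'   factors, statewide means and heterogeneity variances; `"neutral"`:
#'   anchors at 1, all else at the prior-neutral values.
#' @return A state list consumed by the `update_*` blocks.
#' @export
dsfm_init_state <- function(model, method = c("empirical", "neutral"))
  init_state(model, method)

# model bundle shared by the update blocks
build_model <- function(panel, graph, pattern, rates) {
  d <- dim(panel$counts)
  y <- panel$counts
  y[panel$censored] <- 0L       # value at censored cells is never read
  E <- expected_counts(panel, rates)$expected
  list(y = as.numeric(y), cens = as.integer(panel$censored),
       E = as.numeric(E),
       I = d[1], J = d[2], K = d[3], m = ncol(pattern$mask),
       pattern = pattern, graph = graph, csr = graph_csr(graph),
       level_prec = d[1], rates = rates)
}

init_state <- function(model, method = c("empirical", "neutral")) {
  method <- match.arg(method)
  K <- model$K; m <- model$m; I <- model$I; J <- model$J
  mask <- model$pattern$mask
  gamma <- matrix(0, K, m)
  gamma[model$pattern$anchors] <- 1
  f <- array(0, dim = c(I, J, m))
  mu <- matrix(0, J, m)
  sigma2 <- rep(1, K)
  if (method == "empirical") {
    # alternating least squares on the empirical log relative risk, to
    # start the chain inside the basin of the data-supported mode
    y <- array(model$y, c(I, J, K))
    y[array(model$cens == 1L, c(I, J, K))] <- 3
    z <- matrix(log((y + 0.5) / array(model$E, c(I, J, K))), I * J, K)
    fmat <- matrix(0, I * J, m)
    for (sweep in 1:10) {
      fmat <- z %*% gamma %*% solve(crossprod(gamma) + 1e-8 * diag(m))
      for (k in seq_len(K)) {
        cols <- which(mask[k, ])
        X <- fmat[, cols, drop = FALSE]
        gamma[k, cols] <- solve(crossprod(X) + 1e-8 * diag(length(cols)),
                                crossprod(X, z[, k]))
      }
      gamma[model$pattern$anchors] <- pmax(gamma[model$pattern$anchors], 0.05)
    }
    resid <- z - fmat %*% t(gamma)
    sigma2 <- pmax(apply(resid, 2, stats::var), 0.01)
    f <- array(fmat, c(I, J, m))
    mu <- matrix(apply(f, c(2, 3), mean), J, m)
  }
  lq <- lq_fast(gamma, model$pattern$outcome_order, m)
  list(gamma = gamma, L = lq$L, Q = lq$Q, M = lq$L %*% lq$Q,
       f = f, mu = mu, eta = rep(0.5, m),
       sigma2 = sigma2,
       eps = array(0, dim = c(I, J, K)),
       loglik = NULL)
}

state_loglik <- function(state, model) {
  if (model$prior_only %||% FALSE) return(0)
  cpp_full_loglik(model$y, model$cens, model$E, state$M,
                  as.numeric(state$f), as.numeric(state$eps),
                  model$I, model$J, model$K, model$m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Metropolis-Hastings sweep over the free loadings
#'
#' Each structurally free entry is updated in a fixed column-major scan by a
#' normal random walk.  Every proposal is LQ-decomposed (a rank-deficient
#' leading block rejects the move), the likelihood is evaluated through the
#' identified product `L Q`, anchors proposed nonpositive are rejected by
#' the truncated-positive prior, and structural zeros are never proposed.
#'
#' @param state sampler state list (`gamma`, `L`, `Q`, `M`, `f`, `eps`,
#'   `loglik`, ...).
#' @param model model bundle from a fitted run (see [dsfm_fit()]); contains
#'   data arrays and the pattern.
#' @param sd random-walk standard deviation.
#' @param record keep a per-proposal log (columns: entry, current,
#'   proposal, log acceptance ratio, accepted) as attribute `"proposals"`.
#' @return Updated state with elements `acc` and `tries` describing the
#'   sweep.
#' @export
update_loadings <- function(state, model, sd, record = FALSE) {
  pat <- model$pattern
  K <- model$K; m <- model$m
  if (is.null(state$loglik)) state$loglik <- state_loglik(state, model)
  free <- which(pat$mask)
  anchor_idx <- (pat$anchors[, 2] - 1L) * K + pat$anchors[, 1]
  prior_only <- model$prior_only %||% FALSE
  acc <- 0L
  log <- if (record) vector("list", length(free))
  for (ii in seq_along(free)) {
    idx <- free[ii]
    cur <- state$gamma[idx]
    prop <- cur + sd * stats::rnorm(1)
    accepted <- FALSE
    logr <- -Inf
    if (idx %in% anchor_idx && prop <= 0) {
      # truncated-positive prior: zero density, auto-reject
    } else {
      gamma2 <- state$gamma
      gamma2[idx] <- prop
      lq2 <- tryCatch(lq_fast(gamma2, pat$outcome_order, m),
                      error = function(e) NULL)
      if (!is.null(lq2)) {
        M2 <- lq2$L %*% lq2$Q
        ll2 <- if (prior_only) 0 else
          cpp_full_loglik(model$y, model$cens, model$E, M2,
                          as.numeric(state$f), as.numeric(state$eps),
                          model$I, model$J, model$K, m)
        logr <- (ll2 + stats::dnorm(prop, 0, 10, log = TRUE)) -
          (state$loglik + stats::dnorm(cur, 0, 10, log = TRUE))
        if (is.finite(logr) && log(stats::runif(1)) < logr) {
          state$gamma <- gamma2
          state$L <- lq2$L; state$Q <- lq2$Q; state$M <- M2
          state$loglik <- ll2
          accepted <- TRUE
        }
      }
    }
    acc <- acc + accepted
    if (record)
      log[[ii]] <- data.frame(entry = idx, current = cur, proposal = prop,
                              log_ratio = logr, accepted = accepted)
  }
  state$acc <- acc; state$tries <- length(free)
  if (record) attr(state, "proposals") <- do.call(rbind, log)
  state
}

# ICAR + AR(1) log prior (pairwise + statewide-mean completion) of a single
# factor column; used by the scale move and the eta update
factor_col_logprior <- function(fcol, mucol, eta_m, edges, level_prec,
                                from_year = 1L) {
  J <- ncol(fcol)
  a <- edges[, 1]; b <- edges[, 2]
  tot <- 0
  for (j in seq.int(from_year, J)) {
    e <- fcol[, j] - mucol[j]
    if (j > 1L) e <- e - eta_m * (fcol[, j - 1] - mucol[j - 1])
    tot <- tot + sum((e[a] - e[b])^2) + level_prec * mean(e)^2
  }
  -0.5 * tot
}

#' Interweaving scale move on each factor column
#'
#' Proposes `Gamma[, m] -> c Gamma[, m]`, `F[,, m] -> F[,, m] / c`,
#' `mu[, m] -> mu[, m] / c` with `log c` a normal random walk.  The
#' likelihood is invariant along this direction (the product `Gamma' F` is
#' unchanged), so the move travels the scale ridge that single-site updates
#' cross only slowly; the acceptance ratio carries the loadings prior, the
#' factor prior and the Jacobian.  The LQ pair is recomputed on acceptance.
#'
#' @inheritParams update_loadings
#' @param sd random-walk standard deviation of `log c`.
#' @return Updated state with `acc` / `tries`.
#' @export
update_scale <- function(state, model, sd = 0.02) {
  pat <- model$pattern
  prior_only <- model$prior_only %||% FALSE
  acc <- 0L
  for (mm in seq_len(model$m)) {
    cc <- exp(sd * stats::rnorm(1))
    free <- which(pat$mask[, mm])
    gamma2 <- state$gamma
    gamma2[, mm] <- cc * gamma2[, mm]
    f2 <- state$f
    f2[, , mm] <- f2[, , mm] / cc
    mu2 <- state$mu
    mu2[, mm] <- mu2[, mm] / cc
    logr <-
      factor_col_logprior(matrix(f2[, , mm], model$I), mu2[, mm],
                          state$eta[mm], model$graph$edges,
                          model$level_prec) -
      factor_col_logprior(matrix(state$f[, , mm], model$I), state$mu[, mm],
                          state$eta[mm], model$graph$edges,
                          model$level_prec) +
      sum(stats::dnorm(gamma2[free, mm], 0, 10, log = TRUE) -
            stats::dnorm(state$gamma[free, mm], 0, 10, log = TRUE)) +
      (length(free) - model$I * model$J - model$J) * log(cc)
    lq2 <- tryCatch(lq_fast(gamma2, pat$outcome_order, model$m),
                    error = function(e) NULL)
    if (is.null(lq2)) next
    M2 <- lq2$L %*% lq2$Q
    if (!prior_only) {
      if (is.null(state$loglik)) state$loglik <- state_loglik(state, model)
      ll2 <- cpp_full_loglik(model$y, model$cens, model$E, M2,
                             as.numeric(f2), as.numeric(state$eps),
                             model$I, model$J, model$K, model$m)
      logr <- logr + ll2 - state$loglik
    }
    if (is.finite(logr) && log(stats::runif(1)) < logr) {
      state$gamma <- gamma2
      state$L <- lq2$L; state$Q <- lq2$Q; state$M <- M2
      state$f <- f2; state$mu <- mu2
      if (!prior_only) state$loglik <- ll2
      acc <- acc + 1L
    }
  }
  state$acc <- acc; state$tries <- model$m
  state
}

#' Metropolis-Hastings sweep over the latent factor sites
#'
#' Single-site random walk against the ICAR + AR(1) prior conditional
#' (spatial neighbours at the same year, temporal neighbours at adjacent
#' years, and the statewide-mean completion) times the Poisson /
#' interval-censored likelihood through the identified loadings.
#'
#' @inheritParams update_loadings
#' @return Updated state with `acc` / `tries`.
#' @export
update_factors <- function(state, model, sd) {
  f <- as.numeric(state$f)
  acc <- cpp_factor_sweep(model$y, model$cens, model$E, state$M, f,
                          as.numeric(state$eps), state$mu, state$eta,
                          model$csr$nbr, model$csr$ptr, sd,
                          model$I, model$J, model$K, model$m,
                          as.integer(model$prior_only %||% FALSE),
                          model$level_prec)
  state$f <- array(f, dim = dim(state$f))
  state$loglik <- NULL
  state$acc <- acc; state$tries <- model$I * model$J * model$m
  state
}

#' Update the uncorrelated heterogeneity terms
#'
#' Random-walk MH per cell against the observation likelihood times
#' `N(0, sigma2_k)`.  With the likelihood switched off the full conditional
#' is exactly `N(0, sigma2_k)` and an exact Gibbs draw is taken instead.
#'
#' @inheritParams update_loadings
#' @return Updated state with `acc` / `tries`.
#' @export
update_epsilon <- function(state, model, sd) {
  n <- model$I * model$J * model$K
  if (model$prior_only %||% FALSE) {
    sdk <- sqrt(state$sigma2)[rep(seq_len(model$K),
                                  each = model$I * model$J)]
    state$eps <- array(stats::rnorm(n, 0, sdk), dim = dim(state$eps))
    state$acc <- n
  } else {
    eps <- as.numeric(state$eps)
    state$acc <- cpp_eps_sweep(model$y, model$cens, model$E, state$M,
                               as.numeric(state$f), eps, state$sigma2, sd,
                               model$I, model$J, model$K, model$m)
    state$eps <- array(eps, dim = dim(state$eps))
  }
  state$loglik <- NULL
  state$tries <- n
  state
}

#' Gibbs update of the statewide factor means
#'
#' Under the flat prior, `mu[j, m]` has a Gaussian full conditional coming
#' from the statewide-mean innovation terms of years `j` and `j + 1`, each
#' with precision `I` (see the vignette for the completion of the improper
#' pairwise ICAR density).  Years are scanned in order.
#'
#' @inheritParams update_loadings
#' @return Updated state.
#' @export
update_mu <- function(state, model) {
  J <- model$J
  Iu <- model$level_prec
  fbar <- apply(state$f, c(2, 3), mean)   # J x m
  fbar <- matrix(fbar, nrow = J)
  eta <- state$eta
  for (j in seq_len(J)) {
    a <- if (j == 1L) fbar[1, ] else
      fbar[j, ] - eta * (fbar[j - 1, ] - state$mu[j - 1, ])
    if (j < J) {
      b <- (fbar[j + 1, ] - state$mu[j + 1, ]) - eta * fbar[j, ]
      prec <- Iu * (1 + eta^2)
      mean_ <- (a - eta * b) / (1 + eta^2)
    } else {
      prec <- rep(Iu, model$m)
      mean_ <- a
    }
    state$mu[j, ] <- stats::rnorm(model$m, mean_, sqrt(1 / prec))
  }
  state
}

#' Metropolis-Hastings update of the temporal AR coefficients
#'
#' Random walk with reflection at 0 and 1 (the Uniform(0,1) prior
#' contributes nothing inside the interval); the target is the product of
#' the ICAR innovation densities of years 2..J plus the statewide-mean
#' completion.
#'
#' @inheritParams update_loadings
#' @return Updated state with `acc` / `tries`.
#' @export
update_eta <- function(state, model, sd) {
  J <- model$J
  a <- model$graph$edges[, 1]; b <- model$graph$edges[, 2]
  target <- function(eta, mm) {
    if (J < 2L) return(0)
    tot <- 0
    for (j in 2:J) {
      e <- (state$f[, j, mm] - state$mu[j, mm]) -
        eta * (state$f[, j - 1, mm] - state$mu[j - 1, mm])
      tot <- tot + sum((e[a] - e[b])^2) + model$level_prec * mean(e)^2
    }
    -0.5 * tot
  }
  acc <- 0L
  for (mm in seq_len(model$m)) {
    cur <- state$eta[mm]
    prop <- cur + sd * stats::rnorm(1)
    while (prop <= 0 || prop >= 1) {
      if (prop <= 0) prop <- -prop
      if (prop >= 1) prop <- 2 - prop
    }
    if (log(stats::runif(1)) < target(prop, mm) - target(cur, mm)) {
      state$eta[mm] <- prop
      acc <- acc + 1L
    }
  }
  state$acc <- acc; state$tries <- model$m
  state
}

#' Conjugate Gibbs update of the heterogeneity variances
#'
#' `sigma2_k ~ InvGamma(0.5 + n_k / 2, 0.5 + sum(eps_ijk^2) / 2)` with
#' `n_k = I * J`, exact given the current heterogeneity field.
#'
#' @inheritParams update_loadings
#' @return Updated state.
#' @export
update_sigma2 <- function(state, model) {
  n_k <- model$I * model$J
  ssq <- apply(state$eps^2, 3, sum)
  state$sigma2 <- 1 / stats::rgamma(model$K, shape = 0.5 + n_k / 2,
                                    rate = 0.5 + ssq / 2)
  state
}

#' Fit the dynamic spatial factor model by Metropolis-within-Gibbs
#'
#' Runs the full sampler: loadings (with LQ maintenance on every proposal),
#' the scale interweaving move, latent factor sites, heterogeneity terms,
#' statewide means, temporal AR coefficients and heterogeneity variances,
#' in that order.  The per-year centering constraint is carried by the
#' statewide-mean component of the factor prior, which keeps the mean of
#' `f - mu` within `O(1/sqrt(I))` of zero in distribution (see the
#' vignette); no hard projection is applied inside the chain.  Retains
#' thinned post-burn-in draws of the raw and identified quantities.
#' Identical seed, config and data reproduce the chain bit for bit.
#'
#' @param panel a [count_panel].
#' @param graph an [adjacency_graph] over the panel's units.
#' @param pattern a [loadings_pattern] (default: [default_pattern()]).
#' @param config a [sampler_config].
#' @param baseline_time time index used for the statewide baseline rates.
#' @param progress print progress and acceptance rates every this many
#'   iterations (0 = silent).
#' @return An object of class `dsfm_samples`: retained draws (`gamma`, `L`,
#'   `Q`, `mu`, `eta`, `sigma2`, and optionally `f`, `f_tilde`, `eps`; one
#'   row per draw, columns in column-major layout of the underlying
#'   arrays), acceptance rates per block, the config, pattern and model
#'   metadata.
#' @export
dsfm_fit <- function(panel, graph, pattern = default_pattern(),
                     config = sampler_config(), baseline_time = 1L,
                     progress = 0L) {
  stopifnot(inherits(config, "sampler_config"))
  model <- dsfm_model(panel, graph, pattern, baseline_time,
                      prior_only = config$prior_only)
  rates <- model$rates

  set.seed(config$seed)
  state <- init_state(model,
                      method = if (config$prior_only) "neutral" else
                        "empirical")
  state$f <- center_factors(state$f, state$mu)

  n_ret <- (config$n_iter - config$burn_in) %/% config$thin
  K <- model$K; m <- model$m; J <- model$J; I <- model$I
  draws <- list(gamma = matrix(NA_real_, n_ret, K * m),
                L = matrix(NA_real_, n_ret, K * m),
                Q = matrix(NA_real_, n_ret, m * m),
                mu = matrix(NA_real_, n_ret, J * m),
                eta = matrix(NA_real_, n_ret, m),
                sigma2 = matrix(NA_real_, n_ret, K))
  if (config$store_factors) {
    draws$f <- matrix(NA_real_, n_ret, I * J * m)
    draws$f_tilde <- matrix(NA_real_, n_ret, I * J * m)
  }
  if (config$store_epsilon) draws$eps <- matrix(NA_real_, n_ret, I * J * K)

  blocks <- c("loadings", "scale", "factors", "epsilon", "eta")
  sds <- unlist(config$proposal_sd[blocks])
  acc_hist <- matrix(0, config$n_iter, length(blocks),
                     dimnames = list(NULL, blocks))
  batch <- 50L
  batch_acc <- batch_try <- stats::setNames(numeric(5), blocks)
  post_acc <- post_try <- stats::setNames(numeric(5), blocks)

  ret <- 0L
  for (it in seq_len(config$n_iter)) {
    state$loglik <- state_loglik(state, model)

    state <- update_loadings(state, model, sds["loadings"])
    r_load <- c(state$acc, state$tries)
    state <- update_scale(state, model, sds["scale"])
    r_scale <- c(state$acc, state$tries)
    state <- update_factors(state, model, sds["factors"])
    r_fac <- c(state$acc, state$tries)
    state <- update_epsilon(state, model, sds["epsilon"])
    r_eps <- c(state$acc, state$tries)
    state <- update_mu(state, model)
    state <- update_eta(state, model, sds["eta"])
    r_eta <- c(state$acc, state$tries)
    state <- update_sigma2(state, model)

    accv <- c(r_load[1], r_scale[1], r_fac[1], r_eps[1], r_eta[1])
    tryv <- c(r_load[2], r_scale[2], r_fac[2], r_eps[2], r_eta[2])
    rates_now <- accv / tryv
    acc_hist[it, ] <- rates_now
    batch_acc <- batch_acc + accv
    batch_try <- batch_try + tryv
    if (it > config$burn_in) {
      post_acc <- post_acc + accv
      post_try <- post_try + tryv
    }

    if (config$adapt && it <= config$burn_in && it %% batch == 0L) {
      gain <- 1 / sqrt(it / batch)
      sds <- sds * exp(gain * (batch_acc / batch_try - 0.44))
      sds <- pmin(pmax(sds, 1e-4), 10)
      batch_acc[] <- 0; batch_try[] <- 0
    }

    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thin == 0L) {
      ret <- ret + 1L
      draws$gamma[ret, ] <- state$gamma
      draws$L[ret, ] <- state$L
      draws$Q[ret, ] <- state$Q
      draws$mu[ret, ] <- state$mu
      draws$eta[ret, ] <- state$eta
      draws$sigma2[ret, ] <- state$sigma2
      if (config$store_factors) {
        draws$f[ret, ] <- state$f
        fmat <- matrix(state$f, nrow = I * J, ncol = m)
        draws$f_tilde[ret, ] <- fmat %*% t(state$Q)
      }
      if (config$store_epsilon) draws$eps[ret, ] <- state$eps
    }
    if (progress > 0L && it %% progress == 0L)
      message(sprintf(
        "iter %d/%d  acc: loadings %.2f scale %.2f factors %.2f eps %.2f eta %.2f",
        it, config$n_iter, rates_now[1], rates_now[2], rates_now[3],
        rates_now[4], rates_now[5]))
  }

  structure(list(
    draws = draws, n_retained = ret,
    acceptance = list(history = acc_hist,
                      post_burn_in = post_acc / pmax(post_try, 1),
                      final_proposal_sd = sds),
    config = config, pattern = pattern,
    dims = list(I = I, J = J, K = K, m = m),
    rates = rates,
    unit_labels = panel$unit_labels, time_labels = panel$time_labels,
    outcome_labels = panel$outcome_labels
  ), class = "dsfm_samples")
}

#' @export
print.dsfm_samples <- function(x, ...) {
  cat(sprintf("dsfm_samples: %d retained draws (I=%d, J=%d, K=%d, m=%d)\n",
              x$n_retained, x$dims$I, x$dims$J, x$dims$K, x$dims$m))
  cat("post-burn-in acceptance: ",
      paste(sprintf("%s %.2f", names(x$acceptance$post_burn_in),
                    x$acceptance$post_burn_in), collapse = ", "), "\n")
  invisible(x)
}
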