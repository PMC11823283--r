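# shared fixtures, all built in code

# random loadings matrix conforming to a pattern (anchors strictly positive)
rand_conforming_gamma <- function(pattern, sd = 0.5) {
  g <- matrix(0, nrow(pattern$mask), ncol(pattern$mask))
  g[pattern$mask] <- stats::rnorm(sum(pattern$mask), sd = sd)
  g[pattern$anchors] <- abs(g[pattern$anchors]) + 0.1
  g
}

# random orthogonal matrix (Haar-ish via Householder QR with sign fix)
rand_orthogonal <- function(m) {
  qr_ <- qr(matrix(stats::rnorm(m * m), m))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), m)
}

# tiny panel with arbitrary counts for likelihood tests
toy_panel <- function(I = 3, J = 2, K = 2, seed = 1, censor = FALSE) {
  set.seed(seed)
  counts <- array(stats::rpois(I * J * K, 5), c(I, J, K))
  censored <- array(FALSE, c(I, J, K))
  if (censor) {
    censored[1, 1, K] <- TRUE
    counts[1, 1, K] <- NA
  }
  pops <- matrix(stats::runif(I * J, 1e4, 1e5), I, J)
  count_panel(counts, censored, pops)
}

# inverse-gamma CDF for KS tests
pinvgamma <- function(q, shape, rate) {
  stats::pgamma(1 / q, shape = shape, rate = rate, lower.tail = FALSE)
}

# small end-to-end simulation + fit used by several tests
small_fit <- function(n_iter = 400, burn_in = 200, thin = 2, seed = 1,
                      sim_seed = 11, rows = 3, cols = 3, J = 2) {
  sim <- simulate_panel(truth_config(rows = rows, cols = cols, J = J),
                        seed = sim_seed)
  fit <- dsfm_fit(sim$panel, sim$graph,
                  config = sampler_config(n_iter = n_iter, burn_in = burn_in,
                                          thin = thin, seed = seed))
  list(sim = sim, fit = fit)
}
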