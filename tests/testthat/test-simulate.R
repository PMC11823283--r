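test_that("lattice graphs have rook adjacency with the expected degrees and edge counts", {
  g <- lattice_graph(2, 2)
  expect_equal(g$n, 4L)
  expect_equal(nrow(g$edges), 4L)
  expect_equal(g$degrees, rep(2L, 4))

  g3 <- lattice_graph(3, 3)
  expect_equal(g3$degrees[5], 4L)                 # centre
  expect_equal(sort(g3$degrees)[1:4], rep(2L, 4)) # corners

  g10 <- lattice_graph(10, 10)
  expect_equal(g10$n, 100L)
  expect_equal(nrow(g10$edges), 180L)             # r(c-1) + c(r-1)
  expect_error(lattice_graph(1, 1), "at least 2")
})

test_that("simulation censors exactly the treatment counts in the suppression interval", {
  sim <- simulate_panel(truth_config(rows = 4, cols = 4, J = 3), seed = 101)
  kk <- 3L
  y_full <- sim$truth$counts_uncensored
  cns <- sim$panel$censored
  expect_true(all(cns[, , -kk] == FALSE))
  in_band <- y_full[, , kk] >= 1 & y_full[, , kk] <= 5
  expect_equal(cns[, , kk], in_band)
  expect_true(all(is.na(sim$panel$counts[, , kk][in_band])))
  expect_equal(sim$panel$counts[, , kk][!in_band], y_full[, , kk][!in_band])
})

test_that("simulation is reproducible from the seed", {
  a <- simulate_panel(truth_config(rows = 3, cols = 3, J = 2), seed = 103)
  b <- simulate_panel(truth_config(rows = 3, cols = 3, J = 2), seed = 103)
  d <- simulate_panel(truth_config(rows = 3, cols = 3, J = 2), seed = 104)
  expect_identical(a$panel$counts, b$panel$counts)
  expect_identical(a$truth$f, b$truth$f)
  expect_false(identical(a$panel$counts, d$panel$counts))
})

test_that("with flat truth the counts are Poisson around their offsets", {
  # vanishing loadings and noise: lambda = 1 everywhere, so counts / E
  # should average to 1 within CLT error
  g <- default_truth_loadings()
  g[default_pattern()$mask] <- 0
  g[cbind(1:4, 1:4)] <- 1e-8
  cfg <- truth_config(rows = 10, cols = 10, J = 5, gamma = g,
                      sigma2 = rep(0, 6), mu = matrix(0, 5, 4),
                      censor_outcome = NA)
  sim <- simulate_panel(cfg, seed = 105)
  E <- sim$truth$expected
  ratio <- sim$panel$counts / E
  expect_lt(abs(mean(ratio) - 1), 3 * sqrt(mean(1 / E) / length(E)))
})

test_that("the generative truth outranks random perturbations under the likelihood", {
  sim <- simulate_panel(truth_config(rows = 4, cols = 4, J = 3), seed = 107)
  E <- sim$truth$expected
  ll <- function(gamma) obs_loglik(sim$panel, E,
                                   linear_predictor(gamma, sim$truth$f,
                                                    list(epsilon = sim$truth$eps)))
  ll0 <- ll(sim$truth$gamma)
  expect_true(is.finite(ll0))
  set.seed(108)
  worse <- replicate(100, {
    pert <- sim$truth$gamma
    pert[default_pattern()$mask] <- pert[default_pattern()$mask] +
      rnorm(sum(default_pattern()$mask), sd = 0.5)
    ll(pert) < ll0
  })
  expect_gte(mean(worse), 0.95)
})

test_that("recovery metrics behave on hand-built degenerate chains", {
  sim <- simulate_panel(truth_config(rows = 2, cols = 2, J = 2), seed = 109)
  truth <- sim$truth
  dm <- list(I = 4L, J = 2L, K = 6L, m = 4L)
  point_mass <- function(n) {
    iq <- truth
    draws <- list(
      gamma = matrix(rep(as.vector(truth$gamma), each = n), n),
      L = matrix(rep(as.vector(truth$L), each = n), n),
      Q = matrix(rep(as.vector(truth$Q), each = n), n),
      mu = matrix(rep(as.vector(truth$mu), each = n), n),
      eta = matrix(rep(truth$eta, each = n), n),
      sigma2 = matrix(rep(truth$sigma2, each = n), n),
      f = matrix(rep(as.vector(truth$f), each = n), n),
      f_tilde = matrix(rep(as.vector(truth$f_tilde), each = n), n))
    structure(list(draws = draws, n_retained = n, dims = dm,
                   pattern = truth$pattern,
                   outcome_labels = truth$pattern$outcome_labels),
              class = "dsfm_samples")
  }
  # a point mass at truth: zero bias and RMSE, but zero-width intervals
  # never cover
  rec <- recovery_metrics(truth, point_mass(10))
  expect_true(all(abs(rec$scalars$bias) < 1e-12))
  expect_true(all(rec$blocks$rmse < 1e-12))
  expect_true(all(!rec$scalars$covered))
  expect_true(rec$anchor_sign_correct)

  # symmetric noise around truth: small bias, near-full coverage
  fake <- point_mass(400)
  set.seed(110)
  for (nm in names(fake$draws))
    fake$draws[[nm]] <- fake$draws[[nm]] +
      matrix(rnorm(length(fake$draws[[nm]]), sd = 0.05),
             nrow(fake$draws[[nm]]))
  rec2 <- recovery_metrics(truth, fake)
  expect_lt(max(abs(rec2$scalars$bias)), 0.02)
  expect_gt(mean(rec2$scalars$covered), 0.9)

  # 3-draw chain: intervals checked by hand
  tiny <- point_mass(3)
  tiny$draws$eta[, 1] <- c(0.2, 0.5, 0.8)
  rec3 <- recovery_metrics(truth, tiny)
  row <- rec3$scalars[rec3$scalars$parameter == "eta[1]", ]
  expect_equal(row$post_mean, 0.5)
  expect_equal(unname(c(row$lo95, row$hi95)),
               unname(quantile(c(0.2, 0.5, 0.8), c(0.025, 0.975))))
  expect_true(row$covered)   # truth eta = 0.5 lies strictly inside
})
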