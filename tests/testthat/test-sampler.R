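test_that("initial states are balanced, prior-consistent and reproducible", {
  d <- make_test_data(10, J = 2, K = 3, seed = 5)
  pri <- prior_spec(K = d$K)
  cfg1 <- sampler_config(n_init_clusters = 1, seed = 1)
  set.seed(1)
  st <- init_state(d, pri, cfg1)
  expect_true(all(st$Z == 1L))
  cfg5 <- sampler_config(n_init_clusters = 5, seed = 1)
  set.seed(1)
  st <- init_state(d, pri, cfg5)
  expect_equal(unname(table(st$Z)), rep(2L, 5) |> as.integer() |> array(5))
  expect_true(all(st$u < st$psi[st$Z]))
  expect_equal(st$psi, stick_weights(st$V))
  expect_equal(st$beta, numeric(0))
  set.seed(99); st1 <- init_state(d, pri, cfg5)
  set.seed(99); st2 <- init_state(d, pri, cfg5)
  expect_identical(st1, st2)
  expect_error(init_state(d, pri, sampler_config(n_init_clusters = 11)),
               "exceeds")
})

test_that("slice-marginalised allocations follow psi-weighted likelihoods", {
  # one subject, two fixed components covering the whole stick:
  # marginalising the slice, P(Z = c) must be proportional to psi_c f_c
  d <- profile_data(matrix(1L, 1, 1), K = 2L)
  pri <- prior_spec(K = 2L, alpha = alpha_fixed(1))
  base <- make_test_state(d, C = 2, alpha = 1, seed = 2)
  base$V <- c(0.6, 1 - 1e-12)       # psi sums to 1: no extension needed
  base$psi <- stick_weights(base$V)
  base$Phi[[1]] <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  target <- base$psi * base$Phi[[1]][, 1]
  target <- target / sum(target)
  set.seed(31)
  m <- 3e4
  zs <- integer(m)
  z <- 1L
  for (s in seq_len(m)) {
    st <- base
    st$Z <- z
    z <- update_slice_allocations(st, d, pri)$Z  # parameters held fixed
    zs[s] <- z
  }
  frac <- mean(zs == 1)
  batches <- colMeans(matrix(zs == 1, ncol = 50))
  se <- stats::sd(batches) / sqrt(50)
  expect_lt(abs(frac - target[1]), 4 * se)
  # a dominated component is essentially never chosen
  base$Phi[[1]] <- rbind(c(1 - 1e-7, 1e-7), c(1e-7, 1 - 1e-7))
  z <- 1L
  hits <- 0
  for (s in 1:2000) {
    st <- base
    st$Z <- z
    z <- update_slice_allocations(st, d, pri)$Z
    hits <- hits + (z == 2L)
  }
  expect_lt(hits / 2000, 0.01)
})

test_that("stick updates have the conjugate Beta posteriors", {
  d <- make_test_data(5, J = 1, K = 2, seed = 8)
  st <- make_test_state(d, C = 2, alpha = 1, seed = 8)
  st$Z <- rep(1L, 5)   # counts (5, 0)
  set.seed(12)
  v1 <- replicate(2e4, update_sticks(st, d)$V[1])
  expect_lt(abs(mean(v1) - 6 / 7), 4 * stats::sd(v1) / sqrt(length(v1)))
  # cross-module: posterior mean weights match expected_weight_given_z
  st3 <- make_test_state(make_test_data(6, seed = 9), C = 3, alpha = 1, seed = 9)
  st3$Z <- rep(1:3, c(3, 2, 1))
  set.seed(13)
  ps <- replicate(2e4, update_sticks(st3, make_test_data(6, seed = 9))$psi)
  for (cc in 1:3) {
    se <- stats::sd(ps[cc, ]) / sqrt(ncol(ps))
    expect_lt(abs(mean(ps[cc, ]) - expected_weight_given_z(cc, c(3, 2, 1), 1)),
              4 * se)
  }
})

test_that("category-probability updates are conjugate Dirichlet draws", {
  d <- profile_data(matrix(rep(1L, 3), 3, 1), K = 2L)
  pri <- prior_spec(K = 2L)
  st <- make_test_state(d, C = 2, seed = 4)
  st$Z <- rep(1L, 3)  # cluster 1: counts (3, 0); cluster 2 empty
  set.seed(21)
  draws <- replicate(2e4, update_phi(st, d, pri)$Phi[[1]][, 1])
  se1 <- stats::sd(draws[1, ]) / sqrt(ncol(draws))
  expect_lt(abs(mean(draws[1, ]) - 0.8), 4 * se1)  # Dirichlet(4, 1)
  se2 <- stats::sd(draws[2, ]) / sqrt(ncol(draws))
  expect_lt(abs(mean(draws[2, ]) - 0.5), 4 * se2)  # prior restored
})

test_that("intercept updates target the logistic posterior", {
  set.seed(6)
  n <- 200
  y <- stats::rbinom(n, 1, stats::plogis(1.2))
  d <- profile_data(matrix(1L, n, 1), Y = y, K = 1L)
  pri <- prior_spec(K = 1L)
  st <- make_test_state(d, C = 1, seed = 6)
  st$Z <- rep(1L, n)
  # posterior mode by independent 1-D optimisation
  mode <- stats::optimize(function(t)
    sum(y * t - log1p(exp(t))) + stats::dt((t) / 2.5, 7, log = TRUE) - log(2.5),
    c(-5, 5), maximum = TRUE)$maximum
  set.seed(61)
  th <- numeric(4000)
  for (s in seq_len(4000)) {
    st <- update_theta(st, d, pri, scale = 0.4)
    th[s] <- st$theta[1]
  }
  batches <- colMeans(matrix(th[1001:4000], ncol = 30))
  se <- stats::sd(batches) / sqrt(30)
  expect_lt(abs(mean(th[1001:4000]) - mode), 4 * se + 0.05)
  # without a response the update is a no-op
  d0 <- make_test_data(5, seed = 1)
  st0 <- make_test_state(d0, C = 2, seed = 1)
  expect_identical(update_theta(st0, d0, prior_spec(K = d0$K))$theta, st0$theta)
})

test_that("adapted proposal scales give healthy acceptance rates", {
  sim <- gen_dataset1(sim_spec("dataset1", n = 150, seed = 14))
  dW <- profile_data(sim$data$X, Y = sim$data$Y,
                     W = matrix(stats::rnorm(150), 150, 1),
                     K = sim$data$K)
  ch <- run_chain(dW, cfg = sampler_config(n_init_clusters = 5, n_burn = 600,
                                           n_keep = 400, seed = 15))
  expect_gt(mean(ch$acc_theta, na.rm = TRUE), 0.2)
  expect_lt(mean(ch$acc_theta, na.rm = TRUE), 0.6)
  expect_gt(mean(ch$acc_beta, na.rm = TRUE), 0.1)
  expect_lt(mean(ch$acc_beta, na.rm = TRUE), 0.6)
})

test_that("with no data every marginal reproduces its prior", {
  d0 <- profile_data(matrix(integer(0), 0, 1), Y = integer(0), K = 2L)
  pri <- prior_spec(K = 2L, alpha = alpha_gamma(9, 0.5))
  ch <- run_chain(d0, pri, sampler_config(n_init_clusters = 1, n_burn = 500,
                                          n_keep = 5000, thin = 2, seed = 33))
  ks_alpha <- stats::ks.test(ch$alpha, stats::pgamma, shape = 9, rate = 0.5)
  expect_lt(unname(ks_alpha$statistic), 0.02)
})

test_that("chains are reproducible and respect run-length accounting", {
  d <- gen_tiny_fixture(6, seed = 3)
  cfg <- sampler_config(n_init_clusters = 3, n_burn = 50, n_keep = 80, seed = 9)
  ch1 <- run_chain(d, cfg = cfg)
  ch2 <- run_chain(d, cfg = cfg)
  expect_identical(ch1$Z, ch2$Z)
  expect_identical(ch1$alpha, ch2$alpha)
  expect_identical(ch1$accept, ch2$accept)
  expect_equal(nrow(ch1$Z), 80L)
  ch0 <- run_chain(d, cfg = sampler_config(n_init_clusters = 2, n_burn = 10,
                                           n_keep = 0, seed = 1))
  expect_equal(nrow(ch0$Z), 0L)
  # thinning: kept records are every thin-th sweep
  cht <- run_chain(d, cfg = sampler_config(n_init_clusters = 3, n_burn = 20,
                                           n_keep = 30, thin = 3, seed = 9))
  expect_equal(length(cht$alpha), 30L)
})

test_that("state invariants hold along a sweeping chain", {
  d <- gen_tiny_fixture(6, J = 2, seed = 2)
  pri <- prior_spec(K = d$K)
  cfg <- sampler_config(n_init_clusters = 4, seed = 17)
  set.seed(17)
  st <- init_state(d, pri, cfg)
  for (s in 1:60) {
    st <- update_slice_allocations(st, d, pri)
    # the slice invariant holds at allocation time (u is regenerated each sweep)
    expect_true(all(st$u < st$psi[st$Z]))
    st <- update_sticks(st, d)
    st <- update_phi(st, d, pri)
    st <- update_alpha(st, d, pri)
    expect_equal(st$psi, stick_weights(st$V))
    expect_true(sum(st$psi) <= 1 + 1e-12)
    expect_true(max(st$Z) <= st$C)
    for (j in seq_len(d$J))
      expect_equal(unname(rowSums(st$Phi[[j]])), rep(1, st$C), tolerance = 1e-10)
  }
})
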