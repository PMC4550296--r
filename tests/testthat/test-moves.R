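test_that("the weight-matched swap ratio matches hand computation and edge cases", {
  # all exponents vanish when both clusters are empty
  expect_identical(move3_acceptance_ratio(0, 0, 0, 1, 0.4, 0.2), 1)
  expect_identical(move3_acceptance_ratio(0, 0, 5, 2.3, 0.1, 0.05), 1)
  # direct substitution: R1 = 1.5, R2 = 0.75
  expect_equal(move3_acceptance_ratio(2, 1, 0, 1, 0.4, 0.2), 0.84375,
               tolerance = 1e-12)
  expect_error(move3_acceptance_ratio(1, 1, 0, -1, 0.4, 0.2), "positive")
  expect_error(move3_acceptance_ratio(1, 1, 0, 1, 0, 0.2), "positive")
})

test_that("the weight-matched swap ratio agrees with the joint-density oracle", {
  set.seed(202)
  n_checked <- 0
  while (n_checked < 300) {
    C <- sample(3:6, 1)
    d <- make_test_data(sample(8:20, 1), J = 2, K = 2,
                        seed = sample.int(1e6, 1))
    st <- make_test_state(d, C = C, alpha = stats::runif(1, 0.2, 5),
                          seed = sample.int(1e6, 1))
    cc <- sample.int(C - 1L, 1)
    prop <- build_move3_proposal(st, cc)
    if (any(prop$V[c(cc, cc + 1)] <= 0 | prop$V[c(cc, cc + 1)] >= 1)) next
    counts <- tabulate(st$Z, C)
    tail <- if (cc + 1 < C) sum(counts[(cc + 2):C]) else 0
    pri <- prior_spec(K = d$K, alpha = alpha_fixed(st$alpha))
    log_oracle <- joint_log_density(prop, d, pri) - joint_log_density(st, d, pri)
    logR <- log(move3_acceptance_ratio(counts[cc], counts[cc + 1], tail,
                                       st$alpha, st$psi[cc], st$psi[cc + 1]))
    expect_lt(abs(logR - log_oracle), 1e-8)
    n_checked <- n_checked + 1
  }
})

test_that("the weight-matched proposal is an involution satisfying detailed balance", {
  set.seed(77)
  for (r in 1:50) {
    C <- sample(3:5, 1)
    d <- make_test_data(12, J = 2, K = 2, seed = r)
    st <- make_test_state(d, C = C, alpha = stats::runif(1, 0.3, 4), seed = r + 500)
    cc <- sample.int(C - 1L, 1)
    prop <- build_move3_proposal(st, cc)
    back <- build_move3_proposal(prop, cc)
    expect_equal(back$psi, st$psi, tolerance = 1e-10)
    expect_equal(back$V, st$V, tolerance = 1e-10)
    expect_equal(back$Z, st$Z)
    # forward x reverse ratio = 1 (the deterministic map is measure-preserving
    # for the pair given the conserved sum)
    counts <- tabulate(st$Z, C)
    tail <- if (cc + 1 < C) sum(counts[(cc + 2):C]) else 0
    Rf <- move3_acceptance_ratio(counts[cc], counts[cc + 1], tail, st$alpha,
                                 st$psi[cc], st$psi[cc + 1])
    counts2 <- tabulate(prop$Z, C)
    Rb <- move3_acceptance_ratio(counts2[cc], counts2[cc + 1], tail, st$alpha,
                                 prop$psi[cc], prop$psi[cc + 1])
    expect_lt(abs(Rf * Rb - 1), 1e-8)
  }
})

test_that("weight-matched swap preserves the pair's total weight and the stick map", {
  set.seed(31)
  for (r in 1:30) {
    d <- make_test_data(10, J = 2, K = 2, seed = r)
    st <- make_test_state(d, C = 4, alpha = 1.5, seed = r + 90)
    pri <- prior_spec(K = d$K, alpha = alpha_fixed(st$alpha))
    res <- move3_swap(st, d, pri)
    if (!isTRUE(res$accepted)) next
    cc <- res$c
    new <- res$state
    expect_lt(abs((new$psi[cc] + new$psi[cc + 1]) -
                    (st$psi[cc] + st$psi[cc + 1])), 1e-12)
    expect_equal(stick_weights(new$V), new$psi, tolerance = 1e-12)
  }
})

test_that("random label swaps follow the closed-form weight ratio", {
  set.seed(14)
  for (r in 1:40) {
    d <- make_test_data(15, J = 2, K = 2, seed = r)
    st <- make_test_state(d, C = 4, alpha = 1, seed = r + 40)
    pri <- prior_spec(K = d$K, alpha = alpha_fixed(1))
    res <- move1_swap(st, d, pri)
    counts <- tabulate(st$Z, st$C)
    c1 <- res$labels[1]; c2 <- res$labels[2]
    closed <- (counts[c1] - counts[c2]) * (log(st$psi[c2]) - log(st$psi[c1]))
    expect_lt(abs(res$log_ratio - closed), 1e-10)
  }
  # equal cluster sizes: ratio exactly 1, always accepted
  d <- make_test_data(6, J = 1, K = 2, seed = 2)
  st <- make_test_state(d, C = 2, seed = 2)
  st$Z <- rep(1:2, each = 3)
  res <- move1_swap(st, d, prior_spec(K = d$K, alpha = alpha_fixed(1)))
  expect_equal(res$log_ratio, 0)
  expect_true(res$accepted)
})

test_that("neighbour stick swaps follow the closed-form ratio and empty-cluster rule", {
  set.seed(15)
  for (r in 1:40) {
    d <- make_test_data(15, J = 2, K = 2, seed = r)
    st <- make_test_state(d, C = 4, alpha = 1, seed = r + 70)
    pri <- prior_spec(K = d$K, alpha = alpha_fixed(1))
    res <- move2_swap(st, d, pri)
    cc <- res$c
    counts <- tabulate(st$Z, st$C)
    closed <- counts[cc] * log(1 - st$V[cc + 1]) -
      counts[cc + 1] * log(1 - st$V[cc])
    expect_lt(abs(res$log_ratio - closed), 1e-10)
  }
  # lower-labelled cluster of the pair empty: ratio >= 1, always accepted
  d <- make_test_data(6, J = 1, K = 2, seed = 3)
  st <- make_test_state(d, C = 2, seed = 3)
  st$Z <- rep(2L, 6)
  res <- move2_swap(st, d, prior_spec(K = d$K, alpha = alpha_fixed(1)))
  expect_gte(res$log_ratio, 0)
  expect_true(res$accepted)
})

test_that("accepted moves never change the data log-likelihood", {
  set.seed(88)
  d <- make_test_data(20, J = 3, K = 3, response = TRUE, seed = 88)
  pri <- prior_spec(K = d$K, alpha = alpha_fixed(1))
  for (r in 1:30) {
    st <- make_test_state(d, C = 4, alpha = 1, seed = r)
    before <- fsbmix:::state_loglik(st, d)
    for (mv in list(move1_swap, move2_swap, move3_swap)) {
      res <- mv(st, d, pri)
      expect_equal(fsbmix:::state_loglik(res$state, d), before,
                   tolerance = 1e-9)
    }
  }
})

test_that("moves keep the slice invariant intact and no-op on a single cluster", {
  d <- make_test_data(10, J = 2, K = 2, seed = 6)
  pri <- prior_spec(K = d$K, alpha = alpha_fixed(1))
  set.seed(6)
  for (r in 1:20) {
    st <- make_test_state(d, C = 3, seed = r)
    for (mv in list(move1_swap, move2_swap, move3_swap)) {
      out <- mv(st, d, pri)$state
      expect_true(all(out$u < out$psi[out$Z]))
    }
  }
  st1 <- make_test_state(d, C = 1, seed = 1)
  for (mv in list(move1_swap, move2_swap, move3_swap)) {
    res <- mv(st1, d, pri)
    expect_true(is.na(res$accepted))
    expect_identical(res$state$Z, st1$Z)
  }
})

test_that("acceptance windows aggregate per-move indicators", {
  d <- gen_tiny_fixture(6, seed = 4)
  ch <- run_chain(d, cfg = sampler_config(n_init_clusters = 3, n_burn = 100,
                                          n_keep = 1000, seed = 5))
  aw <- acceptance_windows(ch, window = 500)
  expect_equal(nrow(aw), 6L)  # 2 windows x 3 moves
  expect_true(all(aw$rate >= 0 & aw$rate <= 1, na.rm = TRUE))
  expect_equal(unique(aw$window_start), c(1L, 501L))
})
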