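# shared fixtures and independent oracles used across test files

# small covariate(-response) dataset with random categories
make_test_data <- function(n, J = 2, K = 2, response = FALSE, L = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(sample.int(K, n * J, replace = TRUE), n, J)
  Y <- if (response) stats::rbinom(n, 1, 0.5) else NULL
  W <- if (L > 0) matrix(stats::rnorm(n * L), n, L) else NULL
  profile_data(X, Y = Y, W = W, K = rep(K, J))
}

# a consistent mixture_state over a given dataset with random parameters
make_test_state <- function(data, C, alpha = 1, seed = 1) {
  set.seed(seed)
  V <- pmin(stats::rbeta(C, 1, alpha), 1 - 1e-9)
  psi <- stick_weights(V)
  Phi <- lapply(seq_len(data$J), function(j)
    t(vapply(seq_len(C), function(c) {
      g <- stats::rgamma(data$K[j], 1)
      g / sum(g)
    }, numeric(data$K[j]))))
  Z <- sample.int(C, data$n, replace = TRUE)
  structure(
    list(C = C, V = V, psi = psi, Phi = Phi,
         theta = stats::rnorm(C), beta = rep(0, data$L), Z = Z,
         u = stats::runif(data$n, 0, psi[Z]), alpha = alpha),
    class = "mixture_state"
  )
}

partition_id <- function(z) paste(match(z, unique(z)), collapse = ".")

# total variation between a chain's empirical partition frequencies and an
# exact enumeration table
partition_tv <- function(chain, exact) {
  ids <- apply(chain$Z, 1, partition_id)
  emp <- table(ids) / length(ids)
  p <- as.numeric(emp[exact$id])
  p[is.na(p)] <- 0
  0.5 * sum(abs(p - exact$prob))
}

# proposal of the weight-matched neighbour swap, built directly from its
# defining equations (allocation swap, parameter swap, expectation-matched
# weights, stick back-solve) — used to oracle-check the closed-form ratio
build_move3_proposal <- function(state, c) {
  counts <- tabulate(state$Z, state$C)
  counts2 <- counts
  counts2[c(c, c + 1L)] <- counts[c(c + 1L, c)]
  r_c <- expected_weight_given_z(c, counts2, state$alpha) /
    expected_weight_given_z(c + 1L, counts, state$alpha)
  r_c1 <- expected_weight_given_z(c + 1L, counts2, state$alpha) /
    expected_weight_given_z(c, counts, state$alpha)
  psi_c <- state$psi[c]; psi_c1 <- state$psi[c + 1L]
  psip <- psi_c + psi_c1
  Psi_norm <- psi_c1 * r_c + psi_c * r_c1
  prop <- state
  Z <- state$Z
  prop$Z[Z == c] <- c + 1L
  prop$Z[Z == c + 1L] <- c
  prop$theta[c(c, c + 1L)] <- state$theta[c(c + 1L, c)]
  for (j in seq_along(state$Phi))
    prop$Phi[[j]][c(c, c + 1L), ] <- state$Phi[[j]][c(c + 1L, c), ]
  prop$psi[c] <- psi_c1 * psip / Psi_norm * r_c
  prop$psi[c + 1L] <- psi_c * psip / Psi_norm * r_c1
  prefix <- prod(1 - state$V[seq_len(c - 1L)])
  prop$V[c] <- prop$psi[c] / prefix
  prop$V[c + 1L] <- prop$psi[c + 1L] / ((1 - prop$V[c]) * prefix)
  prop
}

# adaptive Gauss-Hermite quadrature of exp(logf) over R^d, centred and scaled
# by a numerically found mode/Hessian (independent of the package's Newton)
gauss_hermite_integral <- function(logf, d, nodes = 21, start = rep(0, d)) {
  opt <- stats::optim(start, function(x) -logf(x), method = "BFGS",
                      hessian = TRUE)
  mu <- opt$par
  Hc <- chol(opt$hessian)          # -Hessian of logf
  gh <- pracma::gaussHermite(nodes)
  grids <- replicate(d, gh$x, simplify = FALSE)
  nodes_grid <- as.matrix(expand.grid(grids))
  wts <- as.matrix(expand.grid(replicate(d, gh$w, simplify = FALSE)))
  logw <- rowSums(log(wts)) + rowSums(nodes_grid^2)
  pts <- t(mu + sqrt(2) * solve(Hc, t(nodes_grid)))
  vals <- apply(pts, 1, logf)
  m <- max(vals + logw)
  log(sum(exp(vals + logw - m))) + m +
    0.5 * d * log(2) - sum(log(diag(Hc)))
}
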