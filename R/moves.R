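#' Joint log density of the full stick-breaking mixture state
#'
#' Unnormalised log joint of the represented state: Beta(1, alpha) stick
#' densities, Dirichlet and Student-t parameter priors, the allocation term
#' `sum_i log psi_{Z_i}`, optionally the data log-likelihood, and the
#' concentration hyperprior when one is set.  Label-switching acceptance
#' ratios are computed from differences of this quantity (with the
#' label-invariant likelihood term omitted), so they are exact by
#' construction rather than transcribed closed forms.
#'
#' @param state a `mixture_state`.
#' @param data a [profile_data()] object.
#' @param priors a [prior_spec()] object.
#' @param include_likelihood include the data log-likelihood term.
#' @return scalar log density (may be `-Inf`).
#' @export
joint_log_density <- function(state, data, priors, include_likelihood = TRUE) {
  lp <- sum(stats::dbeta(state$V, 1, state$alpha, log = TRUE))
  for (j in seq_len(data$J)) {
    aj <- priors$a[[j]]
    lp <- lp + sum(log(state$Phi[[j]]) %*% (aj - 1)) +
      state$C * (lgamma(sum(aj)) - sum(lgamma(aj)))
  }
  if (!is.null(data$Y)) {
    lp <- lp + sum(log_t_prior(state$theta, priors$theta_prior))
    if (data$L > 0) lp <- lp + sum(log_t_prior(state$beta, priors$beta_prior))
  }
  if (length(state$Z)) {
    counts <- tabulate(state$Z, state$C)
    lp <- lp + sum(counts * log(state$psi))
  }
  if (priors$alpha$type == "gamma")
    lp <- lp + stats::dgamma(state$alpha, priors$alpha$shape,
                             priors$alpha$rate, log = TRUE)
  if (include_likelihood) lp <- lp + state_loglik(state, data)
  lp
}

# exchange allocations and component parameters of labels c1, c2
swap_labels <- function(state, c1, c2) {
  Z <- state$Z
  i1 <- Z == c1; i2 <- Z == c2
  Z[i1] <- c2; Z[i2] <- c1
  state$Z <- Z
  state$theta[c(c1, c2)] <- state$theta[c(c2, c1)]
  for (j in seq_along(state$Phi))
    state$Phi[[j]][c(c1, c2), ] <- state$Phi[[j]][c(c2, c1), ]
  state
}

# redraw slice variables of subjects in the two affected labels so that the
# invariant u_i < psi_{Z_i} holds after an accepted move (a valid Gibbs refresh)
refresh_slices <- function(state, c1, c2) {
  idx <- which(state$Z == c1 | state$Z == c2)
  if (length(idx))
    state$u[idx] <- stats::runif(length(idx), 0, state$psi[state$Z[idx]])
  state
}

#' Label-switching move 1: swap two random labels
#'
#' Exchanges the allocations and component parameters of two labels drawn
#' uniformly over the represented components (weights left in place; the
#' represented pool is fixed during the move, which keeps the proposal
#' symmetric even when a swap empties the top label), accepting with the
#' exact Metropolis ratio of the joint density — which reduces to
#' `(psi_{c2}/psi_{c1})^(n_{c1} - n_{c2})`.
#'
#' @param state a `mixture_state`.
#' @param data a [profile_data()] object.
#' @param priors a [prior_spec()] object.
#' @param occupied_only restrict the candidate labels to occupied clusters.
#' @return list with `state`, `accepted` (NA when not attempted) and
#'   `log_ratio`.
#' @export
move1_swap <- function(state, data, priors, occupied_only = FALSE) {
  pool <- if (occupied_only) sort(unique(state$Z)) else seq_len(state$C)
  if (length(pool) < 2) return(list(state = state, accepted = NA, log_ratio = NA_real_))
  pair <- sample(pool, 2)
  prop <- swap_labels(state, pair[1], pair[2])
  logr <- joint_log_density(prop, data, priors, include_likelihood = FALSE) -
    joint_log_density(state, data, priors, include_likelihood = FALSE)
  if (log(stats::runif(1)) < logr) {
    prop <- refresh_slices(prop, pair[1], pair[2])
    list(state = prop, accepted = TRUE, log_ratio = logr, labels = sort(pair))
  } else {
    list(state = state, accepted = FALSE, log_ratio = logr, labels = sort(pair))
  }
}

#' Label-switching move 2: swap neighbouring labels and their sticks
#'
#' Picks `c` uniformly among the represented neighbour pairs and exchanges
#' allocations, component parameters and the stick proportions
#' `V_c, V_{c+1}`; downstream weights are recomputed.  Accepted with the
#' exact joint-density Metropolis ratio,
#' `(1 - V_{c+1})^{n_c} / (1 - V_c)^{n_{c+1}}`, which always accepts when
#' the lower-labelled cluster of the pair is empty.
#'
#' @inheritParams move1_swap
#' @return list with `state`, `accepted` and `log_ratio`.
#' @export
move2_swap <- function(state, data, priors) {
  if (state$C < 2) return(list(state = state, accepted = NA, log_ratio = NA_real_))
  c <- if (state$C == 2) 1L else sample.int(state$C - 1L, 1)
  prop <- swap_labels(state, c, c + 1L)
  prop$V[c(c, c + 1L)] <- prop$V[c(c + 1L, c)]
  prop$psi <- stick_weights(prop$V)
  logr <- joint_log_density(prop, data, priors, include_likelihood = FALSE) -
    joint_log_density(state, data, priors, include_likelihood = FALSE)
  if (log(stats::runif(1)) < logr) {
    prop <- refresh_slices(prop, c, c + 1L)
    list(state = prop, accepted = TRUE, log_ratio = logr, c = c)
  } else {
    list(state = state, accepted = FALSE, log_ratio = logr, c = c)
  }
}

#' Acceptance ratio of the weight-matched label-switching move
#'
#' Closed-form acceptance ratio `R` for the neighbour swap that also
#' proposes new weights matched to their conditional expectations:
#' with `R1 = (1 + alpha + n_{c+1} + T) / (alpha + n_{c+1} + T)`,
#' `R2 = (alpha + n_c + T) / (1 + alpha + n_c + T)`,
#' `T = sum_{l>c+1} n_l` and `psi+ = psi_c + psi_{c+1}`,
#' `R = (psi+ / (psi_{c+1} R1 + psi_c R2))^(n_c + n_{c+1}) * R1^{n_{c+1}} * R2^{n_c}`.
#' Evaluated in log space.
#'
#' @param n_c,n_c1 member counts of clusters `c` and `c+1`.
#' @param tail total count in clusters beyond `c+1`.
#' @param alpha positive concentration parameter.
#' @param psi_c,psi_c1 current weights of the pair (positive).
#' @return the ratio `R` ([move3_swap()] accepts with probability
#'   `min(1, R)` up to the proposal-map volume correction).
#' @examples
#' move3_acceptance_ratio(2, 1, 0, 1, 0.4, 0.2)  # 0.84375
#' @export
move3_acceptance_ratio <- function(n_c, n_c1, tail, alpha, psi_c, psi_c1) {
  if (alpha <= 0) stop("alpha must be positive")
  if (psi_c <= 0 || psi_c1 <= 0) stop("weights must be positive")
  if (n_c < 0 || n_c1 < 0 || tail < 0) stop("counts must be non-negative")
  logR1 <- log1p(1 / (alpha + n_c1 + tail))
  logR2 <- -log1p(1 / (alpha + n_c + tail))
  # log(psi_{c+1} R1 + psi_c R2) via log-sum-exp
  a <- log(psi_c1) + logR1; b <- log(psi_c) + logR2
  m <- max(a, b)
  logden <- m + log(exp(a - m) + exp(b - m))
  logR <- (n_c + n_c1) * (log(psi_c + psi_c1) - logden) + n_c1 * logR1 + n_c * logR2
  exp(logR)
}

#' Label-switching move 3: weight-matched neighbour swap
#'
#' Picks `c` uniformly among the represented neighbour pairs, swaps
#' allocations and component parameters of clusters `c` and `c+1`, and
#' simultaneously proposes new
#' weights for the pair scaled to their conditional expectations given the
#' proposed allocations (preserving `psi_c + psi_{c+1}`), back-solving the
#' stick proportions.  Accepted with probability `min(1, R |det DT|)`:
#' the closed-form ratio from [move3_acceptance_ratio()] times the volume
#' change of the deterministic weight map, which exact balance of a
#' deterministic Metropolis proposal requires (the factor is usually within
#' a few percent of one).  Because the weights travel with the labels,
#' this move keeps a useful acceptance rate even after the sampler settles
#' into the modal size ordering, which is what lets the concentration
#' parameter mix over cluster orderings.
#'
# log |det| of the weight-matched proposal map in stick coordinates.
# In weight coordinates (a, b) = (psi_c, psi_{c+1}) the map is
# a' = r1 S b / D, b' = r2 S a / D with S = a + b, D = b r1 + a r2 and
# constant expectation ratios r1, r2; transforming to (V_c, V_{c+1})
# multiplies the determinant by (P - a) / (P - a') for prefix P.
move3_log_jacobian <- function(a, b, r1, r2, prefix, a_new) {
  S <- a + b; D <- b * r1 + a * r2
  daa <- r1 * b * (D - S * r2) / D^2
  dab <- r1 * ((S + b) * D - S * b * r1) / D^2
  dba <- r2 * ((S + a) * D - S * a * r2) / D^2
  dbb <- r2 * a * (D - S * r1) / D^2
  log(abs(daa * dbb - dab * dba)) + log(prefix - a) - log(prefix - a_new)
}

#' @inheritParams move1_swap
#' @return list with `state`, `accepted` and `log_ratio` (the log of the
#'   closed-form ratio plus the proposal-map volume correction actually
#'   used for acceptance).
#' @export
move3_swap <- function(state, data, priors) {
  if (state$C < 2) return(list(state = state, accepted = NA, log_ratio = NA_real_))
  c <- if (state$C == 2) 1L else sample.int(state$C - 1L, 1)
  counts <- tabulate(state$Z, state$C)
  counts2 <- counts; counts2[c(c, c + 1L)] <- counts[c(c + 1L, c)]
  prefix <- prod(1 - state$V[seq_len(c - 1L)])
  if (prefix <= 0) {
    warning("zero stick prefix in weight-matched swap; proposal rejected")
    return(list(state = state, accepted = FALSE, log_ratio = -Inf))
  }
  psi_c <- state$psi[c]; psi_c1 <- state$psi[c + 1L]
  psip <- psi_c + psi_c1
  r_c <- expected_weight_given_z(c, counts2, state$alpha) /
    expected_weight_given_z(c + 1L, counts, state$alpha)
  r_c1 <- expected_weight_given_z(c + 1L, counts2, state$alpha) /
    expected_weight_given_z(c, counts, state$alpha)
  Psi_norm <- psi_c1 * r_c + psi_c * r_c1
  psi_new_c <- psi_c1 * psip / Psi_norm * r_c
  psi_new_c1 <- psi_c * psip / Psi_norm * r_c1
  tail <- if (c + 1L < state$C) sum(counts[(c + 2L):state$C]) else 0
  R <- move3_acceptance_ratio(counts[c], counts[c + 1L], tail, state$alpha,
                              psi_c, psi_c1)
  # exact balance for the deterministic weight proposal requires the volume
  # change of the (V_c, V_{c+1}) map on top of the density ratio
  logR <- log(R) + move3_log_jacobian(psi_c, psi_c1, r_c, r_c1, prefix,
                                      psi_new_c)
  R <- exp(logR)
  if (stats::runif(1) < R) {
    prop <- swap_labels(state, c, c + 1L)
    prop$psi[c] <- psi_new_c
    prop$psi[c + 1L] <- psi_new_c1
    prop$V[c] <- psi_new_c / prefix
    prop$V[c + 1L] <- psi_new_c1 / ((1 - prop$V[c]) * prefix)
    prop <- refresh_slices(prop, c, c + 1L)
    list(state = prop, accepted = TRUE, log_ratio = log(R), c = c)
  } else {
    list(state = state, accepted = FALSE, log_ratio = log(R), c = c)
  }
}

#' Windowed label-switching acceptance rates
#'
#' Aggregates the per-sweep acceptance indicators of a chain into
#' consecutive windows (default 500 kept sweeps), the scale at which move
#' mixing is usually inspected.
#'
#' @param chain a [run_chain()] result.
#' @param window window length in kept sweeps.
#' @return data frame with columns `window_start`, `move`, `rate`.
#' @export
acceptance_windows <- function(chain, window = 500) {
  stopifnot(inherits(chain, "chain_output"))
  m <- nrow(chain$accept)
  starts <- seq(1L, m, by = window)
  out <- do.call(rbind, lapply(starts, function(s) {
    idx <- s:min(s + window - 1L, m)
    data.frame(window_start = s, move = c("move1", "move2", "move3"),
               rate = colMeans(chain$accept[idx, , drop = FALSE], na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}
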