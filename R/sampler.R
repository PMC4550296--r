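#' Sampler configuration
#'
#' Run-length, initialisation and move settings for [run_chain()].
#'
#' @param n_init_clusters number of clusters the allocation vector is
#'   initialised with (balanced shuffled round-robin).  Starting with more
#'   clusters than the anticipated posterior number is important: the sampler
#'   merges clusters far more easily than it splits them.
#' @param n_burn,n_keep burn-in and kept sweeps.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed; the chain is fully reproducible from it.
#' @param moves logical length-3 vector enabling label-switching moves 1
#'   (random label swap), 2 (neighbour stick swap) and 3 (weight-matched
#'   neighbour swap).
#' @param rw_scales named numeric `c(theta = , beta = )`, initial
#'   random-walk proposal scales for the response-block Metropolis updates.
#' @param adapt_burnin_only adapt proposal scales during burn-in only
#'   (Robbins-Monro toward acceptance 0.44 for scalar updates, 0.23 for the
#'   joint beta block); scales are frozen afterwards so the kept sample
#'   targets the exact posterior.
#' @param store_params store per-sweep component parameters (needed by
#'   [predict_response()]).
#' @param compute_mpp record the log marginal partition posterior at each
#'   kept sweep, conditioned on `mpp_alpha`.
#' @param mpp_alpha fixed concentration used for the marginal partition
#'   posterior record.
#' @param max_stick_extensions cap on slice-coverage stick extensions per
#'   sweep.
#' @param progress_every print progress to standard error every so many
#'   sweeps (0 disables).
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_init_clusters = 10, n_burn = 1000, n_keep = 1000,
                           thin = 1, seed = 1,
                           moves = c(move1 = TRUE, move2 = TRUE, move3 = TRUE),
                           rw_scales = c(theta = 0.5, beta = 0.1),
                           adapt_burnin_only = TRUE,
                           store_params = FALSE,
                           compute_mpp = FALSE, mpp_alpha = 1,
                           max_stick_extensions = 10000,
                           progress_every = 0) {
  stopifnot(n_init_clusters >= 1, n_burn >= 0, n_keep >= 0, thin >= 1)
  moves <- rep_len(as.logical(moves), 3)
  names(moves) <- c("move1", "move2", "move3")
  structure(
    list(n_init_clusters = as.integer(n_init_clusters),
         n_burn = as.integer(n_burn), n_keep = as.integer(n_keep),
         thin = as.integer(thin), seed = as.integer(seed), moves = moves,
         rw_scales = c(theta = unname(rw_scales["theta"]), beta = unname(rw_scales["beta"])),
         adapt_burnin_only = isTRUE(adapt_burnin_only),
         store_params = isTRUE(store_params),
         compute_mpp = isTRUE(compute_mpp), mpp_alpha = mpp_alpha,
         max_stick_extensions = as.integer(max_stick_extensions),
         progress_every = as.integer(progress_every)),
    class = "sampler_config"
  )
}

#' Initialise the sampler state
#'
#' Allocations are assigned by a shuffled round-robin over
#' `n_init_clusters` labels (balanced), sticks and component parameters are
#' drawn from their priors, fixed-effect coefficients start at zero, the
#' concentration starts at its prior mean (or fixed value) and slice
#' variables are drawn consistently with the allocations.
#'
#' @param data a [profile_data()] object.
#' @param priors a [prior_spec()] object.
#' @param cfg a [sampler_config()] object.
#' @return An object of class `mixture_state` with elements `C`, `V`, `psi`,
#'   `Phi` (list of per-covariate C x K_j probability matrices), `theta`,
#'   `beta`, `Z`, `u`, `alpha`.
#' @export
init_state <- function(data, priors, cfg) {
  stopifnot(inherits(data, "profile_data"), inherits(priors, "prior_spec"),
            inherits(cfg, "sampler_config"))
  C <- cfg$n_init_clusters
  if (data$n > 0 && C > data$n) stop("n_init_clusters exceeds the number of subjects")
  if (length(priors$a) != data$J) stop("prior_spec covers ", length(priors$a),
                                       " covariates but data has ", data$J)
  alpha <- alpha_prior_mean(priors$alpha)
  Z <- if (data$n > 0) sample(rep_len(seq_len(C), data$n)) else integer(0)
  V <- pmin(stats::rbeta(C, 1, alpha), 1 - 1e-12)
  psi <- stick_weights(V)
  Phi <- lapply(seq_len(data$J), function(j) {
    t(vapply(seq_len(C), function(c) rdirichlet1(priors$a[[j]]),
             numeric(data$K[j])))
  })
  theta <- draw_theta_prior(C, priors)
  u <- if (data$n > 0) stats::runif(data$n, 0, psi[Z]) else numeric(0)
  structure(
    list(C = C, V = V, psi = psi, Phi = Phi, theta = theta,
         beta = rep(0, data$L), Z = Z, u = u, alpha = alpha),
    class = "mixture_state"
  )
}

#' @export
print.mixture_state <- function(x, ...) {
  cat(sprintf("mixture_state: %d represented component(s), %d occupied, alpha = %.3f\n",
              x$C, length(unique(x$Z)), x$alpha))
  invisible(x)
}

draw_theta_prior <- function(m, priors) {
  p <- priors$theta_prior
  p[2] + p[3] * stats::rt(m, df = p[1])
}

#' Log-likelihood matrix of all subjects under all represented components
#'
#' @param state a `mixture_state`.
#' @param data a [profile_data()] object.
#' @return C x n matrix of `log f(D_i | Theta_c, beta)`.
#' @export
loglik_matrix <- function(state, data) {
  C <- state$C; n <- data$n
  M <- matrix(0, C, n)
  for (j in seq_len(data$J)) {
    M <- M + log(state$Phi[[j]])[, data$X[, j], drop = FALSE]
  }
  if (!is.null(data$Y)) {
    off <- if (data$L > 0) as.vector(data$W %*% state$beta) else rep(0, n)
    eta <- outer(state$theta, off, "+")           # C x n
    M <- M + sweep(eta, 2, data$Y, "*") - log1p_exp(eta)
  }
  M
}

#' Slice and allocation update
#'
#' Draws the slice variables `u_i ~ U(0, psi_{Z_i})`, extends the represented
#' components (new sticks from Beta(1, alpha), new parameters from the
#' priors) until the undistributed stick mass falls below `min(u)`, then
#' redraws every allocation from
#' `P(Z_i = c) proportional to 1{psi_c > u_i} f(D_i | Theta_c, beta)`
#' over the represented components (Gumbel-max, exact).
#'
#' @param state a `mixture_state`.
#' @param data a [profile_data()] object.
#' @param priors a [prior_spec()] object (for extension draws).
#' @param max_ext cap on stick extensions.
#' @return Updated `mixture_state`.
#' @export
update_slice_allocations <- function(state, data, priors, max_ext = 10000) {
  n <- data$n
  if (n == 0) return(state)
  u <- stats::runif(n, 0, state$psi[state$Z])
  min_u <- min(u)
  rest <- prod(1 - state$V)
  n_ext <- 0L
  while (rest >= min_u) {
    if (n_ext >= max_ext)
      stop(sprintf("slice not covered after %d stick extensions (alpha = %.4g)",
                   max_ext, state$alpha))
    # extend in chunks: draw a block of prior sticks, keep those up to (and
    # including) the first that brings the undistributed mass under the slice
    chunk <- min(32L, max_ext - n_ext)
    Vnew <- pmin(stats::rbeta(chunk, 1, state$alpha), 1 - 1e-12)
    rests <- rest * cumprod(1 - Vnew)
    hit <- which(rests < min_u)
    keep <- if (length(hit)) hit[1] else chunk
    Vnew <- Vnew[seq_len(keep)]
    state$psi <- c(state$psi, Vnew * c(rest, rests[seq_len(keep - 1L)]))
    state$V <- c(state$V, Vnew)
    for (j in seq_len(data$J)) {
      aj <- priors$a[[j]]
      g <- matrix(stats::rgamma(keep * length(aj), shape = rep(aj, each = keep)),
                  keep, length(aj))
      state$Phi[[j]] <- rbind(state$Phi[[j]], g / rowSums(g))
    }
    state$theta <- c(state$theta, draw_theta_prior(keep, priors))
    rest <- rests[keep]
    state$C <- state$C + keep
    n_ext <- n_ext + keep
  }
  M <- loglik_matrix(state, data)
  G <- -log(-log(matrix(stats::runif(state$C * n), state$C, n)))
  S <- M + G
  S[!outer(state$psi, u, ">")] <- -Inf
  state$Z <- max.col(t(S), ties.method = "first")
  state$u <- u
  state
}

#' Stick update
#'
#' Conjugate update `V_c ~ Beta(1 + n_c, alpha + sum_{l>c} n_l)` for every
#' represented component; weights recomputed by [stick_weights()].
#'
#' @inheritParams update_slice_allocations
#' @return Updated `mixture_state`.
#' @export
update_sticks <- function(state, data) {
  counts <- tabulate(state$Z, state$C)
  tails <- rev(cumsum(rev(counts))) - counts
  state$V <- pmin(stats::rbeta(state$C, 1 + counts, state$alpha + tails), 1 - 1e-12)
  state$psi <- stick_weights(state$V)
  state
}

#' Category-probability update
#'
#' Conjugate Dirichlet update of each represented component's category
#' probabilities; empty components are redrawn from the prior (the same
#' formula with zero counts), keeping fresh parameters available for splits.
#'
#' @inheritParams update_slice_allocations
#' @return Updated `mixture_state`.
#' @export
update_phi <- function(state, data, priors) {
  C <- state$C
  for (j in seq_len(data$J)) {
    K <- data$K[j]
    cnt <- matrix(tabulate((data$X[, j] - 1L) * C + state$Z, C * K), C, K)
    g <- matrix(stats::rgamma(C * K,
                              shape = cnt + rep(priors$a[[j]], each = C),
                              rate = 1), C, K)
    state$Phi[[j]] <- g / rowSums(g)
  }
  state
}

#' Cluster-intercept update
#'
#' Independent Metropolis random-walk update of each represented component's
#' logit intercept against the Bernoulli likelihood of its members and the
#' Student-t prior; empty components are redrawn from the prior.  A no-op
#' when the data carry no response.
#'
#' @inheritParams update_slice_allocations
#' @param scale random-walk standard deviation.
#' @return Updated `mixture_state` with attribute `accept_rate` (mean
#'   acceptance over occupied components, `NA` if none updated).
#' @export
update_theta <- function(state, data, priors, scale = 0.5) {
  if (is.null(data$Y)) return(state)
  C <- state$C
  counts <- tabulate(state$Z, C)
  off <- if (data$L > 0) as.vector(data$W %*% state$beta) else rep(0, data$n)
  ones <- counts > 0
  # sufficient statistics per component: member loglik at current/proposed theta
  prop <- state$theta + scale * stats::rnorm(C)
  cur_ll <- group_bernoulli_loglik(state$theta, state$Z, data$Y, off, C)
  new_ll <- group_bernoulli_loglik(prop, state$Z, data$Y, off, C)
  logr <- (new_ll + log_t_prior(prop, priors$theta_prior)) -
    (cur_ll + log_t_prior(state$theta, priors$theta_prior))
  acc <- log(stats::runif(C)) < logr
  state$theta[ones & acc] <- prop[ones & acc]
  state$theta[!ones] <- draw_theta_prior(sum(!ones), priors)
  attr(state, "accept_rate") <- if (any(ones)) mean(acc[ones]) else NA_real_
  state
}

# per-component Bernoulli log-likelihood for intercept vector th (length C);
# empty components get 0
group_bernoulli_loglik <- function(th, Z, Y, off, C) {
  eta <- th[Z] + off
  ll <- Y * eta - log1p_exp(eta)
  out <- numeric(C)
  s <- rowsum(ll, Z)
  out[as.integer(rownames(s))] <- s
  out
}

#' Fixed-effect update
#'
#' Joint Metropolis random-walk update of the global coefficient vector
#' against the full Bernoulli likelihood and independent Student-t priors.
#' A no-op without a response or without fixed effects.
#'
#' @inheritParams update_theta
#' @return Updated `mixture_state` with attribute `accept_rate` (0/1).
#' @export
update_beta <- function(state, data, priors, scale = 0.1) {
  if (is.null(data$Y) || data$L == 0) return(state)
  prop <- state$beta + scale * stats::rnorm(data$L)
  th_i <- state$theta[state$Z]
  cur <- sum_bernoulli_loglik(th_i + as.vector(data$W %*% state$beta), data$Y) +
    sum(log_t_prior(state$beta, priors$beta_prior))
  new <- sum_bernoulli_loglik(th_i + as.vector(data$W %*% prop), data$Y) +
    sum(log_t_prior(prop, priors$beta_prior))
  acc <- log(stats::runif(1)) < new - cur
  if (acc) state$beta <- prop
  attr(state, "accept_rate") <- as.numeric(acc)
  state
}

sum_bernoulli_loglik <- function(eta, Y) sum(Y * eta - log1p_exp(eta))

#' Concentration-parameter update
#'
#' Conjugate Gibbs update
#' `alpha ~ Gamma(shape + C*, rate - sum_{c <= C*} log(1 - V_c))` over the
#' sticks up to the largest occupied label `C*` (all represented sticks
#' when nothing is allocated); a no-op when the prior fixes alpha.
#' Conditioning on the slice-extension sticks beyond `C*` as well would
#' bias alpha upwards — their number is informative about alpha through
#' the coverage stopping rule — and the prior-reproduction oracle rejects
#' that convention.
#'
#' @inheritParams update_slice_allocations
#' @return Updated `mixture_state`.
#' @export
update_alpha <- function(state, data, priors) {
  if (priors$alpha$type == "fixed") return(state)
  Cs <- if (length(state$Z)) max(state$Z) else state$C
  rate <- priors$alpha$rate - sum(log1p(-state$V[seq_len(Cs)]))
  if (rate <= 0) stop("non-positive rate in the alpha update; invalid sticks")
  state$alpha <- stats::rgamma(1, shape = priors$alpha$shape + Cs, rate = rate)
  state
}

#' Run the blocked Metropolis-within-Gibbs chain
#'
#' Executes sweeps in fixed order — slice/allocations, sticks, category
#' probabilities, intercepts, fixed effects, concentration, then the enabled
#' label-switching moves (each attempted once) — truncating the represented
#' components to `max(Z)` at the end of every sweep.  Fully reproducible
#' from the configuration seed.
#'
#' @param data a [profile_data()] object.
#' @param priors a [prior_spec()] object; defaults to all-ones Dirichlet
#'   vectors, t(7, 0, 2.5) intercept/coefficient priors and a
#'   Gamma(9, 0.5) concentration hyperprior.
#' @param cfg a [sampler_config()] object.
#' @return An object of class `chain_output`: matrices/vectors of kept-sweep
#'   records (`Z`, `alpha`, `K_occ`, `loglik`, optionally `logmpp`), move
#'   acceptance indicators (`accept`, NA where a move was not attempted),
#'   response-update acceptance rates, optionally per-sweep parameters, and
#'   run metadata.
#' @examples
#' sim <- gen_tiny_fixture(n = 6, seed = 1)
#' ch <- run_chain(sim, cfg = sampler_config(n_init_clusters = 3, n_burn = 50,
#'                                           n_keep = 50, seed = 1))
#' table(ch$K_occ)
#' @export
run_chain <- function(data, priors = NULL, cfg = sampler_config()) {
  stopifnot(inherits(data, "profile_data"), inherits(cfg, "sampler_config"))
  if (is.null(priors)) priors <- prior_spec(K = data$K)
  set.seed(cfg$seed)
  state <- init_state(data, priors, cfg)
  n_sweeps <- cfg$n_burn + cfg$n_keep * cfg$thin
  n_kept <- cfg$n_keep
  scales <- cfg$rw_scales
  rec <- list(
    Z = matrix(NA_integer_, n_kept, data$n),
    alpha = numeric(n_kept), K_occ = integer(n_kept),
    loglik = numeric(n_kept),
    logmpp = if (cfg$compute_mpp) numeric(n_kept) else NULL,
    accept = matrix(NA_real_, n_kept, 3,
                    dimnames = list(NULL, c("move1", "move2", "move3"))),
    acc_theta = rep(NA_real_, n_kept), acc_beta = rep(NA_real_, n_kept),
    params = if (cfg$store_params) vector("list", n_kept) else NULL
  )
  kept <- 0L
  for (s in seq_len(n_sweeps)) {
    state <- update_slice_allocations(state, data, priors, cfg$max_stick_extensions)
    state <- update_sticks(state, data)
    state <- update_phi(state, data, priors)
    state <- update_theta(state, data, priors, scales["theta"])
    at <- attr(state, "accept_rate")
    state <- update_beta(state, data, priors, scales["beta"])
    ab <- attr(state, "accept_rate")
    state <- update_alpha(state, data, priors)
    macc <- rep(NA_real_, 3)
    if (cfg$moves["move1"]) {
      r <- move1_swap(state, data, priors); state <- r$state; macc[1] <- as.numeric(r$accepted)
    }
    if (cfg$moves["move2"]) {
      r <- move2_swap(state, data, priors); state <- r$state; macc[2] <- as.numeric(r$accepted)
    }
    if (cfg$moves["move3"]) {
      r <- move3_swap(state, data, priors); state <- r$state; macc[3] <- as.numeric(r$accepted)
    }
    state <- truncate_state(state, data)
    if (cfg$adapt_burnin_only && s <= cfg$n_burn) {
      step <- 1 / sqrt(s)
      if (!is.null(at) && !is.na(at)) scales["theta"] <- scales["theta"] * exp(step * (at - 0.44))
      if (!is.null(ab) && !is.na(ab)) scales["beta"] <- scales["beta"] * exp(step * (ab - 0.23))
    }
    if (s > cfg$n_burn && (s - cfg$n_burn) %% cfg$thin == 0) {
      kept <- kept + 1L
      rec$Z[kept, ] <- state$Z
      rec$alpha[kept] <- state$alpha
      rec$K_occ[kept] <- length(unique(state$Z))
      rec$loglik[kept] <- state_loglik(state, data)
      if (cfg$compute_mpp)
        rec$logmpp[kept] <- log_marginal_partition_posterior(state$Z, data,
                                                             alpha_fixed = cfg$mpp_alpha,
                                                             priors = priors)
      rec$accept[kept, ] <- macc
      rec$acc_theta[kept] <- if (is.null(at)) NA_real_ else at
      rec$acc_beta[kept] <- if (is.null(ab)) NA_real_ else ab
      if (cfg$store_params)
        rec$params[[kept]] <- list(psi = state$psi, theta = state$theta,
                                   beta = state$beta, Phi = state$Phi)
    }
    if (cfg$progress_every > 0 && s %% cfg$progress_every == 0)
      message(sprintf("sweep %d/%d: K_occ = %d, alpha = %.3f",
                      s, n_sweeps, length(unique(state$Z)), state$alpha))
  }
  structure(
    list(Z = rec$Z, alpha = rec$alpha, K_occ = rec$K_occ, loglik = rec$loglik,
         logmpp = rec$logmpp, accept = rec$accept,
         acc_theta = rec$acc_theta, acc_beta = rec$acc_beta,
         params = rec$params, final_scales = scales,
         config = cfg, seed = cfg$seed, priors = priors,
         data_signature = data_signature(data),
         version = as.character(utils::packageVersion("fsbmix"))),
    class = "chain_output"
  )
}

#' @export
print.chain_output <- function(x, ...) {
  cat(sprintf("chain_output: %d kept sweeps, %d subject(s), seed %d\n",
              nrow(x$Z), ncol(x$Z), x$seed))
  if (length(x$K_occ)) {
    tab <- table(x$K_occ)
    cat("non-empty clusters:",
        paste(sprintf("%s (%.2f)", names(tab), as.numeric(tab) / length(x$K_occ)),
              collapse = ", "), "\n")
    cat(sprintf("alpha: mean %.3f [%.3f, %.3f]\n", mean(x$alpha),
                stats::quantile(x$alpha, 0.025), stats::quantile(x$alpha, 0.975)))
  }
  invisible(x)
}

# drop represented components above the largest occupied label (keep >= 1)
truncate_state <- function(state, data) {
  Zmax <- if (length(state$Z)) max(state$Z) else 1L
  if (Zmax >= state$C) return(state)
  keep <- seq_len(Zmax)
  state$C <- Zmax
  state$V <- state$V[keep]
  state$psi <- state$psi[keep]
  state$theta <- state$theta[keep]
  for (j in seq_along(state$Phi))
    state$Phi[[j]] <- state$Phi[[j]][keep, , drop = FALSE]
  state
}

state_loglik <- function(state, data) {
  if (data$n == 0) return(0)
  M <- loglik_matrix(state, data)
  sum(M[cbind(state$Z, seq_len(data$n))])
}

# cheap deterministic signature used to refuse cross-dataset comparisons
data_signature <- function(data) {
  paste(data$n, data$J, data$L, paste(data$K, collapse = ","),
        if (data$J > 0) sum(data$X) else 0,
        if (!is.null(data$Y)) sum(data$Y) else -1,
        if (data$L > 0) signif(sum(data$W), 10) else 0,
        sep = "|")
}

#' Extract one component's parameters
#'
#' @param state a `mixture_state`.
#' @param c component label (at most `state$C`).
#' @return list with `phi` (per-covariate probability vectors, each summing
#'   to one) and `theta` (logit intercept).
#' @export
component_params <- function(state, c) {
  stopifnot(inherits(state, "mixture_state"), c >= 1, c <= state$C)
  phi <- lapply(state$Phi, function(m) m[c, ])
  for (p in phi) {
    if (abs(sum(p) - 1) > 1e-10) stop("component probabilities do not sum to 1")
  }
  list(phi = phi, theta = state$theta[c])
}
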