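#' Posterior similarity matrix
#'
#' Empirical co-clustering probabilities: `S_ij` is the fraction of kept
#' sweeps in which subjects `i` and `j` share a cluster.  Invariant to
#' relabelling of the allocations, which is what makes it a usable summary
#' despite label switching.
#'
#' @param x a [run_chain()] result or a sweeps-by-subjects allocation
#'   matrix.
#' @param thin_to optional cap on the number of sweeps used (evenly spaced
#'   subset); `NULL` uses all sweeps.
#' @return An object of class `similarity_matrix`: the n x n matrix with
#'   attribute `n_sweeps`.
#' @export
similarity_matrix <- function(x, thin_to = NULL) {
  Z <- if (inherits(x, "chain_output")) x$Z else as.matrix(x)
  m <- nrow(Z)
  stopifnot(m >= 1)
  if (!is.null(thin_to) && thin_to < m) {
    Z <- Z[unique(round(seq(1, m, length.out = thin_to))), , drop = FALSE]
    m <- nrow(Z)
  }
  n <- ncol(Z)
  S <- matrix(0, n, n)
  for (s in seq_len(m)) {
    z <- Z[s, ]
    for (c in unique(z)) {
      idx <- which(z == c)
      S[idx, idx] <- S[idx, idx] + 1
    }
  }
  S <- S / m
  diag(S) <- 1
  structure(S, n_sweeps = m, class = c("similarity_matrix", "matrix"))
}

#' Optimal partition from a posterior similarity matrix
#'
#' Searches partitions of `1..n` for one maximising the pairwise score
#' `sum_{i<j co-clustered} (S_ij - threshold)` (a Binder-type loss).
#' Candidates are produced by partitioning around medoids on the
#' dissimilarity `1 - S` for each number of clusters up to `k_max`; the
#' best-scoring candidate is returned.  Unlike the in-sample MAP partition
#' this estimate uses the whole MCMC output through `S` and may lie outside
#' the sampled partitions.
#'
#' @param S a [similarity_matrix()] (or plain symmetric matrix in [0,1]).
#' @param k_max largest number of clusters tried (default: a small margin
#'   above the apparent structure, `n - 1` capped).
#' @param threshold pairwise score threshold (default 0.5).
#' @return list with `partition` (a [partition()] object), `k` and `score`.
#' @export
optimal_partition <- function(S, k_max = NULL, threshold = 0.5) {
  S <- unclass(S)
  n <- nrow(S)
  if (is.null(k_max)) k_max <- min(n - 1L, 20L)
  k_max <- max(1L, min(k_max, n - 1L))
  score <- function(z) {
    tot <- 0
    for (c in unique(z)) {
      idx <- which(z == c)
      if (length(idx) > 1) {
        B <- S[idx, idx]
        tot <- tot + (sum(B[upper.tri(B)]) - threshold * choose(length(idx), 2))
      }
    }
    tot
  }
  best_z <- rep(1L, n)
  best <- score(best_z)
  best_k <- 1L
  if (k_max >= 2) {
    D <- stats::as.dist(1 - S)
    for (k in 2:k_max) {
      z <- cluster::pam(D, k, diss = TRUE, cluster.only = TRUE)
      sc <- score(z)
      if (sc > best) {
        best <- sc; best_z <- z; best_k <- k
      }
    }
  }
  list(partition = partition(best_z), k = best_k, score = best)
}

#' Rao-Blackwellised response predictions
#'
#' Posterior predictive probability of a positive response for new covariate
#' profiles: at each kept sweep the profile's cluster-membership weights
#' `w_c` are proportional to `psi_c * f_X(x* | Phi_c)` over the represented
#' components (renormalised), the sweep prediction is
#' `sum_c w_c * plogis(theta_c + beta' w*)`, and the estimate is the sweep
#' average.  Averaging over membership probabilities rather than hard
#' allocations makes the estimate robust to label switching and to
#' run-to-run differences in the optimal partition.
#'
#' @param chain a [run_chain()] result produced with `store_params = TRUE`.
#' @param new_X integer matrix (m x J) of new covariate profiles.
#' @param new_W optional numeric matrix (m x L) of new fixed-effect values
#'   (zeros if omitted and the chain has fixed effects).
#' @return numeric vector of length m of predicted response probabilities.
#' @export
predict_response <- function(chain, new_X, new_W = NULL) {
  stopifnot(inherits(chain, "chain_output"))
  if (is.null(chain$params))
    stop("chain was run without store_params = TRUE; rerun with parameter storage enabled")
  if (!is.matrix(new_X)) new_X <- matrix(new_X, nrow = 1)
  m <- nrow(new_X)
  L <- length(chain$params[[1]]$beta)
  if (is.null(new_W)) new_W <- matrix(0, m, L)
  if (!is.matrix(new_W)) new_W <- matrix(new_W, nrow = m)
  preds <- matrix(0, length(chain$params), m)
  for (s in seq_along(chain$params)) {
    ps <- chain$params[[s]]
    C <- length(ps$psi)
    lw <- matrix(log(ps$psi), C, m)
    for (j in seq_len(ncol(new_X)))
      lw <- lw + log(ps$Phi[[j]])[, new_X[, j], drop = FALSE]
    lw <- sweep(lw, 2, apply(lw, 2, max))
    w <- exp(lw)
    w <- sweep(w, 2, colSums(w), "/")
    eta <- outer(ps$theta, as.vector(new_W %*% ps$beta), "+")
    preds[s, ] <- colSums(w * stats::plogis(eta))
  }
  colMeans(preds)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b allocation vectors of equal length.
#' @return adjusted Rand index (1 for identical partitions up to labels).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
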