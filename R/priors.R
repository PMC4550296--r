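#' Gamma hyperprior for the concentration parameter
#'
#' @param shape,rate positive Gamma parameters (rate parameterisation:
#'   mean = shape/rate).
#' @return A prior descriptor used in [prior_spec()].
#' @export
alpha_gamma <- function(shape = 9, rate = 0.5) {
  stopifnot(shape > 0, rate > 0)
  structure(list(type = "gamma", shape = shape, rate = rate), class = "alpha_prior")
}

#' Fixed concentration parameter
#'
#' @param value positive fixed value of the Dirichlet process concentration.
#' @return A prior descriptor used in [prior_spec()].
#' @export
alpha_fixed <- function(value = 1) {
  stopifnot(value > 0)
  structure(list(type = "fixed", value = value), class = "alpha_prior")
}

#' Prior specification for the profile regression mixture
#'
#' Hyperparameters of the FSBDPMM: per-covariate Dirichlet vectors for the
#' cluster category probabilities, Student-t priors (default t with 7 df,
#' location 0, scale 2.5) for the cluster logit intercepts and the global
#' fixed-effect coefficients, and either a Gamma hyperprior or a fixed value
#' for the concentration parameter.
#'
#' @param K integer vector of category counts per covariate (used to build
#'   default all-ones Dirichlet vectors); may be omitted when `a` is given.
#' @param a list of positive Dirichlet parameter vectors, one per covariate.
#' @param theta_prior,beta_prior length-3 numeric `c(df, location, scale)`.
#' @param alpha an [alpha_gamma()] or [alpha_fixed()] descriptor.
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec(K = c(2, 3))
#' @export
prior_spec <- function(K = NULL, a = NULL,
                       theta_prior = c(df = 7, location = 0, scale = 2.5),
                       beta_prior = c(df = 7, location = 0, scale = 2.5),
                       alpha = alpha_gamma(9, 0.5)) {
  if (is.null(a)) {
    if (is.null(K)) K <- integer(0)
    a <- lapply(as.integer(K), function(k) rep(1, k))
  }
  stopifnot(is.list(a))
  for (aj in a) {
    if (any(aj <= 0)) stop("Dirichlet parameters must be strictly positive")
  }
  if (length(theta_prior) != 3 || theta_prior[1] <= 0 || theta_prior[3] <= 0)
    stop("theta_prior must be c(df, location, scale) with df, scale > 0")
  if (length(beta_prior) != 3 || beta_prior[1] <= 0 || beta_prior[3] <= 0)
    stop("beta_prior must be c(df, location, scale) with df, scale > 0")
  stopifnot(inherits(alpha, "alpha_prior"))
  structure(
    list(a = a, theta_prior = unname(theta_prior), beta_prior = unname(beta_prior),
         alpha = alpha),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("prior_spec: %d covariate Dirichlet vector(s); theta ~ t_%g(%g, %g); beta ~ t_%g(%g, %g)\n",
              length(x$a), x$theta_prior[1], x$theta_prior[2], x$theta_prior[3],
              x$beta_prior[1], x$beta_prior[2], x$beta_prior[3]))
  if (x$alpha$type == "gamma") {
    cat(sprintf("alpha ~ Gamma(shape = %g, rate = %g)\n", x$alpha$shape, x$alpha$rate))
  } else {
    cat(sprintf("alpha fixed at %g\n", x$alpha$value))
  }
  invisible(x)
}

# log density of a location-scale Student-t, parameterised c(df, location, scale)
log_t_prior <- function(x, prior) {
  stats::dt((x - prior[2]) / prior[3], df = prior[1], log = TRUE) - log(prior[3])
}

# derivatives of the location-scale t log-density (used by the Laplace step);
# the t tails are not log-concave, so the second derivative may be positive
dlog_t_prior <- function(x, prior) {
  nu <- prior[1]; z <- (x - prior[2]) / prior[3]
  -(nu + 1) * z / ((nu + z^2) * prior[3])
}

d2log_t_prior <- function(x, prior) {
  nu <- prior[1]; z <- (x - prior[2]) / prior[3]
  -(nu + 1) * (nu - z^2) / ((nu + z^2)^2 * prior[3]^2)
}

# log Dirichlet density
log_ddirichlet <- function(p, a) {
  sum((a - 1) * log(p)) + lgamma(sum(a)) - sum(lgamma(a))
}

rdirichlet1 <- function(a) {
  g <- stats::rgamma(length(a), shape = a, rate = 1)
  g / sum(g)
}

# prior mean of alpha, used to initialise the chain
alpha_prior_mean <- function(alpha) {
  if (alpha$type == "fixed") alpha$value else alpha$shape / alpha$rate
}
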