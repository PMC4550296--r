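#' Subject-level profile data
#'
#' Bundles a matrix of discrete categorical covariates with an optional binary
#' response and optional real-valued fixed-effect covariates, the three data
#' blocks of a profile regression model.  Covariate categories are coded
#' `1..K_j` per column.
#'
#' @param X integer matrix (n x J) of categorical covariates, entries in
#'   `1..K[j]` for column `j`.  A data frame is coerced.
#' @param Y optional length-n binary (0/1) response vector.
#' @param W optional numeric matrix (n x L) of fixed-effect covariates.
#' @param K optional integer vector of category counts per covariate; defaults
#'   to the per-column maximum observed category.
#' @return An object of class `profile_data` with elements `X`, `Y`, `W`,
#'   `n`, `J`, `L`, `K`.
#' @examples
#' d <- profile_data(matrix(c(1, 2, 2, 1), 2, 2), Y = c(0, 1))
#' d$n
#' @export
profile_data <- function(X, Y = NULL, W = NULL, K = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(X)) X <- matrix(integer(0), nrow = if (!is.null(Y)) length(Y) else 0, ncol = 0)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  storage.mode(X) <- "integer"
  dimnames(X) <- NULL
  n <- nrow(X)
  J <- ncol(X)
  if (anyNA(X)) stop("missing values in X are not supported")
  if (J > 0 && any(X < 1L)) stop("covariate categories must be coded 1..K_j")
  if (is.null(K)) {
    if (n == 0 && J > 0) stop("K must be given when there are no subjects")
    K <- if (J > 0) apply(X, 2L, max) else integer(0)
  } else {
    K <- as.integer(K)
    if (length(K) != J) stop("length(K) must equal ncol(X)")
    if (J > 0 && n > 0 && any(apply(X, 2L, max) > K)) stop("observed category exceeds K_j")
  }
  if (!is.null(Y)) {
    Y <- as.integer(Y)
    if (anyNA(Y) || !all(Y %in% c(0L, 1L))) stop("Y must be binary 0/1 without missing values")
    if (length(Y) != n) stop("length(Y) must equal nrow(X)")
  }
  if (!is.null(W)) {
    if (is.data.frame(W)) W <- as.matrix(W)
    if (!is.matrix(W)) W <- matrix(W, ncol = 1L)
    storage.mode(W) <- "double"
    dimnames(W) <- NULL
    if (anyNA(W)) stop("missing values in W are not supported")
    if (nrow(W) != n) stop("nrow(W) must equal nrow(X)")
    if (is.null(Y)) stop("fixed effects W require a response Y")
  }
  structure(
    list(X = X, Y = Y, W = W, n = n, J = J,
         L = if (is.null(W)) 0L else ncol(W), K = as.integer(K)),
    class = "profile_data"
  )
}

#' @export
print.profile_data <- function(x, ...) {
  cat(sprintf("profile_data: %d subjects, %d categorical covariate(s)%s%s\n",
              x$n, x$J,
              if (!is.null(x$Y)) ", binary response" else "",
              if (x$L > 0) sprintf(", %d fixed effect(s)", x$L) else ""))
  if (x$J > 0) cat("categories per covariate:", paste(x$K, collapse = " "), "\n")
  invisible(x)
}

#' Read profile data from CSV
#'
#' Expects a header row with covariate columns `X1..XJ` (integer categories),
#' an optional `Y` column (0/1) and optional fixed-effect columns `W1..WL`.
#'
#' @param path file path.
#' @param K optional category counts, as in [profile_data()].
#' @return A [profile_data()] object.
#' @export
read_profile_csv <- function(path, K = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  xcols <- grep("^X[0-9]+$", nm, value = TRUE)
  wcols <- grep("^W[0-9]+$", nm, value = TRUE)
  xcols <- xcols[order(as.integer(sub("X", "", xcols)))]
  wcols <- wcols[order(as.integer(sub("W", "", wcols)))]
  if (length(xcols) == 0 && !"Y" %in% nm)
    stop("no X1..XJ covariate columns or Y column found in ", path)
  if (anyNA(df)) stop("missing values are not supported: ", path)
  profile_data(
    X = if (length(xcols)) as.matrix(df[xcols]) else NULL,
    Y = if ("Y" %in% nm) df$Y else NULL,
    W = if (length(wcols)) as.matrix(df[wcols]) else NULL,
    K = K
  )
}

#' Write profile data to CSV
#'
#' Inverse of [read_profile_csv()].
#'
#' @param data a [profile_data()] object.
#' @param path file path.
#' @export
write_profile_csv <- function(data, path) {
  stopifnot(inherits(data, "profile_data"))
  df <- as.data.frame(data$X)
  if (data$J > 0) names(df) <- paste0("X", seq_len(data$J))
  if (!is.null(data$Y)) df$Y <- data$Y
  if (data$L > 0) {
    wdf <- as.data.frame(data$W)
    names(wdf) <- paste0("W", seq_len(data$L))
    df <- cbind(df, wdf)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
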