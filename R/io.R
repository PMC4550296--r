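#' Write a chain to a directory
#'
#' Writes `alloc.csv` (one row per kept sweep, one column per subject),
#' `scalars.csv` (per-sweep concentration, cluster count, log marginal
#' partition posterior if recorded, log-likelihood and acceptance
#' indicators) and `meta.yaml` (configuration, seed, version, data
#' signature).  Stored per-sweep parameters are not written.
#'
#' @param chain a [run_chain()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_chain <- function(chain, dir) {
  stopifnot(inherits(chain, "chain_output"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(chain$Z, file.path(dir, "alloc.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  sc <- data.frame(
    sweep = seq_along(chain$alpha), alpha = chain$alpha, K_occ = chain$K_occ,
    logmpp = if (is.null(chain$logmpp)) NA_real_ else chain$logmpp,
    loglik = chain$loglik,
    accept_move1 = chain$accept[, 1], accept_move2 = chain$accept[, 2],
    accept_move3 = chain$accept[, 3],
    acc_theta = chain$acc_theta, acc_beta = chain$acc_beta
  )
  utils::write.csv(sc, file.path(dir, "scalars.csv"), row.names = FALSE)
  cfg <- chain$config
  meta <- list(
    seed = chain$seed, version = chain$version,
    data_signature = chain$data_signature,
    config = list(
      n_init_clusters = cfg$n_init_clusters, n_burn = cfg$n_burn,
      n_keep = cfg$n_keep, thin = cfg$thin,
      moves = as.list(cfg$moves), rw_scales = as.list(cfg$rw_scales),
      adapt_burnin_only = cfg$adapt_burnin_only,
      compute_mpp = cfg$compute_mpp, mpp_alpha = cfg$mpp_alpha
    )
  )
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(meta), file.path(dir, "meta.yaml"))
  } else {
    dput(meta, file.path(dir, "meta.yaml"))
  }
  invisible(dir)
}

#' Read a chain directory written by [write_chain()]
#'
#' @param dir chain directory.
#' @return A `chain_output` object (without stored per-sweep parameters).
#' @export
read_chain <- function(dir) {
  Z <- as.matrix(utils::read.table(file.path(dir, "alloc.csv"), sep = ","))
  dimnames(Z) <- NULL
  storage.mode(Z) <- "integer"
  sc <- utils::read.csv(file.path(dir, "scalars.csv"))
  meta_path <- file.path(dir, "meta.yaml")
  meta <- if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(meta_path)
  } else {
    dget(meta_path)
  }
  cfgl <- meta$config
  cfg <- sampler_config(
    n_init_clusters = cfgl$n_init_clusters, n_burn = cfgl$n_burn,
    n_keep = cfgl$n_keep, thin = cfgl$thin, seed = meta$seed,
    moves = unlist(cfgl$moves), rw_scales = unlist(cfgl$rw_scales),
    adapt_burnin_only = cfgl$adapt_burnin_only,
    compute_mpp = cfgl$compute_mpp, mpp_alpha = cfgl$mpp_alpha
  )
  structure(
    list(Z = Z, alpha = sc$alpha, K_occ = sc$K_occ,
         loglik = sc$loglik,
         logmpp = if (all(is.na(sc$logmpp))) NULL else sc$logmpp,
         accept = cbind(move1 = sc$accept_move1, move2 = sc$accept_move2,
                        move3 = sc$accept_move3),
         acc_theta = sc$acc_theta, acc_beta = sc$acc_beta,
         params = NULL, config = cfg, seed = meta$seed, priors = NULL,
         data_signature = meta$data_signature, version = meta$version),
    class = "chain_output"
  )
}
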