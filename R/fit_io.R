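#' Serialize a fitted model to a directory of TSVs plus a JSON manifest
#'
#' Writes \code{Z.tsv}, one \code{W_<view>.tsv} and \code{tau_<view>.tsv}
#' per view, \code{elbo_trace.tsv} and \code{manifest.json} (seed,
#' threshold, k_active, final ELBO, iteration count, convergence flag,
#' per-view ARD scales). All numbers are written at full precision, so a
#' read/write round trip preserves values exactly as printed doubles.
#' The in-memory variational state used by [elbo()] is not serialized.
#'
#' @param fit a \code{factor_fit}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "factor_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_num_table <- function(m, path, id_col) {
    df <- data.frame(rownames(m), stringsAsFactors = FALSE)
    colnames(df) <- id_col
    for (j in seq_len(ncol(m)))
      df[[colnames(m)[j]]] <- format(m[, j], digits = 17, trim = TRUE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  Z <- fit$Z
  if (is.null(rownames(Z))) rownames(Z) <- fit$profile_ids
  write_num_table(Z, file.path(dir, "Z.tsv"), "profile_id")
  for (m in fit$view_names) {
    write_num_table(fit$W[[m]], file.path(dir, paste0("W_", m, ".tsv")), "feature_id")
    tau <- matrix(fit$tau[[m]], ncol = 1, dimnames = list(names(fit$tau[[m]]), "tau"))
    write_num_table(tau, file.path(dir, paste0("tau_", m, ".tsv")), "feature_id")
  }
  tr <- matrix(fit$elbo_trace, ncol = 1,
               dimnames = list(seq_along(fit$elbo_trace), "elbo"))
  write_num_table(tr, file.path(dir, "elbo_trace.tsv"), "iteration")
  manifest <- list(seed = fit$seed, threshold = fit$threshold,
                   k_active = fit$k_active, elbo_final = fit$elbo_final,
                   n_iter = fit$n_iter, converged = fit$converged,
                   view_names = fit$view_names,
                   alpha = fit$alpha)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Reload a fitted model written by [write_fit()]
#'
#' @param dir directory containing the fit artifacts.
#' @return a \code{factor_fit} (without the internal variational state;
#'   scores, loadings, precisions, trace and provenance round-trip at full
#'   precision).
#' @export
read_fit <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  read_num_table <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[-1])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
  }
  Z <- read_num_table(file.path(dir, "Z.tsv"))
  vn <- manifest$view_names
  W <- list(); tau <- list()
  for (m in vn) {
    W[[m]] <- read_num_table(file.path(dir, paste0("W_", m, ".tsv")))
    tm <- read_num_table(file.path(dir, paste0("tau_", m, ".tsv")))
    tau[[m]] <- stats::setNames(tm[, 1], rownames(tm))
  }
  tr <- read_num_table(file.path(dir, "elbo_trace.tsv"))
  alpha <- manifest$alpha
  if (!is.null(alpha)) alpha <- lapply(alpha, as.numeric)
  structure(list(Z = Z, W = W, tau = tau, alpha = alpha,
                 elbo_trace = as.numeric(tr[, 1]),
                 elbo_segments = list(as.numeric(tr[, 1])),
                 elbo_final = manifest$elbo_final,
                 k_active = as.integer(manifest$k_active),
                 seed = as.integer(manifest$seed),
                 threshold = manifest$threshold,
                 n_iter = as.integer(manifest$n_iter),
                 converged = isTRUE(manifest$converged),
                 profile_ids = rownames(Z), view_names = vn, vb = NULL),
            class = "factor_fit")
}

#' Write a matched profile set
#'
#' One TSV per view over the shared profile index, the profile index
#' itself, and an observed-mask TSV.
#'
#' @param ps a [profile_set()].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_profile_set <- function(ps, dir) {
  stopifnot(inherits(ps, "profile_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(ps$profile_index, file.path(dir, "profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mask <- data.frame(profile_id = ps$profile_ids,
                     as.data.frame(lapply(ps$observed, as.integer)),
                     check.names = FALSE)
  utils::write.table(mask, file.path(dir, "observed.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in names(ps$views)) {
    df <- data.frame(feature_id = rownames(ps$views[[m]]),
                     stringsAsFactors = FALSE, check.names = FALSE)
    v <- ps$views[[m]]
    for (j in seq_len(ncol(v)))
      df[[ps$profile_ids[j]]] <- format(v[, j], digits = 17, trim = TRUE)
    utils::write.table(df, file.path(dir, paste0("view_", m, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Reload a profile set written by [write_profile_set()]
#' @param dir directory containing the artifacts.
#' @return a [profile_set()].
#' @export
read_profile_set <- function(dir) {
  idx <- utils::read.delim(file.path(dir, "profiles.tsv"),
                           stringsAsFactors = FALSE)
  mask <- utils::read.delim(file.path(dir, "observed.tsv"), check.names = FALSE,
                            stringsAsFactors = FALSE)
  vn <- setdiff(colnames(mask), "profile_id")
  views <- list(); observed <- list()
  for (m in vn) {
    df <- utils::read.delim(file.path(dir, paste0("view_", m, ".tsv")),
                            check.names = FALSE, stringsAsFactors = FALSE)
    v <- as.matrix(df[-1])
    storage.mode(v) <- "double"
    rownames(v) <- df[[1]]
    colnames(v) <- NULL
    observed[[m]] <- as.logical(mask[[m]])
    v[, !observed[[m]]] <- NA_real_
    views[[m]] <- v
  }
  profile_set(idx, views, observed)
}
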