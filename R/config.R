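#' Run configuration for the integration pipeline
#'
#' Bundles every tunable of the pipeline in one validated list, mirroring
#' the protocol: the low-expression filter (>= \code{filter_min_cpm} cpm in
#' at least \code{filter_min_frac} of samples), the per-view variance-based
#' gene cap (\code{top_k_genes}), the ensemble grid of factor-pruning
#' variance thresholds times random seeds, and the fitting/selection
#' controls.
#'
#' @param filter_min_cpm minimum counts-per-million for the expression
#'   filter (default 5).
#' @param filter_min_frac minimum fraction of samples clearing the cpm
#'   threshold (default 0.10, inclusive).
#' @param top_k_genes number of highest-variance genes kept per RNA view
#'   (default 2500).
#' @param thresholds variance-explained pruning thresholds for the fit
#'   ensemble; default 8 evenly spaced values on [0.02, 0.20].
#' @param seeds_per_threshold number of random restarts per threshold
#'   (default 100).
#' @param k_init initial number of factors for each fit.
#' @param tol relative ELBO change declaring convergence (default 1e-6,
#'   required on two consecutive checks).
#' @param max_iter iteration cap per fit (default 2000).
#' @param elbow_delta minimum gain in overall variance explained that
#'   justifies one more factor (default 0.01 absolute).
#' @param log2_cpm apply log2(cpm+1) after cpm normalization (default TRUE).
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(filter_min_cpm = 5, filter_min_frac = 0.10,
                       top_k_genes = 2500,
                       thresholds = seq(0.02, 0.20, length.out = 8),
                       seeds_per_threshold = 100,
                       k_init = 10, tol = 1e-6, max_iter = 2000,
                       elbow_delta = 0.01, log2_cpm = TRUE) {
  stopifnot(filter_min_cpm >= 0, filter_min_frac > 0, filter_min_frac <= 1,
            top_k_genes >= 1, k_init >= 1, tol > 0, max_iter >= 1,
            elbow_delta >= 0)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) == 0) stop("thresholds must be non-empty")
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  if (any(thresholds <= 0 | thresholds >= 1)) stop("thresholds must lie in (0, 1)")
  if (seeds_per_threshold < 1) stop("seeds_per_threshold must be >= 1")
  structure(list(filter_min_cpm = filter_min_cpm, filter_min_frac = filter_min_frac,
                 top_k_genes = as.integer(top_k_genes), thresholds = thresholds,
                 seeds_per_threshold = as.integer(seeds_per_threshold),
                 k_init = as.integer(k_init), tol = tol,
                 max_iter = as.integer(max_iter), elbow_delta = elbow_delta,
                 log2_cpm = isTRUE(log2_cpm)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected so typos never silently fall back to defaults.
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a validated \code{run_config}.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
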