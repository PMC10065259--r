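#' Fit an ensemble over the threshold-by-seed grid
#'
#' Runs the training protocol: for every pruning threshold in the
#' configuration, \code{seeds_per_threshold} fits from distinct random
#' seeds, giving \code{length(thresholds) * seeds_per_threshold} fits in
#' total. Seeds follow the schedule
#' \code{base_seed + i * 10000 + j} (threshold index i, replicate j), so
#' per-threshold streams never collide. Individual fit failures are
#' recorded in the ensemble table, never silently dropped.
#'
#' @param ps a [profile_set()] of centered, unit-variance views.
#' @param cfg a [run_config()]; uses \code{thresholds},
#'   \code{seeds_per_threshold}, \code{k_init}, \code{tol}, \code{max_iter}.
#' @param base_seed base of the seed schedule (default 0).
#' @param keep_fits keep every fitted model in memory (default TRUE; with
#'   FALSE only the best fit per factor count is retained).
#' @param verbose print one progress line per threshold.
#' @return object of class \code{fit_ensemble}: \code{records} (data.frame
#'   threshold, seed, k_active, elbo_final, converged, error) and
#'   \code{fits} (list parallel to records, NULL where dropped or failed).
#' @export
run_ensemble <- function(ps, cfg = run_config(), base_seed = 0,
                         keep_fits = TRUE, verbose = FALSE) {
  stopifnot(inherits(ps, "profile_set"), inherits(cfg, "run_config"))
  grid <- expand.grid(rep = seq_len(cfg$seeds_per_threshold),
                      ti = seq_along(cfg$thresholds))
  n <- nrow(grid)
  records <- data.frame(threshold = cfg$thresholds[grid$ti],
                        seed = as.integer(base_seed + grid$ti * 1e4 + grid$rep),
                        k_active = NA_integer_, elbo_final = NA_real_,
                        converged = NA, error = NA_character_,
                        stringsAsFactors = FALSE)
  fits <- vector("list", n)
  for (r in seq_len(n)) {
    fit <- tryCatch(
      fit_gfa(ps, k_init = cfg$k_init, threshold = records$threshold[r],
              seed = records$seed[r], tol = cfg$tol, max_iter = cfg$max_iter),
      error = function(e) e)
    if (inherits(fit, "error")) {
      records$error[r] <- conditionMessage(fit)
    } else {
      records$k_active[r] <- fit$k_active
      records$elbo_final[r] <- fit$elbo_final
      records$converged[r] <- fit$converged
      if (keep_fits) fits[[r]] <- fit
    }
    if (verbose && r %% cfg$seeds_per_threshold == 0)
      message(sprintf("threshold %.3f done (%d/%d fits)",
                      records$threshold[r], r, n))
  }
  if (!keep_fits) {
    # retain only the ELBO winner within each factor count
    for (k in unique(stats::na.omit(records$k_active))) {
      rows <- which(records$k_active == k)
      win <- rows[order(-records$elbo_final[rows], records$seed[rows])][1]
      if (is.null(fits[[win]]))
        fits[[win]] <- fit_gfa(ps, k_init = cfg$k_init,
                               threshold = records$threshold[win],
                               seed = records$seed[win], tol = cfg$tol,
                               max_iter = cfg$max_iter)
    }
  }
  structure(list(records = records, fits = fits,
                 grid = list(thresholds = cfg$thresholds,
                             seeds_per_threshold = cfg$seeds_per_threshold,
                             base_seed = base_seed)),
            class = "fit_ensemble")
}

#' @export
print.fit_ensemble <- function(x, ...) {
  ok <- is.na(x$records$error)
  cat(sprintf("fit_ensemble: %d fits (%d ok, %d failed), k_active in [%s]\n",
              nrow(x$records), sum(ok), sum(!ok),
              paste(range(x$records$k_active, na.rm = TRUE), collapse = ", ")))
  invisible(x)
}

#' Best fit per factor count by ELBO
#'
#' Groups the ensemble's successful fits by their converged number of
#' factors and keeps, within each group, the fit with the highest final
#' ELBO (ties broken by smallest seed).
#'
#' @param ens a [run_ensemble()] result (with fits kept).
#' @return named list mapping each factor count (as character) to its
#'   winning \code{factor_fit}; names sorted by increasing K.
#' @export
select_best_per_k <- function(ens) {
  stopifnot(inherits(ens, "fit_ensemble"))
  ok <- which(is.na(ens$records$error) & !is.na(ens$records$k_active))
  if (!length(ok)) stop("ensemble contains no successful fits")
  rec <- ens$records[ok, ]
  out <- list()
  for (k in sort(unique(rec$k_active))) {
    rows <- ok[rec$k_active == k]
    win <- rows[order(-ens$records$elbo_final[rows], ens$records$seed[rows])][1]
    if (is.null(ens$fits[[win]]))
      stop("winning fit for K=", k, " was not kept; rerun with keep_fits=TRUE")
    out[[as.character(k)]] <- ens$fits[[win]]
  }
  out
}

#' Variance-explained curve over candidate factor counts
#'
#' For each best-per-K fit, computes total and per-view variance explained,
#' producing the long-format table used for elbow-based model selection.
#'
#' @param best named list K -> fit, from [select_best_per_k()].
#' @param ps the [profile_set()] the fits were computed on.
#' @return data.frame of class \code{selection_curve} with columns
#'   \code{k}, \code{view} (\code{"overall"} or a view name), \code{r2},
#'   \code{elbo}; the best fits ride along as attribute \code{fits}.
#' @export
selection_curve <- function(best, ps) {
  stopifnot(length(best) >= 1)
  ks <- as.integer(names(best))
  rows <- list()
  for (i in seq_along(best)) {
    ve <- variance_explained(best[[i]], ps)
    rows[[i]] <- data.frame(
      k = ks[i],
      view = c("overall", names(ve$per_view_total)),
      r2 = c(ve$overall_total, unname(ve$per_view_total)),
      elbo = best[[i]]$elbo_final, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$k), ]
  rownames(out) <- NULL
  class(out) <- c("selection_curve", "data.frame")
  attr(out, "fits") <- best
  out
}

#' Choose the number of factors from the curve
#'
#' Default elbow rule: the smallest K whose gain in overall variance
#' explained to the next candidate is below \code{elbow_delta} (absolute).
#' If every gain is large, the largest candidate is chosen with a warning.
#' An explicit \code{k_override} reproduces a visual-inspection choice and
#' always wins.
#'
#' @param curve a [selection_curve()].
#' @param elbow_delta absolute overall-R2 gain below which adding a factor
#'   stops being worth it (default 0.01).
#' @param k_override optional integer; must be one of the curve's K values.
#' @return list with \code{k}, \code{fit}, \code{rationale} (character).
#' @export
select_model <- function(curve, elbow_delta = 0.01, k_override = NULL) {
  stopifnot(inherits(curve, "selection_curve"))
  fits <- attr(curve, "fits")
  ov <- curve[curve$view == "overall", ]
  ov <- ov[order(ov$k), ]
  if (!is.null(k_override)) {
    if (!k_override %in% ov$k)
      stop("k_override = ", k_override, " is not among the candidate K: ",
           paste(ov$k, collapse = ", "))
    return(list(k = as.integer(k_override), fit = fits[[as.character(k_override)]],
                rationale = sprintf("k_override = %d supplied", k_override)))
  }
  if (nrow(ov) == 1) {
    return(list(k = ov$k[1], fit = fits[[as.character(ov$k[1])]],
                rationale = "single candidate K"))
  }
  gains <- diff(ov$r2)
  small <- which(gains < elbow_delta)
  if (length(small)) {
    k <- ov$k[small[1]]
    rationale <- sprintf(
      "gain from K=%d to K=%d is %.4f < elbow_delta = %.4f",
      k, ov$k[small[1] + 1], gains[small[1]], elbow_delta)
  } else {
    k <- ov$k[nrow(ov)]
    rationale <- sprintf(
      "every gain exceeds elbow_delta = %.4f; largest candidate K=%d chosen",
      elbow_delta, k)
    warning(rationale)
  }
  list(k = as.integer(k), fit = fits[[as.character(k)]], rationale = rationale)
}
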