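#' Filter lowly expressed genes
#'
#' Retains a feature iff its counts-per-million (computed on raw library
#' sizes, before any scale factors) reach \code{min_cpm} in at least
#' \code{min_frac} of the samples. Both bounds are inclusive, so with 10
#' samples and \code{min_frac = 0.10} a single qualifying sample suffices.
#' Feature order is preserved.
#'
#' @param view an [omic_view()] with modality \code{"counts"}.
#' @param min_cpm minimum counts-per-million (default 5).
#' @param min_frac minimum fraction of samples clearing it (default 0.10).
#' @return the filtered [omic_view()].
#' @export
filter_low_expression <- function(view, min_cpm = 5, min_frac = 0.10) {
  stopifnot(inherits(view, "omic_view"))
  if (view$modality != "counts") stop("filter_low_expression expects a counts view")
  if (min_cpm < 0) stop("min_cpm must be non-negative")
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must lie in (0, 1]")
  lib <- colSums(view$values)
  if (any(lib == 0)) stop("sample(s) with zero library size: ",
                          paste(view$sample_ids[lib == 0], collapse = ", "))
  cpm <- sweep(view$values, 2, lib, "/") * 1e6
  keep <- rowMeans(cpm >= min_cpm) >= min_frac
  if (!any(keep)) warning("all features removed by the expression filter in view '",
                          view$view_name, "'")
  omic_view(view$values[keep, , drop = FALSE], view_name = view$view_name,
            modality = "counts", feature_ids = view$feature_ids[keep],
            sample_ids = view$sample_ids)
}

#' Trimmed mean of M-values scale factors
#'
#' Between-sample normalization factors for count data, robust to
#' composition bias. The reference sample is the one whose upper-quartile
#' cpm is closest to the mean upper-quartile. For every sample, M-values
#' (log2 ratios to the reference) and A-values (average log2 abundance) are
#' formed over features non-zero in both samples, the \code{trim_m} most
#' extreme M-values and \code{trim_a} most extreme A-values are trimmed from
#' each tail (the published convention),
#' and the factor is 2^(precision-weighted mean of the surviving M-values),
#' with weights the inverse asymptotic binomial variances. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param view counts [omic_view()] with >= 2 samples.
#' @param trim_m total fraction of M-values trimmed (default 0.30).
#' @param trim_a total fraction of A-values trimmed (default 0.05).
#' @return named numeric vector of per-sample scale factors.
#' @export
tmm_factors <- function(view, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(view, "omic_view"))
  if (view$modality != "counts") stop("tmm_factors expects a counts view")
  x <- view$values
  if (ncol(x) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(x)
  allzero <- lib == 0 | apply(x, 2, function(v) all(v == 0))
  if (any(allzero)) stop("sample(s) with all-zero counts: ",
                         paste(view$sample_ids[allzero], collapse = ", "))
  uq <- apply(sweep(x, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref_i <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(x)), function(i)
    tmm_pair(x[, i], x[, ref_i], lib[i], lib[ref_i], trim_m, trim_a),
    numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- view$sample_ids
  f
}

# one sample against the reference: weighted trimmed mean of M-values
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep0 <- obs > 0 & ref > 0
  obs <- obs[keep0]; ref <- ref[keep0]
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  keep <- rank(logR) >= loM & rank(logR) <= hiM &
    rank(absE) >= loA & rank(absE) <= hiA
  f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Normalized counts per million
#'
#' \code{cpm_fs = count_fs / (library_size_s * factor_s) * 1e6}, optionally
#' followed by log2(cpm + 1). The result carries modality
#' \code{"normalized"}.
#'
#' @param view counts [omic_view()].
#' @param factors per-sample scale factors (e.g. from [tmm_factors()]);
#'   default all 1.
#' @param log2 apply log2(cpm + 1) (default TRUE).
#' @return normalized [omic_view()].
#' @export
normalize_cpm <- function(view, factors = rep(1, ncol(view$values)), log2 = TRUE) {
  stopifnot(inherits(view, "omic_view"))
  if (view$modality != "counts") stop("normalize_cpm expects a counts view")
  if (length(factors) != ncol(view$values))
    stop("got ", length(factors), " factors for ", ncol(view$values), " samples")
  if (any(factors <= 0)) stop("scale factors must be positive")
  eff <- colSums(view$values) * factors
  cpm <- sweep(view$values, 2, eff, "/") * 1e6
  if (log2) cpm <- log2(cpm + 1)
  omic_view(cpm, view_name = view$view_name, modality = "normalized",
            feature_ids = view$feature_ids, sample_ids = view$sample_ids)
}

#' Probabilistic quotient normalization
#'
#' Removes per-sample dilution from abundance data: the reference spectrum
#' is the feature-wise median across samples; each sample's dilution factor
#' is the median of its quotients to the reference (over features with
#' positive reference); the sample is divided by that factor.
#'
#' @param view abundance [omic_view()] with >= 2 samples, non-negative
#'   values.
#' @param reference \code{"median"} (default) or \code{"mean"} spectrum.
#' @return list with \code{view} (normalized [omic_view()]) and
#'   \code{dilution} (the per-sample factors that were divided out).
#' @export
pqn_normalize <- function(view, reference = c("median", "mean")) {
  stopifnot(inherits(view, "omic_view"))
  reference <- match.arg(reference)
  x <- view$values
  if (ncol(x) < 2) stop("PQN needs at least 2 samples")
  if (any(x < 0)) stop("PQN expects non-negative abundances")
  ref <- if (reference == "median") apply(x, 1, stats::median) else rowMeans(x)
  ok <- ref > 0
  if (!any(ok)) stop("reference spectrum is all zero")
  q <- sweep(x[ok, , drop = FALSE], 1, ref[ok], "/")
  dil <- apply(q, 2, function(col) {
    col <- col[is.finite(col)]
    if (!length(col)) NA_real_ else stats::median(col)
  })
  bad <- !is.finite(dil) | dil <= 0
  if (any(bad)) stop("sample(s) with no usable quotients: ",
                     paste(view$sample_ids[bad], collapse = ", "))
  out <- sweep(x, 2, dil, "/")
  names(dil) <- view$sample_ids
  list(view = omic_view(out, view_name = view$view_name, modality = "normalized",
                        feature_ids = view$feature_ids, sample_ids = view$sample_ids),
       dilution = dil)
}

#' Keep the k highest-variance features
#'
#' Ranks features by sample variance (descending), breaking ties by feature
#' ID, and keeps the top \code{k}; retained features stay in their original
#' row order. With \code{k >= n_features} this is the identity.
#'
#' @param view an [omic_view()].
#' @param k number of features to keep (> 0).
#' @return reduced [omic_view()].
#' @export
select_top_variance <- function(view, k) {
  stopifnot(inherits(view, "omic_view"))
  if (k <= 0) stop("k must be positive")
  n <- nrow(view$values)
  if (k >= n) return(view)
  v <- apply(view$values, 1, stats::var)
  ord <- order(-v, xtfrm(view$feature_ids))
  keep <- sort(ord[seq_len(k)])
  omic_view(view$values[keep, , drop = FALSE], view_name = view$view_name,
            modality = view$modality, feature_ids = view$feature_ids[keep],
            sample_ids = view$sample_ids)
}

#' Center and scale features to unit variance
#'
#' Each feature is centered to mean 0 and scaled to variance 1 over its
#' observed (non-NA) samples — the scale harmonization applied before
#' multi-view factor fitting. Zero-variance features carry no usable signal
#' and are dropped with a warning.
#'
#' @param view an [omic_view()].
#' @return scaled [omic_view()] with modality \code{"normalized"}.
#' @export
unit_variance_scale <- function(view) {
  stopifnot(inherits(view, "omic_view"))
  x <- view$values
  mu <- rowMeans(x, na.rm = TRUE)
  sdv <- apply(x, 1, stats::sd, na.rm = TRUE)
  drop <- !is.finite(sdv) | sdv == 0
  if (any(drop))
    warning(sum(drop), " zero-variance feature(s) dropped from view '",
            view$view_name, "'")
  x <- (x - mu) / sdv
  x <- x[!drop, , drop = FALSE]
  omic_view(x, view_name = view$view_name, modality = "normalized",
            feature_ids = view$feature_ids[!drop], sample_ids = view$sample_ids)
}

#' Preprocess one RNA-seq counts view
#'
#' The full RNA track: expression filter, TMM factors, normalized cpm
#' (optionally log2), top-variance gene cap. Returns the processed view
#' together with a normalization report.
#'
#' @param view counts [omic_view()].
#' @param cfg a [run_config()].
#' @return list with \code{view} and \code{report} (view_name,
#'   scale_factors, n_features_in/out, transform_log).
#' @export
preprocess_rna <- function(view, cfg = run_config()) {
  n_in <- nrow(view$values)
  filt <- filter_low_expression(view, cfg$filter_min_cpm, cfg$filter_min_frac)
  f <- tmm_factors(filt)
  norm <- normalize_cpm(filt, f, log2 = cfg$log2_cpm)
  red <- select_top_variance(norm, cfg$top_k_genes)
  steps <- c(sprintf("filter_low_expression(min_cpm=%g, min_frac=%g)",
                     cfg$filter_min_cpm, cfg$filter_min_frac),
             "tmm_factors", if (cfg$log2_cpm) "log2_cpm" else "cpm",
             sprintf("select_top_variance(k=%d)", cfg$top_k_genes))
  list(view = red,
       report = list(view_name = view$view_name, scale_factors = f,
                     n_features_in = n_in, n_features_out = nrow(red$values),
                     transform_log = steps))
}

#' Preprocess one LC-MS abundance view
#'
#' PQN dilution correction followed by log transform (log2(x + 1) on the
#' dilution-corrected abundances).
#'
#' @param view abundance [omic_view()].
#' @param log2 apply log2(x + 1) after PQN (default TRUE).
#' @return list with \code{view} and \code{report}.
#' @export
preprocess_abundance <- function(view, log2 = TRUE) {
  n_in <- nrow(view$values)
  pq <- pqn_normalize(view)
  out <- pq$view
  if (log2) {
    vals <- log2(out$values + 1)
    out <- omic_view(vals, view_name = out$view_name, modality = "normalized",
                     feature_ids = out$feature_ids, sample_ids = out$sample_ids)
  }
  list(view = out,
       report = list(view_name = view$view_name, scale_factors = pq$dilution,
                     n_features_in = n_in, n_features_out = nrow(out$values),
                     transform_log = c("pqn_normalize", if (log2) "log2_plus1")))
}

#' Preprocess every view of a study
#'
#' Dispatches each view to its modality's track: counts views through
#' [preprocess_rna()] (filter, TMM, cpm, variance cap), abundance views
#' through [preprocess_abundance()] (PQN, log). Views already normalized
#' pass through untouched.
#'
#' @param views named list of [omic_view()]s.
#' @param cfg a [run_config()].
#' @return list with \code{views} (processed) and \code{reports}.
#' @export
preprocess_views <- function(views, cfg = run_config()) {
  out <- list(); reports <- list()
  for (vn in names(views)) {
    v <- views[[vn]]
    res <- switch(v$modality,
                  counts = preprocess_rna(v, cfg),
                  abundance = preprocess_abundance(v),
                  normalized = list(view = v, report = NULL))
    out[[vn]] <- res$view
    reports[[vn]] <- res$report
  }
  list(views = out, reports = reports)
}
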