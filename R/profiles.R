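#' Construct a profile set
#'
#' A profile set is the matched multi-view dataset the factor model
#' consumes: an ordered index of multiomic profiles — one per
#' (mouse, group, week) key — and, per view, a feature-by-profile matrix
#' plus a logical observation mask. Columns of unobserved profiles hold NA.
#'
#' @param profile_index data.frame with columns \code{mouse_id},
#'   \code{group}, \code{week}, one row per profile.
#' @param views named list of feature-by-profile matrices (ncol = number of
#'   profiles).
#' @param observed named list of logical vectors over profiles, same names
#'   as \code{views}.
#' @return object of class \code{profile_set}.
#' @export
profile_set <- function(profile_index, views, observed) {
  n <- nrow(profile_index)
  stopifnot(is.list(views), length(views) >= 1,
            identical(sort(names(views)), sort(names(observed))))
  for (vn in names(views)) {
    if (ncol(views[[vn]]) != n)
      stop("view '", vn, "' has ", ncol(views[[vn]]), " columns for ", n, " profiles")
    if (length(observed[[vn]]) != n)
      stop("observed mask of view '", vn, "' has wrong length")
    if (any(!observed[[vn]] & colSums(!is.na(views[[vn]])) > 0))
      stop("view '", vn, "' has data in profiles marked unobserved")
  }
  obs_any <- Reduce(`|`, observed)
  if (any(!obs_any))
    stop("profile(s) observed in no view: ",
         paste(which(!obs_any), collapse = ", "))
  pid <- paste0(profile_index$mouse_id, "_wk", sprintf("%02d", profile_index$week))
  structure(list(profile_index = profile_index, profile_ids = pid,
                 views = views, observed = observed),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("profile_set: %d profiles, %d views\n",
              nrow(x$profile_index), length(x$views)))
  for (vn in names(x$views))
    cat(sprintf("  %-12s %5d features, %3d/%d profiles observed\n", vn,
                nrow(x$views[[vn]]), sum(x$observed[[vn]]), nrow(x$profile_index)))
  invisible(x)
}

#' Average samples sharing a multiomic-profile key
#'
#' When two or more samples of one view share the same (mouse, group, week)
#' key — e.g. duplicate muscle preparations from one sacrifice — their
#' normalized values are replaced by the per-feature arithmetic mean.
#' Averaging raw counts would mix library sizes, so counts modality is
#' refused.
#'
#' @param view a normalized [omic_view()].
#' @param meta metadata covering every sample of the view.
#' @return the view with one sample per key (sample IDs of merged groups
#'   are joined with "+").
#' @export
average_duplicates <- function(view, meta) {
  stopifnot(inherits(view, "omic_view"))
  if (view$modality == "counts")
    stop("refusing to average counts; normalize first")
  keys <- view_keys_merged(view, meta)
  kk <- paste(keys$mouse_id, keys$group, keys$week, sep = "|")
  if (!anyDuplicated(kk)) return(view)
  grp <- split(seq_along(kk), factor(kk, levels = unique(kk)))
  vals <- vapply(grp, function(ix) rowMeans(view$values[, ix, drop = FALSE]),
                 numeric(nrow(view$values)))
  vals <- matrix(vals, nrow = nrow(view$values))
  sid <- vapply(grp, function(ix) paste(view$sample_ids[ix], collapse = "+"), "")
  omic_view(vals, view_name = view$view_name, modality = view$modality,
            feature_ids = view$feature_ids, sample_ids = sid)
}

#' Match views into multiomic profiles
#'
#' Builds the profile set over the union of (mouse, group, week) keys seen
#' in any view: each view's samples are assigned to profiles by key, and a
#' profile with no sample in a view is marked unobserved there. Normalized
#' views with several samples on one key are averaged (see
#' [average_duplicates()]); duplicate keys in a counts view are an error.
#' Profiles are ordered by mouse, then week.
#'
#' @param views list of [omic_view()]s.
#' @param meta metadata table covering every sample in every view; a
#'   sample_id carrying two different keys is an error (enforced by
#'   metadata uniqueness).
#' @return a [profile_set()].
#' @export
match_profiles <- function(views, meta) {
  if (length(views) == 0) stop("empty view list")
  meta <- validate_metadata(meta)
  keyed <- lapply(views, function(v) {
    k <- view_keys_merged(v, meta)
    if (anyDuplicated(paste(k$mouse_id, k$week))) {
      if (v$modality == "counts")
        stop("duplicate profile keys in counts view '", v$view_name,
             "'; normalize and average first")
      v <- average_duplicates(v, meta)
    }
    list(view = v, keys = view_keys_merged(v, meta))
  })
  all_keys <- unique(do.call(rbind, lapply(keyed, function(x)
    x$keys[c("mouse_id", "group", "week")])))
  conflict <- all_keys[duplicated(paste(all_keys$mouse_id, all_keys$week)), ]
  if (nrow(conflict))
    stop("conflicting group labels for mouse/week key(s): ",
         paste(utils::head(paste(conflict$mouse_id, conflict$week), 5), collapse = ", "))
  all_keys <- all_keys[order(all_keys$mouse_id, all_keys$week), ]
  rownames(all_keys) <- NULL
  n <- nrow(all_keys)
  ak <- paste(all_keys$mouse_id, all_keys$week, sep = "|")
  vmats <- list(); obs <- list()
  for (x in keyed) {
    v <- x$view
    pos <- match(paste(x$keys$mouse_id, x$keys$week, sep = "|"), ak)
    m <- matrix(NA_real_, nrow(v$values), n,
                dimnames = list(v$feature_ids, NULL))
    m[, pos] <- v$values
    o <- logical(n); o[pos] <- TRUE
    vmats[[v$view_name]] <- m
    obs[[v$view_name]] <- o
  }
  profile_set(all_keys, vmats, obs)
}

# keys for a view whose duplicate samples may have been merged ("a+b" IDs)
view_keys_merged <- function(view, meta) {
  first_id <- vapply(strsplit(view$sample_ids, "+", fixed = TRUE), `[`, "", 1)
  idx <- match(first_id, meta$sample_id)
  if (anyNA(idx)) stop("sample(s) missing from metadata: ",
                       paste(first_id[is.na(idx)], collapse = ", "))
  data.frame(sample_id = view$sample_ids, mouse_id = meta$mouse_id[idx],
             group = as.character(meta$group[idx]), week = meta$week[idx],
             stringsAsFactors = FALSE)
}

#' Per-view observation counts
#'
#' @param ps a [profile_set()].
#' @return data.frame with one row per view (observed profile count and
#'   feature count) plus attribute-free totals in the final row
#'   (\code{view == "total"}): the summed omic data points across views.
#' @export
missingness_report <- function(ps) {
  stopifnot(inherits(ps, "profile_set"))
  n_obs <- vapply(ps$observed, sum, integer(1))
  d <- vapply(ps$views, nrow, integer(1))
  out <- data.frame(view = names(ps$views), n_features = as.integer(d),
                    n_observed = as.integer(n_obs), stringsAsFactors = FALSE)
  rbind(out, data.frame(view = "total", n_features = sum(d),
                        n_observed = sum(n_obs)))
}

#' Center and scale every view of a profile set
#'
#' Applies [unit_variance_scale()] to each view over its observed profiles
#' (unobserved columns stay NA), the harmonization step required before
#' factor fitting.
#'
#' @param ps a [profile_set()].
#' @return a [profile_set()] with centered, unit-variance features.
#' @export
scale_profile_set <- function(ps) {
  stopifnot(inherits(ps, "profile_set"))
  views <- list()
  for (m in names(ps$views)) {
    obs <- ps$observed[[m]]
    v <- omic_view(ps$views[[m]][, obs, drop = FALSE], view_name = m,
                   modality = "normalized",
                   sample_ids = ps$profile_ids[obs])
    sc <- unit_variance_scale(v)
    x <- matrix(NA_real_, nrow(sc$values), length(ps$profile_ids),
                dimnames = list(sc$feature_ids, NULL))
    x[, obs] <- sc$values
    views[[m]] <- x
  }
  profile_set(ps$profile_index, views, ps$observed)
}
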