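#' Study design for a longitudinal four-view mouse experiment
#'
#' Encodes the sampling scheme the pipeline targets: four genotype groups
#' followed with blood draws every six weeks from week 6 to week 30, muscle
#' assayed only at sacrifice, and — because one blood draw cannot feed both
#' assays — each (mouse, week) pair assigned to either blood RNA-seq or the
#' plasma (lipid + metabolite) assays.
#'
#' @param n_mice_per_group mice per genotype group (default 10, i.e. 40
#'   mice overall).
#' @param groups genotype labels; default the four-level set.
#' @param weeks sampling weeks (default 6,12,18,24,30).
#' @param muscle_week the single week at which muscle is assayed
#'   (default 30); must be one of \code{weeks}.
#' @param blood_rna_fraction fraction of (mouse, week) pairs assayed by
#'   blood RNA-seq rather than plasma LC-MS (default 0.5).
#' @return a list of class \code{study_design}.
#' @export
study_design <- function(n_mice_per_group = 10, groups = GROUP_LEVELS,
                         weeks = c(6L, 12L, 18L, 24L, 30L),
                         muscle_week = 30L, blood_rna_fraction = 0.5) {
  stopifnot(n_mice_per_group >= 1, length(groups) >= 1,
            blood_rna_fraction >= 0, blood_rna_fraction <= 1)
  weeks <- sort(as.integer(weeks))
  if (!muscle_week %in% weeks) stop("muscle_week must be one of weeks")
  structure(list(n_mice_per_group = as.integer(n_mice_per_group),
                 groups = as.character(groups), weeks = weeks,
                 muscle_week = as.integer(muscle_week),
                 blood_rna_fraction = blood_rna_fraction),
            class = "study_design")
}

#' Latent-factor effect presets
#'
#' Each preset defines how one true latent factor's mean score depends on
#' genotype group and week, emulating the factor phenotypes the analysis is
#' designed to detect:
#' \describe{
#'   \item{\code{"disease"}}{an offset separating dystrophic groups from WT
#'     plus an extra offset at week 6 (a dystrophic-signature factor that is
#'     also time-structured).}
#'   \item{\code{"growth"}}{a linear trend in week, identical in all groups
#'     (a physiological-growth factor).}
#'   \item{\code{"early_disease"}}{a week-6 offset present only in the
#'     dystrophic groups (an early-damage factor).}
#'   \item{\code{"noise"}}{no group or week structure at all.}
#' }
#'
#' @param preset one of \code{"disease"}, \code{"growth"},
#'   \code{"early_disease"}, \code{"noise"}.
#' @param group_offset mean shift of the three dystrophic groups relative
#'   to WT (presets \code{"disease"}).
#' @param week6_offset additional mean shift at week 6 (\code{"disease"}:
#'   all groups; \code{"early_disease"}: dystrophic groups only).
#' @param slope_per_week linear week trend (\code{"growth"}).
#' @param residual_sd standard deviation of the score around its mean.
#' @return a list of class \code{factor_effect} with a \code{mean_fn(group,
#'   week)} and \code{residual_sd}.
#' @export
factor_preset <- function(preset = c("disease", "growth", "early_disease", "noise"),
                          group_offset = 2, week6_offset = 2,
                          slope_per_week = 1 / 6, residual_sd = 1) {
  if (!is.character(preset) || !preset[1] %in% c("disease", "growth", "early_disease", "noise"))
    stop("unknown factor preset: ", preset[1])
  preset <- preset[1]
  mean_fn <- switch(preset,
    disease = function(group, week)
      group_offset * (group != "WT") + week6_offset * (week == 6),
    growth = function(group, week) slope_per_week * (week - 18),
    early_disease = function(group, week)
      week6_offset * (group != "WT") * (week == 6),
    noise = function(group, week) rep(0, length(group)))
  structure(list(preset = preset, mean_fn = mean_fn, residual_sd = residual_sd),
            class = "factor_effect")
}

#' Truth model for study simulation
#'
#' The generative counterpart of the decomposition the pipeline estimates:
#' a small number of true factors with group/week-structured scores drive
#' all four views through view-specific sparse loadings; RNA views add
#' negative-binomial counting noise, plasma views add log-normal measurement
#' noise and a per-sample dilution multiplier (the artefact probabilistic
#' quotient normalization exists to remove).
#'
#' @param factors list of [factor_preset()] effects, one per true factor.
#' @param n_features named vector of feature counts for views
#'   \code{muscle_rna}, \code{blood_rna}, \code{lipids}, \code{metabolites}.
#' @param loading_sd standard deviation of non-zero true loadings.
#' @param loading_sparsity fraction of loadings set to zero per (view,
#'   factor).
#' @param view_activity optional list, one character vector per factor,
#'   naming the views that factor drives (its loadings are zeroed
#'   elsewhere). Factors in real multi-omic studies differ in which views
#'   they act on — some shared, some view-specific — and this differential
#'   activity is also what renders them identifiable up to sign rather
#'   than up to rotation. \code{NULL} makes every factor active everywhere.
#' @param noise_sd per-view log-scale measurement noise SD for the plasma
#'   views.
#' @param nb_dispersion negative-binomial dispersion of the RNA views
#'   (0 = Poisson).
#' @param dilution_sd log-scale SD of per-sample dilution multipliers in
#'   plasma views.
#' @param lib_size mean library size of simulated RNA samples.
#' @return a list of class \code{truth_model}.
#' @export
truth_model <- function(factors = list(factor_preset("disease", residual_sd = 0.6),
                                       factor_preset("growth", residual_sd = 1.5),
                                       factor_preset("early_disease", residual_sd = 0.8)),
                        n_features = c(muscle_rna = 400, blood_rna = 400,
                                       lipids = 120, metabolites = 60),
                        loading_sd = 1, loading_sparsity = 0.5,
                        view_activity = list(
                          c("muscle_rna", "blood_rna", "lipids", "metabolites"),
                          c("blood_rna", "lipids", "metabolites"),
                          c("muscle_rna", "blood_rna")),
                        noise_sd = 0.3, nb_dispersion = 0.05,
                        dilution_sd = 0.4, lib_size = 1e6) {
  stopifnot(length(factors) >= 1, noise_sd > 0 || noise_sd == 0,
            dilution_sd >= 0, nb_dispersion >= 0)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  lapply(factors, function(f) if (!inherits(f, "factor_effect"))
    stop("each factor must be a factor_effect"))
  if (!is.null(view_activity)) {
    if (length(view_activity) != length(factors))
      stop("view_activity must have one entry per factor (or be NULL)")
    if (!all(unlist(view_activity) %in% names(n_features)))
      stop("view_activity names unknown views")
  }
  structure(list(factors = factors, n_factors_true = length(factors),
                 n_features = n_features, loading_sd = loading_sd,
                 loading_sparsity = loading_sparsity,
                 view_activity = view_activity, noise_sd = noise_sd,
                 nb_dispersion = nb_dispersion, dilution_sd = dilution_sd,
                 lib_size = lib_size),
            class = "truth_model")
}

profile_grid <- function(design) {
  mice <- sprintf("m%02d", seq_len(design$n_mice_per_group * length(design$groups)))
  grp <- rep(design$groups, each = design$n_mice_per_group)
  out <- expand.grid(mouse_id = mice, week = design$weeks,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$group <- grp[match(out$mouse_id, mice)]
  out <- out[order(out$mouse_id, out$week), c("mouse_id", "group", "week")]
  rownames(out) <- NULL
  out
}

#' Simulate true latent-factor scores
#'
#' Draws one score vector per (mouse, week) pair: the preset mean structure
#' evaluated at the pair's group and week plus Normal(0, residual SD) noise.
#'
#' @param design a [study_design()].
#' @param truth a [truth_model()].
#' @param seed integer seed.
#' @return a list with \code{index} (data.frame mouse_id, group, week) and
#'   \code{Z} (profiles-by-factors score matrix).
#' @export
simulate_factor_scores <- function(design, truth, seed = 1) {
  grid <- profile_grid(design)
  set.seed(seed)
  Z <- vapply(truth$factors, function(f) {
    f$mean_fn(grid$group, grid$week) +
      stats::rnorm(nrow(grid), 0, f$residual_sd)
  }, numeric(nrow(grid)))
  Z <- matrix(Z, nrow = nrow(grid))
  colnames(Z) <- paste0("LF", seq_len(ncol(Z)))
  rownames(Z) <- paste0(grid$mouse_id, "_wk", sprintf("%02d", grid$week))
  list(index = grid, Z = Z)
}

#' Simulate sparse true loadings
#'
#' @param n_features number of features.
#' @param n_factors number of factors.
#' @param sd SD of non-zero loadings.
#' @param sparsity fraction of entries zeroed, independently per entry.
#' @param seed integer seed.
#' @param prefix feature-ID prefix.
#' @return feature-by-factor matrix.
#' @export
simulate_loadings <- function(n_features, n_factors, sd = 1, sparsity = 0.5,
                              seed = 1, prefix = "F") {
  set.seed(seed)
  w <- matrix(stats::rnorm(n_features * n_factors, 0, sd), n_features, n_factors)
  mask <- matrix(stats::runif(n_features * n_factors) < sparsity, n_features, n_factors)
  w[mask] <- 0
  dimnames(w) <- list(sprintf("%s%04d", prefix, seq_len(n_features)),
                      paste0("LF", seq_len(n_factors)))
  w
}

#' Simulate an RNA-seq counts view from latent scores
#'
#' Expected per-sample proportions are \code{softmax(baseline + W Z')} over
#' features (exp link renormalized per sample, so library size and
#' composition stay decoupled); counts are negative-binomial with mean
#' \code{lib_size * proportion} and the given dispersion (0 gives Poisson).
#'
#' @param z profiles-by-factors score matrix (samples of this view in rows).
#' @param w feature-by-factor loading matrix.
#' @param lib_sizes per-sample library sizes (positive).
#' @param dispersion NB dispersion; variance = mu + dispersion * mu^2.
#' @param seed integer seed.
#' @param baseline per-feature log-scale baseline; default Normal(0,1) draws.
#' @param view_name view label.
#' @return an [omic_view()] with modality \code{"counts"}.
#' @export
simulate_counts_view <- function(z, w, lib_sizes, dispersion = 0.05, seed = 1,
                                 baseline = NULL, view_name = "rna") {
  z <- as.matrix(z); w <- as.matrix(w)
  if (ncol(z) != ncol(w)) stop("z and w disagree on the number of factors")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  if (length(lib_sizes) == 1) lib_sizes <- rep(lib_sizes, nrow(z))
  if (length(lib_sizes) != nrow(z)) stop("one library size per sample required")
  set.seed(seed)
  if (is.null(baseline)) baseline <- stats::rnorm(nrow(w), 0, 1)
  eta <- baseline + w %*% t(z)                     # features x samples
  p <- exp(eta - matrix(apply(eta, 2, max), nrow(eta), ncol(eta), byrow = TRUE))
  p <- sweep(p, 2, colSums(p), "/")
  mu <- sweep(p, 2, lib_sizes, "*")
  n <- length(mu)
  counts <- if (dispersion <= 0) stats::rpois(n, mu) else
    stats::rnbinom(n, size = 1 / dispersion, mu = mu)
  counts <- matrix(as.double(counts), nrow(mu), ncol(mu))
  dimnames(counts) <- list(rownames(w), rownames(z))
  omic_view(counts, view_name = view_name, modality = "counts")
}

#' Simulate an LC-MS abundance view from latent scores
#'
#' Abundance is \code{dilution_s * exp(baseline_f + (W Z')_fs + noise)} with
#' per-sample dilution multipliers drawn LogNormal(0, dilution_sd); the true
#' dilutions are returned alongside so downstream normalization can be
#' checked against them.
#'
#' @param z profiles-by-factors score matrix.
#' @param w feature-by-factor loading matrix.
#' @param noise_sd log-scale measurement noise SD (>= 0).
#' @param dilution_sd log-scale SD of dilution multipliers.
#' @param seed integer seed.
#' @param baseline per-feature log baseline; default Normal(0,1) draws.
#' @param dilution optional per-sample dilution multipliers to inject
#'   instead of drawing them.
#' @param view_name view label.
#' @return list with \code{view} (an [omic_view()], modality
#'   \code{"abundance"}) and \code{dilution} (the true multipliers).
#' @export
simulate_abundance_view <- function(z, w, noise_sd = 0.3, dilution_sd = 0.4,
                                    seed = 1, baseline = NULL, dilution = NULL,
                                    view_name = "lipids") {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  z <- as.matrix(z); w <- as.matrix(w)
  if (ncol(z) != ncol(w)) stop("z and w disagree on the number of factors")
  set.seed(seed)
  if (is.null(baseline)) baseline <- stats::rnorm(nrow(w), 0, 1)
  if (is.null(dilution)) dilution <- stats::rlnorm(nrow(z), 0, dilution_sd)
  if (any(dilution <= 0)) stop("dilution multipliers must be positive")
  logx <- baseline + w %*% t(z) +
    matrix(stats::rnorm(nrow(w) * nrow(z), 0, noise_sd), nrow(w), nrow(z))
  x <- sweep(exp(logx), 2, dilution, "*")
  dimnames(x) <- list(rownames(w), rownames(z))
  names(dilution) <- rownames(z)
  list(view = omic_view(x, view_name = view_name, modality = "abundance"),
       dilution = dilution)
}

#' Restrict simulated views to the assays each sample actually received
#'
#' Muscle RNA is kept only at the sacrifice week; every other (mouse, week)
#' pair is assigned to exactly one of \{blood RNA, plasma assays\} with
#' probability \code{blood_rna_fraction}, reproducing the per-view
#' missingness pattern of a longitudinal design where one blood draw cannot
#' feed both assay tracks.
#'
#' @param views named list of [omic_view()]s over the full (mouse, week)
#'   sample set: \code{muscle_rna}, \code{blood_rna}, \code{lipids},
#'   \code{metabolites} (any subset).
#' @param design a [study_design()].
#' @param seed integer seed for the assay assignment.
#' @return list with \code{views} (subset views), \code{meta} (master
#'   sample metadata over all retained samples) and \code{assignment}
#'   (data.frame of per-(mouse, week) assay track).
#' @export
apply_missingness <- function(views, design, seed = 1) {
  grid <- profile_grid(design)
  key <- paste0(grid$mouse_id, "_wk", sprintf("%02d", grid$week))
  set.seed(seed)
  to_blood <- stats::runif(nrow(grid)) < design$blood_rna_fraction
  assignment <- data.frame(grid, assay = ifelse(to_blood, "blood_rna", "plasma"),
                           stringsAsFactors = FALSE)
  keep <- list(
    muscle_rna = key[grid$week == design$muscle_week],
    blood_rna = key[to_blood],
    lipids = key[!to_blood],
    metabolites = key[!to_blood])
  meta_rows <- list()
  out_views <- list()
  for (vn in names(views)) {
    v <- views[[vn]]
    if (!vn %in% names(keep)) stop("unknown view name: ", vn)
    ks <- intersect(v$sample_ids, keep[[vn]])
    idx <- match(ks, v$sample_ids)
    sid <- if (length(ks)) paste0(ks, "_", vn) else character(0)
    out_views[[vn]] <- omic_view(v$values[, idx, drop = FALSE], view_name = vn,
                                 modality = v$modality, feature_ids = v$feature_ids,
                                 sample_ids = sid)
    g <- grid[match(ks, key), ]
    tiss <- c(muscle_rna = "muscle", blood_rna = "blood",
              lipids = "plasma", metabolites = "plasma")[[vn]]
    meta_rows[[vn]] <- data.frame(
      sample_id = sid, mouse_id = g$mouse_id, group = g$group, week = g$week,
      tissue = rep(tiss, length(ks)), stringsAsFactors = FALSE)
  }
  meta <- validate_metadata(do.call(rbind, meta_rows))
  rownames(meta) <- NULL
  list(views = out_views, meta = meta, assignment = assignment)
}

#' Simulate a complete longitudinal four-view study
#'
#' One-shot driver tying the generator together: true scores, per-view true
#' loadings, count and abundance views over every (mouse, week) pair, then
#' the design's missingness. Everything needed to score downstream recovery
#' is returned as ground truth.
#'
#' @param design a [study_design()].
#' @param truth a [truth_model()].
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @return list with \code{views}, \code{meta}, \code{truth} (Z_true
#'   restricted per view plus full-grid Z, W_true, dilutions, assignment)
#'   and the inputs.
#' @export
simulate_study <- function(design = study_design(), truth = truth_model(), seed = 1) {
  sc <- simulate_factor_scores(design, truth, seed = seed)
  K <- truth$n_factors_true
  nf <- truth$n_features
  view_names <- names(nf)
  W <- list(); full_views <- list(); dil <- list()
  for (i in seq_along(view_names)) {
    vn <- view_names[i]
    W[[vn]] <- simulate_loadings(nf[[vn]], K, sd = truth$loading_sd,
                                 sparsity = truth$loading_sparsity,
                                 seed = seed + 100 + i,
                                 prefix = c(muscle_rna = "G", blood_rna = "G",
                                            lipids = "L", metabolites = "M")[[vn]])
    if (!is.null(truth$view_activity))
      for (k in seq_len(K))
        if (!vn %in% truth$view_activity[[k]]) W[[vn]][, k] <- 0
    if (vn %in% c("muscle_rna", "blood_rna")) {
      set.seed(seed + 200 + i)
      libs <- round(stats::rlnorm(nrow(sc$Z), log(truth$lib_size), 0.2))
      full_views[[vn]] <- simulate_counts_view(sc$Z, W[[vn]], libs,
                                               dispersion = truth$nb_dispersion,
                                               seed = seed + 300 + i, view_name = vn)
    } else {
      ab <- simulate_abundance_view(sc$Z, W[[vn]], noise_sd = truth$noise_sd,
                                    dilution_sd = truth$dilution_sd,
                                    seed = seed + 300 + i, view_name = vn)
      full_views[[vn]] <- ab$view
      dil[[vn]] <- ab$dilution
    }
  }
  mis <- apply_missingness(full_views, design, seed = seed + 900)
  list(views = mis$views, meta = mis$meta,
       truth = list(Z = sc$Z, index = sc$index, W = W, dilutions = dil,
                    assignment = mis$assignment),
       design = design, truth_model = truth, seed = seed)
}
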