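#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and returned
#' in input order. Thin validating wrapper over
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

P_FLOOR <- 1e-300   # numerical p floor for perfect-separation cases

anova_r2_p <- function(score, fac) {
  fac <- droplevels(fac)
  if (nlevels(fac) < 2) return(list(r2 = 0, p = 1))   # degenerate family
  fit <- stats::lm(score ~ fac)
  s <- suppressWarnings(summary(fit))  # "essentially perfect fit" is expected
                                       # under exact separation; p is floored
  r2 <- s$r.squared
  fs <- s$fstatistic
  p <- if (is.null(fs)) 1 else
    stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  list(r2 = r2, p = max(min(p, 1), P_FLOOR))
}

#' Associate latent factors with genotype group and week
#'
#' For every factor score column, fits three least-squares models with
#' group and week as categorical covariates — \code{score ~ group},
#' \code{score ~ week}, \code{score ~ group * week} — and reports each
#' model's \eqn{R^2} plus the overall F-test p-value of the two main-effect
#' models against the intercept-only model. Benjamini-Hochberg adjustment
#' is applied separately across factors within the group family and within
#' the week family. A constant factor is reported with R2 = 0 and p = 1 by
#' convention; a factor facing a group or week level with fewer than 2
#' profiles is flagged.
#'
#' @param Z profiles-by-factors score matrix (e.g. \code{fit$Z}).
#' @param meta data.frame over the same profiles (same order) with columns
#'   \code{group} and \code{week}.
#' @return data.frame of class \code{association_table}: one row per
#'   factor with r2_group, r2_week, r2_interaction, p_group, p_week,
#'   q_group, q_week, flagged.
#' @export
lf_anova <- function(Z, meta) {
  Z <- as.matrix(Z)
  if (nrow(Z) != nrow(meta)) stop("Z and metadata disagree on profile count")
  if (!all(c("group", "week") %in% colnames(meta)))
    stop("metadata needs 'group' and 'week' columns")
  grp <- factor(as.character(meta$group))
  wk <- factor(meta$week)
  sparse_level <- any(table(grp) < 2) || any(table(wk) < 2)
  K <- ncol(Z)
  out <- data.frame(factor = colnames(Z) %||% paste0("LF", seq_len(K)),
                    r2_group = 0, r2_week = 0, r2_interaction = 0,
                    p_group = 1, p_week = 1, q_group = NA_real_,
                    q_week = NA_real_, flagged = sparse_level,
                    stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    z <- Z[, k]
    if (stats::sd(z) == 0) { out$flagged[k] <- TRUE; next }   # degenerate: R2=0, p=1
    g <- anova_r2_p(z, grp)
    w <- anova_r2_p(z, wk)
    both <- nlevels(droplevels(grp)) >= 2 && nlevels(droplevels(wk)) >= 2
    inter <- if (both) suppressWarnings(summary(stats::lm(z ~ grp * wk)))$r.squared
      else max(g$r2, w$r2)
    out$r2_group[k] <- g$r2; out$p_group[k] <- g$p
    out$r2_week[k] <- w$r2; out$p_week[k] <- w$p
    out$r2_interaction[k] <- inter
  }
  out$q_group <- bh_adjust(out$p_group)
  out$q_week <- bh_adjust(out$p_week)
  class(out) <- c("association_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise group and week contrasts of latent factors
#'
#' For each selected factor, tests all pairwise mean differences between
#' group levels and between week levels using two-sided t-tests with the
#' pooled variance of the one-way fit (classical post-hoc contrasts;
#' \code{welch = TRUE} switches to Welch tests). BH adjustment is applied
#' within each (factor, family). A level with fewer than 2 profiles skips
#' its pairs with a flag.
#'
#' @param Z profiles-by-factors score matrix.
#' @param meta data.frame with \code{group} and \code{week} over the same
#'   profiles.
#' @param factors indices or names of the factors to test (default all).
#' @param welch use Welch rather than pooled-variance t-tests.
#' @return data.frame: factor, family, level_a, level_b, diff, statistic,
#'   df, p, q, skipped.
#' @export
pairwise_contrasts <- function(Z, meta, factors = NULL, welch = FALSE) {
  Z <- as.matrix(Z)
  if (nrow(Z) != nrow(meta)) stop("Z and metadata disagree on profile count")
  if (is.null(factors)) factors <- seq_len(ncol(Z))
  fam <- list(group = factor(as.character(meta$group)),
              week = factor(meta$week))
  rows <- list()
  for (k in factors) {
    z <- Z[, k]
    kname <- (colnames(Z) %||% paste0("LF", seq_len(ncol(Z))))[k]
    for (fname in names(fam)) {
      f <- droplevels(fam[[fname]])
      lev <- levels(f)
      if (length(lev) < 2) next
      cnt <- table(f)
      means <- tapply(z, f, mean)
      # pooled residual variance of the one-way fit
      mse_df <- length(z) - length(lev)
      mse <- sum((z - means[f])^2) / mse_df
      prs <- utils::combn(lev, 2)
      fam_rows <- list()
      for (j in seq_len(ncol(prs))) {
        a <- prs[1, j]; b <- prs[2, j]
        skipped <- cnt[a] < 2 || cnt[b] < 2
        d <- unname(means[b] - means[a])
        if (skipped) {
          stat <- df <- p <- NA_real_
        } else if (welch) {
          tt <- stats::t.test(z[f == b], z[f == a])
          stat <- unname(tt$statistic); df <- unname(tt$parameter)
          p <- tt$p.value
        } else {
          se <- sqrt(mse * (1 / cnt[a] + 1 / cnt[b]))
          if (se == 0) {
            stat <- if (d == 0) 0 else sign(d) * Inf
            p <- if (d == 0) 1 else P_FLOOR
            df <- mse_df
          } else {
            stat <- unname(d / se)
            df <- mse_df
            p <- max(2 * stats::pt(-abs(stat), df), P_FLOOR)
          }
        }
        fam_rows[[j]] <- data.frame(factor = kname, family = fname,
                                    level_a = a, level_b = b, diff = d,
                                    statistic = stat, df = df, p = p,
                                    q = NA_real_, skipped = skipped,
                                    stringsAsFactors = FALSE)
      }
      fam_df <- do.call(rbind, fam_rows)
      keep <- !fam_df$skipped
      if (any(keep)) fam_df$q[keep] <- bh_adjust(fam_df$p[keep])
      rows[[paste(kname, fname)]] <- fam_df
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

get_loadings <- function(fit, view, factor) {
  stopifnot(inherits(fit, "factor_fit"))
  if (!view %in% fit$view_names) stop("unknown view: ", view)
  W <- fit$W[[view]]
  if (is.numeric(factor)) {
    if (factor < 1 || factor > ncol(W)) stop("unknown factor index: ", factor)
  } else {
    if (!factor %in% colnames(W)) stop("unknown factor: ", factor)
  }
  stats::setNames(W[, factor], rownames(W))
}

#' Top features of one factor in one view
#'
#' Features ranked by absolute loading, descending, ties broken by feature
#' ID; the signed loadings are returned.
#'
#' @param fit a \code{factor_fit}.
#' @param view view name.
#' @param factor factor index or name (e.g. \code{"LF1"}).
#' @param k how many features (default 10; capped at the feature count).
#' @return data.frame feature_id, loading, in rank order.
#' @export
top_loadings <- function(fit, view, factor, k = 10) {
  w <- get_loadings(fit, view, factor)
  ord <- order(-abs(w), xtfrm(names(w)))
  sel <- ord[seq_len(min(k, length(w)))]
  data.frame(feature_id = names(w)[sel], loading = unname(w[sel]),
             stringsAsFactors = FALSE)
}

#' Features whose loading magnitude exceeds a cutoff
#'
#' Strict inequality: a loading of exactly \code{cutoff} is excluded.
#'
#' @param fit a \code{factor_fit}.
#' @param view view name.
#' @param factor factor index or name.
#' @param cutoff magnitude cutoff (default 2, the convention for loadings
#'   fitted on unit-variance data).
#' @return data.frame feature_id, loading, for \code{abs(loading) > cutoff}.
#' @export
threshold_loadings <- function(fit, view, factor, cutoff = 2) {
  w <- get_loadings(fit, view, factor)
  sel <- which(abs(w) > cutoff)
  data.frame(feature_id = names(w)[sel], loading = unname(w[sel]),
             stringsAsFactors = FALSE)
}

#' Compare one factor's loadings between two views
#'
#' Inner-joins the two views' loadings on shared feature IDs and reports
#' their Pearson correlation plus which features load with a consistent
#' sign — the check of whether the same molecules drive a factor in, e.g.,
#' muscle and blood gene expression.
#'
#' @param fit a \code{factor_fit}.
#' @param view_a,view_b the two view names.
#' @param factor factor index or name.
#' @return list with \code{table} (feature_id, loading_a, loading_b,
#'   consistent) and \code{correlation}.
#' @export
cross_view_loading_comparison <- function(fit, view_a, view_b, factor) {
  wa <- get_loadings(fit, view_a, factor)
  wb <- get_loadings(fit, view_b, factor)
  shared <- intersect(names(wa), names(wb))
  if (length(shared) < 3)
    stop("need >= 3 shared feature IDs between '", view_a, "' and '", view_b,
         "', got ", length(shared))
  tab <- data.frame(feature_id = shared, loading_a = unname(wa[shared]),
                    loading_b = unname(wb[shared]),
                    stringsAsFactors = FALSE)
  tab$consistent <- sign(tab$loading_a) == sign(tab$loading_b) &
    tab$loading_a != 0 & tab$loading_b != 0
  list(table = tab,
       correlation = stats::cor(tab$loading_a, tab$loading_b))
}
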