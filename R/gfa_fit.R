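#' Fit the multi-view latent factor model
#'
#' Fits the decomposition \eqn{Y_m = Z W_m + E_m} over all views of a
#' profile set by mean-field variational Bayes. The likelihood is Gaussian
#' per view over observed profiles only; priors are standard normal on the
#' factor scores Z, normal with per-(view, factor) automatic relevance
#' determination (ARD) precision on the loadings, and Gamma on the ARD and
#' per-feature noise precisions. Coordinate-ascent updates cycle
#' (W, Z, alpha, tau) until the relative ELBO change stays below \code{tol}
#' on two consecutive iterations or \code{max_iter} is reached.
#'
#' Starting from \code{k_init} factors (initialized by an SVD of the
#' zero-filled concatenated views perturbed by seed-dependent noise), every
#' 5th iteration after a 10-iteration burn-in drops any factor whose
#' variance-explained fraction is below \code{threshold} in every view —
#' a factor survives by clearing the threshold in any single view, so
#' view-specific factors are kept. Because pruning changes the model
#' dimension, the reported \code{elbo_trace} covers the iterations after
#' the last pruning event (within which the bound is non-decreasing); the
#' full segmented history is kept in \code{elbo_segments}.
#'
#' On return, factor signs are fixed so each factor's largest-magnitude
#' loading is positive, and factors are ordered by total variance
#' explained, descending.
#'
#' @param ps a [profile_set()] whose views are centered and unit-variance
#'   scaled (see [unit_variance_scale()]).
#' @param k_init initial number of factors (clamped with a warning if it
#'   exceeds min(n profiles, total features)).
#' @param threshold variance-explained pruning threshold in (0, 1).
#' @param seed integer seed; identical inputs and seed give a bit-identical
#'   fit.
#' @param tol relative ELBO tolerance (default 1e-6, required on two
#'   consecutive iterations).
#' @param max_iter iteration cap (default 2000).
#' @param prior_a,prior_b Gamma prior shape/rate for both ARD and noise
#'   precisions (default 1e-3, a standard vague choice).
#' @return an object of class \code{factor_fit}: Z (profiles x K), per-view
#'   loadings W, per-feature noise precisions tau, per-(view, factor) ARD
#'   scales alpha, \code{elbo_trace}, \code{k_active}, provenance (seed,
#'   threshold) and the variational state needed to re-evaluate the bound.
#' @export
fit_gfa <- function(ps, k_init = 10, threshold = 0.02, seed = 1,
                    tol = 1e-6, max_iter = 2000,
                    prior_a = 1e-3, prior_b = 1e-3) {
  stopifnot(inherits(ps, "profile_set"), k_init >= 1)
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0,1)")
  vn <- names(ps$views)
  N <- nrow(ps$profile_index)
  obs <- ps$observed
  for (m in vn) if (!any(obs[[m]])) stop("view '", m, "' has no observed profiles")
  Y <- lapply(vn, function(m) t(ps$views[[m]][, obs[[m]], drop = FALSE]))
  names(Y) <- vn
  D <- vapply(Y, ncol, integer(1))
  Nm <- vapply(Y, nrow, integer(1))
  kmax <- min(N, sum(D))
  if (k_init > kmax) {
    warning("k_init = ", k_init, " exceeds min(dim); clamped to ", kmax)
    k_init <- kmax
  }
  K <- as.integer(k_init)

  set.seed(seed)
  X0 <- do.call(cbind, lapply(vn, function(m) {
    x <- t(ps$views[[m]]); x[is.na(x)] <- 0; x
  }))
  sv <- svd(X0, nu = K, nv = K)
  dscale <- sqrt(pmax(sv$d[seq_len(K)], 1e-8))
  muZ <- sv$u %*% diag(dscale, K) + matrix(stats::rnorm(N * K, 0, 0.1), N, K)
  csD <- cumsum(c(0, D))
  muW <- lapply(seq_along(vn), function(i) {
    rows <- (csD[i] + 1):csD[i + 1]
    sv$v[rows, , drop = FALSE] %*% diag(dscale, K) +
      matrix(stats::rnorm(D[i] * K, 0, 0.1), D[i], K)
  })
  names(muW) <- vn
  Ea <- stats::setNames(lapply(vn, function(m) rep(1, K)), vn)
  Eloga <- Ea
  a_alpha <- Ea; b_alpha <- Ea
  Et <- stats::setNames(lapply(vn, function(m) rep(1, D[[m]])), vn)
  Elogt <- stats::setNames(lapply(vn, function(m) rep(0, D[[m]])), vn)
  a_tau <- Et; b_tau <- Et

  y_ss <- lapply(Y, function(y) colSums(y^2))
  pat_mat <- do.call(cbind, obs)
  pat_key <- apply(pat_mat, 1, paste, collapse = "")
  pat_levels <- unique(pat_key)
  pat_of <- match(pat_key, pat_levels)
  obs_idx <- stats::setNames(lapply(vn, function(m) which(obs[[m]])), vn)
  # observed profile count per (pattern, view)
  pat_cnt <- vapply(vn, function(m)
    vapply(seq_along(pat_levels), function(pi) sum(pat_of == pi & obs[[m]]), 0L),
    integer(length(pat_levels)))
  pat_cnt <- matrix(pat_cnt, nrow = length(pat_levels),
                    dimnames = list(NULL, vn))

  SigW <- NULL
  SigZ_pat <- NULL
  S_m <- stats::setNames(
    lapply(vn, function(m) crossprod(muZ[obs_idx[[m]], , drop = FALSE])), vn)

  elbo_segments <- list()
  cur_trace <- numeric(0)
  elbo_prev <- -Inf
  hits <- 0L
  iter <- 0L
  converged <- FALSE

  while (iter < max_iter) {
    iter <- iter + 1L

    if (K > 0) {
      ## q(W): Sigma_{m,d} = (diag(Ea) + Et_d * S_m)^-1, stored as C diag(g_d) C'
      SigW <- list()
      for (m in vn) {
        Ahalf <- 1 / sqrt(Ea[[m]])
        eg <- eigen((Ahalf %o% Ahalf) * S_m[[m]], symmetric = TRUE)
        lam <- pmax(eg$values, 0)
        Cm <- Ahalf * eg$vectors
        g <- 1 / (1 + outer(lam, Et[[m]]))                       # K x D
        B <- crossprod(muZ[obs_idx[[m]], , drop = FALSE], Y[[m]])
        muW[[m]] <- t(Cm %*% (g * crossprod(Cm, B)) * rep(Et[[m]], each = K))
        SigW[[m]] <- list(C = Cm, g = g,
                          logdet = -sum(log(Ea[[m]])) -
                            colSums(log1p(outer(lam, Et[[m]]))))
      }

      ## q(Z): per observed-view pattern
      T_m <- stats::setNames(lapply(vn, function(m)
        crossprod(muW[[m]] * Et[[m]], muW[[m]]) +
          SigW[[m]]$C %*% (rowSums(SigW[[m]]$g * rep(Et[[m]], each = K)) *
                             t(SigW[[m]]$C))), vn)
      RHS <- matrix(0, N, K)
      for (m in vn)
        RHS[obs_idx[[m]], ] <- RHS[obs_idx[[m]], , drop = FALSE] +
          Y[[m]] %*% (muW[[m]] * Et[[m]])
      SigZ_pat <- vector("list", length(pat_levels))
      for (pi in seq_along(pat_levels)) {
        rows <- which(pat_of == pi)
        P <- diag(K)
        for (m in vn[pat_mat[rows[1], ]]) P <- P + T_m[[m]]
        SigZ_pat[[pi]] <- chol2inv(chol(P))
        muZ[rows, ] <- RHS[rows, , drop = FALSE] %*% SigZ_pat[[pi]]
      }
      S_m <- stats::setNames(lapply(vn, function(m) {
        S <- crossprod(muZ[obs_idx[[m]], , drop = FALSE])
        for (pi in seq_along(pat_levels))
          if (pat_cnt[pi, m] > 0) S <- S + pat_cnt[pi, m] * SigZ_pat[[pi]]
        S
      }), vn)

      ## q(alpha)
      for (m in vn) {
        Eww_k <- colSums(muW[[m]]^2) +
          as.vector((SigW[[m]]$C^2) %*% rowSums(SigW[[m]]$g))
        a_alpha[[m]] <- rep(prior_a + D[[m]] / 2, K)
        b_alpha[[m]] <- prior_b + Eww_k / 2
        Ea[[m]] <- a_alpha[[m]] / b_alpha[[m]]
        Eloga[[m]] <- digamma(a_alpha[[m]]) - log(b_alpha[[m]])
      }

      ## q(tau)
      for (m in vn) {
        r2 <- expected_resid2(Y[[m]], y_ss[[m]], muZ, obs_idx[[m]],
                              muW[[m]], SigW[[m]], S_m[[m]])
        a_tau[[m]] <- rep(prior_a + Nm[[m]] / 2, D[[m]])
        b_tau[[m]] <- prior_b + r2 / 2
        Et[[m]] <- a_tau[[m]] / b_tau[[m]]
        Elogt[[m]] <- digamma(a_tau[[m]]) - log(b_tau[[m]])
      }
    } else {
      for (m in vn) {
        a_tau[[m]] <- rep(prior_a + Nm[[m]] / 2, D[[m]])
        b_tau[[m]] <- prior_b + y_ss[[m]] / 2
        Et[[m]] <- a_tau[[m]] / b_tau[[m]]
        Elogt[[m]] <- digamma(a_tau[[m]]) - log(b_tau[[m]])
      }
    }

    e <- gfa_elbo_value(Y, vn, D, Nm, K, muZ, SigZ_pat, pat_of, pat_levels,
                        obs_idx, muW, SigW, S_m, Ea, Eloga, a_alpha, b_alpha,
                        Et, Elogt, a_tau, b_tau, y_ss, prior_a, prior_b)
    cur_trace <- c(cur_trace, e)
    rel <- if (is.finite(elbo_prev))
      abs(e - elbo_prev) / max(abs(elbo_prev), 1e-12) else Inf
    hits <- if (rel < tol) hits + 1L else 0L
    elbo_prev <- e
    if (hits >= 2L || K == 0) { converged <- TRUE; break }

    ## prune factors below threshold in every view
    if (iter >= 10 && iter %% 5 == 0) {
      r2f <- prune_r2(Y, vn, obs_idx, muZ, muW)
      drop_k <- which(apply(r2f < threshold, 2, all))
      if (length(drop_k)) {
        keep <- setdiff(seq_len(K), drop_k)
        K <- length(keep)
        muZ <- muZ[, keep, drop = FALSE]
        for (m in vn) {
          muW[[m]] <- muW[[m]][, keep, drop = FALSE]
          Ea[[m]] <- Ea[[m]][keep]; Eloga[[m]] <- Eloga[[m]][keep]
          a_alpha[[m]] <- a_alpha[[m]][keep]; b_alpha[[m]] <- b_alpha[[m]][keep]
          S_m[[m]] <- S_m[[m]][keep, keep, drop = FALSE]
        }
        elbo_segments <- c(elbo_segments, list(cur_trace))
        cur_trace <- numeric(0)
        elbo_prev <- -Inf
        hits <- 0L
      }
    }
  }
  elbo_segments <- c(elbo_segments, list(cur_trace))

  ## order by total variance explained, fix signs; transform stored state
  if (K > 0) {
    r2tot <- colSums(prune_r2_weighted(Y, vn, obs_idx, muZ, muW))
    ord <- order(-r2tot)
    sgn <- rep(1, K)
    allW <- do.call(rbind, muW)[, ord, drop = FALSE]
    for (k in seq_len(K))
      if (allW[which.max(abs(allW[, k])), k] < 0) sgn[k] <- -1
    muZ <- sweep(muZ[, ord, drop = FALSE], 2, sgn, "*")
    SigZ_pat <- lapply(SigZ_pat, function(S)
      sgn * S[ord, ord, drop = FALSE] * rep(sgn, each = K))
    for (m in vn) {
      muW[[m]] <- sweep(muW[[m]][, ord, drop = FALSE], 2, sgn, "*")
      Ea[[m]] <- Ea[[m]][ord]; Eloga[[m]] <- Eloga[[m]][ord]
      a_alpha[[m]] <- a_alpha[[m]][ord]; b_alpha[[m]] <- b_alpha[[m]][ord]
      S_m[[m]] <- sgn * S_m[[m]][ord, ord, drop = FALSE] * rep(sgn, each = K)
      SigW[[m]]$C <- sgn * SigW[[m]]$C[ord, , drop = FALSE]
    }
  }
  dimnames(muZ) <- list(ps$profile_ids, if (K > 0) paste0("LF", seq_len(K)))
  for (m in vn)
    dimnames(muW[[m]]) <- list(rownames(ps$views[[m]]),
                               if (K > 0) paste0("LF", seq_len(K)))
  structure(list(
    Z = muZ, W = muW,
    tau = stats::setNames(lapply(vn, function(m)
      stats::setNames(Et[[m]], rownames(ps$views[[m]]))), vn),
    alpha = stats::setNames(lapply(vn, function(m) Ea[[m]]), vn),
    elbo_trace = elbo_segments[[length(elbo_segments)]],
    elbo_segments = elbo_segments,
    elbo_final = elbo_prev,
    k_active = K, seed = as.integer(seed), threshold = threshold,
    n_iter = iter, converged = converged,
    profile_ids = ps$profile_ids, view_names = vn,
    vb = list(a_alpha = a_alpha, b_alpha = b_alpha,
              a_tau = a_tau, b_tau = b_tau,
              SigW = SigW, SigZ_pat = SigZ_pat, S_m = S_m,
              prior_a = prior_a, prior_b = prior_b)),
    class = "factor_fit")
}

#' @export
print.factor_fit <- function(x, ...) {
  cat(sprintf("factor_fit: %d active factor(s), %d profiles, %d view(s)\n",
              x$k_active, nrow(x$Z), length(x$W)))
  cat(sprintf("  seed %d, threshold %.3f, %d iterations%s, final ELBO %.4f\n",
              x$seed, x$threshold, x$n_iter,
              if (x$converged) " (converged)" else "", x$elbo_final))
  invisible(x)
}

# E[sum_n (y_nd - z_n' w_d)^2] per feature, given variational moments
expected_resid2 <- function(y, y_ss, muZ, idx, muWm, SigWm, Sm) {
  K <- ncol(muZ)
  B <- crossprod(muZ[idx, , drop = FALSE], y)                  # K x D
  quad <- rowSums((muWm %*% Sm) * muWm)
  q <- colSums(SigWm$C * (Sm %*% SigWm$C))                     # diag(C' S C)
  trSSig <- colSums(SigWm$g * q)
  pmax(y_ss - 2 * colSums(B * t(muWm)) + quad + trSSig, 0)
}

# per-factor per-view variance-explained fraction on posterior means
prune_r2 <- function(Y, vn, obs_idx, muZ, muW) {
  K <- ncol(muZ)
  out <- matrix(0, length(vn), K, dimnames = list(vn, NULL))
  for (m in vn) {
    y <- Y[[m]]
    ss <- sum(y^2)
    z <- muZ[obs_idx[[m]], , drop = FALSE]
    for (k in seq_len(K)) {
      res <- y - z[, k, drop = FALSE] %*% t(muW[[m]][, k, drop = FALSE])
      out[m, k] <- max(0, 1 - sum(res^2) / ss)
    }
  }
  out
}

# rows weighted by observed entry counts (for factor ordering)
prune_r2_weighted <- function(Y, vn, obs_idx, muZ, muW) {
  r2 <- prune_r2(Y, vn, obs_idx, muZ, muW)
  w <- vapply(vn, function(m) length(Y[[m]]), numeric(1))
  r2 * (w / sum(w))
}

# assemble the evidence lower bound from the variational state
gfa_elbo_value <- function(Y, vn, D, Nm, K, muZ, SigZ_pat, pat_of, pat_levels,
                           obs_idx, muW, SigW, S_m, Ea, Eloga,
                           a_alpha, b_alpha, Et, Elogt, a_tau, b_tau,
                           y_ss, prior_a, prior_b) {
  gamma_term <- function(a, b, Ex, Elogx)    # E[log p] + H[q], Gamma(a0, b0) prior
    sum((prior_a - 1) * Elogx - prior_b * Ex +
          prior_a * log(prior_b) - lgamma(prior_a)) +
      sum(a - log(b) + lgamma(a) + (1 - a) * digamma(a))
  elbo <- 0
  for (m in vn) {
    r2 <- if (K > 0)
      expected_resid2(Y[[m]], y_ss[[m]], muZ, obs_idx[[m]], muW[[m]],
                      SigW[[m]], S_m[[m]])
    else y_ss[[m]]
    elbo <- elbo + sum(Nm[[m]] / 2 * (Elogt[[m]] - log(2 * pi)) -
                         Et[[m]] * r2 / 2)
    elbo <- elbo + gamma_term(a_tau[[m]], b_tau[[m]], Et[[m]], Elogt[[m]])
    if (K > 0) {
      Eww_k <- colSums(muW[[m]]^2) +
        as.vector((SigW[[m]]$C^2) %*% rowSums(SigW[[m]]$g))
      elbo <- elbo + D[[m]] / 2 * sum(Eloga[[m]]) -
        sum(Ea[[m]] * Eww_k) / 2 + sum(SigW[[m]]$logdet) / 2 +
        D[[m]] * K / 2
      elbo <- elbo + gamma_term(a_alpha[[m]], b_alpha[[m]], Ea[[m]], Eloga[[m]])
    }
  }
  if (K > 0) {
    trEzz <- sum(muZ^2)
    logdetZ <- 0
    for (pi in seq_along(pat_levels)) {
      cnt <- sum(pat_of == pi)
      trEzz <- trEzz + cnt * sum(diag(SigZ_pat[[pi]]))
      logdetZ <- logdetZ + cnt * determinant(SigZ_pat[[pi]])$modulus[1]
    }
    N <- nrow(muZ)
    elbo <- elbo - trEzz / 2 + logdetZ / 2 + N * K / 2
  }
  as.numeric(elbo)
}

#' Evidence lower bound of a fitted model
#'
#' Re-evaluates the variational objective of a [fit_gfa()] result against
#' the data it was fitted to, using the fit's stored variational state;
#' equals the last element of \code{fit$elbo_trace}.
#'
#' @param fit a \code{factor_fit}.
#' @param ps the [profile_set()] the fit was computed on.
#' @return the ELBO (a scalar).
#' @export
elbo <- function(fit, ps) {
  stopifnot(inherits(fit, "factor_fit"), inherits(ps, "profile_set"))
  if (!identical(fit$profile_ids, ps$profile_ids) ||
      !identical(fit$view_names, names(ps$views)))
    stop("fit and profile set do not match")
  vn <- fit$view_names
  for (m in vn)
    if (nrow(ps$views[[m]]) != nrow(fit$W[[m]]))
      stop("feature dimension mismatch in view '", m, "'")
  obs <- ps$observed
  Y <- stats::setNames(
    lapply(vn, function(m) t(ps$views[[m]][, obs[[m]], drop = FALSE])), vn)
  D <- vapply(Y, ncol, integer(1)); Nm <- vapply(Y, nrow, integer(1))
  y_ss <- lapply(Y, function(y) colSums(y^2))
  obs_idx <- stats::setNames(lapply(vn, function(m) which(obs[[m]])), vn)
  pat_key <- apply(do.call(cbind, obs), 1, paste, collapse = "")
  pat_levels <- unique(pat_key)
  pat_of <- match(pat_key, pat_levels)
  vb <- fit$vb
  Eloga <- stats::setNames(lapply(vn, function(m)
    digamma(vb$a_alpha[[m]]) - log(vb$b_alpha[[m]])), vn)
  Elogt <- stats::setNames(lapply(vn, function(m)
    digamma(vb$a_tau[[m]]) - log(vb$b_tau[[m]])), vn)
  gfa_elbo_value(Y, vn, D, Nm, fit$k_active, fit$Z, vb$SigZ_pat, pat_of,
                 pat_levels, obs_idx, fit$W, vb$SigW, vb$S_m, fit$alpha,
                 Eloga, vb$a_alpha, vb$b_alpha, fit$tau, Elogt,
                 vb$a_tau, vb$b_tau, y_ss, vb$prior_a, vb$prior_b)
}

#' Model-based reconstruction of one view
#'
#' Returns \eqn{W_m Z'} as a feature-by-profile matrix over every profile,
#' including those unobserved in the view (model-based imputation).
#'
#' @param fit a \code{factor_fit}.
#' @param view_name name of the view to reconstruct.
#' @return feature-by-profile numeric matrix.
#' @export
reconstruct <- function(fit, view_name) {
  stopifnot(inherits(fit, "factor_fit"))
  if (!view_name %in% fit$view_names) stop("unknown view: ", view_name)
  W <- fit$W[[view_name]]
  if (fit$k_active == 0)
    return(matrix(0, nrow(W), nrow(fit$Z),
                  dimnames = list(rownames(W), fit$profile_ids)))
  out <- W %*% t(fit$Z)
  dimnames(out) <- list(rownames(W), fit$profile_ids)
  out
}

#' Variance explained by the fitted factors
#'
#' Per-factor, per-view \eqn{R^2(m,k) = 1 - \sum_{obs}(Y_m - z_k w_{mk}')^2
#' / \sum_{obs} Y_m^2} (clipped below at 0); per-view totals use the full
#' reconstruction \eqn{Z W_m'}, not the per-factor sum; the overall total
#' is the mean of per-view totals weighted by observed entry counts.
#'
#' @param fit a \code{factor_fit}.
#' @param ps the [profile_set()] it was fitted on.
#' @return list of class \code{variance_explained}: \code{per_factor}
#'   (view-by-K matrix of fractions), \code{per_view_total},
#'   \code{overall_total}.
#' @export
variance_explained <- function(fit, ps) {
  stopifnot(inherits(fit, "factor_fit"), inherits(ps, "profile_set"))
  vn <- fit$view_names
  K <- fit$k_active
  per_factor <- matrix(0, length(vn), K,
                       dimnames = list(vn, if (K > 0) paste0("LF", seq_len(K))))
  per_view <- stats::setNames(numeric(length(vn)), vn)
  wts <- stats::setNames(numeric(length(vn)), vn)
  for (m in vn) {
    y <- t(ps$views[[m]][, ps$observed[[m]], drop = FALSE])
    z <- fit$Z[ps$observed[[m]], , drop = FALSE]
    ss <- sum(y^2)
    wts[m] <- length(y)
    if (K > 0) {
      for (k in seq_len(K)) {
        res <- y - z[, k, drop = FALSE] %*% t(fit$W[[m]][, k, drop = FALSE])
        per_factor[m, k] <- max(0, 1 - sum(res^2) / ss)
      }
      res <- y - z %*% t(fit$W[[m]])
      per_view[m] <- max(0, 1 - sum(res^2) / ss)
    }
  }
  structure(list(per_factor = per_factor, per_view_total = per_view,
                 overall_total = sum(per_view * wts) / sum(wts)),
            class = "variance_explained")
}

#' @export
print.variance_explained <- function(x, ...) {
  cat("variance explained (fractions):\n")
  print(round(cbind(x$per_factor, total = x$per_view_total), 4))
  cat(sprintf("overall total: %.4f\n", x$overall_total))
  invisible(x)
}
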