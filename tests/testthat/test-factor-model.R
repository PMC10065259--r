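test_that("noiseless rank-1 data is reconstructed essentially exactly", {
  set.seed(1)
  z <- rnorm(30); w <- rnorm(40)
  ps <- wrap_ps(outer(z, w))
  fit <- fit_gfa(ps, k_init = 1, threshold = 0.01, seed = 2)
  expect_equal(fit$k_active, 1L)
  rec <- reconstruct(fit, "v1")
  truth <- ps$views$v1
  expect_lt(norm(rec - truth, "F") / norm(truth, "F"), 1e-3)
  ve <- variance_explained(fit, ps)
  expect_gt(ve$overall_total, 0.999)
  expect_gt(ve$per_factor["v1", 1], 0.999)
})

test_that("true factors are recovered on multi-view data with known K", {
  # 2 views, K_true = 3, view-differentiated activity, strong signal
  act <- rbind(c(1, 1, 0), c(1, 0, 1))
  x <- make_gaussian_study(5, N = 80, D = c(60, 60), K = 3, noise = 0.4,
                           act = act)
  fit <- fit_gfa(x$ps, k_init = 10, threshold = 0.01, seed = 3)
  expect_equal(fit$k_active, 3L)
  r <- greedy_match_r(x$Z, fit$Z)
  expect_true(all(r >= 0.9))
})

test_that("pure noise collapses to at most one weak factor", {
  for (s in 1:10) {
    set.seed(1000 + s)
    ps <- wrap_ps(matrix(rnorm(60 * 120), 60, 120))
    fit <- fit_gfa(ps, k_init = 5, threshold = 0.05, seed = s)
    expect_lte(fit$k_active, 1L)
    expect_lt(variance_explained(fit, ps)$overall_total, 0.05)
  }
})

test_that("the ELBO trace is monotone and reproducible", {
  x <- make_gaussian_study(8, N = 40, D = c(30, 25), K = 2, noise = 0.5)
  fit <- fit_gfa(x$ps, k_init = 5, threshold = 0.02, seed = 11)
  for (seg in fit$elbo_segments)
    expect_true(all(diff(seg) >= -1e-6))
  # bit-identical refit
  fit2 <- fit_gfa(x$ps, k_init = 5, threshold = 0.02, seed = 11)
  expect_identical(fit$Z, fit2$Z)
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$elbo_segments, fit2$elbo_segments)
  # a different seed gives a different optimization path
  fit3 <- fit_gfa(x$ps, k_init = 5, threshold = 0.02, seed = 12)
  expect_false(identical(fit$elbo_trace, fit3$elbo_trace))
})

test_that("elbo() re-evaluates the stored bound exactly", {
  x <- make_gaussian_study(9, N = 30, D = c(20, 15), K = 2, noise = 0.5,
                           frac_obs = 0.8)
  fit <- fit_gfa(x$ps, k_init = 4, threshold = 0.02, seed = 21)
  expect_equal(elbo(fit, x$ps), tail(fit$elbo_trace, 1), tolerance = 1e-12)
  # scaling the data changes the ELBO deterministically
  ps_scaled <- x$ps
  for (m in names(ps_scaled$views)) ps_scaled$views[[m]] <- 2 * ps_scaled$views[[m]]
  fa <- fit_gfa(ps_scaled, k_init = 4, threshold = 0.02, seed = 21)
  fb <- fit_gfa(ps_scaled, k_init = 4, threshold = 0.02, seed = 21)
  expect_identical(fa$elbo_trace, fb$elbo_trace)
  expect_false(isTRUE(all.equal(fa$elbo_final, fit$elbo_final)))
  # mismatched data is refused
  expect_error(elbo(fit, ps_scaled2 <- {
    p <- x$ps; p$views$v1 <- p$views$v1[1:5, , drop = FALSE]; p
  }), "dimension")
})

test_that("the assembled ELBO matches a numerical-quadrature evaluation", {
  skip_if_not_installed("pracma")
  # tiny instance: 4 profiles, 3 features, 1 factor, 1 view
  set.seed(6)
  z <- rnorm(4); w <- rnorm(3)
  Y <- 3 * outer(z, w) + matrix(rnorm(12, 0, 0.1), 4, 3)
  ps <- wrap_ps(Y)
  fit <- fit_gfa(ps, k_init = 1, threshold = 0.01, seed = 4, max_iter = 50)
  expect_equal(fit$k_active, 1L)

  vb <- fit$vb
  gh <- pracma::gaussHermite(30)
  e_gauss <- function(f, mu, s2) {  # E[f(X)], X ~ N(mu, s2)
    sum(gh$w * f(mu + sqrt(2 * s2) * gh$x)) / sqrt(pi)
  }
  e_gamma <- function(f, a, b) {    # E[f(X)], X ~ Gamma(a, rate b)
    stats::integrate(function(t) f(t) * stats::dgamma(t, a, rate = b),
                     0, Inf, rel.tol = 1e-12)$value
  }
  yobs <- t(ps$views$v1)            # 4 x 3
  muZ <- fit$Z[, 1]; s2z <- vb$SigZ_pat[[1]][1, 1]
  muW <- fit$W$v1[, 1]
  s2w <- as.numeric(vb$SigW$v1$C)^2 * vb$SigW$v1$g[1, ]
  at <- vb$a_tau$v1; bt <- vb$b_tau$v1
  aa <- vb$a_alpha$v1; ba <- vb$b_alpha$v1
  a0 <- vb$prior_a; b0 <- vb$prior_b

  elbo_num <- 0
  for (d in 1:3) {
    Elogt <- e_gamma(log, at[d], bt[d])
    Et <- e_gamma(identity, at[d], bt[d])
    for (n in 1:4) {
      # E[(y - z w)^2] by 2-D Gauss-Hermite product rule
      E2 <- e_gauss(function(zv)
        vapply(zv, function(z1)
          e_gauss(function(wv) (yobs[n, d] - z1 * wv)^2, muW[d], s2w[d]),
          numeric(1)), muZ[n], s2z)
      elbo_num <- elbo_num + 0.5 * (Elogt - log(2 * pi)) - 0.5 * Et * E2
    }
  }
  # z: E[log p] + entropy, both by quadrature
  for (n in 1:4)
    elbo_num <- elbo_num +
      e_gauss(function(zv) stats::dnorm(zv, log = TRUE), muZ[n], s2z) +
      0.5 * log(2 * pi * exp(1) * s2z)
  # w | alpha, with alpha integrated numerically
  Eloga <- e_gamma(log, aa, ba); Ealpha <- e_gamma(identity, aa, ba)
  for (d in 1:3) {
    Ew2 <- e_gauss(function(wv) wv^2, muW[d], s2w[d])
    elbo_num <- elbo_num + 0.5 * Eloga - 0.5 * log(2 * pi) -
      0.5 * Ealpha * Ew2 + 0.5 * log(2 * pi * exp(1) * s2w[d])
  }
  # gamma prior expectations + entropies, numerically
  gam_num <- function(a, b) {
    e_gamma(function(t) (a0 - 1) * log(t) - b0 * t +
              a0 * log(b0) - lgamma(a0), a, b) -
      e_gamma(function(t) stats::dgamma(t, a, rate = b, log = TRUE), a, b)
  }
  elbo_num <- elbo_num + gam_num(aa, ba)
  for (d in 1:3) elbo_num <- elbo_num + gam_num(at[d], bt[d])

  expect_equal(unname(elbo_num), elbo(fit, ps), tolerance = 1e-4)
})

test_that("variance decomposition is exact, clipped and Pythagorean", {
  # orthogonal scores and loadings: per-factor R2 sums to the total
  set.seed(13)
  Zq <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3))) * sqrt(40)
  Wq <- qr.Q(qr(matrix(rnorm(25 * 3), 25, 3))) %*% diag(c(3, 2, 1))
  Y <- Zq %*% t(Wq)
  X <- t(Y); rownames(X) <- sprintf("f%03d", 1:25)
  idx <- data.frame(mouse_id = sprintf("m%03d", 1:40), group = "WT", week = 6L)
  ps <- profile_set(idx, list(v1 = X), list(v1 = rep(TRUE, 40)))
  fit <- structure(list(Z = Zq, W = list(v1 = Wq), k_active = 3L,
                        view_names = "v1",
                        profile_ids = ps$profile_ids),
                   class = "factor_fit")
  ve <- variance_explained(fit, ps)
  expect_equal(ve$per_view_total[["v1"]], 1, tolerance = 1e-9)
  expect_equal(sum(ve$per_factor["v1", ]), ve$per_view_total[["v1"]],
               tolerance = 1e-6)
  expect_true(all(ve$per_factor >= 0 & ve$per_factor <= 1))

  # an all-zero-loadings factor explains nothing
  fit0 <- fit
  fit0$Z <- cbind(fit$Z, rnorm(40))
  fit0$W$v1 <- cbind(fit$W$v1, 0)
  fit0$k_active <- 4L
  ve0 <- variance_explained(fit0, ps)
  expect_equal(unname(ve0$per_factor["v1", 4]), 0)

  # metrics are invariant to sign flips and column permutations
  flip <- c(-1, 1, -1)
  perm <- c(2, 3, 1)
  fitp <- fit
  fitp$Z <- sweep(fit$Z[, perm], 2, flip[perm], "*")
  fitp$W$v1 <- sweep(fit$W$v1[, perm], 2, flip[perm], "*")
  vep <- variance_explained(fitp, ps)
  expect_equal(vep$per_view_total, ve$per_view_total, tolerance = 1e-12)
  expect_equal(unname(sort(vep$per_factor["v1", ])),
               unname(sort(ve$per_factor["v1", ])), tolerance = 1e-12)
})

test_that("reconstruction imputes masked profiles of noiseless low-rank data", {
  set.seed(17)
  N <- 50
  z <- rnorm(N)
  w1 <- rnorm(100); w2 <- rnorm(30)
  mask <- rep(TRUE, N); mask[sample(N, 10)] <- FALSE  # view-2 holdout
  Y1 <- outer(z, w1)
  Y2 <- outer(z, w2)
  # scale each feature of view 2 on the observed profiles only
  mu2 <- colMeans(Y2[mask, ]); sd2 <- apply(Y2[mask, , drop = FALSE], 2, sd)
  Y2s <- sweep(sweep(Y2, 2, mu2), 2, sd2, "/")
  X1 <- t(scale(Y1)); rownames(X1) <- sprintf("a%03d", 1:100)
  X2 <- t(Y2s); rownames(X2) <- sprintf("b%03d", 1:30)
  X2m <- X2; X2m[, !mask] <- NA
  idx <- data.frame(mouse_id = sprintf("m%03d", 1:N), group = "WT", week = 6L)
  ps <- profile_set(idx, list(v1 = X1, v2 = X2m),
                    list(v1 = rep(TRUE, N), v2 = mask))
  fit <- fit_gfa(ps, k_init = 2, threshold = 0.01, seed = 5)
  rec <- reconstruct(fit, "v2")
  held <- X2[, !mask]
  expect_lt(norm(rec[, !mask] - held, "F") / norm(held, "F"), 0.05)

  expect_error(reconstruct(fit, "v9"), "unknown view")
})

test_that("degenerate requests are caught or clamped", {
  x <- make_gaussian_study(19, N = 12, D = c(8, 6), K = 1, noise = 0.5)
  expect_warning(fit <- fit_gfa(x$ps, k_init = 50, threshold = 0.02, seed = 1),
                 "clamped")
  expect_lte(ncol(fit$Z), 12)
  # a view with no observed profile is refused
  ps_bad <- x$ps
  ps_bad$views$v2[] <- NA
  ps_bad$observed$v2 <- rep(FALSE, 12)
  expect_error(fit_gfa(ps_bad, k_init = 2, threshold = 0.02, seed = 1),
               "no observed")
  expect_error(fit_gfa(x$ps, k_init = 2, threshold = 1.5, seed = 1),
               "threshold")
})

test_that("factor signs anchor the largest loading positive", {
  x <- make_gaussian_study(23, N = 40, D = c(30, 30), K = 2, noise = 0.4,
                           act = rbind(c(1, 1), c(1, 0)))
  fit <- fit_gfa(x$ps, k_init = 4, threshold = 0.02, seed = 7)
  allW <- do.call(rbind, fit$W)
  for (k in seq_len(fit$k_active))
    expect_gt(allW[which.max(abs(allW[, k])), k], 0)
  # and factors are ordered by total variance explained
  ve <- variance_explained(fit, x$ps)
  wts <- c(30, 30) * 40 / sum(c(30, 30) * 40)
  tot <- as.numeric(wts %*% ve$per_factor)
  expect_true(all(diff(tot) <= 1e-8))
})
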