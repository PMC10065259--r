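toy_meta <- function(groups, weeks) {
  data.frame(group = groups, week = weeks, stringsAsFactors = FALSE)
}

test_that("one-way R2 and F match the closed-form sums of squares", {
  z <- matrix(1:6, ncol = 1, dimnames = list(NULL, "LF1"))
  meta <- toy_meta(rep(c("A", "B"), each = 3), rep(1, 6))
  out <- lf_anova(z, meta)
  # SSB = 3*(2-3.5)^2 + 3*(5-3.5)^2 = 13.5 ; SST = 17.5
  expect_equal(out$r2_group, 13.5 / 17.5, tolerance = 1e-12)
  # F = MSB/MSW = 13.5 / (4/4) = 13.5 on (1, 4) df
  expect_equal(out$p_group, pf(13.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # week is constant here: degenerate family, p = 1
  expect_equal(out$p_week, 1)
})

test_that("degenerate and perfectly separated factors follow the conventions", {
  meta <- toy_meta(rep(c("A", "B"), each = 4), rep(c(1, 2), 4))
  zc <- matrix(5, 8, 1)
  out <- lf_anova(zc, meta)
  expect_equal(out$r2_group, 0)
  expect_equal(out$r2_week, 0)
  expect_equal(out$p_group, 1)
  expect_true(out$flagged)

  zp <- matrix(rep(c(0, 1), each = 4), 8, 1)  # exact group indicator
  outp <- lf_anova(zp, meta)
  expect_equal(outp$r2_group, 1, tolerance = 1e-12)
  expect_lte(outp$p_group, 1e-10)
  expect_gte(outp$p_group, 1e-300)            # numerical floor, no zero/overflow
})

test_that("nested-model R2 ordering holds across random factors", {
  set.seed(8)
  n <- 60
  meta <- toy_meta(sample(c("WT", "mdx", "mdxUtrnPP", "mdxUtrnPM"), n, TRUE),
                   sample(c(6, 12, 18, 24, 30), n, TRUE))
  Z <- matrix(rnorm(n * 6), n, 6)
  Z[, 1] <- Z[, 1] + 2 * (meta$group != "WT")
  Z[, 2] <- Z[, 2] + meta$week / 6
  out <- lf_anova(Z, meta)
  expect_true(all(out$r2_interaction >= pmax(out$r2_group, out$r2_week) - 1e-12))
  expect_true(all(out$q_group >= out$p_group - 1e-15))
  expect_true(all(out$q_week >= out$p_week - 1e-15))
})

test_that("BH adjustment reproduces the closed-form step-up on worked examples", {
  p <- seq(0.01, 0.08, by = 0.01)
  # q_(i) = min_{j>=i} p_(j) * 8 / j = 0.08 for every i here
  expect_equal(bh_adjust(p), rep(0.08, 8), tolerance = 1e-12)
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")

  # general closed-form oracle on random p, in input order
  set.seed(12)
  pr <- runif(20)
  m <- length(pr)
  ord <- order(pr)
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(pr[ord][i:m] * m / (i:m))), numeric(1))
  oracle <- numeric(m); oracle[ord] <- q_sorted
  expect_equal(bh_adjust(pr), oracle, tolerance = 1e-12)
  # monotone: larger raw p never gets smaller adjusted p
  expect_true(all(diff(bh_adjust(pr)[order(pr)]) >= -1e-15))
})

test_that("pairwise contrasts use the pooled one-way variance", {
  set.seed(3)
  meta <- toy_meta(rep(c("WT", "mdx", "mdxUtrnPP", "mdxUtrnPM"), each = 5),
                   rep(c(6, 12, 18, 24, 30), 4))
  z <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "LF1"))
  out <- pairwise_contrasts(z, meta)
  gout <- out[out$family == "group", ]
  expect_equal(nrow(gout), choose(4, 2))       # 6 group pairs
  expect_equal(nrow(out[out$family == "week", ]), choose(5, 2))

  # oracle: pooled-variance t for one pair
  f <- factor(meta$group)
  means <- tapply(z[, 1], f, mean)
  mse <- sum((z[, 1] - means[f])^2) / (20 - 4)
  tt <- (means[["mdx"]] - means[["WT"]]) / sqrt(mse * (1 / 5 + 1 / 5))
  row <- gout[gout$level_a == "WT" & gout$level_b == "mdx", ]
  expect_equal(row$statistic, unname(tt), tolerance = 1e-12)
  expect_equal(row$p, 2 * pt(-abs(tt), 16), tolerance = 1e-12)

  # identical group means: difference 0, p = 1
  z0 <- matrix(rep(1:5, 4), 20, 1)
  out0 <- pairwise_contrasts(z0, meta)
  g0 <- out0[out0$family == "group", ]
  expect_true(all(g0$diff == 0))
  expect_true(all(g0$p == 1))

  # near-perfect separation is overwhelmingly significant
  meta2 <- toy_meta(rep(c("WT", "mdx"), each = 3), rep(c(6, 12, 18), 2))
  zs <- matrix(c(rnorm(3, 0, 1e-6), 1 + rnorm(3, 0, 1e-6)), 6, 1)
  outs <- pairwise_contrasts(zs, meta2)
  sep <- outs[outs$family == "group" & outs$level_a == "WT" &
                outs$level_b == "mdx", ]
  expect_lt(sep$p, 1e-4)
})

test_that("sparse levels are skipped with a flag, not silently tested", {
  meta <- toy_meta(c("WT", "WT", "WT", "mdx"), c(6, 6, 12, 12))
  z <- matrix(rnorm(4), 4, 1)
  out <- pairwise_contrasts(z, meta)
  g <- out[out$family == "group", ]
  expect_true(g$skipped[g$level_b == "mdx"])    # mdx has a single profile
  expect_true(is.na(g$p[g$level_b == "mdx"]))
})

test_that("loading rankings and thresholds match brute-force oracles", {
  W <- matrix(c(0.5, -2, 1, 2.0, 2.1, -2.5), 6, 1,
              dimnames = list(paste0("f", 1:6), "LF1"))
  fit <- structure(list(W = list(v1 = W), view_names = "v1", k_active = 1L),
                   class = "factor_fit")
  top2 <- top_loadings(fit, "v1", 1, k = 2)
  expect_identical(top2$feature_id, c("f6", "f5"))
  expect_equal(top2$loading, c(-2.5, 2.1))
  expect_equal(nrow(top_loadings(fit, "v1", 1, k = 100)), 6)

  thr <- threshold_loadings(fit, "v1", 1, cutoff = 2)
  expect_setequal(thr$feature_id, c("f5", "f6"))  # strict: |2.0| excluded
  expect_equal(nrow(threshold_loadings(fit, "v1", 1, cutoff = 0)), 6)
  expect_error(top_loadings(fit, "v1", 3), "unknown factor")
  expect_error(top_loadings(fit, "vX", 1), "unknown view")

  set.seed(4)
  Wbig <- matrix(rnorm(1000), 1000, 1,
                 dimnames = list(sprintf("f%04d", 1:1000), "LF1"))
  fitb <- structure(list(W = list(v1 = Wbig), view_names = "v1", k_active = 1L),
                    class = "factor_fit")
  got <- top_loadings(fitb, "v1", 1, k = 50)
  want <- names(sort(abs(Wbig[, 1]), decreasing = TRUE)[1:50])
  expect_setequal(got$feature_id, want)
  cut <- 1.2
  expect_setequal(threshold_loadings(fitb, "v1", 1, cut)$feature_id,
                  rownames(Wbig)[abs(Wbig[, 1]) > cut])
})

test_that("cross-view loading comparison joins by ID and reports correlation", {
  ids <- paste0("g", 1:20)
  wa <- rnorm(20); names(wa) <- ids
  Wa <- matrix(wa, 20, 1, dimnames = list(ids, "LF1"))
  fit <- structure(list(W = list(muscle = Wa, blood = Wa),
                        view_names = c("muscle", "blood"), k_active = 1L),
                   class = "factor_fit")
  same <- cross_view_loading_comparison(fit, "muscle", "blood", 1)
  expect_equal(same$correlation, 1)
  expect_true(all(same$table$consistent[same$table$loading_a != 0]))

  fit$W$blood <- -Wa
  neg <- cross_view_loading_comparison(fit, "muscle", "blood", 1)
  expect_equal(neg$correlation, -1)
  expect_false(any(neg$table$consistent))

  # random shared subset against the direct covariance formula
  set.seed(6)
  wb <- rnorm(20); names(wb) <- ids
  fit$W$blood <- matrix(wb, 20, 1, dimnames = list(ids, "LF1"))
  out <- cross_view_loading_comparison(fit, "muscle", "blood", 1)
  num <- sum((wa - mean(wa)) * (wb - mean(wb)))
  den <- sqrt(sum((wa - mean(wa))^2) * sum((wb - mean(wb))^2))
  expect_equal(out$correlation, num / den, tolerance = 1e-12)

  fit$W$blood <- matrix(rnorm(2), 2, 1, dimnames = list(ids[1:2], "LF1"))
  expect_error(cross_view_loading_comparison(fit, "muscle", "blood", 1),
               ">= 3 shared")
})

test_that("factor phenotypes are detected in replicated synthetic studies", {
  # growth-like (pure time) factor: significant for week, not group
  n_rep <- 5
  ok_time <- 0L
  for (s in seq_len(n_rep)) {
    des <- study_design(n_mice_per_group = 8)
    tr <- truth_model(factors = list(factor_preset("growth", residual_sd = 1),
                                     factor_preset("noise")),
                      view_activity = NULL)
    sc <- simulate_factor_scores(des, tr, seed = 600 + s)
    out <- lf_anova(sc$Z, sc$index)
    if (out$q_week[1] < 0.05 && out$q_group[1] > 0.05) ok_time <- ok_time + 1L
  }
  expect_gte(ok_time, ceiling(0.8 * n_rep))

  # disease-like factor: highest interaction R2 among factors
  ok_int <- 0L
  for (s in seq_len(n_rep)) {
    des <- study_design(n_mice_per_group = 8)
    tr <- truth_model(view_activity = NULL)   # disease, growth, early presets
    sc <- simulate_factor_scores(des, tr, seed = 700 + s)
    out <- lf_anova(sc$Z, sc$index)
    if (which.max(out$r2_interaction) == 1) ok_int <- ok_int + 1L
  }
  expect_gte(ok_int, ceiling(0.8 * n_rep))
})
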