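# Fixture builders shared across the suite. Everything is generated in code
# under fixed seeds; no data files.

# Gaussian multi-view profile set with known latent structure.
# act: view-by-factor 0/1 activity matrix (NULL = all active).
make_gaussian_study <- function(seed, N = 100, D = c(60, 60, 40, 30), K = 4,
                                noise = 0.5, sparsity = 0.5, act = NULL,
                                frac_obs = 1, Z = NULL) {
  set.seed(seed)
  if (is.null(Z)) Z <- matrix(rnorm(N * K), N, K)
  views <- list(); obs <- list(); W <- list()
  for (m in seq_along(D)) {
    vn <- paste0("v", m)
    W[[vn]] <- simulate_loadings(D[m], K, sd = 1, sparsity = sparsity,
                                 seed = seed * 131 + m,
                                 prefix = paste0(vn, "f"))
    if (!is.null(act)) W[[vn]] <- sweep(W[[vn]], 2, act[m, ], "*")
    Y <- Z %*% t(W[[vn]]) + matrix(rnorm(N * D[m], 0, noise), N, D[m])
    o <- rep(TRUE, N)
    if (m > 1 && frac_obs < 1)
      o[sample(N, round(N * (1 - frac_obs)))] <- FALSE
    Ys <- Y; Ys[!o, ] <- NA
    Ys <- t(scale(Ys))
    attr(Ys, "scaled:center") <- NULL; attr(Ys, "scaled:scale") <- NULL
    Ys[, !o] <- NA
    rownames(Ys) <- rownames(W[[vn]])
    views[[vn]] <- Ys
    obs[[vn]] <- o
  }
  idx <- data.frame(mouse_id = sprintf("m%03d", seq_len(N)), group = "WT",
                    week = 6L, stringsAsFactors = FALSE)
  list(ps = profile_set(idx, views, obs), Z = Z, W = W)
}

# greedy max-|cor| assignment of true to estimated factors
greedy_match_r <- function(Z_true, Z_est) {
  if (is.null(ncol(Z_est)) || ncol(Z_est) == 0) return(rep(0, ncol(Z_true)))
  cors <- abs(stats::cor(Z_true, Z_est))
  out <- numeric(ncol(Z_true)); used <- integer(0)
  for (k in order(-apply(cors, 1, max))) {
    avail <- setdiff(seq_len(ncol(cors)), used)
    if (!length(avail)) break
    best <- avail[which.max(cors[k, avail])]
    out[k] <- cors[k, best]; used <- c(used, best)
  }
  out
}

# tiny metadata table
make_meta <- function(n = 5, group = "WT", tissue = "blood", week = 6) {
  data.frame(sample_id = paste0("s", seq_len(n)),
             mouse_id = paste0("m", seq_len(n)),
             group = rep_len(group, n), week = rep_len(week, n),
             tissue = rep_len(tissue, n), stringsAsFactors = FALSE)
}

# single fully-observed view wrapped as a profile set (scaled)
wrap_ps <- function(Y, scale_it = TRUE) {   # Y: profiles x features
  X <- if (scale_it) t(scale(Y)) else t(Y)
  attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
  rownames(X) <- sprintf("f%03d", seq_len(ncol(Y)))
  profile_set(data.frame(mouse_id = sprintf("m%03d", seq_len(nrow(Y))),
                         group = "WT", week = 6L),
              views = list(v1 = X), observed = list(v1 = rep(TRUE, nrow(Y))))
}

# independent step-by-step oracle following the published recipe
tmm_oracle <- function(counts, ref_col, col, trim_m = 0.30, trim_a = 0.05) {
  nO <- sum(counts[, col]); nR <- sum(counts[, ref_col])
  obs <- counts[, col]; ref <- counts[, ref_col]
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / nO) / (ref / nR))
  A <- (log2(obs / nO) + log2(ref / nR)) / 2
  w <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  sel <- rank(M) >= lo_m & rank(M) <= hi_m & rank(A) >= lo_a & rank(A) <= hi_a
  2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
}

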