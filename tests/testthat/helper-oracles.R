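# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately avoid the package's water-filling / spectral
# shortcuts: they enumerate active sets and optimize on the power simplex, or
# evaluate the Wiener algebra with fully materialized matrices.

# Direct numerical minimization of the expected MSE over power allocations:
# enumerates every candidate active set of size <= min(M, N) and minimizes
# over the simplex via a softmax parameterization with analytic gradients.
oracle_min_mse <- function(lam, a, sn2, sd2, M, P) {
  denom <- a^2 * lam + sn2
  s <- ifelse(denom > 0, lam^2 * a^2 / denom, 0)
  n <- length(lam)
  K <- min(M, n)
  idx <- which(s > 0)
  best <- sum(lam)
  if (length(idx) == 0L) return(best)
  for (k in seq_len(min(K, length(idx)))) {
    for (S in utils::combn(idx, k, simplify = FALSE)) {
      if (k == 1L) {
        best <- min(best, sum(lam) - s[S] * P / (P + sd2))
        next
      }
      sS <- s[S]
      fn <- function(theta) {
        w <- exp(theta - max(theta))
        p <- P * w / sum(w)
        sum(lam) - sum(sS * p / (p + sd2))
      }
      gr <- function(theta) {
        w <- exp(theta - max(theta))
        p <- P * w / sum(w)
        dmse_dp <- -sS * sd2 / (p + sd2)^2
        dmse_dp * p - sum(dmse_dp * p) * p / P
      }
      res <- stats::optim(rep(0, k), fn, gr, method = "BFGS",
                          control = list(maxit = 1000, reltol = 1e-15))
      best <- min(best, res$value)
    }
  }
  best
}

# Wiener decoder and expected MSE with fully materialized covariances -- the
# brute-force check of the package's spectral factorization path.
oracle_wiener_dense <- function(W, signal, a, sn2, sd2) {
  E <- basis_columns(signal)
  Sigma_s <- E %*% (signal$spectrum * t(E))
  A <- E %*% (a * t(E))
  Sigma_x <- A %*% Sigma_s %*% t(A) + sn2 * diag(signal$n)
  Cm <- W %*% Sigma_x %*% t(W) + sd2 * diag(nrow(W))
  J <- Sigma_s %*% t(A) %*% t(W)
  G <- J %*% solve(Cm)
  mse <- sum(diag(Sigma_s)) - sum(diag(G %*% t(J)))
  list(G = G, expected_mse = mse)
}

# Expected MSE of an arbitrary (possibly suboptimal) linear readout G.
oracle_readout_mse <- function(G, W, signal, a, sn2, sd2) {
  E <- basis_columns(signal)
  Sigma_s <- E %*% (signal$spectrum * t(E))
  A <- E %*% (a * t(E))
  Sigma_x <- A %*% Sigma_s %*% t(A) + sn2 * diag(signal$n)
  Cm <- W %*% Sigma_x %*% t(W) + sd2 * diag(nrow(W))
  J <- Sigma_s %*% t(A) %*% t(W)
  sum(diag(Sigma_s)) - 2 * sum(diag(G %*% t(J))) + sum(diag(G %*% Cm %*% t(G)))
}

# Random small coding problem (N <= 8) with a custom spectrum and blur.
random_small_problem <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(2:8, 1)
    lam <- sort(stats::rchisq(n, df = 3), decreasing = TRUE) + 0.05
    a <- stats::runif(n, 0.1, 1.5)
    if (n > 2 && stats::runif(1) < 0.3) a[n] <- 0   # occasional dead component
    sn2 <- stats::runif(1, 0, 1)
    sd2 <- stats::runif(1, 0.3, 2)
    M <- sample.int(n, 1)
    snr <- stats::runif(1, 0, 12)
    sig <- spectral_covariance(lam)
    pr <- coding_problem(sig, blur_model(a), M = M, sensory_variance = sn2,
                         neural_snr_db = snr, sigma_delta2 = sd2)
    pr
  })
}

# The standard spectral-analysis configuration: 100-dimensional 1/f^2 signal
# with a unit-pixel gaussian low-pass blur.
fig_style_problem <- function(M, sensory_snr_db, neural_snr_db = 10) {
  sig <- powerlaw_covariance_1d(100)
  bl <- gaussian_blur(sig, 1)
  coding_problem(sig, bl, M = M, sensory_snr_db = sensory_snr_db,
                 neural_snr_db = neural_snr_db)
}

mean_center_count <- function(summaries) {
  mean(vapply(summaries, `[[`, numeric(1), "center_pixel_count"))
}
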