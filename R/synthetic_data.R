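# Synthetic inputs: gaussian and sparse textures with prescribed spectra,
# degraded observations, and the two-pixel toy problem.  All generators are
# pure functions of (specification, seed).

#' Texture specification
#'
#' @param signal A [spectral_covariance] defining the texture statistics.
#' @param family `"gaussian"` (spectral coefficients iid normal) or
#'   `"sparse_source"` (iid generalized gaussian with exponent
#'   `sparse_exponent`, unit variance -- heavy-tailed coefficients that make
#'   the response-sparsity cost non-degenerate).
#' @param sparse_exponent Shape exponent `q` of the sparse family (default 0.7).
#' @param seed Integer seed.
#' @return An object of class `texture_spec`.
#' @export
texture_spec <- function(signal, family = c("gaussian", "sparse_source"),
                         sparse_exponent = 0.7, seed = 1) {
  stopifnot(inherits(signal, "spectral_covariance"))
  family <- match.arg(family)
  if (sparse_exponent <= 0) stop("texture_spec: sparse_exponent must be > 0")
  structure(list(signal = signal, family = family,
                 sparse_exponent = sparse_exponent, seed = as.integer(seed)),
            class = "texture_spec")
}

# Unit-variance generalized gaussian draws, density prop. to exp(-|x/alpha|^q):
# |X|^q ~ Gamma(1/q, scale alpha^q), with alpha set so Var = 1.
rgen_gaussian <- function(n, q) {
  alpha <- sqrt(gamma(1 / q) / gamma(3 / q))
  mag <- alpha * stats::rgamma(n, shape = 1 / q, scale = 1)^(1 / q)
  mag * sample(c(-1, 1), n, replace = TRUE)
}

#' Sample textures with a prescribed covariance
#'
#' Draws `s = E diag(sqrt(lambda)) u` with iid unit-variance coefficients `u`
#' (normal or generalized gaussian per the spec family).  Components with zero
#' spectrum (e.g. DC) get exactly zero coefficients, so all samples are
#' zero-mean.  Reproducible bit-exactly for a fixed spec.
#'
#' @param spec A [texture_spec].
#' @param n Number of samples (>= 1).
#' @return `N x n` matrix, one texture per column.
#' @export
sample_textures <- function(spec, n) {
  stopifnot(inherits(spec, "texture_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("sample_textures: n must be >= 1")
  sig <- spec$signal
  pos <- which(sig$spectrum > 0)
  if (length(pos) == 0L) return(matrix(0, sig$n, n))
  U <- withr::with_seed(spec$seed, {
    draws <- if (spec$family == "gaussian") {
      stats::rnorm(length(pos) * n)
    } else {
      rgen_gaussian(length(pos) * n, spec$sparse_exponent)
    }
    matrix(draws, length(pos), n)
  })
  basis_columns(sig, pos) %*% (sqrt(sig$spectrum[pos]) * U)
}

#' Degrade signal samples through blur and sensory noise
#'
#' Applies the sensing stage `x = A s + n`: spectral blur co-diagonal with the
#' signal eigenbasis, then seeded white gaussian sensory noise of variance
#' `sigma_n2`.
#'
#' @param samples `N x n` matrix of original-signal samples.
#' @param signal The [spectral_covariance] providing the eigenbasis for the
#'   blur.
#' @param blur A [blur_model] or `NULL` (no blur).
#' @param sigma_n2 Sensory noise variance (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return `N x n` matrix of observed samples.
#' @export
degrade <- function(samples, signal, blur = NULL, sigma_n2 = 0, seed = 1) {
  stopifnot(is.matrix(samples), inherits(signal, "spectral_covariance"),
            nrow(samples) == signal$n)
  x <- samples
  if (!is.null(blur) && any(blur$gains != 1)) {
    E <- basis_columns(signal)
    x <- E %*% (blur$gains * crossprod(E, samples))
  }
  if (sigma_n2 > 0) {
    noise <- withr::with_seed(seed, {
      matrix(stats::rnorm(length(x), sd = sqrt(sigma_n2)), nrow(x), ncol(x))
    })
    x <- x + noise
  }
  x
}

#' Two-pixel toy coding problem
#'
#' The minimal signal for characterizing the optimal code: `N = 2` with
#' covariance `[[1, rho], [rho, 1]]` (eigenbasis the 45-degree rotation,
#' spectrum `1 + rho`, `1 - rho`) and no blur.  With strong correlation and a
#' tight budget, both encoder rows align with the first principal component --
#' the maximally redundant "repetitive" code in which two neurons share one
#' receptive field.
#'
#' @param rho Pixel correlation, `|rho| < 1`.
#' @param sensory_snr_db Sensory SNR in dB (`Inf` for noiseless sensing).
#' @param neural_snr_db Neural SNR per neuron in dB (default 10).
#' @param M Population size (1 undercomplete, 2 complete, 3 overcomplete).
#' @return A [coding_problem].
#' @export
toy2d_problem <- function(rho, sensory_snr_db = Inf, neural_snr_db = 10, M = 2) {
  if (abs(rho) >= 1) stop("toy2d_problem: |rho| must be < 1")
  E <- cbind(c(1, 1) / sqrt(2), c(1, -1) / sqrt(2))
  lam <- c(1 + rho, 1 - rho)
  if (rho < 0) {                      # keep spectrum descending
    lam <- rev(lam)
    E <- E[, 2:1]
  }
  sig <- new_spectral_covariance(2L, lam, c(1, 2), "dense", basis = E,
                                 origin = sprintf("toy2d(rho=%g)", rho))
  coding_problem(sig, blur = NULL, M = M, sensory_snr_db = sensory_snr_db,
                 neural_snr_db = neural_snr_db)
}
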