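# The MSE-optimal linear code and its whitening baseline.
#
# With all covariances co-diagonal in the signal eigenbasis, the expected
# reconstruction MSE decomposes per spectral component.  Component i of the
# observed signal carries recoverable power s_i = lambda_i^2 a_i^2 /
# (a_i^2 lambda_i + sigma_n^2), and allocating encoded-response power p_i to it
# leaves residual lambda_i - s_i p_i / (p_i + sigma_delta^2).  Minimizing the
# total residual subject to sum(p) = P and at most min(M, N) active components
# is a classic water-filling problem with the closed-form KKT solution
# p_i = max(0, sqrt(s_i sigma_delta^2 / mu) - sigma_delta^2).

#' Per-component recoverable power
#'
#' The maximum reduction of expected MSE attainable on one spectral component
#' with unbounded encoding power: `s = lambda^2 a^2 / (a^2 lambda + sigma_n^2)`.
#' A component with zero blur gain and zero sensory noise is unobservable and
#' returns 0.
#'
#' @param lambda Signal variance of the component (>= 0).
#' @param a Blur gain (>= 0).
#' @param sigma_n2 Sensory noise variance (>= 0).
#' @return Recoverable power `s`, vectorized over the inputs.
#' @export
recoverable_power <- function(lambda, a, sigma_n2) {
  denom <- a^2 * lambda + sigma_n2
  ifelse(denom > 0, lambda^2 * a^2 / denom, 0)
}

#' Water-filling power allocation of the optimal encoder
#'
#' Minimizes the expected reconstruction MSE
#' `sum_i (lambda_i - s_i p_i / (p_i + sigma_delta^2))` over per-component
#' encoded powers `p_i >= 0` with `sum(p) = P` and at most `min(M, N)` active
#' components.  The water level `mu` is found by bisection on the monotone
#' budget function; candidate components are ranked by recoverable power
#' (descending, ties by ascending frequency) so the output is deterministic.
#'
#' @param problem A [coding_problem].
#' @return An object of class `power_allocation` with fields `power` (length-N
#'   encoded variance per component), `gains` (encoding spectral gains
#'   `g_i = sqrt(p_i / (a_i^2 lambda_i + sigma_n^2))`), `active` (indices with
#'   `p_i > 0`), `slots` (component index per encoder diagonal slot),
#'   `water_level`, `P`, and `M`.
#' @export
waterfill_allocation <- function(problem) {
  stopifnot(inherits(problem, "coding_problem"))
  lam <- problem$signal$spectrum
  a <- problem$blur
  sn2 <- problem$sigma_n2
  sd2 <- problem$sigma_delta2
  P <- problem$P
  n <- problem$signal$n
  s <- recoverable_power(lam, a, sn2)
  K <- min(problem$M, n)
  f <- problem$signal$frequency
  tie <- if (anyNA(f)) seq_len(n) else f
  cand <- order(-s, tie, seq_len(n))[seq_len(K)]
  cand <- cand[s[cand] > 0]
  if (length(cand) == 0L) {
    stop("waterfill_allocation: no component has recoverable power; infeasible")
  }
  sc <- s[cand]
  budget <- function(mu) sum(pmax(0, sqrt(sc * sd2 / mu) - sd2))
  hi <- max(sc) / sd2            # budget(hi) = 0
  lo <- hi
  while (budget(lo) < P) lo <- lo / 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (budget(mid) > P) lo <- mid else hi <- mid
    if (abs(budget(mid) - P) <= 1e-12 * P) break
  }
  mu <- (lo + hi) / 2
  pc <- pmax(0, sqrt(sc * sd2 / mu) - sd2)
  pc <- pc * (P / sum(pc))       # budget met exactly
  p <- numeric(n)
  p[cand] <- pc
  g <- numeric(n)
  denom <- a^2 * lam + sn2
  g[cand] <- sqrt(pc / denom[cand])
  structure(list(power = p, gains = g, active = which(p > 0), slots = cand,
                 water_level = mu, P = P, M = problem$M),
            class = "power_allocation")
}

#' @export
print.power_allocation <- function(x, ...) {
  cat(sprintf("<power_allocation> P = %.4g over %d active of %d components (M = %d)\n",
              x$P, length(x$active), length(x$power), x$M))
  invisible(x)
}

is_orthogonal <- function(V, tol = 1e-8) {
  is.matrix(V) && nrow(V) == ncol(V) &&
    max(abs(crossprod(V) - diag(nrow(V)))) < tol
}

# Random orthogonal matrix: QR of a seeded gaussian matrix with the sign fix
# that makes the distribution Haar and the result reproducible.
random_orthogonal <- function(M, seed = NULL) {
  draw <- function() {
    qr_ <- qr(matrix(stats::rnorm(M * M), M, M))
    Q <- qr.Q(qr_)
    d <- sign(diag(qr.R(qr_)))
    d[d == 0] <- 1
    Q %*% diag(d, M)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Assemble an encoding matrix from a power allocation
#'
#' The optimal encoder factorizes as `W = V Lambda E'` where `E` is the signal
#' eigenbasis, `Lambda` is the rectangular diagonal matrix of encoding gains,
#' and `V` is an arbitrary M-dimensional orthogonal matrix -- the degenerate
#' degree of freedom that resource constraints later resolve.  Any orthogonal
#' `V` leaves the expected MSE and the total encoded power unchanged.
#'
#' @param allocation A [power_allocation].
#' @param basis The [spectral_covariance] providing the eigenbasis.
#' @param V An `M x M` orthogonal matrix (default identity).
#' @return An object of class `encoder_solution` with fields `W` (`M x N`),
#'   `V`, `slots`, `slot_gains`, `allocation`, `basis`, `kind = "optimal"`.
#' @export
assemble_encoder <- function(allocation, basis, V = NULL) {
  stopifnot(inherits(allocation, "power_allocation"),
            inherits(basis, "spectral_covariance"))
  M <- allocation$M
  if (is.null(V)) V <- diag(M)
  if (!is_orthogonal(V)) stop("assemble_encoder: V is not orthogonal (tol 1e-8)")
  slots <- allocation$slots
  g <- allocation$gains[slots]
  E_act <- basis_columns(basis, slots)
  B <- g * t(E_act)                       # K x N rows g_i e_i'
  W <- V[, seq_along(slots), drop = FALSE] %*% B
  structure(list(W = W, V = V, slots = slots, slot_gains = g,
                 allocation = allocation, basis = basis, kind = "optimal"),
            class = "encoder_solution")
}

#' @export
print.encoder_solution <- function(x, ...) {
  cat(sprintf("<encoder_solution> %s, M = %d, N = %d, %d active slots\n",
              x$kind, nrow(x$W), ncol(x$W), length(x$slots)))
  invisible(x)
}

# Encoded-signal variance per diagonal slot: g_i^2 (a_i^2 lambda_i + sigma_n^2).
slot_power <- function(encoder, problem) {
  i <- encoder$slots
  encoder$slot_gains^2 *
    (problem$blur[i]^2 * problem$signal$spectrum[i] + problem$sigma_n2)
}

#' Encoded-signal row variances (per neuron)
#'
#' Diagonal of `W Sigma_x W'` computed through the spectral factorization,
#' i.e. each neuron's pre-neural-noise response variance.
#'
#' @param encoder An [encoder_solution].
#' @param problem The matching [coding_problem].
#' @return Numeric vector of length `M`.
#' @export
neuron_variances <- function(encoder, problem) {
  p <- slot_power(encoder, problem)
  Va <- encoder$V[, seq_along(encoder$slots), drop = FALSE]
  as.vector((Va^2) %*% p)
}

#' Whitening (redundancy reduction) baseline encoder
#'
#' The whitening code removes all second-order structure of the blurred
#' signal: `W (A Sigma_s A') W' = c^2 I_M`, computed on the top-M principal
#' components of the blurred signal, with the scalar `c` chosen so that the
#' total encoded power meets the same neural capacity budget `P` as the
#' optimal model.  Whitening ignores sensory noise: its shape is independent
#' of `sigma_n^2` up to the scale factor.
#'
#' @param problem A [coding_problem] with `M` at most the number of positive
#'   blurred-signal eigenvalues.
#' @return An `encoder_solution` with `kind = "whitening"` and the scale
#'   stored as `c2`.
#' @export
whitening_encoder <- function(problem) {
  stopifnot(inherits(problem, "coding_problem"))
  lam <- problem$signal$spectrum
  a <- problem$blur
  b <- a^2 * lam
  n <- problem$signal$n
  M <- problem$M
  npos <- sum(b > 0)
  if (M > npos) {
    stop(sprintf("whitening_encoder: M = %d exceeds the %d positive blurred-signal eigenvalues",
                 M, npos))
  }
  f <- problem$signal$frequency
  tie <- if (anyNA(f)) seq_len(n) else f
  slots <- order(-b, tie, seq_len(n))[seq_len(M)]
  c2 <- problem$P / sum((b[slots] + problem$sigma_n2) / b[slots])
  g <- sqrt(c2 / b[slots])
  B <- g * t(basis_columns(problem$signal, slots))
  structure(list(W = B, V = diag(M), slots = slots, slot_gains = g,
                 allocation = NULL, basis = problem$signal, kind = "whitening",
                 c2 = c2),
            class = "encoder_solution")
}

#' Wiener decoder and closed-form expected MSE
#'
#' The minimum-MSE linear readout of the original signal from the neural
#' representation `r = W x + delta`:
#' `G = Sigma_s A' W' (W Sigma_x W' + sigma_delta^2 I)^{-1}`, with expected
#' MSE `tr(Sigma_s) - tr(Sigma_s A' W' (...)^{-1} W A Sigma_s)`.  Exploits the
#' spectral factorization of the encoder so no `N x N` matrix is formed.
#'
#' @param encoder An [encoder_solution] (optimal or whitening).
#' @param problem The matching [coding_problem].
#' @return An object of class `decoder_solution` with fields `G` (`N x M`),
#'   `expected_mse`, `percent_error` (100 * mse / tr(Sigma_s)), and
#'   `component_gain` (decoding spectral gain per slot).
#' @export
wiener_decoder <- function(encoder, problem) {
  stopifnot(inherits(encoder, "encoder_solution"),
            inherits(problem, "coding_problem"))
  lam <- problem$signal$spectrum
  a <- problem$blur
  if (ncol(encoder$W) != problem$signal$n || nrow(encoder$W) != problem$M) {
    stop("wiener_decoder: encoder dimensions do not match problem")
  }
  i <- encoder$slots
  g <- encoder$slot_gains
  p <- slot_power(encoder, problem)
  Va <- encoder$V[, seq_along(i), drop = FALSE]
  # C = W Sigma_x W' + sd2 I = Va diag(p) Va' + sd2 I
  C <- Va %*% (p * t(Va)) + diag(problem$sigma_delta2, problem$M)
  # F = Sigma_s A' W' in spectral rows: nonzero rows at slots, values
  # lambda_i a_i g_i * Va'.
  fa <- lam[i] * a[i] * g
  Fs <- fa * t(Va)                       # K x M
  Minv <- solve((C + t(C)) / 2)
  GM <- Fs %*% Minv                      # K x M
  expected_mse <- sum(lam) - sum(GM * Fs)
  G <- basis_columns(problem$signal, i) %*% GM
  # decoding gain along each active component (co-diagonal when V arbitrary):
  comp_gain <- fa / (p + problem$sigma_delta2)
  structure(list(G = G, expected_mse = expected_mse,
                 percent_error = 100 * expected_mse / sum(lam),
                 component_gain = comp_gain, slots = i),
            class = "decoder_solution")
}

#' @export
print.decoder_solution <- function(x, ...) {
  cat(sprintf("<decoder_solution> expected MSE = %.6g (%.1f%% of signal variance)\n",
              x$expected_mse, x$percent_error))
  invisible(x)
}

#' Infinite-capacity lower bound on the expected MSE
#'
#' The Wiener bound reached as the population size and power budget grow
#' without limit: `sum_i (lambda_i - s_i)`.  No loss occurs in the neural
#' representation, but the error inherent to sensory noise and blur remains.
#'
#' @param problem A [coding_problem].
#' @return Scalar lower bound on the expected MSE.
#' @export
expected_mse_limit <- function(problem) {
  lam <- problem$signal$spectrum
  s <- recoverable_power(lam, problem$blur, problem$sigma_n2)
  sum(lam - s)
}

#' Solve a coding problem end to end
#'
#' Convenience wrapper: water-filling allocation, encoder assembly with a
#' chosen (default identity) orthogonal factor, and Wiener decoder.
#'
#' @param problem A [coding_problem].
#' @param V Optional `M x M` orthogonal factor (default identity).
#' @return List with `allocation`, `encoder`, `decoder`.
#' @export
solve_coding_problem <- function(problem, V = NULL) {
  alloc <- waterfill_allocation(problem)
  enc <- assemble_encoder(alloc, problem$signal, V)
  dec <- wiener_decoder(enc, problem)
  list(allocation = alloc, encoder = enc, decoder = dec)
}

#' Simulate encoding and decoding of signal samples
#'
#' Passes samples through the full pipeline `x = A s + n`,
#' `r = W x + delta`, `s_hat = G r` with seeded gaussian noise draws, and
#' reports the empirical reconstruction error, which converges to the
#' closed-form expected MSE.
#'
#' @param encoder An [encoder_solution].
#' @param decoder A [decoder_solution].
#' @param problem The matching [coding_problem].
#' @param samples `N x n` matrix of original-signal samples (one per column).
#' @param seed Integer seed controlling both noise draws.
#' @return List with `reconstructed` (`N x n`), `empirical_mse`, and
#'   `percent_error`.
#' @export
encode_decode_samples <- function(encoder, decoder, problem, samples, seed = 1) {
  stopifnot(is.matrix(samples), nrow(samples) == problem$signal$n)
  x <- degrade(samples, problem$signal, blur_model(problem$blur),
               problem$sigma_n2, seed = seed)
  nsamp <- ncol(samples)
  delta <- withr::with_seed(seed + 1L, {
    matrix(stats::rnorm(problem$M * nsamp, sd = sqrt(problem$sigma_delta2)),
           problem$M, nsamp)
  })
  r <- encoder$W %*% x + delta
  shat <- decoder$G %*% r
  emp_mse <- mean(colSums((samples - shat)^2))
  list(reconstructed = shat, empirical_mse = emp_mse,
       percent_error = 100 * emp_mse / sum(problem$signal$spectrum))
}
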