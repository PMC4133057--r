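# Signal statistics, blur, and noise: the generative side of the coding model.
#
# The original signal s (N pixels) has covariance Sigma_s = E Lambda Et with an
# orthonormal eigenbasis E and a nonnegative power spectrum lambda_i.  The
# observed signal is x = A s + n with a blur A co-diagonal with E and white
# sensory noise n.  Everything downstream (water-filling, Wiener decoding,
# whitening) works in this co-diagonal spectral representation, so covariances
# are stored compactly and the N x N basis is materialized only on demand.

#' Pixel-grid geometry
#'
#' A rectangular lattice of sensory units (pixels / photoreceptors).  The
#' signal dimension is `n = height * width`.
#'
#' @param height,width Positive integer numbers of rows and columns.
#' @return An object of class `grid_geometry` with fields `height`, `width`,
#'   and `n`.
#' @examples
#' g <- grid_geometry(15, 15)
#' g$n  # 225 sensory units
#' @export
grid_geometry <- function(height, width = height) {
  height <- as.integer(height)
  width <- as.integer(width)
  if (is.na(height) || is.na(width) || height < 1L || width < 1L) {
    stop("grid_geometry: 'height' and 'width' must be integers >= 1")
  }
  structure(list(height = height, width = width, n = height * width),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d (n = %d)\n", x$height, x$width, x$n))
  invisible(x)
}

# Enumerate the real 2-D Fourier components of an H x W grid.
#
# Complex DFT frequencies (fy, fx) are grouped into conjugate classes
# {(fy, fx), (-fy mod H, -fx mod W)}.  A self-conjugate class (DC and Nyquist
# combinations) contributes one +/-1-valued cosine vector; every other class
# contributes a cosine and a sine vector, making the basis real-orthonormal.
# Components are ordered by increasing frequency magnitude, ties broken by
# (fy, fx) of the lexicographically smaller class member, cosine before sine.
fourier_component_table <- function(height, width) {
  H <- height; W <- width; N <- H * W
  seen <- matrix(FALSE, H, W)
  fy <- integer(N); fx <- integer(N); part <- character(N); fmag <- numeric(N)
  m <- 0L
  for (i in 0:(H - 1L)) {
    for (j in 0:(W - 1L)) {
      if (seen[i + 1L, j + 1L]) next
      ci <- (H - i) %% H
      cj <- (W - j) %% W
      seen[i + 1L, j + 1L] <- TRUE
      seen[ci + 1L, cj + 1L] <- TRUE
      f <- sqrt((min(i, H - i) / H)^2 + (min(j, W - j) / W)^2)
      m <- m + 1L
      fy[m] <- i; fx[m] <- j; part[m] <- "cos"; fmag[m] <- f
      if (!(ci == i && cj == j)) {
        m <- m + 1L
        fy[m] <- i; fx[m] <- j; part[m] <- "sin"; fmag[m] <- f
      }
    }
  }
  stopifnot(m == N)
  ord <- order(fmag, fy, fx, match(part, c("cos", "sin")))
  data.frame(fy = fy[ord], fx = fx[ord], part = part[ord], f = fmag[ord],
             stringsAsFactors = FALSE)
}

# Materialize selected columns of the real 2-D Fourier basis (pixels are in
# column-major order, y fastest, matching R matrices).
fourier_basis_columns <- function(grid, tab, idx) {
  H <- grid$height; W <- grid$width; N <- grid$n
  y <- 0:(H - 1L); x <- 0:(W - 1L)
  out <- matrix(0, N, length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    ph <- 2 * pi * outer(y * (tab$fy[i] / H), x * (tab$fx[i] / W), "+")
    ci <- (H - tab$fy[i]) %% H
    cj <- (W - tab$fx[i]) %% W
    selfconj <- (ci == tab$fy[i] && cj == tab$fx[i])
    if (tab$part[i] == "cos") {
      v <- cos(ph)
      v <- v / if (selfconj) sqrt(N) else sqrt(N / 2)
    } else {
      v <- sin(ph) / sqrt(N / 2)
    }
    out[, k] <- as.vector(v)
  }
  out
}

new_spectral_covariance <- function(n, spectrum, frequency, basis_type,
                                    grid = NULL, table = NULL, basis = NULL,
                                    origin = "unspecified") {
  stopifnot(length(spectrum) == n, length(frequency) == n)
  if (any(spectrum < 0)) stop("spectral_covariance: negative spectrum entries")
  structure(list(n = n, spectrum = spectrum, frequency = frequency,
                 basis_type = basis_type, grid = grid, table = table,
                 basis = basis, origin = origin),
            class = "spectral_covariance")
}

#' @export
print.spectral_covariance <- function(x, ...) {
  cat(sprintf("<spectral_covariance> n = %d, basis = %s, origin = %s\n",
              x$n, x$basis_type, x$origin))
  cat(sprintf("  trace = %.6g, positive components = %d\n",
              sum(x$spectrum), sum(x$spectrum > 0)))
  invisible(x)
}

#' Construct a spectral covariance directly
#'
#' Defines signal statistics from an explicit power spectrum and (optionally)
#' an explicit orthonormal eigenbasis.  With `basis = NULL` the identity basis
#' is used, i.e. the signal is expressed in its own spectral coordinates.
#'
#' @param spectrum Nonnegative component variances.
#' @param frequency Optional per-component frequency index (defaults to the
#'   component rank).
#' @param basis Optional dense orthonormal eigenbasis (columns = modes).
#' @param grid Optional [grid_geometry] when components map to a pixel grid.
#' @return A `spectral_covariance`.
#' @export
spectral_covariance <- function(spectrum, frequency = NULL, basis = NULL,
                                grid = NULL) {
  n <- length(spectrum)
  if (is.null(frequency)) frequency <- as.numeric(seq_len(n))
  if (is.null(basis)) {
    return(new_spectral_covariance(n, spectrum, frequency, "identity",
                                   grid = grid, origin = "custom"))
  }
  basis <- as.matrix(basis)
  if (nrow(basis) != n || ncol(basis) != n ||
      max(abs(crossprod(basis) - diag(n))) > 1e-8) {
    stop("spectral_covariance: basis must be an orthonormal n x n matrix")
  }
  new_spectral_covariance(n, spectrum, frequency, "dense", grid = grid,
                          basis = basis, origin = "custom")
}

#' Materialize eigenbasis columns of a spectral covariance
#'
#' Returns the requested columns of the orthonormal eigenbasis `E` as a dense
#' `n x length(idx)` matrix.  Fourier bases are computed on demand so that
#' large problems (e.g. 121 x 121 grids) never hold the full `N x N` matrix.
#'
#' @param cov A [spectral_covariance] object.
#' @param idx Integer component indices (default: all).
#' @return Numeric matrix with one column per requested component.
#' @export
basis_columns <- function(cov, idx = seq_len(cov$n)) {
  stopifnot(inherits(cov, "spectral_covariance"))
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > cov$n)) stop("basis_columns: index out of range")
  switch(cov$basis_type,
    fourier2d = fourier_basis_columns(cov$grid, cov$table, idx),
    identity = {
      out <- matrix(0, cov$n, length(idx))
      out[cbind(idx, seq_along(idx))] <- 1
      out
    },
    dense = cov$basis[, idx, drop = FALSE],
    stop("unknown basis type: ", cov$basis_type)
  )
}

#' Power-law (1/f^gamma) signal covariance on a 2-D pixel grid
#'
#' Builds the stationary gaussian signal model used throughout: the eigenbasis
#' is the real two-dimensional discrete Fourier basis of the grid and the power
#' spectrum falls as `1/f^exponent` over nonzero spatial frequencies.  The DC
#' component is set to exactly zero (the signal is zero-mean), and the spectrum
#' is normalized so that the total signal variance equals the number of pixels
#' (unit variance per pixel on average), which makes percent errors and SNR
#' settings comparable across grid sizes.
#'
#' @param grid A [grid_geometry].
#' @param exponent Positive spectral decay exponent (2 for natural-image-like
#'   1/f^2 power).
#' @return A `spectral_covariance` with fields `spectrum` (variances),
#'   `frequency` (cycles/pixel per component), and an implicit Fourier basis.
#' @examples
#' sc <- make_powerlaw_spectrum(grid_geometry(8, 8))
#' sum(sc$spectrum)        # 64: unit average pixel variance
#' sc$spectrum[sc$frequency == 0]  # DC variance is 0
#' @export
make_powerlaw_spectrum <- function(grid, exponent = 2) {
  stopifnot(inherits(grid, "grid_geometry"))
  if (!is.numeric(exponent) || length(exponent) != 1L || exponent <= 0) {
    stop("make_powerlaw_spectrum: 'exponent' must be a positive number")
  }
  tab <- fourier_component_table(grid$height, grid$width)
  lam <- ifelse(tab$f > 0, tab$f^(-exponent), 0)
  if (sum(lam) > 0) lam <- lam * (grid$n / sum(lam))
  new_spectral_covariance(grid$n, lam, tab$f, "fourier2d", grid = grid,
                          table = tab, origin = sprintf("powerlaw(%g)", exponent))
}

#' Idealized one-dimensional power-law spectral signal
#'
#' An abstract n-component signal whose components are ordered by frequency
#' `f_i = i/(2n)` (up to Nyquist 0.5) with spectrum proportional to
#' `1/f^exponent`; the eigenbasis is the identity, i.e. the signal is already
#' expressed in its spectral coordinates.  This is the idealized model signal
#' used for spectral-stage analysis: it has no DC component, so the whitening
#' baseline is defined even in the complete case.  Normalized to `trace = n`.
#'
#' @param n Number of spectral components.
#' @param exponent Positive spectral decay exponent.
#' @return A `spectral_covariance` with an identity basis.
#' @export
powerlaw_covariance_1d <- function(n, exponent = 2) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("powerlaw_covariance_1d: 'n' must be >= 1")
  if (!is.numeric(exponent) || length(exponent) != 1L || exponent <= 0) {
    stop("powerlaw_covariance_1d: 'exponent' must be a positive number")
  }
  f <- seq_len(n) / (2 * n)
  lam <- f^(-exponent)
  lam <- lam * (n / sum(lam))
  new_spectral_covariance(n, lam, f, "identity",
                          origin = sprintf("powerlaw1d(%g)", exponent))
}

#' Empirical signal covariance from image patches
#'
#' Estimates the signal covariance from zero-meaned sample patches and
#' eigendecomposes it into an orthonormal basis plus spectrum, eigenvalues
#' sorted in descending order.  Eigenvalues below `1e-12 * max` (including
#' small negative round-off) are clipped to zero so the result is positive
#' semidefinite.
#'
#' @param patches Numeric matrix with one patch per row (columns = pixels), or
#'   a list of equal-length numeric vectors.
#' @param grid Optional [grid_geometry] recording the patch shape.
#' @return A `spectral_covariance` with a dense eigenbasis.  The
#'   `frequency` field is `NA`: generic eigenvectors carry no spatial
#'   frequency interpretation.
#' @export
empirical_covariance <- function(patches, grid = NULL) {
  if (is.list(patches) && !is.data.frame(patches)) {
    len <- vapply(patches, length, integer(1))
    if (length(unique(len)) != 1L) {
      stop("empirical_covariance: patches have inconsistent sizes")
    }
    patches <- do.call(rbind, patches)
  }
  patches <- as.matrix(patches)
  n <- ncol(patches)
  if (!is.null(grid) && grid$n != n) {
    stop("empirical_covariance: grid size does not match patch length")
  }
  C <- crossprod(patches) / nrow(patches)
  eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- eg$values
  lam[lam < 1e-12 * max(lam, 0)] <- 0
  new_spectral_covariance(n, lam, rep(NA_real_, n), "dense", grid = grid,
                          basis = eg$vectors, origin = "empirical")
}

#' Blur model (spectral modulation transfer function)
#'
#' A linear distortion of the sensing stage (e.g. optical blur) acting as a
#' circular convolution, i.e. co-diagonal with the signal eigenbasis, so it is
#' fully described by one nonnegative gain per spectral component.
#'
#' @param gains Nonnegative, finite spectral gains, one per component.
#' @return An object of class `blur_model`.
#' @seealso [gaussian_blur()] for the parametric low-pass family.
#' @export
blur_model <- function(gains) {
  gains <- as.numeric(gains)
  if (any(!is.finite(gains)) || any(gains < 0)) {
    stop("blur_model: gains must be finite and >= 0")
  }
  structure(list(gains = gains), class = "blur_model")
}

#' Gaussian low-pass blur for a spectral signal model
#'
#' The modulation transfer function of an isotropic spatial gaussian kernel
#' with standard deviation `sigma` pixels: `a(f) = exp(-2 pi^2 sigma^2 f^2)`
#' with `f` in cycles/pixel.  `sigma = 0` gives the identity (no blur).
#'
#' @param signal A [spectral_covariance] with known component frequencies.
#' @param sigma Kernel standard deviation in pixels (>= 0).
#' @return A [blur_model].
#' @export
gaussian_blur <- function(signal, sigma) {
  stopifnot(inherits(signal, "spectral_covariance"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("gaussian_blur: 'sigma' must be a single number >= 0")
  }
  if (anyNA(signal$frequency)) {
    stop("gaussian_blur: signal has no frequency index (empirical basis); ",
         "supply explicit gains via blur_model()")
  }
  blur_model(exp(-2 * pi^2 * sigma^2 * signal$frequency^2))
}

identity_blur <- function(n) blur_model(rep(1, n))

#' Sensory noise variance achieving a target sensory SNR
#'
#' The sensory SNR in dB is `10 log10(tr(A Sigma_s A') / (N sigma_n^2))`, the
#' ratio of total blurred-signal power to total sensory-noise power.  Given
#' the signal and blur this solves for the white sensory noise variance.
#'
#' @param signal A [spectral_covariance].
#' @param blur A [blur_model] (or `NULL` for no blur).
#' @param snr_db Target sensory SNR in decibels.
#' @return The sensory noise variance `sigma_n^2`.  `snr_db = Inf` gives 0.
#' @export
sensory_noise_for_snr <- function(signal, blur = NULL, snr_db) {
  stopifnot(inherits(signal, "spectral_covariance"))
  a <- if (is.null(blur)) rep(1, signal$n) else blur$gains
  stopifnot(length(a) == signal$n)
  s2 <- sum(a^2 * signal$spectrum)
  if (s2 <= 0) stop("sensory_noise_for_snr: blurred signal has zero power; SNR undefined")
  if (is.infinite(snr_db) && snr_db > 0) return(0)
  s2 / (signal$n * 10^(snr_db / 10))
}

#' Total neural power budget from the per-neuron SNR
#'
#' Each encoding unit carries neural noise of variance `sigma_delta^2`; fixing
#' the neural SNR at `snr_db` per neuron gives each neuron a response variance
#' budget of `sigma_delta^2 * 10^(snr_db/10)`, hence a total population budget
#' `P = M * sigma_delta^2 * 10^(snr_db/10)`.  The budget grows linearly with
#' the population size: this is the mechanism by which added neurons reduce
#' the reconstruction error.
#'
#' @param M Number of encoding units (>= 1).
#' @param sigma_delta2 Neural noise variance (> 0).
#' @param neural_snr_db Neural SNR per neuron in dB.
#' @return Total power budget `P`.
#' @export
neural_power_budget <- function(M, sigma_delta2, neural_snr_db) {
  if (M < 1) stop("neural_power_budget: M must be >= 1")
  if (sigma_delta2 <= 0) stop("neural_power_budget: sigma_delta2 must be > 0")
  M * sigma_delta2 * 10^(neural_snr_db / 10)
}

#' Gaussian-channel information capacity of one unit
#'
#' `(1/2) log2(1 + snr)` bits for a gaussian channel at linear SNR
#' `10^(snr_db/10)`.  At 10 dB this is about 1.7 bits, in the range of
#' measured neural information capacities.
#'
#' @param snr_db SNR in decibels.
#' @return Capacity in bits.
#' @examples
#' round(capacity_bits(10), 1)  # 1.7
#' @export
capacity_bits <- function(snr_db) {
  0.5 * log2(1 + 10^(snr_db / 10))
}

#' Number of encoding units for a sensory-to-neural cell ratio
#'
#' E.g. a 121 x 121 grid at a 16:1 cone-to-RGC ratio yields 915 units.
#'
#' @param n Number of sensory units (pixels).
#' @param ratio Input-to-output cell ratio (sensory units per encoding unit).
#' @return Integer population size, at least 1.
#' @export
population_for_ratio <- function(n, ratio) {
  if (ratio <= 0) stop("population_for_ratio: ratio must be > 0")
  max(1L, as.integer(round(n / ratio)))
}

#' Bundle a complete coding problem
#'
#' Collects the signal statistics, blur, noise levels, population size and
#' total power budget that define one instance of the optimal coding problem.
#' Exactly one of `sensory_snr_db` or `sensory_variance` must be given; the
#' power budget is derived from the per-neuron neural SNR (default 10 dB).
#'
#' @param signal A [spectral_covariance].
#' @param blur A [blur_model], or `NULL` for no blur.
#' @param M Number of encoding units (>= 1).
#' @param sensory_snr_db Sensory SNR in dB (alternative to `sensory_variance`).
#' @param sensory_variance Explicit sensory noise variance `sigma_n^2 >= 0`.
#' @param neural_snr_db Per-neuron neural SNR in dB (default 10).
#' @param sigma_delta2 Neural noise variance (> 0, default 1).
#' @return An object of class `coding_problem` with fields `signal`, `blur`
#'   (gain vector), `sigma_n2`, `sigma_delta2`, `M`, `P`.
#' @export
coding_problem <- function(signal, blur = NULL, M,
                           sensory_snr_db = NULL, sensory_variance = NULL,
                           neural_snr_db = 10, sigma_delta2 = 1) {
  stopifnot(inherits(signal, "spectral_covariance"))
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop("coding_problem: M must be an integer >= 1")
  if (sigma_delta2 <= 0) stop("coding_problem: sigma_delta2 must be > 0")
  a <- if (is.null(blur)) rep(1, signal$n) else blur$gains
  if (length(a) != signal$n) stop("coding_problem: blur gain length != signal dimension")
  if (is.null(sensory_variance) == is.null(sensory_snr_db)) {
    stop("coding_problem: give exactly one of 'sensory_snr_db' or 'sensory_variance'")
  }
  sigma_n2 <- if (!is.null(sensory_variance)) {
    if (sensory_variance < 0) stop("coding_problem: sensory_variance must be >= 0")
    sensory_variance
  } else {
    sensory_noise_for_snr(signal, blur_model(a), sensory_snr_db)
  }
  P <- neural_power_budget(M, sigma_delta2, neural_snr_db)
  structure(list(signal = signal, blur = a, sigma_n2 = sigma_n2,
                 sigma_delta2 = sigma_delta2, M = M, P = P,
                 sensory_snr_db = if (is.null(sensory_snr_db)) NA_real_ else sensory_snr_db,
                 neural_snr_db = neural_snr_db),
            class = "coding_problem")
}

#' @export
print.coding_problem <- function(x, ...) {
  cat(sprintf("<coding_problem> N = %d, M = %d, P = %.4g\n", x$signal$n, x$M, x$P))
  cat(sprintf("  sigma_n2 = %.4g, sigma_delta2 = %.4g, neural SNR = %g dB\n",
              x$sigma_n2, x$sigma_delta2, x$neural_snr_db))
  invisible(x)
}

#' Measured sensory SNR of a problem, in dB
#' @param problem A [coding_problem].
#' @return `10 log10(tr(A Sigma_s A') / (N sigma_n^2))`; `Inf` if noiseless.
#' @export
sensory_snr_db <- function(problem) {
  s2 <- sum(problem$blur^2 * problem$signal$spectrum)
  if (problem$sigma_n2 == 0) return(Inf)
  10 * log10(s2 / (problem$signal$n * problem$sigma_n2))
}
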