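# Spectral-stage analysis and receptive-field characterization.

#' Per-component variances and gains at every coding stage
#'
#' Tabulates, for each spectral component, the variance or gain at every stage
#' of the pipeline: original signal, blur gain, blurred signal, sensory noise,
#' encoding gain, encoded signal, neural noise, decoding gain, and
#' reconstructed-signal variance.  For the optimal model the encoded-signal
#' column sums to the power budget `P`; for whitening the encoded
#' blurred-signal spectrum is constant over the retained components.
#'
#' @param problem A [coding_problem].
#' @param encoder An [encoder_solution].
#' @param decoder The matching [decoder_solution] (optional; recomputed if
#'   missing).
#' @return A data frame of class `stage_spectra`, one row per component,
#'   ordered as the signal components, with columns `component`, `frequency`,
#'   `original`, `blur_gain`, `blurred`, `sensory_noise`, `encoding_gain`,
#'   `encoded`, `neural_noise`, `decoding_gain`, `reconstructed`.
#' @export
stage_spectra <- function(problem, encoder, decoder = NULL) {
  stopifnot(inherits(problem, "coding_problem"),
            inherits(encoder, "encoder_solution"))
  if (is.null(decoder)) decoder <- wiener_decoder(encoder, problem)
  n <- problem$signal$n
  lam <- problem$signal$spectrum
  a <- problem$blur
  g <- numeric(n); g[encoder$slots] <- encoder$slot_gains
  p <- g^2 * (a^2 * lam + problem$sigma_n2)
  dg <- numeric(n); dg[decoder$slots] <- decoder$component_gain
  rec <- dg^2 * (p + problem$sigma_delta2)
  out <- data.frame(
    component = seq_len(n),
    frequency = problem$signal$frequency,
    original = lam,
    blur_gain = a,
    blurred = a^2 * lam,
    sensory_noise = rep(problem$sigma_n2, n),
    encoding_gain = g,
    encoded = p,
    neural_noise = rep(problem$sigma_delta2, n),
    decoding_gain = dg,
    reconstructed = rec
  )
  class(out) <- c("stage_spectra", "data.frame")
  out
}

# 8-connected flood fill from a seed pixel over a logical mask (BFS).
flood_fill8 <- function(mask, seed_y, seed_x) {
  H <- nrow(mask); W <- ncol(mask)
  inside <- matrix(FALSE, H, W)
  if (!mask[seed_y, seed_x]) return(inside)
  queue <- matrix(c(seed_y, seed_x), ncol = 2)
  inside[seed_y, seed_x] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      y <- cur[1] + dy; x <- cur[2] + dx
      if (y >= 1 && y <= H && x >= 1 && x <= W &&
          mask[y, x] && !inside[y, x]) {
        inside[y, x] <- TRUE
        queue <- rbind(queue, c(y, x))
      }
    }
  }
  inside
}

gaussian_smooth_1d <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(v)
  vp <- c(rep(v[1], r), v, rep(v[n], r))
  as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + n)]
}

#' Characterize one receptive field
#'
#' Reshapes a row of the encoding matrix onto the pixel grid and summarizes
#' its center: the peak (maximum-magnitude weight, sign-corrected to be
#' positive), the half-height contour (the 8-connected component around the
#' peak where the weight is at least half the peak value, computed on the raw
#' weights), the number of pixels inside it, and the cross-section through
#' the peak's row (raw, plus a gaussian-smoothed copy for display).
#'
#' @param w Numeric vector of length `geometry$n` (one encoder row).
#' @param geometry The [grid_geometry].
#' @param smooth_sigma Smoothing width in pixels for the displayed
#'   cross-section only (default 0.5; the contour always uses raw weights).
#' @return An object of class `rf_summary`: `peak` (y, x), `peak_value`,
#'   `sign` (+1/-1 polarity at the peak), `contour` (logical H x W mask),
#'   `center_pixel_count`, `cross_section`, `cross_section_smoothed`,
#'   `polarity` (sign map), `field` (the sign-corrected H x W weight map).
#' @export
rf_summary <- function(w, geometry, smooth_sigma = 0.5) {
  stopifnot(inherits(geometry, "grid_geometry"),
            length(w) == geometry$n)
  if (all(w == 0)) stop("rf_summary: all-zero receptive field")
  Wm <- matrix(w, geometry$height, geometry$width)
  k <- which.max(abs(Wm))
  py <- (k - 1L) %% geometry$height + 1L
  px <- (k - 1L) %/% geometry$height + 1L
  s <- sign(Wm[py, px])
  Wc <- s * Wm
  peak <- Wc[py, px]
  contour <- flood_fill8(Wc >= peak / 2, py, px)
  cross <- Wc[py, ]
  structure(list(peak = c(y = py, x = px), peak_value = peak, sign = s,
                 contour = contour, center_pixel_count = sum(contour),
                 cross_section = cross,
                 cross_section_smoothed = gaussian_smooth_1d(cross, smooth_sigma),
                 polarity = sign(Wm), field = Wc),
            class = "rf_summary")
}

#' @export
print.rf_summary <- function(x, ...) {
  cat(sprintf("<rf_summary> peak at (%d, %d), %s polarity, center = %d px\n",
              x$peak["y"], x$peak["x"], if (x$sign > 0) "ON" else "OFF",
              x$center_pixel_count))
  invisible(x)
}

#' Summarize every receptive field of a population
#'
#' All-zero rows (inactive units, possible for an identity orthogonal factor
#' with fewer active components than neurons) are skipped.
#'
#' @param encoder An [encoder_solution] (or a plain `M x N` matrix).
#' @param geometry The [grid_geometry].
#' @param smooth_sigma Passed to [rf_summary()].
#' @return List of `rf_summary` objects, one per nonzero row.
#' @export
population_rf_summaries <- function(encoder, geometry, smooth_sigma = 0.5) {
  W <- if (inherits(encoder, "encoder_solution")) encoder$W else as.matrix(encoder)
  live <- which(rowSums(W != 0) > 0)
  lapply(live, function(j) rf_summary(W[j, ], geometry, smooth_sigma))
}

#' The "typical" receptive field of a population
#'
#' The unit whose peak lies nearest the grid center (used for representative
#' cross-section panels).
#'
#' @param summaries List of [rf_summary] objects.
#' @param geometry The [grid_geometry].
#' @return The selected `rf_summary`.
#' @export
typical_rf <- function(summaries, geometry) {
  if (length(summaries) == 0L) stop("typical_rf: empty population")
  cy <- (geometry$height + 1) / 2
  cx <- (geometry$width + 1) / 2
  d2 <- vapply(summaries, function(s) {
    (s$peak["y"] - cy)^2 + (s$peak["x"] - cx)^2
  }, numeric(1))
  summaries[[which.min(d2)]]
}

#' Classify a receptive field as center-surround
#'
#' A unit is center-surround when its (sign-corrected) half-height center is
#' surrounded by a predominantly negative annulus: the annulus between the
#' effective center radius `r_c = sqrt(count/pi)` and `2 r_c + 2` pixels
#' (toroidal distances, matching the circular-convolution geometry) is split
#' into 8 angular sectors and at least `min_sectors` of them must have
#' negative mean weight.
#'
#' @param summary An [rf_summary].
#' @param geometry The [grid_geometry].
#' @param min_sectors Number of negative sectors required (default 6 of 8).
#' @return Logical.
#' @export
is_center_surround <- function(summary, geometry, min_sectors = 6) {
  H <- geometry$height; W <- geometry$width
  Wc <- summary$field
  py <- summary$peak["y"]; px <- summary$peak["x"]
  rc <- sqrt(summary$center_pixel_count / pi)
  r_in <- rc; r_out <- 2 * rc + 2
  xy <- pixel_coords(geometry)
  dy <- (xy[, 1] + 1 - py + H / 2) %% H - H / 2
  dx <- (xy[, 2] + 1 - px + W / 2) %% W - W / 2
  r <- sqrt(dy^2 + dx^2)
  ann <- r > r_in & r <= r_out
  if (!any(ann)) return(FALSE)
  sector <- floor(((atan2(dy, dx) + pi) / (2 * pi)) * 8) %% 8
  wv <- as.vector(Wc)
  neg <- vapply(0:7, function(sct) {
    i <- ann & sector == sct
    if (!any(i)) return(NA)
    mean(wv[i]) < 0
  }, logical(1))
  sum(neg, na.rm = TRUE) >= min_sectors
}

#' Light-adaptation change of receptive-field center size
#'
#' Percent change in the mean half-height center pixel count between a
#' low-SNR (dark) and a high-SNR (bright) condition on the same grid:
#' `100 * (mean_low / mean_high - 1)`.
#'
#' @param summaries_low List of [rf_summary] at the low sensory SNR.
#' @param summaries_high List of [rf_summary] at the high sensory SNR.
#' @return Percent change (0 for identical populations).
#' @export
adaptation_metric <- function(summaries_low, summaries_high) {
  if (length(summaries_low) == 0L || length(summaries_high) == 0L) {
    stop("adaptation_metric: empty population")
  }
  m_low <- mean(vapply(summaries_low, `[[`, numeric(1), "center_pixel_count"))
  m_high <- mean(vapply(summaries_high, `[[`, numeric(1), "center_pixel_count"))
  100 * (m_low / m_high - 1)
}
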