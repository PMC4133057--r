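# Resolving the orthogonal degeneracy of the optimal encoder.
#
# Every W = V Lambda E' with orthogonal V attains the optimal MSE under the
# total power constraint.  The shaping algorithm picks a V that (i) balances
# the per-neuron response variances to P/M (the individual power constraint)
# and (ii) minimizes an additional resource cost: L1 weight sparsity,
# response sparsity (generalized-gaussian negative log likelihood), or
# spatial locality (distance-weighted squared weights).  Each gradient step in
# the ambient space of W is projected back onto the solution manifold by the
# orthogonal Procrustes solution, so the total power constraint -- and hence
# the optimal expected MSE -- is preserved exactly at every iterate.

#' Resource-cost constraint specification
#'
#' @param kind One of `"none"`, `"weight_sparsity"`, `"response_sparsity"`,
#'   `"locality"`.
#' @param gamma Importance of the resource cost relative to the individual
#'   power constraint (> 0; ignored for `"none"`).
#' @param q Shape exponent of the sparse generalized-gaussian response model
#'   (response sparsity only), in (0, 2].
#' @param locality_squared If `TRUE`, the locality cost penalizes
#'   `d * (w^2)^2` instead of the default `d * w^2` (an alternative reading of
#'   the distance-weighted norm; both are exposed).
#' @return An object of class `constraint_spec`.
#' @export
constraint_spec <- function(kind = c("none", "weight_sparsity",
                                     "response_sparsity", "locality"),
                            gamma = 0.1, q = 0.5, locality_squared = FALSE) {
  kind <- match.arg(kind)
  if (gamma <= 0) stop("constraint_spec: gamma must be > 0")
  if (q <= 0 || q > 2) stop("constraint_spec: q must be in (0, 2]")
  structure(list(kind = kind, gamma = gamma, q = q,
                 locality_squared = isTRUE(locality_squared)),
            class = "constraint_spec")
}

# pixel coordinates of a column-major H x W grid, 0-based
pixel_coords <- function(geometry) {
  H <- geometry$height
  k <- 0:(geometry$n - 1L)
  cbind(y = k %% H, x = k %/% H)
}

# squared pixel distance from every entry to the row's peak-|w| entry
# (ties broken by lowest pixel index, which.max's behavior)
locality_weights <- function(W, geometry) {
  xy <- pixel_coords(geometry)
  D <- matrix(0, nrow(W), ncol(W))
  for (j in seq_len(nrow(W))) {
    k <- which.max(abs(W[j, ]))
    D[j, ] <- (xy[, 1] - xy[k, 1])^2 + (xy[, 2] - xy[k, 2])^2
  }
  D
}

gg_scale <- function(q) sqrt(gamma(1 / q) / gamma(3 / q))

#' Resource cost of an encoding matrix
#'
#' Evaluates the additional constraint cost of a population:
#' * `weight_sparsity`: `sum(|w_jk|)` (L1 norm of all receptive-field weights);
#' * `response_sparsity`: the mean over samples of the negative log likelihood
#'   of the pre-noise responses `z = W x` under a generalized gaussian with
#'   exponent `q` and per-neuron scale `c * sigma_j` (`sigma_j` the response
#'   standard deviation, `c` matching a unit-variance density);
#' * `locality`: `sum_j sum_k d_jk w_jk^2`, `d_jk` the squared pixel distance
#'   from entry `k` to the peak-magnitude entry of row `j`;
#' * `none`: 0.
#'
#' @param W `M x N` encoding matrix.
#' @param spec A [constraint_spec].
#' @param geometry [grid_geometry] (required for `locality`).
#' @param samples `N x n` matrix of observed-signal samples (required for
#'   `response_sparsity`).
#' @return Scalar cost.
#' @export
constraint_cost <- function(W, spec, geometry = NULL, samples = NULL) {
  stopifnot(inherits(spec, "constraint_spec"), is.matrix(W))
  switch(spec$kind,
    none = 0,
    weight_sparsity = sum(abs(W)),
    response_sparsity = {
      if (is.null(samples)) stop("constraint_cost: response_sparsity needs samples")
      z <- W %*% samples
      sdz <- sqrt(rowMeans(z^2))
      sdz[sdz == 0] <- 1e-12
      cq <- gg_scale(spec$q)
      nll_log <- sum(log(2 * cq * sdz * gamma(1 / spec$q) / spec$q))
      mean(colSums((abs(z) / (cq * sdz))^spec$q)) + nll_log
    },
    locality = {
      if (is.null(geometry)) stop("constraint_cost: locality needs geometry")
      D <- locality_weights(W, geometry)
      if (spec$locality_squared) sum(D * W^4) else sum(D * W^2)
    }
  )
}

#' Violation of the per-neuron (individual) power constraint
#'
#' `max_j |(W Sigma_x W')_jj - P/M| / (P/M)`: the largest relative deviation
#' of a neuron's response variance from the common budget share.
#'
#' @param encoder An [encoder_solution], or a raw `M x N` matrix `W`.
#' @param problem The matching [coding_problem].
#' @return Scalar relative violation (>= 0).
#' @export
individual_power_violation <- function(encoder, problem) {
  pbar <- problem$P / problem$M
  v <- if (inherits(encoder, "encoder_solution")) {
    neuron_variances(encoder, problem)
  } else {
    W <- as.matrix(encoder)
    E <- basis_columns(problem$signal)
    U <- W %*% E
    d <- problem$blur^2 * problem$signal$spectrum + problem$sigma_n2
    as.vector(U^2 %*% d)
  }
  max(abs(v - pbar)) / pbar
}

#' Orthogonal Procrustes projection onto the optimal-solution manifold
#'
#' Finds the `M x M` orthogonal `V*` minimizing the Frobenius distance
#' `||V Lambda E' - candidate||_F`, i.e. the point of the optimal-MSE manifold
#' closest to an arbitrary candidate matrix.  Solved algebraically from the
#' SVD of `candidate (Lambda E')'`: `V* = U T'` for SVD factors `U, T`.
#'
#' @param candidate `M x N` matrix to project.
#' @param allocation The frozen [power_allocation] (fixes `Lambda`).
#' @param basis The [spectral_covariance] providing `E`.
#' @return Orthogonal `M x M` matrix `V*`.
#' @export
procrustes_project <- function(candidate, allocation, basis) {
  stopifnot(is.matrix(candidate), inherits(allocation, "power_allocation"))
  M <- allocation$M
  if (nrow(candidate) != M || ncol(candidate) != basis$n) {
    stop("procrustes_project: candidate must be M x N")
  }
  slots <- allocation$slots
  slots <- slots[allocation$gains[slots] > 0]   # zero-gain slots carry nothing
  g <- allocation$gains[slots]
  B <- g * t(basis_columns(basis, slots))       # K x N
  Cm <- candidate %*% t(B)                      # M x K
  K <- ncol(Cm)
  if (K < M) Cm <- cbind(Cm, matrix(0, M, M - K))
  sv <- svd(Cm)
  # deficiency in the first K values is a genuine degeneracy of the
  # candidate; the padded slots (K < M) are structurally zero and silent
  if (min(sv$d[seq_len(K)]) < 1e-12 * max(sv$d, 1e-300)) {
    message("procrustes_project: rank-deficient cross-product; projection still defined")
  }
  sv$u %*% t(sv$v)
}

# internal single-run shaping loop; V0 is the initial orthogonal matrix
shape_once <- function(problem, alloc, spec, V0, eta, max_iter, tol,
                       samples, geometry) {
  M <- problem$M
  slots <- alloc$slots
  K <- length(slots)
  g <- alloc$gains[slots]
  lam <- problem$signal$spectrum[slots]
  a <- problem$blur[slots]
  d <- a^2 * lam + problem$sigma_n2
  p_slot <- g^2 * d
  pbar <- problem$P / M
  E_act <- basis_columns(problem$signal, slots)
  B <- g * t(E_act)                              # K x N
  BSx <- (g * d) * t(E_act)                      # K x N, rows of Lambda D E'
  BBt_diag <- g^2                                # B B' is diagonal

  gamma <- if (spec$kind == "none") 0 else spec$gamma
  cq <- gg_scale(spec$q)

  project <- function(Wt) {
    Cm <- Wt %*% t(B)
    if (K < M) Cm <- cbind(Cm, matrix(0, M, M - K))
    sv <- svd(Cm)
    sv$u %*% t(sv$v)
  }

  # For response sparsity the |z|^q term has an unbounded derivative at
  # z = 0 (q < 1); the loop optimizes a smoothed surrogate
  # ((z^2 + eps^2)^(q/2)) with eps tied to the response scale, which has the
  # same minimizers in practice but admits a stable line search.  Reported
  # costs always use the exact formula via constraint_cost().
  resp_eps2 <- if (spec$kind == "response_sparsity") 1e-4 * pbar else 0
  smooth_psi <- function(W, v) {
    z <- W %*% samples
    sdz <- sqrt(pmax(v, 1e-12))
    mean(colSums((z^2 + resp_eps2)^(spec$q / 2) / (cq * sdz)^spec$q))
  }

  eval_state <- function(V) {
    Va <- V[, seq_len(K), drop = FALSE]
    v <- as.vector(Va^2 %*% p_slot)
    dev <- (v - pbar) / pbar
    W <- Va %*% B
    psi <- if (gamma > 0) {
      if (spec$kind == "response_sparsity") {
        smooth_psi(W, v)
      } else {
        constraint_cost(W, spec, geometry = geometry, samples = samples)
      }
    } else 0
    list(V = V, Va = Va, W = W, v = v, dev = dev, phi = sum(dev^2), psi = psi,
         violation = max(abs(dev)))
  }

  st <- eval_state(V0)
  psi0 <- max(abs(st$psi), 1e-12)
  total <- function(s) s$phi + gamma * s$psi / psi0
  tot <- total(st)
  hist_tot <- rep(NA_real_, max_iter + 1L)
  hist_tot[1L] <- tot
  trace_it <- integer(0); trace_viol <- numeric(0); trace_cost <- numeric(0)
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    # gradient of sum(((v_j - pbar)/pbar)^2) wrt W
    Gw <- (4 * st$dev / pbar) * (st$Va %*% BSx)
    if (gamma > 0) {
      Gpsi <- switch(spec$kind,
        weight_sparsity = sign(st$W),
        locality = {
          D <- locality_weights(st$W, geometry)
          if (spec$locality_squared) 4 * D * st$W^3 else 2 * D * st$W
        },
        response_sparsity = {
          z <- st$W %*% samples
          sdz <- sqrt(pmax(st$v, 1e-12))
          sc <- (cq * sdz)^spec$q
          zz <- (spec$q * z * (z^2 + resp_eps2)^(spec$q / 2 - 1)) / sc
          (zz %*% t(samples)) / ncol(samples)
        })
      Gw <- Gw + (gamma / psi0) * Gpsi
    }
    # backtracking step in the ambient space, projected back to the manifold
    accepted <- FALSE
    for (h in 1:40) {
      Vn <- project(st$W - eta * Gw)
      stn <- eval_state(Vn)
      if (total(stn) < tot - 1e-14) {
        accepted <- TRUE
        break
      }
      eta <- eta / 2
    }
    if (!accepted) {
      # no descent direction left: a full plateau
      converged <- st$violation <= tol
      break
    }
    st <- stn
    tot <- total(st)
    eta <- min(eta * 1.2, 1e3)
    hist_tot[iter + 1L] <- tot
    if (iter %% 10L == 0L || iter == 1L) {
      trace_it <- c(trace_it, iter)
      trace_viol <- c(trace_viol, st$violation)
      trace_cost <- c(trace_cost, st$psi)
    }
    if (st$violation <= tol && iter > 50L) {
      prev <- hist_tot[iter - 49L]
      if (abs(tot - prev) <= 1e-6 * max(abs(tot), 1e-12)) {
        converged <- TRUE
        break
      }
    }
  }
  final_cost <- if (gamma > 0) {
    constraint_cost(st$W, spec, geometry = geometry, samples = samples)
  } else 0
  list(V = st$V, W = st$W, iterations = iter, violation = st$violation,
       cost = final_cost, phi = st$phi, total = tot, converged = converged,
       trace = data.frame(iteration = trace_it, violation = trace_viol,
                          cost = trace_cost))
}

#' Shape the optimal population under a resource constraint
#'
#' Iteratively chooses the orthogonal factor `V` of the optimal encoder
#' `W = V Lambda E'` so that each neuron's response variance approaches the
#' per-neuron budget `P/M` while the selected resource cost is reduced.  Each
#' iteration takes a gradient step on
#' `sum_j ((var_j - P/M)/(P/M))^2 + gamma * cost/cost_0` in the ambient space
#' of `W` and projects back onto the solution manifold with
#' [procrustes_project()], so the total power constraint holds exactly and the
#' expected MSE equals the unconstrained optimum at every iterate.  The
#' algorithm is not guaranteed to converge (it is susceptible to local
#' minima); use `restarts` for seeded random re-initializations.
#'
#' @param problem A [coding_problem].
#' @param spec A [constraint_spec].
#' @param allocation Optional precomputed [power_allocation].
#' @param eta Initial gradient step size (adapted by backtracking halving).
#' @param max_iter Maximum iterations per restart (default 5000).
#' @param tol Individual-power violation tolerance (default 0.01, i.e. 1%).
#' @param seed Integer seed; restart `r` uses `seed + r - 1`.
#' @param restarts Number of random orthogonal initializations (best kept).
#' @param samples Optional observed-signal samples for the response-sparsity
#'   cost; generated internally (`n_samples` gaussian textures degraded by the
#'   problem's blur and noise) when needed.
#' @param n_samples Number of internally generated samples (default 512).
#' @return List with `encoder` (an [encoder_solution]) and `state` (class
#'   `shaping_state`: `V`, `iterations`, `violation`, `cost`, `converged`,
#'   and an iteration `trace` data frame).  A warning is raised when no
#'   restart converged.
#' @export
shape_population <- function(problem, spec, allocation = NULL, eta = 0.01,
                             max_iter = 5000, tol = 0.01, seed = 1,
                             restarts = 1, samples = NULL, n_samples = 512) {
  stopifnot(inherits(problem, "coding_problem"), inherits(spec, "constraint_spec"))
  if (eta <= 0) stop("shape_population: eta must be > 0")
  if (is.null(allocation)) allocation <- waterfill_allocation(problem)
  geometry <- problem$signal$grid
  if (spec$kind == "locality" && is.null(geometry)) {
    stop("shape_population: locality constraint needs a signal with grid geometry")
  }
  if (spec$kind == "response_sparsity" && is.null(samples)) {
    tex <- sample_textures(texture_spec(problem$signal, "gaussian",
                                        seed = seed + 7919L), n_samples)
    samples <- degrade(tex, problem$signal, blur_model(problem$blur),
                       problem$sigma_n2, seed = seed + 7920L)
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    V0 <- random_orthogonal(problem$M, seed = seed + r - 1L)
    res <- shape_once(problem, allocation, spec, V0, eta, max_iter, tol,
                      samples, geometry)
    better <- is.null(best) ||
      (res$converged && !best$converged) ||
      (res$converged == best$converged &&
         (res$violation < best$violation ||
            (res$violation == best$violation && res$cost < best$cost)))
    if (better) best <- res
  }
  if (!best$converged) {
    warning(sprintf(
      "shape_population: not converged (violation %.3g after %d iterations)",
      best$violation, best$iterations))
  }
  encoder <- assemble_encoder(allocation, problem$signal, best$V)
  state <- structure(best[c("V", "iterations", "violation", "cost", "phi",
                            "converged", "trace")], class = "shaping_state")
  list(encoder = encoder, state = state)
}

#' @export
print.shaping_state <- function(x, ...) {
  cat(sprintf("<shaping_state> %d iterations, violation = %.3g%%, cost = %.6g, %s\n",
              x$iterations, 100 * x$violation, x$cost,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Spatially localized population from gaussian-bump targets
#'
#' The alternative route to spatially localized receptive fields: write the
#' desired population as a target matrix `W0` and take the point of the
#' optimal-solution manifold closest to it ([procrustes_project()]).  In the
#' complete case the natural target is the identity ("the neural code should
#' minimally change the observed signal"), giving the symmetric, ZCA-like
#' optimal solution.  In the undercomplete case `W0` holds `M` gaussian bumps
#' whose centers tile the visual field (k-means on uniformly distributed
#' sample points) and whose width is `sigma = kappa * r_pack` with
#' `r_pack = sqrt(N / (pi M))` the radius of ideal circles packing the field.
#'
#' @param problem A [coding_problem] whose signal has grid geometry.
#' @param allocation Optional precomputed [power_allocation].
#' @param sigma_scale Bump width factor `kappa` (> 0, default 0.5).
#' @param seed Integer seed (k-means initialization).
#' @param target `"auto"` (identity when `M == N`, bumps otherwise),
#'   `"identity"`, or `"bumps"`.
#' @return List with `encoder`, `V`, `target` (the `W0` used), and `centers`
#'   (bump centers, or `NULL` for the identity target).
#' @export
bump_target_population <- function(problem, allocation = NULL,
                                   sigma_scale = 0.5, seed = 1,
                                   target = c("auto", "identity", "bumps")) {
  stopifnot(inherits(problem, "coding_problem"))
  target <- match.arg(target)
  if (sigma_scale <= 0) stop("bump_target_population: sigma_scale must be > 0")
  geometry <- problem$signal$grid
  if (is.null(geometry)) {
    stop("bump_target_population: signal has no grid geometry")
  }
  if (is.null(allocation)) allocation <- waterfill_allocation(problem)
  M <- problem$M
  N <- geometry$n
  if (target == "auto") target <- if (M == N) "identity" else "bumps"
  centers <- NULL
  if (target == "identity") {
    if (M != N) stop("bump_target_population: identity target needs M == N")
    W0 <- diag(N)
  } else {
    H <- geometry$height; Wd <- geometry$width
    km <- withr::with_seed(seed, {
      pts <- cbind(stats::runif(max(200L * M, 2000L), 0, H),
                   stats::runif(max(200L * M, 2000L), 0, Wd))
      stats::kmeans(pts, centers = M, nstart = 5, iter.max = 100)
    })
    centers <- km$centers
    r_pack <- sqrt(N / (pi * M))
    sg <- sigma_scale * r_pack
    xy <- pixel_coords(geometry) + 0.5      # pixel centers
    W0 <- matrix(0, M, N)
    for (j in seq_len(M)) {
      d2 <- (xy[, 1] - centers[j, 1])^2 + (xy[, 2] - centers[j, 2])^2
      W0[j, ] <- exp(-d2 / (2 * sg^2))
    }
  }
  V <- procrustes_project(W0, allocation, problem$signal)
  encoder <- assemble_encoder(allocation, problem$signal, V)
  list(encoder = encoder, V = V, target = W0, centers = centers)
}

#' Scan gaussian-bump widths for the best average locality
#'
#' Evaluates [bump_target_population()] over a range of width factors `kappa`
#' and reports the locality cost of each resulting population.
#'
#' @param problem A [coding_problem] with grid geometry.
#' @param kappas Numeric vector of width factors to try.
#' @param seed Integer seed.
#' @return Data frame with columns `kappa` and `locality_cost`.
#' @export
bump_sigma_scan <- function(problem, kappas = seq(0.3, 1, by = 0.1), seed = 1) {
  alloc <- waterfill_allocation(problem)
  spec <- constraint_spec("locality", gamma = 1)
  cost <- vapply(kappas, function(k) {
    pop <- bump_target_population(problem, alloc, sigma_scale = k, seed = seed,
                                  target = "bumps")
    constraint_cost(pop$encoder$W, spec, geometry = problem$signal$grid)
  }, numeric(1))
  data.frame(kappa = kappas, locality_cost = cost)
}
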