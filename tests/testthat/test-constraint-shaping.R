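make_grid_problem <- function(side = 5, M = side^2, snr = 10, blur = 0.5) {
  g <- grid_geometry(side, side)
  sig <- make_powerlaw_spectrum(g)
  coding_problem(sig, gaussian_blur(sig, blur), M = M, sensory_snr_db = snr)
}

test_that("resource costs evaluate their defining formulas", {
  spec_w <- constraint_spec("weight_sparsity")
  expect_equal(constraint_cost(diag(3), spec_w), 3)
  expect_equal(constraint_cost(matrix(c(1, -2, 0, 3), 2), spec_w), 6)
  # a single-pixel receptive field has zero locality cost
  g <- grid_geometry(3, 3)
  W <- matrix(0, 2, 9); W[1, 5] <- 2; W[2, 1] <- -1
  expect_equal(constraint_cost(W, constraint_spec("locality"), geometry = g), 0)
  # spreading weight away from the peak costs distance-weighted power
  W2 <- matrix(0, 1, 9); W2[1, 5] <- 1; W2[1, 4] <- 0.5
  expect_equal(constraint_cost(W2, constraint_spec("locality"), geometry = g),
               0.25)  # d = 1 px^2, w^2 = 0.25
  expect_error(constraint_cost(W2, constraint_spec("locality")), "geometry")
  expect_error(constraint_cost(W2, constraint_spec("response_sparsity")),
               "samples")
  # sparser responses of equal variance score a lower negative log-likelihood
  spec_r <- constraint_spec("response_sparsity", q = 0.5)
  xg <- withr::with_seed(5, matrix(rnorm(4 * 2e4), 4))
  xs <- withr::with_seed(6, matrix(popcode:::rgen_gaussian(4 * 2e4, 0.5), 4))
  expect_lt(constraint_cost(diag(4), spec_r, samples = xs),
            constraint_cost(diag(4), spec_r, samples = xg))
})

test_that("individual power violation measures relative row-variance spread", {
  # white signal, no sensing noise: row variance is the squared row norm
  sig <- spectral_covariance(c(1, 1))
  pr <- coding_problem(sig, NULL, M = 2, sensory_variance = 0,
                       neural_snr_db = 0)  # P = 2, P/M = 1
  W_even <- diag(2)
  expect_equal(individual_power_violation(W_even, pr), 0)
  W_skew <- diag(c(sqrt(1.5), sqrt(0.5)))
  expect_equal(individual_power_violation(W_skew, pr), 0.5)
})

test_that("Procrustes projection is exact on-manifold and idempotent", {
  pr <- make_grid_problem(4, M = 16)
  al <- waterfill_allocation(pr)
  V0 <- popcode:::random_orthogonal(16, seed = 21)
  W0 <- assemble_encoder(al, pr$signal, V0)$W
  V1 <- suppressMessages(procrustes_project(W0, al, pr$signal))
  W1 <- assemble_encoder(al, pr$signal, V1)$W
  expect_lt(max(abs(W1 - W0)), 1e-8)   # already on the manifold
  # idempotence
  V2 <- suppressMessages(procrustes_project(W1, al, pr$signal))
  expect_lt(max(abs(assemble_encoder(al, pr$signal, V2)$W - W1)), 1e-10)
  # orthogonality of the projection output from an arbitrary candidate
  Vr <- suppressMessages(procrustes_project(matrix(rnorm(16 * 16), 16), al,
                                            pr$signal))
  expect_lt(max(abs(crossprod(Vr) - diag(16))), 1e-8)
  # M = 1: the projection picks the sign maximizing the correlation
  pr1 <- coding_problem(spectral_covariance(c(2, 1)), NULL, M = 1,
                        sensory_variance = 0, neural_snr_db = 3)
  al1 <- waterfill_allocation(pr1)
  B1 <- assemble_encoder(al1, pr1$signal)$W
  expect_equal(as.vector(procrustes_project(-2 * B1, al1, pr1$signal)), -1)
  expect_equal(as.vector(procrustes_project(0.3 * B1, al1, pr1$signal)), 1)
})

test_that("shaping balances per-neuron power on the optimal manifold", {
  pr <- make_grid_problem(5, M = 25)
  d0 <- solve_coding_problem(pr)$decoder$expected_mse
  res <- shape_population(pr, constraint_spec("none"), seed = 3,
                          max_iter = 2000)
  expect_true(res$state$converged)
  expect_lte(res$state$violation, 0.01)
  expect_lt(max(abs(crossprod(res$state$V) - diag(25))), 1e-8)
  expect_equal(sum(neuron_variances(res$encoder, pr)), pr$P,
               tolerance = 1e-9 * pr$P)
  expect_equal(wiener_decoder(res$encoder, pr)$expected_mse, d0,
               tolerance = 1e-9)
})

test_that("shaping reduces each resource cost below the random-V level", {
  pr <- make_grid_problem(5, M = 25)
  al <- waterfill_allocation(pr)
  g <- pr$signal$grid
  tex <- sample_textures(texture_spec(pr$signal, seed = 31), 400)
  xs <- degrade(tex, pr$signal, blur_model(pr$blur), pr$sigma_n2, seed = 32)
  W_rand <- assemble_encoder(al, pr$signal,
                             popcode:::random_orthogonal(25, seed = 9))$W
  for (kind in c("weight_sparsity", "response_sparsity", "locality")) {
    spec <- constraint_spec(kind, gamma = 0.1)
    res <- suppressWarnings(
      shape_population(pr, spec, allocation = al, seed = 3, max_iter = 1500,
                       samples = xs))
    c_shaped <- constraint_cost(res$encoder$W, spec, geometry = g, samples = xs)
    c_rand <- constraint_cost(W_rand, spec, geometry = g, samples = xs)
    expect_lt(c_shaped, c_rand)
    # shaping never leaves the optimal-MSE manifold
    expect_equal(wiener_decoder(res$encoder, pr)$expected_mse,
                 solve_coding_problem(pr)$decoder$expected_mse,
                 tolerance = 1e-9)
  }
})

test_that("different seeds give different V but identical expected MSE", {
  pr <- make_grid_problem(4, M = 16)
  r1 <- suppressWarnings(shape_population(pr, constraint_spec("none"),
                                          seed = 1, max_iter = 800))
  r2 <- suppressWarnings(shape_population(pr, constraint_spec("none"),
                                          seed = 2, max_iter = 800))
  expect_gt(max(abs(r1$state$V - r2$state$V)), 1e-6)
  expect_equal(wiener_decoder(r1$encoder, pr)$expected_mse,
               wiener_decoder(r2$encoder, pr)$expected_mse,
               tolerance = 1e-12)
})

test_that("gaussian-bump targets give tiled, local populations", {
  # complete case: identity target yields the symmetric (ZCA-like) solution
  pr <- make_grid_problem(5, M = 25, snr = 15)
  pop <- suppressMessages(bump_target_population(pr, seed = 1))
  expect_lt(max(abs(pop$encoder$W - t(pop$encoder$W))), 1e-8)
  # undercomplete case: k-means centers cover the field
  pru <- make_grid_problem(8, M = 8, snr = 15)
  popu <- suppressMessages(bump_target_population(pru, seed = 2))
  r_pack <- sqrt(64 / (pi * 8))
  xy <- popcode:::pixel_coords(pru$signal$grid) + 0.5
  dmin <- apply(xy, 1, function(p) {
    min(sqrt((popu$centers[, 1] - p[1])^2 + (popu$centers[, 2] - p[2])^2))
  })
  expect_lt(max(dmin), 3 * r_pack)
  # locality cost of the bump population beats a random-V population
  spec <- constraint_spec("locality")
  W_rand <- assemble_encoder(waterfill_allocation(pru), pru$signal,
                             popcode:::random_orthogonal(8, seed = 5))$W
  expect_lt(constraint_cost(popu$encoder$W, spec, geometry = pru$signal$grid),
            constraint_cost(W_rand, spec, geometry = pru$signal$grid))
  # the width scan reports a cost per kappa
  scan <- suppressMessages(bump_sigma_scan(pru, kappas = c(0.4, 0.6), seed = 1))
  expect_identical(dim(scan), c(2L, 2L))
  expect_true(all(is.finite(scan$locality_cost)))
})
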