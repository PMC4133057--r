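test_that("recoverable power follows the per-component closed form", {
  expect_equal(recoverable_power(1, 1, 0), 1)
  expect_equal(recoverable_power(1, 1, 1), 0.5)
  expect_equal(recoverable_power(1, 0, 0.3), 0)
  expect_equal(recoverable_power(1, 0, 0), 0)  # unobservable component
  expect_equal(recoverable_power(c(4, 1), c(1, 1), 1), c(16 / 5, 1 / 2))
})

test_that("water-filling reproduces the enumerable two-component optimum", {
  sig <- spectral_covariance(c(4, 1))
  pr <- coding_problem(sig, NULL, M = 1, sensory_variance = 0,
                       neural_snr_db = 0, sigma_delta2 = 1)  # P = 1
  al <- waterfill_allocation(pr)
  expect_equal(al$power, c(1, 0))
  dec <- wiener_decoder(assemble_encoder(al, sig), pr)
  expect_equal(dec$expected_mse, 3)
  expect_equal(dec$percent_error, 60)
  # brute force over both single-component choices agrees
  expect_equal(oracle_min_mse(c(4, 1), c(1, 1), 0, 1, 1, 1), 3,
               tolerance = 1e-9)
})

test_that("water-filling handles degenerate and symmetric cases", {
  # N = M = 1: everything goes to the one component
  pr1 <- coding_problem(spectral_covariance(2), NULL, M = 1,
                        sensory_variance = 0.5, neural_snr_db = 7)
  expect_equal(sum(waterfill_allocation(pr1)$power), pr1$P)
  # equal recoverable power: equal allocation by symmetry
  pr2 <- coding_problem(spectral_covariance(rep(2, 5)), NULL, M = 5,
                        sensory_variance = 0.25, neural_snr_db = 5)
  al2 <- waterfill_allocation(pr2)
  expect_equal(al2$power, rep(pr2$P / 5, 5), tolerance = 1e-9)
  expect_equal(sum(al2$power), pr2$P, tolerance = 1e-9 * pr2$P)
  expect_true(all((al2$power > 0) == (al2$gains > 0)))
  # no recoverable component is an explicit error
  dead <- coding_problem(spectral_covariance(c(1, 1)), blur_model(c(0, 0)),
                         M = 2, sensory_variance = 1)
  expect_error(waterfill_allocation(dead), "infeasible")
})

test_that("water-filling matches simplex minimization on random problems", {
  for (seed in 1:12) {
    pr <- random_small_problem(seed + 100)
    al <- waterfill_allocation(pr)
    mse <- wiener_decoder(assemble_encoder(al, pr$signal), pr)$expected_mse
    ref <- oracle_min_mse(pr$signal$spectrum, pr$blur, pr$sigma_n2,
                          pr$sigma_delta2, pr$M, pr$P)
    expect_equal(mse, ref, tolerance = 1e-6)
    expect_lte(length(al$active), min(pr$M, pr$signal$n))
  }
})

test_that("encoder assembly satisfies the power constraint for any V", {
  pr <- random_small_problem(7)
  al <- waterfill_allocation(pr)
  d0 <- wiener_decoder(assemble_encoder(al, pr$signal), pr)$expected_mse
  for (seed in 1:4) {
    V <- popcode:::random_orthogonal(pr$M, seed = seed)
    enc <- assemble_encoder(al, pr$signal, V)
    expect_equal(sum(neuron_variances(enc, pr)), pr$P,
                 tolerance = 1e-9 * pr$P)
    # W = V Lambda E' reconstructs from its factors
    B <- enc$slot_gains * t(basis_columns(pr$signal, enc$slots))
    expect_lt(max(abs(enc$W - V[, seq_along(enc$slots), drop = FALSE] %*% B)),
              1e-8)
    # expected MSE is invariant in V
    expect_equal(wiener_decoder(enc, pr)$expected_mse, d0,
                 tolerance = 1e-12)
  }
  expect_error(assemble_encoder(al, pr$signal, matrix(1, pr$M, pr$M) + diag(pr$M)),
               "orthogonal")
})

test_that("whitening flattens the blurred-signal covariance at budget P", {
  # scalar closed form: lambda = 4, a = 1, noiseless, P = 1 -> W = 1/2
  pr <- coding_problem(spectral_covariance(4), NULL, M = 1,
                       sensory_variance = 0, neural_snr_db = 0)
  we <- whitening_encoder(pr)
  expect_equal(as.vector(we$W), 0.5)
  expect_equal(we$c2, 1)
  # flat encoded blurred spectrum, and exact budget, under blur + noise
  sig <- powerlaw_covariance_1d(30)
  bl <- gaussian_blur(sig, 1)
  for (M in c(30, 12)) {
    pr <- coding_problem(sig, bl, M = M, sensory_snr_db = 3)
    we <- whitening_encoder(pr)
    E <- basis_columns(sig)
    Sb <- we$W %*% (E %*% (bl$gains^2 * sig$spectrum * t(E))) %*% t(we$W)
    expect_lt(max(abs(Sb - we$c2 * diag(M))), 1e-8)
    expect_equal(sum(neuron_variances(we, pr)), pr$P, tolerance = 1e-9)
  }
  # encoder shape is independent of sensory noise up to the scalar c
  prA <- coding_problem(sig, bl, M = 12, sensory_snr_db = 20)
  prB <- coding_problem(sig, bl, M = 12, sensory_snr_db = -10)
  wA <- whitening_encoder(prA); wB <- whitening_encoder(prB)
  expect_lt(max(abs(wA$W / sqrt(wA$c2) - wB$W / sqrt(wB$c2))), 1e-9)
  # more units than positive blurred eigenvalues is an error
  g2 <- make_powerlaw_spectrum(grid_geometry(4, 4))  # DC is zero
  pr2 <- coding_problem(g2, NULL, M = 16, sensory_snr_db = 10)
  expect_error(whitening_encoder(pr2), "positive blurred-signal")
})

test_that("the Wiener decoder matches dense-matrix algebra and is optimal", {
  # scalar case: lambda = a = g = 1, sn2 = 0, sd2 = 1 -> G = 0.5, MSE = 0.5
  sig1 <- spectral_covariance(1)
  pr1 <- coding_problem(sig1, NULL, M = 1, sensory_variance = 0,
                        neural_snr_db = 0)  # P = 1 -> g = 1
  sol1 <- solve_coding_problem(pr1)
  expect_equal(as.vector(sol1$encoder$W), 1)
  expect_equal(as.vector(sol1$decoder$G), 0.5)
  expect_equal(sol1$decoder$expected_mse, 0.5)
  # dense-matrix oracle agreement on random problems, optimal and whitening
  for (seed in c(3, 11)) {
    pr <- random_small_problem(seed)
    enc <- assemble_encoder(waterfill_allocation(pr), pr$signal,
                            popcode:::random_orthogonal(pr$M, seed = seed))
    dec <- wiener_decoder(enc, pr)
    ref <- oracle_wiener_dense(enc$W, pr$signal, pr$blur, pr$sigma_n2,
                               pr$sigma_delta2)
    expect_equal(dec$expected_mse, ref$expected_mse, tolerance = 1e-10)
    expect_lt(max(abs(dec$G - ref$G)), 1e-8)
    # any perturbed readout does worse
    for (k in 1:5) {
      Gp <- dec$G + withr::with_seed(k, matrix(rnorm(length(dec$G), sd = 0.05),
                                               nrow(dec$G)))
      expect_gte(oracle_readout_mse(Gp, enc$W, pr$signal, pr$blur,
                                    pr$sigma_n2, pr$sigma_delta2),
                 dec$expected_mse)
    }
  }
  # complete, noiseless, high-budget limit: error vanishes
  sig <- spectral_covariance(c(3, 2, 1))
  prL <- coding_problem(sig, NULL, M = 3, sensory_variance = 0,
                        neural_snr_db = 60)
  expect_lt(solve_coding_problem(prL)$decoder$percent_error, 0.1)
})

test_that("the infinite-capacity bound is the blur-and-noise floor", {
  sig <- spectral_covariance(c(4, 1))
  expect_equal(expected_mse_limit(coding_problem(sig, NULL, M = 2,
                                                 sensory_variance = 1)), 1.3)
  expect_equal(expected_mse_limit(coding_problem(sig, NULL, M = 2,
                                                 sensory_variance = 0)), 0)
  # finite-M optimum approaches the bound from above as M grows
  sigf <- powerlaw_covariance_1d(40)
  bl <- gaussian_blur(sigf, 1)
  mses <- vapply(c(1, 5, 20, 40, 80), function(M) {
    solve_coding_problem(coding_problem(sigf, bl, M = M,
                                        sensory_snr_db = 5))$decoder$expected_mse
  }, numeric(1))
  lim <- expected_mse_limit(coding_problem(sigf, bl, M = 1, sensory_snr_db = 5))
  expect_true(all(diff(mses) <= 1e-9))
  expect_true(all(mses >= lim - 1e-9))
})

test_that("simulated encode-decode converges to the closed-form error", {
  g <- grid_geometry(1, 16)
  sig <- make_powerlaw_spectrum(g)
  pr <- coding_problem(sig, gaussian_blur(sig, 0.5), M = 8,
                       sensory_snr_db = 5)
  sol <- solve_coding_problem(pr)
  ss <- sample_textures(texture_spec(sig, seed = 11), 1e4)
  run <- encode_decode_samples(sol$encoder, sol$decoder, pr, ss, seed = 12)
  # per-sample squared errors have finite variance; 3 sigma of the mean
  se3 <- 3 * sol$decoder$expected_mse / sqrt(1e4)  # conservative scale bound
  expect_lt(abs(run$empirical_mse - sol$decoder$expected_mse),
            max(se3, 0.05 * sol$decoder$expected_mse))
  # bit-identical under a fixed seed
  run2 <- encode_decode_samples(sol$encoder, sol$decoder, pr, ss, seed = 12)
  expect_identical(run$reconstructed, run2$reconstructed)
  # fully noiseless identity pipeline is exact
  sid <- spectral_covariance(c(2, 1))
  prid <- coding_problem(sid, NULL, M = 2, sensory_variance = 0,
                         neural_snr_db = 40)
  solid <- solve_coding_problem(prid)
  s0 <- sample_textures(texture_spec(sid, seed = 3), 50)
  rid <- encode_decode_samples(solid$encoder, solid$decoder, prid, s0, seed = 4)
  expect_lt(rid$percent_error, 0.1)
})
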