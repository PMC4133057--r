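---
title: "Optimal linear population coding: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal linear population coding: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcode)
```

## The model

A sensory system observes a degraded version of an environmental signal and
must represent it with a limited population of noisy neurons.  `popcode`
implements the linear gaussian version of this problem:

* the **original signal** `s` (N pixels, zero mean) has covariance
  `Sigma_s = E Lambda E'` with orthonormal spatial modes `E` and power
  spectrum `lambda_i >= 0`;
* the **observed signal** is `x = A s + n`, where `A` is a blur co-diagonal
  with `E` (spectral gains `a_i`) and `n` is white sensory noise of variance
  `sigma_n^2`;
* the **neural representation** is `r = W x + delta`, with `M` encoding
  units (rows of `W` are receptive fields) and white neural noise of
  variance `sigma_delta^2`;
* the **reconstruction** is `s_hat = G r`, with `G` the Wiener filter, and
  the objective is the expected mean squared error `E ||s - s_hat||^2`.

Neural precision is fixed by a per-neuron SNR: the population's total
response variance is constrained to
`P = M sigma_delta^2 10^(SNR_dB/10)` (the total power constraint), or more
strictly every neuron individually to `P/M` (the individual power
constraint).  Both constraints admit the same minimum MSE.

Because all second-order structure is co-diagonal in `E`, the MSE separates
per spectral component.  Component `i` carries *recoverable power*
`s_i = lambda_i^2 a_i^2 / (a_i^2 lambda_i + sigma_n^2)`, and assigning it
encoded variance `p_i` reduces the error by `s_i p_i / (p_i + sigma_delta^2)`.
Minimizing the total residual subject to `sum(p) = P`, `p_i >= 0`, and at
most `min(M, N)` active components is a water-filling problem with the KKT
solution `p_i = max(0, sqrt(s_i sigma_delta^2 / mu) - sigma_delta^2)`; the
problem is convex, so this allocation is the global optimum.  The encoder
factorizes as `W = V Lambda E'` where `Lambda` holds the spectral gains
`g_i = sqrt(p_i / (a_i^2 lambda_i + sigma_n^2))` and `V` is *any* orthogonal
`M x M` matrix: the MSE, the total power, and the encoding spectrum are all
invariant in `V`.

The **whitening baseline** instead sets
`W (A Sigma_s A') W' = c^2 I` on the top-`M` principal components of the
blurred signal, with `c` scaled to the same budget `P`.  It removes all
second-order redundancy but ignores sensory noise entirely; the package
keeps it as the redundancy-reduction reference against which the optimal
code is compared.

Two regimes worth naming: with no blur and no sensory noise the optimal
representation variance `p_i + sigma_delta^2` is proportional to
`sqrt(lambda_i)` on active components ("half-whitening" — redundancy is
half-preserved rather than removed), and under blur plus noise the encoding
is truncated near the frequency where the blurred signal falls below the
sensory noise floor.

## Resolving the orthogonal degeneracy

The physical layout of receptive fields lives entirely in `V`.
`shape_population()` selects `V` by projected gradient descent: at each
iteration it takes a step on

```
Phi(W) + gamma * psi(W) / psi_0,
Phi(W) = sum_j ((var_j - P/M) / (P/M))^2
```

in the ambient space of `W` and projects back onto the solution manifold by
the orthogonal Procrustes solution (`procrustes_project()`), so the total
power constraint — and hence the optimal MSE — is satisfied *exactly* at
every iterate.  `Phi` drives the individual power constraint; `psi` is one
of three resource costs:

* **weight sparsity** — `sum |w_jk|`;
* **response sparsity** — negative log likelihood of the pre-noise responses
  under a sparse generalized gaussian with shape `q` (default 0.5);
* **spatial locality** — `sum_j sum_k d_jk w_jk^2` with `d_jk` the squared
  pixel distance to the peak-magnitude weight of row `j`.

Design choices that were genuinely open, and how they were resolved:

* *Cost normalization.*  The raw resource costs live on wildly different
  scales (an L1 norm grows with `M sqrt(N)`, a locality cost with the grid
  diagonal squared).  The power penalty is therefore expressed in relative
  units and the resource cost is divided by its value at the initial
  iterate, so `gamma` (default 0.1) has a comparable meaning across
  constraint kinds.  This is a monotone rescaling of the underlying
  objective and does not move its minimizers for a fixed problem.
* *Response-sparsity smoothing.*  For `q < 1` the `|z|^q` term has an
  unbounded derivative at `z = 0`, which defeats a line search.  The loop
  optimizes the smoothed surrogate `(z^2 + eps^2)^(q/2)` with
  `eps^2 = 1e-4 * P/M` (tied to the response scale); reported costs always
  use the exact formula.
* *Peak definition.*  The locality peak is the maximum-magnitude weight
  (ties broken by lowest pixel index), recomputed every iteration; receptive
  fields are sign-corrected at the peak, so ON and OFF units are treated
  symmetrically.  An alternative reading of the locality cost
  (`sum d (w^2)^2`) is available behind `locality_squared = TRUE`.
* *Step control and convergence.*  Backtracking halving from `eta = 0.01`
  with 1.2x growth on acceptance; convergence requires violation <= 1% and
  a relative objective change below 1e-6 over 50 iterations (a line-search
  stall at <= 1% violation also counts — there is no descent direction
  left).  The algorithm is not guaranteed to find a global minimum;
  `restarts` draws additional seeded random orthogonal initializations (QR
  of a gaussian matrix with sign fix) and keeps the best run.

`bump_target_population()` implements the alternative, non-iterative route
to spatially local populations: write the desired layout as a target matrix
`W0` and Procrustes-project it onto the manifold in one step.  With `M = N`
the natural target is the identity, giving the symmetric ZCA-like solution;
for `M < N` the rows of `W0` are gaussian bumps at k-means centers of
uniformly distributed points in the visual field, with width
`sigma = kappa * sqrt(N / (pi M))` (`kappa` default 0.5,
`bump_sigma_scan()` explores alternatives).  This route is deterministic
given the seed, fast, and is what the package uses for the qualitative
center-surround and light-adaptation analyses.

## The synthetic signal models

Nothing in the package requires external data.  Two signal families stand in
for natural-image statistics:

* `make_powerlaw_spectrum()` — a stationary texture on an `H x W` pixel
  grid whose eigenbasis is the real 2-D discrete Fourier basis and whose
  spectrum falls as `1/f^2` (natural-image-like).  The DC component is set
  to exactly zero (zero-mean signal) and the spectrum is normalized to
  `trace = N`, i.e. unit average pixel variance, so SNR settings and percent
  errors are comparable across grid sizes.
* `powerlaw_covariance_1d()` — an abstract n-component signal with
  frequencies `f_i = i/(2n)` and the same `1/f^2` law, expressed directly in
  spectral coordinates.  This is the idealized signal used for
  spectral-stage analysis: it has no DC component, so the whitening
  baseline exists even in the complete case (on the 2-D grid the zeroed DC
  makes the blurred covariance rank `N-1`, and complete whitening is
  undefined by construction).

Blur is an isotropic gaussian MTF `a(f) = exp(-2 pi^2 sigma^2 f^2)` with
`sigma` in pixels — a parametric stand-in for measured eye optics.  Default
conditions follow the retinal modeling setup: neural SNR 10 dB per unit
(about 1.7 bits of capacity), sensory SNR swept over -10 to 20 dB (dark to
bright), cell ratios 1:1 (fovea-like) and 16:1 (periphery-like), blur
`sigma = 1` pixel.  Texture samples are gaussian in the signal eigenbasis;
a `sparse_source` family with generalized-gaussian coefficients (exponent
0.7) provides the higher-order structure that makes the response-sparsity
cost informative.

What these synthetic conditions do *not* capture: true natural images are
non-stationary and non-gaussian beyond the sparse-coefficient idealization,
real optics are not gaussian and vary across the visual field, and the
empirical cone-sampled covariance differs from an exact power law.
Qualitative phenomena (dominance over whitening, truncation, half-whitening,
center-surround emergence under locality, stronger light adaptation at 1:1
than at 16:1 cell ratios) transfer; exact percentages reported for
calibrated natural-image datasets and measured point-spread functions do
not, and the package does not attempt them.

## Numerical choices

* Covariances are never materialized as `N x N` matrices; everything runs in
  the co-diagonal spectral representation and basis columns are generated on
  demand (a 121 x 121-pixel problem with 14,641 components stays cheap as
  long as only the allocation and error are needed).
* The water level `mu` is found by bisection on the monotone budget function
  to `|sum(p) - P| <= 1e-12 P`, followed by an exact rescale of the active
  powers.  Candidate components are ranked by recoverable power, ties broken
  by ascending frequency, so allocations are deterministic.
* Empirical covariance eigenvalues below `1e-12 * max` are clipped to zero.
* Half-height contours are computed on raw (unsmoothed) weights with
  8-connected flood fill; gaussian smoothing (sigma 0.5 px) is applied to
  displayed cross-sections only.  The center-surround classifier requires a
  negative mean weight in at least 6 of 8 angular sectors of the annulus
  between the center radius and `2 r_c + 2` pixels (toroidal distances,
  matching the circular-convolution geometry).
* All randomness flows through explicit integer seeds (`withr::with_seed`);
  identical configuration plus seed reproduces every artifact bit-exactly.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen to make every check
sharp yet quick to re-run: exhaustive water-filling oracles on random
problems with `N <= 8` (active sets enumerable), spectral-stage properties
on the 100-component 1-D signal, shaping on 15 x 15 (complete) and 11 x 11
grids, and the adaptation comparison on 15 x 15 at cell ratios 1:1 versus
16:1 over five seeds.  These are the package's reference conditions; all of
them scale up by changing the configuration only.

## Known limitations

* The shaping loop optimizes a nonconvex objective over the orthogonal
  group; different seeds can give different local minima (all with identical
  MSE, but different violation/cost trade-offs).
* Whitening requires as many positive blurred-signal eigenvalues as neurons;
  it is undefined for overcomplete populations and for complete populations
  of DC-free grid signals.
* Only second-order signal structure enters the optimal code; the
  response-sparsity cost is the single place where higher-order sample
  statistics matter.
* Chromatic signals, space-variant blur, non-gaussian sensory noise, and
  spiking nonlinearities are out of scope.
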