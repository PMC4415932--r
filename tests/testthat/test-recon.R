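p_small <- acquisition_protocol(grid_shape = c(8, 8, 2))
spectrum9 <- fat_spectrum()
tes6 <- echo_times(p_small)

## complex per-echo signal straight from the voxel model
model_signal <- function(W, F, psi, r2s, tes, spectrum) {
  cn <- fat_modulation(spectrum, tes)
  (W + F * cn) * exp(2i * pi * psi * tes) * exp(-r2s * tes)
}

test_that("the linear water-fat solve inverts its own forward model", {
  s <- model_signal(0.2, 0.8, 35, 22, tes6, spectrum9)
  fit <- solve_wf(s, tes6, spectrum9, psi = 35, r2s = 22)
  expect_equal(fit$water, 0.2, tolerance = 1e-10)
  expect_equal(fit$fat, 0.8, tolerance = 1e-10)
  expect_lt(fit$residual, 1e-10)
  expect_false(fit$degenerate)

  ## zero signal
  fit0 <- solve_wf(rep(0 + 0i, 6), tes6, spectrum9, 0, 0)
  expect_equal(fit0$water, 0)
  expect_equal(fit0$fat, 0)
  expect_equal(fit0$residual, 0)

  ## pure fat solved at truth gives FF exactly 1
  sf <- model_signal(0, 1, -20, 15, tes6, spectrum9)
  ff <- solve_wf(sf, tes6, spectrum9, -20, 15)
  expect_equal(ff$fat / (ff$fat + ff$water), 1, tolerance = 1e-10)

  ## a degenerate spectrum (fat column equals water column) is flagged
  fitd <- solve_wf(s, tes6, fat_spectrum(0, 1), 35, 22)
  expect_true(fitd$degenerate)
})

test_that("decoupled R2* search recovers noiseless decay within the step", {
  s <- model_signal(0.17, 0.83, 25, 21.0, tes6, spectrum9)
  expect_equal(estimate_r2s(s, tes6, spectrum9, psi = 25), 21.0)
  s0 <- model_signal(0.5, 0.5, -40, 0, tes6, spectrum9)
  expect_equal(estimate_r2s(s0, tes6, spectrum9, psi = -40), 0)
})

test_that("decoupled estimation matches exhaustive 2D (psi, R2*) search on noiseless voxels", {
  opts <- recon_options()
  psis <- seq(-174, 174, by = 2)
  rs <- seq(0, 150, by = 0.5)
  for (truth in list(c(W = 0.2, F = 0.8, psi = 40, r2s = 21),
                     c(W = 0.9, F = 0.1, psi = -62, r2s = 30),
                     c(W = 0.05, F = 0.95, psi = 110, r2s = 13.5))) {
    s <- model_signal(truth["W"], truth["F"], truth["psi"], truth["r2s"],
                      tes6, spectrum9)
    ## brute-force 2D oracle over the full search lattice
    best <- c(Inf, NA, NA)
    for (psi in psis) {
      ## residual at the 1D-optimal r2s for this psi, scanned exhaustively
      res <- vapply(rs, function(r) solve_wf(s, tes6, spectrum9, psi, r)$residual,
                    numeric(1))
      if (min(res) < best[1]) best <- c(min(res), psi, rs[which.min(res)])
    }
    ## decoupled chain on a uniform voxel image
    tr <- uniform_truth(c(4, 4, 1), ff = unname(truth["F"] / (truth["W"] + truth["F"])),
                        r2s = unname(truth["r2s"]), psi = unname(truth["psi"]),
                        density = unname(truth["W"] + truth["F"]))
    img <- simulate_multiecho(tr, acquisition_protocol(grid_shape = c(4, 4, 1)),
                              spectrum9, noise_sd = 0)
    maps <- reconstruct_maps(img, opts = opts)
    expect_equal(maps$fieldmap[1, 1, 1], best[2])
    expect_equal(maps$r2s[1, 1, 1], best[3])
  }
})

test_that("a constant in-range field map is recovered exactly", {
  tr <- build_neck_phantom(c(16, 16, 4), seed = 5, ff_heterogeneity_sd = 0,
                           fieldmap = 40, tissue_params = ongrid_tissue_params())
  img <- simulate_multiecho(tr, acquisition_protocol(grid_shape = c(16, 16, 4)),
                            spectrum9, noise_sd = 0)
  psi <- estimate_fieldmap_multiscale(img, opts = recon_options())
  tissue <- tr$water + tr$fat > 0
  expect_true(all(abs(psi[tissue] - 40) <= 2))
  expect_true(all(psi[tissue] == 40))
})

test_that("with mu = 0 the multi-scale field map equals the per-voxel exhaustive oracle", {
  p <- acquisition_protocol(grid_shape = c(8, 8, 3))
  tr <- build_neck_phantom(c(8, 8, 3), seed = 11,
                           anatomy_jitter = rep(0, 7))
  img <- simulate_multiecho(tr, p, spectrum9, noise_sd = 0.03, seed = 2)
  oracle <- brute_fieldmap(img)
  for (ns in c(1L, 3L)) {
    est <- estimate_fieldmap_multiscale(img, opts = recon_options(mu = 0, n_scales = ns))
    expect_equal(est, oracle)
  }
})

test_that("reconstructed maps keep their invariants under noise", {
  p <- acquisition_protocol(grid_shape = c(16, 16, 4))
  tr <- build_neck_phantom(c(16, 16, 4), seed = 6)
  img <- simulate_multiecho(tr, p, spectrum9, noise_sd = 0.02, seed = 3)
  maps <- reconstruct_maps(img)
  expect_true(all(is.finite(maps$ff)), all(is.finite(maps$r2s)))
  expect_true(all(maps$ff >= 0 & maps$ff <= 1))
  expect_true(all(maps$r2s >= 0 & maps$r2s <= 150))
  expect_true(all(abs(maps$fieldmap) <= 1 / (2 * p$delta_te)))
  ## true zero-signal voxels are flagged degenerate with FF = 0
  img0 <- simulate_multiecho(tr, p, spectrum9, noise_sd = 0)
  maps0 <- reconstruct_maps(img0)
  bg <- tr$water + tr$fat == 0
  expect_true(all(maps0$degenerate[bg]))
  expect_true(all(maps0$ff[bg] == 0))
})

test_that("FF bias at SNR 50 stays below one percentage point across tissue conditions", {
  p <- acquisition_protocol(grid_shape = c(8, 8, 4))
  set.seed(42)
  for (ff in c(0.1, 0.5, 0.9)) for (r2s in c(10, 30, 60)) {
    tr <- uniform_truth(c(8, 8, 4), ff = ff, r2s = r2s, psi = 20)
    img <- simulate_multiecho(tr, p, spectrum9, noise_sd = 0.02,
                              seed = round(1000 * ff + r2s))
    maps <- reconstruct_maps(img)
    bias <- mean(maps$ff) - ff
    expect_lt(abs(bias), 0.01,
              label = sprintf("|bias| at FF=%.1f R2*=%g (%.4f)", ff, r2s, bias))
  }
})

test_that("a larger smoothness weight never yields a rougher field map", {
  p <- acquisition_protocol(grid_shape = c(24, 24, 4))
  tr <- build_neck_phantom(c(24, 24, 4), seed = 9)
  img <- simulate_multiecho(tr, p, spectrum9, noise_sd = 0.04, seed = 3)
  pen <- vapply(c(0, 1, 10, 100), function(mu) {
    psi <- estimate_fieldmap_multiscale(img, opts = recon_options(mu = mu))
    coolbat:::fieldmap_smoothness(psi, p$delta_te)
  }, numeric(1))
  expect_true(all(diff(pen) <= 0))
})
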