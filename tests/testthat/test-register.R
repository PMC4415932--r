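ff_volume <- function(seed = 2, grid = c(32, 32, 8), motion = NULL) {
  tr <- build_neck_phantom(grid, seed = seed, motion = motion)
  truth_ff(tr)
}

test_that("identical images register to the identity transform", {
  ff <- ff_volume()
  t0 <- register_rigid(ff, ff, voxel_size = c(1, 1, 2))
  expect_lt(max(abs(t0$rotation)), 0.1)
  expect_lt(max(abs(t0$translation)), 0.1)
  expect_error(register_rigid(array(1, c(8, 8, 2)), array(1, c(8, 8, 2))),
               "degenerate")
})

test_that("a known lattice shift is recovered within 0.2 voxel", {
  ff <- ff_volume()
  moving <- array(0, dim(ff))
  moving[3:32, , ] <- ff[1:30, , ]     # anatomy moved +2 voxels along x
  t <- register_rigid(ff, moving, voxel_size = c(1, 1, 2))
  ## the transform maps fixed coordinates into the moving grid, so the
  ## recovered x translation equals the applied shift
  expect_lt(abs(t$translation[1] - 2), 0.2)
  expect_lt(max(abs(t$translation[2:3])), 0.2)
  expect_lt(max(abs(t$rotation)), 0.3)
})

test_that("simulated inter-state motion is recovered on noiseless phantoms", {
  motion <- list(rotation = c(0.5, -0.6, 2), translation = c(2, -1.5, 1))
  grid <- c(48, 48, 10)
  p <- acquisition_protocol(grid_shape = grid)
  sp <- fat_spectrum()
  base <- build_neck_phantom(grid, seed = 3)
  moved <- build_neck_phantom(grid, seed = 3, motion = motion)
  maps_b <- reconstruct_maps(simulate_multiecho(base, p, sp, 0))
  maps_m <- reconstruct_maps(simulate_multiecho(moved, p, sp, 0))
  est <- register_rigid(maps_m$ff, maps_b$ff, voxel_size = c(1, 1, 2))
  truth <- invert_rigid(rigid_transform(motion$rotation, motion$translation))
  expect_lt(max(abs(est$rotation - truth$rotation)), 0.5)
  ## 0.5 voxel = 0.5 mm in plane, 1 mm through plane
  expect_lt(max(abs(est$translation - truth$translation) / c(0.5, 0.5, 1)), 1)
})

test_that("transform inversion composes to the identity", {
  t <- rigid_transform(c(1.5, -2, 3), c(2, -1, 1.5))
  ti <- invert_rigid(t)
  tti <- invert_rigid(ti)
  expect_equal(tti$rotation, t$rotation, tolerance = 1e-10)
  expect_equal(tti$translation, t$translation, tolerance = 1e-10)
  R <- coolbat:::rotation_matrix(t$rotation)
  Ri <- coolbat:::rotation_matrix(ti$rotation)
  expect_equal(R %*% Ri, diag(3), tolerance = 1e-10)
})

test_that("VOI transfer preserves masks under identity and lattice motion", {
  tr <- build_neck_phantom(c(32, 32, 8), seed = 4)
  mask <- voi_mask(label_mask(tr, "sbat"), "refined_sbat", "Baseline")
  ident <- rigid_transform()
  expect_equal(as.logical(transfer_voi(mask, ident, c(1, 1, 2))),
               as.logical(mask))
  ## translation by exactly one voxel: same count away from borders
  t1 <- rigid_transform(translation = c(1, 0, 0))
  moved <- transfer_voi(mask, t1, c(1, 1, 2))
  expect_equal(sum(moved), sum(mask))
  expect_equal(unclass(moved)[1:31, , ] * 1, unclass(mask)[2:32, , ] * 1)
  expect_equal(attr(moved, "provenance"), "registered")
})

test_that("round-trip transfer keeps interior voxels; clipping shrinks the mask", {
  tr <- build_neck_phantom(c(32, 32, 8), seed = 4)
  mask <- voi_mask(label_mask(tr, "sbat"), "refined_sbat")
  t <- rigid_transform(translation = c(2, 1, 2))   # lattice-commensurate
  fwd <- transfer_voi(mask, t, c(1, 1, 2))
  back <- transfer_voi(fwd, invert_rigid(t), c(1, 1, 2))
  interior <- erode_6n(mask)
  expect_gte(sum(back & interior) / sum(interior), 0.95)
  ## a mask straddling the last slice loses voxels when pushed off-grid
  edge <- array(FALSE, c(16, 16, 4)); edge[6:10, 6:10, 3:4] <- TRUE
  pushed <- suppressWarnings(
    transfer_voi(voi_mask(edge, "refined_sbat"),
                 rigid_transform(translation = c(0, 0, -4)), c(1, 1, 2)))
  expect_lt(sum(pushed), sum(edge))
})

test_that("registered VOI statistics match truth-mask statistics under sub-voxel motion", {
  motion <- list(rotation = c(0, 0, 0), translation = c(0.5, -0.5, 0.6))
  grid <- c(48, 48, 10)
  p <- acquisition_protocol(grid_shape = grid)
  sp <- fat_spectrum()
  base <- build_neck_phantom(grid, seed = 6, ff_heterogeneity_sd = 0)
  moved <- build_neck_phantom(grid, seed = 6, ff_heterogeneity_sd = 0,
                              motion = motion)
  maps_b <- reconstruct_maps(simulate_multiecho(base, p, sp, 0))
  maps_m <- reconstruct_maps(simulate_multiecho(moved, p, sp, 0))
  voi_b <- refine_voi(voi_mask(coolbat:::dilate_6n(label_mask(base, "sbat")),
                               "crude_manual"), maps_b)
  est <- register_rigid(maps_m$ff, maps_b$ff, voxel_size = c(1, 1, 2))
  voi_m <- refine_voi(transfer_voi(voi_b, est, c(1, 1, 2)), maps_m)
  s_reg <- voi_statistics(voi_m, maps_m)
  s_truth <- voi_statistics(voi_mask(erode_6n(label_mask(moved, "sbat")),
                                     "refined_sbat"), maps_m)
  expect_lt(abs(s_reg$mean_ff_pct - s_truth$mean_ff_pct), 0.5)
})
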