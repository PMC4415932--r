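test_that("6-neighbourhood erosion matches its set-theoretic definition", {
  ## closed forms
  m1 <- array(FALSE, c(5, 5, 5)); m1[3, 3, 3] <- TRUE
  expect_false(any(erode_6n(m1)))                       # isolated voxel
  m2 <- array(FALSE, c(5, 5, 5)); m2[2:4, 2:4, 2:4] <- TRUE
  e2 <- erode_6n(m2)
  expect_equal(sum(e2), 1)                              # 3x3x3 cube -> centre
  expect_true(e2[3, 3, 3])
  m3 <- array(TRUE, c(4, 5, 3))                         # full grid: shell off
  e3 <- erode_6n(m3)
  expect_equal(sum(e3), 2 * 3 * 1)
  expect_true(all(which(e3, arr.ind = TRUE)[, 3] == 2))
  ## random masks against the brute-force neighbour check
  set.seed(31)
  for (i in 1:20) {
    m <- array(runif(6 * 7 * 4) < runif(1, 0.3, 0.8), c(6, 7, 4))
    expect_identical(erode_6n(m), brute_erode_6n(m))
  }
})

test_that("erosion output is always a subset of its input", {
  set.seed(5)
  for (i in 1:10) {
    m <- array(runif(8^3) < 0.6, c(8, 8, 8))
    e <- erode_6n(m)
    expect_true(all(m[e]))
  }
})

test_that("VOI refinement applies inclusive thresholds then one erosion", {
  d <- c(7, 7, 7)
  crude <- array(FALSE, d); crude[2:6, 2:6, 2:6] <- TRUE   # 5x5x5 cube
  ff <- array(0.40, d); r2s <- array(50, d)
  maps <- make_maps(ff, r2s)
  ref <- refine_voi(crude, maps)
  expect_equal(sum(ref), 27)                # boundary values retained, then eroded
  expect_true(all(which(ref, arr.ind = TRUE) >= 3 & which(ref, arr.ind = TRUE) <= 5))
  ## FF just below threshold excludes everything
  expect_warning(ref2 <- refine_voi(crude, make_maps(array(0.399, d), r2s)),
                 "empty")
  expect_true(attr(ref2, "empty"))
  ## R2* just above the ceiling excludes everything
  expect_warning(ref3 <- refine_voi(crude, make_maps(ff, array(50.1, d))), "empty")
  expect_false(any(ref3))
  ## refined mask is always a subset of the crude input
  set.seed(8)
  ffr <- array(runif(prod(d)), d)
  r2r <- array(runif(prod(d), 0, 100), d)
  ref4 <- suppressWarnings(refine_voi(crude, make_maps(ffr, r2r)))
  expect_true(all(crude[ref4]))
  expect_error(refine_voi(array(TRUE, c(2, 2, 2)), maps), "grid")
})

test_that("refined VOIs beat crude VOIs on boundary partial-volume bias", {
  spec <- cohort_spec(seed = 21, grid_shape = c(32, 32, 8), n_subjects = 2)
  p <- acquisition_protocol(grid_shape = c(32, 32, 8))
  sub <- coolbat:::simulate_subject(spec, 1, p, fat_spectrum())
  st <- coolbat:::cohort_states(spec)[1]
  maps <- reconstruct_maps(sub[[st]]$image)
  truth_val <- 100 * mean(truth_ff(sub[[st]]$truth)[label_mask(sub[[st]]$truth, "sbat")])
  crude_mean <- voi_statistics(sub[[st]]$crude_mask, maps)$mean_ff_pct
  refined_mean <- voi_statistics(refine_voi(sub[[st]]$crude_mask, maps),
                                 maps)$mean_ff_pct
  expect_lt(abs(refined_mean - truth_val), abs(crude_mean - truth_val))
  ## boundary voxels make up a meaningful share of the crude mask
  boundary <- sub[[st]]$crude_mask & !label_mask(sub[[st]]$truth, "sbat")
  expect_gte(sum(boundary) / sum(sub[[st]]$crude_mask), 0.10)
})

test_that("posterior SAT segmentation finds the subcutaneous band", {
  p <- acquisition_protocol(grid_shape = c(48, 48, 8))
  tr <- build_neck_phantom(c(48, 48, 8), seed = 13)
  img <- simulate_multiecho(tr, p, fat_spectrum(), noise_sd = 0.02, seed = 1)
  maps <- reconstruct_maps(img)
  sat <- segment_posterior_sat(maps)
  expect_false(attr(sat, "empty"))
  ## all selected voxels are truly SAT and the VOI mean FF tracks the truth
  expect_gt(mean(label_mask(tr, "sat")[sat]), 0.98)
  truth_val <- 100 * mean(truth_ff(tr)[label_mask(tr, "sat")])
  expect_lt(abs(voi_statistics(sat, maps)$mean_ff_pct - truth_val), 0.5)
  ## a zero-fat body yields an empty, flagged mask
  lowfat <- make_maps(array(0.1, c(12, 12, 4)), array(20, c(12, 12, 4)),
                      water = array(0.9, c(12, 12, 4)), fat = array(0.1, c(12, 12, 4)))
  expect_warning(empty <- segment_posterior_sat(lowfat), "empty|posterior")
  expect_true(attr(empty, "empty"))
})

test_that("SAT segmentation is translation-equivariant along the left-right axis", {
  p <- acquisition_protocol(grid_shape = c(48, 48, 8))
  tr <- build_neck_phantom(c(48, 48, 8), seed = 14, anatomy_jitter = rep(0, 7))
  img <- simulate_multiecho(tr, p, fat_spectrum(), noise_sd = 0.02, seed = 2)
  maps <- reconstruct_maps(img)
  k <- 3
  shifted <- maps
  for (nm in c("water", "fat", "ff", "r2s"))
    shifted[[nm]] <- maps[[nm]][c((48 - k + 1):48, 1:(48 - k)), , ]
  a <- array(as.logical(segment_posterior_sat(maps)), c(48, 48, 8))
  b <- array(as.logical(segment_posterior_sat(shifted)), c(48, 48, 8))
  expect_equal(b[c((k + 1):48, 1:k), , ], a)
})

test_that("VOI statistics are plain means, SDs and volumes", {
  d <- c(4, 4, 2)
  ff <- array(0, d); ff[1, 1, 1] <- 0.80; ff[2, 1, 1] <- 0.90
  maps <- make_maps(ff, array(20, d))
  m2 <- array(FALSE, d); m2[1:2, 1, 1] <- TRUE
  st <- voi_statistics(m2, maps)
  expect_equal(st$mean_ff_pct, 85.0)
  expect_equal(st$n_voxels, 2)
  expect_equal(st$volume_ml, 2 * 2 / 1000)
  ## uniform region: zero SD at the assigned value
  mu <- array(TRUE, d)
  stu <- voi_statistics(mu, make_maps(array(0.828, d)))
  expect_equal(stu$mean_ff_pct, 82.8)
  expect_equal(stu$sd_ff_pct, 0)
  ## single voxel
  m1 <- array(FALSE, d); m1[1, 1, 1] <- TRUE
  st1 <- voi_statistics(m1, maps)
  expect_equal(st1$n_voxels, 1)
  expect_equal(st1$sd_ff_pct, 0)
  expect_error(voi_statistics(array(FALSE, d), maps), "empty")
})
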