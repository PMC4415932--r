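#' Rigid transform between two scan grids
#'
#' The transform maps physical coordinates (mm, rotation about the volume
#' centre) of the *fixed* image's grid into the *moving* image's grid — the
#' standard resampling convention: `moving(T(x)) ~ fixed(x)`.
#'
#' @param rotation rotation angles in degrees about x, y, z (applied
#'   z-y-x order).
#' @param translation translation in mm.
#' @param fixed_state,moving_state optional scan-state labels.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            fixed_state = NA_character_,
                            moving_state = NA_character_) {
  stopifnot(length(rotation) == 3, length(translation) == 3)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 fixed_state = fixed_state, moving_state = moving_state),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform%s: rot (%.2f, %.2f, %.2f) deg, trans (%.2f, %.2f, %.2f) mm\n",
              if (is.na(x$fixed_state)) "" else
                sprintf(" [%s -> %s]", x$fixed_state, x$moving_state),
              x$rotation[1], x$rotation[2], x$rotation[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

rigid_par <- function(t) c(t$rotation, t$translation)

## recover z-y-x Euler angles (degrees) from a rotation matrix
angles_from_matrix <- function(R) {
  b <- asin(max(-1, min(1, -R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  c <- atan2(R[2, 1], R[1, 1])
  c(a, b, c) * 180 / pi
}

#' Invert a rigid transform
#'
#' @param t a [rigid_transform()].
#' @return The inverse transform; composing the two is the identity to
#'   numerical precision.
#' @export
invert_rigid <- function(t) {
  R <- rotation_matrix(t$rotation)
  Ri <- t(R)
  ti <- as.numeric(-Ri %*% t$translation)
  rigid_transform(angles_from_matrix(Ri), ti,
                  fixed_state = t$moving_state, moving_state = t$fixed_state)
}

downsample_vol <- function(vol) {
  d <- dim(vol)
  d2 <- pmax(d %/% 2L, 1L)
  fac <- pmin(2L, d)
  sub <- vol[seq_len(d2[1] * fac[1]), seq_len(d2[2] * fac[2]),
             seq_len(d2[3] * fac[3]), drop = FALSE]
  acc <- sub
  if (fac[1] == 2) acc <- acc[seq(1, dim(acc)[1], 2), , , drop = FALSE] +
      acc[seq(2, dim(acc)[1], 2), , , drop = FALSE]
  if (fac[2] == 2) acc <- acc[, seq(1, dim(acc)[2], 2), , drop = FALSE] +
      acc[, seq(2, dim(acc)[2], 2), , drop = FALSE]
  if (fac[3] == 2) acc <- acc[, , seq(1, dim(acc)[3], 2), drop = FALSE] +
      acc[, , seq(2, dim(acc)[3], 2), drop = FALSE]
  acc / prod(fac)
}

#' Rigid registration of two fat-fraction maps
#'
#' Finds the rigid transform maximizing the normalized cross-correlation
#' (NCC) between the fixed FF map and the rigidly resampled moving FF map,
#' using a multi-resolution pyramid: an exhaustive integer translation
#' search at the coarsest level, followed by Nelder-Mead refinement of all
#' six parameters at every level. Deterministic given its inputs.
#'
#' @param fixed_ff,moving_ff numeric arrays (FF maps) on grids of equal
#'   dimensions and voxel size.
#' @param voxel_size voxel size in mm.
#' @param weight optional non-negative array on the fixed grid; only voxels
#'   with positive weight contribute to the NCC (e.g. a body mask).
#' @param levels number of pyramid levels.
#' @param max_trans_mm half-width of the coarse translation search.
#' @param fixed_state,moving_state optional labels stored on the transform.
#' @return A [rigid_transform()] mapping fixed-grid coordinates into the
#'   moving grid (see [transfer_voi()]).
#' @export
register_rigid <- function(fixed_ff, moving_ff, voxel_size = c(1, 1, 2),
                           weight = NULL, levels = 3L, max_trans_mm = 6,
                           fixed_state = NA_character_,
                           moving_state = NA_character_) {
  stopifnot(all(dim(fixed_ff) == dim(moving_ff)))
  if (sd(as.numeric(fixed_ff)) == 0 || sd(as.numeric(moving_ff)) == 0)
    stop("degenerate (constant) image; cannot register")
  if (is.null(weight)) weight <- array(1, dim(fixed_ff))

  pyr_f <- list(fixed_ff); pyr_m <- list(moving_ff); pyr_w <- list(weight)
  pyr_sp <- list(as.numeric(voxel_size))
  while (length(pyr_f) < levels && all(dim(pyr_f[[length(pyr_f)]]) >= 8 |
                                       c(FALSE, FALSE, TRUE))) {
    k <- length(pyr_f)
    if (any(dim(pyr_f[[k]])[1:2] < 8)) break
    pyr_f[[k + 1]] <- downsample_vol(pyr_f[[k]])
    pyr_m[[k + 1]] <- downsample_vol(pyr_m[[k]])
    pyr_w[[k + 1]] <- downsample_vol(pyr_w[[k]])
    pyr_sp[[k + 1]] <- pyr_sp[[k]] * dim(pyr_f[[k]]) / dim(pyr_f[[k + 1]])
  }

  neg_ncc <- function(par, lv) {
    v <- cpp_ncc_rigid(as.numeric(pyr_f[[lv]]), as.numeric(pyr_m[[lv]]),
                       as.integer(dim(pyr_f[[lv]])), pyr_sp[[lv]], par,
                       as.numeric(pyr_w[[lv]]))
    ## soft barrier keeps the simplex inside the plausible motion range
    -v + sum(pmax(abs(par[4:6]) - max_trans_mm, 0)^2)
  }

  lv <- length(pyr_f)
  ## coarse lattice translation search (rotation 0), symmetric around zero
  sp <- pyr_sp[[lv]]
  lattice <- function(step) {
    n <- floor(max_trans_mm / step)
    seq(-n, n) * step
  }
  best <- c(0, 0, 0, 0, 0, 0); bestv <- neg_ncc(best, lv)
  for (tz in lattice(sp[3])) for (ty in lattice(sp[2])) for (tx in lattice(sp[1])) {
    par <- c(0, 0, 0, tx, ty, tz)
    v <- neg_ncc(par, lv)
    if (v < bestv) { bestv <- v; best <- par }
  }
  par <- best
  for (lv in rev(seq_along(pyr_f))) {
    ## the feet-head axis is short and coarsely sampled, so its translation
    ## basin is probed by a line search before simplex refinement
    spz <- pyr_sp[[lv]][3]
    bestv <- neg_ncc(par, lv); bestz <- par[6]
    for (dz in c(-2, -1, -0.5, 0.5, 1, 2) * spz) {
      cand <- par; cand[6] <- par[6] + dz
      if (abs(cand[6]) > max_trans_mm) next
      v <- neg_ncc(cand, lv)
      if (v < bestv) { bestv <- v; bestz <- cand[6] }
    }
    par[6] <- bestz
    maxit <- if (lv == 1) 150 else 200
    ## restart Nelder-Mead at the finest level: a fresh simplex escapes stalls
    for (rep in seq_len(if (lv == 1) 2 else 1)) {
      opt <- optim(par, neg_ncc, lv = lv, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-9))
      par <- opt$par
    }
  }
  rigid_transform(par[1:3], par[4:6], fixed_state, moving_state)
}

#' Transfer a VOI mask through a rigid transform
#'
#' Nearest-neighbour resampling of a binary mask defined on the transform's
#' *moving* grid onto its *fixed* grid (for VOI transfer, register with the
#' target scan as fixed and the scan the mask was drawn on as moving).
#' Voxels mapping outside the source grid are dropped; an empty result is
#' flagged.
#'
#' @param mask VOI mask (logical array or `voi_mask`) on the moving grid.
#' @param t a [rigid_transform()].
#' @param voxel_size voxel size in mm.
#' @return A `voi_mask` with provenance `"registered"` on the fixed grid.
#' @export
transfer_voi <- function(mask, t, voxel_size = c(1, 1, 2)) {
  stopifnot(inherits(t, "rigid_transform"))
  d <- dim(mask)
  v <- cpp_resample_rigid(as.numeric(mask), as.integer(d),
                          as.numeric(voxel_size), rigid_par(t),
                          nearest = TRUE, fill = 0)
  out <- voi_mask(array(v > 0.5, d), "registered", t$fixed_state)
  if (attr(out, "empty")) warning("transferred VOI is empty")
  out
}

#' Resample a volume through a rigid transform
#'
#' Trilinear resampling of a numeric volume onto the transform's fixed grid.
#'
#' @param vol numeric array.
#' @param t a [rigid_transform()].
#' @param voxel_size voxel size in mm.
#' @param fill value for voxels mapping outside the grid.
#' @return Numeric array of the same dimensions.
#' @export
resample_rigid <- function(vol, t, voxel_size = c(1, 1, 2), fill = 0) {
  d <- dim(vol)
  v <- cpp_resample_rigid(as.numeric(vol), as.integer(d),
                          as.numeric(voxel_size), rigid_par(t),
                          nearest = FALSE, fill = fill)
  array(v, d)
}
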