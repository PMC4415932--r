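#' Construct a VOI mask
#'
#' A volume-of-interest mask is a logical array carrying provenance and the
#' scan state it was defined on.
#'
#' @param mask logical array.
#' @param provenance one of `"crude_manual"`, `"refined_sbat"`, `"auto_sat"`,
#'   `"registered"`.
#' @param state scan state label (e.g. `"Baseline"`).
#' @return Object of class `voi_mask`.
#' @export
voi_mask <- function(mask, provenance = c("crude_manual", "refined_sbat",
                                          "auto_sat", "registered"),
                     state = NA_character_) {
  provenance <- match.arg(provenance)
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  structure(mask, provenance = provenance, state = state,
            empty = !any(mask), class = c("voi_mask", class(mask)))
}

as_voi <- function(mask, provenance, state = NA_character_) {
  if (inherits(mask, "voi_mask")) {
    attr(mask, "provenance") <- provenance
    attr(mask, "empty") <- !any(mask)
    mask
  } else voi_mask(mask, provenance, state)
}

#' @export
print.voi_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("VOI mask (%s%s): %d of %d voxels, grid %d x %d x %d%s\n",
              attr(x, "provenance"),
              if (is.na(attr(x, "state"))) "" else paste0(", ", attr(x, "state")),
              sum(x), length(x), d[1], d[2], d[3],
              if (isTRUE(attr(x, "empty"))) " [EMPTY]" else ""))
  invisible(x)
}

shift_mask <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(FALSE, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- m[sx - dx, sy - dy, sz - dz]
  out
}

#' 3D binary erosion with a six-neighbourhood structuring element
#'
#' A voxel is retained iff it and all six face-neighbours are in the input
#' mask; voxels on the grid border are treated as having out-of-mask
#' neighbours and are therefore always removed.
#'
#' @param mask logical array or `voi_mask`.
#' @return Mask of the same type; `erode_6n(m)` is always a subset of `m`.
#' @seealso [refine_voi()]
#' @export
erode_6n <- function(mask) {
  m <- mask
  out <- m &
    shift_mask(m, 1, 0, 0) & shift_mask(m, -1, 0, 0) &
    shift_mask(m, 0, 1, 0) & shift_mask(m, 0, -1, 0) &
    shift_mask(m, 0, 0, 1) & shift_mask(m, 0, 0, -1)
  ## grid border voxels always have an out-of-mask neighbour
  d <- dim(m)
  out[c(1, d[1]), , ] <- FALSE
  out[, c(1, d[2]), ] <- FALSE
  out[, , c(1, d[3])] <- FALSE
  if (inherits(mask, "voi_mask")) {
    attributes(out) <- attributes(mask)
    attr(out, "empty") <- !any(out)
  }
  out
}

## 6-neighbourhood dilation (used to build over-segmented crude masks)
dilate_6n <- function(mask, passes = 1L) {
  m <- mask
  for (i in seq_len(passes)) {
    m <- m |
      shift_mask(m, 1, 0, 0) | shift_mask(m, -1, 0, 0) |
      shift_mask(m, 0, 1, 0) | shift_mask(m, 0, -1, 0) |
      shift_mask(m, 0, 0, 1) | shift_mask(m, 0, 0, -1)
  }
  m
}

#' Refine a crude sBAT VOI by FF/R2* thresholds and erosion
#'
#' Keeps crude-mask voxels with `FF >= ff_min` (removal of non-fatty tissue)
#' and `R2* <= r2s_max` (reduction of partial-volume boundary voxels), both
#' thresholds inclusive, then applies one pass of 6-neighbourhood erosion.
#' The result is always a subset of the crude input; an empty result is
#' permitted and flagged via `attr(, "empty")`.
#'
#' @param crude crude VOI mask (logical array or `voi_mask`).
#' @param maps a `quantitative_maps` object on the same grid.
#' @param ff_min fat-fraction threshold (fraction, default 0.40).
#' @param r2s_max R2* ceiling in s^-1 (default 50).
#' @return A `voi_mask` with provenance `"refined_sbat"`.
#' @export
refine_voi <- function(crude, maps, ff_min = 0.40, r2s_max = 50) {
  stopifnot(inherits(maps, "quantitative_maps"))
  if (!all(dim(crude) == dim(maps$ff)))
    stop("crude mask grid does not match maps grid")
  kept <- array(as.logical(crude) & (maps$ff >= ff_min) & (maps$r2s <= r2s_max),
                dim(maps$ff))
  out <- erode_6n(kept)
  st <- if (inherits(crude, "voi_mask")) attr(crude, "state") else NA_character_
  out <- voi_mask(array(as.logical(out), dim(maps$ff)), "refined_sbat", st)
  if (attr(out, "empty")) warning("refined VOI is empty")
  out
}

## Otsu's threshold on a 256-bin histogram (maximizes between-class variance)
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) * diff(rng) / nbins
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[nbins]
  valid <- w0 > 0 & w0 < 1
  bc <- (mt * w0 - m0)^2 / (w0 * (1 - w0))
  bc[!valid] <- -Inf
  mids[which.max(bc)]
}

#' Automatic posterior subcutaneous adipose tissue (SAT) segmentation
#'
#' Fully automatic, registration-free extraction of the posterior
#' subcutaneous fat band: a body mask is obtained by Otsu thresholding of
#' the total signal `W + F`; then, per axial slice and per left-right
#' column, voxels are collected inward from the posterior body surface while
#' they pass the fat criteria (`FF >= ff_min`, `R2* <= r2s_max`), up to
#' `depth_mm` below the surface — this keeps the fat component connected to
#' the posterior boundary. One pass of 6-neighbourhood erosion is applied.
#' The y axis (second dimension) is the anterior-posterior axis, increasing
#' toward posterior.
#'
#' @param maps a `quantitative_maps` object.
#' @param ff_min fat-fraction threshold (inclusive).
#' @param r2s_max R2* ceiling in s^-1 (inclusive).
#' @param depth_mm maximum depth of the band below the posterior skin
#'   surface, in mm.
#' @param state optional state label recorded on the mask.
#' @return A `voi_mask` with provenance `"auto_sat"`; empty (and flagged) if
#'   no posterior fat is found.
#' @export
segment_posterior_sat <- function(maps, ff_min = 0.40, r2s_max = 50,
                                  depth_mm = 10, state = NA_character_) {
  stopifnot(inherits(maps, "quantitative_maps"))
  total <- maps$water + maps$fat
  thr <- otsu_threshold(as.numeric(total))
  body <- total > thr
  fatpass <- body & (maps$ff >= ff_min) & (maps$r2s <= r2s_max)
  d <- dim(total)
  depth_vox <- max(1L, as.integer(round(depth_mm / maps$voxel_size[2])))
  out <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    bz <- body[, , z]
    fz <- fatpass[, , z]
    for (x in seq_len(d[1])) {
      ys <- which(bz[x, ])
      if (length(ys) == 0) next
      y_surf <- max(ys)
      for (y in y_surf:max(1L, y_surf - depth_vox + 1L)) {
        if (!fz[x, y]) break
        out[x, y, z] <- TRUE
      }
    }
  }
  out <- erode_6n(out)
  m <- voi_mask(out, "auto_sat", state)
  if (attr(m, "empty")) warning("no posterior fat component found; empty SAT VOI")
  m
}

#' VOI summary statistics
#'
#' Arithmetic mean and standard deviation of FF (percent) and R2* (s^-1)
#' over the masked voxels, plus voxel count and volume.
#'
#' @param mask non-empty VOI mask on the maps' grid.
#' @param maps a `quantitative_maps` object.
#' @return One-row data.frame with columns `mean_ff_pct`, `sd_ff_pct`,
#'   `mean_r2s`, `sd_r2s`, `n_voxels`, `volume_ml`.
#' @export
voi_statistics <- function(mask, maps) {
  stopifnot(inherits(maps, "quantitative_maps"))
  if (!all(dim(mask) == dim(maps$ff))) stop("mask grid does not match maps")
  sel <- as.logical(mask)
  n <- sum(sel)
  if (n < 1) stop("VOI is empty; no statistics to report")
  ffv <- maps$ff[sel] * 100
  r2v <- maps$r2s[sel]
  data.frame(mean_ff_pct = mean(ffv),
             sd_ff_pct = if (n > 1) sd(ffv) else 0,
             mean_r2s = mean(r2v),
             sd_r2s = if (n > 1) sd(r2v) else 0,
             n_voxels = n,
             volume_ml = n * prod(maps$voxel_size) / 1000)
}
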