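#' Options for the water-fat reconstruction
#'
#' @param mu unitless regularization weight of the field-map smoothness
#'   penalty (quadratic on neighbour differences, scaled by the echo
#'   spacing); `mu = 0` gives independent per-voxel estimation.
#' @param psi_step field-map search step in Hz.
#' @param psi_range half-width of the field-map search in Hz; `NULL` uses one
#'   aliasing half-period, `1 / (2 delta_TE)`.
#' @param r2s_max upper bound of the R2* search in s^-1.
#' @param r2s_step R2* search step in s^-1.
#' @param r2s_stride coarse stride (in grid steps) of the two-stage R2*
#'   search; `1` forces exhaustive search over the full grid.
#' @param n_scales number of levels in the coarse-to-fine pyramid.
#' @param icm_sweeps maximum iterated-conditional-modes sweeps per level.
#' @param icm_window_hz half-width (Hz) of the candidate window explored
#'   around the incumbent estimate at the finer pyramid levels. Ignored when
#'   `mu = 0` (the full candidate list is always used so that the result
#'   equals exhaustive per-voxel search).
#' @param magnitude_discrimination resolve exact residual ties between a
#'   field-map candidate and its water-fat-swapped partner by preferring the
#'   solution that explains the voxel as a dominant single species (larger
#'   `max(W, F) / (W + F)`); remaining ties break toward smaller `|psi|`.
#' @param fieldmap_r_set nominal R2* values (s^-1) over which the field-map
#'   data term is minimized per candidate (decay compensation during the
#'   decoupled search; `0` reproduces pure zero-decay scoring).
#' @param psi_refine after the R2* search, re-run a windowed field-map pass
#'   with the basis decay fixed per voxel to the estimated R2*, then repeat
#'   the R2* search (iterated decoupling; restores exact inversion of
#'   noiseless data).
#' @return A list of class `recon_options`.
#' @export
recon_options <- function(mu = 10, psi_step = 2, psi_range = NULL,
                          r2s_max = 150, r2s_step = 0.5, r2s_stride = 10L,
                          n_scales = 3L, icm_sweeps = 6L, icm_window_hz = 24,
                          magnitude_discrimination = TRUE,
                          fieldmap_r_set = c(0, 25, 50, 100),
                          psi_refine = TRUE) {
  stopifnot(mu >= 0, psi_step > 0, r2s_max > 0, r2s_step > 0, n_scales >= 1,
            length(fieldmap_r_set) >= 1, all(fieldmap_r_set >= 0))
  structure(list(mu = mu, psi_step = psi_step, psi_range = psi_range,
                 r2s_max = r2s_max, r2s_step = r2s_step,
                 r2s_stride = as.integer(r2s_stride),
                 n_scales = as.integer(n_scales),
                 icm_sweeps = as.integer(icm_sweeps),
                 icm_window_hz = icm_window_hz,
                 magnitude_discrimination = isTRUE(magnitude_discrimination),
                 fieldmap_r_set = as.numeric(fieldmap_r_set),
                 psi_refine = isTRUE(psi_refine)),
            class = "recon_options")
}

psi_candidates <- function(delta_te, opts) {
  half <- opts$psi_range %||% (1 / (2 * delta_te))
  half <- floor(half / opts$psi_step) * opts$psi_step
  seq(-half, half, by = opts$psi_step)
}

r2s_candidates <- function(opts) seq(0, opts$r2s_max, by = opts$r2s_step)

## deterministic candidate visit order: smaller |psi| first, then smaller psi
psi_order <- function(psis) order(abs(psis), psis) - 1L

signal_matrix <- function(image) {
  d <- dim(image$signal)
  matrix(image$signal, prod(d[1:3]), d[4])
}

#' Linear water-fat solve at fixed field map and R2*
#'
#' Least-squares fit of a single voxel's multi-echo signal to the two-column
#' basis `{exp(-r2s t) exp(i 2 pi psi t), c_n exp(-r2s t) exp(i 2 pi psi t)}`.
#' Water and fat are reported as the magnitudes of the complex coefficients.
#'
#' @param signal complex vector, one value per echo.
#' @param echo_times echo times in seconds (same length as `signal`).
#' @param spectrum a [fat_spectrum()].
#' @param psi off-resonance in Hz.
#' @param r2s transverse decay rate in s^-1.
#' @return List with `water`, `fat` (magnitudes), `residual` (fit residual
#'   norm) and `degenerate` (`TRUE` when the basis is numerically
#'   rank-deficient, e.g. all `c_n = 1`).
#' @export
solve_wf <- function(signal, echo_times, spectrum, psi, r2s) {
  stopifnot(length(signal) == length(echo_times), length(echo_times) >= 2)
  cn <- fat_modulation(spectrum, echo_times)
  w <- exp(-r2s * echo_times) * exp(2i * pi * psi * echo_times)
  A <- cbind(w, cn * w)
  G <- Conj(t(A)) %*% A
  degenerate <- rcond(G) < 1e-12
  if (degenerate) {
    ## collapse to a single-column fit; report the total as water
    x1 <- sum(Conj(w) * signal) / sum(Conj(w) * w)
    res <- sqrt(sum(Mod(signal - w * x1)^2))
    return(list(water = Mod(x1), fat = 0, residual = res, degenerate = TRUE))
  }
  x <- solve(G, Conj(t(A)) %*% signal)
  res <- sqrt(sum(Mod(signal - A %*% x)^2))
  list(water = Mod(x[1]), fat = Mod(x[2]), residual = res, degenerate = FALSE)
}

## block-average complex 4D signal by a factor of 2 in each spatial dimension
downsample_echoes <- function(arr) {
  d <- dim(arr)
  d2 <- pmax(d[1:3] %/% 2L, 1L)
  keep <- lapply(1:3, function(a) seq_len(d2[a] * min(2L, d[a])))
  out <- array(0i, c(d2, d[4]))
  sub <- arr[keep[[1]], keep[[2]], keep[[3]], , drop = FALSE]
  fac <- pmin(2L, d[1:3])
  idx <- lapply(1:3, function(a) rep(seq_len(d2[a]), each = fac[a]))
  ## accumulate block sums via tapply-free aggregation
  for (n in seq_len(d[4])) {
    v <- sub[, , , n, drop = FALSE]
    dim(v) <- d2 * fac
    acc <- v
    if (fac[1] == 2) acc <- acc[seq(1, dim(acc)[1], 2), , , drop = FALSE] +
        acc[seq(2, dim(acc)[1], 2), , , drop = FALSE]
    if (fac[2] == 2) acc <- acc[, seq(1, dim(acc)[2], 2), , drop = FALSE] +
        acc[, seq(2, dim(acc)[2], 2), , drop = FALSE]
    if (fac[3] == 2) acc <- acc[, , seq(1, dim(acc)[3], 2), drop = FALSE] +
        acc[, , seq(2, dim(acc)[3], 2), drop = FALSE]
    out[, , , n] <- acc / prod(fac)
  }
  out
}

## nearest-neighbour upsampling of per-voxel candidate indices to finer dims
upsample_idx <- function(idx, coarse_dim, fine_dim) {
  map <- lapply(1:3, function(a) pmin((seq_len(fine_dim[a]) + 1L) %/% 2L, coarse_dim[a]))
  arr <- array(idx, coarse_dim)
  as.integer(arr[map[[1]], map[[2]], map[[3]]])
}

## magnitude-discrimination tie resolution: for voxels where the chosen
## candidate and its swap partner (offset by the dominant fat peak) have
## numerically identical residual, prefer the dominant-single-species fit
resolve_swap_ties <- function(idx, S, tes, psis, cn, spectrum, opts) {
  f_main <- spectrum$frequencies_hz[which.max(spectrum$amplitudes)]
  shift <- round(-f_main / opts$psi_step)   # grid steps from fat to water solution
  if (shift == 0) return(idx)
  np <- length(psis)
  rset <- opts$fieldmap_r_set
  r_here <- cpp_field_resid_at(S, tes, psis, cn, rset, as.integer(idx))
  energy <- rowSums(Mod(S)^2)
  nontrivial <- energy > 1e-12 * max(energy)
  for (sgn in c(1L, -1L)) {
    partner <- idx + sgn * shift
    ok <- nontrivial & partner >= 0L & partner < np
    if (!any(ok)) next
    v_ok <- which(ok)
    r1 <- cpp_field_resid_at(S[v_ok, , drop = FALSE], tes, psis, cn, rset,
                             as.integer(partner[v_ok]))
    tied <- v_ok[abs(r_here[v_ok] - r1) <= 1e-10]
    for (v in tied) {
      j0 <- idx[v] + 1L
      j1 <- idx[v] + sgn * shift + 1L
      f0 <- solve_wf(S[v, ], tes, spectrum, psis[j0], 0)
      f1 <- solve_wf(S[v, ], tes, spectrum, psis[j1], 0)
      dom0 <- max(f0$water, f0$fat) / max(f0$water + f0$fat, 1e-300)
      dom1 <- max(f1$water, f1$fat) / max(f1$water + f1$fat, 1e-300)
      if (dom1 > dom0 + 1e-12) idx[v] <- j1 - 1L
    }
  }
  idx
}

#' Multi-scale regularized field-map estimation
#'
#' Estimates the per-voxel off-resonance frequency by scoring discrete
#' field-map candidates with the residual of the linear water-fat fit (R2*
#' held at zero during the search: decoupled estimation), linked across
#' 6-neighbours by a quadratic smoothness penalty weighted by `mu`. A
#' coarse-to-fine pyramid first solves block-averaged data with an exhaustive
#' candidate search plus iterated conditional modes (ICM), then propagates
#' the labels down as initialization for windowed ICM at the finer levels.
#' With `mu = 0` the result is exactly the independent per-voxel residual
#' minimizer (ties broken toward smaller `|psi|`, then smaller `psi`).
#'
#' @param image a [simulate_multiecho()] result (or compatible
#'   `multiecho_image`).
#' @param spectrum fat spectrum; defaults to the one stored in `image`.
#' @param opts [recon_options()].
#' @return Numeric array (grid shape) of field-map values in Hz.
#' @export
estimate_fieldmap_multiscale <- function(image, spectrum = NULL,
                                         opts = recon_options()) {
  stopifnot(inherits(image, "multiecho_image"))
  spectrum <- spectrum %||% image$spectrum
  sp <- scale_spectrum(spectrum, image$protocol$field_strength)
  tes <- echo_times(image$protocol)
  psis <- psi_candidates(image$protocol$delta_te, opts)
  ord <- psi_order(psis)
  cn <- fat_modulation(sp, tes)

  ## pyramid of block-averaged complex data
  levels <- list(image$signal)
  dims <- list(dim(image$signal)[1:3])
  while (length(levels) < opts$n_scales && all(dims[[length(dims)]] >= 2)) {
    nxt <- downsample_echoes(levels[[length(levels)]])
    levels[[length(levels) + 1]] <- nxt
    dims[[length(dims) + 1]] <- dim(nxt)[1:3]
  }

  window <- if (opts$mu == 0) -1L else
    max(1L, as.integer(round(opts$icm_window_hz / opts$psi_step)))
  idx <- NULL
  for (li in rev(seq_along(levels))) {
    d <- dims[[li]]
    S <- matrix(levels[[li]], prod(d), length(tes))
    rset <- opts$fieldmap_r_set
    if (is.null(idx)) {
      resid <- cpp_field_residuals(S, tes, psis, cn, rset)
      idx <- apply(resid[, ord + 1L, drop = FALSE], 1, which.min)
      idx <- ord[idx]                       # 0-based candidate indices
      sweeps <- if (opts$mu > 0) opts$icm_sweeps else 0L
      if (sweeps > 0)
        idx <- cpp_icm_fieldmap(S, as.integer(d), tes, psis, cn, opts$mu,
                                as.integer(idx), -1L, image$protocol$delta_te,
                                sweeps, as.integer(ord), rset, integer(0))
    } else {
      idx <- upsample_idx(idx, dims[[li + 1]], d)
      win <- if (opts$mu == 0) -1L else window
      sweeps <- if (opts$mu == 0) 1L else opts$icm_sweeps
      idx <- cpp_icm_fieldmap(S, as.integer(d), tes, psis, cn, opts$mu,
                              as.integer(idx), win, image$protocol$delta_te,
                              sweeps, as.integer(ord), rset, integer(0))
    }
    idx <- as.integer(idx)
  }
  if (opts$magnitude_discrimination) {
    S <- matrix(levels[[1]], prod(dims[[1]]), length(tes))
    idx <- resolve_swap_ties(idx, S, tes, psis, cn, sp, opts)
  }
  array(psis[idx + 1L], dims[[1]])
}

#' Decoupled single-R2* estimation for one voxel
#'
#' 1D search over the R2* grid minimizing the residual of the linear
#' water-fat fit at the (already estimated) field-map value. Ties break
#' toward smaller R2*; the estimate is clamped to the search range by
#' construction.
#'
#' @param signal complex per-echo vector.
#' @param echo_times echo times in seconds.
#' @param spectrum a [fat_spectrum()].
#' @param psi field-map value in Hz.
#' @param opts [recon_options()]; `r2s_stride = 1` makes the search
#'   exhaustive.
#' @return R2* in s^-1 (a value of the search grid).
#' @export
estimate_r2s <- function(signal, echo_times, spectrum, psi,
                         opts = recon_options()) {
  stopifnot(length(signal) == length(echo_times))
  cn <- fat_modulation(spectrum, echo_times)
  rg <- r2s_candidates(opts)
  sd_ <- matrix(signal * exp(-2i * pi * psi * echo_times), 1)
  k <- cpp_r2s_search(sd_, echo_times, cn, rg, 1L)
  rg[k + 1L]
}

#' Reconstruct quantitative water/fat/FF/R2*/field maps
#'
#' Composes the three estimation stages: multi-scale regularized field-map
#' estimation (R2* fixed at zero: decoupled), per-voxel 1D R2* search at the
#' estimated field map, and the final linear water-fat solve. The fat
#' fraction is `FF = F / (F + W)` with `FF = 0` (and a degenerate flag)
#' where `F + W` falls below the machine-noise floor.
#'
#' @param image a `multiecho_image`.
#' @param spectrum fat spectrum; defaults to the one stored in `image`.
#' @param opts [recon_options()].
#' @return An object of class `quantitative_maps`: arrays `water`, `fat`,
#'   `ff` (fraction in `[0, 1]`), `r2s` (s^-1), `fieldmap` (Hz), `residual`,
#'   logical `degenerate`, plus `voxel_size` and the `spectrum` and `options`
#'   used.
#' @export
reconstruct_maps <- function(image, spectrum = NULL, opts = recon_options()) {
  stopifnot(inherits(image, "multiecho_image"))
  spectrum <- spectrum %||% image$spectrum
  sp <- scale_spectrum(spectrum, image$protocol$field_strength)
  tes <- echo_times(image$protocol)
  cn <- fat_modulation(sp, tes)
  d <- dim(image$signal)[1:3]

  psi <- estimate_fieldmap_multiscale(image, sp, opts)

  S <- signal_matrix(image)
  psis <- psi_candidates(image$protocol$delta_te, opts)
  ord <- psi_order(psis)
  rg <- r2s_candidates(opts)
  demod <- function(psi_vec) S * exp(-2i * pi * outer(psi_vec, tes))
  Sd <- demod(as.numeric(psi))
  ridx <- cpp_r2s_search(Sd, tes, cn, rg, opts$r2s_stride)

  if (opts$psi_refine) {
    ## iterated decoupling: windowed field-map pass with the basis decay
    ## fixed per voxel at the estimated R2*, then repeat the R2* search
    pidx <- as.integer(round((as.numeric(psi) - psis[1]) / opts$psi_step))
    window <- max(1L, as.integer(round(opts$icm_window_hz / opts$psi_step)))
    pidx <- cpp_icm_fieldmap(S, as.integer(d), tes, psis, cn, opts$mu,
                             pidx, window, image$protocol$delta_te, 2L,
                             as.integer(ord), rg, as.integer(ridx))
    psi <- array(psis[as.integer(pidx) + 1L], d)
    Sd <- demod(as.numeric(psi))
    ridx <- cpp_r2s_search(Sd, tes, cn, rg, opts$r2s_stride)
  }
  wf <- cpp_wf_solve(Sd, tes, cn, ridx, rg)

  W <- wf[, 1]; Fa <- wf[, 2]
  tot <- W + Fa
  floor_ <- sqrt(.Machine$double.eps) * max(Mod(S))
  degen <- tot <= floor_
  ff <- numeric(length(tot))
  ff[!degen] <- Fa[!degen] / tot[!degen]
  ff <- pmin(1, pmax(0, ff))

  shp <- function(x) array(x, d)
  structure(list(water = shp(W), fat = shp(Fa), ff = shp(ff),
                 r2s = shp(rg[ridx + 1L]), fieldmap = psi,
                 residual = shp(wf[, 3]), degenerate = shp(degen),
                 voxel_size = image$protocol$voxel_size,
                 spectrum = sp, options = opts),
            class = "quantitative_maps")
}

#' @export
print.quantitative_maps <- function(x, ...) {
  d <- dim(x$ff)
  cat(sprintf("Quantitative water-fat maps, grid %d x %d x %d\n",
              d[1], d[2], d[3]))
  cat(sprintf("  FF range %.3f-%.3f, R2* range %.1f-%.1f s^-1\n",
              min(x$ff), max(x$ff), min(x$r2s), max(x$r2s)))
  cat(sprintf("  fieldmap range %.1f to %.1f Hz; %d degenerate voxels\n",
              min(x$fieldmap), max(x$fieldmap), sum(x$degenerate)))
  invisible(x)
}

#' @export
summary.quantitative_maps <- function(object, ...) {
  q <- function(a) c(min = min(a), median = median(a), max = max(a))
  out <- rbind(ff = q(object$ff), r2s = q(object$r2s),
               fieldmap = q(object$fieldmap), residual = q(object$residual))
  structure(list(table = out, n_degenerate = sum(object$degenerate)),
            class = "summary.quantitative_maps")
}

#' @export
print.summary.quantitative_maps <- function(x, ...) {
  print(round(x$table, 4))
  cat(sprintf("degenerate voxels: %d\n", x$n_degenerate))
  invisible(x)
}

#' Display one slice of a quantitative map
#'
#' @param x a `quantitative_maps` object.
#' @param map which map to show.
#' @param slice slice index (default: middle slice).
#' @param ... passed to [graphics::image()].
#' @export
plot.quantitative_maps <- function(x, map = c("ff", "r2s", "fieldmap", "water",
                                              "fat", "residual"),
                                   slice = NULL, ...) {
  map <- match.arg(map)
  vol <- x[[map]]
  slice <- slice %||% ((dim(vol)[3] + 1) %/% 2)
  graphics::image(vol[, , slice], asp = dim(vol)[2] / dim(vol)[1],
                  col = grDevices::gray.colors(128), axes = FALSE,
                  main = sprintf("%s, slice %d", map, slice), ...)
  invisible(x)
}

## field-map smoothness penalty of a map (used by tests and diagnostics):
## sum over 6-neighbour pairs of ((psi_a - psi_b) * delta_te)^2
fieldmap_smoothness <- function(psi, delta_te) {
  d <- dim(psi)
  s <- 0
  if (d[1] > 1) s <- s + sum((psi[-1, , ] - psi[-d[1], , ])^2)
  if (d[2] > 1) s <- s + sum((psi[, -1, ] - psi[, -d[2], ])^2)
  if (d[3] > 1) s <- s + sum((psi[, , -1] - psi[, , -d[3]])^2)
  s * delta_te^2
}
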