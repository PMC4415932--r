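## Digital neck phantom: analytic tissue geometry evaluated on the scan grid,
## so that rigid subject motion between scans can be applied exactly (the
## geometry is re-evaluated at rigidly transformed coordinates, no
## interpolation of label volumes).

TISSUE_LEVELS <- c("background", "sbat", "sat", "muscle", "vessel", "bone_marrow")

#' Default tissue parameters for the neck phantom
#'
#' Fat fraction (FF), transverse relaxation rate R2* and relative proton
#' density per tissue label. Adipose FF and R2* defaults are group means for
#' cervical-supraclavicular (sBAT) and posterior subcutaneous (SAT) adipose
#' tissue at thermoneutrality; the remaining tissues take typical literature
#' values.
#'
#' @return A data.frame with columns `tissue`, `ff` (fraction), `r2s`
#'   (s^-1), `density` (arbitrary units).
#' @export
default_tissue_params <- function() {
  data.frame(
    tissue = c("sbat", "sat", "muscle", "vessel", "bone_marrow"),
    ff = c(0.828, 0.852, 0.05, 0.0, 0.85),
    r2s = c(21.0, 19.6, 30.0, 12.0, 60.0),
    density = c(1.0, 1.0, 0.9, 1.0, 0.9),
    stringsAsFactors = FALSE
  )
}

## physical voxel-centre coordinates (mm, origin at volume centre)
grid_coords_mm <- function(grid_shape, voxel_size) {
  ax <- lapply(1:3, function(a) {
    (seq_len(grid_shape[a]) - 1 - 0.5 * (grid_shape[a] - 1)) * voxel_size[a]
  })
  list(x = ax[[1]], y = ax[[2]], z = ax[[3]])
}

rotation_matrix <- function(rotation) {
  a <- rotation * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

## anatomy description; radii and centres in normalized coordinates
## (x, y in [-1, 1] across the grid; y increases toward posterior)
default_anatomy <- function(jitter = NULL) {
  a <- list(
    body_centre = c(0, -0.05),
    body_radii = c(0.82, 0.72),
    body_taper = 0.10,           # cross-section widens toward the shoulders

    sat_thickness = 0.26,        # radial fraction of the body shell
    sat_posterior_min = 0.08,    # normalized y above which the shell is SAT
    sbat_centres = list(c(-0.45, 0.08, 0), c(0.45, 0.08, 0)),
    sbat_radii = c(0.18, 0.16, 0.80),
    vessel_centres = list(c(-0.26, 0.0), c(0.26, 0.0)),
    vessel_radius = 0.05,
    marrow_centre = c(0, -0.22),
    marrow_radius = 0.09
  )
  if (!is.null(jitter)) {
    a$body_radii <- a$body_radii * (1 + jitter[1:2])
    a$sbat_radii <- a$sbat_radii * (1 + jitter[3:5] * 0.5)
    a$sbat_centres <- lapply(a$sbat_centres, function(ct) ct + c(jitter[6], jitter[7], 0) * 0.3)
  }
  a
}

#' Build a digital neck phantom with known ground truth
#'
#' Generates water density, fat density, R2*, off-resonance field map and a
#' tissue label volume on the scan grid. The anatomy holds two interior
#' cervical-supraclavicular adipose (sBAT) blobs flanked by vessels and
#' embedded in muscle, a posterior subcutaneous adipose (SAT) band along the
#' posterior body surface, and a small bone-marrow core. Per-voxel water and
#' fat densities satisfy `F / (F + W) = FF` of the voxel's label, plus an
#' optional smooth zero-mean within-tissue FF variation. The off-resonance
#' field is a smooth low-order polynomial.
#'
#' Rigid subject motion (`motion`) is applied analytically: the geometry is
#' evaluated at inverse-transformed coordinates, so moved phantoms stay
#' exact.
#'
#' @param grid_shape volume dimensions in voxels (x, y, slices).
#' @param tissue_params data.frame as [default_tissue_params()]; must cover
#'   all non-background labels.
#' @param seed integer seed controlling anatomy jitter and the heterogeneity
#'   field.
#' @param voxel_size voxel size in mm (x, y, z); y increases toward
#'   posterior.
#' @param ff_heterogeneity_sd standard deviation (FF fraction) of the smooth
#'   within-tissue FF variation applied to adipose labels; 0 disables it.
#' @param fieldmap either `NULL` (random smooth polynomial, coefficients
#'   drawn from `seed`), a single number (constant field in Hz), or a numeric
#'   array of the grid shape.
#' @param motion `NULL` or `list(rotation = degrees[3], translation = mm[3])`
#'   moving the subject within the scanner frame.
#' @param anatomy_jitter `NULL` for seed-drawn per-subject anatomy variation,
#'   or a numeric(7) in [-0.1, 0.1].
#' @return An object of class `truth_maps`: list with arrays `water`, `fat`,
#'   `r2s`, `fieldmap`, integer `label` (levels in `attr(label, "levels")`),
#'   plus `voxel_size`, `tissue_params`, `motion`.
#' @export
build_neck_phantom <- function(grid_shape, tissue_params = default_tissue_params(),
                               seed = 1L, voxel_size = c(1, 1, 2),
                               ff_heterogeneity_sd = 0.01, fieldmap = NULL,
                               motion = NULL, anatomy_jitter = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0))
  need <- setdiff(TISSUE_LEVELS[-1], tissue_params$tissue)
  if (length(need) > 0)
    stop("tissue_params is missing labels: ", paste(need, collapse = ", "))

  draws <- with_seed(derive_seed(seed, 11L), {
    list(jitter = if (is.null(anatomy_jitter)) runif(7, -0.08, 0.08) else anatomy_jitter,
         fm_coef = runif(6, -1, 1),
         het_par = list(freq = matrix(runif(9, 0.8, 2.4), 3, 3),
                        phase = runif(3, 0, 2 * pi)))
  })
  anat <- default_anatomy(draws$jitter)

  co <- grid_coords_mm(grid_shape, voxel_size)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  X <- rep(co$x, times = ny * nz)
  Y <- rep(rep(co$y, each = nx), times = nz)
  Z <- rep(co$z, each = nx * ny)

  ## subject/body coordinates: invert the rigid motion
  if (!is.null(motion)) {
    R <- rotation_matrix(motion$rotation)
    P <- rbind(X - motion$translation[1], Y - motion$translation[2],
               Z - motion$translation[3])
    P <- t(R) %*% P
    Xb <- P[1, ]; Yb <- P[2, ]; Zb <- P[3, ]
  } else {
    Xb <- X; Yb <- Y; Zb <- Z
  }
  ## normalized body coordinates
  half <- 0.5 * grid_shape * voxel_size
  u <- Xb / half[1]; v <- Yb / half[2]; w <- Zb / half[3]

  ## the cross-section widens toward the shoulders (negative w = feet-ward),
  ## giving the anatomy a feet-head gradient as in a real neck
  zscale <- 1 - anat$body_taper * w
  relsq <- ((u - anat$body_centre[1]) / (anat$body_radii[1] * zscale))^2 +
           ((v - anat$body_centre[2]) / (anat$body_radii[2] * zscale))^2
  body <- relsq <= 1
  shell <- body & relsq >= (1 - anat$sat_thickness)^2
  sat <- shell & v > anat$sat_posterior_min

  ## thin structures keep an effective radius of at least ~one voxel so they
  ## survive coarse demonstration grids
  vox_norm <- 2.2 / min(grid_shape[1], grid_shape[2])
  sbat <- rep(FALSE, length(u))
  sr <- pmax(anat$sbat_radii, c(vox_norm, vox_norm, 0))
  for (ct in anat$sbat_centres) {
    sbat <- sbat | (((u - ct[1]) / sr[1])^2 +
                    ((v - ct[2]) / sr[2])^2 +
                    ((w - ct[3]) / sr[3])^2) <= 1
  }
  sbat <- sbat & body & !sat

  vessel <- rep(FALSE, length(u))
  vr <- max(anat$vessel_radius, vox_norm)
  for (ct in anat$vessel_centres) {
    vessel <- vessel | ((u - ct[1])^2 + (v - ct[2])^2) <= vr^2
  }
  vessel <- vessel & body

  mr <- max(anat$marrow_radius, vox_norm)
  marrow <- body & !sat &
    ((u - anat$marrow_centre[1])^2 + (v - anat$marrow_centre[2])^2) <= mr^2

  label <- integer(length(u))                      # background = 0
  label[body] <- match("muscle", TISSUE_LEVELS) - 1L
  label[sat] <- match("sat", TISSUE_LEVELS) - 1L
  label[marrow] <- match("bone_marrow", TISSUE_LEVELS) - 1L
  label[sbat] <- match("sbat", TISSUE_LEVELS) - 1L
  label[vessel] <- match("vessel", TISSUE_LEVELS) - 1L

  for (ti in TISSUE_LEVELS[-1]) {
    if (!any(label == match(ti, TISSUE_LEVELS) - 1L))
      stop("grid too small to host label '", ti, "'")
  }

  ff <- r2s <- dens <- numeric(length(label))
  for (i in seq_len(nrow(tissue_params))) {
    li <- match(tissue_params$tissue[i], TISSUE_LEVELS) - 1L
    sel <- label == li
    ff[sel] <- tissue_params$ff[i]
    r2s[sel] <- tissue_params$r2s[i]
    dens[sel] <- tissue_params$density[i]
  }

  ## smooth zero-mean within-tissue FF variation, fixed in body coordinates
  if (ff_heterogeneity_sd > 0) {
    hp <- draws$het_par
    h <- sin(hp$freq[1, 1] * pi * u + hp$freq[1, 2] * pi * v +
             hp$freq[1, 3] * pi * w + hp$phase[1]) +
         sin(hp$freq[2, 1] * pi * u + hp$freq[2, 2] * pi * v +
             hp$freq[2, 3] * pi * w + hp$phase[2]) +
         sin(hp$freq[3, 1] * pi * u + hp$freq[3, 2] * pi * v +
             hp$freq[3, 3] * pi * w + hp$phase[3])
    h <- h / sqrt(1.5)  # three unit-amplitude sines: variance ~ 3/2
    fatty <- label %in% (match(c("sbat", "sat", "bone_marrow"), TISSUE_LEVELS) - 1L)
    ff[fatty] <- pmin(1, pmax(0, ff[fatty] + ff_heterogeneity_sd * h[fatty]))
  }

  water <- dens * (1 - ff)
  fat <- dens * ff

  if (is.null(fieldmap)) {
    cf <- draws$fm_coef
    un <- X / half[1]; vn <- Y / half[2]; wn <- Z / half[3]  # scanner frame
    psi <- 15 * cf[1] + 30 * cf[2] * un + 30 * cf[3] * vn + 15 * cf[4] * wn +
      20 * cf[5] * un * vn + 15 * cf[6] * (un^2 - vn^2)
  } else if (length(fieldmap) == 1) {
    psi <- rep(as.numeric(fieldmap), length(label))
  } else {
    stopifnot(all(dim(fieldmap) == grid_shape))
    psi <- as.numeric(fieldmap)
  }

  shp <- function(x) array(x, dim = grid_shape)
  lab <- shp(label)
  attr(lab, "levels") <- TISSUE_LEVELS
  structure(list(water = shp(water), fat = shp(fat), r2s = shp(r2s),
                 fieldmap = shp(psi), label = lab,
                 voxel_size = as.numeric(voxel_size),
                 tissue_params = tissue_params, motion = motion),
            class = "truth_maps")
}

#' True fat-fraction volume of a phantom
#'
#' `F / (F + W)` per voxel; 0 where `F + W = 0`.
#'
#' @param truth a `truth_maps` object.
#' @return Numeric array of the grid shape, values in `[0, 1]`.
#' @export
truth_ff <- function(truth) {
  stopifnot(inherits(truth, "truth_maps"))
  tot <- truth$water + truth$fat
  out <- truth$fat
  out[tot > 0] <- truth$fat[tot > 0] / tot[tot > 0]
  out[tot <= 0] <- 0
  out
}

#' Logical mask of a tissue label
#'
#' @param truth a `truth_maps` object.
#' @param tissue one of `"sbat"`, `"sat"`, `"muscle"`, `"vessel"`,
#'   `"bone_marrow"`, `"background"`.
#' @return Logical array.
#' @export
label_mask <- function(truth, tissue) {
  stopifnot(inherits(truth, "truth_maps"))
  tissue <- match.arg(tissue, TISSUE_LEVELS)
  truth$label == match(tissue, TISSUE_LEVELS) - 1L
}

#' @export
print.truth_maps <- function(x, ...) {
  d <- dim(x$label)
  cat(sprintf("Neck phantom truth maps, grid %d x %d x %d\n", d[1], d[2], d[3]))
  tab <- table(factor(attr(x$label, "levels")[as.integer(x$label) + 1L],
                      levels = attr(x$label, "levels")))
  print(tab)
  invisible(x)
}

#' Simulate a multi-echo chemical-shift-encoded acquisition
#'
#' Evaluates the complex gradient-echo signal model per voxel and echo,
#' `s(TE_n) = (W + F c_n) exp(i 2 pi psi TE_n) exp(-R2* TE_n)`, with `c_n`
#' the fat modulation of `spectrum` (rescaled to the protocol's field
#' strength), and adds independent complex Gaussian noise of standard
#' deviation `noise_sd` to the real and imaginary parts of every voxel and
#' echo.
#'
#' @param truth a [build_neck_phantom()] result (or any `truth_maps`).
#' @param protocol an [acquisition_protocol()]; its grid must match `truth`.
#' @param spectrum a [fat_spectrum()].
#' @param noise_sd Gaussian noise standard deviation per real/imaginary
#'   channel, in the arbitrary signal units of the phantom (>= 0).
#' @param seed optional integer seed for the noise draw.
#' @return An object of class `multiecho_image`: list with the complex 4D
#'   `signal` array (grid x echoes), the `protocol` and the `spectrum` used.
#' @export
simulate_multiecho <- function(truth, protocol, spectrum, noise_sd = 0,
                               seed = NULL) {
  stopifnot(inherits(truth, "truth_maps"),
            inherits(protocol, "acquisition_protocol"),
            inherits(spectrum, "fat_spectrum"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!all(dim(truth$label) == protocol$grid_shape))
    stop("truth grid does not match protocol grid_shape")
  sp <- scale_spectrum(spectrum, protocol$field_strength)
  tes <- echo_times(protocol)
  cn <- fat_modulation(sp, tes)
  nv <- prod(protocol$grid_shape)
  W <- as.numeric(truth$water); Fa <- as.numeric(truth$fat)
  r2s <- as.numeric(truth$r2s); psi <- as.numeric(truth$fieldmap)
  sig <- matrix(0i, nv, protocol$n_echoes)
  for (n in seq_along(tes)) {
    sig[, n] <- (W + Fa * cn[n]) *
      exp(complex(imaginary = 2 * pi * psi * tes[n])) * exp(-r2s * tes[n])
  }
  if (noise_sd > 0) {
    noise_fun <- function() {
      matrix(complex(real = rnorm(nv * length(tes), sd = noise_sd),
                     imaginary = rnorm(nv * length(tes), sd = noise_sd)),
             nv, length(tes))
    }
    sig <- sig + if (is.null(seed)) noise_fun() else with_seed(seed, noise_fun())
  }
  structure(list(signal = array(sig, c(protocol$grid_shape, protocol$n_echoes)),
                 protocol = protocol, spectrum = sp),
            class = "multiecho_image")
}

#' @export
print.multiecho_image <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("Multi-echo complex image: %d x %d x %d voxels, %d echoes\n",
              d[1], d[2], d[3], d[4]))
  print(x$protocol)
  invisible(x)
}
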