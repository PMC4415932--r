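## Independent oracles and small fixture builders used across the suite.

## Set-theoretic 6-neighbourhood erosion: voxel kept iff all face
## neighbours (out-of-grid counts as background) are in the mask.
brute_erode_6n <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    keep <- TRUE
    for (nb in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))) {
      p <- c(x, y, z) + nb
      if (any(p < 1) || any(p > d) || !mask[p[1], p[2], p[3]]) {
        keep <- FALSE
        break
      }
    }
    out[x, y, z] <- keep
  }
  out
}

## Exact two-sided signed-rank p by full 2^n enumeration of sign patterns
## (midranks for tied |d|, zeros dropped), using the same two-sided
## convention as stats::wilcox.test.
brute_signed_rank_p <- function(d) {
  dz <- d[d != 0]
  n <- length(dz)
  if (n == 0) return(1)
  r <- rank(abs(dz))
  V <- sum(r[dz > 0])
  tot <- n * (n + 1) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.numeric(signs %*% r)
  pl <- mean(W <= V)
  pg <- mean(W >= V)
  min(1, if (V > tot / 2) 2 * pg else 2 * pl)
}

## Exhaustive per-voxel field-map search sharing only the *definition* of
## the objective: residual of the linear water-fat fit of the demodulated
## signal, minimized over the nominal decay set; ties toward smaller
## |psi| then smaller psi. Implemented with plain R linear algebra.
brute_fieldmap <- function(image, opts = recon_options()) {
  sp <- scale_spectrum(image$spectrum, image$protocol$field_strength)
  tes <- echo_times(image$protocol)
  cn <- fat_modulation(sp, tes)
  psis <- seq(-floor((1 / (2 * image$protocol$delta_te)) / opts$psi_step) * opts$psi_step,
              by = opts$psi_step,
              length.out = 2 * floor((1 / (2 * image$protocol$delta_te)) / opts$psi_step) + 1)
  ord <- order(abs(psis), psis)
  d <- dim(image$signal)[1:3]
  S <- matrix(image$signal, prod(d), length(tes))
  projs <- lapply(opts$fieldmap_r_set, function(r) {
    B <- cbind(exp(-r * tes), cn * exp(-r * tes))
    diag(length(tes)) - B %*% solve(Conj(t(B)) %*% B) %*% Conj(t(B))
  })
  out <- numeric(nrow(S))
  for (v in seq_len(nrow(S))) {
    s <- S[v, ]
    best <- Inf
    bestp <- psis[ord[1]]
    for (j in ord) {
      sd_ <- s * exp(-2i * pi * psis[j] * tes)
      resid <- min(vapply(projs, function(P) sum(Mod(P %*% sd_)^2), numeric(1)))
      resid <- resid / max(sum(Mod(s)^2), 1e-280)
      if (resid < best) {
        best <- resid
        bestp <- psis[j]
      }
    }
    out[v] <- bestp
  }
  array(out, d)
}

## Uniform-tissue ground truth on an arbitrary grid (bypasses the neck
## geometry; exercises the voxelwise signal model directly).
uniform_truth <- function(grid_shape, ff, r2s, psi = 0, density = 1,
                          voxel_size = c(1, 1, 2)) {
  shp <- function(x) array(x, grid_shape)
  lab <- shp(3L)  # muscle slot; irrelevant for these tests
  attr(lab, "levels") <- c("background", "sbat", "sat", "muscle", "vessel",
                           "bone_marrow")
  structure(list(water = shp(density * (1 - ff)), fat = shp(density * ff),
                 r2s = shp(r2s), fieldmap = shp(psi), label = lab,
                 voxel_size = voxel_size,
                 tissue_params = default_tissue_params(), motion = NULL),
            class = "truth_maps")
}

## Minimal quantitative_maps container for segmentation unit tests.
make_maps <- function(ff, r2s = NULL, water = NULL, fat = NULL,
                      voxel_size = c(1, 1, 2)) {
  d <- dim(ff)
  r2s <- r2s %||% array(20, d)
  fat <- fat %||% ff
  water <- water %||% (1 - ff)
  structure(list(water = water, fat = fat, ff = ff, r2s = r2s,
                 fieldmap = array(0, d), residual = array(0, d),
                 degenerate = array(FALSE, d), voxel_size = voxel_size,
                 spectrum = fat_spectrum(), options = recon_options()),
            class = "quantitative_maps")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## On-grid tissue table (R2* values representable on the 0.5 s^-1 search
## grid) for exact-inversion checks.
ongrid_tissue_params <- function() {
  tp <- default_tissue_params()
  tp$r2s <- c(21.0, 19.5, 30.0, 12.0, 60.0)
  tp
}
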