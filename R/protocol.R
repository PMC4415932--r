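#' Multi-echo gradient-echo acquisition protocol
#'
#' Describes the chemical-shift-encoded acquisition: field strength, echo
#' train timing and volume geometry. Defaults reproduce a 1.5 T protocol with
#' six unipolar echoes (TE1 = 1.68 ms, echo spacing 2.87 ms, TR = 32.7 ms,
#' flip angle 6 degrees) and 1.0 x 1.0 x 2.0 mm voxels; the default demo grid
#' is 64 x 64 x 12.
#'
#' @param field_strength main field in tesla.
#' @param n_echoes number of echoes (>= 3).
#' @param te_first first echo time in seconds.
#' @param delta_te echo spacing in seconds.
#' @param voxel_size voxel edge lengths in mm, length 3
#'   (x = right-left, y = anterior-posterior, z = feet-head).
#' @param grid_shape volume dimensions in voxels (x, y, slices).
#' @param flip_angle excitation flip angle in degrees (kept small so that T1
#'   weighting is negligible; T1 is not modelled).
#' @param tr repetition time in seconds.
#' @return An object of class `acquisition_protocol`.
#' @examples
#' p <- acquisition_protocol()
#' echo_times(p) * 1e3  # ms
#' @export
acquisition_protocol <- function(field_strength = 1.5, n_echoes = 6L,
                                 te_first = 1.68e-3, delta_te = 2.87e-3,
                                 voxel_size = c(1, 1, 2),
                                 grid_shape = c(64L, 64L, 12L),
                                 flip_angle = 6, tr = 32.7e-3) {
  n_echoes <- as.integer(n_echoes)
  stopifnot(length(field_strength) == 1, field_strength > 0,
            length(voxel_size) == 3, all(voxel_size > 0),
            length(grid_shape) == 3, all(grid_shape >= 1))
  if (n_echoes < 3) stop("n_echoes must be >= 3")
  if (te_first <= 0) stop("te_first must be > 0")
  if (delta_te <= 0) stop("delta_te must be > 0")
  structure(list(field_strength = field_strength, n_echoes = n_echoes,
                 te_first = te_first, delta_te = delta_te,
                 voxel_size = as.numeric(voxel_size),
                 grid_shape = as.integer(grid_shape),
                 flip_angle = flip_angle, tr = tr),
            class = "acquisition_protocol")
}

#' Echo times of a protocol
#'
#' @param protocol an [acquisition_protocol()].
#' @return Numeric vector of echo times in seconds, strictly increasing.
#' @export
echo_times <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  protocol$te_first + (seq_len(protocol$n_echoes) - 1) * protocol$delta_te
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("Multi-echo GRE protocol: %.1f T, %d echoes\n",
              x$field_strength, x$n_echoes))
  cat(sprintf("  TE1/dTE/TR = %.2f/%.2f/%.1f ms, flip %.0f deg\n",
              x$te_first * 1e3, x$delta_te * 1e3, x$tr * 1e3, x$flip_angle))
  cat(sprintf("  grid %d x %d x %d, voxel %.1f x %.1f x %.1f mm\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

## gyromagnetic ratio of 1H in MHz/T
.GAMMA_MHZ_PER_T <- 42.577478518

#' Multi-peak fat resonance spectrum
#'
#' Relative amplitudes and frequency offsets (with respect to water) of the
#' fat proton resonances used to model the per-echo fat signal modulation.
#' The default is a nine-peak triglyceride spectrum with the dominant
#' methylene peak at -3.40 ppm (about -217 Hz at 1.5 T); amplitudes are
#' normalized to sum to one. The exact table is configurable and is carried
#' along with every simulation and reconstruction.
#'
#' @param frequencies_hz peak frequency offsets from water, in Hz at
#'   `reference_field`. `NULL` uses the default nine-peak table.
#' @param amplitudes relative peak amplitudes (positive; normalized to sum 1).
#' @param reference_field field strength in tesla at which `frequencies_hz`
#'   are expressed.
#' @return An object of class `fat_spectrum` with elements `frequencies_hz`,
#'   `amplitudes`, `reference_field`.
#' @seealso [fat_modulation()], [scale_spectrum()]
#' @export
fat_spectrum <- function(frequencies_hz = NULL, amplitudes = NULL,
                         reference_field = 1.5) {
  if (is.null(frequencies_hz) != is.null(amplitudes))
    stop("give both frequencies_hz and amplitudes, or neither")
  if (is.null(frequencies_hz)) {
    ## nine-peak triglyceride model; ppm offsets relative to water at 4.7 ppm
    ppm <- c(0.59, 0.49, -0.50, -1.95, -2.46, -2.68, -3.10, -3.40, -3.80)
    amp <- c(0.047, 0.039, 0.006, 0.012, 0.024, 0.065, 0.071, 0.647, 0.089)
    frequencies_hz <- ppm * .GAMMA_MHZ_PER_T * reference_field
    amplitudes <- amp
  }
  stopifnot(length(frequencies_hz) == length(amplitudes),
            length(amplitudes) >= 1)
  if (any(amplitudes <= 0)) stop("relative amplitudes must be positive")
  amplitudes <- amplitudes / sum(amplitudes)
  structure(list(frequencies_hz = as.numeric(frequencies_hz),
                 amplitudes = as.numeric(amplitudes),
                 reference_field = reference_field),
            class = "fat_spectrum")
}

#' Rescale a fat spectrum to another field strength
#'
#' Frequency offsets scale linearly with the main field; amplitudes are
#' unchanged.
#'
#' @param spectrum a [fat_spectrum()].
#' @param field_strength target field in tesla.
#' @return A `fat_spectrum` expressed at `field_strength`.
#' @export
scale_spectrum <- function(spectrum, field_strength) {
  stopifnot(inherits(spectrum, "fat_spectrum"))
  fat_spectrum(spectrum$frequencies_hz * field_strength / spectrum$reference_field,
               spectrum$amplitudes, reference_field = field_strength)
}

#' @export
print.fat_spectrum <- function(x, ...) {
  cat(sprintf("Fat spectrum: %d peaks at %.1f T (amplitudes sum to 1)\n",
              length(x$amplitudes), x$reference_field))
  print(data.frame(frequency_hz = round(x$frequencies_hz, 1),
                   amplitude = round(x$amplitudes, 4)), row.names = FALSE)
  invisible(x)
}

#' Complex fat modulation coefficients per echo
#'
#' Evaluates `c_n = sum_p alpha_p exp(i 2 pi f_p TE_n)`, the net complex
#' modulation of the fat signal relative to water at each echo time.
#'
#' @param spectrum a [fat_spectrum()].
#' @param echo_times echo times in seconds (non-empty).
#' @return Complex vector, one coefficient per echo; `Mod(c_n) <= 1`.
#' @export
fat_modulation <- function(spectrum, echo_times) {
  stopifnot(inherits(spectrum, "fat_spectrum"))
  if (length(echo_times) == 0) stop("echo_times must be non-empty")
  vapply(echo_times, function(te) {
    sum(spectrum$amplitudes * exp(2i * pi * spectrum$frequencies_hz * te))
  }, complex(1))
}
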