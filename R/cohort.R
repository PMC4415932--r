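COOLING_STATES <- c("Baseline", "Cold", "Reheated")
PROCEDURE_STATES <- c("Scan1", "Scan2")

#' Cohort simulation specification
#'
#' Defines the statistical structure of a simulated cooling-reheating (or
#' procedure-study) cohort: per-subject baseline tissue values are drawn
#' from normal distributions, and per-subject state effects are drawn from
#' the effect distributions below (means in FF percentage points, pp; R2*
#' effects in s^-1). Defaults reproduce the group statistics of the study
#' conditions the package emulates:
#' baseline sBAT-FF 82.8 +- 5.0 %, SAT-FF 85.2 +- 5.1 %, sBAT-R2*
#' 21.0 +- 1.8 s^-1, SAT-R2* 19.6 +- 2.8 s^-1; a persistent (lipid-type)
#' sBAT-FF cold effect of -1.94 +- 1.83 pp; a SAT-FF cold effect of
#' 0.23 +- 0.53 pp; a posture-related SAT-FF drift of -0.79 +- 0.27 pp
#' between the Cold and Reheated scans (-0.75 +- 0.64 pp between the two
#' scans of the procedure mode); a reversible sBAT-R2* cold effect of
#' 0.65 +- 0.88 s^-1 and a persistent SAT-R2* cold effect of
#' 0.40 +- 0.46 s^-1.
#'
#' Lipid-type effects persist through reheating; perfusion-type effects
#' reverse on reheating; the posture drift is applied between the Cold and
#' Reheated states regardless of temperature (and between the two scans of
#' the procedure mode).
#'
#' @param n_subjects number of subjects (default 9 for the
#'   cooling-reheating mode, 8 for the procedure mode).
#' @param mode `"cooling_reheating"` (three states) or `"procedure_study"`
#'   (two scans, no temperature effects).
#' @param baseline list of `c(mean, sd)` pairs: `sbat_ff`, `sat_ff`
#'   (FF fraction), `sbat_r2s`, `sat_r2s` (s^-1).
#' @param sbat_lipid_ff_change `c(mean, sd)` pp; persists through reheating.
#' @param sbat_perfusion_ff_change `c(mean, sd)` pp; reverses on reheating.
#' @param sat_cold_ff_change `c(mean, sd)` pp applied to SAT at the Cold
#'   state (persists; not temperature-attributed).
#' @param sat_posture_ff_drift `c(mean, sd)` pp applied to SAT between Cold
#'   and Reheated (or between the two procedure scans).
#' @param r2s_changes list with elements `sbat` and `sat`, each
#'   `list(cold = c(mean, sd), reversible = TRUE/FALSE)`.
#' @param noise_sd complex-channel noise standard deviation in the
#'   simulator's arbitrary units (adipose total signal is about 1, so 0.02
#'   corresponds to SNR 50).
#' @param ff_heterogeneity_sd within-tissue FF standard deviation (fraction).
#' @param motion_max rigid inter-state motion bounds:
#'   `list(trans_mm = c(x, y, z), rot_deg = c(x, y, z))`.
#' @param grid_shape simulated volume dimensions.
#' @param seed integer seed; fixed seed gives bit-identical cohorts.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = NULL,
                        mode = c("cooling_reheating", "procedure_study"),
                        baseline = list(sbat_ff = c(0.828, 0.050),
                                        sat_ff = c(0.852, 0.051),
                                        sbat_r2s = c(21.0, 1.8),
                                        sat_r2s = c(19.6, 2.8)),
                        sbat_lipid_ff_change = c(-1.94, 1.83),
                        sbat_perfusion_ff_change = c(0, 0),
                        sat_cold_ff_change = c(0.23, 0.53),
                        sat_posture_ff_drift = NULL,
                        r2s_changes = list(
                          sbat = list(cold = c(0.65, 0.88), reversible = TRUE),
                          sat = list(cold = c(0.40, 0.46), reversible = FALSE)),
                        noise_sd = 0.02,
                        ff_heterogeneity_sd = 0.01,
                        motion_max = list(trans_mm = c(3, 3, 2),
                                          rot_deg = c(1, 1, 3)),
                        grid_shape = c(64L, 64L, 12L),
                        seed = 1L) {
  mode <- match.arg(mode)
  n_subjects <- n_subjects %||% if (mode == "cooling_reheating") 9L else 8L
  sat_posture_ff_drift <- sat_posture_ff_drift %||%
    if (mode == "cooling_reheating") c(-0.79, 0.27) else c(-0.75, 0.64)
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  for (nm in c("sbat_ff", "sat_ff")) {
    b <- baseline[[nm]]
    if (is.null(b) || b[1] <= 0 || b[1] >= 1)
      stop("baseline FF means must lie in (0, 1)")
    if (b[2] < 0) stop("baseline SDs must be >= 0")
  }
  structure(list(n_subjects = as.integer(n_subjects), mode = mode,
                 baseline = baseline,
                 sbat_lipid_ff_change = sbat_lipid_ff_change,
                 sbat_perfusion_ff_change = sbat_perfusion_ff_change,
                 sat_cold_ff_change = sat_cold_ff_change,
                 sat_posture_ff_drift = sat_posture_ff_drift,
                 r2s_changes = r2s_changes,
                 noise_sd = noise_sd,
                 ff_heterogeneity_sd = ff_heterogeneity_sd,
                 motion_max = motion_max,
                 grid_shape = as.integer(grid_shape),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: %d subjects, %s mode, seed %d\n",
              x$n_subjects, x$mode, x$seed))
  cat(sprintf("  sBAT lipid effect %.2f +- %.2f pp, perfusion %.2f +- %.2f pp\n",
              x$sbat_lipid_ff_change[1], x$sbat_lipid_ff_change[2],
              x$sbat_perfusion_ff_change[1], x$sbat_perfusion_ff_change[2]))
  cat(sprintf("  SAT posture drift %.2f +- %.2f pp; noise sd %.3f\n",
              x$sat_posture_ff_drift[1], x$sat_posture_ff_drift[2], x$noise_sd))
  invisible(x)
}

cohort_states <- function(spec) {
  if (spec$mode == "cooling_reheating") COOLING_STATES else PROCEDURE_STATES
}

rnorm2 <- function(n, ms) rnorm(n, ms[1], ms[2])

## Draw the exact per-subject truth: assigned tissue values per state plus
## rigid inter-state motions. All cohort randomness flows through spec$seed.
draw_cohort_truth <- function(spec) {
  ns <- spec$n_subjects
  states <- cohort_states(spec)
  with_seed(derive_seed(spec$seed, 1L), {
    base <- data.frame(
      subject = seq_len(ns),
      sbat_ff = rnorm2(ns, spec$baseline$sbat_ff),
      sat_ff = rnorm2(ns, spec$baseline$sat_ff),
      sbat_r2s = rnorm2(ns, spec$baseline$sbat_r2s),
      sat_r2s = rnorm2(ns, spec$baseline$sat_r2s))
    eff <- data.frame(
      subject = seq_len(ns),
      lipid = rnorm2(ns, spec$sbat_lipid_ff_change) / 100,
      perfusion = rnorm2(ns, spec$sbat_perfusion_ff_change) / 100,
      sat_cold = rnorm2(ns, spec$sat_cold_ff_change) / 100,
      drift = rnorm2(ns, spec$sat_posture_ff_drift) / 100,
      sbat_r2s_cold = rnorm2(ns, spec$r2s_changes$sbat$cold),
      sat_r2s_cold = rnorm2(ns, spec$r2s_changes$sat$cold))
    motions <- lapply(seq_len(ns), function(i) {
      out <- list()
      for (st in states) {
        out[[st]] <- if (st == states[1]) {
          list(rotation = c(0, 0, 0), translation = c(0, 0, 0))
        } else {
          list(rotation = runif(3, -1, 1) * spec$motion_max$rot_deg,
               translation = runif(3, -1, 1) * spec$motion_max$trans_mm)
        }
      }
      out
    })

    rows <- list()
    rev_sbat <- isTRUE(spec$r2s_changes$sbat$reversible)
    rev_sat <- isTRUE(spec$r2s_changes$sat$reversible)
    for (i in seq_len(ns)) {
      for (st in states) {
        if (spec$mode == "cooling_reheating") {
          sbat_ff <- switch(st,
            Baseline = base$sbat_ff[i],
            Cold = base$sbat_ff[i] + eff$lipid[i] + eff$perfusion[i],
            Reheated = base$sbat_ff[i] + eff$lipid[i])
          sat_ff <- switch(st,
            Baseline = base$sat_ff[i],
            Cold = base$sat_ff[i] + eff$sat_cold[i],
            Reheated = base$sat_ff[i] + eff$sat_cold[i] + eff$drift[i])
          sbat_r2s <- switch(st,
            Baseline = base$sbat_r2s[i],
            Cold = base$sbat_r2s[i] + eff$sbat_r2s_cold[i],
            Reheated = base$sbat_r2s[i] + if (rev_sbat) 0 else eff$sbat_r2s_cold[i])
          sat_r2s <- switch(st,
            Baseline = base$sat_r2s[i],
            Cold = base$sat_r2s[i] + eff$sat_r2s_cold[i],
            Reheated = base$sat_r2s[i] + if (rev_sat) 0 else eff$sat_r2s_cold[i])
        } else {
          sbat_ff <- base$sbat_ff[i]
          sat_ff <- base$sat_ff[i] + if (st == "Scan2") eff$drift[i] else 0
          sbat_r2s <- base$sbat_r2s[i]
          sat_r2s <- base$sat_r2s[i]
        }
        rows[[length(rows) + 1]] <- data.frame(
          subject = i, state = st,
          sbat_ff = min(0.99, max(0.01, sbat_ff)),
          sat_ff = min(0.99, max(0.01, sat_ff)),
          sbat_r2s = max(0, sbat_r2s), sat_r2s = max(0, sat_r2s))
      }
    }
    ledger <- do.call(rbind, rows)
    ledger$state <- factor(ledger$state, levels = states)
    list(ledger = ledger, effects = eff, motions = motions)
  })
}

#' Per-subject true VOI means without image simulation
#'
#' Draws the cohort truth ledger (per-subject, per-state assigned sBAT and
#' SAT values) and returns it in the measurement format used by
#' [summarize_protocol()], bypassing image simulation and reconstruction.
#' Useful for fast statistical power and attribution studies of the cohort
#' design itself.
#'
#' @param spec a [cohort_spec()].
#' @return Measurements data.frame with columns `subject`, `state`, `voi`
#'   (`"sbat"`/`"sat"`), `mean_ff_pct`, `mean_r2s`, with attribute `mode`.
#' @export
simulate_measurements <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  led <- draw_cohort_truth(spec)$ledger
  long <- rbind(
    data.frame(subject = led$subject, state = led$state, voi = "sbat",
               mean_ff_pct = led$sbat_ff * 100, mean_r2s = led$sbat_r2s),
    data.frame(subject = led$subject, state = led$state, voi = "sat",
               mean_ff_pct = led$sat_ff * 100, mean_r2s = led$sat_r2s))
  attr(long, "mode") <- spec$mode
  long
}

## Build the full imaging data of one subject: per state a truth phantom
## (with rigid motion), a noisy multi-echo image, and an over-segmenting
## crude sBAT mask drawn on that state's grid.
simulate_subject <- function(spec, subject, protocol, spectrum,
                             truth_draws = NULL) {
  truth_draws <- truth_draws %||% draw_cohort_truth(spec)
  states <- cohort_states(spec)
  led <- truth_draws$ledger
  out <- list()
  for (si in seq_along(states)) {
    st <- states[si]
    row <- led[led$subject == subject & led$state == st, ]
    tp <- default_tissue_params()
    tp$ff[tp$tissue == "sbat"] <- row$sbat_ff
    tp$ff[tp$tissue == "sat"] <- row$sat_ff
    tp$r2s[tp$tissue == "sbat"] <- row$sbat_r2s
    tp$r2s[tp$tissue == "sat"] <- row$sat_r2s
    motion <- truth_draws$motions[[subject]][[st]]
    truth <- build_neck_phantom(spec$grid_shape, tp,
                                seed = derive_seed(spec$seed, 2L, subject),
                                voxel_size = protocol$voxel_size,
                                ff_heterogeneity_sd = spec$ff_heterogeneity_sd,
                                motion = motion)
    image <- simulate_multiecho(truth, protocol, spectrum,
                                noise_sd = spec$noise_sd,
                                seed = derive_seed(spec$seed, 3L, subject, si))
    ## crude manual over-segmentation: a 2-pass dilation of the true blob,
    ## minus the subcutaneous band (manual outlining excludes SAT), so that
    ## boundary muscle/vessel voxels exercise the threshold-and-erosion
    ## refinement
    crude <- voi_mask(dilate_6n(label_mask(truth, "sbat"), passes = 2L) &
                        !dilate_6n(label_mask(truth, "sat"), passes = 1L),
                      "crude_manual", st)
    out[[st]] <- list(image = image, truth = truth, crude_mask = crude,
                      motion = motion)
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Generates, for every subject and scan state, a ground-truth phantom
#' (rigidly moved between states), a noisy multi-echo acquisition and an
#' over-segmenting crude sBAT mask, together with the exact truth ledger of
#' assigned per-subject VOI values.
#'
#' @param spec a [cohort_spec()].
#' @param protocol an [acquisition_protocol()]; its `grid_shape` is taken
#'   from `spec`.
#' @param spectrum a [fat_spectrum()].
#' @return Object of class `cohort_sim`: list with `subjects` (list of
#'   per-state `image`/`truth`/`crude_mask`/`motion`), `ledger`, `spec`.
#' @export
simulate_cohort <- function(spec, protocol = NULL, spectrum = fat_spectrum()) {
  stopifnot(inherits(spec, "cohort_spec"))
  protocol <- protocol %||% acquisition_protocol(grid_shape = spec$grid_shape)
  protocol$grid_shape <- spec$grid_shape
  draws <- draw_cohort_truth(spec)
  subjects <- lapply(seq_len(spec$n_subjects), function(i) {
    simulate_subject(spec, i, protocol, spectrum, draws)
  })
  structure(list(subjects = subjects, ledger = draws$ledger,
                 motions = draws$motions, spec = spec, protocol = protocol),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d subjects x %d states, grid %s\n",
              x$spec$n_subjects, length(cohort_states(x$spec)),
              paste(x$spec$grid_shape, collapse = " x ")))
  invisible(x)
}
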