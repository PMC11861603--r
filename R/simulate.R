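#' Activity archetypes for the synthetic signal simulator
#'
#' An archetype describes the generative shape of one activity class on a
#' chest-worn tri-axial accelerometer. Four kinds are supported:
#' \describe{
#'   \item{periodic}{gait-like motion: a fundamental plus two harmonics at a
#'     class-specific cadence, riding on the standing gravity projection
#'     (walking cadence defaults near 1.5 Hz, about 90 steps per minute).}
#'   \item{transition}{a postural transition (sit/stand/lie): the gravity
#'     projection interpolates smoothly between two orientations over 1-2 s,
#'     with a movement burst during the transition.}
#'   \item{transient_fall}{a quiescent phase, a short high-magnitude impact
#'     spike at a random time in the middle third of the window, then the
#'     reoriented (post-fall) gravity projection.}
#'   \item{static}{a fixed gravity projection plus sensor noise.}
#' }
#' All amplitudes are in units of g; the simulator multiplies by
#' `unit_scale` (raw counts per g) at the end.
#'
#' @param name class abbreviation.
#' @param kind one of `"periodic"`, `"transition"`, `"transient_fall"`,
#'   `"static"`.
#' @param base_freq_hz fundamental frequency in Hz (periodic kinds).
#' @param freq_jitter relative frequency jitter per segment (uniform).
#' @param amplitude length-3 numeric, per-axis motion amplitude in g.
#' @param gravity_before,gravity_after unit 3-vectors: gravity orientation
#'   before/after the event (equal for non-transition kinds).
#' @param impact_magnitude impact spike peak in g (falls).
#' @param impact_axis unit 3-vector: direction of the impact spike.
#' @param noise_sigma sensor noise standard deviation in g.
#' @return Object of class `activity_archetype`.
#' @export
activity_archetype <- function(name, kind, base_freq_hz = 1.5,
                               freq_jitter = 0.1,
                               amplitude = c(0.2, 0.2, 0.2),
                               gravity_before = c(0, 0, 1),
                               gravity_after = gravity_before,
                               impact_magnitude = 0,
                               impact_axis = c(0, 0, 1),
                               noise_sigma = 0.04) {
  kind <- match.arg(kind, c("periodic", "transition", "transient_fall", "static"))
  if (kind == "periodic" && base_freq_hz <= 0)
    stop("`base_freq_hz` must be positive for periodic archetypes", call. = FALSE)
  unit <- function(v) v / sqrt(sum(v^2))
  stopifnot(length(amplitude) == 3L, length(gravity_before) == 3L,
            length(gravity_after) == 3L, length(impact_axis) == 3L)
  structure(list(name = name, kind = kind, base_freq_hz = base_freq_hz,
                 freq_jitter = freq_jitter, amplitude = as.double(amplitude),
                 gravity_before = unit(as.double(gravity_before)),
                 gravity_after = unit(as.double(gravity_after)),
                 impact_magnitude = impact_magnitude,
                 impact_axis = unit(as.double(impact_axis)),
                 noise_sigma = noise_sigma),
            class = "activity_archetype")
}

# Reference gravity orientations (unit vectors) for a chest-worn sensor:
# x lateral, y anterior-posterior, z body-vertical.
.g_stand <- c(0.05, 0.08, 1)
.g_sit   <- c(0.05, 0.30, 0.95)
.g_supine <- c(0.08, 0.95, 0.30)
.g_prone  <- c(0.10, -0.95, 0.25)
.g_prone_knees <- c(0.10, -0.85, 0.52)
.g_left  <- c(0.95, 0.05, 0.30)

# Mirror an archetype across the lateral (x) axis sign.
mirror_x <- function(a, name) {
  a$name <- name
  a$gravity_before[1] <- -a$gravity_before[1]
  a$gravity_after[1] <- -a$gravity_after[1]
  a$impact_axis[1] <- -a$impact_axis[1]
  a
}

#' Default archetype set: the 15-activity taxonomy
#'
#' Ships one archetype per class of [default_taxonomy()], with deliberately
#' similar parameter pairs (FF vs FFK differ only in impact magnitude and
#' post-fall pitch; LF and RF are mirror images across the lateral-axis
#' sign) so that the confusability structure of real fall data is emulated.
#'
#' @return Named list of 15 [activity_archetype()] objects.
#' @export
default_archetypes <- function() {
  lf <- activity_archetype("LF", "transient_fall", amplitude = c(0.05, 0.05, 0.05),
                           gravity_before = .g_stand, gravity_after = .g_left,
                           impact_magnitude = 5.0, impact_axis = c(0.9, 0.1, 0.35))
  a <- list(
    activity_archetype("UPS", "periodic", base_freq_hz = 0.9,
                       amplitude = c(0.20, 0.15, 0.40), gravity_before = .g_stand),
    activity_archetype("DWS", "periodic", base_freq_hz = 1.1,
                       amplitude = c(0.25, 0.18, 0.50), gravity_before = .g_stand),
    activity_archetype("SC", "transition", amplitude = c(0.25, 0.35, 0.50),
                       gravity_before = .g_stand, gravity_after = .g_sit),
    activity_archetype("GC", "transition", amplitude = c(0.25, 0.35, 0.50),
                       gravity_before = .g_sit, gravity_after = .g_stand),
    activity_archetype("LUB", "transition", amplitude = c(0.20, 0.40, 0.40),
                       gravity_before = .g_sit, gravity_after = .g_supine),
    activity_archetype("LDB", "transition", amplitude = c(0.20, 0.40, 0.40),
                       gravity_before = .g_supine, gravity_after = .g_sit),
    activity_archetype("WK", "periodic", base_freq_hz = 1.5,
                       amplitude = c(0.25, 0.20, 0.45), gravity_before = .g_stand),
    activity_archetype("SQ", "periodic", base_freq_hz = 0.4,
                       amplitude = c(0.15, 0.45, 0.70), gravity_before = .g_stand),
    activity_archetype("JR", "periodic", base_freq_hz = 2.4,
                       amplitude = c(0.30, 0.35, 0.90), gravity_before = .g_stand),
    activity_archetype("FF", "transient_fall", amplitude = c(0.05, 0.05, 0.05),
                       gravity_before = .g_stand, gravity_after = .g_prone,
                       impact_magnitude = 5.5, impact_axis = c(0.1, -0.9, 0.4)),
    activity_archetype("FFK", "transient_fall", amplitude = c(0.05, 0.05, 0.05),
                       gravity_before = .g_stand, gravity_after = .g_prone_knees,
                       impact_magnitude = 4.0, impact_axis = c(0.1, -0.9, 0.4)),
    activity_archetype("FB", "transient_fall", amplitude = c(0.05, 0.05, 0.05),
                       gravity_before = .g_stand, gravity_after = .g_supine,
                       impact_magnitude = 5.0, impact_axis = c(0.1, 0.9, 0.35)),
    lf,
    mirror_x(lf, "RF"),
    activity_archetype("FOB", "transient_fall", amplitude = c(0.05, 0.05, 0.05),
                       gravity_before = .g_supine, gravity_after = .g_prone,
                       impact_magnitude = 3.5, impact_axis = c(0.3, -0.85, 0.3))
  )
  names(a) <- vapply(a, function(x) x$name, character(1))
  a
}

#' Simulator configuration
#'
#' @param archetypes named list of [activity_archetype()]; defaults to the
#'   full 15-class set.
#' @param classes optional character vector of abbreviations to keep (e.g.
#'   `c("WK", "JR", "SC", "FF")` for a 4-class problem).
#' @param n_subjects number of subjects (>= 3).
#' @param reps_per_class segments per subject per class (default 5,
#'   mirroring five repetitions of each activity per subject).
#' @param fs sampling rate in Hz (default 250).
#' @param segment_seconds segment length in seconds (default 10).
#' @param subject_effect_sd standard deviation of the per-subject log-normal
#'   amplitude multiplier (frequency multiplier uses half this value).
#' @param unit_scale raw counts per g. The default is calibrated so that the
#'   pooled standard deviation of the full 15-class default dataset is close
#'   to 550 raw counts, the scale at which the noise-sweep sigma values
#'   \[22.5, 55, 110, 165, 220, 275\] are meaningful.
#' @param seed integer master seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(archetypes = default_archetypes(), classes = NULL,
                             n_subjects = 10, reps_per_class = 5, fs = 250,
                             segment_seconds = 10, subject_effect_sd = 0.15,
                             unit_scale = 989, seed = 1L) {
  if (!is.null(classes)) {
    missing <- setdiff(classes, names(archetypes))
    if (length(missing))
      stop("unknown classes: ", paste(missing, collapse = ", "), call. = FALSE)
    archetypes <- archetypes[classes]
  }
  if (n_subjects < 3) stop("`n_subjects` must be >= 3", call. = FALSE)
  if (reps_per_class < 1) stop("`reps_per_class` must be >= 1", call. = FALSE)
  structure(list(archetypes = archetypes, n_subjects = as.integer(n_subjects),
                 reps_per_class = as.integer(reps_per_class), fs = fs,
                 segment_seconds = segment_seconds,
                 subject_effect_sd = subject_effect_sd,
                 unit_scale = unit_scale, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Smoothstep ramp from 0 to 1 centred at `t0` with width `w` seconds.
smoothstep <- function(t, t0, w) {
  u <- pmin(pmax((t - (t0 - w / 2)) / w, 0), 1)
  u * u * (3 - 2 * u)
}

#' Simulate one segment from an archetype
#'
#' @param archetype an [activity_archetype()].
#' @param subject_effects list with elements `amp` and `freq`, multiplicative
#'   per-subject effects (default both 1).
#' @param fs sampling rate in Hz.
#' @param seconds segment length in seconds.
#' @param seed integer seed (deterministic output).
#' @param unit_scale raw counts per g.
#' @inheritParams accel_segment
#' @return An [accel_segment()] of `fs * seconds` samples.
#' @export
simulate_segment <- function(archetype, subject_effects = list(amp = 1, freq = 1),
                             fs = 250, seconds = 10, seed = 1L,
                             unit_scale = 989, subject_id = "S1",
                             segment_index = 1L) {
  stopifnot(inherits(archetype, "activity_archetype"))
  n <- as.integer(round(fs * seconds))
  t <- (seq_len(n) - 1) / fs
  a <- archetype
  x <- with_seed(seed, {
    grav <- switch(a$kind,
      static = ,
      periodic = outer(rep(1, n), a$gravity_before),
      transition = {
        t0 <- runif(1, 0.3 * seconds, 0.7 * seconds)
        w <- runif(1, 1, 2)
        s <- smoothstep(t, t0, w)
        outer(1 - s, a$gravity_before) + outer(s, a$gravity_after)
      },
      transient_fall = {
        t0 <- runif(1, seconds / 3, 2 * seconds / 3)
        s <- smoothstep(t, t0 + 0.15, 0.3)
        outer(1 - s, a$gravity_before) + outer(s, a$gravity_after)
      })
    motion <- matrix(0, n, 3)
    if (a$kind == "periodic") {
      f <- a$base_freq_hz * (1 + runif(1, -a$freq_jitter, a$freq_jitter)) *
        subject_effects$freq
      ph <- runif(3, 0, 2 * pi)
      axph <- runif(3, 0, 2 * pi)
      for (k in 1:3)
        motion[, k] <- a$amplitude[k] * subject_effects$amp *
          (sin(2 * pi * f * t + ph[1] + axph[k]) +
             0.4 * sin(2 * pi * 2 * f * t + ph[2] + axph[k]) +
             0.2 * sin(2 * pi * 3 * f * t + ph[3] + axph[k]))
      # cadence-locked step impacts (heel strikes): short broadband pulses at
      # the fundamental period, the component that makes real gait
      # spectrograms informative well above the stride frequency
      step_t <- seq(ph[1] / (2 * pi * f), seconds, by = 1 / f)
      step_t <- step_t + rnorm(length(step_t), 0, 0.01 / f)
      amp_mag <- sqrt(sum(a$amplitude^2)) * subject_effects$amp
      pulse <- numeric(n)
      for (tk in step_t) {
        lo <- max(1L, floor((tk - 0.04) * fs)); hi <- min(n, ceiling((tk + 0.04) * fs))
        if (lo <= hi)
          pulse[lo:hi] <- pulse[lo:hi] +
            runif(1, 0.7, 1.3) * exp(-0.5 * ((t[lo:hi] - tk) / 0.008)^2)
      }
      dir <- a$gravity_before
      for (k in 1:3)
        motion[, k] <- motion[, k] + 1.2 * amp_mag * dir[k] * pulse
    } else if (a$kind == "transition") {
      # movement burst centred on the gravity midpoint along the axis that
      # changes most during the transition
      k0 <- which.max(abs(a$gravity_after - a$gravity_before))
      mid <- t[which.min(abs(grav[, k0] -
                               (a$gravity_before[k0] + a$gravity_after[k0]) / 2))]
      env <- exp(-0.5 * ((t - mid) / 0.6)^2)
      for (k in 1:3)
        motion[, k] <- a$amplitude[k] * subject_effects$amp * env *
          sin(2 * pi * 1.2 * (t - mid))
    } else if (a$kind == "transient_fall") {
      # impact spike at the gravity switch point
      sw <- t[which.max(abs(diff(grav[, which.max(abs(a$gravity_after -
                                                        a$gravity_before))]))) ]
      pulse <- exp(-0.5 * ((t - sw) / 0.04)^2)
      ring <- 0.25 * exp(-(t - sw) / 0.25) * (t >= sw) *
        sin(2 * pi * 9 * (t - sw))
      for (k in 1:3)
        motion[, k] <- a$impact_magnitude * subject_effects$amp *
          a$impact_axis[k] * (pulse + ring) +
          a$amplitude[k] * subject_effects$amp * rnorm(n, 0, 0.3)
    }
    noise <- matrix(rnorm(3 * n, 0, a$noise_sigma), n, 3)
    (grav + motion + noise) * unit_scale
  })
  accel_segment(x, fs = fs, subject_id = subject_id, label = a$name,
                segment_index = segment_index)
}

#' Simulate a subject-grouped dataset
#'
#' Generates `n_subjects * n_classes * reps_per_class` segments. Per-subject
#' multiplicative amplitude and frequency effects are drawn once per subject
#' and held fixed across all of that subject's segments, inducing the
#' intra-subject correlation that motivates subject-independent evaluation.
#' Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return List of [accel_segment()], class-balanced.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  eff <- with_seed(cfg$seed, list(
    amp = exp(rnorm(cfg$n_subjects, 0, cfg$subject_effect_sd)),
    freq = exp(rnorm(cfg$n_subjects, 0, cfg$subject_effect_sd / 2))))
  out <- vector("list", cfg$n_subjects * length(cfg$archetypes) * cfg$reps_per_class)
  i <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    se <- list(amp = eff$amp[s], freq = eff$freq[s])
    for (ci in seq_along(cfg$archetypes)) {
      for (r in seq_len(cfg$reps_per_class)) {
        i <- i + 1L
        out[[i]] <- simulate_segment(
          cfg$archetypes[[ci]], subject_effects = se, fs = cfg$fs,
          seconds = cfg$segment_seconds,
          seed = derive_seed(cfg$seed, s, ci, r),
          unit_scale = cfg$unit_scale,
          subject_id = sprintf("S%03d", s), segment_index = r)
      }
    }
  }
  out
}
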