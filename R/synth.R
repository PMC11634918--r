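#' Synthetic study design
#'
#' Describes a reach-to-grasp dataset to simulate. The defaults emulate a
#' dyadic motor-distance study: one confederate contributing 16 sessions
#' (treated downstream as 16 separate subject-instances sharing a single
#' movement style), 16 distinct participants, about 20 trials per instance,
#' two grip conditions (precision grip PG, whole-hand prehension WHP),
#' sampled at 100 Hz.
#'
#' @param n_participants Number of participants (default 16).
#' @param n_confederate_instances Confederate sessions (default 16).
#' @param trials_per_instance Trials per subject-instance (default 20).
#' @param conditions Character vector of grip conditions
#'   (default `c("PG", "WHP")`).
#' @param sample_rate Sampling rate in Hz (default 100).
#' @return A list of class `synth_design`.
#' @export
synth_design <- function(n_participants = 16L, n_confederate_instances = 16L,
                         trials_per_instance = 20L,
                         conditions = c("PG", "WHP"), sample_rate = 100) {
  stopifnot(n_participants >= 1L, n_confederate_instances >= 1L,
            trials_per_instance >= 1L, length(conditions) >= 1L,
            sample_rate > 0)
  structure(list(n_participants = as.integer(n_participants),
                 n_confederate_instances = as.integer(n_confederate_instances),
                 trials_per_instance = as.integer(trials_per_instance),
                 conditions = conditions, sample_rate = sample_rate),
            class = "synth_design")
}

#' Population hyperparameters for subject movement styles
#'
#' Ranges from which subject styles are drawn, in units natural to a
#' tabletop reach-to-grasp: reach amplitude 200-400 mm, movement time
#' 0.6-1.4 s, time-asymmetry exponent 0.8-1.25 (skews time-to-peak-speed),
#' path curvature 10-60 mm. Trial-to-trial noise is a 5% coefficient of
#' variation on the style parameters plus 1.5 mm of smooth positional
#' noise, keeping within-subject variability well below between-subject
#' style differences.
#'
#' @param amplitude_mm,duration_s,asymmetry,curvature_mm Length-2 numeric
#'   ranges (min, max).
#' @param param_cv Per-trial coefficient of variation on amplitude,
#'   duration and asymmetry; must be < 0.3.
#' @param additive_mm Standard deviation of smooth additive positional
#'   noise, mm.
#' @return A list of class `style_hyperparams`.
#' @export
style_hyperparams <- function(amplitude_mm = c(200, 400),
                              duration_s = c(0.6, 1.4),
                              asymmetry = c(0.8, 1.25),
                              curvature_mm = c(10, 60),
                              param_cv = 0.05, additive_mm = 1.5) {
  check_range <- function(r, nm) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] <= 0) {
      stop("`", nm, "` must be a positive (min, max) range.")
    }
  }
  check_range(amplitude_mm, "amplitude_mm")
  check_range(duration_s, "duration_s")
  check_range(asymmetry, "asymmetry")
  check_range(curvature_mm, "curvature_mm")
  if (param_cv < 0 || param_cv >= 0.3) {
    stop("`param_cv` must lie in [0, 0.3) to keep trials non-degenerate.")
  }
  if (additive_mm < 0) stop("`additive_mm` must be non-negative.")
  structure(list(amplitude_mm = amplitude_mm, duration_s = duration_s,
                 asymmetry = asymmetry, curvature_mm = curvature_mm,
                 param_cv = param_cv, additive_mm = additive_mm),
            class = "style_hyperparams")
}

#' Draw one subject's movement style
#'
#' Samples style parameters uniformly from the hyperparameter ranges.
#' Deterministic given a seed.
#'
#' @param hyper A [style_hyperparams()] object.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside [simulate_trials()]).
#' @return A list of class `synth_style` with scalar `amplitude_mm`,
#'   `duration_s`, `asymmetry`, `curvature_mm` and the noise settings.
#' @export
draw_style <- function(hyper = style_hyperparams(), seed = NULL) {
  if (!is.null(seed)) {
    rng <- local_rng(seed)
    on.exit(restore_rng(rng))
  }
  u <- function(r) stats::runif(1, r[1], r[2])
  structure(list(amplitude_mm = u(hyper$amplitude_mm),
                 duration_s = u(hyper$duration_s),
                 asymmetry = u(hyper$asymmetry),
                 curvature_mm = u(hyper$curvature_mm),
                 param_cv = hyper$param_cv,
                 additive_mm = hyper$additive_mm),
            class = "synth_style")
}

# Minimum-jerk position fraction s(u) = 10u^3 - 15u^4 + 6u^5.
min_jerk_s <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5

#' Generate one synthetic reach-to-grasp trial
#'
#' Simulates a wrist trajectory along a reach axis following the
#' minimum-jerk path `D * (10u^3 - 15u^4 + 6u^5)` with the time warp
#' `u = tau^gamma` (asymmetry), a curvature bow in a second axis, and
#' smooth additive positional noise (white noise low-pass filtered at
#' 6 Hz). Trial-level variability multiplies amplitude, duration and
#' asymmetry by `1 + param_cv * z`. The result is pre-windowed from onset
#' to offset, sampled at `sample_rate`.
#'
#' @param style A `synth_style` object.
#' @param seed Optional integer seed for this trial.
#' @param sample_rate Sampling rate in Hz (default 100).
#' @return A tibble with columns `t` (s), `x`, `y`, `z` (mm).
#' @export
generate_trial <- function(style, seed = NULL, sample_rate = 100) {
  if (!is.null(seed)) {
    rng <- local_rng(seed)
    on.exit(restore_rng(rng))
  }
  jitter1 <- function(v) v * (1 + style$param_cv * stats::rnorm(1))
  D <- jitter1(style$amplitude_mm)
  Tm <- jitter1(style$duration_s)
  g <- jitter1(style$asymmetry)
  if (!all(is.finite(c(D, Tm, g))) || D <= 0 || Tm <= 0 || g <= 0) {
    stop("Non-finite or non-positive trial parameters.")
  }
  # midpoint sampling at the exact rate: n samples centred in [0, T], so a
  # symmetric speed profile is sampled palindromically
  n <- max(10L, round(Tm * sample_rate))
  tt <- (seq_len(n) - 0.5) / sample_rate
  tau <- tt / Tm
  s <- min_jerk_s(tau^g)
  x <- D * s
  y <- style$curvature_mm * sin(pi * s)
  z <- numeric(length(tt))
  if (style$additive_mm > 0) {
    noise <- matrix(stats::rnorm(3 * length(tt), sd = style$additive_mm),
                    ncol = 3)
    noise <- apply(noise, 2, lowpass_filter, cutoff = 6,
                   sample_rate = sample_rate)
    x <- x + noise[, 1]
    y <- y + noise[, 2]
    z <- z + noise[, 3]
  }
  tibble::tibble(t = tt, x = x, y = y, z = z)
}

#' Simulate a full synthetic dataset
#'
#' Generates long-format raw trials for the whole design. All confederate
#' instances share a single style (their trials differ only by trial
#' noise), while each participant gets a fresh style -- the ground truth
#' that within-person distances should come out smaller than between-person
#' ones. Beyond the first condition, each subject's style parameters are
#' perturbed by a per-subject condition factor (`condition_cv`, default 8%
#' coefficient of variation), so the conditions' distance structures are
#' correlated but not identical.
#'
#' @param design A [synth_design()] object.
#' @param seed Integer seed; the output is fully determined by
#'   (seed, design).
#' @param hyper Population [style_hyperparams()].
#' @param condition_cv Coefficient of variation of the per-subject style
#'   perturbation applied in conditions after the first (default 0.08).
#' @return A tibble with columns `subject`, `group`, `condition`, `trial`,
#'   `t`, `x`, `y`, `z`; the simulation manifest (design, seed, true
#'   styles) is attached as attribute `"manifest"`.
#' @examples
#' trials <- simulate_trials(design = synth_design(n_participants = 2,
#'   n_confederate_instances = 2, trials_per_instance = 3,
#'   conditions = "PG"), seed = 1)
#' @export
simulate_trials <- function(design = synth_design(), seed,
                            hyper = style_hyperparams(),
                            condition_cv = 0.08) {
  stopifnot(inherits(design, "synth_design"))
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  conf_style <- draw_style(hyper)
  subjects <- c(
    sprintf("C%02d", seq_len(design$n_confederate_instances)),
    sprintf("P%02d", seq_len(design$n_participants))
  )
  groups <- c(rep("confederate_instance", design$n_confederate_instances),
              rep("participant", design$n_participants))
  base_styles <- c(
    rep(list(conf_style), design$n_confederate_instances),
    lapply(seq_len(design$n_participants), function(i) draw_style(hyper))
  )
  rows <- list()
  style_log <- list()
  for (si in seq_along(subjects)) {
    for (ci in seq_along(design$conditions)) {
      st <- base_styles[[si]]
      if (ci > 1L && condition_cv > 0) {
        st$amplitude_mm <- st$amplitude_mm * (1 + condition_cv * stats::rnorm(1))
        st$duration_s <- st$duration_s * (1 + condition_cv * stats::rnorm(1))
        st$asymmetry <- st$asymmetry * (1 + condition_cv * stats::rnorm(1))
      }
      style_log[[length(style_log) + 1L]] <- tibble::tibble(
        subject = subjects[si], group = groups[si],
        condition = design$conditions[ci],
        amplitude_mm = st$amplitude_mm, duration_s = st$duration_s,
        asymmetry = st$asymmetry, curvature_mm = st$curvature_mm)
      for (tr in seq_len(design$trials_per_instance)) {
        trial <- generate_trial(st, sample_rate = design$sample_rate)
        trial$subject <- subjects[si]
        trial$group <- groups[si]
        trial$condition <- design$conditions[ci]
        trial$trial <- sprintf("T%02d", tr)
        rows[[length(rows) + 1L]] <- trial
      }
    }
  }
  out <- dplyr::bind_rows(rows)[, c("subject", "group", "condition",
                                    "trial", "t", "x", "y", "z")]
  attr(out, "manifest") <- list(design = design, seed = seed,
                                styles = dplyr::bind_rows(style_log))
  out
}
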