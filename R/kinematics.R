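#' Zero-phase low-pass Butterworth filtering
#'
#' Applies a 2nd-order low-pass Butterworth filter forward and backward
#' (zero phase, effective 4th order, squared magnitude response) with
#' odd-reflection edge padding so that transients do not contaminate the
#' movement window.
#'
#' @param x Numeric vector, uniformly sampled.
#' @param cutoff Cutoff frequency in Hz. Must be below the Nyquist frequency.
#' @param sample_rate Sampling rate in Hz.
#' @return Filtered numeric vector of the same length as `x`.
#' @examples
#' lowpass_filter(rep(3, 50), cutoff = 8, sample_rate = 100)
#' @export
lowpass_filter <- function(x, cutoff, sample_rate) {
  stopifnot(is.numeric(x), length(cutoff) == 1L, length(sample_rate) == 1L)
  if (!is.finite(cutoff) || !is.finite(sample_rate) || sample_rate <= 0) {
    stop("`cutoff` and `sample_rate` must be finite and `sample_rate` positive.")
  }
  if (cutoff <= 0 || cutoff >= sample_rate / 2) {
    stop("`cutoff` must lie strictly between 0 and the Nyquist frequency (",
         sample_rate / 2, " Hz).")
  }
  bf <- signal::butter(2, cutoff / (sample_rate / 2), type = "low")
  b <- bf$b
  a <- bf$a
  # odd-reflection padding, 3x the coefficient count on each side
  pad <- 3L * max(length(a), length(b))
  n <- length(x)
  if (n <= pad) {
    stop("Series too short for zero-phase filtering: need more than ",
         pad, " samples, got ", n, ".")
  }
  head_pad <- 2 * x[1] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, xp, zi * xp[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

# Steady-state initial filter state (direct form II transposed), so a
# constant input produces a constant output from the first sample.
lfilter_zi <- function(b, a) {
  m <- length(a) - 1L
  A <- rbind(-a[-1] / a[1],
             cbind(diag(1, m - 1L, m - 1L), rep(0, m - 1L)))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(m) - t(A), B)
}

# IIR difference equation with explicit initial state.
iir_filter <- function(b, a, x, zi) {
  nb <- length(b)
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    yi <- b[1] * x[i] + z[1]
    if (nb > 2L) {
      for (j in seq_len(nb - 2L)) {
        z[j] <- b[j + 1L] * x[i] + z[j + 1L] - a[j + 1L] * yi
      }
    }
    z[nb - 1L] <- b[nb] * x[i] - a[nb] * yi
    y[i] <- yi
  }
  y
}

# Central-difference derivative with one-sided differences at the endpoints.
finite_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2L) stop("Need at least 2 samples to differentiate.")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2L) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

#' Wrist kinematics from a position time series
#'
#' Computes the three scalar kinematic series used throughout the package
#' from a wrist marker trajectory: wrist velocity `wv` (the module of the
#' velocity vector, mm/s), wrist acceleration `wa` (the rate of change of
#' `wv`, mm/s^2, may be negative), and wrist jerk `wj` (the rate of change
#' of the module of the acceleration vector, mm/s^3). Derivatives use
#' central differences on interior samples and one-sided differences at the
#' endpoints.
#'
#' @param positions Numeric matrix with one row per sample and columns
#'   x, y, z in mm (a single column is accepted for 1-D motion).
#' @param sample_rate Sampling rate in Hz.
#' @param wa_method `"dspeed"` (default) defines `wa` as d(wv)/dt;
#'   `"dnorm"` uses the module of the acceleration vector instead (always
#'   non-negative). Both readings are standard; the default keeps `wa`
#'   signed so deceleration is visible.
#' @return A tibble with columns `wv`, `wa`, `wj`, one row per sample.
#' @examples
#' pos <- cbind(100 * seq(0, 1, by = 0.01), 0, 0)
#' compute_kinematics(pos, sample_rate = 100)
#' @export
compute_kinematics <- function(positions, sample_rate,
                               wa_method = c("dspeed", "dnorm")) {
  wa_method <- match.arg(wa_method)
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || anyNA(positions)) {
    stop("`positions` must be a numeric matrix with no missing samples.")
  }
  if (nrow(positions) < 5L) stop("Need at least 5 position samples.")
  dt <- 1 / sample_rate
  vel <- apply(positions, 2, finite_diff, dt = dt)
  wv <- sqrt(rowSums(vel^2))
  acc <- apply(vel, 2, finite_diff, dt = dt)
  acc_norm <- sqrt(rowSums(acc^2))
  wa <- if (wa_method == "dspeed") finite_diff(wv, dt) else acc_norm
  wj <- finite_diff(acc_norm, dt)
  tibble::tibble(wv = wv, wa = wa, wj = wj)
}

#' Non-overlapping decile averages of a series
#'
#' Divides a series into `n_bins` contiguous, non-overlapping, exhaustive
#' bins and returns the arithmetic mean of each. Bin `b` (1-based) covers
#' the 0-based sample indices in `[floor((b-1)*N/n_bins), floor(b*N/n_bins))`,
#' which makes trials of different durations comparable on a common
#' normalized time base.
#'
#' @param x Numeric vector of length at least `n_bins`.
#' @param n_bins Number of bins (default 10, i.e. deciles).
#' @return Numeric vector of `n_bins` bin means.
#' @examples
#' decile_average(1:100) # 5.5, 15.5, ..., 95.5
#' @export
decile_average <- function(x, n_bins = 10L) {
  n <- length(x)
  if (n < n_bins) {
    stop("Series length (", n, ") must be at least `n_bins` (", n_bins, ").")
  }
  edges <- floor((0:n_bins) * n / n_bins)
  vapply(seq_len(n_bins), function(b) {
    mean(x[(edges[b] + 1L):edges[b + 1L]])
  }, numeric(1))
}

#' Build one time-normalized trial matrix
#'
#' Runs the per-trial preprocessing pipeline on a single trial: low-pass
#' filter each position axis, differentiate into wv/wa/wj, and decile-average
#' each variable into `n_timepoints` bins, yielding the `n_timepoints x 3`
#' matrix (columns WV, WA, WJ) that the Procrustes machinery treats as a
#' shape with the time points as landmarks.
#'
#' @param positions Numeric matrix of x,y,z positions (mm), or `NULL` when
#'   `scalars` is supplied.
#' @param scalars Optional matrix/data frame with columns wv, wa, wj when
#'   kinematics are precomputed; filtering and differentiation are bypassed.
#' @param sample_rate Sampling rate in Hz (default 100).
#' @param filter_cutoff Low-pass cutoff in Hz (default 8); `NA` disables
#'   filtering.
#' @param n_timepoints Number of time bins (default 10).
#' @inheritParams compute_kinematics
#' @return Numeric `n_timepoints x 3` matrix with columns `wv`, `wa`, `wj`.
#' @export
build_trial_matrix <- function(positions = NULL, scalars = NULL,
                               sample_rate = 100, filter_cutoff = 8,
                               n_timepoints = 10L,
                               wa_method = c("dspeed", "dnorm")) {
  if (is.null(positions) == is.null(scalars)) {
    stop("Supply exactly one of `positions` or `scalars`.")
  }
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (anyNA(positions)) stop("Missing position samples are not allowed.")
    if (!is.na(filter_cutoff)) {
      positions <- apply(positions, 2, lowpass_filter,
                         cutoff = filter_cutoff, sample_rate = sample_rate)
    }
    kin <- compute_kinematics(positions, sample_rate, wa_method = wa_method)
  } else {
    scalars <- as.matrix(scalars)
    if (ncol(scalars) != 3L) stop("`scalars` must have columns wv, wa, wj.")
    if (anyNA(scalars)) stop("Missing kinematic samples are not allowed.")
    kin <- tibble::tibble(wv = scalars[, 1], wa = scalars[, 2],
                          wj = scalars[, 3])
  }
  m <- cbind(wv = decile_average(kin$wv, n_timepoints),
             wa = decile_average(kin$wa, n_timepoints),
             wj = decile_average(kin$wj, n_timepoints))
  if (!all(is.finite(m))) stop("Trial matrix contains non-finite values.")
  m
}

#' Time-normalized trial matrices for a whole dataset
#'
#' Tidy front end to [build_trial_matrix()]: takes long-format trial records
#' and returns one row per (trial, timepoint, variable). Input columns are
#' `subject`, `group`, `condition`, `trial`, `t`, and either `x`,`y`,`z`
#' (marker position in mm) or `wv`,`wa`,`wj` (precomputed kinematics).
#' Rows must be time-ordered within trial; trials are assumed pre-windowed
#' from reach onset to offset.
#'
#' @param trials Data frame of raw trials in long format.
#' @param sample_rate Sampling rate in Hz (default 100).
#' @param filter_cutoff Butterworth cutoff in Hz (default 8); ignored for
#'   precomputed kinematics.
#' @param n_timepoints Number of time bins (default 10).
#' @inheritParams compute_kinematics
#' @return A tibble with columns `subject`, `group`, `condition`, `trial`,
#'   `timepoint`, `variable` (wv/wa/wj), `value`.
#' @examples
#' trials <- simulate_trials(design = synth_design(n_participants = 2,
#'   n_confederate_instances = 2, trials_per_instance = 3), seed = 1)
#' tm <- trial_matrices(trials)
#' @export
trial_matrices <- function(trials, sample_rate = 100, filter_cutoff = 8,
                           n_timepoints = 10L,
                           wa_method = c("dspeed", "dnorm")) {
  wa_method <- match.arg(wa_method)
  req <- c("subject", "group", "condition", "trial", "t")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("Missing columns: ", paste(miss, collapse = ", "))
  has_pos <- all(c("x", "y", "z") %in% names(trials))
  has_scal <- all(c("wv", "wa", "wj") %in% names(trials))
  if (!has_pos && !has_scal) {
    stop("Need either x,y,z position columns or wv,wa,wj kinematic columns.")
  }
  trials |>
    dplyr::group_by(.data$subject, .data$group, .data$condition, .data$trial) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      m <- if (has_pos) {
        build_trial_matrix(positions = as.matrix(df[, c("x", "y", "z")]),
                           sample_rate = sample_rate,
                           filter_cutoff = filter_cutoff,
                           n_timepoints = n_timepoints,
                           wa_method = wa_method)
      } else {
        build_trial_matrix(scalars = as.matrix(df[, c("wv", "wa", "wj")]),
                           n_timepoints = n_timepoints)
      }
      tibble::tibble(timepoint = rep(seq_len(n_timepoints), 3L),
                     variable = rep(c("wv", "wa", "wj"),
                                    each = n_timepoints),
                     value = as.vector(m))
    }) |>
    dplyr::ungroup()
}

# Reassemble the n_timepoints x 3 matrix of one trial/FPT from tidy rows.
tidy_to_matrix <- function(df, value_col = "value") {
  wide <- tidyr::pivot_wider(df[, c("timepoint", "variable", value_col)],
                             names_from = "variable",
                             values_from = dplyr::all_of(value_col))
  wide <- wide[order(wide$timepoint), ]
  as.matrix(wide[, c("wv", "wa", "wj")])
}

#' Read a long-format trial CSV
#'
#' @param path Path to a UTF-8 CSV with header
#'   `subject,group,condition,trial,t,x,y,z` or
#'   `subject,group,condition,trial,t,wv,wa,wj`.
#' @return A tibble of trial records; missing samples are a load-time error.
#' @export
read_trials_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("subject", "group", "condition", "trial", "t")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("Malformed trial CSV, missing: ",
                         paste(miss, collapse = ", "))
  num_cols <- intersect(c("t", "x", "y", "z", "wv", "wa", "wj"), names(df))
  bad <- which(!stats::complete.cases(df[num_cols]))
  if (length(bad)) {
    stop("Missing samples at data row(s) ", paste(utils::head(bad, 5),
         collapse = ", "), "; gaps are not interpolated.")
  }
  df
}
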