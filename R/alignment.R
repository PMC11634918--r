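#' Inter-trial alignment: collapse one subject's trials into an FPT trial
#'
#' Aligns every non-target trial of one subject onto a chosen target trial
#' with a full Procrustes fit (scaling and reflection enabled), stacks the
#' target (untransformed) with the transformed trials, and averages
#' elementwise across the stack to produce the subject's final
#' Procrustes-transformed (FPT) trial. Per-cell standard deviation across
#' the stack captures inter-trial variability; the population (divide-by-t)
#' convention is the default since the stack is the full set of retained
#' trials, not a sample.
#'
#' @param trials List of `n_timepoints x 3` trial matrices for one subject.
#' @param target_index Index of the trial used as Procrustes target
#'   (default 1, the first available trial).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A list of class `fpt_trial` with elements `mean` (the FPT
#'   matrix), `sd` (per-cell standard deviation), `t` (number of trials) and
#'   `target_index`.
#' @examples
#' X <- matrix(rnorm(30), 10, 3)
#' f <- align_trials(list(X, 2 * X + 1, 0.5 * X - 3))
#' max(abs(f$mean - X)) # ~0: similarity transforms collapse onto the target
#' @export
align_trials <- function(trials, target_index = 1L,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  t_n <- length(trials)
  if (t_n < 1L) stop("Need at least one trial.")
  if (target_index < 1L || target_index > t_n) {
    stop("`target_index` out of range (1..", t_n, ").")
  }
  target <- as.matrix(trials[[target_index]])
  stack <- array(NA_real_, dim = c(nrow(target), ncol(target), t_n))
  stack[, , 1L] <- target
  others <- setdiff(seq_len(t_n), target_index)
  for (s in seq_along(others)) {
    i <- others[s]
    fit <- tryCatch(procrustes_fit(target, as.matrix(trials[[i]])),
                    error = function(e) {
                      stop("Trial ", i, ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    stack[, , s + 1L] <- fit$Z
  }
  mu <- apply(stack, c(1, 2), mean)
  if (t_n == 1L) {
    sdm <- matrix(0, nrow(target), ncol(target))
  } else {
    denom <- if (sd_type == "population") t_n else t_n - 1L
    sdm <- sqrt(apply(stack, c(1, 2), function(v) sum((v - mean(v))^2)) / denom)
  }
  dimnames(mu) <- dimnames(target)
  dimnames(sdm) <- dimnames(target)
  structure(list(mean = mu, sd = sdm, t = t_n, target_index = target_index),
            class = "fpt_trial")
}

# Resolve a target rule into an index given the trial ids in order of
# appearance. Rules: "first" (default), an integer index, or a trial id.
resolve_target <- function(rule, trial_ids) {
  if (identical(rule, "first")) return(1L)
  if (is.numeric(rule)) {
    idx <- as.integer(rule)
    if (idx < 1L || idx > length(trial_ids)) {
      stop("Target index ", idx, " out of range for ", length(trial_ids),
           " trials.")
    }
    return(idx)
  }
  idx <- match(rule, trial_ids)
  if (is.na(idx)) stop("Trial id '", rule, "' not found.")
  idx
}

#' FPT trials for every subject-instance in a dataset
#'
#' Tidy wrapper around [align_trials()]: one FPT trial per
#' (subject, condition) group. The confederate is expected to appear as one
#' subject-instance per interaction partner so that within-person distances
#' define the ground truth downstream.
#'
#' @param tm Tidy trial-matrix tibble from [trial_matrices()].
#' @param target_rule `"first"` (default: the first available trial), an
#'   integer trial index, or a trial id, applied per subject.
#' @param sd_type Passed to [align_trials()].
#' @return A tibble with columns `subject`, `group`, `condition`,
#'   `timepoint`, `variable`, `mean`, `sd`, `n_trials`, `target_trial`.
#' @export
fpt_trials <- function(tm, target_rule = "first",
                       sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  tm |>
    dplyr::group_by(.data$subject, .data$group, .data$condition) |>
    dplyr::group_modify(function(df, key) {
      ids <- unique(df$trial)
      mats <- lapply(ids, function(id) {
        tidy_to_matrix(df[df$trial == id, ])
      })
      idx <- resolve_target(target_rule, ids)
      fpt <- tryCatch(
        align_trials(mats, target_index = idx, sd_type = sd_type),
        error = function(e) {
          stop("Subject '", key$subject, "': ", conditionMessage(e),
               call. = FALSE)
        })
      n_tp <- nrow(fpt$mean)
      tibble::tibble(
        timepoint = rep(seq_len(n_tp), 3L),
        variable = rep(c("wv", "wa", "wj"), each = n_tp),
        mean = as.vector(fpt$mean),
        sd = as.vector(fpt$sd),
        n_trials = fpt$t,
        target_trial = ids[idx]
      )
    }) |>
    dplyr::ungroup()
}
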