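#' Inter-subject motor-distance matrix
#'
#' Computes the normalized Procrustes distance between every pair of FPT
#' trials, yielding the labelled symmetric distance matrix that covers all
#' confederate-confederate, participant-participant and
#' confederate-participant couplings. The analytic form is symmetric; any
#' residual numerical asymmetry (<= 1e-12) is removed by averaging the two
#' directions.
#'
#' @param fpt FPT tibble from [fpt_trials()], all rows in a single
#'   condition.
#' @return An object of class `motor_dist`: a list with `values` (n x n
#'   matrix, zero diagonal, labelled), `labels`, `groups`, `condition` and
#'   `method = "procrustes"`. `as.matrix()`, `tidy()`, `glance()` and
#'   `autoplot()` methods are provided.
#' @examples
#' trials <- simulate_trials(design = synth_design(n_participants = 3,
#'   n_confederate_instances = 3, trials_per_instance = 4), seed = 2)
#' D <- motor_distance(fpt_trials(trial_matrices(trials)))
#' @export
motor_distance <- function(fpt) {
  info <- fpt_info(fpt)
  mats <- info$mats
  n <- length(mats)
  if (n < 2L) stop("Need at least 2 FPT trials.")
  D <- matrix(0, n, n, dimnames = list(info$labels, info$labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- tryCatch(
        procrustes_distance(mats[[i]], mats[[j]]),
        error = function(e) {
          stop("FPT pair ('", info$labels[i], "', '", info$labels[j],
               "'): ", conditionMessage(e), call. = FALSE)
        })
      D[i, j] <- dij
      D[j, i] <- dij
    }
  }
  new_motor_dist(D, info$labels, info$groups, info$condition, "procrustes")
}

new_motor_dist <- function(values, labels, groups, condition, method,
                           per_variable = NULL) {
  stopifnot(isSymmetric(values, tol = 1e-12))
  values <- (values + t(values)) / 2
  diag(values) <- 0
  structure(list(values = values, labels = labels, groups = groups,
                 condition = condition, method = method,
                 per_variable = per_variable),
            class = "motor_dist")
}

# Extract per-subject matrices + metadata from an FPT tibble; enforces a
# single condition.
fpt_info <- function(fpt) {
  cond <- unique(fpt$condition)
  if (length(cond) != 1L) {
    stop("FPT trials span multiple conditions (",
         paste(cond, collapse = ", "), "); distance matrices are built ",
         "per condition.")
  }
  meta <- dplyr::distinct(fpt, .data$subject, .data$group)
  meta <- meta[order(match(meta$subject, unique(fpt$subject))), ]
  mats <- lapply(meta$subject, function(s) {
    tidy_to_matrix(dplyr::rename(fpt[fpt$subject == s, ], value = "mean"))
  })
  list(mats = mats, labels = as.character(meta$subject),
       groups = as.character(meta$group), condition = cond)
}

#' @export
as.matrix.motor_dist <- function(x, ...) x$values

#' @export
print.motor_dist <- function(x, ...) {
  cat("<motor_dist> ", x$method, " distances, ", nrow(x$values), " x ",
      ncol(x$values), ", condition ", x$condition, "\n", sep = "")
  cat("groups:", paste(sprintf("%s (%d)", names(table(x$groups)),
                               table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

# Upper-triangle (i < j) pair tibble of a motor_dist.
dist_pairs <- function(D) {
  v <- D$values
  idx <- which(upper.tri(v), arr.ind = TRUE)
  tibble::tibble(
    subject1 = D$labels[idx[, 1]],
    subject2 = D$labels[idx[, 2]],
    group1 = D$groups[idx[, 1]],
    group2 = D$groups[idx[, 2]],
    distance = v[idx]
  )
}

# Logical upper-triangle mask for a group-pair block. For a within-group
# block this is the unique unordered couples; for a between-group block all
# cross cells appear exactly once.
block_mask <- function(D, g1, g2) {
  gi <- D$groups
  m <- outer(gi == g1, gi == g2) | outer(gi == g2, gi == g1)
  m & upper.tri(m)
}

block_values <- function(D, g1, g2) D$values[block_mask(D, g1, g2)]

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname motor_distance
#' @param x A `motor_dist` object.
#' @param ... Unused.
#' @method tidy motor_dist
#' @export
tidy.motor_dist <- function(x, ...) dist_pairs(x)

#' @rdname motor_distance
#' @method glance motor_dist
#' @export
glance.motor_dist <- function(x, ...) {
  p <- dist_pairs(x)
  p$block <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "-"),
                    p$group1, p$group2)
  out <- p |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     mean = mean(.data$distance),
                     min = min(.data$distance),
                     max = max(.data$distance), .groups = "drop")
  out$condition <- x$condition
  out$method <- x$method
  out
}

#' Rank a reference subject's neighbours by motor distance
#'
#' Sorts the distances from a reference subject to all others in ascending
#' order and flags the nearest subject, the 33rd and 66th percentile
#' subjects, and the most dissimilar subject -- the profile-inspection set
#' used to visualize what the distance responds to. Percentile positions
#' use `ceiling(q * (n - 1))` on 1-based ranks; ties are broken by label
#' order, deterministically.
#'
#' @param D A `motor_dist` object.
#' @param reference Label of the reference subject.
#' @return A tibble sorted by ascending distance with columns `subject`,
#'   `group`, `distance`, `rank`, `flag` (`nearest`/`p33`/`p66`/`farthest`
#'   or `NA`).
#' @export
rank_neighbours <- function(D, reference) {
  i <- match(reference, D$labels)
  if (is.na(i)) stop("Unknown reference subject '", reference, "'.")
  others <- setdiff(seq_along(D$labels), i)
  tab <- tibble::tibble(subject = D$labels[others],
                        group = D$groups[others],
                        distance = D$values[others, i])
  tab <- tab[order(tab$distance, tab$subject), ]
  m <- nrow(tab)
  tab$rank <- seq_len(m)
  flags <- rep(NA_character_, m)
  flags[max(1L, ceiling(0.33 * m))] <- "p33"
  flags[max(1L, ceiling(0.66 * m))] <- "p66"
  flags[1L] <- "nearest"
  flags[m] <- "farthest"
  tab$flag <- flags
  tab
}

#' Sensitivity of the distance matrix to the Procrustes target trial
#'
#' The inter-trial alignment fixes one trial per subject as the Procrustes
#' target; this analysis repeats the full alignment + distance pipeline for
#' several target rules and reports all pairwise Mantel correlations
#' between the resulting distance matrices, quantifying how much the
#' arbitrary target choice matters.
#'
#' @param tm Tidy trial-matrix tibble from [trial_matrices()] (one
#'   condition).
#' @param target_rules List/vector of target rules accepted by
#'   [fpt_trials()].
#' @param n_perm Mantel permutations per pair (default 999).
#' @param seed Integer seed for the Mantel permutations.
#' @return A tibble with columns `rule1`, `rule2`, `mantel_r`, `p_value`.
#' @export
target_sensitivity <- function(tm, target_rules, n_perm = 999, seed = 1L) {
  mats <- lapply(target_rules, function(rule) {
    motor_distance(fpt_trials(tm, target_rule = rule))
  })
  k <- length(mats)
  out <- list()
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        r <- 1
        p <- NA_real_
      } else {
        mt <- mantel_test(mats[[i]], mats[[j]], n_perm = n_perm, seed = seed)
        r <- mt$observed_stat
        p <- mt$p_empirical
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        rule1 = as.character(target_rules[[i]]),
        rule2 = as.character(target_rules[[j]]),
        mantel_r = r, p_value = p)
    }
  }
  dplyr::bind_rows(out)
}

#' Write / read a motor distance matrix as CSV + JSON sidecar
#'
#' The square matrix goes to `<path>` with subject ids as header row and
#' first column; group tags, condition and method go to `<path>.json`.
#'
#' @param D A `motor_dist` object.
#' @param path CSV path.
#' @return `path`, invisibly (for `write_`); a `motor_dist` (for `read_`).
#' @export
write_distance_csv <- function(D, path) {
  df <- as.data.frame(D$values)
  df <- cbind(subject = D$labels, df)
  readr::write_csv(df, path)
  jsonlite::write_json(
    list(labels = D$labels, groups = D$groups, condition = D$condition,
         method = D$method),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- as.matrix(df[, -1])
  dimnames(v) <- list(meta$labels, meta$labels)
  new_motor_dist(v, meta$labels, meta$groups, meta$condition, meta$method)
}
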