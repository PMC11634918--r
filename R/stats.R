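new_perm_test <- function(kind, observed, p, n_perm, seed, extra = list()) {
  structure(c(list(kind = kind, observed_stat = observed, p_empirical = p,
                   n_perm = n_perm, seed = seed), extra),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test:", x$kind, "> observed =", format(x$observed_stat,
      digits = 4), ", p =", format(x$p_empirical, digits = 4),
      paste0("(", x$n_perm, " permutations, seed ", x$seed, ")"), "\n")
  invisible(x)
}

#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(kind = x$kind, observed_stat = x$observed_stat,
                 p_empirical = x$p_empirical, n_perm = x$n_perm,
                 seed = x$seed)
}

#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) tidy(x)

#' Swap permutation test of within- vs between-person distances
#'
#' Tests whether the average distance among the confederate's instances
#' (within-person couples) is genuinely small: each permutation replaces
#' the distance of a randomly chosen confederate-confederate couple (i, j)
#' with the distance from the same confederate i to a randomly chosen
#' participant, recomputes the block mean, and the empirical p-value is the
#' fraction of permutations in which this substitution reduces the mean.
#' Ties do not count toward p (strict reduction).
#'
#' @param D A `motor_dist` object.
#' @param confederate_tag,participant_tag Group labels (defaults
#'   `"confederate_instance"`, `"participant"`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A `perm_test` object (kind `"swap_test"`) whose
#'   `observed_stat` is the confederate-confederate block mean.
#' @export
swap_test <- function(D, confederate_tag = "confederate_instance",
                      participant_tag = "participant", n_perm = 1000,
                      seed = 1L) {
  conf <- which(D$groups == confederate_tag)
  part <- which(D$groups == participant_tag)
  if (!length(conf) || !length(part)) {
    stop("Both groups must be present (looked for '", confederate_tag,
         "' and '", participant_tag, "').")
  }
  if (length(conf) < 2L) stop("Need at least 2 confederate instances.")
  pairs <- t(utils::combn(conf, 2L))
  cc_vals <- D$values[pairs]
  observed <- mean(cc_vals)
  n_cc <- length(cc_vals)
  rng <- local_rng(seed)
  cell <- sample.int(nrow(pairs), n_perm, replace = TRUE)
  k <- part[sample.int(length(part), n_perm, replace = TRUE)]
  # substituting one cell shifts the block mean by (new - old) / n_cc
  new_vals <- D$values[cbind(pairs[cell, 1L], k)]
  perm_means <- observed + (new_vals - cc_vals[cell]) / n_cc
  p <- mean(perm_means < observed)
  restore_rng(rng)
  new_perm_test("swap_test", observed, p, n_perm, seed,
                extra = list(block_mean_perm = perm_means))
}

#' Metric MDS embedding with Kruskal stress
#'
#' Embeds a motor-distance matrix into `dims` dimensions: initial
#' coordinates from classical scaling (principal coordinates of the
#' double-centered squared distances) refined by iterative metric-stress
#' majorization (SMACOF). Goodness of fit is Kruskal stress-1,
#' `sqrt(sum((delta - dhat)^2) / sum(delta^2))` over the upper triangle,
#' where `delta` are the input distances and `dhat` the embedded ones.
#'
#' @param D A `motor_dist` object (n >= 3).
#' @param dims Embedding dimensionality (default 2).
#' @param max_steps Maximum majorization steps (default 300).
#' @param tol Stop when the stress decrease per step falls below this
#'   (default 1e-6).
#' @return An object of class `motor_mds` with `coords` (n x dims, centered
#'   at the origin), `stress`, `n_steps`, `stress_trace`, plus the input
#'   labels/groups.
#' @export
mds_embed <- function(D, dims = 2L, max_steps = 300L, tol = 1e-6) {
  delta <- as.matrix(D)
  n <- nrow(delta)
  if (n < 3L) stop("Need at least 3 subjects to embed.")
  if (!all(is.finite(delta))) stop("Non-finite distances cannot be embedded.")
  # classical scaling (Torgerson) initialization
  X <- suppressWarnings(
    stats::cmdscale(delta, k = dims, eig = FALSE, add = FALSE))
  if (ncol(X) < dims) { # rank-deficient input: pad with zeros
    X <- cbind(X, matrix(0, n, dims - ncol(X)))
  }
  denom <- sum(delta[upper.tri(delta)]^2)
  stress1 <- function(X) {
    dhat <- as.matrix(stats::dist(X))
    sqrt(sum((delta[upper.tri(delta)] - dhat[upper.tri(dhat)])^2) / denom)
  }
  trace <- stress1(X)
  steps <- 0L
  for (it in seq_len(max_steps)) {
    dhat <- as.matrix(stats::dist(X))
    ratio <- ifelse(dhat > 1e-12, delta / dhat, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X_new <- (B %*% X) / n # Guttman transform (unweighted SMACOF)
    s_new <- stress1(X_new)
    steps <- it
    trace <- c(trace, s_new)
    X <- X_new
    if (trace[it] - s_new < tol) break
  }
  X <- sweep(X, 2, colMeans(X))
  rownames(X) <- D$labels
  colnames(X) <- paste0("dim", seq_len(dims))
  structure(list(coords = X, stress = stress1(X), n_steps = steps,
                 stress_trace = trace, labels = D$labels,
                 groups = D$groups, condition = D$condition),
            class = "motor_mds")
}

#' @export
print.motor_mds <- function(x, ...) {
  cat("<motor_mds> ", nrow(x$coords), " points in ", ncol(x$coords),
      "-D, Kruskal stress-1 = ", format(x$stress, digits = 4),
      " after ", x$n_steps, " steps\n", sep = "")
  invisible(x)
}

#' @method tidy motor_mds
#' @export
tidy.motor_mds <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(subject = x$labels, group = x$groups),
                   tibble::as_tibble(x$coords))
}

#' @method glance motor_mds
#' @export
glance.motor_mds <- function(x, ...) {
  tibble::tibble(stress = x$stress, n_steps = x$n_steps,
                 n = nrow(x$coords), dims = ncol(x$coords))
}

#' Intraclass correlation, absolute agreement, single measurement
#'
#' ICC(A,1) in the McGraw & Wong taxonomy: a two-way ANOVA with the paired
#' vectors as two "raters" over n "subjects",
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with k = 2.
#' Unlike Pearson correlation it penalizes systematic offsets, so it
#' measures whether two measurement sets yield the same absolute values.
#'
#' @param x,y Numeric vectors of equal length (>= 3), e.g. the
#'   upper-triangular distances of a full and a reduced matrix.
#' @return The ICC(A,1) value (a scalar <= 1).
#' @export
icc_absolute_agreement <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3L) stop("Need at least 3 paired values.")
  if (stats::var(x) < .Machine$double.eps &&
      stats::var(y) < .Machine$double.eps) {
    stop("ICC undefined: both vectors have zero variance.")
  }
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sum((dat - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Robustness of the distance matrix under trial subsampling
#'
#' Quantifies how many movement repetitions the method needs: for each
#' removal fraction, trials are dropped uniformly at random per subject
#' (keeping at least 2), the full alignment + distance pipeline is rerun,
#' the `n_iter` resulting matrices are averaged elementwise, and ICC(A,1)
#' is computed between the averaged matrix's upper triangle and the
#' full-data matrix's.
#'
#' @param tm Tidy trial-matrix tibble from [trial_matrices()] (one
#'   condition).
#' @param fractions Removal fractions in (0, 1)
#'   (default `seq(0.1, 0.8, 0.1)`).
#' @param n_iter Random subsamples per fraction (default 1000).
#' @param seed Integer seed.
#' @param target_rule Target rule for [fpt_trials()] (applied to the
#'   retained trials).
#' @return An object of class `robustness_curve` with a `curve` tibble
#'   (`fraction`, `icc`), the per-fraction `mean_matrices`, the
#'   `full` matrix, `n_iter` and `seed`.
#' @export
robustness_subsample <- function(tm, fractions = seq(0.1, 0.8, by = 0.1),
                                 n_iter = 1000L, seed = 1L,
                                 target_rule = "first") {
  if (any(fractions <= 0 | fractions >= 1)) {
    stop("Removal fractions must lie strictly in (0, 1).")
  }
  if (any(diff(fractions) <= 0)) stop("Fractions must be strictly increasing.")
  D_full <- motor_distance(fpt_trials(tm, target_rule = target_rule))
  full_ut <- D_full$values[upper.tri(D_full$values)]
  # pre-split per subject into a list of trial matrices, in order of appearance
  per_subject <- split_trial_stacks(tm)
  counts <- vapply(per_subject, function(s) length(s$mats), integer(1))
  fmax <- max(fractions)
  short <- names(counts)[pmax(2L, round((1 - fmax) * counts)) > counts]
  if (length(short)) {
    stop("Subject(s) ", paste(short, collapse = ", "),
         " have too few trials for removal fraction ", fmax, ".")
  }
  rng <- local_rng(seed)
  n <- length(per_subject)
  mean_mats <- list()
  icc <- numeric(length(fractions))
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    acc <- matrix(0, n, n)
    for (it in seq_len(n_iter)) {
      fpt_mats <- lapply(per_subject, function(s) {
        keep_n <- max(2L, round((1 - f) * length(s$mats)))
        keep <- sort(sample.int(length(s$mats), keep_n))
        align_trials(s$mats[keep], target_index = 1L)$mean
      })
      acc <- acc + pairwise_matrix(fpt_mats)
    }
    m <- acc / n_iter
    dimnames(m) <- dimnames(D_full$values)
    mean_mats[[fi]] <- m
    icc[fi] <- icc_absolute_agreement(full_ut, m[upper.tri(m)])
  }
  restore_rng(rng)
  structure(list(curve = tibble::tibble(fraction = fractions, icc = icc),
                 mean_matrices = mean_mats, full = D_full,
                 n_iter = n_iter, seed = seed),
            class = "robustness_curve")
}

# subject -> list(mats = list of matrices, group) preserving appearance order
split_trial_stacks <- function(tm) {
  subjects <- unique(tm$subject)
  out <- lapply(subjects, function(s) {
    df <- tm[tm$subject == s, ]
    ids <- unique(df$trial)
    list(mats = lapply(ids, function(id) tidy_to_matrix(df[df$trial == id, ])),
         group = df$group[1])
  })
  names(out) <- subjects
  out
}

# plain n x n procrustes distance matrix from a list of matrices
pairwise_matrix <- function(mats) {
  n <- length(mats)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- procrustes_fit(mats[[i]], mats[[j]])$d
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat("<robustness_curve> ICC(A,1) vs removal fraction (", x$n_iter,
      " iterations, seed ", x$seed, ")\n", sep = "")
  print(x$curve)
  invisible(x)
}

#' @method tidy robustness_curve
#' @export
tidy.robustness_curve <- function(x, ...) x$curve

#' @method glance robustness_curve
#' @export
glance.robustness_curve <- function(x, ...) {
  tibble::tibble(n_fractions = nrow(x$curve), n_iter = x$n_iter,
                 min_icc = min(x$curve$icc), max_icc = max(x$curve$icc),
                 seed = x$seed)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation between the upper-triangular off-diagonal vectors of
#' two distance matrices over the same subjects, with significance from a
#' permutation test that jointly relabels rows and columns of the second
#' matrix. One-sided for positive association. With
#' `p_convention = "add_one"` (default) the observed statistic is included
#' in the null set, so p >= 1/(n_perm + 1); `"pure_count"` reports the raw
#' fraction of permuted correlations >= observed.
#'
#' @param D1,D2 `motor_dist` objects with identical labels in identical
#'   order.
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed.
#' @param p_convention `"add_one"` or `"pure_count"`.
#' @return A `perm_test` object (kind `"mantel"`) with the correlation as
#'   `observed_stat`.
#' @export
mantel_test <- function(D1, D2, n_perm = 5000, seed = 1L,
                        p_convention = c("add_one", "pure_count")) {
  p_convention <- match.arg(p_convention)
  if (!identical(D1$labels, D2$labels)) {
    stop("Distance matrices must share identical labels in the same order.")
  }
  m1 <- as.matrix(D1)
  m2 <- as.matrix(D2)
  n <- nrow(m1)
  if (n < 4L) stop("Need at least 4 subjects for a Mantel test.")
  ut <- upper.tri(m1)
  r_obs <- stats::cor(m1[ut], m2[ut])
  rng <- local_rng(seed)
  v1 <- m1[ut]
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    mp <- m2[p, p]
    stats::cor(v1, mp[ut])
  }, numeric(1))
  restore_rng(rng)
  hits <- sum(r_perm >= r_obs)
  p <- switch(p_convention,
              add_one = (hits + 1) / (n_perm + 1),
              pure_count = hits / n_perm)
  new_perm_test("mantel", r_obs, p, n_perm, seed,
                extra = list(p_convention = p_convention))
}

# Seed scoping: set the RNG for a stochastic op and restore the caller's
# state afterwards, so package functions never clobber user RNG streams.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
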