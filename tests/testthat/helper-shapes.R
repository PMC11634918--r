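# Shared fixtures and independent oracles, built in code.

# random non-degenerate n x k shape
rand_shape <- function(n = 10, k = 3) matrix(rnorm(n * k), n, k)

# Brute-force Procrustes oracle for 2-D shapes: minimize the normalized
# residual over rotation angle and reflection; for a fixed rotation the
# optimal scale and translation have closed forms on the centered,
# unit-norm matrices (residual = 1 - trace(t(X0) Y0 R)^2). A fine angle
# grid is refined with optimize(), independent of the SVD path.
brute_force_procrustes_2d <- function(X, Y) {
  X0 <- scale(X, scale = FALSE)
  Y0 <- scale(Y, scale = FALSE)
  X0 <- X0 / sqrt(sum(X0^2))
  Y0 <- Y0 / sqrt(sum(Y0^2))
  resid <- function(theta, refl) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    if (refl) R <- R %*% diag(c(1, -1))
    1 - sum(diag(crossprod(X0, Y0 %*% R)))^2
  }
  best <- Inf
  for (refl in c(FALSE, TRUE)) {
    grid <- seq(0, 2 * pi, length.out = 721)
    vals <- vapply(grid, resid, numeric(1), refl = refl)
    i <- which.min(vals)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    opt <- optimize(resid, c(lo, hi), refl = refl, tol = 1e-12)
    best <- min(best, opt$objective)
  }
  best
}

# minimum-jerk positions along x, D mm over T s at fs Hz
min_jerk_positions <- function(D = 300, T_s = 1, fs = 100) {
  tt <- seq(0, T_s, by = 1 / fs)
  u <- tt / T_s
  cbind(x = D * (10 * u^3 - 15 * u^4 + 6 * u^5), y = 0, z = 0)
}

# small toy FPT tibble from a named list of 10x3 matrices (one condition)
toy_fpt <- function(mats, groups = NULL, condition = "PG") {
  if (is.null(groups)) groups <- rep("participant", length(mats))
  dplyr::bind_rows(lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    tibble::tibble(subject = names(mats)[i], group = groups[i],
                   condition = condition,
                   timepoint = rep(seq_len(nrow(m)), 3),
                   variable = rep(c("wv", "wa", "wj"), each = nrow(m)),
                   mean = as.vector(m), sd = 0,
                   n_trials = 1L, target_trial = "T01")
  }))
}

# build a motor_dist directly from a symmetric matrix (test-only backdoor)
toy_dist <- function(values, groups, condition = "PG") {
  labels <- rownames(values)
  if (is.null(labels)) {
    labels <- sprintf("S%02d", seq_len(nrow(values)))
    dimnames(values) <- list(labels, labels)
  }
  motordist:::new_motor_dist(values, labels, groups, condition, "procrustes")
}

# all permutations of 1..n (for exhaustive Mantel enumeration at small n)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(all_perms(n - 1L), function(p) {
      c(i, setdiff(seq_len(n), i)[p])
    })
  }))
}

# small synthetic design used across tests
small_design <- function(np = 5, nc = 5, tpi = 6, conditions = "PG") {
  synth_design(n_participants = np, n_confederate_instances = nc,
               trials_per_instance = tpi, conditions = conditions)
}
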