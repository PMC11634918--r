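# exhaustive enumeration oracle for the swap test: every (conf-conf cell,
# participant) combination, counting strict reductions of the block mean
swap_exhaustive_p <- function(D, conf_tag = "confederate_instance",
                              part_tag = "participant") {
  conf <- which(D$groups == conf_tag)
  part <- which(D$groups == part_tag)
  pairs <- t(combn(conf, 2))
  obs <- mean(D$values[pairs])
  hits <- 0L
  total <- 0L
  for (c_i in seq_len(nrow(pairs))) {
    for (k in part) {
      vals <- D$values[pairs]
      vals[c_i] <- D$values[pairs[c_i, 1], k]
      total <- total + 1L
      if (mean(vals) < obs) hits <- hits + 1L
    }
  }
  hits / total
}

test_that("swap test matches its exhaustive enumeration oracle", {
  # separable case: every substitution raises the mean
  v <- matrix(0.5, 5, 5)
  conf <- 1:3
  v[1, 2] <- v[2, 1] <- 0.01
  v[1, 3] <- v[3, 1] <- 0.02
  v[2, 3] <- v[3, 2] <- 0.03
  diag(v) <- 0
  D <- toy_dist(v, c(rep("confederate_instance", 3), rep("participant", 2)))
  st <- swap_test(D, n_perm = 500, seed = 1)
  expect_equal(st$p_empirical, 0)
  expect_equal(st$observed_stat, 0.02)

  # inverted case: every substitution lowers it
  v2 <- v
  v2[v2 == 0.5] <- 0.001
  v2[1, 2] <- v2[2, 1] <- 0.8
  v2[1, 3] <- v2[3, 1] <- 0.9
  v2[2, 3] <- v2[3, 2] <- 0.7
  D2 <- toy_dist(v2, D$groups)
  expect_equal(swap_test(D2, n_perm = 500, seed = 1)$p_empirical, 1)

  # mixed hand-set values: Monte-Carlo within 3 binomial SDs of enumeration
  set.seed(2)
  v3 <- matrix(0, 5, 5)
  v3[upper.tri(v3)] <- runif(10)
  v3 <- v3 + t(v3)
  D3 <- toy_dist(v3, D$groups)
  p_true <- swap_exhaustive_p(D3)
  n_perm <- 2000
  st3 <- swap_test(D3, n_perm = n_perm, seed = 7)
  tol <- 3 * sqrt(max(p_true * (1 - p_true), 0.25 / n_perm) / n_perm)
  expect_lt(abs(st3$p_empirical - p_true), tol + 1e-12)
  expect_error(swap_test(toy_dist(v3, rep("participant", 5))), "groups")
})

test_that("exact planar configurations embed with negligible stress", {
  # unit square: side 1, diagonal sqrt(2)
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  dm <- as.matrix(dist(sq))
  dimnames(dm) <- list(letters[1:4], letters[1:4])
  D <- toy_dist(dm, rep("participant", 4))
  e <- mds_embed(D)
  expect_lte(e$stress, 1e-6)
  rec <- as.matrix(dist(e$coords))
  expect_equal(rec[upper.tri(rec)], dm[upper.tri(dm)], tolerance = 1e-4)
  expect_equal(colMeans(e$coords), c(dim1 = 0, dim2 = 0), tolerance = 1e-10)

  # collinear points embed exactly too
  cl <- as.matrix(dist(cbind(c(0, 1, 3), 0)))
  dimnames(cl) <- list(letters[1:3], letters[1:3])
  e2 <- mds_embed(toy_dist(cl, rep("participant", 3)))
  expect_lte(e2$stress, 1e-6)
})

test_that("majorization stress is monotone non-increasing", {
  set.seed(3)
  mats <- lapply(1:8, function(i) rand_shape())
  names(mats) <- sprintf("S%02d", 1:8)
  D <- motor_distance(toy_fpt(mats))
  e <- mds_embed(D)
  expect_true(all(diff(e$stress_trace) <= 1e-12))
  expect_gte(e$stress, 0)
})

test_that("ICC(A,1) matches an independent ANOVA decomposition", {
  # perfect agreement
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(icc_absolute_agreement(x, x), 1)

  # systematic offset is penalized despite correlation 1
  y_off <- x + 10 * sd(x)
  expect_lt(icc_absolute_agreement(x, y_off), 0.2)

  # fixed toy table against mean squares from stats::aov
  x6 <- c(9, 6, 8, 7, 10, 6)
  y6 <- c(2, 1, 4, 1, 5, 2)
  df <- data.frame(value = c(x6, y6),
                   subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  tab <- summary(stats::aov(value ~ subj + rater, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- 6; k <- 2
  oracle <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  expect_equal(icc_absolute_agreement(x6, y6), oracle, tolerance = 1e-12)
  expect_equal(icc_absolute_agreement(y6, x6), oracle, tolerance = 1e-12)

  expect_error(icc_absolute_agreement(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(icc_absolute_agreement(1:4, 1:5), "equal length")
})

test_that("subsampling identical trials leaves the matrix unchanged (ICC 1)", {
  hyper <- style_hyperparams(param_cv = 0, additive_mm = 0)
  tr <- simulate_trials(design = small_design(np = 3, nc = 3, tpi = 5),
                        seed = 61, hyper = hyper)
  tm <- trial_matrices(tr)
  rb <- robustness_subsample(tm, fractions = c(0.2, 0.6), n_iter = 3,
                             seed = 1)
  expect_equal(rb$curve$icc, c(1, 1), tolerance = 1e-9)
  expect_error(robustness_subsample(tm, fractions = c(0, 0.5)), "strictly")
  expect_error(robustness_subsample(tm, fractions = c(0.5, 0.4)),
               "increasing")
})

test_that("robustness degrades with heavier subsampling on noisy data", {
  tr <- simulate_trials(design = small_design(np = 4, nc = 4, tpi = 8),
                        seed = 62)
  tm <- trial_matrices(tr)
  rb <- robustness_subsample(tm, fractions = c(0.1, 0.7), n_iter = 20,
                             seed = 2)
  expect_true(all(rb$curve$icc <= 1 + 1e-12))
  expect_gte(rb$curve$icc[1], rb$curve$icc[2] - 0.02) # monotone trend
})

test_that("Mantel r and p match direct formula and exhaustive enumeration", {
  set.seed(4)
  n <- 5
  v1 <- matrix(0, n, n); v1[upper.tri(v1)] <- runif(10); v1 <- v1 + t(v1)
  v2 <- matrix(0, n, n); v2[upper.tri(v2)] <- runif(10); v2 <- v2 + t(v2)
  dimnames(v1) <- dimnames(v2) <- list(letters[1:n], letters[1:n])
  D1 <- toy_dist(v1, rep("participant", n))
  D2 <- toy_dist(v2, rep("participant", n))

  r_direct <- cor(v1[upper.tri(v1)], v2[upper.tri(v2)])
  mt <- mantel_test(D1, D2, n_perm = 2000, seed = 5,
                    p_convention = "pure_count")
  expect_equal(mt$observed_stat, r_direct, tolerance = 1e-12)
  expect_gte(mt$observed_stat, -1)
  expect_lte(mt$observed_stat, 1)

  # exhaustive oracle over all 120 joint relabellings
  perms <- all_perms(n)
  r_all <- vapply(perms, function(p) {
    vp <- v2[p, p]
    cor(v1[upper.tri(v1)], vp[upper.tri(vp)])
  }, numeric(1))
  p_true <- mean(r_all >= r_direct)
  tol <- 3 * sqrt(max(p_true * (1 - p_true), 0.25 / 2000) / 2000)
  expect_lt(abs(mt$p_empirical - p_true), tol + 1e-12)

  # self-correlation and affine invariance
  expect_equal(mantel_test(D1, D1, n_perm = 99, seed = 1)$observed_stat, 1)
  v3 <- 0.5 * v1 + 0.1
  diag(v3) <- 0
  D3 <- toy_dist(v3, rep("participant", n))
  expect_equal(mantel_test(D1, D3, n_perm = 99, seed = 1)$observed_stat, 1,
               tolerance = 1e-12)

  # add-one convention never returns p below 1/(n_perm + 1)
  mt_a <- mantel_test(D1, D1, n_perm = 99, seed = 1)
  expect_gte(mt_a$p_empirical, 1 / 100)
  D_bad <- toy_dist(v2[c(2:5, 1), c(2:5, 1)], rep("participant", n))
  expect_error(mantel_test(D1, D_bad, n_perm = 9), "labels")
})

test_that("Mantel statistic agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(6)
  n <- 8
  v1 <- matrix(0, n, n); v1[upper.tri(v1)] <- runif(28); v1 <- v1 + t(v1)
  v2 <- matrix(0, n, n); v2[upper.tri(v2)] <- runif(28); v2 <- v2 + t(v2)
  D1 <- toy_dist(v1, rep("participant", n))
  D2 <- toy_dist(v2, rep("participant", n))
  ref <- vegan::mantel(as.dist(v1), as.dist(v2), permutations = 99)
  expect_equal(mantel_test(D1, D2, n_perm = 99, seed = 1)$observed_stat,
               unname(ref$statistic), tolerance = 1e-12)
})

test_that("stochastic results are reproducible from their recorded seed", {
  set.seed(7)
  n <- 6
  v1 <- matrix(0, n, n); v1[upper.tri(v1)] <- runif(15); v1 <- v1 + t(v1)
  v2 <- matrix(0, n, n); v2[upper.tri(v2)] <- runif(15); v2 <- v2 + t(v2)
  D1 <- toy_dist(v1, c(rep("confederate_instance", 3),
                       rep("participant", 3)))
  D2 <- toy_dist(v2, D1$groups)
  a <- mantel_test(D1, D2, n_perm = 200, seed = 42)
  b <- mantel_test(D1, D2, n_perm = 200, seed = 42)
  expect_identical(a$p_empirical, b$p_empirical)
  s1 <- swap_test(D1, n_perm = 200, seed = 42)
  s2 <- swap_test(D1, n_perm = 200, seed = 42)
  expect_identical(s1$p_empirical, s2$p_empirical)
  # and package RNG use does not clobber the caller's stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(swap_test(D1, n_perm = 10, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})
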