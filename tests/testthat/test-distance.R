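test_that("pairwise distances form a valid labelled symmetric matrix", {
  set.seed(51)
  mats <- lapply(1:5, function(i) rand_shape())
  names(mats) <- sprintf("S%02d", 1:5)
  D <- motor_distance(toy_fpt(mats))
  v <- as.matrix(D)
  expect_true(isSymmetric(v))
  expect_equal(diag(v), setNames(rep(0, 5), names(mats)))
  off <- v[upper.tri(v)]
  expect_true(all(off >= 0 & off <= 1))
  expect_equal(nrow(tidy(D)), 10) # n(n-1)/2 unique couples

  # identical FPTs give zero distance
  D0 <- motor_distance(toy_fpt(list(A = mats[[1]], B = mats[[1]])))
  expect_equal(as.matrix(D0)[1, 2], 0, tolerance = 1e-12)
})

test_that("similarity-equivalent FPTs are nearer than perturbed ones", {
  set.seed(52)
  A <- rand_shape()
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  B <- 2 * A %*% q + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  C <- A + matrix(rnorm(30, sd = 0.5), 10, 3)
  D <- motor_distance(toy_fpt(list(A = A, B = B, C = C)))
  v <- as.matrix(D)
  expect_lt(v["A", "B"], 1e-10)
  expect_lt(v["A", "B"], v["A", "C"])
})

test_that("group blocks have the expected cell counts for 16+16 instances", {
  set.seed(53)
  mats <- lapply(1:32, function(i) rand_shape())
  names(mats) <- c(sprintf("C%02d", 1:16), sprintf("P%02d", 1:16))
  groups <- rep(c("confederate_instance", "participant"), each = 16)
  D <- motor_distance(toy_fpt(mats, groups))
  expect_equal(nrow(tidy(D)), 496) # 32*31/2
  cc <- motordist:::block_values(D, "confederate_instance",
                                 "confederate_instance")
  cp <- motordist:::block_values(D, "confederate_instance", "participant")
  pp <- motordist:::block_values(D, "participant", "participant")
  expect_length(cc, 120)
  expect_length(cp, 256)
  expect_length(pp, 120)
})

test_that("relabelling subjects permutes the matrix consistently", {
  set.seed(54)
  mats <- lapply(1:6, function(i) rand_shape())
  names(mats) <- sprintf("S%02d", 1:6)
  fpt <- toy_fpt(mats)
  D <- motor_distance(fpt)
  perm <- sample(6)
  fpt_p <- toy_fpt(mats[perm])
  D_p <- motor_distance(fpt_p)
  expect_equal(as.matrix(D_p), as.matrix(D)[perm, perm])
})

test_that("mixed conditions are rejected and degenerate FPTs named", {
  set.seed(55)
  fpt_pg <- toy_fpt(list(A = rand_shape(), B = rand_shape()))
  fpt_whp <- toy_fpt(list(C = rand_shape()), condition = "WHP")
  expect_error(motor_distance(dplyr::bind_rows(fpt_pg, fpt_whp)),
               "multiple conditions")
  fpt_bad <- toy_fpt(list(A = rand_shape(), BAD = matrix(1, 10, 3)))
  expect_error(motor_distance(fpt_bad), "BAD")
})

test_that("neighbour ranking flags the documented percentile ranks", {
  # 4 subjects: hand-set column for the reference
  v <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  v["a", "b"] <- v["b", "a"] <- 0.1
  v["a", "c"] <- v["c", "a"] <- 0.2
  v["a", "d"] <- v["d", "a"] <- 0.3
  v["b", "c"] <- v["c", "b"] <- 0.5
  v["b", "d"] <- v["d", "b"] <- 0.5
  v["c", "d"] <- v["d", "c"] <- 0.5
  D <- toy_dist(v, rep("participant", 4))
  rk <- rank_neighbours(D, "a")
  expect_equal(rk$subject[rk$flag == "nearest" & !is.na(rk$flag)], "b")
  expect_equal(rk$subject[rk$flag == "farthest" & !is.na(rk$flag)], "d")

  # 32 subjects: percentile ranks are ceil(q * 31) = 11 and 21
  set.seed(56)
  n <- 32
  vv <- matrix(0, n, n)
  vv[upper.tri(vv)] <- runif(n * (n - 1) / 2)
  vv <- vv + t(vv)
  D32 <- toy_dist(vv, rep("participant", n))
  rk32 <- rank_neighbours(D32, D32$labels[1])
  expect_equal(rk32$rank[!is.na(rk32$flag)], c(1L, 11L, 21L, 31L))

  # ties at the minimum: lexicographically first label wins
  v2 <- v
  v2["a", "c"] <- v2["c", "a"] <- 0.1
  Dt <- toy_dist(v2, rep("participant", 4))
  rkt <- rank_neighbours(Dt, "a")
  expect_equal(rkt$subject[1], "b")
  expect_error(rank_neighbours(D, "zzz"), "Unknown reference")
})

test_that("target choice barely matters on clean data (Mantel sensitivity)", {
  hyper <- style_hyperparams(param_cv = 0, additive_mm = 0)
  tr <- simulate_trials(design = small_design(np = 3, nc = 3, tpi = 3),
                        seed = 57, hyper = hyper)
  tm <- trial_matrices(tr)
  sens <- target_sensitivity(tm, list("first", 2L), n_perm = 99, seed = 1)
  expect_equal(sens$mantel_r[sens$rule1 == "first" & sens$rule2 == "2"], 1,
               tolerance = 1e-9)

  # single rule: trivially the 1x1 identity
  sens1 <- target_sensitivity(tm, list("first"), n_perm = 9, seed = 1)
  expect_equal(nrow(sens1), 1L)
  expect_equal(sens1$mantel_r, 1)

  # noisy data, 3 rules: positive agreement throughout
  tr_n <- simulate_trials(design = small_design(np = 4, nc = 4, tpi = 5),
                          seed = 58)
  sens3 <- target_sensitivity(trial_matrices(tr_n), list("first", 2L, 3L),
                              n_perm = 99, seed = 2)
  expect_true(all(sens3$mantel_r > 0))
})

test_that("distance matrices round-trip through CSV + JSON sidecar", {
  set.seed(59)
  mats <- lapply(1:4, function(i) rand_shape())
  names(mats) <- sprintf("S%02d", 1:4)
  D <- motor_distance(toy_fpt(mats))
  path <- withr::local_tempfile(fileext = ".csv")
  write_distance_csv(D, path)
  D2 <- read_distance_csv(path)
  expect_equal(as.matrix(D2), as.matrix(D), tolerance = 1e-12)
  expect_equal(D2$groups, D$groups)
  expect_equal(D2$condition, D$condition)
})
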