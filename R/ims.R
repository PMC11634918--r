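#' Individual-motor-signature (IMS) baseline distance matrix
#'
#' The comparison baseline: for each kinematic variable separately, the
#' root mean squared error over the 10 time points between subjects' FPT
#' columns gives an n x n matrix; each per-variable matrix is normalized by
#' its maximum off-diagonal entry (mapping it to [0, 1]) and the three are
#' averaged elementwise. Unlike the Procrustes distance, which models the
#' three variables jointly as one shape, IMS treats them one at a time.
#'
#' @param fpt FPT tibble from [fpt_trials()], single condition.
#' @return A `motor_dist` object with `method = "ims"`; the
#'   pre-normalization per-variable RMSE matrices are kept in
#'   `$per_variable`.
#' @export
ims_distance <- function(fpt) {
  info <- fpt_info(fpt)
  mats <- info$mats
  n <- length(mats)
  if (n < 2L) stop("Need at least 2 FPT trials.")
  vars <- c("wv", "wa", "wj")
  per_var <- lapply(seq_along(vars), function(v) {
    M <- matrix(0, n, n, dimnames = list(info$labels, info$labels))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        rmse <- sqrt(mean((mats[[i]][, v] - mats[[j]][, v])^2))
        M[i, j] <- rmse
        M[j, i] <- rmse
      }
    }
    M
  })
  names(per_var) <- vars
  normed <- lapply(per_var, function(M) {
    mx <- max(M[upper.tri(M)])
    if (mx <= 0) M else M / mx
  })
  final <- Reduce(`+`, normed) / length(normed)
  new_motor_dist(final, info$labels, info$groups, info$condition, "ims",
                 per_variable = per_var)
}

#' Cell-substitution comparison of two distance methods
#'
#' Compares the Procrustes and IMS distance matrices on one group-pair
#' block. The effect size is the difference of block means
#' (`delta = mean(IMS block) - mean(Procrustes block)`); significance comes
#' from exhaustive enumeration: each cell of the block in turn is replaced,
#' in a fresh copy of the Procrustes matrix, by the corresponding IMS
#' value, the block mean is recomputed, and the empirical p-value is the
#' fraction of substitutions that strictly reduce the original mean. Under
#' the ground truth that the confederate's instances are one person, the
#' better method is the one giving the smaller within-person block mean.
#'
#' @param D_proc,D_ims `motor_dist` objects over the same subjects (labels
#'   must match).
#' @param block Two group tags selecting the block, e.g.
#'   `c("confederate_instance", "confederate_instance")` (default) for the
#'   within-person couples.
#' @return A `perm_test` object (kind `"method_comparison"`) with
#'   `observed_stat` the Procrustes block mean, plus `delta`,
#'   `ims_mean` and `n_cells`.
#' @export
method_comparison <- function(D_proc, D_ims,
                              block = c("confederate_instance",
                                        "confederate_instance")) {
  if (!identical(D_proc$labels, D_ims$labels)) {
    stop("Distance matrices must share identical labels in the same order.")
  }
  if (length(block) != 2L) stop("`block` must name two group tags.")
  mask <- block_mask(D_proc, block[1], block[2])
  if (!any(mask)) stop("Empty block for groups '", block[1], "' / '",
                       block[2], "'.")
  proc_vals <- D_proc$values[mask]
  ims_vals <- D_ims$values[mask]
  m <- length(proc_vals)
  proc_mean <- mean(proc_vals)
  # substituting cell c changes the block mean by (ims_c - proc_c)/m
  perm_means <- proc_mean + (ims_vals - proc_vals) / m
  p <- mean(perm_means < proc_mean)
  new_perm_test("method_comparison", proc_mean, p, m, NA_integer_,
                extra = list(delta = mean(ims_vals) - proc_mean,
                             ims_mean = mean(ims_vals), n_cells = m))
}
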