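#' Run the full motor-distance pipeline
#'
#' Ties the whole analysis together: preprocessing into trial matrices,
#' inter-trial alignment into FPT trials, the inter-subject Procrustes
#' distance matrix, the swap permutation test, the MDS embedding, the IMS
#' baseline with the cell-substitution method comparison, the subsampling
#' robustness curve, and -- when two conditions are present -- the
#' cross-condition Mantel test. Every stochastic step derives its seed from
#' `seed`, so reruns with the same inputs and seed reproduce the bundle
#' bit-for-bit.
#'
#' @param trials Long-format trial tibble (e.g. from [simulate_trials()] or
#'   [read_trials_csv()]).
#' @param seed Integer master seed.
#' @param sample_rate,filter_cutoff,n_timepoints Preprocessing settings
#'   (defaults 100 Hz, 8 Hz, 10).
#' @param target_rule Procrustes target rule for [fpt_trials()].
#' @param n_perm_swap Swap-test permutations (default 1000).
#' @param n_perm_mantel Mantel permutations (default 5000).
#' @param fractions,n_iter_robustness Robustness settings (defaults 10-80%
#'   and 1000); set `n_iter_robustness = 0` to skip the robustness stage.
#' @param out_dir Optional directory; when given, every intermediate
#'   artifact is written there (tidy CSVs, JSON results, and a
#'   `manifest.json` listing each file with its MD5 content hash).
#' @return A list of class `motor_pipeline` with elements
#'   `trial_matrices`, `fpt`, and per-condition `distance`, `swap`, `mds`,
#'   `ims`, `method_comparison`, `robustness`, plus `mantel` when at least
#'   two conditions are present.
#' @export
run_pipeline <- function(trials, seed, sample_rate = 100, filter_cutoff = 8,
                         n_timepoints = 10L, target_rule = "first",
                         n_perm_swap = 1000, n_perm_mantel = 5000,
                         fractions = seq(0.1, 0.8, by = 0.1),
                         n_iter_robustness = 1000, out_dir = NULL) {
  tm <- trial_matrices(trials, sample_rate = sample_rate,
                       filter_cutoff = filter_cutoff,
                       n_timepoints = n_timepoints)
  conditions <- unique(tm$condition)
  fpt <- fpt_trials(tm, target_rule = target_rule)
  per_cond <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    tm_c <- tm[tm$condition == cond, ]
    fpt_c <- fpt[fpt$condition == cond, ]
    D <- motor_distance(fpt_c)
    res <- list(
      distance = D,
      swap = swap_test(D, n_perm = n_perm_swap, seed = seed + 100L * ci),
      mds = mds_embed(D),
      ims = ims_distance(fpt_c)
    )
    res$method_comparison <- method_comparison(D, res$ims)
    if (n_iter_robustness > 0) {
      res$robustness <- robustness_subsample(
        tm_c, fractions = fractions, n_iter = n_iter_robustness,
        seed = seed + 100L * ci + 1L, target_rule = target_rule)
    }
    per_cond[[cond]] <- res
  }
  bundle <- list(trial_matrices = tm, fpt = fpt, conditions = per_cond,
                 seed = seed)
  if (length(conditions) >= 2L) {
    bundle$mantel <- mantel_test(per_cond[[1]]$distance,
                                 per_cond[[2]]$distance,
                                 n_perm = n_perm_mantel, seed = seed + 7L)
  }
  class(bundle) <- "motor_pipeline"
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.motor_pipeline <- function(x, ...) {
  cat("<motor_pipeline> conditions:",
      paste(names(x$conditions), collapse = ", "), "\n")
  for (cond in names(x$conditions)) {
    res <- x$conditions[[cond]]
    g <- glance(res$distance)
    cat("  [", cond, "] swap p =", format(res$swap$p_empirical, digits = 3),
        "| stress =", format(res$mds$stress, digits = 3),
        "| IMS delta =", format(res$method_comparison$delta, digits = 3),
        "\n")
  }
  if (!is.null(x$mantel)) {
    cat("  cross-condition Mantel r =",
        format(x$mantel$observed_stat, digits = 3),
        ", p =", format(x$mantel$p_empirical, digits = 3), "\n")
  }
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p)
    paths <<- c(paths, p)
  }
  wr_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA)
    paths <<- c(paths, p)
  }
  wr_csv(bundle$trial_matrices, "trial_matrices.csv")
  wr_csv(bundle$fpt, "fpt_trials.csv")
  for (cond in names(bundle$conditions)) {
    res <- bundle$conditions[[cond]]
    dp <- file.path(out_dir, paste0("distance_procrustes_", cond, ".csv"))
    write_distance_csv(res$distance, dp)
    di <- file.path(out_dir, paste0("distance_ims_", cond, ".csv"))
    write_distance_csv(res$ims, di)
    paths <- c(paths, dp, paste0(dp, ".json"), di, paste0(di, ".json"))
    wr_json(tidy(res$swap), paste0("swap_test_", cond, ".json"))
    wr_csv(tidy(res$mds), paste0("mds_", cond, ".csv"))
    wr_json(glance(res$mds), paste0("mds_stress_", cond, ".json"))
    wr_json(c(tidy(res$method_comparison),
              list(delta = res$method_comparison$delta,
                   ims_mean = res$method_comparison$ims_mean)),
            paste0("method_comparison_", cond, ".json"))
    if (!is.null(res$robustness)) {
      wr_csv(tidy(res$robustness), paste0("robustness_", cond, ".csv"))
    }
  }
  if (!is.null(bundle$mantel)) {
    wr_json(tidy(bundle$mantel), "mantel_cross_condition.json")
  }
  manifest <- tibble::tibble(file = basename(paths),
                             md5 = unname(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(out_dir)
}
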