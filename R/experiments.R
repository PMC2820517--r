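#' @title Simulation experiments: power of the pooled Granger test
#' @description Harness functions reproducing the package's simulation
#'   study: detection power (recall) as a function of series length, sampling
#'   interval and pooling of short series, plus permutation-based false
#'   positive rates. Every row of every table is regenerable exactly from its
#'   condition label and the master seed.
#' @name experiments
NULL

new_power_table <- function(df, alpha, seed) {
  df$alpha <- alpha
  df$seed <- seed
  structure(df, class = c("power_table", "data.frame"))
}

# recall of the per-series causality test over `reps` causal pairs of a
# given length, optionally thinned; raw and Bonferroni-corrected calls
.recall_once <- function(params, length, reps, alpha, seed, interval = 1L,
                         stream = "len") {
  hit_raw <- 0L
  hit_corr <- 0L
  tested <- 0L
  for (r in seq_len(reps)) {
    s <- simulate_bvar_pair(params, length,
                            derive_seed(seed, paste0(stream, length, "_",
                                                     interval, "_", r)))
    if (interval > 1L) s <- thin_series(s, interval)
    res <- tryCatch(granger_test_series(s),
                    temponet_insufficient_data = function(e) NULL)
    if (is.null(res)) next
    tested <- tested + 1L
    if (res$p_value < alpha) hit_raw <- hit_raw + 1L
    if (res$p_value < alpha / reps) hit_corr <- hit_corr + 1L
  }
  c(tested = tested, recall = if (tested) hit_raw / tested else NA_real_,
    recall_corrected = if (tested) hit_corr / tested else NA_real_)
}

#' Detection power versus series length
#'
#' Simulates `reps` causal BVAR pairs at each length, tests each series on
#' its own, and reports the fraction detected (recall) at the raw threshold
#' and at a Bonferroni-corrected threshold over the `reps` tests. Lengths too
#' short to support the F test are reported as skipped.
#'
#' @param params a [bvar_params()].
#' @param lengths integer vector of series lengths.
#' @param reps replicates per condition (the reference simulations use 1000;
#'   200 is a practical default).
#' @param alpha raw significance threshold.
#' @param seed master seed.
#' @return A `power_table` with one row per length: `condition`, `length`,
#'   `n_replicates`, `recall`, `recall_corrected`, `alpha`, `seed`.
#' @export
power_vs_length <- function(params, lengths, reps = 200, alpha = 0.05,
                            seed = 1) {
  stopifnot(reps >= 1)
  rows <- lapply(lengths, function(L) {
    if (L < 5L) { # 4 lagged rows minimum for df2 >= 1
      return(data.frame(condition = paste0("length_", L), length = L,
                        n_replicates = 0L, recall = NA_real_,
                        recall_corrected = NA_real_,
                        status = "skipped_too_short"))
    }
    r <- .recall_once(params, L, reps, alpha, seed)
    data.frame(condition = paste0("length_", L), length = L,
               n_replicates = as.integer(r["tested"]),
               recall = r["recall"], recall_corrected = r["recall_corrected"],
               status = "ok")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  new_power_table(out, alpha, seed)
}

#' Detection power versus sampling interval at fixed point count
#'
#' For each interval k, simulates series of length `fixed_point_count * k`
#' and keeps every k-th point, so all conditions are tested on the same
#' number of points but sampled at different spacings. Wider spacing weakens
#' the observable lag-1 dependence, so recall is expected to drop.
#'
#' @inheritParams power_vs_length
#' @param intervals integer vector of sampling intervals.
#' @param fixed_point_count number of points retained per series.
#' @return A `power_table` with one row per interval.
#' @export
power_vs_interval <- function(params, intervals, fixed_point_count = 60,
                              reps = 200, alpha = 0.05, seed = 1) {
  stopifnot(reps >= 1, fixed_point_count >= 5)
  rows <- lapply(intervals, function(k) {
    k <- as.integer(k)
    r <- .recall_once(params, fixed_point_count * k, reps, alpha, seed,
                      interval = k, stream = "int")
    data.frame(condition = paste0("interval_", k), interval = k,
               points = as.integer(fixed_point_count),
               n_replicates = as.integer(r["tested"]),
               recall = r["recall"], recall_corrected = r["recall_corrected"],
               status = "ok")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  new_power_table(out, alpha, seed)
}

#' Pooled short series versus one long series
#'
#' Compares the recall of the pooled test on `n_series` short series of
#' `short_len` points (stacked into a virtual long series) against the
#' ordinary test on a single series of `long_len` points, at the same
#' threshold. With `n_series * (short_len - 1)` close to `long_len`, the two
#' designs carry comparable numbers of transitions.
#'
#' @inheritParams power_vs_length
#' @param n_series number of short series pooled per replicate.
#' @param short_len,long_len lengths of the short and long series.
#' @return A `power_table` with rows `pooled` and `long`.
#' @export
pooled_vs_long <- function(params, n_series = 40, short_len = 6,
                           long_len = 240, reps = 200, alpha = 0.05,
                           seed = 1) {
  stopifnot(reps >= 1, n_series >= 1, short_len >= 2, long_len >= 5)
  hit_pool <- 0L
  hit_long <- 0L
  for (r in seq_len(reps)) {
    rep_seed <- derive_seed(seed, paste0("pool", r))
    pop <- simulate_pair_population(params, n_series, short_len, rep_seed)
    res_p <- granger_test_pooled(pop)
    if (res_p$p_value < alpha) hit_pool <- hit_pool + 1L
    # the long arm extends the seed stream of the pooled arm's first series,
    # so n_series = 1 with short_len = long_len compares identical data
    s <- simulate_bvar_pair(params, long_len, derive_seed(rep_seed, 1L))
    if (granger_test_series(s)$p_value < alpha) hit_long <- hit_long + 1L
  }
  out <- data.frame(
    condition = c("pooled", "long"),
    n_series = c(n_series, 1L),
    length = c(short_len, long_len),
    n_rows = as.integer(c(n_series * (short_len - 1L), long_len - 1L)),
    n_replicates = reps,
    recall = c(hit_pool, hit_long) / reps
  )
  new_power_table(out, alpha, seed)
}

#' Empirical false positive rate on permuted pairings
#'
#' Simulates a population of causal pairs, permutes the X/Y pairing so no
#' true cross dependence remains, tests every permuted pair, and reports the
#' rejection rate over a grid of thresholds. Under a sound null these rates
#' track the nominal levels.
#'
#' @inheritParams power_vs_length
#' @param reps number of permuted pairs (population size).
#' @param alphas numeric vector of thresholds.
#' @param length series length.
#' @return A `power_table` with one row per threshold: `condition`,
#'   `n_replicates`, `fpr`; p-values attached as attribute `"p_values"`.
#' @export
empirical_fpr <- function(params, reps = 1000, alphas = c(0.01, 0.05),
                          length = 240, seed = 1) {
  stopifnot(reps >= 2)
  pop <- simulate_pair_population(params, reps, length,
                                  derive_seed(seed, "fpr_pop"))
  null_pop <- permute_pair_assignment(pop, derive_seed(seed, "fpr_perm"))
  pvals <- vapply(null_pop, function(s) granger_test_series(s)$p_value,
                  numeric(1))
  rows <- lapply(alphas, function(a) {
    data.frame(condition = paste0("alpha_", a), threshold = a,
               n_replicates = reps, fpr = mean(pvals < a))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- new_power_table(out, NA_real_, seed)
  attr(out, "p_values") <- pvals
  out
}
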