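#' Bootstrap edge confidence by resampling individuals
#'
#' The sampling unit is the individual together with their whole short time
#' series: each replicate draws N individuals with replacement (duplicates
#' contribute duplicate pooled rows), re-runs the all-pairs scan with the
#' same correction and threshold, and an edge scores a success when its
#' adjusted p-value falls below the threshold in that replicate. The
#' confidence of an edge is the fraction of replicates in which it was
#' significant. (The scoring is significance *below* the corrected cutoff;
#' stated here explicitly because "above a threshold" reads ambiguously when
#' thresholds are on p-values.) Scoring happens before any pruning.
#'
#' @param panel an `expression_panel`, already baseline-referenced.
#' @param B number of bootstrap replicates (default 100).
#' @param alpha,method significance threshold and correction, as in
#'   [adjust_and_threshold()].
#' @param seed master seed; each replicate draws from a derived sub-stream.
#' @param network optional point-estimate `causal_network` whose edges to
#'   score; computed from the panel when omitted.
#' @param intercept passed to [granger_test()].
#' @return A `bootstrap_report`: list with `B`, `edges` (the point-estimate
#'   edges with a `confidence` column, each a multiple of 1/B), and
#'   `replicate_seeds`.
#' @export
bootstrap_confidence <- function(panel, B = 100, alpha = 0.01,
                                 method = c("bonferroni", "bh"),
                                 seed = 1, network = NULL,
                                 intercept = TRUE) {
  stopifnot(inherits(panel, "expression_panel"))
  method <- match.arg(method)
  if (!is.numeric(B) || length(B) != 1L || B < 1) {
    arg_error("B must be a single integer >= 1")
  }
  B <- as.integer(B)
  ni <- length(panel$individuals)
  if (ni < 2L) arg_error("need at least 2 individuals to bootstrap")

  if (is.null(network)) {
    network <- adjust_and_threshold(scan_all_pairs(panel, intercept),
                                    method = method, alpha = alpha)
  }
  edges <- network$edges
  key <- paste(edges$source, edges$target, sep = "\r")
  hits <- setNames(integer(length(key)), key)
  replicate_seeds <- vapply(seq_len(B), function(b) {
    derive_seed(seed, paste0("bootstrap", b))
  }, integer(1))

  for (b in seq_len(B)) {
    idx <- with_seed(replicate_seeds[b], sample.int(ni, ni, replace = TRUE))
    vals <- panel$values[, idx, , drop = FALSE]
    boot_panel <- expression_panel(
      vals, panel$genes,
      individuals = sprintf("bs%03d", seq_len(ni)), # duplicates need fresh ids
      timepoints = panel$timepoints, arm = panel$arm)
    net_b <- adjust_and_threshold(scan_all_pairs(boot_panel, intercept),
                                  method = method, alpha = alpha)
    kb <- paste(net_b$edges$source, net_b$edges$target, sep = "\r")
    found <- key %in% kb
    hits[found] <- hits[found] + 1L
  }
  edges$confidence <- as.numeric(hits) / B
  structure(
    list(B = B, edges = edges, replicate_seeds = replicate_seeds,
         alpha = network$alpha, method = network$method),
    class = "bootstrap_report"
  )
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("Bootstrap report: %d edges scored over B = %d replicates\n",
              nrow(x$edges), x$B))
  if (nrow(x$edges)) {
    cat(sprintf("  median confidence %.2f; %d edge(s) with confidence >= 0.5\n",
                stats::median(x$edges$confidence),
                sum(x$edges$confidence >= 0.5)))
  }
  invisible(x)
}
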