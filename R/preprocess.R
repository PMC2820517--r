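#' Reference each individual's profile to their own time-0 profile
#'
#' Subtracts, per gene and individual, the value at the first timepoint from
#' every later timepoint, then drops the first timepoint. On log-scale data
#' this removes individual baseline (scale) differences, which is what makes
#' the subsequent pooling of individuals into one virtual long series
#' defensible: all series are deviations from their own starting state. A
#' 7-timepoint panel becomes a 6-timepoint panel.
#'
#' @param panel an `expression_panel` whose first timepoint is the baseline.
#' @return An `expression_panel` with one fewer timepoint.
#' @export
#' @examples
#' gt <- simulate_cohort_panel(c("g1", "g2"), n_individuals = 3,
#'                             n_timepoints = 4, seed = 1)
#' dim(reference_to_baseline(gt$panel))
reference_to_baseline <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  if (length(panel$timepoints) < 2L) {
    data_error("need at least 2 timepoints to reference to baseline")
  }
  baseline <- panel$values[, , 1L, drop = FALSE]
  if (anyNA(baseline)) {
    bad <- panel$individuals[apply(is.na(baseline[, , 1, drop = FALSE]), 2, any)]
    data_error(paste0("missing baseline (timepoint ",
                      panel$timepoints[1L], ") profile for: ",
                      paste(bad, collapse = ", ")))
  }
  keep <- 2:length(panel$timepoints)
  referenced <- sweep(panel$values[, , keep, drop = FALSE], c(1, 2),
                      baseline[, , 1])
  expression_panel(referenced, panel$genes, panel$individuals,
                   panel$timepoints[keep], arm = panel$arm)
}

#' Stack lagged regression rows for one ordered gene pair
#'
#' For each individual and each consecutive timepoint pair (t-1, t), emits one
#' row (target_t, target_{t-1}, source_{t-1}). Rows never cross individual
#' boundaries, so N individuals with L timepoints yield N(L-1) rows -- the
#' virtual long series on which the pooled Granger test runs.
#'
#' @param panel an `expression_panel` (typically already baseline-referenced).
#' @param source_gene,target_gene gene ids; the test asks whether the source's
#'   past improves prediction of the target.
#' @return A `lagged_design`: data frame with columns `y`, `y_lag`, `x_lag`,
#'   `individual`, `t`.
#' @export
stack_lagged_rows <- function(panel, source_gene, target_gene) {
  stopifnot(inherits(panel, "expression_panel"))
  for (g in c(source_gene, target_gene)) {
    if (!(g %in% panel$genes)) arg_error(paste0("unknown gene id: ", g))
  }
  L <- length(panel$timepoints)
  if (L < 2L) data_error("every individual needs at least 2 timepoints")
  ni <- length(panel$individuals)
  tgt <- panel$values[target_gene, , , drop = TRUE]
  src <- panel$values[source_gene, , , drop = TRUE]
  if (ni == 1L) { tgt <- matrix(tgt, 1L); src <- matrix(src, 1L) }
  cur <- 2:L
  lag <- 1:(L - 1L)
  design <- data.frame(
    y = as.vector(t(tgt[, cur, drop = FALSE])),
    y_lag = as.vector(t(tgt[, lag, drop = FALSE])),
    x_lag = as.vector(t(src[, lag, drop = FALSE])),
    individual = rep(panel$individuals, each = L - 1L),
    t = rep(panel$timepoints[cur], ni)
  )
  structure(design, class = c("lagged_design", "data.frame"))
}
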