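#' Parameters of the first-order bivariate autoregressive (BVAR) generator
#'
#' The generative model for one causal pair X -> Y is the stationary
#' first-order system
#' \deqn{X_t = a X_{t-1} + \epsilon_{x,t}, \qquad
#'       Y_t = b Y_{t-1} + c X_{t-1} + \epsilon_{y,t},}
#' where the coefficients (a, b, c) are drawn once per series from normal
#' distributions, the noises are i.i.d. normal, and initial values are drawn
#' uniformly on `[-init_halfwidth, init_halfwidth]`. Coefficients are held
#' fixed over time, so each realized series is a stationary model.
#'
#' @param a_mean,a_sd mean and SD of the autoregressive coefficient of X.
#' @param b_mean,b_sd mean and SD of the autoregressive coefficient of Y.
#' @param c_mean,c_sd mean and SD of the causal coefficient X at t-1 -> Y at t.
#' @param noise_sd_x,noise_sd_y innovation SDs, strictly positive unless the
#'   deterministic limit (exactly zero) is requested.
#' @param init_halfwidth half-width of the uniform initial distribution.
#' @return An object of class `bvar_params`.
#' @export
#' @examples
#' p <- bvar_params()
#' p$c_mean
bvar_params <- function(a_mean = 0.5, a_sd = 0.1,
                        b_mean = 0.5, b_sd = 0.1,
                        c_mean = 0.5, c_sd = 0.1,
                        noise_sd_x = 1, noise_sd_y = 1,
                        init_halfwidth = 1) {
  p <- list(
    a_mean = a_mean, a_sd = a_sd,
    b_mean = b_mean, b_sd = b_sd,
    c_mean = c_mean, c_sd = c_sd,
    noise_sd_x = noise_sd_x, noise_sd_y = noise_sd_y,
    init_halfwidth = init_halfwidth
  )
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                logical(1))
  if (!all(num)) {
    arg_error(paste0("non-finite or non-scalar BVAR parameter(s): ",
                     paste(names(p)[!num], collapse = ", ")))
  }
  if (p$noise_sd_x < 0 || p$noise_sd_y < 0 ||
      p$a_sd < 0 || p$b_sd < 0 || p$c_sd < 0) {
    arg_error("standard deviations must be non-negative")
  }
  if (p$init_halfwidth < 0) arg_error("init_halfwidth must be non-negative")
  if (abs(p$a_mean) >= 1 || abs(p$b_mean) >= 1) {
    warning("|a_mean| or |b_mean| >= 1: the mean process is non-stationary")
  }
  structure(p, class = "bvar_params")
}

#' @export
print.bvar_params <- function(x, ...) {
  cat("BVAR parameters (first-order, stationary per series)\n")
  cat(sprintf("  a ~ N(%g, %g^2)  b ~ N(%g, %g^2)  c ~ N(%g, %g^2)\n",
              x$a_mean, x$a_sd, x$b_mean, x$b_sd, x$c_mean, x$c_sd))
  cat(sprintf("  noise SD (x, y) = (%g, %g); init ~ U(-%g, %g)\n",
              x$noise_sd_x, x$noise_sd_y, x$init_halfwidth, x$init_halfwidth))
  invisible(x)
}

new_pair_series <- function(x, y, series_id, coefficients, null_pair = FALSE) {
  structure(
    list(x = x, y = y, series_id = series_id,
         coefficients = coefficients, null_pair = null_pair),
    class = "pair_series"
  )
}

#' @export
print.pair_series <- function(x, ...) {
  cat(sprintf("BVAR pair series '%s': T = %d%s\n", x$series_id,
              length(x$x), if (isTRUE(x$null_pair)) " (permuted null)" else ""))
  if (!is.null(x$coefficients)) {
    cat(sprintf("  realized (a, b, c) = (%.4g, %.4g, %.4g)\n",
                x$coefficients["a"], x$coefficients["b"], x$coefficients["c"]))
  }
  invisible(x)
}

#' Simulate one causal BVAR pair
#'
#' Draws per-series coefficients (a, b, c) from the configured normals, then
#' evolves the pair for `length` time points from uniform initial values.
#'
#' @param params a [bvar_params()] object.
#' @param length number of time points (>= 2).
#' @param seed integer seed fixing coefficients, initial values and noise.
#' @param series_id identifier attached to the output.
#' @return A `pair_series`: vectors `x` and `y` of length `length`, plus the
#'   realized `coefficients` named `a`, `b`, `c`.
#' @export
#' @examples
#' s <- simulate_bvar_pair(bvar_params(), length = 240, seed = 1)
#' length(s$x)
simulate_bvar_pair <- function(params, length, seed, series_id = "s1") {
  stopifnot(inherits(params, "bvar_params"))
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) ||
      length < 2) {
    arg_error("length must be a single integer >= 2")
  }
  length <- as.integer(length)
  with_seed(seed, {
    a <- rnorm(1, params$a_mean, params$a_sd)
    b <- rnorm(1, params$b_mean, params$b_sd)
    cc <- rnorm(1, params$c_mean, params$c_sd)
    x <- numeric(length)
    y <- numeric(length)
    x[1] <- runif(1, -params$init_halfwidth, params$init_halfwidth)
    y[1] <- runif(1, -params$init_halfwidth, params$init_halfwidth)
    ex <- rnorm(length - 1L, 0, params$noise_sd_x)
    ey <- rnorm(length - 1L, 0, params$noise_sd_y)
    for (t in 2:length) {
      x[t] <- a * x[t - 1L] + ex[t - 1L]
      y[t] <- b * y[t - 1L] + cc * x[t - 1L] + ey[t - 1L]
    }
    new_pair_series(x, y, series_id, c(a = a, b = b, c = cc))
  })
}

#' Simulate a population of independent BVAR pairs
#'
#' @param params a [bvar_params()] object.
#' @param n_series number of independent series (>= 1).
#' @param length time points per series.
#' @param seed master seed; each series gets a derived sub-seed.
#' @return List of `pair_series`, ids `"s1" ... "s<n>"`.
#' @export
simulate_pair_population <- function(params, n_series, length, seed) {
  if (!is.numeric(n_series) || length(n_series) != 1L || n_series < 1) {
    arg_error("n_series must be a single integer >= 1")
  }
  n_series <- as.integer(n_series)
  lapply(seq_len(n_series), function(i) {
    simulate_bvar_pair(params, length, derive_seed(seed, i),
                       series_id = paste0("s", i))
  })
}

#' Re-pair X and Y series to form a permutation null
#'
#' Each response series Y_i is re-paired with a predictor series X_j from a
#' different pair (j != i), destroying the causal X -> Y dependence while
#' keeping Y's own autoregressive structure valid. The re-pairing is a seeded
#' cyclic shift by a random nonzero offset, which guarantees a derangement.
#'
#' @param population list of `pair_series` (length >= 2).
#' @param seed integer seed for the shift offset.
#' @return List of `pair_series` with `null_pair = TRUE` and no true causal
#'   coefficient recorded.
#' @export
permute_pair_assignment <- function(population, seed) {
  n <- length(population)
  if (n < 2) arg_error("need at least 2 series to re-pair (no valid derangement)")
  offset <- with_seed(seed, sample.int(n - 1L, 1L))
  idx <- ((seq_len(n) - 1L + offset) %% n) + 1L # partner index, never i
  lapply(seq_len(n), function(i) {
    new_pair_series(
      x = population[[idx[i]]]$x,
      y = population[[i]]$y,
      series_id = paste0(population[[i]]$series_id, "_null"),
      coefficients = NULL,
      null_pair = TRUE
    )
  })
}

#' Subsample a pair series at a fixed interval
#'
#' Keeps every `interval`-th point starting from the first, emulating sparser
#' sampling designs; the result has `ceiling(T / interval)` points.
#'
#' @param series a `pair_series`.
#' @param interval sampling interval (>= 1); 1 is the identity.
#' @return A thinned `pair_series`.
#' @export
thin_series <- function(series, interval) {
  stopifnot(inherits(series, "pair_series"))
  if (!is.numeric(interval) || length(interval) != 1L || interval < 1) {
    arg_error("interval must be a single integer >= 1")
  }
  interval <- as.integer(interval)
  keep <- seq(1L, length(series$x), by = interval)
  new_pair_series(series$x[keep], series$y[keep],
                  paste0(series$series_id, "_int", interval),
                  series$coefficients, series$null_pair)
}

#' Simulate a multi-gene cohort panel with known two-slice ground truth
#'
#' Emulates the geometry of a short-time-series cohort: `n_individuals`
#' subjects, each measured at `n_timepoints` occasions, with shared
#' linear-Gaussian two-slice dynamics and an individual-specific baseline
#' offset per gene (removed downstream by [reference_to_baseline()]).
#'
#' Per individual, deviations d from baseline evolve as
#' \deqn{d_t(g) = \sum_{p \to g \in inter} c_{pg} d_{t-1}(p)
#'              + \sum_{p \to g \in intra} c_{pg} d_t(p) + \epsilon_t(g),}
#' with d_0(g) drawn N(0, `init_sd`). The emitted log-scale value is
#' baseline offset + deviation. With the default `init_sd = 0` each
#' individual starts exactly at their personal baseline state, so baseline
#' referencing removes the offsets exactly and the referenced series follow
#' the stated dynamics with known coefficients. A positive `init_sd` makes
#' time 0 itself noisy: referencing then leaves a residual individual-level
#' intercept in every later timepoint, a deliberate, tunable violation of
#' the downstream models' assumptions for robustness studies. Intra-slice
#' edges must form a DAG; self links are allowed only in the inter-slice
#' set.
#'
#' @param genes character vector of gene ids.
#' @param inter_edges data frame with columns `parent`, `child` and optional
#'   `coefficient` (edges parent at t-1 -> child at t; self pairs allowed).
#' @param intra_edges data frame like `inter_edges` for within-slice edges
#'   (acyclic; no self pairs). May be `NULL` for none.
#' @param n_individuals,n_timepoints cohort geometry; the defaults mirror a
#'   40-subject, 7-occasion daily sampling design.
#' @param noise_sd innovation SD of the deviations.
#' @param baseline_sd SD of the per-individual, per-gene baseline offsets.
#' @param init_sd SD of the time-0 deviation from baseline (default 0: the
#'   baseline sample measures the individual's resting state exactly).
#' @param default_coefficient used for edges lacking a `coefficient` column.
#' @param arm panel arm label.
#' @param seed integer seed.
#' @return A `ground_truth_panel`: list with the `expression_panel` in
#'   `$panel`, `$true_inter_edges`, `$true_intra_edges` (data frames with
#'   coefficients) and the generator settings.
#' @export
simulate_cohort_panel <- function(genes,
                                  inter_edges = NULL,
                                  intra_edges = NULL,
                                  n_individuals = 40,
                                  n_timepoints = 7,
                                  noise_sd = 1,
                                  baseline_sd = 1,
                                  init_sd = 0,
                                  default_coefficient = 0.5,
                                  arm = "synthetic",
                                  seed = 1) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) arg_error("duplicate gene ids")
  norm_edges <- function(e, slice) {
    if (is.null(e) || nrow(as.data.frame(e)) == 0L) {
      return(data.frame(parent = character(), child = character(),
                        coefficient = numeric()))
    }
    e <- as.data.frame(e)
    if (!all(c("parent", "child") %in% names(e))) {
      arg_error("edge tables need 'parent' and 'child' columns")
    }
    if (is.null(e$coefficient)) e$coefficient <- default_coefficient
    bad <- setdiff(c(e$parent, e$child), genes)
    if (length(bad)) {
      arg_error(paste0("edge endpoint(s) not in gene set: ",
                       paste(unique(bad), collapse = ", ")))
    }
    if (slice == "intra" && any(e$parent == e$child)) {
      arg_error("self edges are only allowed in the inter-slice set")
    }
    data.frame(parent = as.character(e$parent), child = as.character(e$child),
               coefficient = as.numeric(e$coefficient))
  }
  inter <- norm_edges(inter_edges, "inter")
  intra <- norm_edges(intra_edges, "intra")

  order_idx <- topological_order(genes, intra) # errors on intra cycles
  p <- length(genes)
  n_individuals <- as.integer(n_individuals)
  n_timepoints <- as.integer(n_timepoints)
  stopifnot(n_individuals >= 1, n_timepoints >= 1)

  # coefficient matrices: Ainter[p_, g] multiplies d_{t-1}(p_); same for intra
  Ainter <- matrix(0, p, p, dimnames = list(genes, genes))
  if (nrow(inter)) {
    Ainter[cbind(inter$parent, inter$child)] <- inter$coefficient
  }
  Aintra <- matrix(0, p, p, dimnames = list(genes, genes))
  if (nrow(intra)) {
    Aintra[cbind(intra$parent, intra$child)] <- intra$coefficient
  }

  individuals <- sprintf("ind%02d", seq_len(n_individuals))
  values <- with_seed(seed, {
    v <- array(NA_real_, dim = c(p, n_individuals, n_timepoints),
               dimnames = list(genes, individuals, NULL))
    for (i in seq_len(n_individuals)) {
      offset <- rnorm(p, 0, baseline_sd)
      d <- rnorm(p, 0, init_sd)
      v[, i, 1L] <- offset + d
      if (n_timepoints > 1L) {
        for (t in 2:n_timepoints) {
          eps <- rnorm(p, 0, noise_sd)
          dn <- drop(crossprod(Ainter, d)) + eps
          for (g in order_idx) { # topological order: intra parents settled first
            dn[g] <- dn[g] + sum(Aintra[, g] * dn)
          }
          d <- dn
          v[, i, t] <- offset + d
        }
      }
    }
    v
  })

  panel <- expression_panel(values, genes = genes, individuals = individuals,
                            timepoints = seq_len(n_timepoints) - 1L, arm = arm)
  structure(
    list(panel = panel, true_inter_edges = inter, true_intra_edges = intra,
         noise_sd = noise_sd, baseline_sd = baseline_sd, init_sd = init_sd,
         seed = seed),
    class = "ground_truth_panel"
  )
}

#' @export
print.ground_truth_panel <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort panel: %d genes x %d individuals x %d timepoints\n",
    length(x$panel$genes), length(x$panel$individuals),
    length(x$panel$timepoints)))
  cat(sprintf("  true edges: %d inter-slice, %d intra-slice\n",
              nrow(x$true_inter_edges), nrow(x$true_intra_edges)))
  invisible(x)
}

# Kahn topological sort over the intra-slice DAG; returns child indices in an
# order where every intra parent precedes its children. Errors on cycles.
topological_order <- function(genes, intra) {
  p <- length(genes)
  if (nrow(intra) == 0L) return(seq_len(p))
  parents <- split(match(intra$parent, genes), match(intra$child, genes))
  indeg <- integer(p)
  indeg[as.integer(names(parents))] <- lengths(parents)
  children <- split(match(intra$child, genes), match(intra$parent, genes))
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    g <- queue[1L]; queue <- queue[-1L]
    out <- c(out, g)
    for (ch in children[[as.character(g)]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < p) arg_error("intra-slice edges contain a cycle")
  out
}
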