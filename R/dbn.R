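#' Pool transition rows for two-slice network learning
#'
#' Collects, across individuals, every consecutive timepoint pair (t-1, t)
#' into matched row pairs of all gene values: the data a first-order Markov
#' two-slice model is trained on. Pairs never span two individuals.
#' Individuals with fewer than 2 timepoints are dropped with a warning.
#'
#' @param panel an `expression_panel`, typically baseline-referenced.
#' @return A `transition_data`: list with matrices `prev` and `cur` (rows x
#'   genes; row r of `prev` holds all gene values at t-1 matching row r of
#'   `cur` at t), `genes`, and a `provenance` data frame (`individual`, `t`).
#' @export
transition_rows <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  L <- length(panel$timepoints)
  if (L < 2L) data_error("need at least 2 timepoints for transitions")
  ni <- length(panel$individuals)
  p <- length(panel$genes)
  n_rows <- ni * (L - 1L)
  prev <- matrix(NA_real_, n_rows, p, dimnames = list(NULL, panel$genes))
  cur <- matrix(NA_real_, n_rows, p, dimnames = list(NULL, panel$genes))
  r <- 0L
  for (i in seq_len(ni)) {
    for (t in 2:L) {
      r <- r + 1L
      prev[r, ] <- panel$values[, i, t - 1L]
      cur[r, ] <- panel$values[, i, t]
    }
  }
  structure(
    list(prev = prev, cur = cur, genes = panel$genes,
         provenance = data.frame(
           individual = rep(panel$individuals, each = L - 1L),
           t = rep(panel$timepoints[-1L], ni))),
    class = "transition_data"
  )
}

# residual sum of squares of an OLS fit, tolerant of pivoting
.rss <- function(X, y) {
  fit <- stats::.lm.fit(X, y)
  sum(fit$residuals^2)
}

#' BIC score of one child's local linear-Gaussian model
#'
#' Regresses the child at time t on an intercept, its intra-slice parents at
#' time t, and its inter-slice parents at time t-1, and scores the fit with
#' the Gaussian profile-likelihood form
#' \deqn{BIC = n \ln(RSS/n) + k \ln(n),}
#' where k counts the regression coefficients plus one for the noise
#' variance. Lower is better. An exact fit (RSS = 0) scores -Inf. Because
#' intra-slice structure is fixed and inter-slice parents point backward in
#' time, the total network score decomposes as the sum of these local
#' scores, so children can be learned independently.
#'
#' @param child gene id.
#' @param intra_parents,inter_parents character vectors of gene ids (either
#'   may be empty; `inter_parents` may include the child itself, a self
#'   link).
#' @param data a `transition_data`.
#' @return The BIC score (scalar).
#' @export
node_bic_score <- function(child, intra_parents, inter_parents, data) {
  stopifnot(inherits(data, "transition_data"))
  for (g in c(child, intra_parents, inter_parents)) {
    if (!(g %in% data$genes)) arg_error(paste0("unknown gene id: ", g))
  }
  n <- nrow(data$cur)
  n_par <- length(intra_parents) + length(inter_parents)
  if (n <= n_par + 2L) {
    abort_tn(sprintf(
      "BIC undefined: %d rows cannot support %d parents plus intercept",
      n, n_par), "temponet_insufficient_data")
  }
  X <- cbind(1, data$cur[, intra_parents, drop = FALSE],
             data$prev[, inter_parents, drop = FALSE])
  y <- data$cur[, child]
  rss <- .rss(X, y)
  k <- ncol(X) + 1L
  if (rss <= 1e-12 * sum((y - mean(y))^2)) return(-Inf) # exact fit
  n * log(rss / n) + k * log(n)
}

new_two_slice_network <- function(genes, intra_edges, inter_edges,
                                  bic = NULL) {
  structure(
    list(genes = genes, intra_edges = intra_edges, inter_edges = inter_edges,
         bic = bic),
    class = "two_slice_network"
  )
}

#' @export
print.two_slice_network <- function(x, ...) {
  cat(sprintf("Two-slice network: %d genes, %d intra-slice, %d inter-slice edge(s)\n",
              length(x$genes), nrow(x$intra_edges), nrow(x$inter_edges)))
  if (!is.null(x$inter_edges$frequency)) {
    cat(sprintf("  consensus frequencies %.2f-%.2f\n",
                min(x$inter_edges$frequency), max(x$inter_edges$frequency)))
  }
  if (!is.null(x$bic)) cat(sprintf("  total BIC %.4f\n", x$bic))
  invisible(x)
}

empty_edges <- function(with_freq = FALSE) {
  e <- data.frame(parent = character(), child = character())
  if (with_freq) e$frequency <- numeric()
  e
}

#' Learn inter-slice links of a two-slice dynamic Bayesian network
#'
#' The supplied intra-slice network (e.g. a static Bayesian network learned
#' on a large steady-state cohort) is held fixed: its edges are never added
#' or removed, though their regression coefficients are re-estimated inside
#' every candidate model. Only inter-slice links (parent at t-1 -> child at
#' t, self links allowed) are searched. Because the score decomposes per
#' child, each child is optimized independently by greedy hill-climbing over
#' single-link additions and removals from its candidate set, started from a
#' seeded random subset with a shuffled candidate order, until no move lowers
#' the BIC. One network is returned per restart.
#'
#' @param data a `transition_data`.
#' @param intra_edges data frame (`parent`, `child`) of fixed intra-slice
#'   edges (must be acyclic); `NULL` for none.
#' @param candidates optional named list mapping each child gene to its
#'   candidate inter-slice parents; defaults to all genes (including the
#'   child itself).
#' @param restarts number of random restarts (the reference protocol uses
#'   1000; scale down for small studies).
#' @param seed master seed; restart r uses a derived sub-seed.
#' @param screen_top_k optional integer: restrict each child's candidates to
#'   the k genes with the largest absolute lagged correlation, bounding cost
#'   on large panels.
#' @return List of `two_slice_network` objects, one per restart, each with
#'   its total BIC.
#' @export
learn_inter_slice <- function(data, intra_edges = NULL, candidates = NULL,
                              restarts = 10, seed = 1, screen_top_k = NULL) {
  stopifnot(inherits(data, "transition_data"))
  genes <- data$genes
  if (is.null(intra_edges) || nrow(as.data.frame(intra_edges)) == 0L) {
    intra_edges <- empty_edges()
  } else {
    intra_edges <- as.data.frame(intra_edges)[, c("parent", "child")]
    topological_order(genes, data.frame(intra_edges, coefficient = 1)) # DAG check
  }
  if (!is.numeric(restarts) || restarts < 1) {
    arg_error("restarts must be >= 1")
  }
  restarts <- as.integer(restarts)

  intra_parents <- lapply(genes, function(g) {
    intra_edges$parent[intra_edges$child == g]
  })
  names(intra_parents) <- genes

  if (is.null(candidates)) {
    candidates <- setNames(rep(list(genes), length(genes)), genes)
  }
  if (!is.null(screen_top_k)) {
    k <- as.integer(screen_top_k)
    candidates <- lapply(genes, function(g) {
      cand <- candidates[[g]]
      if (length(cand) <= k) return(cand)
      r <- abs(suppressWarnings(
        stats::cor(data$prev[, cand, drop = FALSE], data$cur[, g])))
      r[is.na(r)] <- 0
      cand[order(-r)[seq_len(k)]]
    })
    names(candidates) <- genes
  }

  n <- nrow(data$cur)
  lapply(seq_len(restarts), function(r) {
    rseed <- derive_seed(seed, paste0("restart", r))
    with_seed(rseed, {
      inter <- lapply(genes, function(g) {
        cand <- candidates[[g]]
        max_par <- n - length(intra_parents[[g]]) - 3L # keep score defined
        if (length(cand) == 0L || max_par <= 0L) {
          return(.greedy_child(g, character(), intra_parents[[g]], data,
                               max_par))
        }
        start <- cand[stats::runif(length(cand)) < 0.5]
        if (length(start) > max_par) start <- start[seq_len(max_par)]
        .greedy_child(g, cand, intra_parents[[g]], data, max_par,
                      start = start)
      })
      names(inter) <- genes
      edges <- do.call(rbind, lapply(genes, function(g) {
        if (length(inter[[g]]$parents) == 0L) return(NULL)
        data.frame(parent = inter[[g]]$parents, child = g)
      }))
      if (is.null(edges)) edges <- empty_edges()
      rownames(edges) <- NULL
      new_two_slice_network(genes, intra_edges, edges,
                            bic = sum(vapply(inter, `[[`, numeric(1), "bic")))
    })
  })
}

# greedy hill-climbing for one child; assumes RNG already seeded
.greedy_child <- function(child, cand, intra, data, max_par,
                          start = character()) {
  current <- start
  score <- node_bic_score(child, intra, current, data)
  if (length(cand)) {
    repeat {
      improved <- FALSE
      for (g in sample(cand)) { # shuffled candidate order each sweep
        if (g %in% current) {
          proposal <- setdiff(current, g)
        } else {
          if (length(current) >= max_par) next
          proposal <- c(current, g)
        }
        s <- node_bic_score(child, intra, proposal, data)
        if (s < score - 1e-9) {
          current <- proposal
          score <- s
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  list(parents = sort(current), bic = score)
}

#' Exhaustive inter-slice parent-set search for one child
#'
#' Enumerates every subset of the candidate set and returns the BIC-optimal
#' one. Exponential in the number of candidates; intended as an exact
#' reference for small candidate sets.
#'
#' @inheritParams node_bic_score
#' @param candidates candidate inter-slice parents (<= ~15 practical).
#' @return List with `parents` (sorted) and `bic`.
#' @export
exhaustive_child_search <- function(child, candidates, intra_parents, data) {
  stopifnot(inherits(data, "transition_data"))
  m <- length(candidates)
  best <- list(parents = character(),
               bic = node_bic_score(child, intra_parents, character(), data))
  if (m == 0L) return(best)
  for (mask in seq_len(2^m - 1L)) {
    subset <- candidates[bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0]
    n_par <- length(intra_parents) + length(subset)
    if (nrow(data$cur) <= n_par + 2L) next
    s <- node_bic_score(child, intra_parents, subset, data)
    if (s < best$bic - 1e-9) best <- list(parents = sort(subset), bic = s)
  }
  best
}

#' Consensus over networks learned from random restarts
#'
#' An inter-slice edge enters the consensus network iff it appears in at
#' least `freq_threshold` of the structures (the boundary is inclusive: an
#' edge at exactly the threshold is kept). Appearance frequencies are
#' recorded for every edge in the union of the structures.
#'
#' @param structures list of `two_slice_network` objects (all over the same
#'   genes and intra-slice edges).
#' @param freq_threshold fraction in (0, 1]; the reference protocol keeps
#'   edges appearing in at least 30% of structures.
#' @return A `two_slice_network` whose `inter_edges` carry a `frequency`
#'   column; the union-edge frequencies are attached as attribute
#'   `"all_frequencies"`.
#' @export
consensus_network <- function(structures, freq_threshold = 0.3) {
  if (!is.list(structures) || length(structures) == 0L ||
      !all(vapply(structures, inherits, logical(1), "two_slice_network"))) {
    arg_error("structures must be a non-empty list of two_slice_network")
  }
  if (!is.numeric(freq_threshold) || freq_threshold <= 0 ||
      freq_threshold > 1) {
    arg_error("freq_threshold must be in (0, 1]")
  }
  B <- length(structures)
  keys <- unlist(lapply(structures, function(s) {
    if (nrow(s$inter_edges) == 0L) return(character())
    paste(s$inter_edges$parent, s$inter_edges$child, sep = "\r")
  }))
  first <- structures[[1L]]
  if (length(keys) == 0L) {
    net <- new_two_slice_network(first$genes, first$intra_edges,
                                 empty_edges(with_freq = TRUE))
    attr(net, "all_frequencies") <- empty_edges(with_freq = TRUE)
    return(net)
  }
  tab <- table(keys)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  union_edges <- data.frame(
    parent = vapply(parts, `[`, character(1), 1L),
    child = vapply(parts, `[`, character(1), 2L),
    frequency = as.numeric(tab) / B
  )
  union_edges <- union_edges[order(union_edges$parent, union_edges$child), ,
                             drop = FALSE]
  rownames(union_edges) <- NULL
  kept <- union_edges[union_edges$frequency >= freq_threshold, , drop = FALSE]
  rownames(kept) <- NULL
  net <- new_two_slice_network(first$genes, first$intra_edges, kept)
  attr(net, "all_frequencies") <- union_edges
  net
}

#' Fraction of inter-slice links that are self links
#'
#' A self link connects a gene at t-1 to the same gene at t: temporal
#' autoregulation. Undefined (NA) when the network has no inter-slice edges.
#'
#' @param network a `two_slice_network`.
#' @return Scalar in `[0, 1]`, or `NA_real_` for an empty inter-slice set.
#' @export
self_link_fraction <- function(network) {
  stopifnot(inherits(network, "two_slice_network"))
  e <- network$inter_edges
  if (nrow(e) == 0L) return(NA_real_)
  mean(e$parent == e$child)
}
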