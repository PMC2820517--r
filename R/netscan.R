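#' Run the Granger causality test on every ordered gene pair
#'
#' For p genes, performs p(p-1) pooled tests (source -> target, source !=
#' target) on the panel's stacked lagged rows. Pairs whose test cannot be run
#' are kept as rows with an explanatory status rather than dropped silently.
#'
#' @param panel an `expression_panel`, already baseline-referenced.
#' @param intercept passed to [granger_test()].
#' @return Data frame with one row per ordered pair: `source`, `target`,
#'   `n_rows`, `f_stat`, `df2`, `p_raw`, `status` (one of `"ok"`,
#'   `"degenerate"`, `"collinear"`, `"insufficient_data"`).
#' @export
scan_all_pairs <- function(panel, intercept = TRUE) {
  stopifnot(inherits(panel, "expression_panel"))
  p <- length(panel$genes)
  if (p < 2L) arg_error("need at least 2 genes to scan pairs")
  pairs <- expand.grid(source = panel$genes, target = panel$genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  pairs <- pairs[order(pairs$source, pairs$target), , drop = FALSE]
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    design <- stack_lagged_rows(panel, pairs$source[k], pairs$target[k])
    res <- tryCatch(granger_test(design, intercept = intercept),
                    temponet_insufficient_data = function(e) e)
    if (inherits(res, "condition")) {
      return(data.frame(source = pairs$source[k], target = pairs$target[k],
                        n_rows = nrow(design), f_stat = NA_real_,
                        df2 = NA_integer_, p_raw = NA_real_,
                        status = "insufficient_data"))
    }
    status <- if (res$collinear) "collinear"
              else if (res$degenerate) "degenerate" else "ok"
    data.frame(source = pairs$source[k], target = pairs$target[k],
               n_rows = res$n_rows, f_stat = res$f_stat, df2 = res$df2,
               p_raw = res$p_value, status = status)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "genes") <- panel$genes
  res
}

#' Apply multiple-testing correction and keep significant edges
#'
#' Adjusts the raw p-values over all tested ordered pairs (Bonferroni by
#' default; Benjamini-Hochberg available), keeps edges with adjusted p below
#' `alpha`, and always reports Benjamini-Hochberg q-values alongside as the
#' FDR estimate for the retained set.
#'
#' @param edge_table output of [scan_all_pairs()] (or a compatible data frame
#'   with `source`, `target`, `p_raw`).
#' @param method `"bonferroni"` or `"bh"`.
#' @param alpha significance threshold on the adjusted p-value, in (0, 1).
#' @return A `causal_network`: list with `edges` (significant edges, columns
#'   `source`, `target`, `p_raw`, `p_adjusted`, `q_value`), `all_tests`,
#'   `genes`, `alpha`, `method`, `n_tests`, and `pruned = FALSE`.
#' @export
adjust_and_threshold <- function(edge_table, method = c("bonferroni", "bh"),
                                 alpha = 0.01) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    arg_error("alpha must be in (0, 1)")
  }
  tab <- as.data.frame(edge_table)
  genes <- attr(edge_table, "genes")
  if (is.null(genes)) genes <- sort(unique(c(tab$source, tab$target)))
  tested <- tab[!is.na(tab$p_raw), , drop = FALSE]
  if (nrow(tested) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        p_raw = numeric(), p_adjusted = numeric(),
                        q_value = numeric())
  } else {
    tested$p_adjusted <- stats::p.adjust(
      tested$p_raw, method = if (method == "bh") "BH" else "bonferroni")
    tested$q_value <- stats::p.adjust(tested$p_raw, method = "BH")
    edges <- tested[tested$p_adjusted < alpha,
                    c("source", "target", "p_raw", "p_adjusted", "q_value"),
                    drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(
    list(edges = edges, all_tests = tab, genes = genes, alpha = alpha,
         method = method, n_tests = nrow(tested), pruned = FALSE),
    class = "causal_network"
  )
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf(
    "Granger causal network: %d edges over %d genes (%s-adjusted p < %g%s)\n",
    nrow(x$edges), length(x$genes), x$method, x$alpha,
    if (x$pruned) ", pruned to in-degree <= 1" else ""))
  invisible(x)
}

#' Prune putative indirect links: keep one incoming edge per target
#'
#' A bivariate test marks every upstream gene of a regulatory chain as causal
#' for every downstream one, so targets accumulate redundant incoming links.
#' Following the single-strongest-cause rule, each target keeps only its most
#' significant (smallest raw p) incoming edge; ties are broken by
#' lexicographic source id, with a message.
#'
#' @param network a thresholded `causal_network`.
#' @return The network with `edges` filtered so every target has in-degree
#'   <= 1, and `pruned = TRUE`.
#' @export
prune_incoming <- function(network) {
  stopifnot(inherits(network, "causal_network"))
  e <- network$edges
  if (nrow(e) > 1L) {
    keep <- unlist(lapply(split(seq_len(nrow(e)), e$target), function(idx) {
      sub <- e[idx, , drop = FALSE]
      best <- which(sub$p_raw == min(sub$p_raw))
      if (length(best) > 1L) {
        message(sprintf("tie on p-value for target %s: keeping source %s",
                        sub$target[1], min(sub$source[best])))
        best <- best[sub$source[best] == min(sub$source[best])][1L]
      }
      idx[best]
    }), use.names = FALSE)
    e <- e[sort(keep), , drop = FALSE]
    rownames(e) <- NULL
  }
  network$edges <- e
  network$pruned <- TRUE
  network
}

#' Rank causal regulators by out-degree
#'
#' A causal regulator is a gene supported as Granger-causal for at least one
#' other gene; regulators are ranked by the number of genes they regulate.
#'
#' @param network a (typically pruned) `causal_network`.
#' @return Data frame `gene`, `out_degree`, sorted descending by out-degree
#'   then by gene id; genes with out-degree 0 are excluded.
#' @export
rank_regulators <- function(network) {
  stopifnot(inherits(network, "causal_network"))
  if (nrow(network$edges) == 0L) {
    return(data.frame(gene = character(), out_degree = integer()))
  }
  deg <- table(network$edges$source)
  out <- data.frame(gene = names(deg), out_degree = as.integer(deg))
  out <- out[order(-out$out_degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Out-degree distribution of a causal network
#'
#' Exact histogram of out-degrees over the full gene universe, including the
#' zero-degree genes (heavy-tailed, approximately scale-free shapes are
#' typical of these networks; no power-law fit is performed here).
#'
#' @param network a `causal_network`.
#' @return Data frame `degree`, `count`; counts sum to the number of genes.
#' @export
out_degree_distribution <- function(network) {
  stopifnot(inherits(network, "causal_network"))
  deg <- setNames(integer(length(network$genes)), network$genes)
  if (nrow(network$edges)) {
    tab <- table(network$edges$source)
    deg[names(tab)] <- as.integer(tab)
  }
  counts <- table(deg)
  data.frame(degree = as.integer(names(counts)), count = as.integer(counts))
}
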