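# small in-code fixtures shared across test files

# panel with hand-set values: 2 genes, 2 individuals, 3 timepoints
tiny_panel <- function() {
  vals <- array(0, dim = c(2, 2, 3),
                dimnames = list(c("gA", "gB"), c("i1", "i2"), 0:2))
  vals["gA", "i1", ] <- c(0.5, 1.0, 2.0)
  vals["gA", "i2", ] <- c(1.0, 1.0, 1.0)
  vals["gB", "i1", ] <- c(0.0, 0.5, 1.5)
  vals["gB", "i2", ] <- c(2.0, 2.5, 3.0)
  expression_panel(vals, c("gA", "gB"), c("i1", "i2"), 0:2, arm = "fasted")
}

# pure-noise panel (no regulatory structure at all)
noise_panel <- function(n_genes = 5, n_individuals = 20, n_timepoints = 7,
                        seed = 1) {
  genes <- paste0("n", seq_len(n_genes))
  gt <- simulate_cohort_panel(genes, inter_edges = NULL, intra_edges = NULL,
                              n_individuals = n_individuals,
                              n_timepoints = n_timepoints, seed = seed)
  gt$panel
}

# causal network object built from a bare p-value table (for pruning and
# ranking tests that do not need a panel)
network_from_pvals <- function(edges, alpha = 0.05, method = "bh",
                               genes = NULL) {
  tab <- data.frame(source = edges$source, target = edges$target,
                    p_raw = edges$p_raw)
  attr(tab, "genes") <- genes %||% sort(unique(c(tab$source, tab$target)))
  adjust_and_threshold(tab, method = method, alpha = alpha)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
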