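test_that("all-pairs scan covers every ordered pair once", {
  gt <- simulate_cohort_panel(paste0("g", 1:3), n_individuals = 10,
                              n_timepoints = 5, seed = 1)
  tab <- scan_all_pairs(reference_to_baseline(gt$panel))
  expect_identical(nrow(tab), 6L)
  expect_false(any(tab$source == tab$target))
  expect_identical(anyDuplicated(paste(tab$source, tab$target)), 0L)
  expect_true(all(tab$status == "ok"))
  expect_error(scan_all_pairs(reference_to_baseline(
    simulate_cohort_panel("solo", n_individuals = 3, n_timepoints = 4)$panel)),
    class = "temponet_argument_error")
})

test_that("correction arithmetic follows Bonferroni and Benjamini-Hochberg", {
  net <- network_from_pvals(
    data.frame(source = c("a", "b", "c"), target = c("x", "y", "z"),
               p_raw = c(0.001, 0.02, 0.04)),
    alpha = 0.01, method = "bonferroni")
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$p_adjusted, 0.003)

  # BH step-up on {0.01, 0.02, 0.03, 0.04} with m = 4: all q = 0.04
  net2 <- network_from_pvals(
    data.frame(source = letters[1:4], target = LETTERS[1:4],
               p_raw = c(0.01, 0.02, 0.03, 0.04)),
    alpha = 0.05, method = "bh")
  expect_equal(net2$edges$q_value, rep(0.04, 4))
  expect_equal(net2$edges$p_adjusted, rep(0.04, 4))

  # hopeless p-values leave an empty network
  net3 <- network_from_pvals(
    data.frame(source = "a", target = "b", p_raw = 1), alpha = 0.01)
  expect_identical(nrow(net3$edges), 0L)
  expect_error(network_from_pvals(
    data.frame(source = "a", target = "b", p_raw = 0.5), alpha = 0),
    class = "temponet_argument_error")
})

test_that("Bonferroni networks are nested inside BH networks", {
  set.seed(7)
  tab <- data.frame(source = rep(letters[1:6], each = 5),
                    target = rep(LETTERS[1:5], 6),
                    p_raw = stats::rbeta(30, 0.3, 4))
  bon <- network_from_pvals(tab, alpha = 0.05, method = "bonferroni")
  bh <- network_from_pvals(tab, alpha = 0.05, method = "bh")
  key <- function(n) paste(n$edges$source, n$edges$target)
  expect_true(all(key(bon) %in% key(bh)))
})

test_that("pruning keeps only the most significant incoming link", {
  net <- network_from_pvals(
    data.frame(source = c("A", "B", "D"), target = c("C", "C", "E"),
               p_raw = c(0.004, 0.001, 0.002)),
    alpha = 0.05, method = "bh")
  pruned <- prune_incoming(net)
  kept_c <- pruned$edges[pruned$edges$target == "C", ]
  expect_identical(kept_c$source, "B")
  expect_true(all(table(pruned$edges$target) <= 1L))
  # unique incoming links are untouched
  expect_true("D" %in% pruned$edges$source)
  expect_identical(nrow(pruned$edges), 2L)
  # ties broken towards the lexicographically smaller source
  tie <- network_from_pvals(
    data.frame(source = c("Z", "M"), target = c("T", "T"),
               p_raw = c(0.001, 0.001)),
    alpha = 0.05, method = "bh")
  expect_message(tiep <- prune_incoming(tie), "tie")
  expect_identical(tiep$edges$source, "M")
})

test_that("pruned networks conserve degree sums and bound edge count", {
  set.seed(11)
  for (rep in 1:20) {
    genes <- paste0("g", 1:8)
    tab <- expand.grid(source = genes, target = genes,
                       stringsAsFactors = FALSE)
    tab <- tab[tab$source != tab$target, ]
    tab$p_raw <- stats::rbeta(nrow(tab), 0.2, 3)
    net <- prune_incoming(network_from_pvals(tab, alpha = 0.3, method = "bh",
                                             genes = genes))
    e <- nrow(net$edges)
    expect_lte(e, length(genes))
    expect_identical(sum(table(net$edges$source)), e)
    expect_identical(sum(table(net$edges$target)), e)
  }
})

test_that("regulators rank by out-degree with zero-degree genes omitted", {
  net <- network_from_pvals(
    data.frame(source = c("A", "A", "A", "B"),
               target = c("w", "x", "y", "z"),
               p_raw = rep(1e-4, 4)),
    alpha = 0.05, method = "bh", genes = c("A", "B", "C", "w", "x", "y", "z"))
  rk <- rank_regulators(net)
  expect_identical(rk$gene, c("A", "B"))
  expect_identical(rk$out_degree, c(3L, 1L))
  expect_false("C" %in% rk$gene)

  dist <- out_degree_distribution(net)
  expect_identical(sum(dist$count), 7L)
  expect_identical(dist$count[dist$degree == 0L], 5L)
  expect_identical(dist$count[dist$degree == 3L], 1L)

  empty <- network_from_pvals(
    data.frame(source = "A", target = "B", p_raw = 1),
    alpha = 0.05, genes = c("A", "B", "C"))
  d0 <- out_degree_distribution(empty)
  expect_identical(d0$degree, 0L)
  expect_identical(d0$count, 3L)
  expect_identical(nrow(rank_regulators(empty)), 0L)
})

test_that("a designed hub is recovered as the top regulator", {
  hits <- 0L
  n_rep <- 50L
  genes <- c("hub", paste0("t", 1:10), "bystander")
  inter <- rbind(
    data.frame(parent = "hub", child = paste0("t", 1:10), coefficient = 0.6),
    data.frame(parent = genes, child = genes, coefficient = 0.4))
  for (r in seq_len(n_rep)) {
    gt <- simulate_cohort_panel(genes, inter_edges = inter,
                                n_individuals = 40, n_timepoints = 7,
                                seed = 4000 + r)
    net <- adjust_and_threshold(
      scan_all_pairs(reference_to_baseline(gt$panel)),
      method = "bonferroni", alpha = 0.01)
    rk <- rank_regulators(prune_incoming(net))
    if (nrow(rk) && rk$gene[1] == "hub") hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("a structureless panel yields almost no corrected calls", {
  false_edges <- vapply(1:100, function(r) {
    panel <- reference_to_baseline(noise_panel(5, 20, 7, seed = 6000 + r))
    net <- adjust_and_threshold(scan_all_pairs(panel),
                                method = "bonferroni", alpha = 0.01)
    nrow(net$edges)
  }, numeric(1))
  expect_lte(mean(false_edges), 1)
})

test_that("the true edge dominates a small panel scan", {
  genes <- paste0("g", 1:5)
  inter <- rbind(data.frame(parent = "g1", child = "g2", coefficient = 0.6),
                 data.frame(parent = genes, child = genes, coefficient = 0.4))
  top <- vapply(1:100, function(r) {
    gt <- simulate_cohort_panel(genes, inter_edges = inter,
                                n_individuals = 40, n_timepoints = 7,
                                seed = 7000 + r)
    tab <- scan_all_pairs(reference_to_baseline(gt$panel))
    best <- tab[which.min(tab$p_raw), ]
    best$source == "g1" && best$target == "g2"
  }, logical(1))
  expect_gte(mean(top), 0.95)
})
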