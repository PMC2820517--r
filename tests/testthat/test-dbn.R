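test_that("transition rows pool (t-1, t) pairs within individuals", {
  gt <- simulate_cohort_panel(c("a", "b"), n_individuals = 40,
                              n_timepoints = 7, seed = 1)
  panel <- reference_to_baseline(gt$panel)
  td <- transition_rows(panel)
  expect_identical(nrow(td$cur), 200L) # 40 individuals x 5 transitions
  expect_identical(nrow(td$prev), 200L)

  # brute-force re-extraction
  for (k in sample(200, 20)) {
    i <- td$provenance$individual[k]
    t <- as.character(td$provenance$t[k])
    tp <- as.character(td$provenance$t[k] - 1L)
    expect_identical(td$cur[k, ], panel$values[, i, t])
    expect_identical(td$prev[k, ], panel$values[, i, tp])
  }

  one <- expression_panel(panel$values[, 1, 1:2, drop = FALSE], panel$genes,
                          panel$individuals[1], panel$timepoints[1:2])
  expect_identical(nrow(transition_rows(one)$cur), 1L)
})

test_that("node BIC matches its closed form and degenerates sensibly", {
  gt <- simulate_cohort_panel(c("a", "b"), n_individuals = 40,
                              n_timepoints = 7, seed = 2)
  td <- transition_rows(reference_to_baseline(gt$panel))
  n <- nrow(td$cur)
  # parent-free model: intercept-only regression, k = 2
  got <- node_bic_score("a", character(), character(), td)
  v <- stats::var(td$cur[, "a"])
  expect_equal(got, n * log(v * (n - 1) / n) + 2 * log(n), tolerance = 1e-8)

  # child identical to its own lag: exact fit, unbounded preference for the
  # self link
  td2 <- td
  td2$cur[, "b"] <- td2$prev[, "b"]
  expect_identical(node_bic_score("b", character(), "b", td2), -Inf)
  st <- learn_inter_slice(td2, restarts = 3, seed = 3)
  for (s in st) {
    expect_true(any(s$inter_edges$parent == "b" & s$inter_edges$child == "b"))
  }

  expect_error(node_bic_score("zz", character(), character(), td),
               class = "temponet_argument_error")
})

test_that("an irrelevant parent usually worsens the BIC", {
  worse <- vapply(1:100, function(r) {
    gt <- simulate_cohort_panel(c("child", "noisegene"),
                                inter_edges = data.frame(parent = "child",
                                                         child = "child",
                                                         coefficient = 0.5),
                                n_individuals = 40, n_timepoints = 7,
                                seed = 800 + r)
    td <- transition_rows(reference_to_baseline(gt$panel))
    with_parent <- node_bic_score("child", character(),
                                  c("child", "noisegene"), td)
    without <- node_bic_score("child", character(), "child", td)
    with_parent > without
  }, logical(1))
  expect_gte(mean(worse), 0.9)
})

test_that("a single strong candidate is always selected", {
  gt <- simulate_cohort_panel(c("p", "q"),
                              inter_edges = data.frame(
                                parent = c("p", "p"), child = c("p", "q"),
                                coefficient = c(0.5, 0.9)),
                              n_individuals = 40, n_timepoints = 7, seed = 4)
  td <- transition_rows(reference_to_baseline(gt$panel))
  st <- learn_inter_slice(td, candidates = list(p = character(), q = "p"),
                          restarts = 5, seed = 5)
  for (s in st) {
    expect_identical(s$inter_edges$parent, "p")
    expect_identical(s$inter_edges$child, "q")
  }
})

test_that("network score decomposes over children", {
  gt <- simulate_cohort_panel(paste0("g", 1:4),
                              inter_edges = data.frame(
                                parent = paste0("g", 1:4),
                                child = paste0("g", 1:4), coefficient = 0.5),
                              n_individuals = 30, n_timepoints = 6, seed = 6)
  td <- transition_rows(reference_to_baseline(gt$panel))
  s <- learn_inter_slice(td, restarts = 1, seed = 7)[[1]]
  total <- sum(vapply(td$genes, function(g) {
    node_bic_score(g, character(),
                   sort(s$inter_edges$parent[s$inter_edges$child == g]), td)
  }, numeric(1)))
  expect_equal(s$bic, total, tolerance = 1e-10)
})

test_that("fixed intra-slice edges are honoured, cycles rejected", {
  intra <- data.frame(parent = c("x", "y"), child = c("y", "z"))
  gt <- simulate_cohort_panel(c("x", "y", "z"),
                              inter_edges = data.frame(
                                parent = c("x", "y", "z"),
                                child = c("x", "y", "z"), coefficient = 0.5),
                              intra_edges = data.frame(intra,
                                                       coefficient = 0.6),
                              n_individuals = 30, n_timepoints = 6, seed = 8)
  td <- transition_rows(reference_to_baseline(gt$panel))
  st <- learn_inter_slice(td, intra_edges = intra, restarts = 2, seed = 9)
  for (s in st) expect_identical(s$intra_edges, intra)
  expect_error(
    learn_inter_slice(td, intra_edges = data.frame(parent = c("x", "y"),
                                                   child = c("y", "x")),
                      restarts = 1, seed = 1),
    class = "temponet_argument_error")
})

test_that("consensus keeps edges at or above the frequency threshold", {
  mk <- function(parents, children) {
    new_net <- temponet:::new_two_slice_network
    new_net(c("a", "b", "c"), data.frame(parent = character(),
                                         child = character()),
            data.frame(parent = parents, child = children))
  }
  # ten identical structures: consensus is the common structure at freq 1
  same <- replicate(10, mk(c("a", "b"), c("a", "b")), simplify = FALSE)
  cons <- consensus_network(same, 0.3)
  expect_identical(nrow(cons$inter_edges), 2L)
  expect_true(all(cons$inter_edges$frequency == 1))

  # edge in 2 of 10 excluded at 0.3; edge in 3 of 10 included (inclusive)
  mixed <- c(replicate(7, mk("a", "a"), simplify = FALSE),
             replicate(2, mk(c("a", "b"), c("a", "c")), simplify = FALSE),
             replicate(1, mk(c("a", "c"), c("a", "b")), simplify = FALSE))
  cons2 <- consensus_network(mixed, 0.3)
  keys <- paste(cons2$inter_edges$parent, cons2$inter_edges$child)
  expect_true("a a" %in% keys)
  expect_false("b c" %in% keys)
  allf <- attr(cons2, "all_frequencies")
  expect_equal(allf$frequency[allf$parent == "b" & allf$child == "c"], 0.2)

  # boundary: exactly at threshold is kept
  three <- c(replicate(3, mk("b", "b"), simplify = FALSE),
             replicate(7, mk("a", "a"), simplify = FALSE))
  keys3 <- paste(consensus_network(three, 0.3)$inter_edges$parent,
                 consensus_network(three, 0.3)$inter_edges$child)
  expect_true("b b" %in% keys3)

  # threshold 1 yields the intersection; consensus is a subset of the union
  inter1 <- consensus_network(mixed, 1)$inter_edges
  expect_identical(paste(inter1$parent, inter1$child), "a a")
  expect_true(all(paste(cons2$inter_edges$parent, cons2$inter_edges$child)
                  %in% paste(allf$parent, allf$child)))

  expect_error(consensus_network(list(), 0.3),
               class = "temponet_argument_error")
  expect_error(consensus_network(same, 0), class = "temponet_argument_error")
})

test_that("self-link fraction counts inter-slice self pairs", {
  mk <- temponet:::new_two_slice_network
  none <- data.frame(parent = character(), child = character())
  net <- mk(letters[1:3], none,
            data.frame(parent = c("a", "a", "b", "c"),
                       child = c("a", "b", "b", "b")))
  expect_equal(self_link_fraction(net), 0.5)
  allself <- mk(letters[1:2], none,
                data.frame(parent = c("a", "b"), child = c("a", "b")))
  expect_identical(self_link_fraction(allself), 1)
  expect_true(is.na(self_link_fraction(mk(letters[1:2], none, none))))
})
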