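toy_network <- function(edges) {
  planktonnet:::new_cor_network(
    data.frame(taxon_a = edges[, 1], taxon_b = edges[, 2],
               rho = rep(0.9, nrow(edges)), p = rep(0.001, nrow(edges)),
               sign = rep("+", nrow(edges))),
    "toy", "positive", 0.05, 999)
}

test_that("pair counts tally edges between labels, self pairs included", {
  net <- toy_network(cbind(c(1, 1, 2, 3, 4), c(2, 3, 3, 4, 5)))
  labels <- c("1" = "A", "2" = "A", "3" = "B", "4" = "B", "5" = "C")
  pc <- pair_counts(net, labels)
  expect_equal(sum(pc$count), 5L)
  get <- function(a, b) pc$count[pc$label_a == a & pc$label_b == b]
  expect_equal(get("A", "A"), 1L)  # 1-2
  expect_equal(get("A", "B"), 2L)  # 1-3, 2-3
  expect_equal(get("B", "B"), 1L)  # 3-4
  expect_equal(get("B", "C"), 1L)  # 4-5
  expect_equal(get("A", "C"), 0L)
  # one label only: single self pair with count E
  one <- pair_counts(net, setNames(rep("X", 5), 1:5))
  expect_equal(one$count, 5L)
  # bipartite edges between two labels
  bip <- toy_network(cbind(c(1, 1, 2), c(3, 4, 3)))
  pcb <- pair_counts(bip, c("1" = "L", "2" = "L", "3" = "R", "4" = "R"))
  expect_equal(pcb$count[pcb$label_a == "L" & pcb$label_b == "R"], 3L)
  expect_equal(sum(pcb$count), 3L)
  expect_error(pair_counts(net, labels[-5]), "unlabelled")
})

test_that("G(n,m) sampling is exhaustive at the extremes and uniform inside", {
  full <- sample_er(4, 6, seed = 1)
  expect_equal(nrow(full), 6L)
  expect_equal(full[order(full[, 1], full[, 2]), , drop = FALSE],
               planktonnet:::all_node_pairs(4)[, , drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(nrow(sample_er(5, 0, seed = 1)), 0L)
  expect_error(sample_er(4, 7), "between 0 and")
  # n=4, m=2: all 15 two-edge sets equally frequent over 10000 draws
  draws <- vapply(1:10000, function(s) {
    e <- sample_er(4, 2, seed = s)
    key <- paste(sort(paste(e[, 1], e[, 2])), collapse = ";")
  }, character(1))
  tab <- table(draws)
  expect_equal(length(tab), 15L)
  expect_gt(stats::chisq.test(as.vector(tab))$p.value, 0.01)
})

test_that("ER edge-set draws match an independent igraph cross-check", {
  # compare edge-count distribution inside a fixed node subset
  subset_count <- function(edges) sum(edges[, 1] <= 5 & edges[, 2] <= 5)
  ours <- vapply(1:2000, function(s) subset_count(sample_er(10, 12, seed = s)),
                 numeric(1))
  set.seed(1)
  theirs <- vapply(1:2000, function(i) {
    el <- igraph::as_edgelist(igraph::sample_gnm(10, 12))
    sum(pmax(el[, 1], el[, 2]) <= 5)
  }, numeric(1))
  expect_lt(abs(mean(ours) - mean(theirs)), 0.25)
})

test_that("replicate pair counts always conserve the edge total", {
  net <- toy_network(planktonnet:::all_node_pairs(8)[1:13, ])
  labels <- setNames(rep(c("A", "B", "C"), c(3, 3, 2)), 1:8)
  cl <- classify_pairs(net, labels, n_random = 99, seed = 5)
  expect_equal(sum(cl$empirical), 13L)
  expect_s3_class(cl, "dominance_classification")
  expect_identical(cl, classify_pairs(net, labels, n_random = 99, seed = 5))
})

test_that("concentrated within-group edges classify as dominant/rare versus the exact null", {
  # 8 nodes, labels A (1-4) and B (5-8); all 6 edges inside A
  aa_edges <- planktonnet:::all_node_pairs(4)
  net <- toy_network(aa_edges)
  labels <- setNames(rep(c("A", "B"), each = 4), 1:8)
  cl <- classify_pairs(net, labels, n_random = 999, seed = 3, nodes = 1:8)
  get <- function(a, b) cl[cl$label_a == a & cl$label_b == b, ]
  expect_equal(get("A", "A")$verdict, "dominant")
  expect_equal(get("A", "B")$verdict, "rare")
  # exact null by enumeration over all C(28,6) edge sets: count the A-A
  # edges in every possible 6-edge graph on 8 labelled nodes
  pairs8 <- planktonnet:::all_node_pairs(8)
  is_aa <- pairs8[, 2] <= 4
  sets <- combn(28, 6)
  aa_counts <- colSums(matrix(is_aa[sets], nrow = 6))
  q <- quantile(aa_counts, c(0.025, 0.975), type = 1)
  # Monte-Carlo thresholds bracket the enumerated ones within one count
  expect_lte(abs(get("A", "A")$null_q025 - q[[1]]), 1)
  expect_lte(abs(get("A", "A")$null_q975 - q[[2]]), 1)
  expect_gt(6, q[[2]])   # the empirical count is genuinely extreme
})

test_that("degenerate nulls give neutral verdicts", {
  # complete graph: every replicate equals the empirical network
  net <- toy_network(planktonnet:::all_node_pairs(5))
  labels <- setNames(rep(c("A", "B"), c(2, 3)), 1:5)
  cl <- classify_pairs(net, labels, n_random = 199, seed = 1)
  expect_true(all(cl$verdict == "neutral"))
  # empty network
  empty <- planktonnet:::new_cor_network(
    data.frame(taxon_a = integer(), taxon_b = integer(), rho = numeric(),
               p = numeric(), sign = character()),
    "toy", "negative", 0.05, 999)
  expect_error(pair_counts(empty, labels), NA)
})

test_that("relabelling permutes the classification table identically", {
  net <- toy_network(planktonnet:::all_node_pairs(8)[c(1, 3, 7, 9, 12, 20), ])
  labels <- setNames(rep(c("A", "B"), each = 4), 1:8)
  swapped <- setNames(ifelse(labels == "A", "Z", "A"), names(labels))
  cl1 <- classify_pairs(net, labels, n_random = 499, seed = 9)
  cl2 <- classify_pairs(net, swapped, n_random = 499, seed = 9)
  remap <- c(A = "Z", B = "A")
  for (i in seq_len(nrow(cl1))) {
    la <- remap[[cl1$label_a[i]]]; lb <- remap[[cl1$label_b[i]]]
    j <- which(cl2$label_a == min(la, lb) & cl2$label_b == max(la, lb))
    expect_equal(cl2$verdict[j], cl1$verdict[i])
    expect_equal(cl2$empirical[j], cl1$empirical[i])
  }
})

test_that("summary networks highlight non-neutral pairs with direction", {
  mk <- function(verdicts) {
    df <- data.frame(label_a = c("A", "A", "B"), label_b = c("A", "B", "B"),
                     empirical = c(3L, 1L, 2L), null_q025 = c(0L, 2L, 0L),
                     null_q975 = c(2L, 5L, 4L), verdict = verdicts,
                     stringsAsFactors = FALSE)
    planktonnet:::as_dominance(df, 999L, "negative")
  }
  all_neutral <- summary_network(list(negative = mk(rep("neutral", 3))))
  expect_equal(nrow(all_neutral$edges), 0L)
  one <- summary_network(list(negative = mk(c("dominant", "neutral",
                                              "neutral"))))
  expect_equal(nrow(one$edges), 1L)
  expect_equal(one$edges$direction, "more")
  expect_equal(igraph::E(one$graph)$style, "solid")
  # a pair non-neutral in both sign modes appears once per mode
  both <- summary_network(list(negative = mk(c("dominant", "neutral",
                                               "neutral")),
                               positive = mk(c("rare", "neutral",
                                               "neutral"))))
  expect_equal(nrow(both$edges), 2L)
  expect_setequal(both$edges$sign_mode, c("negative", "positive"))
  expect_setequal(both$edges$direction, c("more", "fewer"))
  # mismatched groupings abort
  other <- planktonnet:::as_dominance(
    data.frame(label_a = "X", label_b = "Y", empirical = 1L,
               null_q025 = 0L, null_q975 = 2L, verdict = "neutral"),
    999L, "positive")
  expect_error(summary_network(list(negative = mk(rep("neutral", 3)),
                                    positive = other)),
               "different label groupings")
})
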