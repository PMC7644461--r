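test_that("spearman rho matches concordance extremes and a tied oracle", {
  expect_equal(spearman_rho(1:3, 1:3), 1)
  expect_equal(spearman_rho(1:3, 3:1), -1)
  x <- c(1, 2, 2, 4); y <- c(2, 1, 3, 4)
  # mid-rank + Pearson by hand: 3 / sqrt(4.5 * 5)
  expect_equal(spearman_rho(x, y), 3 / sqrt(22.5))
  expect_equal(spearman_rho(x, y), oracle_spearman(x, y))
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
  expect_equal(spearman_rho(x, y), spearman_rho(y, x))
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:4, 1:5), "length")
})

test_that("permutation p-value approaches the exact enumeration value", {
  x <- 1:5
  exact <- oracle_exact_perm_fraction(x, x)   # 2/120: identity and reversal
  expect_equal(exact, 2 / 120)
  res <- permutation_pvalue(x, x, n_iter = 9999, seed = 1)
  expect_equal(res$rho, 1)
  # add-one estimator concentrates near (1 + B * 2/120) / (B + 1)
  expect_lt(abs(res$p - exact), 0.01)
  expect_gt(res$p, 0)
})

test_that("permutation p-value is deterministic in the seed and monotone-invariant", {
  set.seed(99)
  x <- rnorm(15); y <- rnorm(15)
  a <- permutation_pvalue(x, y, n_iter = 999, seed = 5)
  b <- permutation_pvalue(x, y, n_iter = 999, seed = 5)
  expect_identical(a, b)
  c2 <- permutation_pvalue(exp(x), y, n_iter = 999, seed = 5)
  expect_identical(a, c2)   # depends on ranks only
  d <- permutation_pvalue(x, y, n_iter = 999, seed = 6)
  expect_equal(d$rho, a$rho)   # the statistic does not depend on the seed
  expect_equal(a$rho, permutation_pvalue(y, x, n_iter = 999, seed = 5)$rho)
})

test_that("perfectly monotone pairs always form a positive edge", {
  taxa <- generate_taxa(c(phytoplankton = 6L), seed = 3)
  m <- generate_abundances(taxa, 19, seed = 8)
  vals <- unclass(m)
  vals[, 1] <- sort(vals[, 1])
  vals[, 2] <- sort(vals[, 2])           # increasing together: rho = 1
  m2 <- abundance_matrix(vals, abundance_dates(m), colnames(m))
  nets <- build_networks(m2, n_iter = 999, seed = 4)
  pos <- nets$positive$edges
  expect_true(any(pos$taxon_a == 1 & pos$taxon_b == 2))
  expect_equal(pos$rho[pos$taxon_a == 1 & pos$taxon_b == 2], 1)
})

test_that("network construction keeps the false-positive rate near alpha", {
  counts <- vapply(1:30, function(s) {
    m <- independent_matrix(12, 20, seed = 1000 + s)
    nets <- build_networks(m, alpha = 0.05, n_iter = 499, seed = s)
    nrow(nets$combined$edges)
  }, numeric(1))
  expected <- 0.05 * choose(12, 2)       # 3.3 edges per replicate
  expect_lt(abs(mean(counts) - expected), 1.2)
})

test_that("constant columns are dropped and logged, not fatal", {
  taxa <- generate_taxa(c(phytoplankton = 5L), seed = 2)
  m <- generate_abundances(taxa, 10, seed = 2)
  vals <- unclass(m); vals[, 3] <- 7
  m2 <- abundance_matrix(vals, abundance_dates(m), colnames(m))
  nets <- build_networks(m2, n_iter = 199, seed = 1)
  expect_equal(attr(nets, "dropped_taxa"), 3L)
  expect_false(3L %in% nets$combined$nodes)
})

test_that("descriptor arithmetic matches published-style rounding", {
  stats <- network_summary_stats(67, 295, 107)
  expect_equal(stats$mean_degree, 8.81)
  expect_equal(stats$pct_negative, 36)
  expect_equal(network_summary_stats(0, 0)$mean_degree, 0)
})

test_that("descriptors and sign-mode invariants hold on constructed networks", {
  plan <- interaction_plan(data.frame(
    taxon_a = c(1L, 3L, 5L, 7L), taxon_b = c(2L, 4L, 6L, 8L),
    rho = c(0.9, 0.9, -0.9, -0.9)))
  comm <- small_community(seed = 9, n_weeks = 19, plan = plan)
  nets <- build_networks(comm$m, n_iter = 999, seed = 2,
                         period_label = "fixture")
  for (mode in names(nets)) {
    net <- nets[[mode]]
    d <- descriptors(net)
    expect_equal(sum(node_degrees(net)), 2 * d$n_edges)
    if (d$n_nodes > 0)
      expect_equal(d$mean_degree, round(2 * d$n_edges / d$n_nodes, 2))
    expect_true(all(net$edges$p < net$alpha))
    expect_equal(sort(unique(c(net$edges$taxon_a, net$edges$taxon_b))),
                 net$nodes)
  }
  expect_true(all(nets$negative$edges$rho < 0))
  expect_true(all(nets$positive$edges$rho > 0))
  # combined is the disjoint union of the signed networks
  key <- function(e) paste(e$taxon_a, e$taxon_b, e$rho)
  expect_setequal(key(nets$combined$edges),
                  c(key(nets$negative$edges), key(nets$positive$edges)))
  expect_gte(length(nets$combined$nodes),
             max(length(nets$negative$nodes), length(nets$positive$nodes)))
})

test_that("hubs rank by degree with id tie-breaking", {
  star <- data.frame(taxon_a = rep(1L, 4), taxon_b = 2:5,
                     rho = rep(0.9, 4), p = rep(0.001, 4),
                     sign = rep("+", 4))
  net <- planktonnet:::new_cor_network(star, "toy", "positive", 0.05, 999)
  h <- hubs(net, k = 3)
  expect_equal(h$taxon_id[1], 1L)
  expect_equal(h$degree[1], 4L)
  # two tied nodes: lower id first
  two <- data.frame(taxon_a = c(1L, 2L), taxon_b = c(3L, 4L),
                    rho = c(0.9, 0.9), p = c(0.01, 0.01), sign = c("+", "+"))
  net2 <- planktonnet:::new_cor_network(two, "toy", "positive", 0.05, 999)
  h2 <- hubs(net2, k = 4)
  expect_equal(h2$degree, rep(1L, 4))
  expect_equal(h2$taxon_id, 1:4)
})

test_that("a taxon sharing many strong planted edges becomes the top hub", {
  # star structure: hub correlations r with sum(r^2) < 1 keep the planted
  # matrix positive definite
  hub_plan <- interaction_plan(data.frame(
    taxon_a = rep(4L, 6), taxon_b = c(5L, 6L, 7L, 8L, 9L, 10L),
    rho = rep(0.4, 6)))
  comm <- small_community(seed = 21, n_weeks = 60, plan = hub_plan)
  nets <- suppressWarnings(build_networks(comm$m, n_iter = 999, seed = 3))
  expect_equal(hubs(nets$positive, 1)$taxon_id, 4L)
})

test_that("autocorrelation report flags trends and handles degenerate input", {
  set.seed(31)
  dates <- as.Date("2016-01-01") + 7 * 0:19
  vals <- cbind(1:20, rep(5, 20), abs(rnorm(20)) + 0.1)
  m <- abundance_matrix(vals, dates, 1:3)
  rep_ <- autocorrelation_report(m, max_lag = 3)
  lin <- rep_[rep_$taxon_id == 1 & rep_$lag == 1, ]
  n <- 20; x <- 1:20
  # direct formula for the lag-1 sample autocorrelation of a linear trend
  closed <- sum((x[-n] - mean(x)) * (x[-1] - mean(x))) / sum((x - mean(x))^2)
  expect_equal(lin$acf, closed)
  expect_true(lin$flagged)
  expect_true(all(is.na(rep_$acf[rep_$taxon_id == 2])))
  m_short <- abundance_matrix(vals[1:5, ], dates[1:5], 1:3)
  expect_error(autocorrelation_report(m_short), "at least 8")
})
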