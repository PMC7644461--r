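#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties). Equivalent to
#' `stats::cor(x, y, method = "spearman")`; exposed as the building block of
#' the permutation test.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return The rank correlation, in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  check_pair(x, y)
  cor(rank(x), rank(y))
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant series")
  invisible(TRUE)
}

#' Monte-Carlo permutation p-value for a Spearman correlation
#'
#' Estimates the two-sided significance of the rank correlation by
#' independently permuting one series `n_iter` times and applying the
#' add-one estimator `p = (1 + #{|rho_b| >= |rho_obs|}) / (n_iter + 1)`,
#' which is strictly positive and valid under exchangeability.
#'
#' @param x,y Numeric vectors (equal length >= 3, non-constant).
#' @param n_iter Number of Monte-Carlo permutations (default 9999).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A list with elements `rho` and `p`.
#' @examples
#' permutation_pvalue(1:10, (1:10)^2, n_iter = 999, seed = 1)
#' @export
permutation_pvalue <- function(x, y, n_iter = 9999L, seed = 1L) {
  check_pair(x, y)
  stopifnot(n_iter >= 1)
  .perm_spearman_pair(rank(x), rank(y), as.integer(n_iter),
                      0, 1, as.double(seed))
}

new_cor_network <- function(edges, period_label, sign_mode, alpha,
                            n_permutations) {
  edges <- edges[order(edges$taxon_a, edges$taxon_b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
  out <- list(period_label = period_label, sign_mode = sign_mode,
              nodes = as.integer(nodes), edges = edges, alpha = alpha,
              n_permutations = n_permutations)
  class(out) <- "cor_network"
  out
}

#' @export
print.cor_network <- function(x, ...) {
  cat(sprintf("<cor_network> %s / %s: %d nodes, %d edges (alpha=%g, %d permutations)\n",
              x$period_label, x$sign_mode, length(x$nodes), nrow(x$edges),
              x$alpha, x$n_permutations))
  invisible(x)
}

#' Build negative, positive and combined correlation networks for one period
#'
#' Tests every unordered pair of taxa in the (period-sliced) abundance
#' matrix with the Monte-Carlo Spearman permutation test and keeps edges
#' with `p < alpha`. Columns that are constant within the period are dropped
#' first (recorded in the `dropped_taxa` attribute), since taxa absent in a
#' season carry no rank information. Three networks are returned: negative
#' edges only, positive edges only, and their disjoint union. Node sets
#' contain only non-isolated taxa (the endpoints of retained edges).
#'
#' Per-pair permutation streams are seeded by a stable hash of the master
#' seed and the ordered taxon-id pair, so each edge's p-value does not
#' depend on which other taxa are present or on evaluation order.
#'
#' @param m An `abundance_matrix` (>= 4 samples).
#' @param alpha Significance threshold on the permutation p-value.
#' @param n_iter Permutations per pair (default 9999).
#' @param seed Master integer seed.
#' @param period_label Label stored on the resulting networks.
#' @return Named list of three `cor_network` objects: `negative`,
#'   `positive`, `combined`.
#' @export
build_networks <- function(m, alpha = 0.05, n_iter = 9999L, seed = 1L,
                           period_label = "") {
  stopifnot(inherits(m, "abundance_matrix"))
  if (nrow(m) < 4L) stop("need at least 4 samples")
  vals <- unclass(m)
  attr(vals, "dates") <- NULL
  keep <- apply(vals, 2L, function(col) sd(col) > 0)
  dropped <- as.integer(colnames(vals)[!keep])
  vals <- vals[, keep, drop = FALSE]
  if (ncol(vals) < 2L) stop("fewer than 2 non-constant taxa in period")
  ranks <- apply(vals, 2L, rank)
  ids <- as.integer(colnames(vals))
  res <- .perm_spearman_all(ranks, ids, as.integer(n_iter), as.double(seed))
  all_edges <- data.frame(taxon_a = res$taxon_a, taxon_b = res$taxon_b,
                          rho = res$rho, p = res$p)
  sig <- all_edges[all_edges$p < alpha & all_edges$rho != 0, , drop = FALSE]
  sig$sign <- ifelse(sig$rho > 0, "+", "-")
  nets <- list(
    negative = new_cor_network(sig[sig$sign == "-", , drop = FALSE],
                               period_label, "negative", alpha, n_iter),
    positive = new_cor_network(sig[sig$sign == "+", , drop = FALSE],
                               period_label, "positive", alpha, n_iter),
    combined = new_cor_network(sig, period_label, "combined", alpha, n_iter))
  attr(nets, "dropped_taxa") <- dropped
  nets
}

#' Degree of every node in a network
#'
#' @param net A `cor_network`.
#' @return Named integer vector of degrees, one per (non-isolated) node.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "cor_network"))
  deg <- table(factor(c(net$edges$taxon_a, net$edges$taxon_b),
                      levels = net$nodes))
  stats::setNames(as.integer(deg), names(deg))
}

#' Descriptor-table statistics from node and edge counts
#'
#' The reporting arithmetic behind the descriptor table: mean degree
#' `2E/N` rounded to two decimals, and the percentage of negative edges
#' `100 E_neg / E` rounded to the nearest integer. Exposed separately so
#' published descriptor tables can be checked for internal consistency.
#'
#' @param n_nodes Number of non-isolated nodes (N).
#' @param n_edges Number of edges (E).
#' @param n_negative Number of negative edges, or `NULL` when not applicable.
#' @return List with `mean_degree` and `pct_negative` (NA when
#'   `n_negative` is `NULL`).
#' @examples
#' network_summary_stats(67, 295, 107)  # mean degree 8.81, 36% negative
#' @export
network_summary_stats <- function(n_nodes, n_edges, n_negative = NULL) {
  mean_degree <- if (n_nodes > 0) round(2 * n_edges / n_nodes, 2) else 0
  pct_negative <- if (!is.null(n_negative) && n_edges > 0)
    round(100 * n_negative / n_edges) else NA_real_
  list(mean_degree = mean_degree, pct_negative = pct_negative)
}

#' Structural descriptors of a correlation network
#'
#' Number of nodes (N), edges (E), percentage of negative correlations (for
#' combined-mode networks), mean degree `2E/N`, the full degree map and the
#' top-degree hub taxa.
#'
#' @param net A `cor_network`.
#' @param k_hubs Number of hubs to report.
#' @return A `network_descriptors` list.
#' @export
descriptors <- function(net, k_hubs = 3L) {
  stopifnot(inherits(net, "cor_network"))
  n <- length(net$nodes)
  e <- nrow(net$edges)
  e_neg <- sum(net$edges$sign == "-")
  stats <- network_summary_stats(n, e, if (net$sign_mode == "combined") e_neg)
  out <- list(period_label = net$period_label, sign_mode = net$sign_mode,
              n_nodes = n, n_edges = e,
              pct_negative = stats$pct_negative,
              mean_degree = stats$mean_degree,
              degree_by_node = node_degrees(net),
              hubs = if (e > 0) hubs(net, k_hubs) else
                data.frame(taxon_id = integer(), degree = integer()))
  class(out) <- "network_descriptors"
  out
}

#' @export
print.network_descriptors <- function(x, ...) {
  cat(sprintf("<network_descriptors> %s / %s: N=%d E=%d mean degree=%.2f%s\n",
              x$period_label, x$sign_mode, x$n_nodes, x$n_edges,
              x$mean_degree,
              if (!is.na(x$pct_negative))
                sprintf(", %d%% negative", x$pct_negative) else ""))
  invisible(x)
}

#' Hub taxa of a network
#'
#' Taxa ranked by degree (number of significant correlations), descending;
#' ties are broken by ascending taxon id.
#'
#' @param net A `cor_network`.
#' @param k Number of hubs to return.
#' @return Data frame with columns `taxon_id`, `degree`.
#' @export
hubs <- function(net, k = 3L) {
  deg <- node_degrees(net)
  if (!length(deg))
    return(data.frame(taxon_id = integer(), degree = integer()))
  ids <- as.integer(names(deg))
  ord <- order(-as.integer(deg), ids)
  head(data.frame(taxon_id = ids[ord], degree = as.integer(deg)[ord],
                  row.names = NULL), k)
}

#' Autocorrelation diagnostics for the abundance series
#'
#' Sample autocorrelations at lags 1..`max_lag` for every taxon, flagging
#' values outside the approximate white-noise band `+/- 1.96/sqrt(n)`.
#' Purely diagnostic: no series is removed or altered.
#'
#' @param m An `abundance_matrix` with >= 8 samples.
#' @param max_lag Largest lag to report.
#' @return Data frame with columns `taxon_id`, `lag`, `acf`, `flagged`.
#'   Constant columns are reported with `NA` autocorrelations.
#' @export
autocorrelation_report <- function(m, max_lag = 5L) {
  stopifnot(inherits(m, "abundance_matrix"))
  n <- nrow(m)
  if (n < 8L) stop("need at least 8 samples for ACF diagnostics")
  threshold <- 1.96 / sqrt(n)
  rows <- lapply(colnames(m), function(id) {
    x <- unclass(m)[, id]
    if (sd(x) == 0) {
      data.frame(taxon_id = as.integer(id), lag = seq_len(max_lag),
                 acf = NA_real_, flagged = NA)
    } else {
      a <- acf(x, lag.max = max_lag, plot = FALSE)$acf[-1L]
      data.frame(taxon_id = as.integer(id), lag = seq_len(max_lag),
                 acf = a, flagged = abs(a) > threshold)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

#' Induced subnetwork on a set of taxa
#'
#' Keeps only edges with both endpoints in `ids`; used for dominant-species
#' networks.
#'
#' @param net A `cor_network`.
#' @param ids Integer taxon ids to retain.
#' @return A `cor_network`.
#' @export
subnetwork <- function(net, ids) {
  stopifnot(inherits(net, "cor_network"))
  keep <- net$edges$taxon_a %in% ids & net$edges$taxon_b %in% ids
  new_cor_network(net$edges[keep, , drop = FALSE], net$period_label,
                  net$sign_mode, net$alpha, net$n_permutations)
}
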