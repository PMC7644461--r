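# Enumerate unordered label pairs (including self pairs) for a label set.
label_pair_table <- function(levels) {
  grid <- which(upper.tri(diag(length(levels)), diag = TRUE), arr.ind = TRUE)
  data.frame(label_a = levels[grid[, "row"]], label_b = levels[grid[, "col"]],
             stringsAsFactors = FALSE)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Count network edges between label pairs
#'
#' Tallies how many edges connect each unordered pair of labels (functional
#' groups or ESD classes), including within-label self pairs. Every edge
#' contributes to exactly one pair, so the counts sum to E.
#'
#' @param net A `cor_network`.
#' @param labels Named character vector mapping taxon id (as name) to label;
#'   every network node must be labelled.
#' @return A `pair_count_table` data frame with columns `label_a`,
#'   `label_b`, `count`, zero-filled over all pairs of labels in the map (so
#'   tables from different sign modes of one period are comparable).
#' @export
pair_counts <- function(net, labels) {
  stopifnot(inherits(net, "cor_network"))
  node_chr <- as.character(net$nodes)
  missing <- node_chr[!node_chr %in% names(labels)]
  if (length(missing))
    stop("unlabelled node(s): ", paste(missing, collapse = ", "))
  labs <- labels[node_chr]
  levels <- sort(unique(unname(labels)))
  tab <- label_pair_table(levels)
  keys <- pair_key(tab$label_a, tab$label_b)
  counts <- integer(nrow(tab))
  if (nrow(net$edges)) {
    ek <- pair_key(unname(labs[as.character(net$edges$taxon_a)]),
                   unname(labs[as.character(net$edges$taxon_b)]))
    cnt <- table(factor(ek, levels = keys))
    counts <- as.integer(cnt)
  }
  out <- data.frame(tab, count = counts, stringsAsFactors = FALSE)
  class(out) <- c("pair_count_table", "data.frame")
  out
}

#' Sample an Erdős–Rényi G(n, m) graph
#'
#' Draws uniformly among all simple undirected graphs on `n_nodes` vertices
#' with exactly `n_edges` edges: `n_edges` distinct vertex pairs are sampled
#' without replacement from all C(n, 2) pairs.
#'
#' @param n_nodes Number of vertices.
#' @param n_edges Number of edges, between 0 and C(n_nodes, 2).
#' @param seed Integer seed.
#' @return Integer matrix with columns `a`, `b` (vertex indices, a < b).
#' @export
sample_er <- function(n_nodes, n_edges, seed = 1L) {
  n_pairs <- choose(n_nodes, 2)
  if (n_edges < 0 || n_edges > n_pairs)
    stop("n_edges must be between 0 and C(n_nodes, 2)")
  pairs <- all_node_pairs(n_nodes)
  ids <- with_seed(seed, sample.int(n_pairs, n_edges))
  out <- pairs[ids, , drop = FALSE]
  colnames(out) <- c("a", "b")
  out
}

all_node_pairs <- function(n) {
  if (n < 2L) return(matrix(integer(), 0L, 2L))
  t(combn(n, 2L))
}

#' Classify label-pair edge counts as rare, dominant or neutral
#'
#' The null-model procedure: `n_random` Erdős–Rényi G(n, m) graphs are drawn
#' on the empirical network's node set (same N and E, labels riding on node
#' identity), the label-pair edge counts are tallied in each, and the
#' empirical count of every pair is compared to the 2.5th and 97.5th
#' percentiles of its null distribution (order statistics at ranks
#' `ceiling(0.025 R)` and `ceiling(0.975 R)`). Counts strictly below the
#' lower threshold are `rare`, strictly above the upper one `dominant`,
#' otherwise `neutral` — boundary ties are conservatively neutral.
#'
#' @param net A `cor_network`.
#' @param labels Named character vector mapping taxon id to label.
#' @param n_random Number of random networks (default 999).
#' @param seed Integer seed (one stream drives all replicates).
#' @param nodes Node set for the random graphs. The default is the
#'   empirical network's non-isolated nodes (matching the N of the
#'   descriptor table); pass the full taxon id set to retain isolated taxa
#'   instead.
#' @return A `dominance_classification` data frame with columns `label_a`,
#'   `label_b`, `empirical`, `null_q025`, `null_q975`, `verdict`, plus
#'   attributes `n_random` and `sign_mode`.
#' @export
classify_pairs <- function(net, labels, n_random = 999L, seed = 1L,
                           nodes = net$nodes) {
  stopifnot(inherits(net, "cor_network"), n_random >= 1L)
  nodes <- sort(as.integer(nodes))
  if (!all(net$nodes %in% nodes))
    stop("'nodes' must contain every non-isolated network node")
  emp <- pair_counts(net, labels)
  n <- length(nodes)
  e <- nrow(net$edges)
  n_pair_labels <- nrow(emp)
  if (e == 0L || n < 2L) {
    out <- data.frame(emp[, c("label_a", "label_b")],
                      empirical = emp$count,
                      null_q025 = 0L, null_q975 = 0L, verdict = "neutral",
                      stringsAsFactors = FALSE)
    return(as_dominance(out, n_random, net$sign_mode))
  }
  labs <- labels[as.character(nodes)]
  if (anyNA(labs))
    stop("unlabelled node(s): ",
         paste(nodes[is.na(labs)], collapse = ", "))
  keys <- pair_key(emp$label_a, emp$label_b)
  node_pairs <- all_node_pairs(n)
  # label-pair index of every possible node pair, reused across replicates
  pk <- pair_key(unname(labs[node_pairs[, 1L]]), unname(labs[node_pairs[, 2L]]))
  pair_idx <- match(pk, keys)
  n_pairs <- nrow(node_pairs)
  lo_rank <- ceiling(0.025 * n_random)
  hi_rank <- ceiling(0.975 * n_random)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_random), function(r) {
      tabulate(pair_idx[sample.int(n_pairs, e)], nbins = n_pair_labels)
    }, integer(n_pair_labels))
  })
  null_counts <- matrix(null_counts, nrow = n_pair_labels)
  q025 <- apply(null_counts, 1L, function(z) sort(z)[lo_rank])
  q975 <- apply(null_counts, 1L, function(z) sort(z)[hi_rank])
  verdict <- ifelse(emp$count < q025, "rare",
                    ifelse(emp$count > q975, "dominant", "neutral"))
  out <- data.frame(emp[, c("label_a", "label_b")], empirical = emp$count,
                    null_q025 = q025, null_q975 = q975, verdict = verdict,
                    stringsAsFactors = FALSE)
  as_dominance(out, n_random, net$sign_mode)
}

as_dominance <- function(df, n_random, sign_mode) {
  class(df) <- c("dominance_classification", "data.frame")
  attr(df, "n_random") <- n_random
  attr(df, "sign_mode") <- sign_mode
  df
}

#' Summary graph of rare and dominant label pairs across sign modes
#'
#' Combines the classifications of the negative and positive (and possibly
#' combined) networks of one period into a single label-level summary: one
#' node per label, one record per non-neutral (pair, sign mode) with a
#' direction — `more` (dominant: more correlations than random, drawn solid)
#' or `fewer` (rare, drawn dotted). Neutral pairs are kept as background.
#'
#' @param per_mode Named list of `dominance_classification` objects (names
#'   are sign modes), all from the same period and grouping.
#' @return A `summary_network` list with `edges` (non-neutral records),
#'   `background` (neutral pairs) and `graph` (an igraph object whose edges
#'   carry `sign_mode`, `verdict` and `direction` attributes).
#' @export
summary_network <- function(per_mode) {
  stopifnot(is.list(per_mode), length(per_mode) >= 1L,
            !is.null(names(per_mode)))
  ref <- per_mode[[1L]]
  ref_keys <- sort(pair_key(ref$label_a, ref$label_b))
  for (cl in per_mode) {
    stopifnot(inherits(cl, "dominance_classification"))
    if (!identical(sort(pair_key(cl$label_a, cl$label_b)), ref_keys))
      stop("classifications use different label groupings")
  }
  recs <- do.call(rbind, lapply(names(per_mode), function(mode) {
    cl <- per_mode[[mode]]
    data.frame(sign_mode = mode, cl, stringsAsFactors = FALSE)
  }))
  recs$direction <- ifelse(recs$verdict == "dominant", "more",
                           ifelse(recs$verdict == "rare", "fewer", NA))
  highlighted <- recs[recs$verdict != "neutral", , drop = FALSE]
  background <- recs[recs$verdict == "neutral", , drop = FALSE]
  rownames(highlighted) <- rownames(background) <- NULL
  labels <- sort(unique(c(ref$label_a, ref$label_b)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(labels), name = labels)
  if (nrow(highlighted)) {
    g <- igraph::add_edges(
      g, rbind(match(highlighted$label_a, labels),
               match(highlighted$label_b, labels)),
      sign_mode = highlighted$sign_mode, verdict = highlighted$verdict,
      direction = highlighted$direction,
      style = ifelse(highlighted$direction == "more", "solid", "dotted"))
  }
  out <- list(edges = highlighted, background = background, graph = g)
  class(out) <- "summary_network"
  out
}

#' Map taxa to labels for null-model grouping
#'
#' @param taxa A `taxon_table`.
#' @param grouping `"functional_group"` (the six guilds) or `"esd_class"`
#'   (guild crossed with its PELT size class for the multi-taxon guilds;
#'   requires `size_class` to be filled, see [size_classes()]).
#' @return Named character vector, names are taxon ids.
#' @export
taxon_labels <- function(taxa, grouping = c("functional_group", "esd_class")) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(taxa, "taxon_table"))
  labs <- as.character(taxa$group)
  if (grouping == "esd_class") {
    multi <- !is.na(taxa$size_class)
    labs[multi] <- paste(taxa$group[multi], taxa$size_class[multi])
  }
  stats::setNames(labs, as.character(taxa$taxon_id))
}
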