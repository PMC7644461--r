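#' Read and write the plain-text input formats
#'
#' The abundance CSV has an ISO-8601 `date` first column and one numeric
#' column per taxon id; the taxon CSV carries `taxon_id`, `name`, `group`,
#' `esd_um`, `size_class`; the fluorescence CSV carries `date`, `value`.
#' Readers validate strictly and report the offending row/column.
#'
#' @param path File path.
#' @param taxa Optional `taxon_table`; when supplied, abundance columns must
#'   all be known taxon ids.
#' @return `read_abundance_csv`: an `abundance_matrix`;
#'   `read_taxa_csv`: a `taxon_table`;
#'   `read_fluorescence_csv`: a `fluorescence_series`.
#' @name io
NULL

#' @rdname io
#' @export
read_abundance_csv <- function(path, taxa = NULL) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("abundance CSV needs a date column and taxa")
  dates <- as.Date(raw[[1L]])
  if (anyNA(dates)) stop("unparseable date in row ",
                         which(is.na(dates))[1L])
  if (anyDuplicated(dates))
    stop("duplicated date row: ", format(dates[duplicated(dates)][1L]))
  ids_chr <- names(raw)[-1L]
  ids <- suppressWarnings(as.integer(ids_chr))
  if (anyNA(ids)) stop("non-integer taxon id in header: ",
                       ids_chr[is.na(ids)][1L])
  if (!is.null(taxa)) {
    unknown <- setdiff(ids, taxa$taxon_id)
    if (length(unknown))
      stop("unknown taxon id(s) in header: ", paste(unknown, collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow(raw), length(ids))
  for (j in seq_along(ids)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric or missing cell at row ", bad[1L], ", column '",
           ids_chr[j], "'")
    vals[, j] <- v
  }
  ord <- order(dates)
  abundance_matrix(vals[ord, , drop = FALSE], dates = dates[ord],
                   taxon_ids = ids)
}

#' @rdname io
#' @param m An `abundance_matrix`.
#' @export
write_abundance_csv <- function(m, path) {
  stopifnot(inherits(m, "abundance_matrix"))
  df <- data.frame(date = format(abundance_dates(m), "%Y-%m-%d"),
                   unclass(m), check.names = FALSE)
  names(df) <- c("date", colnames(m))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_taxa_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", "name", "group", "esd_um")
  if (!all(need %in% names(df)))
    stop("taxon CSV must have columns: ", paste(need, collapse = ", "))
  if (!"size_class" %in% names(df)) df$size_class <- NA_character_
  df$size_class[df$size_class %in% ""] <- NA_character_
  df$taxon_id <- as.integer(df$taxon_id)
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon_id")
  if (any(df$esd_um <= 0)) stop("esd_um must be > 0")
  if (any(!df$group %in% microbial_groups()))
    stop("unknown group: ",
         paste(setdiff(df$group, microbial_groups()), collapse = ", "))
  df <- df[order(df$taxon_id), c(need, "size_class")]
  rownames(df) <- NULL
  class(df) <- c("taxon_table", "data.frame")
  df
}

#' @rdname io
#' @param taxa_table A `taxon_table` to write.
#' @export
write_taxa_csv <- function(taxa_table, path) {
  df <- as.data.frame(taxa_table)
  df$size_class[is.na(df$size_class)] <- ""
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_fluorescence_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "value") %in% names(df)))
    stop("fluorescence CSV must have columns date, value")
  df$date <- as.Date(df$date)
  if (anyNA(df$date) || anyNA(df$value)) stop("missing date or value")
  df <- df[order(df$date), c("date", "value")]
  rownames(df) <- NULL
  class(df) <- c("fluorescence_series", "data.frame")
  df
}

#' @rdname io
#' @param f A `fluorescence_series` to write.
#' @export
write_fluorescence_csv <- function(f, path) {
  df <- data.frame(date = format(f$date, "%Y-%m-%d"), value = f$value)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a correlation network to an igraph object
#'
#' Nodes carry `label` (taxon name), `group`, `esd` and `size_class`
#' attributes from the taxon table; edges carry `rho`, `p` and `sign`.
#'
#' @param net A `cor_network`.
#' @param taxa A `taxon_table` covering every network node.
#' @return An undirected igraph graph.
#' @export
as_igraph <- function(net, taxa) {
  stopifnot(inherits(net, "cor_network"), inherits(taxa, "taxon_table"))
  missing <- setdiff(net$nodes, taxa$taxon_id)
  if (length(missing))
    stop("node(s) missing from taxon table: ", paste(missing, collapse = ", "))
  tt <- taxa[match(net$nodes, taxa$taxon_id), , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(net$nodes))
  g <- igraph::set_vertex_attr(g, "label", value = tt$name)
  g <- igraph::set_vertex_attr(g, "group", value = as.character(tt$group))
  g <- igraph::set_vertex_attr(g, "esd", value = tt$esd_um)
  g <- igraph::set_vertex_attr(g, "size_class",
                               value = ifelse(is.na(tt$size_class), "",
                                              tt$size_class))
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(match(net$edges$taxon_a, net$nodes),
                                    match(net$edges$taxon_b, net$nodes)),
                           rho = net$edges$rho, p = net$edges$p,
                           sign = net$edges$sign)
  }
  g
}

#' Write a correlation network to disk
#'
#' Either a tab-separated edge list (`taxon_a`, `taxon_b`, `rho`, `p`,
#' `sign`, sorted by taxon pair) or GraphML with node attributes from the
#' taxon table. Output is byte-stable for fixed inputs.
#'
#' @param net A `cor_network`.
#' @param taxa A `taxon_table` covering every node.
#' @param path Output file path.
#' @param format `"edge_list_tsv"` or `"graphml"`.
#' @return The path, invisibly.
#' @export
write_network <- function(net, taxa, path,
                          format = c("edge_list_tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "cor_network"))
  missing <- setdiff(net$nodes, taxa$taxon_id)
  if (length(missing))
    stop("node(s) missing from taxon table: ", paste(missing, collapse = ", "))
  if (format == "edge_list_tsv") {
    edges <- net$edges[order(net$edges$taxon_a, net$edges$taxon_b), ,
                       drop = FALSE]
    write.table(edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    igraph::write_graph(as_igraph(net, taxa), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @param cl A `dominance_classification`.
#' @export
write_classification <- function(cl, path) {
  stopifnot(inherits(cl, "dominance_classification"))
  df <- as.data.frame(cl)
  df$sign_mode <- attr(cl, "sign_mode")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
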