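#' PELT changepoint detection (Gaussian change in mean)
#'
#' Exact penalised segmentation of an ordered numeric series by the Pruned
#' Exact Linear Time dynamic program. The segment cost is the Gaussian
#' change-in-mean cost — residual sum of squares around the segment mean,
#' scaled by a pooled variance estimate (half the variance of first
#' differences, robust to mean shifts) — and each changepoint pays
#' `penalty`. Pruning never discards the optimum for this cost (it is
#' subadditive), so the result equals exhaustive optimal partitioning.
#'
#' @param values Numeric vector, sorted ascending by the caller when used
#'   for size classes.
#' @param penalty Penalty per changepoint; default `2 * log(n)` (BIC-like on
#'   the variance-scaled cost).
#' @param min_segment Minimum points per segment.
#' @return A `pelt_result` list: `sorted_values`, `changepoints` (indices of
#'   the last point of each non-final segment), `class_boundaries`
#'   (midpoints between the values flanking each changepoint), `penalty`,
#'   `cost_name`, `n_segments`.
#' @examples
#' pelt_changepoints(c(0, 0, 0, 0, 0, 5, 5, 5, 5, 5))
#' @export
pelt_changepoints <- function(values, penalty = NULL, min_segment = 2L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L * min_segment)
    stop("series too short: need at least 2 * min_segment points")
  if (is.null(penalty)) penalty <- 2 * log(n)
  stopifnot(penalty >= 0)
  sig2 <- var(diff(values)) / 2
  if (!is.finite(sig2) || sig2 <= 0) sig2 <- var(values)
  if (!is.finite(sig2) || sig2 <= 0) {
    # constant series: a single segment, nothing to detect
    return(new_pelt_result(values, integer(), penalty))
  }
  s1 <- c(0, cumsum(values))
  s2 <- c(0, cumsum(values^2))
  segcost <- function(i, j) {
    # RSS of values[i..j] around the segment mean, variance-scaled
    len <- j - i + 1
    (s2[j + 1] - s2[i] - (s1[j + 1] - s1[i])^2 / len) / sig2
  }
  f <- c(-penalty, rep(Inf, n))
  prev <- integer(n)
  cand <- 0L
  # With a minimum segment length, a candidate dominated at time t can only
  # be discarded once t itself is old enough to replace it as a last
  # changepoint, so removals are scheduled min_segment steps ahead.
  pending <- vector("list", n + min_segment)
  for (t in seq_len(n)) {
    if (!is.null(pending[[t]])) cand <- setdiff(cand, pending[[t]])
    usable <- cand[t - cand >= min_segment]
    if (!length(usable)) {
      f[t + 1L] <- Inf
      prev[t] <- 0L
    } else {
      base <- f[usable + 1L] +
        vapply(usable, function(tau) segcost(tau + 1L, t), numeric(1))
      best <- which.min(base)
      f[t + 1L] <- base[best] + penalty
      prev[t] <- usable[best]
      dominated <- usable[base > f[t + 1L]]
      if (length(dominated) && t + min_segment <= length(pending))
        pending[[t + min_segment]] <- c(pending[[t + min_segment]], dominated)
    }
    cand <- c(cand, t)
  }
  cps <- integer()
  t <- n
  while (t > 0L) {
    tau <- prev[t]
    if (tau > 0L) cps <- c(tau, cps)
    t <- tau
  }
  new_pelt_result(values, cps, penalty)
}

new_pelt_result <- function(values, cps, penalty) {
  boundaries <- if (length(cps)) (values[cps] + values[cps + 1L]) / 2
                else numeric()
  out <- list(sorted_values = values, changepoints = as.integer(cps),
              class_boundaries = boundaries, penalty = penalty,
              cost_name = "gaussian_mean_shift",
              n_segments = length(cps) + 1L)
  class(out) <- "pelt_result"
  out
}

#' @export
print.pelt_result <- function(x, ...) {
  cat(sprintf("<pelt_result> %d segments, penalty %.3f", x$n_segments,
              x$penalty))
  if (length(x$class_boundaries))
    cat(", boundaries at", paste(signif(x$class_boundaries, 4),
                                 collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Derive ESD size classes for a functional group
#'
#' Orders the group's taxa by mean ESD, runs [pelt_changepoints()] on the
#' ordered ESDs, and labels the resulting segments `"<b1"`, `"b1-b2"`, ...,
#' `">bk"`, where each boundary is the midpoint between the ESDs flanking a
#' changepoint, rounded to `digits` decimals for reporting. Class
#' membership itself follows the exact segmentation, not the rounded
#' boundaries.
#'
#' @param taxa A `taxon_table`.
#' @param group One functional group name.
#' @param penalty Optional PELT penalty (default `2 * log(n)`).
#' @param digits Decimals for the reported boundaries.
#' @return The `taxon_table` with `size_class` filled for that group; the
#'   `pelt_result` is attached as attribute `pelt`.
#' @export
size_classes <- function(taxa, group, penalty = NULL, digits = 0L) {
  stopifnot(inherits(taxa, "taxon_table"))
  rows <- which(taxa$group == group)
  if (!length(rows)) stop("group '", group, "' absent from taxon table")
  if (length(rows) < 4L)
    stop("need at least 4 taxa in group '", group, "' for size classes")
  ord <- rows[order(taxa$esd_um[rows])]
  vals <- taxa$esd_um[ord]
  res <- pelt_changepoints(vals, penalty = penalty)
  cps <- res$changepoints
  if (!length(cps)) {
    labels_per_seg <- "all"
    seg_of <- rep(1L, length(vals))
  } else {
    b <- round(res$class_boundaries, digits)
    fmt <- function(x) formatC(x, format = "fg")
    k <- length(b)
    labels_per_seg <- c(paste0("<", fmt(b[1])),
                        if (k > 1)
                          paste0(fmt(b[-k]), "-", fmt(b[-1])),
                        paste0(">", fmt(b[k])))
    seg_of <- findInterval(seq_along(vals) - 0.5, cps) + 1L
  }
  taxa$size_class[ord] <- labels_per_seg[seg_of]
  attr(taxa, "pelt") <- res
  taxa
}

#' Spherical biovolume from equivalent spherical diameter
#'
#' @param esd_um ESD in micrometres, > 0.
#' @return Biovolume `(pi/6) * ESD^3` in cubic micrometres.
#' @examples
#' biovolume(1)   # pi/6
#' biovolume(10)  # ~523.6
#' @export
biovolume <- function(esd_um) {
  if (any(esd_um <= 0)) stop("ESD must be > 0")
  pi / 6 * esd_um^3
}

#' Per-taxon biovolume table for a period
#'
#' Mean abundance over the (period-sliced) matrix, spherical biovolume from
#' ESD, mean biovolume per mL (their product) and the within-group share of
#' each taxon's biovolume.
#'
#' @param m An `abundance_matrix`.
#' @param taxa A `taxon_table` covering every column of `m`.
#' @return A `biovolume_table` data frame: `taxon_id`, `group`, `esd_um`,
#'   `mean_abundance`, `biovolume_um3`, `mean_biovolume_per_ml`, `share`.
#' @export
biovolume_table <- function(m, taxa) {
  stopifnot(inherits(m, "abundance_matrix"), inherits(taxa, "taxon_table"))
  ids <- as.integer(colnames(m))
  if (any(!ids %in% taxa$taxon_id))
    stop("abundance matrix contains taxa missing from the taxon table")
  tt <- taxa[match(ids, taxa$taxon_id), , drop = FALSE]
  mean_ab <- colMeans(unclass(m))
  bv <- biovolume(tt$esd_um)
  per_ml <- mean_ab * bv
  share <- stats::ave(per_ml, tt$group, FUN = function(z) {
    tot <- sum(z)
    if (tot > 0) z / tot else rep(0, length(z))
  })
  out <- data.frame(taxon_id = ids, group = tt$group, esd_um = tt$esd_um,
                    mean_abundance = unname(mean_ab), biovolume_um3 = bv,
                    mean_biovolume_per_ml = unname(per_ml),
                    share = unname(share), stringsAsFactors = FALSE)
  class(out) <- c("biovolume_table", "data.frame")
  out
}

#' Select biomass-dominant taxa per functional group
#'
#' Within each multi-taxon guild (phytoplankton, naked ciliates,
#' tintinnids), taxa are sorted by mean biovolume per mL (descending) and
#' the minimal prefix whose cumulative biovolume share reaches
#' `share_threshold` is selected; taxa tied in biovolume with the last
#' selected one are included too. Single-taxon and pooled guilds (virus,
#' bacteria, HF) pass through whole. A guild whose total biovolume is zero
#' contributes no taxa (with a warning).
#'
#' @param m A period-sliced `abundance_matrix`.
#' @param taxa A `taxon_table`.
#' @param share_threshold Cumulative biovolume fraction to cover
#'   (default 0.90).
#' @return The [biovolume_table()] with an added logical `dominant` column.
#' @export
dominant_taxa <- function(m, taxa, share_threshold = 0.90) {
  stopifnot(share_threshold > 0, share_threshold <= 1)
  bt <- biovolume_table(m, taxa)
  multi <- c("phytoplankton", "naked_ciliate", "tintinnid")
  bt$dominant <- FALSE
  for (g in unique(bt$group)) {
    idx <- which(bt$group == g)
    if (!(g %in% multi)) {
      bt$dominant[idx] <- TRUE
      next
    }
    vol <- bt$mean_biovolume_per_ml[idx]
    if (sum(vol) <= 0) {
      warning("group '", g, "' has zero total biovolume; no dominant taxa")
      next
    }
    ord <- idx[order(-vol, bt$taxon_id[idx])]
    cum <- cumsum(bt$share[ord])
    cut <- which(cum >= share_threshold - 1e-12)[1L]
    sel <- ord[seq_len(cut)]
    tied <- ord[bt$mean_biovolume_per_ml[ord] ==
                  bt$mean_biovolume_per_ml[ord[cut]]]
    bt$dominant[union(sel, tied)] <- TRUE
  }
  attr(bt, "share_threshold") <- share_threshold
  bt
}
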