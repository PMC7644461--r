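#' Daily net growth rates of a fluorescence series
#'
#' The net growth rate on day *t* is the log-ratio of consecutive daily
#' means, `r_t = ln(F_t / F_{t-1})`, the standard phytoplankton net growth
#' estimator: the sum of rates over a window equals the net log-increase
#' over that window. Rates are dated on the day they end, so the series is
#' one element shorter than the fluorescence series.
#'
#' @param f A `fluorescence_series` (columns `date`, `value`, all > 0).
#' @return A `growth_rate_series` data frame with columns `date`, `rate`,
#'   carrying the campaign's first day as attribute `first_date`.
#' @examples
#' f <- generate_fluorescence(10, noise_sd = 0, seed = 1)
#' growth_rates(f)
#' @export
growth_rates <- function(f) {
  stopifnot(is.data.frame(f), all(c("date", "value") %in% names(f)))
  if (nrow(f) < 2L) stop("need at least 2 days of fluorescence")
  bad <- which(f$value <= 0)
  if (length(bad))
    stop("nonpositive fluorescence on ", format(f$date[bad[1]], "%Y-%m-%d"))
  out <- data.frame(date = f$date[-1L],
                    rate = diff(log(f$value)))
  class(out) <- c("growth_rate_series", "data.frame")
  attr(out, "first_date") <- f$date[1L]
  out
}

new_period_set <- function(label, start, end, provenance = character()) {
  out <- data.frame(label = label, start = as.Date(start), end = as.Date(end),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("period_set", "data.frame")
  attr(out, "provenance") <- provenance
  out
}

#' Segment a campaign into bloom and non-bloom periods
#'
#' Applies the two bloom rules to the daily growth-rate series: a bloom
#' starts on the first day of a run of at least `min_pos_start` consecutive
#' positive growth rates such that some window of at least `min_window`
#' consecutive days starting there has a positive rate sum; it ends on the
#' day before the first subsequent run of `end_neg_run` consecutive negative
#' rates (or at the campaign end, flagged as truncated in the provenance).
#' Zero rates count as neither positive nor negative. All remaining days are
#' labelled non-bloom, so the periods partition the campaign span.
#'
#' @param g A `growth_rate_series` from [growth_rates()].
#' @param min_pos_start Minimum run of positive rates opening a bloom.
#' @param min_window Minimum window length whose rate sum must be positive.
#' @param end_neg_run Length of the negative run that closes a bloom.
#' @return A `period_set` data frame (`label`, `start`, `end`) covering every
#'   campaign day exactly once.
#' @export
detect_blooms <- function(g, min_pos_start = 2L, min_window = 5L,
                          end_neg_run = 5L) {
  stopifnot(inherits(g, "growth_rate_series"))
  r <- g$rate
  m <- length(r)
  if (m < min_window) stop("growth-rate series shorter than min_window")
  pos <- r > 0
  neg <- r < 0
  prov <- character()
  blooms <- list()
  t <- 1L
  while (t <= m - min_pos_start + 1L) {
    if (all(pos[t:(t + min_pos_start - 1L)])) {
      cs <- cumsum(r[t:m])
      if (length(cs) >= min_window && any(cs[min_window:length(cs)] > 0)) {
        end_idx <- m
        truncated <- TRUE
        jj <- t + min_pos_start
        while (jj <= m - end_neg_run + 1L) {
          if (all(neg[jj:(jj + end_neg_run - 1L)])) {
            end_idx <- jj - 1L
            truncated <- FALSE
            break
          }
          jj <- jj + 1L
        }
        blooms[[length(blooms) + 1L]] <- c(start = t, end = end_idx)
        prov <- c(prov, sprintf(
          "bloom %s..%s%s", format(g$date[t]), format(g$date[end_idx]),
          if (truncated) " (truncated by campaign end)" else ""))
        t <- if (truncated) m + 1L else jj + end_neg_run
        next
      }
    }
    t <- t + 1L
  }
  first_day <- attr(g, "first_date") %||% (g$date[1L] - 1L)
  last_day <- g$date[m]
  if (!length(blooms)) {
    return(new_period_set("non_bloom", first_day, last_day,
                          provenance = c(prov, "no bloom detected")))
  }
  labels <- character(); starts <- as.Date(character()); ends <- as.Date(character())
  cursor <- first_day
  for (b in blooms) {
    bs <- g$date[b["start"]]; be <- g$date[b["end"]]
    if (cursor < bs) {
      labels <- c(labels, "non_bloom")
      starts <- c(starts, cursor); ends <- c(ends, bs - 1L)
    }
    labels <- c(labels, "bloom")
    starts <- c(starts, bs); ends <- c(ends, be)
    cursor <- be + 1L
  }
  if (cursor <= last_day) {
    labels <- c(labels, "non_bloom")
    starts <- c(starts, cursor); ends <- c(ends, last_day)
  }
  new_period_set(labels, starts, ends, provenance = prov)
}

#' Pool consecutive blooms separated by a short non-bloom gap
#'
#' Consecutive bloom periods interrupted by at most `max_gap_weeks` weeks of
#' non-bloom are merged into a single bloom analysis period (the gap days are
#' absorbed into the pooled bloom); the merge is recorded in the provenance.
#'
#' @param p A `period_set`.
#' @param max_gap_weeks Maximum pooled gap, in weeks (7 days each).
#' @return A `period_set` with pooled blooms.
#' @export
pool_blooms <- function(p, max_gap_weeks = 2L) {
  stopifnot(inherits(p, "period_set"))
  prov <- attr(p, "provenance") %||% character()
  max_gap <- 7L * max_gap_weeks
  rows <- split(p, seq_len(nrow(p)))
  out <- list()
  for (row in rows) {
    n <- length(out)
    if (n >= 1L && row$label == "bloom" && out[[n]]$label == "bloom" &&
        as.numeric(row$start - out[[n]]$end) - 1 <= max_gap) {
      prov <- c(prov, sprintf("pooled blooms %s..%s and %s..%s",
                              format(out[[n]]$start), format(out[[n]]$end),
                              format(row$start), format(row$end)))
      out[[n]]$end <- row$end
    } else if (n >= 2L && row$label == "bloom" &&
               out[[n]]$label == "non_bloom" &&
               out[[n - 1L]]$label == "bloom" &&
               as.numeric(row$start - out[[n - 1L]]$end) - 1 <= max_gap) {
      prov <- c(prov, sprintf("pooled blooms %s..%s and %s..%s",
                              format(out[[n - 1L]]$start),
                              format(out[[n - 1L]]$end),
                              format(row$start), format(row$end)))
      out[[n - 1L]]$end <- row$end
      out[[n]] <- NULL
    } else {
      out[[n + 1L]] <- row
    }
  }
  merged <- do.call(rbind, out)
  new_period_set(merged$label, merged$start, merged$end, provenance = prov)
}

#' Restrict an abundance matrix to the periods carrying a label
#'
#' @param m An `abundance_matrix`.
#' @param p A `period_set`.
#' @param label Period label to keep (`"bloom"` or `"non_bloom"`), or a
#'   single row index of `p` to slice one specific period.
#' @return An `abundance_matrix` with rows restricted to sampling dates
#'   inside the matching periods; columns unchanged.
#' @export
slice_abundance <- function(m, p, label) {
  stopifnot(inherits(m, "abundance_matrix"), inherits(p, "period_set"))
  dates <- abundance_dates(m)
  sel <- if (is.numeric(label)) p[label, , drop = FALSE]
         else p[p$label == label, , drop = FALSE]
  keep <- rep(FALSE, length(dates))
  for (i in seq_len(nrow(sel)))
    keep <- keep | (dates >= sel$start[i] & dates <= sel$end[i])
  if (!any(keep)) stop("no samples in period")
  abundance_matrix(unclass(m)[keep, , drop = FALSE], dates = dates[keep],
                   taxon_ids = colnames(m))
}
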