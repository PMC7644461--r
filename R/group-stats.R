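#' Pair two campaigns' samples by ISO-8601 week number
#'
#' Maps each sampling date to its ISO-8601 week number and pairs the weeks
#' present in both campaigns, so that, e.g., 2015-01-08 and 2016-01-12 are
#' paired as both fall in week 2 of their years. With
#' `truncate_to_common = TRUE` (the default) only weeks present in both
#' campaigns are kept, which drops the longer campaign's unmatched trailing
#' weeks; with `FALSE`, unmatched weeks are kept with `NA` in the missing
#' year.
#'
#' @param dates_a,values_a Dates and values of the first campaign.
#' @param dates_b,values_b Dates and values of the second campaign.
#' @param truncate_to_common Drop weeks not present in both campaigns.
#' @return Data frame with columns `iso_week`, `value_a`, `value_b`, ordered
#'   by week number.
#' @export
iso_week_pairing <- function(dates_a, values_a, dates_b, values_b,
                             truncate_to_common = TRUE) {
  stopifnot(length(dates_a) == length(values_a),
            length(dates_b) == length(values_b))
  wa <- as.integer(format(as.Date(dates_a), "%V"))
  wb <- as.integer(format(as.Date(dates_b), "%V"))
  if (anyDuplicated(wa))
    stop("duplicate ISO week within the first campaign: week ",
         wa[duplicated(wa)][1L])
  if (anyDuplicated(wb))
    stop("duplicate ISO week within the second campaign: week ",
         wb[duplicated(wb)][1L])
  weeks <- if (truncate_to_common) sort(intersect(wa, wb))
           else sort(union(wa, wb))
  data.frame(iso_week = weeks,
             value_a = values_a[match(weeks, wa)],
             value_b = values_b[match(weeks, wb)])
}

# Exact null distribution of W+ for (possibly tied) mid-ranks, by
# shift-convolution of the generating polynomial over doubled ranks
# (doubling makes .5 mid-ranks integral). Returns P(2*W+ = k) for
# k = 0..2*sum(ranks).
signed_rank_distribution <- function(ranks) {
  d2 <- as.integer(round(2 * ranks))
  probs <- 1
  for (d in d2) {
    shifted <- c(rep(0, d), probs)
    probs <- c(probs, rep(0, d)) + shifted
  }
  probs / 2^length(d2)
}

#' Paired Wilcoxon signed-rank test
#'
#' Compares two paired series (e.g., the same group's weekly abundances in
#' two years). Zero differences are discarded; absolute differences are
#' mid-ranked; the statistic `W` is the smaller of the positive- and
#' negative-signed rank sums. The two-sided p-value is exact for
#' `n_effective <= exact_limit` (computed from the full sign-flip
#' distribution of the observed mid-ranks, so ties are handled exactly) and
#' uses the normal approximation with continuity and tie correction above.
#'
#' @param pairs Data frame with columns `value_a`, `value_b` (one row per
#'   paired week), e.g. from [iso_week_pairing()].
#' @param exact_limit Largest `n_effective` for which the exact distribution
#'   is used.
#' @return List: `statistic` (W), `p_value`, `n_effective`, `W_plus`,
#'   `W_minus`, `direction` (`"b_greater"`, `"a_greater"` or `"none"`),
#'   `method`, and `degenerate` (`TRUE` when all differences are zero, in
#'   which case `p_value = 1`).
#' @examples
#' pw <- iso_week_pairing(as.Date("2015-01-08") + 7 * 0:4, 1:5,
#'                        as.Date("2016-01-12") + 7 * 0:4, c(2, 4, 6, 8, 10))
#' paired_wilcoxon(pw)  # W = 0, exact p = 0.0625
#' @export
paired_wilcoxon <- function(pairs, exact_limit = 25L) {
  stopifnot(is.data.frame(pairs), all(c("value_a", "value_b") %in% names(pairs)))
  if (!nrow(pairs)) stop("need at least 1 pair")
  d <- pairs$value_b - pairs$value_a
  if (anyNA(d)) stop("missing values in pairs")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n_effective = 0L, W_plus = 0,
                W_minus = 0, direction = "none",
                method = "no nonzero differences", degenerate = TRUE))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  total <- w_plus + w_minus
  if (n <= exact_limit) {
    probs <- signed_rank_distribution(r)
    vals <- seq_along(probs) - 1  # doubled W+ values 0..2*total
    p <- sum(probs[vals <= 2 * w + 1e-9]) +
      sum(probs[vals >= 2 * (total - w) - 1e-9])
    method <- "exact signed-rank distribution"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(w_plus - mu) - 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-max(z, 0))
    method <- "normal approximation with tie and continuity correction"
  }
  p <- min(1, p)
  list(statistic = w, p_value = p, n_effective = n, W_plus = w_plus,
       W_minus = w_minus,
       direction = if (w_plus > w_minus) "b_greater"
                   else if (w_minus > w_plus) "a_greater" else "none",
       method = method, degenerate = FALSE)
}

#' Compare groups between two campaigns by paired Wilcoxon tests
#'
#' Sums abundances over the taxa of each label (functional group or size
#' class) per sampling date, pairs the two campaigns by ISO week, and runs
#' [paired_wilcoxon()] per label. No correction across labels is applied;
#' individual p-values are reported.
#'
#' @param m_a,m_b `abundance_matrix` objects for the two campaigns.
#' @param labels Named character vector mapping taxon id to label (see
#'   [taxon_labels()]).
#' @param truncate_to_common Passed to [iso_week_pairing()].
#' @return Data frame with one row per label: `label`, `n_pairs`, `W`, `p`,
#'   `direction`.
#' @export
compare_groups <- function(m_a, m_b, labels, truncate_to_common = TRUE) {
  stopifnot(inherits(m_a, "abundance_matrix"), inherits(m_b, "abundance_matrix"))
  shared <- intersect(colnames(m_a), colnames(m_b))
  labs <- labels[shared]
  if (anyNA(labs)) stop("unlabelled taxa in abundance matrices")
  rows <- lapply(sort(unique(unname(labs))), function(lab) {
    cols <- shared[labs == lab]
    sa <- rowSums(unclass(m_a)[, cols, drop = FALSE])
    sb <- rowSums(unclass(m_b)[, cols, drop = FALSE])
    pw <- iso_week_pairing(abundance_dates(m_a), sa, abundance_dates(m_b), sb,
                           truncate_to_common = truncate_to_common)
    res <- paired_wilcoxon(pw)
    data.frame(label = lab, n_pairs = nrow(pw), W = res$statistic,
               p = res$p_value, direction = res$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
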