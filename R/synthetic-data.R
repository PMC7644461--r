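#' Default functional-group partition of the community
#'
#' The default taxon inventory: 1 virioplankton node, 2 bacterioplankton
#' nodes (HNA/LNA), 46 phytoplankton, 4 heterotrophic nanoflagellate size
#' classes, 28 naked ciliates and 29 tintinnids — 110 nodes in total.
#'
#' @return Named integer vector of taxa per functional group.
#' @export
default_group_counts <- function() {
  c(virus = 1L, bacteria = 2L, phytoplankton = 46L, HF = 4L,
    naked_ciliate = 28L, tintinnid = 29L)
}

#' Default ESD sampling ranges per functional group
#'
#' Plausible equivalent-spherical-diameter ranges (micrometres) for each
#' guild: sub-micron viruses and bacteria, pico- to microphytoplankton,
#' nanoflagellates, and the two ciliate guilds spanning the tens of microns.
#'
#' @return Named list of `c(lo, hi)` ESD ranges in micrometres.
#' @export
default_esd_ranges <- function() {
  list(virus = c(0.05, 0.2),
       bacteria = c(0.3, 1),
       phytoplankton = c(0.8, 60),
       HF = c(2, 15),
       naked_ciliate = c(12, 100),
       tintinnid = c(20, 150))
}

#' Generate a synthetic taxon metadata table
#'
#' Draws a taxon inventory with per-group ESDs sampled uniformly within each
#' group's range. Identifiers are assigned contiguously from 1 in canonical
#' group order (virus first, tintinnids last), matching the node ordering
#' used in the networks.
#'
#' @param group_counts Named integer vector, taxa per group; defaults to
#'   [default_group_counts()].
#' @param esd_ranges Named list of `c(lo, hi)` ESD ranges in micrometres;
#'   defaults to [default_esd_ranges()].
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @return A `taxon_table` data frame with columns `taxon_id`, `name`,
#'   `group`, `esd_um` and `size_class` (initially `NA`).
#' @examples
#' taxa <- generate_taxa(seed = 1)
#' nrow(taxa)            # 110
#' table(taxa$group)
#' @export
generate_taxa <- function(group_counts = default_group_counts(),
                          esd_ranges = default_esd_ranges(),
                          seed = 1L) {
  groups <- microbial_groups()
  counts <- integer(length(groups))
  names(counts) <- groups
  counts[names(group_counts)] <- as.integer(group_counts)
  if (any(counts < 0)) stop("group counts must be >= 0")
  if (sum(counts) == 0L) stop("no taxa: all group counts are zero")
  for (g in groups[counts > 0L]) {
    rg <- esd_ranges[[g]]
    if (is.null(rg) || length(rg) != 2L || rg[1] <= 0 || rg[1] >= rg[2])
      stop("invalid ESD range for group '", g, "'")
  }
  with_seed(seed, {
    rows <- lapply(groups[counts > 0L], function(g) {
      k <- counts[[g]]
      rg <- esd_ranges[[g]]
      data.frame(name = sprintf("%s_%02d", g, seq_len(k)),
                 group = g,
                 esd_um = sort(runif(k, rg[1], rg[2])),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- data.frame(taxon_id = seq_len(nrow(out)), out,
                      size_class = NA_character_,
                      stringsAsFactors = FALSE)
    class(out) <- c("taxon_table", "data.frame")
    out
  })
}

#' Generate a daily fluorescence series with planted bloom windows
#'
#' Produces a strictly positive daily chlorophyll-a fluorescence proxy:
#' baseline level, a linear ramp up to `base_level * (1 + bloom_amplitude)`
#' across each planted window, a linear decay back to baseline over
#' `decay_days` days after the window, and multiplicative lognormal noise.
#' With `noise_sd = 0` the bloom-detection rules recover each planted window
#' within one day at each boundary (ramp up = consecutive positive growth
#' rates, decay = consecutive negative ones). Planted windows should be at
#' least `min_window + 2` days long for the detection rules to engage.
#'
#' @param n_days Number of daily values.
#' @param bloom_windows List of `c(start, end)` day indices, non-overlapping.
#' @param base_level Baseline fluorescence (arbitrary units), > 0.
#' @param bloom_amplitude Peak relative increase over baseline, >= 0.
#' @param noise_sd Standard deviation of the multiplicative log-noise, >= 0.
#' @param seed Integer seed.
#' @param decay_days Days of post-window decay back to baseline (>= 5 keeps
#'   the bloom-end rule exact).
#' @param baseline_drift Baseline log-trend per day (0 = flat). A negative
#'   drift emulates the net biomass loss of non-bloom conditions, under
#'   which growth-rate bloom rules stay quiet outside the planted windows.
#' @param start_date First calendar day of the series.
#' @return A `fluorescence_series` data frame with columns `date`, `value`.
#' @export
generate_fluorescence <- function(n_days, bloom_windows = list(),
                                  base_level = 1, bloom_amplitude = 3,
                                  noise_sd = 0.05, seed = 1L,
                                  decay_days = 5L, baseline_drift = 0,
                                  start_date = as.Date("2016-01-01")) {
  stopifnot(n_days >= 1, base_level > 0, noise_sd >= 0, decay_days >= 1)
  if (bloom_amplitude < 0) stop("bloom_amplitude must be >= 0")
  wins <- lapply(bloom_windows, function(w) {
    w <- as.integer(w)
    if (length(w) != 2L || w[1] < 1L || w[2] > n_days || w[1] > w[2])
      stop("bloom window out of range [1, n_days]")
    w
  })
  if (length(wins) > 1L) {
    ord <- order(vapply(wins, `[`, integer(1), 1L))
    wins <- wins[ord]
    starts <- vapply(wins, `[`, integer(1), 1L)
    ends <- vapply(wins, `[`, integer(1), 2L)
    if (any(starts[-1L] <= ends[-length(ends)]))
      stop("bloom windows overlap")
  }
  shape <- numeric(n_days)
  for (i in seq_along(wins)) {
    w <- wins[[i]]
    len <- w[2] - w[1] + 1L
    shape[w[1]:w[2]] <- seq_len(len) / len
    nxt <- if (i < length(wins)) wins[[i + 1L]][1] - 1L else n_days
    dn <- min(decay_days, max(0L, nxt - w[2]))
    if (dn > 0L)
      shape[w[2] + seq_len(dn)] <- 1 - seq_len(dn) / (dn + 1L)
  }
  with_seed(seed, {
    noise <- exp(rnorm(n_days, 0, noise_sd))
    trend <- exp(baseline_drift * (seq_len(n_days) - 1L))
    out <- data.frame(date = start_date + seq_len(n_days) - 1L,
                      value = base_level * trend *
                        (1 + bloom_amplitude * shape) * noise)
    class(out) <- c("fluorescence_series", "data.frame")
    attr(out, "bloom_windows") <- wins
    out
  })
}

#' Plan of planted pairwise correlations for the synthetic community
#'
#' Describes the latent rank-correlation structure to plant into a synthetic
#' abundance matrix: a set of taxon pairs with target Spearman correlations,
#' plus per-group abundance scales for the lognormal marginals.
#'
#' @param planted_edges Data frame with columns `taxon_a`, `taxon_b`, `rho`
#'   (latent correlation in (-1, 1)); may have zero rows.
#' @param abundance_scale Named numeric vector of per-group median abundances
#'   (units per mL).
#' @param sdlog Lognormal log-scale standard deviation shared by all taxa.
#' @return An `interaction_plan` object.
#' @export
interaction_plan <- function(planted_edges = empty_planted_edges(),
                             abundance_scale = c(virus = 1e7, bacteria = 1e6,
                                                 phytoplankton = 1e3, HF = 5e2,
                                                 naked_ciliate = 10,
                                                 tintinnid = 10),
                             sdlog = 1) {
  pe <- as.data.frame(planted_edges)
  stopifnot(all(c("taxon_a", "taxon_b", "rho") %in% names(pe)), sdlog > 0)
  if (nrow(pe)) {
    if (any(pe$taxon_a == pe$taxon_b)) stop("self pairs are not allowed")
    if (any(abs(pe$rho) >= 1)) stop("|rho| must be < 1")
    key <- paste(pmin(pe$taxon_a, pe$taxon_b), pmax(pe$taxon_a, pe$taxon_b))
    if (anyDuplicated(key)) stop("pair listed more than once")
  }
  out <- list(planted_edges = pe, abundance_scale = abundance_scale,
              sdlog = sdlog)
  class(out) <- "interaction_plan"
  out
}

#' @rdname interaction_plan
#' @export
empty_planted_edges <- function() {
  data.frame(taxon_a = integer(), taxon_b = integer(), rho = numeric())
}

#' Generate a weekly abundance matrix with planted correlation structure
#'
#' Samples a latent multivariate Gaussian whose correlation matrix carries
#' the planted pairwise correlations (identity elsewhere), then maps each
#' taxon through a monotone lognormal quantile transform scaled by its
#' group's typical abundance. Because the transform is monotone, the
#' planted latent correlations are preserved as rank (Spearman)
#' correlations in the output. If the planted matrix is not positive
#' definite it is repaired by eigenvalue clipping (with a warning); if the
#' repair moves any planted entry by more than `repair_tol` the function
#' aborts and lists the offending pairs.
#'
#' @param taxa A `taxon_table`.
#' @param n_weeks Number of weekly samples (>= 4).
#' @param plan An [interaction_plan()].
#' @param seed Integer seed.
#' @param start_date Date of the first weekly sample.
#' @param repair_tol Maximum tolerated change of a planted correlation under
#'   positive-definite repair.
#' @return An `abundance_matrix`: numeric matrix (weeks x taxa) with taxon
#'   ids as column names and a `dates` attribute.
#' @export
generate_abundances <- function(taxa, n_weeks, plan = interaction_plan(),
                                seed = 1L,
                                start_date = as.Date("2016-01-07"),
                                repair_tol = 0.1) {
  stopifnot(inherits(taxa, "taxon_table"), n_weeks >= 4)
  k <- nrow(taxa)
  sigma <- diag(k)
  pe <- plan$planted_edges
  if (nrow(pe)) {
    if (any(!pe$taxon_a %in% taxa$taxon_id) ||
        any(!pe$taxon_b %in% taxa$taxon_id))
      stop("planted edge refers to an unknown taxon_id")
    ia <- match(pe$taxon_a, taxa$taxon_id)
    ib <- match(pe$taxon_b, taxa$taxon_id)
    sigma[cbind(ia, ib)] <- pe$rho
    sigma[cbind(ib, ia)] <- pe$rho
  }
  eig <- eigen(sigma, symmetric = TRUE)
  if (min(eig$values) < 1e-8) {
    vals <- pmax(eig$values, 1e-8)
    sig2 <- eig$vectors %*% (vals * t(eig$vectors))
    d <- sqrt(diag(sig2))
    sig2 <- sig2 / tcrossprod(d)
    if (nrow(pe)) {
      shift <- abs(sig2[cbind(ia, ib)] - pe$rho)
      bad <- shift > repair_tol
      if (any(bad))
        stop("planted correlation matrix not repairable to positive-definite; ",
             "offending pairs: ",
             paste(sprintf("(%d,%d)", pe$taxon_a[bad], pe$taxon_b[bad]),
                   collapse = ", "))
    }
    warning("planted correlation matrix repaired to positive-definite ",
            "by eigenvalue clipping")
    sigma <- sig2
  }
  ch <- chol(sigma + diag(1e-10, k))
  with_seed(seed, {
    z <- matrix(rnorm(n_weeks * k), n_weeks, k) %*% ch
    scl <- plan$abundance_scale[taxa$group]
    if (anyNA(scl)) stop("abundance_scale missing for some group")
    u <- pnorm(z)
    x <- vapply(seq_len(k), function(j) {
      qlnorm(u[, j], meanlog = log(scl[j]), sdlog = plan$sdlog)
    }, numeric(n_weeks))
    abundance_matrix(x, dates = start_date + 7L * (seq_len(n_weeks) - 1L),
                     taxon_ids = taxa$taxon_id)
  })
}

#' Construct an abundance matrix
#'
#' @param values Numeric matrix, samples in rows, taxa in columns.
#' @param dates Date vector, one per row, strictly increasing.
#' @param taxon_ids Integer taxon identifiers, one per column.
#' @return An `abundance_matrix` (numeric matrix with a `dates` attribute).
#' @export
abundance_matrix <- function(values, dates, taxon_ids = colnames(values)) {
  values <- as.matrix(values)
  dates <- as.Date(dates)
  if (length(dates) != nrow(values)) stop("one date per row required")
  if (is.unsorted(dates, strictly = TRUE)) stop("dates must strictly increase")
  if (anyNA(values)) stop("missing abundance values are not allowed")
  if (is.null(taxon_ids)) stop("taxon ids required as column names")
  colnames(values) <- as.character(as.integer(taxon_ids))
  rownames(values) <- format(dates, "%Y-%m-%d")
  attr(values, "dates") <- dates
  class(values) <- c("abundance_matrix", class(values))
  values
}

#' @rdname abundance_matrix
#' @param m An `abundance_matrix`.
#' @export
abundance_dates <- function(m) {
  attr(m, "dates") %||% as.Date(rownames(m))
}
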