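#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis in one object. Defaults
#' are the study conditions: significance threshold 0.05 on Monte-Carlo
#' p-values from 9999 permutations, 999 random networks with 2.5/97.5%
#' thresholds, 90% biovolume dominance, bloom rules (2 positive days to
#' start, 5-day positive-sum window, 5 negative days to end, 2-week pooling
#' gap).
#'
#' @param abundance,taxa,fluorescence Input objects, or paths to their CSVs.
#' @param outdir Output directory (created if needed).
#' @param alpha Edge significance threshold.
#' @param n_permutations Monte-Carlo permutations per taxon pair.
#' @param n_random_networks Erdős–Rényi replicates for the null model.
#' @param seed Master integer seed for every stochastic stage.
#' @param min_pos_start,min_window,end_neg_run Bloom-detection rules, days.
#' @param max_gap_weeks Bloom pooling gap, weeks.
#' @param pelt_penalty PELT penalty (`NULL` = `2 * log(n)` per group).
#' @param dominance_threshold Cumulative biovolume share defining dominants.
#' @param min_samples Minimum weekly samples for a period to be analysed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(abundance, taxa, fluorescence, outdir,
                            alpha = 0.05, n_permutations = 9999L,
                            n_random_networks = 999L, seed = 1L,
                            min_pos_start = 2L, min_window = 5L,
                            end_neg_run = 5L, max_gap_weeks = 2L,
                            pelt_penalty = NULL,
                            dominance_threshold = 0.90,
                            min_samples = 4L) {
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 1,
            n_random_networks >= 1, dominance_threshold > 0,
            dominance_threshold <= 1, min_samples >= 4)
  out <- list(abundance = abundance, taxa = taxa, fluorescence = fluorescence,
              outdir = outdir, alpha = alpha,
              n_permutations = as.integer(n_permutations),
              n_random_networks = as.integer(n_random_networks),
              seed = as.integer(seed), min_pos_start = as.integer(min_pos_start),
              min_window = as.integer(min_window),
              end_neg_run = as.integer(end_neg_run),
              max_gap_weeks = as.integer(max_gap_weeks),
              pelt_penalty = pelt_penalty,
              dominance_threshold = dominance_threshold,
              min_samples = as.integer(min_samples))
  class(out) <- "pipeline_config"
  out
}

load_input <- function(x, reader) if (is.character(x)) reader(x) else x

#' Run the full analysis pipeline
#'
#' Chains every stage for one campaign: bloom/non-bloom segmentation of the
#' fluorescence series (with pooling of close blooms), PELT size classes for
#' the multi-taxon guilds, and then, per analysis period (each period with
#' at least `min_samples` weekly samples): the negative/positive/combined
#' Spearman permutation networks, a descriptor table, null-model
#' classifications under both the functional-group and ESD-class groupings
#' with their summary networks, biomass-dominant taxa and the dominant-
#' species networks. All outputs are written as plain text (CSV/TSV/
#' GraphML/JSON) under `config$outdir` and are byte-identical across reruns
#' with the same seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list bundle with `periods`, `taxa` (size classes
#'   filled), per-period results, and the descriptor table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  m <- load_input(config$abundance, read_abundance_csv)
  taxa <- load_input(config$taxa, read_taxa_csv)
  fluor <- load_input(config$fluorescence, read_fluorescence_csv)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("seed: %d", config$seed))

  # --- periods ---------------------------------------------------------
  g <- growth_rates(fluor)
  periods <- detect_blooms(g, config$min_pos_start, config$min_window,
                           config$end_neg_run)
  periods <- pool_blooms(periods, config$max_gap_weeks)
  log_lines <- c(log_lines, attr(periods, "provenance"))
  write.csv(data.frame(label = periods$label,
                       start = format(periods$start, "%Y-%m-%d"),
                       end = format(periods$end, "%Y-%m-%d")),
            file.path(config$outdir, "periods.csv"), row.names = FALSE,
            quote = FALSE)

  # --- size classes ----------------------------------------------------
  for (grp in c("phytoplankton", "naked_ciliate", "tintinnid")) {
    if (sum(taxa$group == grp) >= 4L)
      taxa <- size_classes(taxa, grp, penalty = config$pelt_penalty)
  }
  write_taxa_csv(taxa, file.path(config$outdir, "taxa_size_classes.csv"))
  labelings <- list(functional_group = taxon_labels(taxa, "functional_group"),
                    esd_class = taxon_labels(taxa, "esd_class"))

  # --- analysis periods ------------------------------------------------
  dates <- abundance_dates(m)
  n_in <- vapply(seq_len(nrow(periods)), function(i)
    sum(dates >= periods$start[i] & dates <= periods$end[i]), integer(1))
  keep <- which(n_in >= config$min_samples)
  counters <- c(bloom = 0L, non_bloom = 0L)
  desc_rows <- list()
  results <- list()
  for (i in keep) {
    lab <- periods$label[i]
    counters[lab] <- counters[lab] + 1L
    pname <- sprintf("%s_%d", lab, counters[lab])
    pdir <- file.path(config$outdir, pname)
    dir.create(pdir, showWarnings = FALSE)
    slice <- slice_abundance(m, periods, i)
    nets <- build_networks(slice, alpha = config$alpha,
                           n_iter = config$n_permutations,
                           seed = config$seed, period_label = pname)
    if (length(attr(nets, "dropped_taxa")))
      log_lines <- c(log_lines, sprintf(
        "%s: dropped constant taxa %s", pname,
        paste(attr(nets, "dropped_taxa"), collapse = ",")))
    period_res <- list(nets = nets, classifications = list(),
                       summaries = list())
    for (mode in names(nets)) {
      net <- nets[[mode]]
      write_network(net, taxa, file.path(pdir, paste0(mode, "_edges.tsv")),
                    "edge_list_tsv")
      write_network(net, taxa, file.path(pdir, paste0(mode, "_network.graphml")),
                    "graphml")
      d <- descriptors(net)
      desc_rows[[length(desc_rows) + 1L]] <- data.frame(
        period = pname, sign_mode = mode, n_nodes = d$n_nodes,
        n_edges = d$n_edges,
        pct_negative = ifelse(is.na(d$pct_negative), NA, d$pct_negative),
        mean_degree = d$mean_degree)
    }
    stage_seed <- config$seed + 1000L * i
    for (grouping in names(labelings)) {
      cls <- list()
      for (mode in c("negative", "positive")) {
        cl <- classify_pairs(nets[[mode]], labelings[[grouping]],
                             n_random = config$n_random_networks,
                             seed = stage_seed + match(mode, c("negative",
                                                               "positive")))
        write_classification(cl, file.path(
          pdir, sprintf("nullmodel_%s_%s.tsv", grouping, mode)))
        cls[[mode]] <- cl
      }
      period_res$classifications[[grouping]] <- cls
      period_res$summaries[[grouping]] <- summary_network(cls)
    }
    dom <- dominant_taxa(slice, taxa, config$dominance_threshold)
    write.table(as.data.frame(dom), file.path(pdir, "dominant_taxa.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    dom_ids <- dom$taxon_id[dom$dominant]
    for (mode in c("negative", "positive")) {
      write_network(subnetwork(nets[[mode]], dom_ids), taxa,
                    file.path(pdir, sprintf("dominant_%s_edges.tsv", mode)),
                    "edge_list_tsv")
    }
    period_res$dominant <- dom
    results[[pname]] <- period_res
  }
  desc <- do.call(rbind, desc_rows)
  jsonlite::write_json(desc, file.path(config$outdir, "descriptors.json"),
                       dataframe = "rows", na = "null", digits = NA)
  run_log <- list(
    seed = config$seed,
    alpha = config$alpha,
    n_permutations = config$n_permutations,
    n_random_networks = config$n_random_networks,
    dominance_threshold = config$dominance_threshold,
    bloom_rules = list(min_pos_start = config$min_pos_start,
                       min_window = config$min_window,
                       end_neg_run = config$end_neg_run,
                       max_gap_weeks = config$max_gap_weeks),
    package_version = as.character(utils::packageVersion("planktonnet")),
    events = log_lines)
  jsonlite::write_json(run_log, file.path(config$outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(periods = periods, taxa = taxa, descriptors = desc,
                 results = results))
}

#' Simulate a complete synthetic campaign
#'
#' Convenience wrapper tying the generators together: taxon table, daily
#' fluorescence with planted bloom windows, and weekly abundances with
#' planted correlation structure, all deterministic in `seed`.
#'
#' @param seed Integer seed.
#' @param n_days Length of the daily fluorescence series.
#' @param bloom_windows Planted bloom windows (day indices).
#' @param group_counts Taxa per functional group.
#' @param plan An [interaction_plan()].
#' @param noise_sd Fluorescence log-noise standard deviation. Daily means
#'   of a high-frequency sensor average out most noise, hence the small
#'   default.
#' @param baseline_drift Baseline log-trend per day outside blooms; the
#'   negative default encodes net biomass loss during non-bloom conditions,
#'   so the growth-rate rules segment the campaign cleanly.
#' @param start_date First day of the campaign.
#' @return List with `taxa`, `fluorescence`, `abundance`.
#' @export
simulate_campaign <- function(seed = 1L, n_days = 140L,
                              bloom_windows = list(c(30, 50), c(70, 90)),
                              group_counts = default_group_counts(),
                              plan = interaction_plan(),
                              noise_sd = 0.02, baseline_drift = -0.02,
                              start_date = as.Date("2016-01-01")) {
  taxa <- generate_taxa(group_counts = group_counts, seed = seed)
  fluor <- generate_fluorescence(n_days, bloom_windows, noise_sd = noise_sd,
                                 seed = seed + 1L,
                                 baseline_drift = baseline_drift,
                                 start_date = start_date)
  n_weeks <- n_days %/% 7L
  m <- generate_abundances(taxa, n_weeks, plan = plan, seed = seed + 2L,
                           start_date = start_date + 3L)
  list(taxa = taxa, fluorescence = fluor, abundance = m)
}
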