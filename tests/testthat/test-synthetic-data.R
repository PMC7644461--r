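test_that("default taxon table reproduces the community partition", {
  taxa <- generate_taxa(seed = 1)
  expect_s3_class(taxa, "taxon_table")
  expect_equal(nrow(taxa), 110L)
  counts <- table(taxa$group)
  expect_equal(unname(counts[microbial_groups()]),
               unname(table(factor(rep(microbial_groups(),
                                       times = c(1, 2, 46, 4, 28, 29)),
                                   levels = microbial_groups()))))
  expect_equal(sum(taxa$group == "phytoplankton"), 46L)
  # ids contiguous from 1 in canonical group order
  expect_equal(taxa$taxon_id, seq_len(110L))
  expect_equal(taxa$group[1], "virus")
  expect_equal(taxa$group[110], "tintinnid")
  expect_true(all(taxa$esd_um > 0))
})

test_that("taxon generation is deterministic and bookkeeps group counts", {
  expect_identical(generate_taxa(seed = 7), generate_taxa(seed = 7))
  for (gc in list(c(virus = 3L, bacteria = 5L),
                  c(phytoplankton = 12L),
                  small_group_counts())) {
    expect_equal(nrow(generate_taxa(gc, seed = 2)), sum(gc))
  }
  expect_error(generate_taxa(c(virus = 0L)), "no taxa")
})

test_that("fluorescence generator honours baseline, windows and noise", {
  f0 <- generate_fluorescence(20, noise_sd = 0, seed = 1, base_level = 2.5)
  expect_equal(f0$value, rep(2.5, 20))
  f <- generate_fluorescence(60, list(c(10, 25)), noise_sd = 0, seed = 1)
  r <- diff(log(f$value))   # r[k] is the growth into day k + 1
  # ramp up across the planted window (growth into days 10..25), then decay
  expect_true(all(r[9:24] > 0))
  expect_true(all(r[25:29] < 0))
  expect_true(all(f$value > 0))
  expect_error(generate_fluorescence(30, list(c(5, 40))), "out of range")
  expect_error(generate_fluorescence(30, list(c(5, 15), c(10, 20))),
               "overlap")
  expect_error(generate_fluorescence(30, bloom_amplitude = -1), ">= 0")
  expect_identical(generate_fluorescence(50, list(c(10, 20)), seed = 3),
                   generate_fluorescence(50, list(c(10, 20)), seed = 3))
  # negative baseline drift: uniform negative growth outside windows
  fd <- generate_fluorescence(20, noise_sd = 0, baseline_drift = -0.05,
                              seed = 1)
  expect_equal(diff(log(fd$value)), rep(-0.05, 19))
})

test_that("planted rank correlations survive the lognormal transform", {
  taxa <- generate_taxa(c(phytoplankton = 6L), seed = 5)
  plan <- interaction_plan(data.frame(taxon_a = 1L, taxon_b = 2L, rho = 0.95))
  m <- generate_abundances(taxa, 200, plan = plan, seed = 11)
  expect_lt(abs(spearman_rho(m[, "1"], m[, "2"]) - 0.95), 0.1)
  # independence elsewhere: off-plan correlations centred on zero
  others <- c(spearman_rho(m[, "3"], m[, "4"]),
              spearman_rho(m[, "5"], m[, "6"]),
              spearman_rho(m[, "3"], m[, "6"]))
  expect_true(all(abs(others) < 0.2))
  expect_identical(generate_abundances(taxa, 20, plan = plan, seed = 4),
                   generate_abundances(taxa, 20, plan = plan, seed = 4))
})

test_that("negative planted correlations and monotone invariance hold", {
  taxa <- generate_taxa(c(phytoplankton = 4L), seed = 6)
  plan <- interaction_plan(data.frame(taxon_a = 1L, taxon_b = 2L,
                                      rho = -0.9))
  m <- generate_abundances(taxa, 150, plan = plan, seed = 3)
  expect_lt(abs(spearman_rho(m[, "1"], m[, "2"]) - (-0.9)), 0.1)
  # rank correlation invariant under a strictly increasing transform
  expect_equal(spearman_rho(log(m[, "1"]), sqrt(m[, "2"])),
               spearman_rho(m[, "1"], m[, "2"]))
})

test_that("interaction plans are validated", {
  expect_error(interaction_plan(data.frame(taxon_a = 1, taxon_b = 1,
                                           rho = 0.5)), "self pairs")
  expect_error(interaction_plan(data.frame(taxon_a = 1, taxon_b = 2,
                                           rho = 1)), "< 1")
  expect_error(interaction_plan(data.frame(taxon_a = c(1, 2),
                                           taxon_b = c(2, 1),
                                           rho = c(0.5, 0.4))),
               "more than once")
})

test_that("inconsistent planted structure is repaired or rejected", {
  taxa <- generate_taxa(c(phytoplankton = 3L), seed = 2)
  # rho(1,2)=0.9, rho(1,3)=0.9, rho(2,3)=-0.9 is infeasible
  plan <- interaction_plan(data.frame(taxon_a = c(1L, 1L, 2L),
                                      taxon_b = c(2L, 3L, 3L),
                                      rho = c(0.9, 0.9, -0.9)))
  expect_error(suppressWarnings(generate_abundances(taxa, 20, plan = plan,
                                                    seed = 1)),
               "offending pairs")
  # mildly inconsistent structure is repaired with a warning
  plan2 <- interaction_plan(data.frame(taxon_a = c(1L, 1L, 2L),
                                       taxon_b = c(2L, 3L, 3L),
                                       rho = c(0.8, 0.8, 0.2)))
  expect_warning(generate_abundances(taxa, 20, plan = plan2, seed = 1),
                 "repaired")
})
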