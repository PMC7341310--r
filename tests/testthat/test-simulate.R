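test_that("the generator is deterministic under a fixed seed", {
  cfg <- trio_sim_config(n_genes = 50, n_events = 20, seed = 123)
  a <- simulate_trio_dataset(cfg)
  b <- simulate_trio_dataset(cfg)
  expect_identical(a, b)
})

test_that("planted group means respect the declared gene-action mode", {
  cfg <- trio_sim_config(n_genes = 600, effect_size_log2 = 2, seed = 21)
  tr <- simulate_trio_counts(cfg)$truth$genes
  e <- cfg$effect_size_log2
  with_mode <- function(m) tr[tr$mode == m, ]
  ov <- with_mode("over_dominance")
  expect_true(all(log2(ov$mu_hybrid / pmax(ov$mu_paternal, ov$mu_maternal)) >= e / 2))
  un <- with_mode("under_dominance")
  expect_true(all(log2(pmin(un$mu_paternal, un$mu_maternal) / un$mu_hybrid) >= e / 2))
  ad <- with_mode("additive")
  expect_equal(ad$mu_hybrid, (ad$mu_paternal + ad$mu_maternal) / 2)
  expect_true(all(ad$mu_paternal != ad$mu_maternal))
  hi <- with_mode("high_parent_dominance")
  expect_equal(hi$mu_hybrid, pmax(hi$mu_paternal, hi$mu_maternal))
  co <- with_mode("conserved")
  expect_true(all(co$mu_hybrid == co$mu_paternal & co$mu_paternal == co$mu_maternal))
})

test_that("a conserved-only simulation has no systematic fold changes", {
  cfg <- trio_sim_config(n_genes = 800, mode_proportions = c(conserved = 1),
                         effect_size_log2 = 0, seed = 31)
  d <- simulate_trio_counts(cfg)
  tr <- d$truth$genes
  expect_true(all(tr$mu_hybrid == tr$mu_paternal))
  de <- test_de(d$counts, d$samples, "paternal_parent", "maternal_parent")
  expect_lt(abs(median(de$log2fc)), 0.05)
})

test_that("method-of-moments dispersion recovers the generator's alpha", {
  # 40 replicates per parent give the moment estimator enough degrees of
  # freedom for a tight per-gene check against the planted alpha = 0.1
  cfg <- trio_sim_config(n_genes = 2000, replicates_per_group = 40,
                         mode_proportions = c(conserved = 1), dispersion = 0.1,
                         seed = 7)
  d <- simulate_trio_counts(cfg)
  m <- as.matrix(d$counts[, -1])
  sheet <- d$samples
  idx <- lapply(c("paternal_parent", "maternal_parent"),
                function(r) sheet$sample_id[sheet$species_role == r])
  sf <- size_factors(d$counts)
  norm <- sweep(m, 2, setNames(sf$size_factor, sf$sample_id)[colnames(m)], "/")
  mp <- rowMeans(norm[, idx[[1]]]); mm <- rowMeans(norm[, idx[[2]]])
  s2 <- (rowSums((norm[, idx[[1]]] - mp)^2) +
           rowSums((norm[, idx[[2]]] - mm)^2)) / (80 - 2)
  a_hat <- (s2 - (mp + mm) / 2) / ((mp + mm) / 2)^2
  expect_gte(mean(a_hat > 0.05 & a_hat < 0.2), 0.9)
})

test_that("planted PSI generates the expected junction counts", {
  # psi = 1 everywhere -> no skipping reads at all
  cfg <- trio_sim_config(n_events = 40, mode_proportions = c(conserved = 1),
                         psi_base_range = c(1, 1), seed = 13)
  sim <- simulate_splice_events(cfg)
  s_cols <- grep("^S:", names(sim$events), value = TRUE)
  expect_true(all(sapply(s_cols, function(cc) all(sim$events[[cc]] == 0))))

  # equal effective lengths and psi = 0.5 -> inclusion and skipping balance
  cfg2 <- trio_sim_config(n_events = 400, mode_proportions = c(conserved = 1),
                          psi_base_range = c(0.5, 0.5), event_types = "A5SS",
                          event_coverage_mean = 100, seed = 14)
  sim2 <- simulate_splice_events(cfg2)
  expect_equal(sim2$events$len_inclusion, sim2$events$len_exclusion)
  itot <- sum(sapply(grep("^I:", names(sim2$events), value = TRUE),
                     function(cc) sum(sim2$events[[cc]])))
  stot <- sum(sapply(grep("^S:", names(sim2$events), value = TRUE),
                     function(cc) sum(sim2$events[[cc]])))
  expect_lt(abs(itot / (itot + stot) - 0.5), 0.01)
})

test_that("planted delta-psi is recovered without bias", {
  cfg <- trio_sim_config(n_events = 500,
                         mode_proportions = c(over_dominance = 1),
                         delta_psi_planted = 0.3, event_coverage_mean = 200,
                         seed = 15)
  sim <- simulate_splice_events(cfg)
  das <- test_das(sim$events, sim$samples, "paternal_parent", "hybrid")
  # hybrid - paternal is exactly +0.3 for every over-dominant planting
  expect_lt(abs(mean(das$delta_psi) - 0.3), 0.05)
})

test_that("long-read emission follows depth, psi and the uncovered fraction", {
  cfg0 <- trio_sim_config(n_events = 10, longread_depth = 0, seed = 16)
  sim0 <- simulate_splice_events(cfg0)
  lr0 <- simulate_long_reads(sim0$events, sim0$truth, cfg0)
  expect_equal(nrow(lr0$reads), 0L)

  # psi = 1: every read copies the inclusion chain
  cfg1 <- trio_sim_config(n_events = 30, mode_proportions = c(conserved = 1),
                          psi_base_range = c(1, 1), longread_depth = 10,
                          uncovered_fraction = 0, seed = 17)
  sim1 <- simulate_splice_events(cfg1)
  lr1 <- simulate_long_reads(sim1$events, sim1$truth, cfg1)
  expect_true(all(lr1$emitted$n_exclusion == 0))
  incl <- sim1$events$inclusion_chain[match(sub("^lr_(ev\\d+)_\\d+$", "\\1",
                                               lr1$reads$read_id),
                                            sim1$events$event_id)]
  expect_true(all(mapply(identical, lr1$reads$blocks, incl)))

  # Poisson zero mass: covered fraction ~ (1 - u) * (1 - exp(-depth))
  cfg2 <- trio_sim_config(n_events = 1000, longread_depth = 5,
                          uncovered_fraction = 0.3, seed = 18)
  sim2 <- simulate_splice_events(cfg2)
  lr2 <- simulate_long_reads(sim2$events, sim2$truth, cfg2)
  expect_lt(abs(mean(lr2$emitted$n_reads > 0) - 0.7 * (1 - exp(-5))), 0.05)
})

test_that("generated tables pass the package's own validators", {
  cfg <- trio_sim_config(n_genes = 40, n_events = 25,
                         event_types = c("SE", "RI", "MXE"), seed = 19)
  d <- simulate_trio_dataset(cfg)
  expect_silent(validate_sample_sheet(d$samples))
  expect_silent(validate_splice_events(d$events))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts(d$counts, f)
  expect_equal(read_counts(f), d$counts)
})

test_that("invalid configurations are rejected", {
  expect_error(trio_sim_config(mode_proportions = c(conserved = 0.5)), "sum to 1")
  expect_error(trio_sim_config(delta_psi_planted = 1.2), "< 1")
  cfg <- trio_sim_config(replicates_per_group = 1)
  expect_error(simulate_trio_counts(cfg), ">= 2")
  expect_error(simulate_splice_events(cfg), ">= 2")
})
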