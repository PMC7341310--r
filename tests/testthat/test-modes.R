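test_that("pairwise relations follow the significance/sign truth table", {
  expect_equal(pairwise_relation(2, 0.3), "equal")
  expect_equal(pairwise_relation(-0.4, 0.001), "less")
  expect_warning(r0 <- pairwise_relation(0, 0.001), "equal")
  expect_equal(r0, "equal")
  grid <- expand.grid(est = c(-1, 1), padj = c(0.001, 0.049, 0.05, 0.3))
  got <- pairwise_relation(grid$est, grid$padj)
  want <- ifelse(grid$padj >= 0.05, "equal", ifelse(grid$est > 0, "greater", "less"))
  expect_equal(got, want)
})

# independent rule table, framed through "which parent is higher" rather than
# the implementation's decision sequence
oracle_mode <- function(hp, hm, pm, mid) {
  if (hp == "equal" && hm == "equal" && pm == "equal") return("conserved")
  if (hp == "greater" && hm == "greater") return("over_dominance")
  if (hp == "less" && hm == "less") return("under_dominance")
  hi_rel <- switch(pm, greater = hp, less = hm, equal = NA_character_)
  lo_rel <- switch(pm, greater = hm, less = hp, equal = NA_character_)
  if (!is.na(hi_rel) && hi_rel == "equal") return("high_parent_dominance")
  if (!is.na(lo_rel) && lo_rel == "equal") return("low_parent_dominance")
  if (pm != "equal" && mid == "equal") return("additive")
  "other_non_additive"
}

test_that("the classifier matches the brute-force rule table on all 81 cases", {
  rel <- c("greater", "less", "equal")
  grid <- expand.grid(hp = rel, hm = rel, pm = rel, mid = rel,
                      stringsAsFactors = FALSE)
  grid <- grid[!duplicated(grid[c("hp", "hm", "pm", "mid")]), ]
  got <- classify_gene_action(grid$hp, grid$hm, grid$pm, grid$mid)
  want <- mapply(oracle_mode, grid$hp, grid$hm, grid$pm, grid$mid)
  expect_equal(got, unname(want))
  expect_length(got, 81L)
})

test_that("relabelling the parents is a symmetry of the classifier", {
  rel <- c("greater", "less", "equal")
  flip <- c(greater = "less", less = "greater", equal = "equal")
  grid <- expand.grid(hp = rel, hm = rel, pm = rel, mid = rel,
                      stringsAsFactors = FALSE)
  orig <- classify_gene_action(grid$hp, grid$hm, grid$pm, grid$mid)
  swapped <- classify_gene_action(grid$hm, grid$hp, flip[grid$pm], grid$mid)
  expect_equal(swapped, orig)  # every mode label is parent-symmetric
})

test_that("a trio with identical data everywhere is conserved", {
  samples <- tiny_samples(2)
  set.seed(81)
  col <- rpois(40, 60)
  m <- matrix(rep(col, 6), ncol = 6)
  cts <- counts_tbl(m, sample_ids = samples$sample_id)
  calls <- classify_modes(trio_calls_expression(cts, samples))
  expect_true(all(calls$rel_hp == "equal" & calls$rel_hm == "equal" &
                    calls$rel_pm == "equal"))
  expect_true(all(calls$mode == "conserved"))
})

test_that("the mid-parent test behaves under planted additivity and over-dominance", {
  # a conserved majority keeps median-of-ratios normalization well-posed
  cfg <- trio_sim_config(n_genes = 600, baseline_log_mean = c(log(500), 0.5),
                         mode_proportions = c(conserved = 0.5, additive = 0.25,
                                              over_dominance = 0.25),
                         effect_size_log2 = 2, seed = 82)
  d <- simulate_trio_counts(cfg)
  calls <- trio_calls_expression(d$counts, d$samples)
  tr <- d$truth$genes
  add <- tr$mode == "additive"; ov <- tr$mode == "over_dominance"
  # additive hybrids sit exactly at the mid-parent: "equal" except type-I loss
  expect_gte(mean(calls$rel_mid[add] == "equal"), 0.85)
  # over-dominant hybrids are far above it
  expect_gte(mean(calls$rel_mid[ov] == "greater"), 0.95)
})

test_that("planted-conserved genes are rarely given a mode label", {
  # under a null-majority composition the BH threshold stays near the raw
  # level, so the conserved error is bounded by roughly one alpha per
  # pairwise contrast
  cfg <- trio_sim_config(n_genes = 900, baseline_log_mean = c(log(500), 0.5),
                         mode_proportions = c(conserved = 0.8, over_dominance = 0.1,
                                              under_dominance = 0.1),
                         effect_size_log2 = 2, seed = 85)
  d <- simulate_trio_counts(cfg)
  calls <- classify_modes(trio_calls_expression(d$counts, d$samples))
  tr <- d$truth$genes
  expect_lte(mean(calls$mode[tr$mode == "conserved"] != "conserved"), 0.10)
})

test_that("PSI trio calls recover planted splicing modes", {
  cfg <- trio_sim_config(n_events = 400, event_coverage_mean = 200,
                         delta_psi_planted = 0.3,
                         mode_proportions = c(conserved = 0.25, over_dominance = 0.25,
                                              under_dominance = 0.25,
                                              high_parent_dominance = 0.25),
                         seed = 83)
  sim <- simulate_splice_events(cfg)
  calls <- classify_modes(trio_calls_psi(sim$events, sim$samples))
  tr <- sim$truth
  for (m in c("over_dominance", "under_dominance", "high_parent_dominance")) {
    expect_gte(mean(calls$mode[tr$mode == m] == m), 0.8)
  }
  expect_gte(mean(calls$mode[tr$mode == "conserved"] == "conserved"), 0.85)
})

test_that("mode summaries count, percentage and aggregate correctly", {
  s <- summarize_modes(c("additive"))
  expect_equal(tidy(s)$pct[tidy(s)$mode == "additive"], 100.0)
  expect_equal(attr(s, "total_classified"), 1L)

  mix <- c(rep("over_dominance", 3), rep("additive", 2), rep("conserved", 5))
  s2 <- summarize_modes(mix)
  g <- glance(s2)
  expect_equal(g$total_classified, 5L)
  expect_equal(g$conserved_n, 5L)
  expect_equal(g$non_additive_total, 3L)
  expect_equal(sum(tidy(s2)$n), g$total_classified)

  expect_error(summarize_modes(rep("conserved", 4)), "no classified")
  expect_error(summarize_modes(c("additive", "bogus")), "unknown mode")
})

test_that("mode_table lays out strata in the conventional column order", {
  long <- tibble::tibble(tissue = "muscle", hybrid = "mule",
                         mode = c("over_dominance", "under_dominance", "additive"),
                         n = c(7L, 3L, 2L))
  tab <- mode_table(long)
  expect_equal(names(tab)[3:8],
               c("over_dominance", "high_parent_dominance", "additive",
                 "low_parent_dominance", "under_dominance", "other_non_additive"))
  expect_equal(tab$total_classified, 12)
  expect_equal(tab$over_plus_under, 10)
  expect_equal(tab$non_additive_total, 10)
  expect_error(mode_table(long[0, ]), "non-empty")
})
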