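test_that("PSI follows its closed form and coverage rule", {
  expect_equal(compute_psi(10, 0, 1, 1), 1)
  expect_equal(compute_psi(30, 10, 2, 1), 0.6)        # (30/2)/(30/2 + 10/1)
  expect_equal(compute_psi(20, 10, 2, 1), 0.5)        # I/lI == S/lS
  expect_true(is.na(compute_psi(4, 3, 1, 1)))         # below min_total
  expect_equal(compute_psi(4, 3, 1, 1, min_total = 5), 4 / 7)
  expect_error(compute_psi(-1, 3, 1, 1), "non-negative")
  # scale invariance in the effective lengths
  set.seed(71)
  I <- rpois(50, 40); S <- rpois(50, 25)
  expect_equal(compute_psi(I, S, 100, 50), compute_psi(I, S, 300, 150))
})

# independent binomial-likelihood oracle: grid/optimize over psi directly
oracle_das <- function(I_a, S_a, I_b, S_b, lI, lS) {
  ll <- function(psi, I, S) {
    p <- psi * lI / (psi * lI + (1 - psi) * lS)
    sum(dbinom(I, I + S, p, log = TRUE))
  }
  fit <- function(I, S) optimize(function(ps) ll(ps, I, S), c(1e-9, 1 - 1e-9),
                                 maximum = TRUE, tol = 1e-10)
  fa <- fit(I_a, S_a); fb <- fit(I_b, S_b); f0 <- fit(c(I_a, I_b), c(S_a, S_b))
  lrt <- 2 * (fa$objective + fb$objective - f0$objective)
  list(psi_a = fa$maximum, psi_b = fb$maximum, lrt = lrt,
       p = pchisq(lrt, 1, lower.tail = FALSE))
}

test_that("the DAS likelihood-ratio test matches an independent oracle", {
  samples <- tiny_samples(2)
  pa <- role_ids(samples, "paternal_parent"); ma <- role_ids(samples, "maternal_parent")
  I <- setNames(c(90L, 95L, 10L, 5L), c(pa, ma))
  S <- setNames(c(10L, 5L, 90L, 95L), c(pa, ma))
  ev <- make_se_event(I, S, lI = 1, lS = 1)
  res <- test_das(ev, samples, "paternal_parent", "maternal_parent")
  orc <- oracle_das(c(90, 95), c(10, 5), c(10, 5), c(90, 95), 1, 1)
  expect_equal(res$delta_psi, orc$psi_b - orc$psi_a, tolerance = 1e-6)
  expect_equal(res$delta_psi, -0.85, tolerance = 1e-9)
  expect_equal(res$lrt_stat, orc$lrt, tolerance = 1e-6)
  expect_lt(res$p, 1e-6)

  # unequal effective lengths: closed-form inversion still matches the oracle
  I2 <- setNames(c(80L, 70L, 30L, 35L), c(pa, ma))
  S2 <- setNames(c(20L, 25L, 60L, 70L), c(pa, ma))
  ev2 <- make_se_event(I2, S2, lI = 100, lS = 50)
  res2 <- test_das(ev2, samples, "paternal_parent", "maternal_parent")
  orc2 <- oracle_das(c(80, 70), c(20, 25), c(30, 35), c(60, 70), 100, 50)
  expect_equal(res2$psi_a, orc2$psi_a, tolerance = 1e-6)
  expect_equal(res2$psi_b, orc2$psi_b, tolerance = 1e-6)
  expect_equal(res2$lrt_stat, orc2$lrt, tolerance = 1e-5)
})

test_that("identical groups give a null DAS result", {
  samples <- tiny_samples(2)
  pa <- role_ids(samples, "paternal_parent"); ma <- role_ids(samples, "maternal_parent")
  I <- setNames(c(40L, 45L, 40L, 45L), c(pa, ma))
  S <- setNames(c(20L, 15L, 20L, 15L), c(pa, ma))
  ev <- make_se_event(I, S)
  res <- test_das(ev, samples, "paternal_parent", "maternal_parent")
  expect_equal(res$delta_psi, 0)
  expect_equal(res$lrt_stat, 0)
  expect_equal(res$p, 1)
})

test_that("swapping groups negates delta-psi and preserves the p-value", {
  samples <- tiny_samples(3)
  cfg <- trio_sim_config(n_events = 50, seed = 72)
  sim <- simulate_splice_events(cfg)
  ab <- test_das(sim$events, sim$samples, "paternal_parent", "hybrid")
  ba <- test_das(sim$events, sim$samples, "hybrid", "paternal_parent")
  expect_equal(ab$delta_psi, -ba$delta_psi)
  expect_equal(ab$p, ba$p)
})

test_that("with equal effective lengths the group MLE is the pooled ratio", {
  samples <- tiny_samples(2)
  pa <- role_ids(samples, "paternal_parent"); ma <- role_ids(samples, "maternal_parent")
  I <- setNames(c(33L, 27L, 12L, 18L), c(pa, ma))
  S <- setNames(c(17L, 23L, 48L, 42L), c(pa, ma))
  ev <- make_se_event(I, S, lI = 7, lS = 7)
  res <- test_das(ev, samples, "paternal_parent", "maternal_parent")
  expect_equal(res$psi_a, (33 + 27) / (33 + 27 + 17 + 23))
  expect_equal(res$psi_b, (12 + 18) / (12 + 18 + 48 + 42))
})

test_that("DAS calling uses strict delta-psi and inclusive FDR boundaries", {
  res <- tibble::tibble(event_id = c("e1", "e2", "e3"), gene_id = "g",
                        psi_a = 0.5, psi_b = 0.5,
                        delta_psi = c(0.15, 0.10, 0.5),
                        lrt_stat = 1, p = 0.01, testable = TRUE,
                        padj = c(0.01, 0.001, 0.05))
  called <- call_das(res)
  expect_equal(called$called, c(TRUE, FALSE, TRUE))
})

test_that("untestable events are flagged and never called", {
  samples <- tiny_samples(2)
  pa <- role_ids(samples, "paternal_parent"); ma <- role_ids(samples, "maternal_parent")
  I <- setNames(c(2L, 3L, 40L, 45L), c(pa, ma))   # paternal below min_total
  S <- setNames(c(1L, 2L, 20L, 15L), c(pa, ma))
  ev <- make_se_event(I, S)
  res <- test_das(ev, samples, "paternal_parent", "maternal_parent")
  expect_false(res$testable)
  expect_true(is.na(res$p))
  expect_false(call_das(res)$called)
})

test_that("DAS genes are the unique genes with called events", {
  res <- tibble::tibble(event_id = sprintf("e%d", 1:6),
                        gene_id = c("gA", "gA", "gA", "gB", "gC", "gC"),
                        called = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_setequal(das_genes(res), c("gA", "gC"))
  expect_length(das_genes(dplyr::mutate(res, called = FALSE)), 0)
  set.seed(73)
  for (rep in 1:10) {
    res$called <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    expect_equal(sort(das_genes(res)),
                 sort(unique(res$gene_id[res$called])))
  }
})
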