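# Percent-spliced-in (PSI) estimation and differential alternative splicing.
# Replicates enter a joint binomial likelihood whose success probability
# folds in the isoform effective lengths; groups are compared by a 1-df
# likelihood-ratio test and called with the |delta psi| > 10%, FDR <= 0.05
# rule.

#' Percent spliced-in from junction counts
#'
#' `psi = (I/lI) / (I/lI + S/lS)`: inclusion and skipping counts debiased by
#' the effective lengths of the two isoform forms. Events with
#' `I + S < min_total` are reported as `NA` (insufficient coverage).
#'
#' @param inclusion,skipping Non-negative junction counts (vectorized).
#' @param len_inclusion,len_exclusion Positive effective lengths.
#' @param min_total Minimum `I + S` for a defined PSI.
#' @return PSI values in `[0, 1]`, `NA` where coverage is insufficient.
#' @export
compute_psi <- function(inclusion, skipping, len_inclusion, len_exclusion,
                        min_total = 10) {
  if (any(inclusion < 0) || any(skipping < 0)) abort("counts must be non-negative.")
  if (any(len_inclusion < 1) || any(len_exclusion < 1)) {
    abort("effective lengths must be >= 1.")
  }
  num <- inclusion / len_inclusion
  den <- num + skipping / len_exclusion
  psi <- ifelse(den > 0, num / den, NA_real_)
  psi[inclusion + skipping < min_total] <- NA_real_
  psi
}

#' Per-sample PSI matrix for an event table
#'
#' @param events Event tibble with `I:`/`S:` columns.
#' @param min_total Minimum junction counts for a defined PSI.
#' @return A tibble: `event_id` plus one PSI column per sample.
#' @export
psi_matrix <- function(events, min_total = 10) {
  ids <- event_sample_ids(events)
  out <- tibble(event_id = events$event_id)
  for (s in ids) {
    out[[s]] <- compute_psi(events[[paste0("I:", s)]], events[[paste0("S:", s)]],
                            events$len_inclusion, events$len_exclusion, min_total)
  }
  out
}

# invert the read-level success probability back to psi:
# p = psi*lI/(psi*lI+(1-psi)*lS)  =>  psi = p*lS / (lI*(1-p) + p*lS)
p_to_psi <- function(p, lI, lS) p * lS / (lI * (1 - p) + p * lS)

xlogy <- function(x, y) ifelse(x > 0, x * log(y), 0)

# binomial log-likelihood kernel at success probability p for totals (I, S)
binom_kernel <- function(I, S, p) xlogy(I, p) + xlogy(S, 1 - p)

#' Differential alternative splicing test
#'
#' For each event, replicate inclusion/skipping counts within each group are
#' modelled as binomial draws with a shared group-level success probability;
#' the null of one common probability across both groups is compared to free
#' group probabilities by a likelihood-ratio test on 1 df. Group PSI
#' estimates are the alternative-model MLEs mapped back through the
#' effective-length weighting. Samples with `I + S < min_total` are dropped;
#' a group with fewer than 2 usable replicates makes the event untestable
#' (`p = NA`).
#'
#' @param events Event tibble.
#' @param samples Sample sheet.
#' @param group_a,group_b Role names or sample-id vectors;
#'   `delta_psi = psi_b - psi_a`.
#' @param tissue Optional tissue restriction.
#' @param min_total Per-sample minimum junction count.
#' @return A tibble: `event_id`, `gene_id`, `psi_a`, `psi_b`, `delta_psi`,
#'   `lrt_stat`, `p`, `padj`, `testable`.
#' @export
test_das <- function(events, samples, group_a, group_b, tissue = NULL,
                     min_total = 10) {
  samples <- validate_sample_sheet(samples)
  events <- validate_splice_events(events)
  ids_a <- resolve_group(group_a, samples, tissue)
  ids_b <- resolve_group(group_b, samples, tissue)
  ids_a <- intersect(ids_a, event_sample_ids(events))
  ids_b <- intersect(ids_b, event_sample_ids(events))
  if (length(ids_a) < 2L || length(ids_b) < 2L) {
    abort("each group needs at least 2 replicates with event counts.")
  }
  group_totals <- function(ids) {
    I <- vapply(ids, function(s) events[[paste0("I:", s)]],
                integer(nrow(events)))
    S <- vapply(ids, function(s) events[[paste0("S:", s)]],
                integer(nrow(events)))
    if (nrow(events) == 1L) { I <- t(I); S <- t(S) }
    usable <- (I + S) >= min_total
    list(I = rowSums(I * usable), S = rowSums(S * usable),
         n_usable = rowSums(usable))
  }
  a <- group_totals(ids_a); b <- group_totals(ids_b)
  testable <- a$n_usable >= 2L & b$n_usable >= 2L
  tot_a <- a$I + a$S; tot_b <- b$I + b$S
  p_a <- ifelse(tot_a > 0, a$I / tot_a, NA_real_)
  p_b <- ifelse(tot_b > 0, b$I / tot_b, NA_real_)
  p_0 <- ifelse(tot_a + tot_b > 0, (a$I + b$I) / (tot_a + tot_b), NA_real_)
  ll1 <- binom_kernel(a$I, a$S, p_a) + binom_kernel(b$I, b$S, p_b)
  ll0 <- binom_kernel(a$I, a$S, p_0) + binom_kernel(b$I, b$S, p_0)
  lrt <- pmax(2 * (ll1 - ll0), 0)
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  psi_a <- p_to_psi(p_a, events$len_inclusion, events$len_exclusion)
  psi_b <- p_to_psi(p_b, events$len_inclusion, events$len_exclusion)
  out <- tibble(event_id = events$event_id, gene_id = events$gene_id,
                psi_a = psi_a, psi_b = psi_b, delta_psi = psi_b - psi_a,
                lrt_stat = lrt, p = p, testable = testable)
  out$psi_a[!testable] <- NA_real_; out$psi_b[!testable] <- NA_real_
  out$delta_psi[!testable] <- NA_real_; out$lrt_stat[!testable] <- NA_real_
  out$p[!testable] <- NA_real_
  out$padj <- rep(NA_real_, nrow(out))
  if (any(testable)) out$padj[testable] <- bh_adjust(out$p[testable])
  out
}

#' Call differential splicing events
#'
#' Called when `|delta_psi| > min_dpsi` (strict) and `padj <= max_fdr`
#' (inclusive), the conventional rigorous rule. Untestable events are never
#' called.
#'
#' @param results Tibble from [test_das()].
#' @param min_dpsi Minimum absolute PSI difference.
#' @param max_fdr FDR ceiling.
#' @return `results` with a logical `called` column.
#' @export
call_das <- function(results, min_dpsi = 0.10, max_fdr = 0.05) {
  results |>
    mutate(called = !is.na(.data$padj) & !is.na(.data$delta_psi) &
             abs(.data$delta_psi) > min_dpsi & .data$padj <= max_fdr)
}

#' Genes with at least one called splicing event
#'
#' @param results Tibble from [call_das()].
#' @return Character vector of unique gene ids.
#' @export
das_genes <- function(results) {
  if (!"called" %in% names(results)) abort("run call_das() first.")
  unique(results$gene_id[results$called])
}
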