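# Gene-action (inheritance-mode) classification from trio comparisons.
# Each gene or splicing event gets three pairwise relations (hybrid vs each
# parent, parent vs parent) plus a hybrid-vs-mid-parent relation, and is
# classified as conserved, over-/under-dominant, high-/low-parent dominant,
# additive, or residual non-additive. "Equal" means not significantly
# different at the BH-adjusted level within that contrast family.

#' Relation of a pairwise contrast
#'
#' `equal` when `padj >= alpha`; otherwise `greater`/`less` by the sign of
#' the estimate. A significant contrast with estimate exactly 0 is treated
#' as `equal` with a warning.
#'
#' @param estimate Effect estimate (log2 fold change or delta PSI);
#'   vectorized.
#' @param padj BH-adjusted p-values.
#' @param alpha Significance level.
#' @return Character vector in `c("greater", "less", "equal")`.
#' @export
pairwise_relation <- function(estimate, padj, alpha = 0.05) {
  assert_scalar_number(alpha, "alpha", 0, 1)
  if (any(!is.na(padj) & (padj < 0 | padj > 1))) abort("padj must lie in [0, 1].")
  sig <- !is.na(padj) & padj < alpha
  zero_sig <- sig & !is.na(estimate) & estimate == 0
  if (any(zero_sig)) {
    warn(sprintf("%d significant contrast(s) with estimate exactly 0 treated as 'equal'.",
                 sum(zero_sig)))
  }
  case_when(sig & estimate > 0 ~ "greater",
            sig & estimate < 0 ~ "less",
            TRUE ~ "equal")
}

#' Classify gene action from trio relations
#'
#' Decision sequence (first match wins), with H the hybrid, P/M the parents
#' and MID the mid-parent value (P + M) / 2:
#' 1. all three pairwise relations equal: `conserved`;
#' 2. H > P and H > M: `over_dominance`;
#' 3. H < P and H < M: `under_dominance`;
#' 4. (H = P and P > M) or (H = M and M > P): `high_parent_dominance`;
#' 5. (H = P and P < M) or (H = M and M < P): `low_parent_dominance`;
#' 6. P != M and H = MID: `additive`;
#' 7. otherwise `other_non_additive`.
#'
#' @param rel_hp,rel_hm Relations of the hybrid to the paternal and maternal
#'   parent (`greater` means hybrid higher).
#' @param rel_pm Relation of paternal to maternal parent.
#' @param rel_mid Relation of the hybrid to the mid-parent value.
#' @return Character vector of gene-action modes; vectorized and total.
#' @export
classify_gene_action <- function(rel_hp, rel_hm, rel_pm, rel_mid) {
  rels <- list(rel_hp, rel_hm, rel_pm, rel_mid)
  ok <- c("greater", "less", "equal")
  if (!all(unlist(rels) %in% ok)) {
    abort(sprintf("relations must be one of: %s", paste(ok, collapse = ", ")))
  }
  case_when(
    rel_hp == "equal" & rel_hm == "equal" & rel_pm == "equal" ~ "conserved",
    rel_hp == "greater" & rel_hm == "greater" ~ "over_dominance",
    rel_hp == "less" & rel_hm == "less" ~ "under_dominance",
    (rel_hp == "equal" & rel_pm == "greater") |
      (rel_hm == "equal" & rel_pm == "less") ~ "high_parent_dominance",
    (rel_hp == "equal" & rel_pm == "less") |
      (rel_hm == "equal" & rel_pm == "greater") ~ "low_parent_dominance",
    rel_pm != "equal" & rel_mid == "equal" ~ "additive",
    TRUE ~ "other_non_additive")
}

# floored means + variance for a derived quantity (mid-parent) on log2 scale
wald_log2_p <- function(num, var_num, den, var_den) {
  ln2sq <- log(2)^2
  se <- sqrt(var_num / (num^2 * ln2sq) + var_den / (den^2 * ln2sq))
  stat <- (log2(num) - log2(den)) / se
  list(est = log2(num) - log2(den), se = se, stat = stat,
       p = 2 * pnorm(-abs(stat)))
}

#' Trio comparison calls on expression
#'
#' Runs the three pairwise negative-binomial Wald tests (hybrid vs paternal,
#' hybrid vs maternal, paternal vs maternal) plus a Wald test of the hybrid
#' mean against the arithmetic mid-parent mean, all on shared size factors,
#' each BH-adjusted across genes within its own contrast family.
#'
#' @param counts Count tibble.
#' @param samples Sample sheet.
#' @param tissue Optional tissue restriction.
#' @param alpha Significance level used to derive relations.
#' @return A tibble with, per gene, estimate/padj/relation for the four
#'   contrasts (`hp`, `hm`, `pm`, `mid`).
#' @export
trio_calls_expression <- function(counts, samples, tissue = NULL, alpha = 0.05) {
  samples <- validate_sample_sheet(samples)
  ids <- lapply(setNames(species_roles, c("h", "p", "m")),
                resolve_group, samples = samples, tissue = tissue)
  if (any(lengths(ids) < 2L)) abort("each trio group needs >= 2 replicates.")
  all_ids <- unlist(ids, use.names = FALSE)
  sf <- size_factors(counts[, c("gene_id", all_ids)], pseudo_reference = TRUE)

  de_hp <- test_de(counts, samples, ids$p, ids$h, size_factors_df = sf)
  de_hm <- test_de(counts, samples, ids$m, ids$h, size_factors_df = sf)
  de_pm <- test_de(counts, samples, ids$m, ids$p, size_factors_df = sf)

  # mid-parent Wald on a joint three-group fit
  m <- counts_matrix(counts)[, all_ids, drop = FALSE]
  sfv <- setNames(sf$size_factor, sf$sample_id)[colnames(m)]
  norm <- sweep(m, 2, sfv, "/")
  groups <- list(h = seq_along(ids$h),
                 p = length(ids$h) + seq_along(ids$p),
                 m = length(ids$h) + length(ids$p) + seq_along(ids$m))
  fit <- nb_group_fit(norm, groups)
  mid <- (fit$means[, 2] + fit$means[, 3]) / 2
  var_mid <- (fit$var_means[, 2] + fit$var_means[, 3]) / 4
  k_par <- fit$k[2] + fit$k[3]
  w <- wald_log2_p(fit$means_floored[, 1], fit$var_means[, 1],
                   pmax(mid, 0.5 / k_par), var_mid)
  p_mid <- w$p
  allzero <- fit$means[, 1] == 0 & mid == 0
  p_mid[allzero] <- 1
  est_mid <- w$est; est_mid[allzero] <- 0
  padj_mid <- bh_adjust(p_mid)

  tibble(gene_id = de_hp$gene_id,
         est_hp = de_hp$log2fc, padj_hp = de_hp$padj,
         rel_hp = pairwise_relation(de_hp$log2fc, de_hp$padj, alpha),
         est_hm = de_hm$log2fc, padj_hm = de_hm$padj,
         rel_hm = pairwise_relation(de_hm$log2fc, de_hm$padj, alpha),
         est_pm = de_pm$log2fc, padj_pm = de_pm$padj,
         rel_pm = pairwise_relation(de_pm$log2fc, de_pm$padj, alpha),
         est_mid = est_mid, padj_mid = padj_mid,
         rel_mid = pairwise_relation(est_mid, padj_mid, alpha))
}

#' Trio comparison calls on PSI
#'
#' Pairwise differential-splicing LRTs for the three trio contrasts plus a
#' 1-df LRT of the hybrid PSI against the fixed mid-parent PSI
#' `(psi_P + psi_M) / 2` evaluated on the hybrid samples.
#'
#' @param events Event tibble.
#' @param samples Sample sheet.
#' @param tissue Optional tissue restriction.
#' @param alpha Significance level for relations.
#' @param min_total Per-sample minimum junction count.
#' @return A tibble with, per event, estimate/padj/relation for `hp`, `hm`,
#'   `pm` and `mid` contrasts, plus `gene_id` and `testable`.
#' @export
trio_calls_psi <- function(events, samples, tissue = NULL, alpha = 0.05,
                           min_total = 10) {
  samples <- validate_sample_sheet(samples)
  events <- validate_splice_events(events)
  ids <- lapply(setNames(species_roles, c("h", "p", "m")),
                resolve_group, samples = samples, tissue = tissue)
  das_hp <- test_das(events, samples, ids$p, ids$h, min_total = min_total)
  das_hm <- test_das(events, samples, ids$m, ids$h, min_total = min_total)
  das_pm <- test_das(events, samples, ids$m, ids$p, min_total = min_total)

  # mid-parent LRT on the hybrid samples at fixed psi_mid
  totals <- function(grp_ids) {
    grp_ids <- intersect(grp_ids, event_sample_ids(events))
    I <- vapply(grp_ids, function(s) events[[paste0("I:", s)]],
                integer(nrow(events)))
    S <- vapply(grp_ids, function(s) events[[paste0("S:", s)]],
                integer(nrow(events)))
    if (nrow(events) == 1L) { I <- t(I); S <- t(S) }
    usable <- (I + S) >= min_total
    list(I = rowSums(I * usable), S = rowSums(S * usable),
         n = rowSums(usable))
  }
  th <- totals(ids$h); tp <- totals(ids$p); tm <- totals(ids$m)
  testable <- th$n >= 2L & tp$n >= 2L & tm$n >= 2L
  p_hat <- function(t) ifelse(t$I + t$S > 0, t$I / (t$I + t$S), NA_real_)
  lI <- events$len_inclusion; lS <- events$len_exclusion
  psi_h <- p_to_psi(p_hat(th), lI, lS)
  psi_mid <- (p_to_psi(p_hat(tp), lI, lS) + p_to_psi(p_hat(tm), lI, lS)) / 2
  # clamp the fixed null away from the boundary so its likelihood is finite
  psi_mid_c <- pmin(pmax(psi_mid, 1e-6), 1 - 1e-6)
  p_of_psi <- function(ps) ps * lI / (ps * lI + (1 - ps) * lS)
  ll_h <- binom_kernel(th$I, th$S, p_hat(th))
  ll_0 <- binom_kernel(th$I, th$S, p_of_psi(psi_mid_c))
  lrt <- pmax(2 * (ll_h - ll_0), 0)
  p_mid <- pchisq(lrt, df = 1, lower.tail = FALSE)
  est_mid <- psi_h - psi_mid
  p_mid[!testable] <- NA_real_; est_mid[!testable] <- NA_real_
  padj_mid <- rep(NA_real_, length(p_mid))
  if (any(testable)) padj_mid[testable] <- bh_adjust(p_mid[testable])

  rel_or_equal <- function(est, padj) {
    r <- pairwise_relation(ifelse(is.na(est), 0, est),
                           ifelse(is.na(padj), 1, padj), alpha)
    r
  }
  tibble(event_id = events$event_id, gene_id = events$gene_id,
         est_hp = das_hp$delta_psi, padj_hp = das_hp$padj,
         rel_hp = rel_or_equal(das_hp$delta_psi, das_hp$padj),
         est_hm = das_hm$delta_psi, padj_hm = das_hm$padj,
         rel_hm = rel_or_equal(das_hm$delta_psi, das_hm$padj),
         est_pm = das_pm$delta_psi, padj_pm = das_pm$padj,
         rel_pm = rel_or_equal(das_pm$delta_psi, das_pm$padj),
         est_mid = est_mid, padj_mid = padj_mid,
         rel_mid = rel_or_equal(est_mid, padj_mid),
         testable = testable & das_hp$testable & das_hm$testable & das_pm$testable)
}

#' Add gene-action modes to trio calls
#'
#' @param calls Tibble from [trio_calls_expression()] or [trio_calls_psi()].
#' @return `calls` with a `mode` column.
#' @export
classify_modes <- function(calls) {
  need <- c("rel_hp", "rel_hm", "rel_pm", "rel_mid")
  if (!all(need %in% names(calls))) {
    abort(sprintf("calls must contain columns: %s", paste(need, collapse = ", ")))
  }
  calls |>
    mutate(mode = classify_gene_action(.data$rel_hp, .data$rel_hm,
                                       .data$rel_pm, .data$rel_mid))
}

#' Summarize gene-action modes
#'
#' Counts and percentages per mode over the classified (non-conserved)
#' features, plus the aggregate counts conventionally reported: total
#' non-additive, over- plus under-dominance, and high- plus low-parent
#' dominance. Percentages are rounded half away from zero to one decimal.
#'
#' @param assignments A data frame with a `mode` column, or a character
#'   vector of modes.
#' @return A `mode_summary` tibble (`mode`, `n`, `pct`) with aggregate
#'   attributes; see [glance.mode_summary()].
#' @export
summarize_modes <- function(assignments) {
  modes <- if (is.data.frame(assignments)) assignments$mode else assignments
  bad <- setdiff(unique(modes), gene_action_modes)
  if (length(bad)) abort(sprintf("unknown mode(s): %s", paste(bad, collapse = ", ")))
  conserved_n <- sum(modes == "conserved")
  classified <- modes[modes != "conserved"]
  if (length(classified) == 0L) abort("no classified (non-conserved) features to summarize.")
  lev <- setdiff(gene_action_modes, "conserved")
  n <- vapply(lev, function(m) sum(classified == m), integer(1))
  out <- tibble(mode = lev, n = as.integer(n),
                pct = round_half_up(100 * n / length(classified), 1))
  structure(out,
            class = c("mode_summary", class(out)),
            total_classified = length(classified),
            conserved_n = conserved_n,
            non_additive_total = sum(n[lev != "additive"]),
            over_plus_under = sum(n[lev %in% c("over_dominance", "under_dominance")]),
            high_plus_low = sum(n[lev %in% c("high_parent_dominance", "low_parent_dominance")]))
}

#' @export
#' @method tidy mode_summary
#' @rdname summarize_modes
#' @param x A `mode_summary`.
#' @param ... Unused.
tidy.mode_summary <- function(x, ...) {
  as_tibble(unclass(x)[c("mode", "n", "pct")])
}

#' One-row aggregate view of a mode summary
#'
#' @param x A `mode_summary` from [summarize_modes()].
#' @param ... Unused.
#' @return A one-row tibble with `total_classified`, `conserved_n`,
#'   `non_additive_total`, `over_plus_under`, `high_plus_low`.
#' @export
#' @method glance mode_summary
glance.mode_summary <- function(x, ...) {
  tibble(total_classified = attr(x, "total_classified"),
         conserved_n = attr(x, "conserved_n"),
         non_additive_total = attr(x, "non_additive_total"),
         over_plus_under = attr(x, "over_plus_under"),
         high_plus_low = attr(x, "high_plus_low"))
}

#' Mode table across tissues and hybrids
#'
#' Reshapes per-(tissue, hybrid) mode counts into one row per stratum with
#' modes as columns in the conventional reporting order, plus the aggregate
#' totals.
#'
#' @param counts_long A data frame with columns `tissue`, `hybrid`, `mode`,
#'   `n`.
#' @return A tibble, one row per (tissue, hybrid).
#' @export
mode_table <- function(counts_long) {
  need <- c("tissue", "hybrid", "mode", "n")
  if (!is.data.frame(counts_long) || !all(need %in% names(counts_long)) ||
      nrow(counts_long) == 0L) {
    abort("counts_long must be a non-empty data frame with columns tissue, hybrid, mode, n.")
  }
  order_cols <- c("over_dominance", "high_parent_dominance", "additive",
                  "low_parent_dominance", "under_dominance", "other_non_additive")
  wide <- counts_long |>
    filter(.data$mode != "conserved") |>
    tidyr::pivot_wider(id_cols = c("tissue", "hybrid"), names_from = "mode",
                       values_from = "n", values_fill = 0L)
  for (mcol in setdiff(order_cols, names(wide))) wide[[mcol]] <- 0L
  wide |>
    select("tissue", "hybrid", dplyr::all_of(order_cols)) |>
    mutate(total_classified = rowSums(across(dplyr::all_of(order_cols))),
           non_additive_total = .data$total_classified - .data$additive,
           over_plus_under = .data$over_dominance + .data$under_dominance,
           high_plus_low = .data$high_parent_dominance + .data$low_parent_dominance)
}
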