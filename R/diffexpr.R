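# Self-contained two-group negative-binomial differential expression:
# median-of-ratios normalization, method-of-moments dispersion, Wald test,
# Benjamini-Hochberg FDR. A deliberately minimal test whose calibration is
# checked by simulation, not a reimplementation of any published package.

# tibble (gene_id + sample columns) -> integer matrix
counts_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), names(counts)[1L] == "gene_id")
  m <- as.matrix(counts[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$gene_id
  if (any(m < 0)) abort("counts must be non-negative.")
  m
}

# resolve a group selector (role name or explicit sample ids) to sample ids
resolve_group <- function(selector, samples, tissue = NULL) {
  sheet <- samples
  if (!is.null(tissue)) sheet <- sheet[sheet$tissue %in% tissue, , drop = FALSE]
  if (length(selector) == 1L && selector %in% species_roles) {
    ids <- sheet$sample_id[sheet$species_role == selector]
  } else {
    unknown <- setdiff(selector, sheet$sample_id)
    if (length(unknown)) {
      abort(sprintf("unknown sample id(s) in group selector: %s",
                    paste(unknown, collapse = ", ")))
    }
    ids <- selector
  }
  if (length(ids) == 0L) abort("group selector matched no samples.")
  ids
}

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median, over genes positive in all samples, of
#' its count divided by the gene's geometric mean across samples; factors are
#' rescaled to have geometric mean 1.
#'
#' @param counts Count tibble (first column `gene_id`).
#' @param pseudo_reference If `TRUE`, the per-gene reference is the geometric
#'   mean over the positive entries only, so samples with many zeros can
#'   still be normalized when no gene is positive everywhere.
#' @return A tibble with columns `sample_id` and `size_factor`.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  m <- counts_matrix(counts)
  if (ncol(m) < 2L) abort("need at least two samples to normalize.")
  if (pseudo_reference) {
    logm <- log(m); logm[!is.finite(logm)] <- NA
    ref <- exp(rowMeans(logm, na.rm = TRUE))
    keep <- rowSums(m > 0) > 0
  } else {
    keep <- rowSums(m > 0) == ncol(m)
    if (!any(keep)) {
      abort(paste("no gene has positive counts in every sample;",
                  "re-run with pseudo_reference = TRUE."))
    }
    ref <- exp(rowMeans(log(pmax(m, 1e-300))))
  }
  f <- vapply(seq_len(ncol(m)), function(j) {
    r <- m[keep, j] / ref[keep]
    median(r[is.finite(r) & r > 0])
  }, numeric(1))
  if (any(!is.finite(f) | f <= 0)) abort("size-factor computation failed for a sample.")
  f <- f / geometric_mean(f)
  tibble(sample_id = colnames(m), size_factor = f)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; order-preserving, monotone, clipped to `[0, 1]`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) abort("empty p-value vector.")
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!all(ok)) abort("p-values must lie in [0, 1].")
  p.adjust(pvals, method = "BH")
}

# per-group NB fit used by the Wald tests: group means, pooled MoM dispersion
# and the variance of each group mean on the normalized scale
nb_group_fit <- function(norm, groups) {
  k <- vapply(groups, length, integer(1))
  means <- vapply(groups, function(idx) rowMeans(norm[, idx, drop = FALSE]), numeric(nrow(norm)))
  rss <- 0
  for (g in seq_along(groups)) {
    rss <- rss + rowSums((norm[, groups[[g]], drop = FALSE] - means[, g])^2)
  }
  df <- sum(k) - length(groups)
  s2 <- rss / df
  mbar <- as.vector(means %*% k) / sum(k)
  alpha_raw <- ifelse(mbar > 0, (s2 - mbar) / mbar^2, NA_real_)
  pos <- alpha_raw[is.finite(alpha_raw) & alpha_raw > 0]
  alpha_fallback <- if (length(pos)) median(pos) else 1e-8
  # the pooled median acts as a floor, not just a fallback: with few
  # replicates the per-gene moment estimate is noisy downward, which would
  # anti-conservatively shrink the Wald standard error
  alpha <- ifelse(is.finite(alpha_raw), pmax(alpha_raw, alpha_fallback),
                  alpha_fallback)
  alpha <- pmax(alpha, 1e-8)
  # Var(mean_g) with Var(n_ij) = mu + alpha*mu^2 on the normalized scale,
  # so results are invariant to jointly rescaling a sample and its size
  # factor; zero means are floored at half a normalized count so degenerate
  # groups keep a finite test statistic
  var_mean <- function(g) {
    mu <- pmax(means[, g], 0.5 / k[g])
    (mu + alpha * mu^2) / k[g]
  }
  list(means = means, k = k, alpha = alpha,
       var_means = vapply(seq_along(groups), var_mean, numeric(nrow(norm))),
       means_floored = vapply(seq_along(groups), function(g)
         pmax(means[, g], 0.5 / k[g]), numeric(nrow(norm))))
}

#' Two-group negative-binomial Wald test
#'
#' Counts are normalized by median-of-ratios size factors; per-gene dispersion
#' comes from method-of-moments on pooled within-group residuals (median
#' fallback when non-positive); the Wald statistic is the log2 fold change of
#' fitted group means over its delta-method standard error, with a two-sided
#' normal p-value and BH adjustment across all genes in the comparison.
#' The reported `log2fc` uses a pseudocount of 0.5 for display stability;
#' the test statistic uses the fitted means themselves.
#'
#' @param counts Count tibble (first column `gene_id`).
#' @param samples Sample sheet matching the count columns.
#' @param group_a,group_b Role name (`hybrid`, `paternal_parent`,
#'   `maternal_parent`) or explicit sample-id vectors. Fold changes are
#'   `group_b` over `group_a`.
#' @param tissue Optional tissue to restrict the comparison to.
#' @param size_factors_df Optional precomputed size factors (tibble
#'   `sample_id`, `size_factor`); defaults to computing them from the two
#'   groups' samples.
#' @return A tibble with `gene_id`, `base_mean`, `log2fc`, `se_log2fc`,
#'   `stat`, `p`, `padj`.
#' @export
test_de <- function(counts, samples, group_a, group_b, tissue = NULL,
                    size_factors_df = NULL) {
  samples <- validate_sample_sheet(samples)
  ids_a <- resolve_group(group_a, samples, tissue)
  ids_b <- resolve_group(group_b, samples, tissue)
  if (length(ids_a) < 2L || length(ids_b) < 2L) {
    abort("each group needs at least 2 replicates.")
  }
  if (length(intersect(ids_a, ids_b))) abort("groups overlap.")
  m <- counts_matrix(counts)
  missing_ids <- setdiff(c(ids_a, ids_b), colnames(m))
  if (length(missing_ids)) {
    abort(sprintf("samples absent from count matrix: %s",
                  paste(missing_ids, collapse = ", ")))
  }
  sub <- m[, c(ids_a, ids_b), drop = FALSE]
  if (is.null(size_factors_df)) {
    size_factors_df <- size_factors(counts[, c("gene_id", c(ids_a, ids_b))],
                                    pseudo_reference = TRUE)
  }
  sf <- setNames(size_factors_df$size_factor, size_factors_df$sample_id)[colnames(sub)]
  if (anyNA(sf)) abort("size factors missing for some samples.")
  norm <- sweep(sub, 2, sf, "/")
  groups <- list(a = seq_along(ids_a), b = length(ids_a) + seq_along(ids_b))
  fit <- nb_group_fit(norm, groups)

  log2fc <- log2((fit$means[, 2] + 0.5) / (fit$means[, 1] + 0.5))
  ln2sq <- log(2)^2
  se <- sqrt(fit$var_means[, 1] / (fit$means_floored[, 1]^2 * ln2sq) +
             fit$var_means[, 2] / (fit$means_floored[, 2]^2 * ln2sq))
  stat <- (log2(fit$means_floored[, 2]) - log2(fit$means_floored[, 1])) / se
  p <- 2 * pnorm(-abs(stat))
  allzero <- fit$means[, 1] == 0 & fit$means[, 2] == 0
  log2fc[allzero] <- 0; stat[allzero] <- 0; p[allzero] <- 1
  se[allzero] <- NA_real_
  tibble(gene_id = rownames(sub), base_mean = unname(rowMeans(norm)),
         log2fc = unname(log2fc), se_log2fc = unname(se),
         stat = unname(stat), p = unname(p), padj = unname(bh_adjust(p)))
}

#' Call differentially expressed genes
#'
#' A gene is `up` when `padj < alpha` and `log2fc > min_abs_log2fc`, `down`
#' when `padj < alpha` and `log2fc < -min_abs_log2fc`, otherwise `ns`.
#' Both inequalities are strict, following the usual printed rule
#' (adjusted p below 0.05, |log2 fold change| above 1).
#'
#' @param results Tibble from [test_de()].
#' @param alpha Adjusted-p cutoff.
#' @param min_abs_log2fc Fold-change cutoff in log2 units.
#' @return `results` with a `direction` column (`up`/`down`/`ns`).
#' @export
call_degs <- function(results, alpha = 0.05, min_abs_log2fc = 1) {
  results |>
    mutate(direction = case_when(
      .data$padj < alpha & .data$log2fc > min_abs_log2fc ~ "up",
      .data$padj < alpha & .data$log2fc < -min_abs_log2fc ~ "down",
      TRUE ~ "ns"))
}
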