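# Sample-correlation clustering and the end-to-end pipeline orchestrator.

#' Pearson correlation and clustering of samples
#'
#' Expression input is normalized (median-of-ratios) and transformed to
#' `log2(normalized + 1)` before correlating; PSI input is used as-is with
#' pairwise-complete handling of missing values. Samples are clustered by
#' average-linkage hierarchical clustering on the distance `1 - r`.
#'
#' @param x A tibble whose first column is a feature id (`gene_id` or
#'   `event_id`) followed by one column per sample.
#' @param transform `"log2_normalized"` for counts, `"none"` for PSI or
#'   pre-transformed values.
#' @return A `sample_correlation` object: correlation matrix, `hclust` tree
#'   and leaf order. See [tidy.sample_correlation()].
#' @export
correlate_samples <- function(x, transform = c("log2_normalized", "none")) {
  transform <- match.arg(transform)
  m <- as.matrix(x[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(x[[1L]])
  if (ncol(m) < 2L) abort("need at least two samples.")
  if (transform == "log2_normalized") {
    sf <- size_factors(x, pseudo_reference = TRUE)
    m <- sweep(m, 2, setNames(sf$size_factor, sf$sample_id)[colnames(m)], "/")
    m <- log2(m + 1)
  }
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  flat <- !is.finite(sds) | sds == 0
  if (any(flat)) {
    abort(sprintf("sample(s) with zero variance, correlation undefined: %s",
                  paste(colnames(m)[flat], collapse = ", ")))
  }
  r <- cor(m, use = "pairwise.complete.obs", method = "pearson")
  if (anyNA(r)) abort("correlation undefined for some sample pair (no complete observations).")
  tree <- hclust(as.dist(1 - r), method = "average")
  structure(list(cor = r, hclust = tree, leaf_order = colnames(r)[tree$order]),
            class = "sample_correlation")
}

#' @export
print.sample_correlation <- function(x, ...) {
  cat(sprintf("sample correlation: %d samples, r in [%.3f, %.3f]\n",
              ncol(x$cor), min(x$cor), max(x$cor[upper.tri(x$cor)])))
  invisible(x)
}

#' Pairwise correlations in long form
#' @param x A `sample_correlation`.
#' @param ... Unused.
#' @return Tibble `sample_a`, `sample_b`, `r` (upper triangle).
#' @export
#' @method tidy sample_correlation
tidy.sample_correlation <- function(x, ...) {
  idx <- which(upper.tri(x$cor), arr.ind = TRUE)
  tibble(sample_a = rownames(x$cor)[idx[, 1L]],
         sample_b = colnames(x$cor)[idx[, 2L]],
         r = x$cor[idx])
}

#' @rdname tidy.sample_correlation
#' @export
#' @method glance sample_correlation
glance.sample_correlation <- function(x, ...) {
  tibble(n_samples = ncol(x$cor),
         min_r = min(x$cor),
         median_r = median(x$cor[upper.tri(x$cor)]))
}

#' Top split of the sample dendrogram
#'
#' Membership of the two clusters obtained by cutting the tree at its root,
#' used e.g. to check that samples separate by tissue before species.
#'
#' @param x A `sample_correlation`.
#' @return Tibble `sample_id`, `cluster` (1 or 2).
#' @export
top_split <- function(x) {
  stopifnot(inherits(x, "sample_correlation"))
  cl <- cutree(x$hclust, k = 2)
  tibble(sample_id = names(cl), cluster = unname(cl))
}

#' Pipeline configuration
#'
#' Inputs may be in-memory objects (tibbles from the readers or the
#' simulator) or file paths, which are read with the package's readers.
#'
#' @param counts Count tibble or TSV path.
#' @param samples Sample sheet tibble or TSV path.
#' @param events Event tibble or TSV path (optional).
#' @param reads Long-read tibble or BED12 path (optional).
#' @param gene_sets GMT tibble or path (optional).
#' @param outdir Output directory for per-stage TSVs and the run manifest;
#'   `NULL` keeps everything in memory.
#' @param alpha Significance level for DE calls and mode relations.
#' @param min_abs_log2fc DEG fold-change cutoff (log2).
#' @param min_dpsi,max_fdr DAS calling rule.
#' @param min_total Per-sample minimum junction count for PSI.
#' @param validation_mode,tolerance Long-read verification settings.
#' @param min_set_size Enrichment set-size floor.
#' @return A `trio_pipeline_config` list.
#' @export
trio_pipeline_config <- function(counts, samples, events = NULL, reads = NULL,
                                 gene_sets = NULL, outdir = NULL, alpha = 0.05,
                                 min_abs_log2fc = 1, min_dpsi = 0.10,
                                 max_fdr = 0.05, min_total = 10,
                                 validation_mode = "both_isoforms",
                                 tolerance = 10, min_set_size = 3) {
  assert_scalar_number(alpha, "alpha", 0, 1)
  assert_scalar_number(min_dpsi, "min_dpsi", 0, 1)
  assert_scalar_number(max_fdr, "max_fdr", 0, 1)
  for (nm in c("counts", "samples", "events", "reads", "gene_sets")) {
    obj <- get(nm)
    if (is.character(obj) && !file.exists(obj)) {
      abort(sprintf("input file for `%s` does not exist: %s", nm, obj))
    }
  }
  structure(list(counts = counts, samples = samples, events = events,
                 reads = reads, gene_sets = gene_sets, outdir = outdir,
                 alpha = alpha, min_abs_log2fc = min_abs_log2fc,
                 min_dpsi = min_dpsi, max_fdr = max_fdr, min_total = min_total,
                 validation_mode = validation_mode, tolerance = tolerance,
                 min_set_size = min_set_size),
            class = "trio_pipeline_config")
}

resolve_input <- function(obj, reader) {
  if (is.null(obj) || !is.character(obj)) obj else reader(obj)
}

#' Run the full trio heterosis pipeline
#'
#' Per tissue: three pairwise differential-expression tests with DEG calls,
#' expression gene-action classification with a mode summary, differential
#' splicing against each parent with DAS calls and gene counts, PSI
#' gene-action classification, long-read verification of the called events,
#' gene-set enrichment of the hybrid-vs-paternal DEGs, and sample-correlation
#' clustering on both expression and PSI. With `outdir` set, every stage is
#' written as TSV plus a JSON manifest of thresholds; outputs are
#' deterministic functions of the inputs.
#'
#' @param config A [trio_pipeline_config()].
#' @return A nested list of per-tissue results plus correlation reports,
#'   invisibly when `outdir` is set.
#' @export
run_trio_pipeline <- function(config) {
  stopifnot(inherits(config, "trio_pipeline_config"))
  counts <- resolve_input(config$counts, read_counts)
  samples <- validate_sample_sheet(resolve_input(config$samples, read_sample_sheet))
  events <- resolve_input(config$events, read_splice_events)
  reads <- resolve_input(config$reads, read_bed12)
  gene_sets <- resolve_input(config$gene_sets, read_gmt)

  contrasts <- list(
    hybrid_vs_paternal = c(a = "paternal_parent", b = "hybrid"),
    hybrid_vs_maternal = c(a = "maternal_parent", b = "hybrid"),
    paternal_vs_maternal = c(a = "maternal_parent", b = "paternal_parent"))

  per_tissue <- lapply(unique(samples$tissue), function(tis) {
    res <- list(tissue = tis)
    res$de <- lapply(contrasts, function(ct)
      call_degs(test_de(counts, samples, ct[["a"]], ct[["b"]], tissue = tis),
                alpha = config$alpha, min_abs_log2fc = config$min_abs_log2fc))
    res$deg_counts <- bind_rows(lapply(names(res$de), function(nm) {
      d <- res$de[[nm]]
      tibble(tissue = tis, contrast = nm,
             up = sum(d$direction == "up"), down = sum(d$direction == "down"))
    }))
    res$expr_modes <- classify_modes(
      trio_calls_expression(counts, samples, tissue = tis, alpha = config$alpha))
    res$expr_mode_summary <- summarize_modes(res$expr_modes)
    if (!is.null(events)) {
      res$das <- lapply(contrasts[1:2], function(ct)
        call_das(test_das(events, samples, ct[["a"]], ct[["b"]], tissue = tis,
                          min_total = config$min_total),
                 min_dpsi = config$min_dpsi, max_fdr = config$max_fdr))
      res$das_counts <- bind_rows(lapply(names(res$das), function(nm)
        tibble(tissue = tis, contrast = nm,
               n_events = sum(res$das[[nm]]$called),
               n_genes = length(das_genes(res$das[[nm]])))))
      res$psi_modes <- classify_modes(
        trio_calls_psi(events, samples, tissue = tis, alpha = config$alpha,
                       min_total = config$min_total))
      res$psi_mode_summary <- summarize_modes(res$psi_modes)
      if (!is.null(reads)) {
        res$validation <- lapply(res$das, function(d) {
          if (!any(d$called)) return(NULL)
          validate_long_reads(d, events, reads, mode = config$validation_mode,
                              tolerance = config$tolerance)
        })
      }
    }
    if (!is.null(gene_sets)) {
      degs <- res$de$hybrid_vs_paternal
      deg_ids <- degs$gene_id[degs$direction != "ns"]
      if (length(deg_ids)) {
        res$enrichment <- tryCatch(
          enrich_sets(deg_ids, gene_sets, universe = counts$gene_id,
                      min_set_size = config$min_set_size),
          error = function(e) NULL)
      }
    }
    res
  })
  names(per_tissue) <- unique(samples$tissue)

  out <- list(tissues = per_tissue,
              expr_correlation = correlate_samples(counts, "log2_normalized"))
  if (!is.null(events)) {
    psi <- psi_matrix(events, min_total = config$min_total)
    ok <- vapply(psi[, -1L, drop = FALSE], function(v)
      sum(!is.na(v)) >= 2 && stats::sd(v, na.rm = TRUE) > 0, logical(1))
    if (sum(ok) >= 2) {
      out$psi_correlation <- correlate_samples(psi[, c(TRUE, ok)], "none")
    }
  }
  out$mode_table <- mode_table(bind_rows(lapply(per_tissue, function(res)
    tidy.mode_summary(res$expr_mode_summary) |>
      mutate(tissue = res$tissue, hybrid = "hybrid"))))

  if (!is.null(config$outdir)) {
    write_pipeline_outputs(out, config)
    return(invisible(out))
  }
  out
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) readr::write_tsv(df, file.path(config$outdir, name),
                                            progress = FALSE)
  for (tis in names(out$tissues)) {
    res <- out$tissues[[tis]]
    for (nm in names(res$de)) wt(res$de[[nm]], sprintf("de_%s_%s.tsv", tis, nm))
    wt(res$deg_counts, sprintf("deg_counts_%s.tsv", tis))
    wt(res$expr_modes, sprintf("expr_modes_%s.tsv", tis))
    wt(tidy.mode_summary(res$expr_mode_summary), sprintf("expr_mode_summary_%s.tsv", tis))
    if (!is.null(res$das)) {
      for (nm in names(res$das)) wt(res$das[[nm]], sprintf("das_%s_%s.tsv", tis, nm))
      wt(res$das_counts, sprintf("das_counts_%s.tsv", tis))
      wt(res$psi_modes, sprintf("psi_modes_%s.tsv", tis))
      wt(tidy.mode_summary(res$psi_mode_summary), sprintf("psi_mode_summary_%s.tsv", tis))
    }
    if (!is.null(res$validation)) {
      for (nm in names(res$validation)) {
        v <- res$validation[[nm]]
        if (is.null(v)) next
        wt(glance.das_validation(v), sprintf("validation_%s_%s.tsv", tis, nm))
        wt(v$genes |> mutate(supporting_reads =
             map_chr(.data$supporting_reads, paste, collapse = ",")),
           sprintf("validation_genes_%s_%s.tsv", tis, nm))
      }
    }
    if (!is.null(res$enrichment)) wt(res$enrichment, sprintf("enrichment_%s.tsv", tis))
  }
  wt(out$mode_table, "mode_table.tsv")
  wt(tidy.sample_correlation(out$expr_correlation), "expr_correlation.tsv")
  if (!is.null(out$psi_correlation)) {
    wt(tidy.sample_correlation(out$psi_correlation), "psi_correlation.tsv")
  }
  manifest <- list(
    package = "triohet",
    package_version = as.character(utils::packageVersion("triohet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    thresholds = config[c("alpha", "min_abs_log2fc", "min_dpsi", "max_fdr",
                          "min_total", "validation_mode", "tolerance",
                          "min_set_size")])
  jsonlite::write_json(manifest, file.path(config$outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$outdir)
}
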