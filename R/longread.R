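# Verification of called splicing events against long-read alignments.
# A read supports an isoform when its intron junctions, restricted to the
# event's span, coincide with the isoform chain's junctions within a small
# boundary tolerance (long reads carry alignment noise at splice sites).

#' Genomic span of splice events
#'
#' The interval from the smallest block start to the largest block end over
#' both isoform chains, 0-based half-open.
#'
#' @param events Event tibble.
#' @return A tibble: `event_id`, `chrom`, `strand`, `span_start`, `span_end`.
#' @export
event_span <- function(events) {
  tibble(event_id = events$event_id, chrom = events$chrom, strand = events$strand,
         span_start = map2_int(events$inclusion_chain, events$exclusion_chain,
                               function(a, b) min(a[, 1L], b[, 1L])),
         span_end = map2_int(events$inclusion_chain, events$exclusion_chain,
                             function(a, b) max(a[, 2L], b[, 2L])))
}

# read junctions whose gap overlaps [span_start, span_end)
junctions_in_span <- function(blocks, span_start, span_end) {
  j <- chain_junctions(blocks)
  if (nrow(j) == 0L) return(j)
  keep <- j[, 2L] > span_start & j[, 1L] < span_end
  j[keep, , drop = FALSE]
}

#' Does a long read support an isoform chain?
#'
#' `TRUE` when the read's intron junctions inside the event span equal the
#' chain's junctions, each boundary within `tolerance` bases. A chain with
#' no junctions inside the span (e.g. the retained form of an RI event)
#' matches when the read has one block fully covering the span with no
#' junction inside it.
#'
#' @param read_blocks Exon-block matrix of the read.
#' @param chain Exon-block matrix of the isoform.
#' @param span_start,span_end Event span (0-based half-open). Defaults to
#'   the chain's own extent.
#' @param tolerance Maximum per-boundary discrepancy in bases.
#' @return A single logical.
#' @export
chain_matches <- function(read_blocks, chain, span_start = NULL, span_end = NULL,
                          tolerance = 10) {
  span_start <- span_start %||% min(chain[, 1L])
  span_end <- span_end %||% max(chain[, 2L])
  cj <- junctions_in_span(chain, span_start, span_end)
  rj <- junctions_in_span(read_blocks, span_start, span_end)
  if (nrow(cj) == 0L) {
    # junction-free form: need one read block covering the whole span
    covering <- read_blocks[, 1L] <= span_start & read_blocks[, 2L] >= span_end
    return(any(covering) && nrow(rj) == 0L)
  }
  if (nrow(rj) != nrow(cj)) return(FALSE)
  all(abs(rj - cj) <= tolerance)
}

#' Validate called splicing events against long reads
#'
#' A gene is *covered* when at least one read (same chromosome and strand)
#' overlaps the span of one of its called events, and *verified* when for at
#' least one called event the required isoform chains are each supported by
#' at least one read: both inclusion and exclusion under
#' `mode = "both_isoforms"` (the default, since a differential event claims
#' two expressed forms), either one under `mode = "any_isoform"`.
#'
#' @param das_results Tibble from [call_das()] (needs `event_id`, `gene_id`,
#'   `called`).
#' @param events Event tibble with isoform chains.
#' @param reads Long-read tibble from [read_bed12()] or
#'   [simulate_long_reads()].
#' @param mode `"both_isoforms"` or `"any_isoform"`.
#' @param tolerance Junction-boundary tolerance in bases.
#' @return A `das_validation` object; see [tidy.das_validation()] and
#'   [glance.das_validation()].
#' @export
validate_long_reads <- function(das_results, events, reads,
                                mode = c("both_isoforms", "any_isoform"),
                                tolerance = 10) {
  mode <- match.arg(mode)
  if (!"called" %in% names(das_results)) abort("run call_das() first.")
  called_ids <- das_results$event_id[das_results$called]
  ev <- events[events$event_id %in% called_ids, , drop = FALSE]
  spans <- event_span(ev)
  read_span <- if (nrow(reads)) t(vapply(reads$blocks, function(b)
    c(min(b[, 1L]), max(b[, 2L])), numeric(2))) else matrix(numeric(0), ncol = 2)

  per_event <- map(seq_len(nrow(ev)), function(i) {
    hit <- which(reads$chrom == spans$chrom[i] & reads$strand == spans$strand[i] &
                 read_span[, 1L] < spans$span_end[i] &
                 read_span[, 2L] > spans$span_start[i])
    if (length(hit) == 0L) {
      return(list(covered = FALSE, incl = FALSE, excl = FALSE, support = character(0)))
    }
    m_incl <- map_lgl(hit, function(r) chain_matches(
      reads$blocks[[r]], ev$inclusion_chain[[i]],
      spans$span_start[i], spans$span_end[i], tolerance))
    m_excl <- map_lgl(hit, function(r) chain_matches(
      reads$blocks[[r]], ev$exclusion_chain[[i]],
      spans$span_start[i], spans$span_end[i], tolerance))
    list(covered = TRUE, incl = any(m_incl), excl = any(m_excl),
         support = reads$read_id[hit[m_incl | m_excl]])
  })
  ev_verified <- map_lgl(per_event, function(e)
    if (mode == "both_isoforms") e$incl && e$excl else e$incl || e$excl)
  detail <- tibble(event_id = ev$event_id, gene_id = ev$gene_id,
                   covered = map_lgl(per_event, "covered"),
                   verified = ev_verified,
                   supporting_reads = map(per_event, "support"))
  genes <- detail |>
    group_by(.data$gene_id) |>
    summarise(covered = any(.data$covered), verified = any(.data$verified),
              n_called_events = n(),
              supporting_reads = list(unique(unlist(.data$supporting_reads))),
              .groups = "drop")
  n_cov <- sum(genes$covered); n_ver <- sum(genes$verified)
  if (n_cov == 0L) {
    warn("no DAS gene is covered by any long read; verification percentage undefined.")
  }
  pct <- if (n_cov == 0L) NA_real_ else verification_rate(n_cov, n_ver)
  structure(list(genes = genes, events = detail, mode = mode,
                 n_das_genes = nrow(genes), covered = n_cov, verified = n_ver,
                 pct_verified_of_covered = pct),
            class = "das_validation")
}

#' Verification percentage
#'
#' `round(100 * verified / covered)`, rounded half away from zero to match
#' integer-percent reporting; `NA` (with a warning) when nothing is covered.
#'
#' @param covered,verified Gene counts.
#' @return Integer percent, or `NA` when `covered` is 0.
#' @export
verification_rate <- function(covered, verified) {
  if (covered == 0) {
    warn("verification rate undefined: no covered genes.")
    return(NA_real_)
  }
  if (verified > covered) abort("verified cannot exceed covered.")
  round_half_up(100 * verified / covered)
}

#' @export
print.das_validation <- function(x, ...) {
  cat(sprintf("DAS long-read validation (%s): %d genes, %d covered, %d verified (%s%%)\n",
              x$mode, x$n_das_genes, x$covered, x$verified,
              ifelse(is.na(x$pct_verified_of_covered), "NA",
                     format(x$pct_verified_of_covered))))
  invisible(x)
}

#' Per-gene validation detail
#' @param x A `das_validation`.
#' @param ... Unused.
#' @return Tibble with one row per DAS gene.
#' @export
#' @method tidy das_validation
tidy.das_validation <- function(x, ...) x$genes

#' One-row validation summary
#' @param x A `das_validation`.
#' @param ... Unused.
#' @return Tibble with `n_das_genes`, `covered`, `verified`,
#'   `pct_verified_of_covered`.
#' @export
#' @method glance das_validation
glance.das_validation <- function(x, ...) {
  tibble(n_das_genes = x$n_das_genes, covered = x$covered,
         verified = x$verified,
         pct_verified_of_covered = x$pct_verified_of_covered)
}
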