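# Readers and writers for the tabular formats the pipeline exchanges:
# gene-count TSVs, sample sheets, splice-event tables, BED12 long-read
# alignments and GMT gene sets. All genomic coordinates are 0-based
# half-open, matching BED semantics, both on disk and in memory.

#' Read a gene-by-sample count table
#'
#' The file is tab-separated with gene identifiers in the first column and one
#' column of non-negative integer counts per sample. Duplicate gene or sample
#' identifiers and non-integer cells are errors.
#'
#' @param path Path to a TSV file.
#' @return A tibble whose first column is `gene_id` followed by one integer
#'   column per sample.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        name_repair = "minimal", progress = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    abort("count table must have a gene-id column, at least one sample column and at least one row.")
  }
  sample_ids <- names(df)[-1L]
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("duplicate sample id(s) in count table header: %s",
                  paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  gene_id <- df[[1L]]
  if (anyDuplicated(gene_id)) {
    abort(sprintf("duplicate gene id(s) in count table: %s",
                  paste(unique(gene_id[duplicated(gene_id)]), collapse = ", ")))
  }
  counts <- map(seq_along(sample_ids), function(j) {
    x <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(x) | x < 0 | x != floor(x))
    if (length(bad)) {
      abort(sprintf("non-integer or negative count '%s' at row %d (gene %s), column '%s'.",
                    df[[j + 1L]][bad[1L]], bad[1L], gene_id[bad[1L]], sample_ids[j]))
    }
    as.integer(x)
  })
  out <- tibble(gene_id = gene_id)
  for (j in seq_along(sample_ids)) out[[sample_ids[j]]] <- counts[[j]]
  out
}

#' Write a count table
#'
#' @param counts A tibble as returned by [read_counts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  stopifnot(is.data.frame(counts), names(counts)[1L] == "gene_id")
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Required columns: `sample_id`, `species_role` (one of `hybrid`,
#' `paternal_parent`, `maternal_parent`), `species_name`, `tissue`,
#' `replicate` (positive integer).
#'
#' @param path Path to a TSV file.
#' @return A validated tibble of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param samples A data frame to validate in place of a file.
#' @export
validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "species_role", "species_name", "tissue", "replicate")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    abort(sprintf("sample sheet is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(samples) == 0L) abort("sample sheet has no rows.")
  if (anyDuplicated(samples$sample_id)) {
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", ")))
  }
  bad_role <- setdiff(unique(samples$species_role), species_roles)
  if (length(bad_role)) {
    abort(sprintf("unknown species_role '%s'; allowed values are: %s",
                  bad_role[1L], paste(species_roles, collapse = ", ")))
  }
  rep_num <- suppressWarnings(as.numeric(samples$replicate))
  if (any(is.na(rep_num) | rep_num < 1 | rep_num != floor(rep_num))) {
    abort("`replicate` must be a positive integer for every sample.")
  }
  as_tibble(samples) |> mutate(replicate = as.integer(rep_num))
}

#' Write a sample sheet
#' @param samples Sample-sheet tibble.
#' @param path Output TSV path.
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_tsv(validate_sample_sheet(samples), path, progress = FALSE)
  invisible(path)
}

# --- splice events -----------------------------------------------------------

#' Read a splice-event table
#'
#' One row per alternative-splicing event. Fixed columns: `event_id`,
#' `gene_id`, `event_type` (SE/MXE/A5SS/A3SS/RI), `chrom`, `strand`,
#' `inclusion_chain` and `exclusion_chain` (comma-separated `start-end`
#' exon blocks, 0-based half-open), `len_inclusion`, `len_exclusion`
#' (positive effective lengths). Per-sample inclusion and skipping junction
#' counts live in columns named `I:<sample_id>` and `S:<sample_id>`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with list-columns `inclusion_chain`/`exclusion_chain`
#'   holding block matrices, plus the `I:`/`S:` count columns.
#' @export
read_splice_events <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        name_repair = "minimal", progress = FALSE)
  fixed <- c("event_id", "gene_id", "event_type", "chrom", "strand",
             "inclusion_chain", "exclusion_chain", "len_inclusion", "len_exclusion")
  missing_cols <- setdiff(fixed, names(df))
  if (length(missing_cols)) {
    abort(sprintf("event table is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) abort("event table has no rows.")
  out <- tibble(
    event_id = df$event_id, gene_id = df$gene_id, event_type = df$event_type,
    chrom = df$chrom, strand = df$strand,
    inclusion_chain = map(seq_len(nrow(df)), function(i)
      string_to_chain(df$inclusion_chain[i], sprintf("inclusion_chain of %s", df$event_id[i]))),
    exclusion_chain = map(seq_len(nrow(df)), function(i)
      string_to_chain(df$exclusion_chain[i], sprintf("exclusion_chain of %s", df$event_id[i]))),
    len_inclusion = as.numeric(df$len_inclusion),
    len_exclusion = as.numeric(df$len_exclusion)
  )
  cnt_cols <- grep("^[IS]:", names(df), value = TRUE)
  for (cc in cnt_cols) {
    x <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(x) | x < 0 | x != floor(x))
    if (length(bad)) {
      abort(sprintf("non-integer or negative count '%s' in column '%s', row %d.",
                    df[[cc]][bad[1L]], cc, bad[1L]))
    }
    out[[cc]] <- as.integer(x)
  }
  validate_splice_events(out)
}

#' @rdname read_splice_events
#' @param events An in-memory event tibble to validate.
#' @export
validate_splice_events <- function(events) {
  if (anyDuplicated(events$event_id)) {
    abort(sprintf("duplicate event id(s): %s",
                  paste(unique(events$event_id[duplicated(events$event_id)]), collapse = ", ")))
  }
  bad_type <- setdiff(unique(events$event_type), splice_event_types)
  if (length(bad_type)) {
    abort(sprintf("unknown event_type '%s'; allowed: %s",
                  bad_type[1L], paste(splice_event_types, collapse = ", ")))
  }
  if (!all(events$strand %in% c("+", "-"))) abort("strand must be '+' or '-'.")
  if (any(!is.finite(events$len_inclusion)) || any(events$len_inclusion < 1) ||
      any(!is.finite(events$len_exclusion)) || any(events$len_exclusion < 1)) {
    abort("effective lengths len_inclusion/len_exclusion must be >= 1.")
  }
  for (i in seq_len(nrow(events))) {
    validate_chain(events$inclusion_chain[[i]],
                   sprintf("inclusion_chain of %s", events$event_id[i]))
    validate_chain(events$exclusion_chain[[i]],
                   sprintf("exclusion_chain of %s", events$event_id[i]))
  }
  i_samples <- sub("^I:", "", grep("^I:", names(events), value = TRUE))
  s_samples <- sub("^S:", "", grep("^S:", names(events), value = TRUE))
  if (!setequal(i_samples, s_samples)) {
    abort("I: and S: count columns must cover the same samples.")
  }
  as_tibble(events)
}

#' Write a splice-event table
#' @param events Event tibble as returned by [read_splice_events()] or
#'   [simulate_splice_events()].
#' @param path Output TSV path.
#' @export
write_splice_events <- function(events, path) {
  events <- validate_splice_events(events)
  flat <- events |>
    mutate(inclusion_chain = map_chr(.data$inclusion_chain, chain_to_string),
           exclusion_chain = map_chr(.data$exclusion_chain, chain_to_string))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

# sample ids covered by an event table's count columns
event_sample_ids <- function(events) sub("^I:", "", grep("^I:", names(events), value = TRUE))

# long view of the per-sample counts: event_id, sample_id, inclusion, skipping
event_counts_long <- function(events) {
  ids <- event_sample_ids(events)
  bind_rows(lapply(ids, function(s) {
    tibble(event_id = events$event_id, sample_id = s,
           inclusion = events[[paste0("I:", s)]],
           skipping = events[[paste0("S:", s)]])
  }))
}

# --- BED12 -------------------------------------------------------------------

#' Read long-read alignments from a BED12 file
#'
#' Standard BED12: the block columns (`blockCount`, `blockSizes`,
#' `blockStarts`) must be mutually consistent; a trailing comma in the list
#' columns is accepted, as commonly written. Coordinates are 0-based
#' half-open.
#'
#' @param path Path to a BED12 file.
#' @return A tibble with columns `read_id`, `chrom`, `strand` and a
#'   list-column `blocks` of exon-block matrices.
#' @export
read_bed12 <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort("BED12 file is empty.")
  rows <- map(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) {
      abort(sprintf("line %d: expected 12 BED columns, found %d.", i, length(f)))
    }
    chrom_start <- as.integer(f[2]); chrom_end <- as.integer(f[3])
    n_blocks <- as.integer(f[10])
    sizes <- as.integer(strsplit(sub(",$", "", f[11]), ",", fixed = TRUE)[[1]])
    starts <- as.integer(strsplit(sub(",$", "", f[12]), ",", fixed = TRUE)[[1]])
    if (anyNA(c(chrom_start, chrom_end, n_blocks, sizes, starts))) {
      abort(sprintf("line %d: non-numeric BED12 coordinate fields.", i))
    }
    if (length(sizes) != n_blocks || length(starts) != n_blocks) {
      abort(sprintf("line %d: blockCount is %d but blockSizes/blockStarts list %d/%d entries.",
                    i, n_blocks, length(sizes), length(starts)))
    }
    if (!f[6] %in% c("+", "-")) {
      abort(sprintf("line %d: strand must be '+' or '-'.", i))
    }
    blocks <- new_chain(chrom_start + starts, chrom_start + starts + sizes)
    if (max(blocks[, 2L]) > chrom_end) {
      abort(sprintf("line %d: blocks extend past chromEnd.", i))
    }
    tibble(read_id = f[4], chrom = f[1], strand = f[6], blocks = list(blocks))
  })
  bind_rows(rows)
}

#' Write long-read alignments as BED12
#' @param reads Tibble as returned by [read_bed12()] or [simulate_long_reads()].
#' @param path Output BED path.
#' @export
write_bed12 <- function(reads, path) {
  lines <- map_chr(seq_len(nrow(reads)), function(i) {
    b <- reads$blocks[[i]]
    cs <- b[1L, 1L]; ce <- b[nrow(b), 2L]
    paste(reads$chrom[i], cs, ce, reads$read_id[i], 0L, reads$strand[i],
          cs, ce, "0,0,0", nrow(b),
          paste0(paste(b[, 2L] - b[, 1L], collapse = ","), ","),
          paste0(paste(b[, 1L] - cs, collapse = ","), ","),
          sep = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

# --- GMT ---------------------------------------------------------------------

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (set id, description, then member genes,
#'   tab-separated).
#' @return A tibble with columns `set_id` and list-column `genes`.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0L) abort("GMT file contains no gene sets.")
  tibble(set_id = names(sets), genes = unname(map(sets, unique)))
}
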