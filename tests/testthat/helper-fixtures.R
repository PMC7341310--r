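# In-code fixtures shared across test files.

# minimal sample sheet: one tissue, k replicates per trio role
tiny_samples <- function(k = 2, tissue = "muscle") {
  roles <- c("hybrid", "paternal_parent", "maternal_parent")
  species <- c(hybrid = "mule", paternal_parent = "donkey", maternal_parent = "horse")
  tibble::tibble(
    sample_id = as.vector(vapply(roles, function(r)
      sprintf("%s_%s_%d", tissue, substr(r, 1, 3), seq_len(k)), character(k))),
    species_role = rep(roles, each = k),
    species_name = species[rep(roles, each = k)],
    tissue = tissue,
    replicate = rep(seq_len(k), times = 3))
}

# count tibble from a plain matrix
counts_tbl <- function(m, gene_ids = sprintf("g%03d", seq_len(nrow(m))),
                       sample_ids = sprintf("s%d", seq_len(ncol(m)))) {
  out <- tibble::tibble(gene_id = gene_ids)
  for (j in seq_len(ncol(m))) out[[sample_ids[j]]] <- as.integer(m[, j])
  out
}

# one skipped-exon event with per-sample I/S counts
make_se_event <- function(I, S, lI = 1, lS = 1, sample_ids = names(I),
                          event_id = "ev1", gene_id = "gA", offset = 1000L) {
  ev <- tibble::tibble(
    event_id = event_id, gene_id = gene_id, event_type = "SE",
    chrom = "chrT", strand = "+",
    inclusion_chain = list(cbind(start = offset + c(0L, 500L, 900L),
                                 end = offset + c(200L, 600L, 1100L))),
    exclusion_chain = list(cbind(start = offset + c(0L, 900L),
                                 end = offset + c(200L, 1100L))),
    len_inclusion = lI, len_exclusion = lS)
  for (s in sample_ids) {
    ev[[paste0("I:", s)]] <- as.integer(I[[s]])
    ev[[paste0("S:", s)]] <- as.integer(S[[s]])
  }
  ev
}

# sample sheet whose 6 samples are a 3v3 two-group layout (parents only)
# is just tiny_samples(3); helpers below name the role groups
role_ids <- function(samples, role) samples$sample_id[samples$species_role == role]
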