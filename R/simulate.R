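# Synthetic trio datasets with planted ground truth. The generator emulates
# the hybrid/paternal/maternal design: negative-binomial gene counts whose
# group means encode a planted gene-action mode, binomial inclusion/skipping
# junction counts around planted group-wise PSI, and long reads that copy an
# event's inclusion or exclusion intron chain.

#' Configuration for the trio simulator
#'
#' @param n_genes Number of genes in the count matrix.
#' @param n_events Number of splice events.
#' @param replicates_per_group Biological replicates per (tissue, role) group.
#' @param tissues Character vector of tissue names.
#' @param mode_proportions Named probabilities over the plantable gene-action
#'   modes (`conserved`, `additive`, `high_parent_dominance`,
#'   `low_parent_dominance`, `over_dominance`, `under_dominance`); must sum
#'   to 1.
#' @param effect_size_log2 Planted effect size in log2 units: the parental
#'   difference for non-conserved genes, and the margin by which an
#'   over-/under-dominant hybrid exceeds/undershoots the extreme parent.
#' @param baseline_log_mean Length-2 vector `(meanlog, sdlog)` of the
#'   log-normal distribution of baseline gene means.
#' @param dispersion Negative-binomial dispersion `alpha`
#'   (variance = mu + alpha * mu^2).
#' @param library_size_range Range of per-sample library-size multipliers,
#'   drawn log-uniformly.
#' @param psi_base_range Range of baseline PSI values.
#' @param delta_psi_planted Planted PSI difference for non-conserved events.
#' @param event_coverage_mean Mean of the Poisson total (inclusion + skipping)
#'   junction count per event and sample.
#' @param longread_depth Mean long reads per covered event (Poisson).
#' @param uncovered_fraction Fraction of events that receive no long reads.
#' @param event_types Event types to cycle through (subset of
#'   SE/MXE/A5SS/A3SS/RI).
#' @param tissue_effect_log2 SD of the per-gene log2 shift distinguishing
#'   tissues beyond the first.
#' @param seed Master seed; each generator stage uses a documented offset
#'   (`seed` for counts, `seed + 1` for events, `seed + 2` for long reads).
#' @return A validated `trio_sim_config` list.
#' @export
trio_sim_config <- function(n_genes = 2000, n_events = 500,
                            replicates_per_group = 3, tissues = "muscle",
                            mode_proportions = c(conserved = 0.4, additive = 0.12,
                                                 high_parent_dominance = 0.12,
                                                 low_parent_dominance = 0.12,
                                                 over_dominance = 0.12,
                                                 under_dominance = 0.12),
                            effect_size_log2 = 2, baseline_log_mean = c(5, 1.5),
                            dispersion = 0.1, library_size_range = c(0.7, 1.4),
                            psi_base_range = c(0.2, 0.8), delta_psi_planted = 0.3,
                            event_coverage_mean = 200, longread_depth = 5,
                            uncovered_fraction = 0.1, event_types = "SE",
                            tissue_effect_log2 = 1, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_events = as.integer(n_events),
              replicates_per_group = as.integer(replicates_per_group),
              tissues = as.character(tissues),
              mode_proportions = mode_proportions,
              effect_size_log2 = effect_size_log2,
              baseline_log_mean = baseline_log_mean, dispersion = dispersion,
              library_size_range = library_size_range,
              psi_base_range = psi_base_range,
              delta_psi_planted = delta_psi_planted,
              event_coverage_mean = event_coverage_mean,
              longread_depth = longread_depth,
              uncovered_fraction = uncovered_fraction,
              event_types = match.arg(event_types, splice_event_types, several.ok = TRUE),
              tissue_effect_log2 = tissue_effect_log2,
              seed = as.integer(seed))
  plantable <- setdiff(gene_action_modes, "other_non_additive")
  if (is.null(names(cfg$mode_proportions)) ||
      !all(names(cfg$mode_proportions) %in% plantable)) {
    abort(sprintf("mode_proportions must be named with plantable modes: %s",
                  paste(plantable, collapse = ", ")))
  }
  if (abs(sum(cfg$mode_proportions) - 1) > 1e-9) {
    abort("mode_proportions must sum to 1.")
  }
  assert_scalar_number(cfg$effect_size_log2, "effect_size_log2", lower = 0)
  assert_scalar_number(cfg$dispersion, "dispersion", lower = 1e-12)
  assert_scalar_number(cfg$delta_psi_planted, "delta_psi_planted", lower = 0)
  if (cfg$delta_psi_planted >= 1) abort("delta_psi_planted must be < 1.")
  assert_scalar_number(cfg$event_coverage_mean, "event_coverage_mean", lower = 0)
  assert_scalar_number(cfg$longread_depth, "longread_depth", lower = 0)
  assert_scalar_number(cfg$uncovered_fraction, "uncovered_fraction", 0, 1)
  if (any(cfg$library_size_range <= 0) || diff(cfg$library_size_range) < 0) {
    abort("library_size_range must be positive and increasing.")
  }
  if (cfg$n_genes < 1 || cfg$n_events < 0) abort("n_genes/n_events out of range.")
  structure(cfg, class = "trio_sim_config")
}

# deterministic sample sheet implied by a config
trio_sample_sheet <- function(config) {
  role_tag <- c(hybrid = "hyb", paternal_parent = "pat", maternal_parent = "mat")
  species <- c(hybrid = "mule", paternal_parent = "donkey", maternal_parent = "horse")
  tidyr::expand_grid(tissue = config$tissues, species_role = species_roles,
                     replicate = seq_len(config$replicates_per_group)) |>
    mutate(sample_id = sprintf("%s_%s_%d", .data$tissue,
                               role_tag[.data$species_role], .data$replicate),
           species_name = species[.data$species_role]) |>
    select("sample_id", "species_role", "species_name", "tissue", "replicate")
}

# planted group means for one gene: base mean, which parent is high, mode
plant_gene_means <- function(mode, base, parent_high, e) {
  up <- 2^(e / 2); dn <- 2^(-e / 2)
  if (mode == "conserved") return(c(h = base, p = base, m = base))
  p <- if (parent_high == "p") base * up else base * dn
  m <- if (parent_high == "p") base * dn else base * up
  h <- switch(mode,
    additive = (p + m) / 2,
    high_parent_dominance = max(p, m),
    low_parent_dominance = min(p, m),
    over_dominance = max(p, m) * 2^e,
    under_dominance = min(p, m) * 2^(-e))
  c(h = h, p = p, m = m)
}

#' Simulate a trio count matrix with planted gene-action modes
#'
#' Counts are negative-binomial with variance `mu + alpha * mu^2`; each
#' sample gets a log-uniform library-size multiplier. Group means per gene
#' follow the planted mode: additive hybrids sit at the arithmetic mid-parent,
#' dominant hybrids at one parent, over-/under-dominant hybrids beyond the
#' extreme parent by `effect_size_log2` log2 units.
#'
#' @param config A [trio_sim_config()].
#' @return A list with `counts` (tibble), `samples` (sample sheet) and
#'   `truth` (list with `genes` and `library_factors` tibbles).
#' @export
simulate_trio_counts <- function(config) {
  stopifnot(inherits(config, "trio_sim_config"))
  if (config$replicates_per_group < 2L) {
    abort("replicates_per_group must be >= 2 (downstream tests need replicates).")
  }
  set.seed(config$seed)
  samples <- trio_sample_sheet(config)
  gene_id <- sprintf("g%05d", seq_len(config$n_genes))
  modes <- sample(names(config$mode_proportions), config$n_genes,
                  replace = TRUE, prob = config$mode_proportions)
  base <- rlnorm(config$n_genes, config$baseline_log_mean[1], config$baseline_log_mean[2])
  parent_high <- sample(c("p", "m"), config$n_genes, replace = TRUE)
  mu <- t(vapply(seq_len(config$n_genes), function(g)
    plant_gene_means(modes[g], base[g], parent_high[g], config$effect_size_log2),
    numeric(3)))
  colnames(mu) <- c("h", "p", "m")

  n_tis <- length(config$tissues)
  tissue_shift <- matrix(0, config$n_genes, n_tis)
  if (n_tis > 1L) {
    tissue_shift[, -1L] <- rnorm(config$n_genes * (n_tis - 1L),
                                 sd = config$tissue_effect_log2)
  }
  lsr <- log(config$library_size_range)
  size_factor <- exp(runif(nrow(samples), lsr[1], lsr[2]))
  role_col <- c(hybrid = "h", paternal_parent = "p", maternal_parent = "m")

  cnt <- matrix(0L, config$n_genes, nrow(samples),
                dimnames = list(gene_id, samples$sample_id))
  truth_genes <- vector("list", n_tis)
  for (t in seq_len(n_tis)) {
    mu_t <- mu * 2^tissue_shift[, t]
    truth_genes[[t]] <- tibble(gene_id = gene_id, tissue = config$tissues[t],
                               mode = modes, mu_hybrid = mu_t[, "h"],
                               mu_paternal = mu_t[, "p"], mu_maternal = mu_t[, "m"])
    for (j in which(samples$tissue == config$tissues[t])) {
      mu_j <- mu_t[, role_col[[samples$species_role[j]]]] * size_factor[j]
      cnt[, j] <- rnbinom(config$n_genes, mu = mu_j, size = 1 / config$dispersion)
    }
  }
  counts <- bind_cols(tibble(gene_id = gene_id),
                      as_tibble(as.data.frame(cnt, check.names = FALSE)))
  list(counts = counts, samples = samples,
       truth = list(genes = bind_rows(truth_genes),
                    library_factors = tibble(sample_id = samples$sample_id,
                                             size_factor = size_factor)))
}

# synthetic but structurally valid isoform chains for one event
event_chains <- function(type, offset) {
  o <- offset
  switch(type,
    SE = list(incl = new_chain(c(o, o + 500, o + 900), c(o + 200, o + 600, o + 1100)),
              excl = new_chain(c(o, o + 900), c(o + 200, o + 1100)),
              lI = 100, lS = 50),
    RI = list(incl = new_chain(o, o + 700),
              excl = new_chain(c(o, o + 500), c(o + 200, o + 700)),
              lI = 100, lS = 50),
    A5SS = list(incl = new_chain(c(o, o + 600), c(o + 300, o + 800)),
                excl = new_chain(c(o, o + 600), c(o + 200, o + 800)),
                lI = 50, lS = 50),
    A3SS = list(incl = new_chain(c(o, o + 500), c(o + 200, o + 800)),
                excl = new_chain(c(o, o + 600), c(o + 200, o + 800)),
                lI = 50, lS = 50),
    MXE = list(incl = new_chain(c(o, o + 400, o + 1000), c(o + 200, o + 500, o + 1200)),
               excl = new_chain(c(o, o + 700, o + 1000), c(o + 200, o + 800, o + 1200)),
               lI = 100, lS = 100))
}

# planted group PSI for one event; base is drawn inside the mode's feasible
# window so psi stays within [margin, 1 - margin]
plant_event_psi <- function(mode, d, range, parent_high, margin = 0.02) {
  draw <- function(a, b) runif(1, min(a, b), max(a, b))
  # conserved events carry no planted difference, so the full range
  # (including the boundaries 0 and 1) is allowed
  if (mode == "conserved") {
    b <- draw(range[1], range[2]); return(c(h = b, p = b, m = b))
  }
  lo <- max(range[1], margin); hi <- min(range[2], 1 - margin)
  if (mode == "over_dominance") {
    b <- draw(lo, min(hi, 1 - margin - d)); return(c(h = b + d, p = b, m = b))
  }
  if (mode == "under_dominance") {
    b <- draw(max(lo, margin + d), hi); return(c(h = b - d, p = b, m = b))
  }
  # parents split by d around base for additive/dominance modes
  b <- draw(max(lo, margin + d / 2), min(hi, 1 - margin - d / 2))
  p <- if (parent_high == "p") b + d / 2 else b - d / 2
  m <- if (parent_high == "p") b - d / 2 else b + d / 2
  h <- switch(mode, additive = b, high_parent_dominance = max(p, m),
              low_parent_dominance = min(p, m))
  c(h = h, p = p, m = m)
}

#' Simulate splice events with planted group-wise PSI
#'
#' Per event and sample the total junction count is Poisson with mean
#' `event_coverage_mean`; the inclusion count is binomial with success
#' probability `psi * lI / (psi * lI + (1 - psi) * lS)`, folding the
#' effective lengths into the read-level probability.
#'
#' @param config A [trio_sim_config()].
#' @return A list with `events` (tibble with chains and `I:`/`S:` columns),
#'   `samples`, and `truth` (tibble of planted PSI and DAS flags).
#' @export
simulate_splice_events <- function(config) {
  stopifnot(inherits(config, "trio_sim_config"))
  if (config$replicates_per_group < 2L) {
    abort("replicates_per_group must be >= 2.")
  }
  set.seed(config$seed + 1L)
  samples <- trio_sample_sheet(config)
  n <- config$n_events
  d <- config$delta_psi_planted
  event_id <- sprintf("ev%05d", seq_len(n))
  gene_id <- sprintf("sg%05d", ceiling(seq_len(n) * 0.8))
  types <- rep(config$event_types, length.out = n)
  modes <- sample(names(config$mode_proportions), n, replace = TRUE,
                  prob = config$mode_proportions)
  parent_high <- sample(c("p", "m"), n, replace = TRUE)
  psi <- t(vapply(seq_len(n), function(i)
    plant_event_psi(modes[i], d, config$psi_base_range, parent_high[i]), numeric(3)))
  colnames(psi) <- c("h", "p", "m")

  chains <- map2(types, seq_len(n), function(ty, i) event_chains(ty, (i - 1L) * 10000L + 1000L))
  events <- tibble(event_id = event_id, gene_id = gene_id, event_type = types,
                   chrom = "chrSim", strand = rep(c("+", "-"), length.out = n),
                   inclusion_chain = map(chains, "incl"),
                   exclusion_chain = map(chains, "excl"),
                   len_inclusion = map_dbl(chains, "lI"),
                   len_exclusion = map_dbl(chains, "lS"))
  role_col <- c(hybrid = "h", paternal_parent = "p", maternal_parent = "m")
  for (j in seq_len(nrow(samples))) {
    ps <- psi[, role_col[[samples$species_role[j]]]]
    p_read <- ps * events$len_inclusion /
      (ps * events$len_inclusion + (1 - ps) * events$len_exclusion)
    tot <- rpois(n, config$event_coverage_mean)
    incl <- rbinom(n, tot, p_read)
    events[[paste0("I:", samples$sample_id[j])]] <- incl
    events[[paste0("S:", samples$sample_id[j])]] <- tot - incl
  }
  truth <- tibble(event_id = event_id, gene_id = gene_id, mode = modes,
                  psi_hybrid = psi[, "h"], psi_paternal = psi[, "p"],
                  psi_maternal = psi[, "m"],
                  das_vs_paternal = abs(psi[, "h"] - psi[, "p"]) >= d - 1e-9,
                  das_vs_maternal = abs(psi[, "h"] - psi[, "m"]) >= d - 1e-9)
  truth$das <- truth$das_vs_paternal | truth$das_vs_maternal
  list(events = validate_splice_events(events), samples = samples, truth = truth)
}

#' Simulate long reads supporting event isoforms
#'
#' Each covered event receives a Poisson number of reads; each read copies
#' the inclusion chain with probability equal to the hybrid's true PSI,
#' otherwise the exclusion chain. A configurable fraction of events is left
#' uncovered.
#'
#' @param events Event tibble from [simulate_splice_events()].
#' @param truth Matching truth tibble (needs `psi_hybrid`).
#' @param config A [trio_sim_config()].
#' @return A list with `reads` (BED12-style tibble) and `emitted`
#'   (per-event isoform read counts).
#' @export
simulate_long_reads <- function(events, truth, config) {
  stopifnot(inherits(config, "trio_sim_config"))
  set.seed(config$seed + 2L)
  n <- nrow(events)
  psi_h <- truth$psi_hybrid[match(events$event_id, truth$event_id)]
  covered <- runif(n) >= config$uncovered_fraction
  n_reads <- ifelse(covered, rpois(n, config$longread_depth), 0L)
  n_incl <- rbinom(n, n_reads, psi_h)
  rows <- map(seq_len(n), function(i) {
    if (n_reads[i] == 0L) return(NULL)
    k <- n_reads[i]
    isoform <- c(rep("inclusion", n_incl[i]), rep("exclusion", k - n_incl[i]))
    tibble(read_id = sprintf("lr_%s_%03d", events$event_id[i], seq_len(k)),
           chrom = events$chrom[i], strand = events$strand[i],
           blocks = map(isoform, function(iso)
             if (iso == "inclusion") events$inclusion_chain[[i]]
             else events$exclusion_chain[[i]]))
  })
  emitted <- tibble(event_id = events$event_id, n_reads = n_reads,
                    n_inclusion = n_incl, n_exclusion = n_reads - n_incl)
  list(reads = bind_rows(rows), emitted = emitted)
}

#' Simulate a complete trio dataset
#'
#' Runs the count, splice-event and long-read generators off one master seed
#' and returns every piece needed by [run_trio_pipeline()].
#'
#' @param config A [trio_sim_config()].
#' @return A list with `counts`, `samples`, `events`, `reads` and `truth`.
#' @export
simulate_trio_dataset <- function(config) {
  cnt <- simulate_trio_counts(config)
  ev <- simulate_splice_events(config)
  lr <- simulate_long_reads(ev$events, ev$truth, config)
  list(counts = cnt$counts, samples = cnt$samples, events = ev$events,
       reads = lr$reads,
       truth = list(genes = cnt$truth$genes,
                    library_factors = cnt$truth$library_factors,
                    events = ev$truth, reads_emitted = lr$emitted))
}
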