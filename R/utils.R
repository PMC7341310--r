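# Shared internal helpers: rounding, interval chains, input checks.

#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows bind_cols left_join inner_join across n case_when distinct pull
#'   rename row_number if_else
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map2 map2_int map_dbl map_int map_lgl map_chr
#' @importFrom stats median pnorm pchisq phyper p.adjust rnbinom rpois rbinom
#'   rlnorm runif rnorm cor hclust as.dist cutree setNames var quantile
NULL

# round() in R rounds half to even; tables in this field print half away
# from zero.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

geometric_mean <- function(x) exp(mean(log(x)))

#' @keywords internal
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# --- exon-block chains -------------------------------------------------------
# A chain is an integer matrix with columns start, end; 0-based half-open,
# sorted, non-overlapping (adjacency allowed). Used for splice-event isoform
# structures and BED12 read blocks alike.

new_chain <- function(starts, ends) {
  m <- cbind(start = as.integer(starts), end = as.integer(ends))
  validate_chain(m)
  m
}

validate_chain <- function(m, context = "chain") {
  if (!is.matrix(m) || ncol(m) != 2L || nrow(m) < 1L) {
    abort(sprintf("%s must be a two-column matrix with at least one block.", context))
  }
  if (any(m[, 2L] <= m[, 1L])) {
    abort(sprintf("%s has an empty or inverted block.", context))
  }
  if (nrow(m) > 1L) {
    if (is.unsorted(m[, 1L], strictly = TRUE)) {
      abort(sprintf("%s blocks are not sorted by start.", context))
    }
    if (any(m[-1L, 1L] < m[-nrow(m), 2L])) {
      abort(sprintf("%s blocks overlap.", context))
    }
  }
  invisible(m)
}

# "100-200,300-400" <-> chain matrix
chain_to_string <- function(m) paste(sprintf("%d-%d", m[, 1L], m[, 2L]), collapse = ",")

string_to_chain <- function(s, context = "chain") {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) abort(sprintf("%s string is empty.", context))
  se <- strsplit(parts, "-", fixed = TRUE)
  if (any(lengths(se) != 2L)) {
    abort(sprintf("%s string '%s' is not of the form start-end[,start-end...].", context, s))
  }
  se <- matrix(as.numeric(unlist(se)), ncol = 2L, byrow = TRUE)
  if (anyNA(se)) abort(sprintf("%s string '%s' contains non-numeric coordinates.", context, s))
  m <- cbind(start = as.integer(se[, 1L]), end = as.integer(se[, 2L]))
  validate_chain(m, context)
  m
}

# junctions of a chain: (end_i, start_{i+1}) pairs, as a k x 2 matrix (k >= 0)
chain_junctions <- function(m) {
  k <- nrow(m) - 1L
  if (k < 1L) return(matrix(integer(0), ncol = 2L))
  cbind(m[seq_len(k), 2L], m[seq_len(k) + 1L, 1L])
}

species_roles <- c("hybrid", "paternal_parent", "maternal_parent")

gene_action_modes <- c("additive", "high_parent_dominance", "low_parent_dominance",
                       "over_dominance", "under_dominance", "other_non_additive",
                       "conserved")

splice_event_types <- c("SE", "MXE", "A5SS", "A3SS", "RI")
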