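#' Collapse probe-level expression to one profile per gene
#'
#' Each probe's expression is averaged across samples; for genes interrogated
#' by several probes, the probe with the highest across-sample mean wins.
#' Probes with an empty symbol are dropped with a tally. If an alias table is
#' given, probe symbols are harmonized first (ambiguous and unmappable
#' symbols count as symbol-less). Profiles are returned sorted by decreasing
#' level, ties broken by ascending symbol for determinism.
#'
#' @param probe_table Data.frame from [read_expression_table()].
#' @param aliases Optional [alias_table] used to harmonize probe symbols.
#' @return A data.frame of class `transcript_profiles` with columns `gene`,
#'   `level` (mean of the winning probe's per-sample values), `probe_id`, and
#'   the per-sample value columns; attributes `n_dropped_symbolless` and
#'   `sample_cols`.
#' @export
collapse_probes <- function(probe_table, aliases = NULL) {
  sample_cols <- setdiff(names(probe_table), c("probe_id", "gene_symbol"))
  stopifnot(length(sample_cols) >= 1L)
  sym <- probe_table$gene_symbol
  if (!is.null(aliases)) {
    res <- resolve_symbols(sym, aliases)
    sym <- ifelse(is.na(res$approved), "", res$approved)
  }
  keep <- nzchar(sym)
  n_dropped <- sum(!keep)
  tab <- probe_table[keep, , drop = FALSE]
  sym <- sym[keep]
  level <- rowMeans(as.matrix(tab[, sample_cols, drop = FALSE]))
  # winner per gene: highest mean; ties by probe order for determinism
  ord <- order(sym, -level, tab$probe_id)
  first <- !duplicated(sym[ord])
  win <- ord[first]
  out <- data.frame(gene = sym[win], level = level[win],
                    probe_id = tab$probe_id[win],
                    stringsAsFactors = FALSE)
  out <- cbind(out, tab[win, sample_cols, drop = FALSE])
  out <- out[order(-out$level, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_symbolless") <- n_dropped
  attr(out, "sample_cols") <- sample_cols
  class(out) <- c("transcript_profiles", "data.frame")
  out
}

#' Mark which transcripts have a detected protein
#'
#' @param profiles A `transcript_profiles` data.frame sorted by decreasing
#'   level (as returned by [collapse_probes()]).
#' @param detected Character vector of detected gene symbols.
#' @return Integer vector of 0/1 indicators, parallel to `profiles` rows.
#' @export
mark_overlap <- function(profiles, detected) {
  as.integer(profiles$gene %in% detected)
}

#' Sliding-window overlap scores along the sorted transcript list
#'
#' Sums the detection indicator over windows of `w` consecutive genes in the
#' expression-sorted list, moving by `step` ranks. `step = 1` gives a true
#' sliding window; `step = w` gives tumbling blocks ("every consecutive 50
#' genes"); both readings are supported.
#'
#' @param indicator Integer 0/1 vector from [mark_overlap()].
#' @param w Window size (default 50).
#' @param step Step between window starts (default 1).
#' @return A data.frame with columns `start_rank` (1-based rank of the
#'   window's first gene) and `score` (detected count in the window,
#'   between 0 and `w`).
#' @export
window_scores <- function(indicator, w = 50L, step = 1L) {
  w <- as.integer(w); step <- as.integer(step)
  if (is.na(w) || w < 1L) stop("window size w must be a positive integer")
  if (is.na(step) || step < 1L) stop("step must be a positive integer")
  n <- length(indicator)
  if (w > n) stop("window size w (", w, ") exceeds list length (", n, ")")
  cs <- c(0L, cumsum(as.integer(indicator)))
  starts <- seq.int(1L, n - w + 1L, by = step)
  data.frame(start_rank = starts, score = cs[starts + w] - cs[starts])
}

#' Cumulative count of detected proteins along the sorted transcript list
#'
#' @param indicator Integer 0/1 vector from [mark_overlap()].
#' @return Integer vector of running sums (monotone non-decreasing; the last
#'   element is the total proteome-transcriptome overlap).
#' @export
cumulative_overlap <- function(indicator) {
  cumsum(as.integer(indicator))
}

#' Split profiled genes into high/low expression groups at a threshold
#'
#' The boundary belongs to the high group (level greater than or equal to the
#' threshold). Genes absent from the profiles form an implicit third class
#' when cross-tabulated (see [concordance_table()]).
#'
#' @param profiles A `transcript_profiles` data.frame.
#' @param threshold Expression threshold in array log-scale units
#'   (default 6.0).
#' @return List with character vectors `high` and `low`.
#' @export
expression_groups <- function(profiles, threshold = 6.0) {
  list(high = profiles$gene[profiles$level >= threshold],
       low = profiles$gene[profiles$level < threshold])
}

#' Array reproducibility ratio (max - min) / mean
#'
#' Spread of a gene's per-sample signals relative to its mean, used to judge
#' reproducibility across array samples (0 for a constant signal).
#'
#' @param per_sample Numeric vector of per-sample values with positive mean.
#' @return The dimensionless ratio.
#' @export
variation_ratio <- function(per_sample) {
  m <- mean(per_sample)
  if (!is.finite(m) || m <= 0) {
    stop("variation_ratio requires a positive mean; got ", m)
  }
  (max(per_sample) - min(per_sample)) / m
}

#' Variation ratios for every profile
#'
#' @param profiles A `transcript_profiles` data.frame.
#' @return Numeric vector, one ratio per profile row.
#' @export
variation_ratios <- function(profiles) {
  sample_cols <- attr(profiles, "sample_cols")
  stopifnot(!is.null(sample_cols))
  vals <- as.matrix(profiles[, sample_cols, drop = FALSE])
  apply(vals, 1L, variation_ratio)
}

#' Cross-tabulate gene sets against transcript expression groups
#'
#' Partitions each named set into three disjoint, exhaustive cells: high
#' expression (level >= threshold), low expression, and absent from the
#' transcript set. Percentages are computed against each set's size; genes
#' without a transcript profile are reported explicitly, never dropped.
#'
#' @param detected_sets Named list of character vectors of gene symbols.
#' @param profiles A `transcript_profiles` data.frame.
#' @param threshold Expression threshold (default 6.0).
#' @return A data.frame with one row per set: `set`, `n`, `high`, `low`,
#'   `absent` counts and `high_pct`, `low_pct`, `absent_pct`.
#' @export
concordance_table <- function(detected_sets, profiles, threshold = 6.0) {
  stopifnot(is.list(detected_sets), !is.null(names(detected_sets)))
  groups <- expression_groups(profiles, threshold)
  rows <- lapply(names(detected_sets), function(nm) {
    s <- unique(detected_sets[[nm]])
    n <- length(s)
    high <- sum(s %in% groups$high)
    low <- sum(s %in% groups$low)
    absent <- n - high - low
    data.frame(set = nm, n = n, high = high, low = low, absent = absent,
               high_pct = format_percent(high, n),
               low_pct = format_percent(low, n),
               absent_pct = format_percent(absent, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
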