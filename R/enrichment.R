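#' Exact hypergeometric probability mass
#'
#' Probability of drawing exactly `k` members of a `K`-gene set when `n`
#' genes are sampled without replacement from a universe of `N` genes:
#' `C(K,k) * C(N-K, n-k) / C(N,n)`. Computed with log binomial coefficients
#' so it is stable at realistic sizes (N ~ 10^4, n ~ 10^3).
#'
#' @param N Universe size (genes in the gene-set collection).
#' @param K Size of the gene set under test.
#' @param n Number of detected genes (within the universe).
#' @param k Overlap between the detected genes and the set; may be a vector.
#' @return Numeric vector of probabilities, parallel to `k`.
#' @export
hypergeom_pmf <- function(N, K, n, k) {
  check_hyper_counts(N, K, n, k)
  exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n))
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of an overlap at least as large as the one observed:
#' the probability mass summed from `P(X = k)` up the support. Terms beyond
#' `min(n, K)` are zero, so summation nominally "to n" is honored. The
#' result is clamped to `[0, 1]` against floating-point drift.
#'
#' @inheritParams hypergeom_pmf
#' @param k Observed overlap (scalar or vector).
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
enrichment_pvalue <- function(N, K, n, k) {
  check_hyper_counts(N, K, n, k)
  top <- min(n, K)
  vapply(k, function(ki) {
    if (ki > top) return(0)
    p <- sum(hypergeom_pmf(N, K, n, ki:top))
    min(max(p, 0), 1)
  }, numeric(1L))
}

# shared count validation; names the violated inequality
check_hyper_counts <- function(N, K, n, k) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L,
            length(k) >= 1L)
  if (any(c(N, K, n, k) < 0)) stop("counts must be non-negative")
  if (K > N) stop("K (", K, ") must not exceed N (", N, ")")
  if (n > N) stop("n (", n, ") must not exceed N (", N, ")")
  if (any(k > pmin(n, K))) {
    stop("k (", max(k), ") must not exceed min(n, K) = ", min(n, K))
  }
  if (any(n - k > N - K)) {
    stop("n - k (", max(n - k), ") must not exceed N - K = ", N - K,
         " (too few non-members to fill the draw)")
  }
  invisible(TRUE)
}

#' Over-representation analysis of detected genes against a collection
#'
#' For each gene set, counts the overlap with the detected genes and
#' computes the upper-tail hypergeometric p-value. The universe is the union
#' of all member genes of the collection; detected genes outside that
#' universe are excluded from `n` (and tallied), keeping the sampling model
#' internally consistent. No multiple-testing correction is applied by
#' default (selection is at raw p below the cutoff); Benjamini-Hochberg can
#' be switched on, in which case `enriched` uses the adjusted values.
#'
#' @param detected Character vector of detected (approved) gene symbols.
#' @param collection A [gene_set_collection].
#' @param cutoff Enrichment p-value cutoff (default 0.01, strict `<`).
#' @param correction `"none"` (default) or `"BH"`.
#' @return A data.frame of class `enrichment_results`, one row per set,
#'   sorted by p-value then name: `set_name`, `N`, `K`, `n`, `k`, `p_value`
#'   (plus `p_adjusted` under BH), `enriched`. Attributes: `n_detected_raw`
#'   (before universe restriction), `n_outside_universe`, `cutoff`,
#'   `correction`.
#' @export
enrich_collection <- function(detected, collection, cutoff = 0.01,
                              correction = c("none", "BH")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  correction <- match.arg(correction)
  if (length(collection$sets) == 0L) stop("empty gene-set collection")
  detected <- unique(detected)
  universe <- collection$universe
  in_univ <- detected[detected %in% universe]
  N <- length(universe)
  n <- length(in_univ)
  k <- vapply(collection$sets, function(members) sum(members %in% in_univ),
              integer(1L))
  K <- lengths(collection$sets)
  p <- vapply(seq_along(k), function(i)
    enrichment_pvalue(N, K[i], n, k[i]), numeric(1L))
  out <- data.frame(set_name = names(collection$sets),
                    N = N, K = K, n = n, k = k, p_value = p,
                    stringsAsFactors = FALSE)
  if (correction == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$enriched <- out$p_adjusted < cutoff
  } else {
    out$enriched <- out$p_value < cutoff
  }
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_detected_raw") <- length(detected)
  attr(out, "n_outside_universe") <- length(detected) - n
  attr(out, "cutoff") <- cutoff
  attr(out, "correction") <- correction
  class(out) <- c("enrichment_results", "data.frame")
  out
}

#' Expand enriched gene sets into a predicted proteome
#'
#' The union of all member genes of the sets flagged enriched: the
#' knowledge-based prediction of what else is expressed beyond the directly
#' detected proteins. Monotone in the cutoff - relaxing it never shrinks the
#' expansion.
#'
#' @param results An `enrichment_results` data.frame.
#' @param collection The [gene_set_collection] the results came from.
#' @return List of class `expanded_set`: `member_genes` (sorted union),
#'   `source_sets` (enriched set names), `n_sets`, `n_genes`.
#' @export
expand_enriched <- function(results, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  enriched_names <- results$set_name[results$enriched]
  members <- sort(unique(unlist(collection$sets[enriched_names],
                                use.names = FALSE)))
  structure(list(member_genes = members,
                 source_sets = enriched_names,
                 n_sets = length(enriched_names),
                 n_genes = length(members)),
            class = "expanded_set")
}

#' @export
print.expanded_set <- function(x, ...) {
  cat("Expanded target set: ", x$n_genes, " genes from ", x$n_sets,
      " enriched gene sets\n", sep = "")
  invisible(x)
}

#' Verify an expanded target set against reference gene sets
#'
#' For each reference set (own-run detections, replicate intersection /
#' twice / union, the all-runs proteome, transcript expression groups...)
#' reports the overlap with the expansion and the fraction of the expansion
#' it covers.
#'
#' @param expanded An `expanded_set`.
#' @param reference_sets Named list of character vectors of gene symbols.
#' @return A data.frame: `reference`, `n_reference`, `n_overlap`,
#'   `pct_of_expanded` (percentage of expanded genes found in the
#'   reference).
#' @export
verify_expansion <- function(expanded, reference_sets) {
  stopifnot(inherits(expanded, "expanded_set"),
            is.list(reference_sets), !is.null(names(reference_sets)))
  genes <- expanded$member_genes
  rows <- lapply(names(reference_sets), function(nm) {
    ref <- unique(reference_sets[[nm]])
    ov <- sum(genes %in% ref)
    data.frame(reference = nm, n_reference = length(ref), n_overlap = ov,
               pct_of_expanded = format_percent(ov, length(genes)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene sets enriched in every run
#'
#' @param per_run_results List (length >= 2) of `enrichment_results`
#'   data.frames, one per run.
#' @return Sorted character vector of set names enriched in all runs.
#' @export
common_pathways <- function(per_run_results) {
  stopifnot(is.list(per_run_results), length(per_run_results) >= 2L)
  enriched <- lapply(per_run_results, function(r) r$set_name[r$enriched])
  sort(Reduce(intersect, enriched))
}
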