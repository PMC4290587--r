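#' Build a detection matrix from per-run gene sets
#'
#' Presence/absence of each gene across replicate runs. Only genes detected
#' in at least one run appear (no all-zero rows); quantitative aggregation is
#' deliberately out of scope.
#'
#' @param run_genes Named list, one character vector of detected gene symbols
#'   per run.
#' @return An object of class `detection_matrix`: `genes` (sorted, unique),
#'   `runs`, and `present`, a logical genes x runs matrix.
#' @export
detection_matrix <- function(run_genes) {
  stopifnot(is.list(run_genes), length(run_genes) >= 1L,
            !is.null(names(run_genes)), !anyDuplicated(names(run_genes)))
  genes <- sort(unique(unlist(run_genes, use.names = FALSE)))
  present <- vapply(run_genes, function(g) genes %in% g,
                    logical(length(genes)))
  present <- matrix(present, nrow = length(genes),
                    dimnames = list(genes, names(run_genes)))
  structure(list(genes = genes, runs = names(run_genes), present = present),
            class = "detection_matrix")
}

#' Genes detected in at least k runs
#'
#' `k = 1` is the union across runs, `k = length(runs)` the intersection;
#' the field's "twice" set for triplicates is `k = 2` (at least two of
#' three). Thresholds are nested: the `k+1` set is always contained in the
#' `k` set.
#'
#' @param m A [detection_matrix].
#' @param k Positive integer threshold, `1 <= k <=` number of runs.
#' @return Sorted character vector of gene symbols.
#' @export
detected_in_at_least <- function(m, k) {
  stopifnot(inherits(m, "detection_matrix"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > length(m$runs)) {
    stop("k must be an integer between 1 and the number of runs (",
         length(m$runs), "); got ", k)
  }
  m$genes[rowSums(m$present) >= k]
}

#' Summary counts per detection threshold
#'
#' @param m A [detection_matrix].
#' @return A data.frame with columns `threshold` (k) and `count`
#'   (number of genes detected in at least k runs).
#' @export
replicate_counts <- function(m) {
  stopifnot(inherits(m, "detection_matrix"))
  ks <- seq_along(m$runs)
  data.frame(threshold = ks,
             count = vapply(ks, function(k)
               length(detected_in_at_least(m, k)), integer(1L)))
}

#' The standard replicate gene sets for a triplicate experiment
#'
#' @param m A [detection_matrix].
#' @return Named list with elements `union` (k = 1), `twice` (k = 2, only if
#'   there are >= 2 runs) and `intersection` (k = number of runs).
#' @export
replicate_sets <- function(m) {
  stopifnot(inherits(m, "detection_matrix"))
  n <- length(m$runs)
  out <- list(union = detected_in_at_least(m, 1L))
  if (n >= 2L) out$twice <- detected_in_at_least(m, 2L)
  out$intersection <- detected_in_at_least(m, n)
  out
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat("Detection matrix: ", length(x$genes), " genes x ",
      length(x$runs), " runs\n", sep = "")
  print(replicate_counts(x), row.names = FALSE)
  invisible(x)
}
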