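#' Percentage of a count pair, rounded as printed in reports
#'
#' @param k Numerator count(s).
#' @param n Denominator count(s).
#' @param digits Decimal places (default 2).
#' @return Numeric percentage(s); `NA` where `n` is zero.
#' @export
format_percent <- function(k, n, digits = 2L) {
  ifelse(n > 0, round(100 * k / n, digits), NA_real_)
}

#' Estimated coverage of the expressed proteome
#'
#' A rough coverage estimate against an assumed expressed-proteome size of
#' about 10,000 proteins for a mammalian cell line: about 1,000 detections
#' from a 50-cell run is 10% coverage; about 5,000 across all runs is 50%.
#'
#' @param detected_count Number of distinct detected genes.
#' @param assumed_proteome Assumed expressed-proteome size (default 10,000).
#' @return List with `fraction`, `percent`, and the echoed
#'   `assumed_proteome`.
#' @export
estimate_coverage <- function(detected_count, assumed_proteome = 10000L) {
  stopifnot(assumed_proteome > 0)
  frac <- detected_count / assumed_proteome
  list(fraction = frac,
       percent = format_percent(detected_count, assumed_proteome),
       assumed_proteome = assumed_proteome)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir Directory containing `aliases.tsv`, `pathways.gmt`,
#'   `expression.tsv`, `contaminants.txt`, `report_<run>.tsv` and
#'   `manifest.txt`.
#' @return A list shaped like a `sim_bundle` (without ground truth).
#' @export
read_bundle <- function(dir) {
  manifest <- readLines(file.path(dir, "manifest.txt"), warn = FALSE)
  kv <- strsplit(manifest, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x)
    paste(x[-1L], collapse = "="), ""), vapply(kv, `[[`, "", 1L))
  runs <- strsplit(vals[["runs"]], ",", fixed = TRUE)[[1L]]
  reports <- lapply(runs, function(r)
    read_protein_report(file.path(dir, sprintf("report_%s.tsv", r)), r))
  names(reports) <- runs
  list(aliases = read_alias_table(file.path(dir, "aliases.tsv")),
       collection = read_gmt(file.path(dir, "pathways.gmt")),
       expression = read_expression_table(file.path(dir, "expression.tsv")),
       reports = reports,
       contaminants = read_contaminants(file.path(dir, "contaminants.txt")),
       manifest = vals)
}

#' Run the full knowledge-based proteome-elucidation analysis
#'
#' End-to-end orchestration over an input bundle (simulated or read from
#' disk): harmonize each run's report, build the replicate detection
#' matrix, collapse the expression table to gene profiles, score
#' proteome-transcriptome concordance (sliding window, cumulative curve,
#' threshold groups), run over-representation analysis per replicate set,
#' expand enriched pathways into predicted proteomes, and verify the
#' predictions. Fully deterministic for fixed inputs and parameters.
#'
#' @param bundle A `sim_bundle` or the list returned by [read_bundle()].
#' @param out_dir Optional directory; when given, all report tables are
#'   written there as TSV / gene-list text.
#' @param window Sliding-window size over the sorted transcript list
#'   (default 50).
#' @param step Window step (default 1; use `step = window` for tumbling
#'   blocks).
#' @param threshold Expression threshold splitting high/low groups
#'   (default 6.0).
#' @param cutoff Enrichment p-value cutoff (default 0.01).
#' @param assumed_proteome Assumed expressed-proteome size for coverage
#'   estimates.
#' @return List of class `proteopath_analysis` with elements `harmonized`,
#'   `ledgers`, `detection`, `sets` (per-run and union/twice/intersection
#'   gene sets), `profiles`, `indicator`, `windows`, `cumulative`,
#'   `concordance`, `enrichment` (one `enrichment_results` per set),
#'   `expansions`, `verification`, `common_pathways`, `coverage`, `params`.
#' @export
analyze_bundle <- function(bundle, out_dir = NULL, window = 50L, step = 1L,
                           threshold = 6.0, cutoff = 0.01,
                           assumed_proteome = 10000L) {
  harmonized <- lapply(bundle$reports, preprocess_report,
                       aliases = bundle$aliases,
                       contaminants = bundle$contaminants)
  ledgers <- lapply(harmonized, harmonization_ledger)
  run_genes <- lapply(harmonized, `[[`, "genes")
  dm <- detection_matrix(run_genes)
  rep_sets <- replicate_sets(dm)
  sets <- c(run_genes, rep_sets)

  profiles <- collapse_probes(bundle$expression, aliases = bundle$aliases)
  indicator <- mark_overlap(profiles, rep_sets$union)
  windows <- window_scores(indicator, w = window, step = step)
  cumul <- cumulative_overlap(indicator)
  concordance <- concordance_table(sets, profiles, threshold = threshold)

  enrichment <- lapply(sets, enrich_collection, collection = bundle$collection,
                       cutoff = cutoff)
  expansions <- lapply(enrichment, expand_enriched,
                       collection = bundle$collection)
  groups <- expression_groups(profiles, threshold)
  verification <- do.call(rbind, lapply(names(expansions), function(nm) {
    refs <- c(stats::setNames(list(sets[[nm]]), paste0("detected_", nm)),
              list(intersection = rep_sets$intersection,
                   union = rep_sets$union,
                   transcripts_high = groups$high,
                   transcripts_low = groups$low))
    v <- verify_expansion(expansions[[nm]], refs)
    cbind(data.frame(expansion = nm, n_expanded = expansions[[nm]]$n_genes,
                     stringsAsFactors = FALSE), v)
  }))
  rownames(verification) <- NULL
  common <- if (length(bundle$reports) >= 2L) {
    common_pathways(enrichment[names(bundle$reports)])
  } else character(0)
  coverage <- data.frame(
    set = names(sets),
    n_detected = lengths(sets),
    coverage_pct = vapply(sets, function(s)
      estimate_coverage(length(s), assumed_proteome)$percent, numeric(1L)),
    stringsAsFactors = FALSE)
  rownames(coverage) <- NULL

  out <- structure(list(
    harmonized = harmonized, ledgers = ledgers, detection = dm,
    sets = sets, profiles = profiles, indicator = indicator,
    windows = windows, cumulative = cumul, concordance = concordance,
    enrichment = enrichment, expansions = expansions,
    verification = verification, common_pathways = common,
    coverage = coverage,
    params = list(window = window, step = step, threshold = threshold,
                  cutoff = cutoff, assumed_proteome = assumed_proteome)),
    class = "proteopath_analysis")
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

#' Write every table of an analysis to a report directory
#'
#' @param analysis A `proteopath_analysis`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(analysis, out_dir) {
  stopifnot(inherits(analysis, "proteopath_analysis"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(analysis$ledgers)) {
    write_tsv(analysis$ledgers[[nm]],
              file.path(out_dir, sprintf("ledger_%s.tsv", nm)))
  }
  write_tsv(replicate_counts(analysis$detection),
            file.path(out_dir, "replicate_counts.tsv"))
  for (nm in names(analysis$sets)) {
    write_gene_list(analysis$sets[[nm]],
                    file.path(out_dir, sprintf("genes_%s.txt", nm)))
  }
  prof <- data.frame(rank = seq_len(nrow(analysis$profiles)),
                     gene = analysis$profiles$gene,
                     level = analysis$profiles$level,
                     indicator = analysis$indicator,
                     cumulative = analysis$cumulative)
  write_tsv(prof, file.path(out_dir, "sorted_profiles.tsv"))
  write_tsv(analysis$windows, file.path(out_dir, "window_scores.tsv"))
  write_tsv(analysis$concordance, file.path(out_dir, "concordance.tsv"))
  for (nm in names(analysis$enrichment)) {
    e <- analysis$enrichment[[nm]]
    header <- sprintf("# cutoff=%g correction=%s n_detected_raw=%d n_outside_universe=%d",
                      attr(e, "cutoff"), attr(e, "correction"),
                      attr(e, "n_detected_raw"), attr(e, "n_outside_universe"))
    path <- file.path(out_dir, sprintf("enrichment_%s.tsv", nm))
    writeLines(header, path)
    suppressWarnings(utils::write.table(
      e, path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
    write_gene_list(analysis$expansions[[nm]]$member_genes,
                    file.path(out_dir, sprintf("expansion_%s.txt", nm)))
  }
  write_tsv(analysis$verification, file.path(out_dir, "verification.tsv"))
  write_gene_list(analysis$common_pathways,
                  file.path(out_dir, "common_pathways.txt"))
  write_tsv(analysis$coverage, file.path(out_dir, "coverage.tsv"))
  p <- analysis$params
  writeLines(sprintf("%s=%s", names(p), unlist(p)),
             file.path(out_dir, "analysis_manifest.txt"))
  invisible(out_dir)
}

#' @export
print.proteopath_analysis <- function(x, ...) {
  cat("Knowledge-based proteome analysis\n")
  cat("Runs:", paste(names(x$harmonized), collapse = ", "), "\n")
  print(replicate_counts(x$detection), row.names = FALSE)
  cat("Transcript profiles:", nrow(x$profiles), "genes\n")
  for (nm in names(x$expansions)) {
    cat(sprintf("  %s: %d enriched sets -> %d predicted genes\n", nm,
                x$expansions[[nm]]$n_sets, x$expansions[[nm]]$n_genes))
  }
  cat("Pathways enriched in every run:", length(x$common_pathways), "\n")
  invisible(x)
}
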