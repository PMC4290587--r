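#' Common contaminant proteins removed before analysis
#'
#' UniProt-style mnemonics of standards and adventitious proteins (cRAP)
#' routinely seen in shotgun-proteomics experiments: bovine serum albumin,
#' rabbit aldolase, bovine carbonic anhydrase 2, bovine caseins, bovine
#' glutamate dehydrogenase, Lysobacter lysyl endopeptidase, and bovine and
#' porcine trypsins. Used as the default contaminant list throughout.
#'
#' @format Character vector of 9 accessions.
#' @export
crap_contaminants <- c(
  "ALBU_BOVIN", "ALDOA_RABIT", "CAH2_BOVIN", "CAS1_BOVIN", "CAS2_BOVIN",
  "DHE3_BOVIN", "LYSC_LYSEN", "TRY1_BOVIN", "TRYP_PIG")

#' Remove contaminant accessions from a protein report
#'
#' Matching is by exact accession (the contaminant list uses the same
#' namespace as the report accessions), never by gene symbol. The number of
#' rows removed is recorded in the `n_removed` attribute of the result.
#'
#' @param rows Protein-report data.frame (see [read_protein_report()]).
#' @param contaminants Character vector of contaminant accessions; an empty
#'   vector is legal and leaves the input unchanged.
#' @return The filtered data.frame with attribute `n_removed`.
#' @export
filter_contaminants <- function(rows, contaminants = crap_contaminants) {
  hit <- rows$accession %in% contaminants
  out <- rows[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Resolve raw gene symbols to approved symbols
#'
#' Approved-first lookup: a symbol that is already approved resolves to
#' itself; otherwise it is looked up among previous symbols and synonyms.
#' Ambiguous aliases (claimed by more than one approved symbol) and symbols
#' found nowhere stay unresolved with a status explaining why.
#'
#' @param symbols Character vector of raw symbols (may contain empties).
#' @param aliases An [alias_table].
#' @return A data.frame with columns `raw_symbol`, `approved` (`NA` where
#'   unresolved) and `status` in `approved`, `alias`, `ambiguous`, `unmapped`.
#' @export
resolve_symbols <- function(symbols, aliases) {
  stopifnot(inherits(aliases, "alias_table"))
  symbols <- trimws(as.character(symbols))
  approved <- rep(NA_character_, length(symbols))
  status <- rep("unmapped", length(symbols))
  is_app <- symbols %in% aliases$approved
  approved[is_app] <- symbols[is_app]
  status[is_app] <- "approved"
  is_amb <- !is_app & symbols %in% aliases$ambiguous
  status[is_amb] <- "ambiguous"
  is_ali <- !is_app & !is_amb & symbols %in% names(aliases$alias_to_approved)
  approved[is_ali] <- unname(aliases$alias_to_approved[symbols[is_ali]])
  status[is_ali] <- "alias"
  data.frame(raw_symbol = symbols, approved = approved, status = status,
             stringsAsFactors = FALSE)
}

#' Harmonize a contaminant-filtered protein report to approved gene symbols
#'
#' Resolves every row's raw symbol via [resolve_symbols()], excludes rows
#' with empty, unmappable or ambiguous symbols (tallied, never guessed), and
#' collapses duplicates: accessions resolving to the same approved symbol
#' count as one gene, since all downstream analysis is at gene-symbol level.
#'
#' @param rows Contaminant-filtered protein-report data.frame.
#' @param aliases An [alias_table].
#' @param n_contaminant Count of rows already removed as contaminants,
#'   carried into the run's ledger.
#' @return An object of class `harmonized_run`: `run_id`, `genes` (sorted
#'   character vector of approved symbols), and the tallies `n_input`
#'   (including contaminants), `n_contaminant`, `n_unmapped`, `n_ambiguous`,
#'   `n_duplicate`.
#' @export
harmonize_run <- function(rows, aliases, n_contaminant = 0L) {
  res <- resolve_symbols(rows$raw_symbol, aliases)
  unmapped <- res$status == "unmapped" | !nzchar(res$raw_symbol)
  ambiguous <- res$status == "ambiguous" & nzchar(res$raw_symbol)
  mapped <- res$approved[!is.na(res$approved)]
  genes <- sort(unique(mapped))
  run_id <- if (nrow(rows)) rows$run_id[1L] else NA_character_
  structure(list(
    run_id = run_id,
    genes = genes,
    n_input = nrow(rows) + n_contaminant,
    n_contaminant = as.integer(n_contaminant),
    n_unmapped = sum(unmapped),
    n_ambiguous = sum(ambiguous),
    n_duplicate = length(mapped) - length(genes)),
    class = "harmonized_run")
}

#' One-call pre-processing of a raw protein report
#'
#' [filter_contaminants()] followed by [harmonize_run()].
#'
#' @inheritParams filter_contaminants
#' @inheritParams harmonize_run
#' @return A `harmonized_run`.
#' @export
preprocess_report <- function(rows, aliases,
                              contaminants = crap_contaminants) {
  filtered <- filter_contaminants(rows, contaminants)
  harmonize_run(filtered, aliases,
                n_contaminant = attr(filtered, "n_removed"))
}

#' Harmonization ledger for a run
#'
#' Accounts for every input row of the report: contaminants, unmapped and
#' ambiguous symbols, duplicate collapses, and the distinct genes that
#' remain. Categories sum exactly to the input row count, making the losses
#' of pre-processing auditable.
#'
#' @param run A `harmonized_run`.
#' @return A data.frame with columns `category` and `count`.
#' @export
harmonization_ledger <- function(run) {
  stopifnot(inherits(run, "harmonized_run"))
  df <- data.frame(
    category = c("input_rows", "contaminant", "unmapped_symbol",
                 "ambiguous_symbol", "duplicate_collapsed", "distinct_genes"),
    count = c(run$n_input, run$n_contaminant, run$n_unmapped,
              run$n_ambiguous, run$n_duplicate, length(run$genes)),
    stringsAsFactors = FALSE)
  stopifnot(sum(df$count[-1L]) == df$count[1L])
  df
}

#' @export
print.harmonized_run <- function(x, ...) {
  cat("Harmonized run '", x$run_id, "': ", length(x$genes),
      " distinct genes from ", x$n_input, " rows (",
      x$n_contaminant, " contaminant, ", x$n_unmapped, " unmapped, ",
      x$n_ambiguous, " ambiguous, ", x$n_duplicate,
      " duplicate)\n", sep = "")
  invisible(x)
}
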