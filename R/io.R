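#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-separated gene-set exchange format used by MSigDB: one set
#' per line, with the set name, a free-text description, and then one member
#' symbol per field. Duplicate member symbols within a set are collapsed and
#' empty member fields are dropped.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection] object.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    bad <- which(n_fields < 3)[1L]
    stop("GMT line ", bad, " has ", n_fields[bad],
         " fields; at least 3 (name, description, members...) are required")
  }
  names_ <- trimws(vapply(fields, `[[`, "", 1L))
  if (anyDuplicated(names_)) {
    dup <- which(duplicated(names_))[1L]
    stop("duplicate gene-set name '", names_[dup], "' at GMT line ", dup)
  }
  descriptions <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) {
    members <- trimws(f[-(1:2)])
    unique(members[nzchar(members)])
  })
  names(sets) <- names_
  names(descriptions) <- names_
  gene_set_collection(sets, descriptions)
}

#' Write a gene-set collection to a GMT file
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, path))` reproduces `x`
#' exactly for canonical collections (unique names, deduplicated members).
#'
#' @param collection A [gene_set_collection].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of member symbols.
#' @param descriptions Optional named character vector of descriptions.
#' @return An object of class `gene_set_collection` with elements `sets`,
#'   `descriptions` and `universe` (the union of all member symbols, the
#'   default gene universe for enrichment).
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(
    list(sets = sets,
         descriptions = descriptions[names(sets)],
         universe = sort(unique(unlist(sets, use.names = FALSE)))),
    class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat("Gene-set collection: ", length(x$sets), " sets, ",
      length(x$universe), " genes in universe\n", sep = "")
  if (length(sizes)) {
    cat("Set sizes: min ", min(sizes), ", median ", stats::median(sizes),
        ", max ", max(sizes), "\n", sep = "")
  }
  invisible(x)
}

#' Read a per-run protein identification report
#'
#' Tab-separated text with a header. Empty gene-symbol cells are preserved as
#' empty strings (they are tallied downstream as unmapped, never dropped at
#' parse time). Windows and Unix line endings are both accepted.
#'
#' @param path Path to the report.
#' @param run_id Label for the run the report belongs to.
#' @param accession_col,symbol_col Names of the accession and gene-symbol
#'   columns in the header.
#' @return A data.frame with columns `accession`, `raw_symbol`, `run_id`.
#' @export
read_protein_report <- function(path, run_id,
                                accession_col = "accession",
                                symbol_col = "gene_symbol") {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = NULL,
                          quote = "", stringsAsFactors = FALSE)
  for (col in c(accession_col, symbol_col)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path,
           "; available columns: ", paste(names(df), collapse = ", "))
    }
  }
  acc <- trimws(df[[accession_col]])
  if (any(!nzchar(acc))) {
    stop("empty accession at row ", which(!nzchar(acc))[1L], " of ", path)
  }
  data.frame(accession = acc,
             raw_symbol = trimws(df[[symbol_col]]),
             run_id = run_id,
             stringsAsFactors = FALSE)
}

#' Read a probe-level expression table
#'
#' Tab-separated with a header: a probe-id column, a gene-symbol column, and
#' one numeric column per sample. Values must use decimal points (no
#' thousands separators); any unparseable cell aborts with the probe and
#' column named. Probes with an empty symbol are retained at probe level and
#' flagged, so the caller can tally them when collapsing to genes.
#'
#' @param path Path to the table.
#' @param probe_col,symbol_col Names of the probe-id and symbol columns.
#' @return A data.frame with columns `probe_id`, `gene_symbol` and one
#'   numeric column per sample.
#' @export
read_expression_table <- function(path, probe_col = "probe_id",
                                  symbol_col = "gene_symbol") {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = NULL,
                          quote = "", stringsAsFactors = FALSE)
  for (col in c(probe_col, symbol_col)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path,
           "; available columns: ", paste(names(df), collapse = ", "))
    }
  }
  sample_cols <- setdiff(names(df), c(probe_col, symbol_col))
  if (length(sample_cols) == 0L) stop("no sample columns in ", path)
  out <- data.frame(probe_id = trimws(df[[probe_col]]),
                    gene_symbol = trimws(df[[symbol_col]]),
                    stringsAsFactors = FALSE)
  for (col in sample_cols) {
    raw <- trimws(df[[col]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & !is.na(raw)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("non-numeric value '", raw[i], "' for probe '",
           out$probe_id[i], "' in column '", col, "'")
    }
    out[[col]] <- val
  }
  if (anyDuplicated(out$probe_id)) {
    stop("duplicated probe id '", out$probe_id[duplicated(out$probe_id)][1L],
         "' in ", path)
  }
  out
}

#' Build an alias table mapping historical gene symbols to approved symbols
#'
#' Mirrors the HGNC nomenclature model: each gene has one approved symbol and
#' possibly several previous symbols and synonyms. An alias claimed by more
#' than one approved symbol is ambiguous and cannot be resolved; an alias
#' string that equals an approved symbol is dropped (the approved meaning
#' wins). Symbol comparison is case-sensitive after trimming whitespace.
#'
#' @param approved Character vector of approved symbols (no duplicates).
#' @param previous,synonyms Lists (parallel to `approved`) of character
#'   vectors of historical symbols, or `NULL`.
#' @return An object of class `alias_table` with elements `approved` (set of
#'   approved symbols), `alias_to_approved` (named character vector), and
#'   `ambiguous` (set of unresolvable aliases).
#' @export
alias_table <- function(approved, previous = NULL, synonyms = NULL) {
  approved <- trimws(as.character(approved))
  if (anyDuplicated(approved)) {
    stop("duplicated approved symbol '",
         approved[duplicated(approved)][1L], "'")
  }
  empty <- rep(list(character()), length(approved))
  if (is.null(previous)) previous <- empty
  if (is.null(synonyms)) synonyms <- empty
  alias <- character(0)
  target <- character(0)
  for (i in seq_along(approved)) {
    a <- unique(trimws(c(previous[[i]], synonyms[[i]])))
    a <- a[nzchar(a)]
    alias <- c(alias, a)
    target <- c(target, rep(approved[i], length(a)))
  }
  # alias equal to an approved symbol: the approved meaning wins
  keep <- !(alias %in% approved)
  alias <- alias[keep]; target <- target[keep]
  # alias claimed by >1 approved symbol -> ambiguous
  tgt_per_alias <- tapply(target, alias, function(x) length(unique(x)))
  ambiguous <- names(tgt_per_alias)[tgt_per_alias > 1L]
  keep <- !(alias %in% ambiguous)
  map <- stats::setNames(target[keep], alias[keep])
  map <- map[!duplicated(names(map))]
  structure(list(approved = sort(approved),
                 alias_to_approved = map,
                 ambiguous = sort(ambiguous)),
            class = "alias_table")
}

#' @export
print.alias_table <- function(x, ...) {
  cat("Alias table: ", length(x$approved), " approved symbols, ",
      length(x$alias_to_approved), " resolvable aliases, ",
      length(x$ambiguous), " ambiguous\n", sep = "")
  invisible(x)
}

#' Read an HGNC-style alias table
#'
#' Expects a tab-separated file with a header containing an approved-symbol
#' column and multi-valued previous-symbol and synonym columns, whose cells
#' use `delim` between values (HGNC exports vary, so the delimiter is
#' configurable).
#'
#' @param path Path to the table.
#' @param approved_col,previous_col,synonyms_col Column names.
#' @param delim Delimiter inside multi-valued cells.
#' @return An [alias_table].
#' @export
read_alias_table <- function(path, approved_col = "approved_symbol",
                             previous_col = "previous_symbols",
                             synonyms_col = "synonyms", delim = ",") {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = NULL,
                          quote = "", stringsAsFactors = FALSE)
  for (col in c(approved_col, previous_col, synonyms_col)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path,
           "; available columns: ", paste(names(df), collapse = ", "))
    }
  }
  split_cell <- function(x) {
    lapply(strsplit(x, delim, fixed = TRUE),
           function(v) { v <- trimws(v); v[nzchar(v)] })
  }
  alias_table(df[[approved_col]],
              previous = split_cell(df[[previous_col]]),
              synonyms = split_cell(df[[synonyms_col]]))
}

#' Read a contaminant accession list
#'
#' One accession per line (cRAP-style mnemonics); blank lines and surrounding
#' whitespace are ignored.
#'
#' @param path Path to the list.
#' @return Character vector of contaminant accessions.
#' @export
read_contaminants <- function(path) {
  stopifnot(file.exists(path))
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Write a one-symbol-per-line gene list
#' @param genes Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

# internal: consistent TSV writer for report tables
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
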