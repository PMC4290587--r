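# Small programmatic fixtures shared across test files.

# alias table with one approved/alias pair of each interesting kind
tiny_aliases <- function() {
  alias_table(c("G1", "G2", "G3"),
              previous = list("oldG1", character(0), "AMB"),
              synonyms = list(character(0), c("synG2", "AMB"), character(0)))
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# protein-report data.frame in the in-memory layout
report_rows <- function(accession, raw_symbol, run_id = "run1") {
  data.frame(accession = accession, raw_symbol = raw_symbol,
             run_id = run_id, stringsAsFactors = FALSE)
}

# random genes x runs detection structure as a named list of gene sets
random_run_genes <- function(n_genes = 50L, n_runs = 3L, p = 0.4) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  repeat {
    sets <- lapply(seq_len(n_runs), function(i) genes[runif(n_genes) < p])
    if (length(unique(unlist(sets))) > 0L) break
  }
  names(sets) <- sprintf("run%d", seq_len(n_runs))
  sets
}

# independent upper-tail oracle by explicit subset enumeration: draw all
# C(N, n) subsets of the universe, count those overlapping the K-set by >= k
enumerate_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# transcript_profiles built directly from gene/level vectors (one sample
# column equal to the level, so invariants hold)
profiles_from_levels <- function(genes, levels, n_samples = 1L) {
  df <- data.frame(gene = genes, level = levels,
                   probe_id = paste0("P_", genes),
                   stringsAsFactors = FALSE)
  for (s in seq_len(n_samples)) df[[paste0("sample_", s)]] <- levels
  df <- df[order(-df$level, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "sample_cols") <- paste0("sample_", seq_len(n_samples))
  class(df) <- c("transcript_profiles", "data.frame")
  df
}

# small simulation config so unit tests stay fast
small_config <- function(seed = 1L, ...) {
  sim_config(n_genes = 1500L, n_protein_only = 150L, n_pathways = 120L,
             pathway_size_range = c(10L, 80L), run_depth = 250,
             seed = seed, ...)
}
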