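#' Configuration for the synthetic input generator
#'
#' Defaults emulate the structure of a triplicate 50-cell shotgun-proteomics
#' experiment on a well-profiled cell line: a transcriptome of 13,187 genes
#' with collapsed log-scale levels spanning 2.80-14.48 units, a
#' canonical-pathway collection of 1,452 gene sets, per-gene protein
#' detection probability that decays with decreasing transcript level from
#' near-certainty at the top to a 10% floor below 6.0 units, about 1,000
#' expected detections per run of which about 20% come from genes with no
#' transcript row, 8 array samples with small per-sample jitter, 9 spiked
#' contaminants, and a tenth of symbols carrying a historical alias.
#'
#' @param n_genes Transcript genes in the expression table.
#' @param n_protein_only Pool of genes detectable at the protein level but
#'   absent from the transcript table.
#' @param n_pathways Number of gene sets in the synthetic collection.
#' @param pathway_size_range Min/max members per set (sizes are drawn
#'   log-uniformly, giving the right-skewed spread of curated collections).
#' @param expression_range Low/high collapsed expression levels (log-scale
#'   array units).
#' @param curve_shape Exponent of the sorted-expression curve; the default
#'   puts the crossing of the 6.0-unit threshold near rank 7,500.
#' @param plateau_level Expression level below which detection probability
#'   sits at its floor.
#' @param detection_floor Detection probability for low-expression genes.
#' @param n_runs Replicate proteomics runs.
#' @param run_depth Expected number of detected genes per run.
#' @param frac_protein_only Expected fraction of a run's detections drawn
#'   from the protein-only pool.
#' @param n_samples Array samples per probe.
#' @param sample_jitter SD of per-sample noise around a gene's level.
#' @param multi_probe_rate Fraction of genes interrogated by a second,
#'   dimmer probe.
#' @param alias_rate Fraction of symbols that carry a previous-symbol alias.
#' @param duplicate_rate Fraction of detected genes reported under a second
#'   accession.
#' @param unannotated_per_run Report rows per run with no gene annotation.
#' @param n_contaminants Contaminant rows spiked into each report.
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 13187L,
                       n_protein_only = 1000L,
                       n_pathways = 1452L,
                       pathway_size_range = c(10L, 300L),
                       expression_range = c(2.80, 14.48),
                       curve_shape = 1.46,
                       plateau_level = 6.0,
                       detection_floor = 0.10,
                       n_runs = 3L,
                       run_depth = 1000,
                       frac_protein_only = 0.20,
                       n_samples = 8L,
                       sample_jitter = 0.15,
                       multi_probe_rate = 0.15,
                       alias_rate = 0.10,
                       duplicate_rate = 0.05,
                       unannotated_per_run = 20L,
                       n_contaminants = 9L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_protein_only = as.integer(n_protein_only),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              expression_range = as.numeric(expression_range),
              curve_shape = curve_shape,
              plateau_level = plateau_level,
              detection_floor = detection_floor,
              n_runs = as.integer(n_runs),
              run_depth = run_depth,
              frac_protein_only = frac_protein_only,
              n_samples = as.integer(n_samples),
              sample_jitter = sample_jitter,
              multi_probe_rate = multi_probe_rate,
              alias_rate = alias_rate,
              duplicate_rate = duplicate_rate,
              unannotated_per_run = as.integer(unannotated_per_run),
              n_contaminants = as.integer(n_contaminants),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fracs <- c(frac_protein_only = cfg$frac_protein_only,
             alias_rate = cfg$alias_rate,
             detection_floor = cfg$detection_floor,
             multi_probe_rate = cfg$multi_probe_rate,
             duplicate_rate = cfg$duplicate_rate)
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) {
    stop("fraction field out of [0, 1]: ", names(fracs)[bad][1L])
  }
  if (cfg$n_genes < 1L || cfg$n_runs < 1L || cfg$n_samples < 1L ||
      cfg$n_pathways < 1L) {
    stop("n_genes, n_runs, n_samples and n_pathways must be positive")
  }
  if (cfg$pathway_size_range[1L] < 1L ||
      cfg$pathway_size_range[2L] < cfg$pathway_size_range[1L]) {
    stop("invalid pathway_size_range")
  }
  if (cfg$pathway_size_range[2L] > cfg$n_genes + cfg$n_protein_only) {
    stop("pathway_size_range exceeds the gene universe")
  }
  if (cfg$expression_range[2L] <= cfg$expression_range[1L]) {
    stop("expression_range must be increasing")
  }
  if (cfg$run_depth > cfg$n_genes + cfg$n_protein_only) {
    stop("run_depth (", cfg$run_depth, ") exceeds the number of genes")
  }
  if (cfg$frac_protein_only > 0 && cfg$n_protein_only > 0 &&
      cfg$run_depth * cfg$frac_protein_only > cfg$n_protein_only) {
    stop("run_depth * frac_protein_only exceeds the protein-only pool")
  }
  invisible(cfg)
}

#' Generate a complete ground-truthed synthetic input bundle
#'
#' Builds, deterministically from the seed, everything the pipeline reads:
#' an alias table, a gene-set collection, a probe-level expression table,
#' one protein report per run (with contaminants, duplicate accessions,
#' alias-form symbols and unannotated rows spiked in), and a contaminant
#' list - together with the ground truth behind them.
#'
#' The sorted expression curve is `lo + (hi - lo) * (1 - q)^shape` over rank
#' quantiles `q`, a concave decay. Detection probability is a linear ramp in
#' level from 1.0 at the top of the range down to `detection_floor` at
#' `plateau_level`, flat below; per-run probabilities are scaled so each
#' run's expected transcript-backed detections equal
#' `run_depth * (1 - frac_protein_only)`. Protein-only genes are detected
#' with a flat per-run probability giving `run_depth * frac_protein_only`
#' expected detections.
#'
#' @param config A [sim_config].
#' @return List of class `sim_bundle`: `aliases` ([alias_table]),
#'   `collection` ([gene_set_collection]), `expression` (probe-level
#'   data.frame), `reports` (list of per-run data.frames), `contaminants`,
#'   `truth` (per-gene levels and detection probabilities, per-run detected
#'   gene sets, protein-only symbols), and `config`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lo <- config$expression_range[1L]; hi <- config$expression_range[2L]

  genes <- sprintf("GENE%05d", seq_len(config$n_genes))
  ponly <- if (config$n_protein_only > 0L) {
    sprintf("PONLY%04d", seq_len(config$n_protein_only))
  } else character(0)
  all_genes <- c(genes, ponly)

  # alias table: a fraction of symbols carry a previous symbol; a few
  # deliberately ambiguous aliases shared by symbol pairs
  has_alias <- stats::runif(length(all_genes)) < config$alias_rate
  previous <- rep(list(character(0)), length(all_genes))
  previous[has_alias] <- lapply(all_genes[has_alias],
                                function(s) paste0("OLD_", s))
  n_amb <- min(5L, length(all_genes) %/% 2L)
  if (n_amb > 0L) {
    pick <- sample.int(length(all_genes), 2L * n_amb)
    for (j in seq_len(n_amb)) {
      amb <- sprintf("AMBIG%02d", j)
      i1 <- pick[2L * j - 1L]; i2 <- pick[2L * j]
      previous[[i1]] <- c(previous[[i1]], amb)
      previous[[i2]] <- c(previous[[i2]], amb)
    }
  }
  aliases <- alias_table(all_genes, previous = previous)
  names(previous) <- all_genes

  # sorted concave expression curve, assigned to genes in random order
  q <- (seq_len(config$n_genes) - 0.5) / config$n_genes
  sorted_levels <- lo + (hi - lo) * (1 - q)^config$curve_shape
  level <- sorted_levels[sample.int(config$n_genes)]
  names(level) <- genes

  # probe table: one probe per gene (per-sample jitter), a second dimmer
  # probe for some genes, plus a handful of symbol-less probes
  probe_sym <- genes
  use_alias <- has_alias[seq_len(config$n_genes)] &
    stats::runif(config$n_genes) < 0.5
  probe_sym[use_alias] <- paste0("OLD_", genes[use_alias])
  main <- data.frame(probe_id = sprintf("P%05d_at", seq_len(config$n_genes)),
                     gene_symbol = probe_sym, stringsAsFactors = FALSE)
  vals <- matrix(stats::rnorm(config$n_genes * config$n_samples,
                              mean = level, sd = config$sample_jitter),
                 nrow = config$n_genes)
  extra_idx <- which(stats::runif(config$n_genes) < config$multi_probe_rate)
  extra <- data.frame(probe_id = sprintf("P%05d_x_at", extra_idx),
                      gene_symbol = probe_sym[extra_idx],
                      stringsAsFactors = FALSE)
  extra_vals <- matrix(stats::rnorm(length(extra_idx) * config$n_samples,
                                    mean = pmax(lo, level[extra_idx] -
                                                  stats::runif(length(extra_idx), 0.5, 3)),
                                    sd = config$sample_jitter),
                       nrow = length(extra_idx))
  n_nosym <- 10L
  nosym <- data.frame(probe_id = sprintf("PNOSYM%02d_at", seq_len(n_nosym)),
                      gene_symbol = "", stringsAsFactors = FALSE)
  nosym_vals <- matrix(stats::runif(n_nosym * config$n_samples, lo, hi),
                       nrow = n_nosym)
  expression <- rbind(main, extra, nosym)
  value_mat <- rbind(vals, extra_vals, nosym_vals)
  colnames(value_mat) <- sprintf("sample_%d", seq_len(config$n_samples))
  expression <- cbind(expression, as.data.frame(round(value_mat, 4L)))

  # detection model: ramp in level with a floor, per-run depth calibration
  p_base <- detection_curve(level, lo = config$plateau_level, hi = hi,
                            floor = config$detection_floor)
  depth_t <- config$run_depth * (1 - config$frac_protein_only)
  scale <- if (sum(p_base) > 0) depth_t / sum(p_base) else 0
  if (scale > 1 + 1e-9) {
    stop("infeasible config: run_depth requires detection probabilities > 1")
  }
  p_run <- pmin(1, p_base * scale)
  q_ponly <- if (config$n_protein_only > 0L) {
    config$run_depth * config$frac_protein_only / config$n_protein_only
  } else 0
  if (q_ponly > 1) stop("infeasible config: protein-only detection > 1")

  contaminants <- if (config$n_contaminants <= length(crap_contaminants)) {
    crap_contaminants[seq_len(config$n_contaminants)]
  } else {
    c(crap_contaminants,
      sprintf("CONT%02d_SYNTH",
              seq_len(config$n_contaminants - length(crap_contaminants))))
  }

  run_ids <- sprintf("run%d", seq_len(config$n_runs))
  detected <- vector("list", config$n_runs)
  reports <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    det_t <- genes[stats::runif(config$n_genes) < p_run]
    det_p <- ponly[stats::runif(length(ponly)) < q_ponly]
    det <- c(det_t, det_p)
    detected[[r]] <- sort(det)
    reports[[r]] <- build_report(det, run_ids[r], aliases, has_alias,
                                 all_genes, contaminants, config)
  }
  names(detected) <- run_ids
  names(reports) <- run_ids

  # pathway collection: log-uniform sizes, members drawn from all genes
  sz <- config$pathway_size_range
  sizes <- round(exp(stats::runif(config$n_pathways, log(sz[1L]),
                                  log(sz[2L]))))
  sets <- lapply(sizes, function(s) sample(all_genes, s))
  names(sets) <- sprintf("PATHWAY_%04d", seq_len(config$n_pathways))
  collection <- gene_set_collection(
    sets, stats::setNames(rep("synthetic canonical pathway", length(sets)),
                          names(sets)))

  structure(list(aliases = aliases,
                 alias_previous = previous,
                 collection = collection,
                 expression = expression,
                 reports = reports,
                 contaminants = contaminants,
                 truth = list(level = level,
                              p_base = p_base,
                              p_run = p_run,
                              q_protein_only = q_ponly,
                              detected = detected,
                              protein_only = ponly,
                              spiked_set = NULL),
                 config = config),
            class = "sim_bundle")
}

# monotone detection curve: 1.0 at the top of the expression range, linear
# ramp down to `floor` at `lo`, flat below
detection_curve <- function(level, lo, hi, floor) {
  # lo >= hi collapses the ramp: detection sits at the floor everywhere
  ramp <- if (hi > lo) {
    pmin(1, pmax(0, (level - lo) / (hi - lo)))
  } else {
    numeric(length(level))
  }
  floor + (1 - floor) * ramp
}

# assemble one run's report: detected genes (some under alias symbols),
# duplicate accessions, unannotated rows, contaminants
build_report <- function(det, run_id, aliases, has_alias, all_genes,
                         contaminants, config) {
  raw <- det
  aliasable <- has_alias[match(det, all_genes)] & stats::runif(length(det)) < 0.5
  raw[aliasable] <- paste0("OLD_", det[aliasable])
  rows <- data.frame(accession = paste0("ACC_", det), raw_symbol = raw,
                     stringsAsFactors = FALSE)
  n_dup <- round(config$duplicate_rate * length(det))
  if (n_dup > 0L) {
    di <- sample.int(length(det), n_dup)
    rows <- rbind(rows, data.frame(accession = paste0("ACC2_", det[di]),
                                   raw_symbol = det[di],
                                   stringsAsFactors = FALSE))
  }
  if (config$unannotated_per_run > 0L) {
    rows <- rbind(rows, data.frame(
      accession = sprintf("UNK_%s_%03d", run_id,
                          seq_len(config$unannotated_per_run)),
      raw_symbol = "", stringsAsFactors = FALSE))
  }
  if (length(contaminants)) {
    rows <- rbind(rows, data.frame(accession = contaminants,
                                   raw_symbol = "",
                                   stringsAsFactors = FALSE))
  }
  rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
  rownames(rows) <- NULL
  rows$run_id <- run_id
  rows
}

#' Spike a pathway's members into every run
#'
#' Overrides background detection for one gene set: in every run, each
#' member is additionally reported with probability `detect_frac`
#' (independently per run), on top of whatever the background model already
#' detected. Used to test enrichment recovery.
#'
#' @param bundle A `sim_bundle`.
#' @param set_name Name of a set in the bundle's collection.
#' @param detect_frac Per-run detection probability for the set's members.
#' @return The modified bundle; `truth$spiked_set` records the set name.
#' @export
spike_pathway <- function(bundle, set_name, detect_frac) {
  stopifnot(inherits(bundle, "sim_bundle"),
            detect_frac >= 0, detect_frac <= 1)
  if (!set_name %in% names(bundle$collection$sets)) {
    stop("unknown gene set '", set_name, "'")
  }
  members <- bundle$collection$sets[[set_name]]
  for (r in names(bundle$reports)) {
    hit <- members[stats::runif(length(members)) < detect_frac]
    add <- setdiff(hit, bundle$truth$detected[[r]])
    if (length(add)) {
      extra <- data.frame(accession = paste0("ACC_", add),
                          raw_symbol = add,
                          run_id = r, stringsAsFactors = FALSE)
      bundle$reports[[r]] <- rbind(bundle$reports[[r]], extra)
      bundle$truth$detected[[r]] <- sort(c(bundle$truth$detected[[r]], add))
    }
  }
  bundle$truth$spiked_set <- set_name
  bundle
}

#' Write a simulated bundle to disk in the pipeline's input formats
#'
#' Emits `aliases.tsv`, `pathways.gmt`, `expression.tsv`, one
#' `report_<run>.tsv` per run, `contaminants.txt`, and a key-value
#' `manifest.txt` recording the configuration, seed and file names. Files
#' round-trip through the package's readers.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # the raw previous-symbol lists (ambiguity included) are written out; the
  # reader re-derives the ambiguous set from the collision
  prev <- bundle$alias_previous
  write_tsv(data.frame(
    approved_symbol = names(prev),
    previous_symbols = vapply(prev, paste, "", collapse = ","),
    synonyms = "",
    stringsAsFactors = FALSE), file.path(dir, "aliases.tsv"))
  write_gmt(bundle$collection, file.path(dir, "pathways.gmt"))
  write_tsv(bundle$expression, file.path(dir, "expression.tsv"))
  for (r in names(bundle$reports)) {
    write_tsv(data.frame(accession = bundle$reports[[r]]$accession,
                         gene_symbol = bundle$reports[[r]]$raw_symbol,
                         stringsAsFactors = FALSE),
              file.path(dir, sprintf("report_%s.tsv", r)))
  }
  writeLines(bundle$contaminants, file.path(dir, "contaminants.txt"))
  cfg <- bundle$config
  manifest <- c(
    sprintf("%s=%s", names(cfg),
            vapply(cfg, function(v) paste(v, collapse = ","), "")),
    sprintf("runs=%s", paste(names(bundle$reports), collapse = ",")),
    "files=aliases.tsv,pathways.gmt,expression.tsv,contaminants.txt")
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
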