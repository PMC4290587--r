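test_that("simulation is byte-identical for a fixed seed", {
  b1 <- simulate_bundle(small_config(seed = 4))
  b2 <- simulate_bundle(small_config(seed = 4))
  expect_identical(b1$reports, b2$reports)
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$collection$sets, b2$collection$sets)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("with frac_protein_only = 0 every detected gene has a transcript row", {
  b <- simulate_bundle(small_config(seed = 6, frac_protein_only = 0))
  transcript_genes <- sprintf("GENE%05d", seq_len(b$config$n_genes))
  for (r in names(b$truth$detected)) {
    expect_true(all(b$truth$detected[[r]] %in% transcript_genes))
  }
})

test_that("mean detections per run track the configured run depth", {
  depths <- unlist(lapply(1:6, function(s) {
    lengths(simulate_bundle(small_config(seed = s))$truth$detected)
  }))
  expect_lt(abs(mean(depths) - 250) / 250, 0.10)
})

test_that("emitted files parse through the readers back to the same analysis inputs", {
  b <- simulate_bundle(small_config(seed = 9))
  dir <- tempfile()
  write_bundle(b, dir)
  back <- read_bundle(dir)
  expect_identical(back$collection$sets, b$collection$sets)
  expect_identical(back$aliases$approved, b$aliases$approved)
  expect_identical(back$aliases$alias_to_approved,
                   b$aliases$alias_to_approved)
  expect_identical(back$contaminants, b$contaminants)
  h1 <- preprocess_report(b$reports$run1, b$aliases, b$contaminants)
  h2 <- preprocess_report(back$reports$run1, back$aliases,
                          back$contaminants)
  expect_identical(h1$genes, h2$genes)
  expect_identical(harmonization_ledger(h1), harmonization_ledger(h2))
  p1 <- collapse_probes(b$expression, b$aliases)
  p2 <- collapse_probes(back$expression, back$aliases)
  expect_equal(p1$gene, p2$gene)
  expect_equal(p1$level, p2$level)
})

test_that("reports contain the spiked contaminants and they are filtered out", {
  b <- simulate_bundle(small_config(seed = 2))
  expect_true(all(b$contaminants %in% b$reports$run1$accession))
  f <- filter_contaminants(b$reports$run1, b$contaminants)
  expect_equal(attr(f, "n_removed"), b$config$n_contaminants)
})

test_that("detection probability is non-increasing in rank down the sorted list", {
  b <- simulate_bundle(small_config(seed = 3))
  ord <- order(-b$truth$level)
  expect_true(all(diff(b$truth$p_base[ord]) <= 1e-12))
  expect_true(all(b$truth$p_base >= b$config$detection_floor - 1e-12))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(frac_protein_only = 1.2), "out of \\[0, 1\\]")
  expect_error(sim_config(run_depth = 1e6), "exceeds")
  expect_error(sim_config(n_protein_only = 10, frac_protein_only = 0.5,
                          run_depth = 1000), "protein-only pool")
  expect_error(sim_config(pathway_size_range = c(50, 10)), "invalid")
})

test_that("pathway spiking controls member detection in every run", {
  b <- simulate_bundle(small_config(seed = 12))
  expect_error(spike_pathway(b, "NOT_A_SET", 0.5), "unknown gene set")

  full <- spike_pathway(b, "PATHWAY_0010", 1.0)
  members <- full$collection$sets$PATHWAY_0010
  for (r in names(full$reports)) {
    expect_true(all(members %in% full$truth$detected[[r]]))
    h <- preprocess_report(full$reports[[r]], full$aliases,
                           full$contaminants)
    expect_true(all(members %in% h$genes))
  }

  none <- spike_pathway(simulate_bundle(small_config(seed = 12)),
                        "PATHWAY_0010", 0.0)
  expect_identical(none$truth$detected, b$truth$detected)
  expect_identical(none$truth$spiked_set, "PATHWAY_0010")
})
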