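test_that("the hypergeometric pmf matches direct enumeration on small cases", {
  # C(5,2) * C(5,2) / C(10,4) = 100/210
  expect_equal(hypergeom_pmf(10, 5, 4, 2), 100 / 210, tolerance = 1e-12)
  # enumeration over all C(8,4) = 70 draws
  expect_equal(hypergeom_pmf(8, 3, 4, 2),
               mean(colSums(combn(8, 4) <= 3) == 2), tolerance = 1e-12)
  expect_equal(hypergeom_pmf(10, 0, 4, 0), 1.0)
  # n = N exhausts the urn: all of K is drawn
  expect_equal(hypergeom_pmf(6, 4, 6, 4), 1.0)
  expect_equal(sum(hypergeom_pmf(20, 7, 9, 0:7)), 1.0, tolerance = 1e-12)
})

test_that("the upper-tail p-value matches enumeration and is 1 at k = 0", {
  # C(5,4) * C(5,0) / C(10,4) = 5/210
  expect_equal(enrichment_pvalue(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(enrichment_pvalue(10, 5, 4, 0), 1.0)
  expect_equal(enrichment_pvalue(9, 4, 5, 2), enumerate_tail(9, 4, 5, 2),
               tolerance = 1e-12)
})

test_that("pmf sums to one and the tail agrees with an independent log-gamma route", {
  set.seed(55)
  for (i in 1:1000) {
    N <- sample(20:5000, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    lo <- max(0L, n + K - N)
    hi <- min(n, K)
    k <- if (lo == hi) lo else sample(lo:hi, 1)
    p <- enrichment_pvalue(N, K, n, k)
    oracle <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(p, oracle, tolerance = 1e-10)
    if (i <= 50) {
      expect_equal(sum(hypergeom_pmf(N, K, n, lo:hi)), 1.0,
                   tolerance = 1e-12)
    }
  }
})

test_that("the tail p-value is non-increasing in the observed overlap", {
  for (params in list(c(100, 30, 20), c(5000, 400, 900), c(50, 50, 10))) {
    N <- params[1]; K <- params[2]; n <- params[3]
    ks <- max(0, n + K - N):min(n, K)
    p <- enrichment_pvalue(N, K, n, ks)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("invalid counts are rejected with the violated inequality named", {
  expect_error(hypergeom_pmf(10, 11, 4, 2), "K \\(11\\) must not exceed N")
  expect_error(hypergeom_pmf(10, 5, 11, 2), "n \\(11\\) must not exceed N")
  expect_error(hypergeom_pmf(10, 5, 4, 5), "must not exceed min\\(n, K\\)")
  expect_error(enrichment_pvalue(10, 8, 6, 3), "too few non-members")
  expect_error(hypergeom_pmf(10, -1, 4, 0), "non-negative")
})

test_that("enrich_collection flags exact membership and ignores disjoint sets", {
  col <- gene_set_collection(list(A = sprintf("a%d", 1:20),
                                  B = sprintf("b%d", 1:30)))
  res <- enrich_collection(sprintf("a%d", 1:20), col)
  expect_true(res$enriched[res$set_name == "A"])
  expect_identical(res$set_name[1], "A")
  expect_true(all(res$n == 20))

  none <- enrich_collection(c("z1", "z2"), col)
  expect_false(any(none$enriched))
  expect_true(all(none$p_value == 1))
  expect_equal(attr(none, "n_outside_universe"), 2L)
  expect_equal(unique(none$n), 0L)

  expect_error(enrich_collection("a1", gene_set_collection(
    structure(list(), names = character(0)))), "empty")
})

test_that("a spiked set dominates a flat background", {
  set.seed(77)
  genes <- sprintf("G%04d", 1:2000)
  sets <- lapply(1:100, function(i) sample(genes, 50))
  names(sets) <- sprintf("S%03d", 1:100)
  col <- gene_set_collection(sets)
  spiked <- sets$S050
  detected <- union(spiked[runif(50) < 0.8],
                    genes[runif(2000) < 0.10])
  res <- enrich_collection(detected, col)
  expect_identical(res$set_name[1], "S050")
  # counts agree with brute-force intersections
  expect_equal(res$k[match("S050", res$set_name)],
               length(intersect(detected, spiked)))
})

test_that("BH correction is off by default and flagged when on", {
  col <- gene_set_collection(list(A = sprintf("a%d", 1:20),
                                  B = sprintf("b%d", 1:30)))
  raw <- enrich_collection(sprintf("a%d", 1:20), col)
  expect_identical(attr(raw, "correction"), "none")
  expect_false("p_adjusted" %in% names(raw))
  bh <- enrich_collection(sprintf("a%d", 1:20), col, correction = "BH")
  expect_identical(attr(bh, "correction"), "BH")
  expect_true(all(bh$p_adjusted >= bh$p_value))
})

test_that("expansion is the exact union of enriched members and monotone in the cutoff", {
  col <- gene_set_collection(list(S1 = c("A", "B"), S2 = c("B", "C"),
                                  S3 = c("D", "E", "F", "G")))
  res <- data.frame(set_name = c("S1", "S2", "S3"),
                    enriched = c(TRUE, TRUE, FALSE))
  ex <- expand_enriched(res, col)
  expect_identical(ex$member_genes, c("A", "B", "C"))
  expect_identical(ex$source_sets, c("S1", "S2"))

  res$enriched <- FALSE
  expect_length(expand_enriched(res, col)$member_genes, 0L)

  set.seed(10)
  genes <- sprintf("g%03d", 1:400)
  sets <- lapply(1:40, function(i) sample(genes, 30))
  names(sets) <- sprintf("S%02d", 1:40)
  col2 <- gene_set_collection(sets)
  detected <- sample(genes, 80)
  loose <- expand_enriched(enrich_collection(detected, col2, cutoff = 0.5),
                           col2)
  tight <- expand_enriched(enrich_collection(detected, col2, cutoff = 0.05),
                           col2)
  expect_true(all(tight$member_genes %in% loose$member_genes))
})

test_that("verification fractions match brute-force intersections", {
  ex <- structure(list(member_genes = sprintf("g%04d", 1:4231),
                       source_sets = "S", n_sets = 1L, n_genes = 4231L),
                  class = "expanded_set")
  v <- verify_expansion(ex, list(own_run = sprintf("g%04d", 1:737),
                                 self = ex$member_genes))
  expect_equal(v$n_overlap, c(737L, 4231L))
  expect_equal(v$pct_of_expanded, c(17.42, 100))
  set.seed(61)
  ref <- sample(sprintf("g%04d", 1:6000), 1500)
  v2 <- verify_expansion(ex, list(r = ref))
  expect_equal(v2$n_overlap, length(intersect(ex$member_genes, ref)))
})

test_that("common pathways are the intersection of enriched names across runs", {
  mk <- function(names_, enriched_) {
    data.frame(set_name = names_, enriched = enriched_,
               stringsAsFactors = FALSE)
  }
  same <- mk(c("A", "B", "C"), c(TRUE, TRUE, FALSE))
  expect_identical(common_pathways(list(same, same, same)), c("A", "B"))
  expect_length(common_pathways(list(mk("A", TRUE), mk("B", TRUE))), 0L)
  expect_error(common_pathways(list(same)), ">= 2")
})
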