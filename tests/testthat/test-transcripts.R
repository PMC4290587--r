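probe_table <- function(probe_id, gene_symbol, values) {
  df <- data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(values))
}

test_that("collapse keeps the highest-averaging probe per gene", {
  tab <- probe_table(c("p1", "p2", "p3"), c("G1", "G1", "G2"),
                     matrix(c(5, 5, 7.2, 7.2, 4, 4), nrow = 3, byrow = TRUE,
                            dimnames = list(NULL, c("s1", "s2"))))
  prof <- collapse_probes(tab)
  expect_equal(nrow(prof), 2L)
  expect_equal(prof$level[prof$gene == "G1"], 7.2)
  expect_identical(prof$probe_id[prof$gene == "G1"], "p2")
  expect_equal(prof$level[prof$gene == "G2"], 4.0)
})

test_that("collapse drops symbol-less probes with a tally and harmonizes aliases", {
  tab <- probe_table(c("p1", "p2", "p3"), c("oldG1", "", "junk"),
                     matrix(c(8, 8, 5, 5, 3, 3), nrow = 3, byrow = TRUE,
                            dimnames = list(NULL, c("s1", "s2"))))
  prof <- collapse_probes(tab, aliases = tiny_aliases())
  expect_identical(prof$gene, "G1")
  expect_equal(attr(prof, "n_dropped_symbolless"), 2L)
})

test_that("profiles are sorted by decreasing level with ties broken by symbol", {
  tab <- probe_table(c("p1", "p2", "p3"), c("B", "A", "C"),
                     matrix(c(5, 5, 5, 5, 9, 9), nrow = 3, byrow = TRUE,
                            dimnames = list(NULL, c("s1", "s2"))))
  prof <- collapse_probes(tab)
  expect_identical(prof$gene, c("C", "A", "B"))
})

test_that("overlap marking matches set membership at the extremes", {
  prof <- profiles_from_levels(c("A", "B", "C"), c(9, 7, 3))
  expect_identical(mark_overlap(prof, c("A", "B", "C")), c(1L, 1L, 1L))
  expect_identical(mark_overlap(prof, character(0)), c(0L, 0L, 0L))
})

test_that("total overlap of probabilistic detection stays within 3 SD of its expectation", {
  set.seed(8)
  n <- 4000L
  levels <- sort(runif(n, 2.8, 14.48), decreasing = TRUE)
  prof <- profiles_from_levels(sprintf("G%04d", 1:n), levels)
  p <- 0.1 + 0.9 * (levels - 2.8) / (14.48 - 2.8)
  detected <- prof$gene[runif(n) < p]
  total <- sum(mark_overlap(prof, detected))
  expect_lt(abs(total - sum(p)), 3 * sqrt(sum(p * (1 - p))))
})

test_that("window scores equal brute-force sums for sliding and tumbling windows", {
  expect_equal(window_scores(c(1, 0, 1, 1), w = 2, step = 1)$score,
               c(1, 1, 2))
  expect_true(all(window_scores(rep(1, 30), w = 7)$score == 7))
  set.seed(13)
  ind <- rbinom(300, 1, 0.4)
  for (step in c(1L, 10L, 50L)) {
    ws <- window_scores(ind, w = 50, step = step)
    brute <- vapply(ws$start_rank, function(s) sum(ind[s:(s + 49)]), 0)
    expect_equal(ws$score, brute)
  }
  expect_error(window_scores(ind, w = 0), "positive")
  expect_error(window_scores(ind, w = 10, step = 0), "positive")
  expect_error(window_scores(ind, w = 301), "exceeds")
})

test_that("cumulative overlap is a monotone running sum ending at the total", {
  expect_equal(cumulative_overlap(c(1, 0, 1)), c(1, 1, 2))
  expect_equal(cumulative_overlap(rep(0, 5)), rep(0, 5))
  set.seed(3)
  ind <- rbinom(500, 1, 0.3)
  cum <- cumulative_overlap(ind)
  expect_true(all(diff(cum) >= 0))
  expect_equal(cum[length(cum)], sum(ind))
})

test_that("tumbling window scores sum to the final cumulative count", {
  set.seed(17)
  ind <- rbinom(600, 1, 0.5)
  ws <- window_scores(ind, w = 50, step = 50)
  expect_equal(sum(ws$score), cumulative_overlap(ind)[600])
})

test_that("the expression threshold boundary belongs to the high group", {
  prof <- profiles_from_levels(c("A", "B"), c(6.0, 5.99))
  groups <- expression_groups(prof, 6.0)
  expect_identical(groups$high, "A")
  expect_identical(groups$low, "B")
  none_low <- expression_groups(prof, 2.0)
  expect_length(none_low$low, 0L)
})

test_that("variation ratio is (max - min) / mean with a positive-mean guard", {
  expect_equal(variation_ratio(c(4, 4, 4, 4)), 0)
  expect_equal(variation_ratio(c(2, 4)), 2 / 3)
  expect_error(variation_ratio(c(-2, 2)), "positive mean")
  prof <- profiles_from_levels(c("A", "B"), c(5, 7), n_samples = 3)
  expect_equal(variation_ratios(prof), c(0, 0))
})

test_that("most variation ratios stay small under mild per-sample jitter", {
  set.seed(44)
  n <- 2000L
  level <- runif(n, 4, 14)
  vals <- matrix(rnorm(n * 8, mean = level, sd = 0.15), nrow = n)
  ratios <- apply(vals, 1, variation_ratio)
  expect_gt(mean(ratios <= 0.2), 0.90)
})

test_that("concordance cells are disjoint, exhaustive and match brute force", {
  set.seed(29)
  genes <- sprintf("G%03d", 1:300)
  prof <- profiles_from_levels(genes[1:250], runif(250, 2.8, 14.48))
  groups <- expression_groups(prof, 6)
  sets <- list(s1 = sample(genes, 120), s2 = sample(genes, 40),
               all_high = groups$high)
  tab <- concordance_table(sets, prof, 6)
  expect_equal(tab$high + tab$low + tab$absent, tab$n)
  expect_true(all(abs(tab$high_pct + tab$low_pct + tab$absent_pct - 100)
                  < 0.05))
  for (nm in c("s1", "s2")) {
    s <- sets[[nm]]
    row <- tab[tab$set == nm, ]
    expect_equal(row$high, length(intersect(s, groups$high)))
    expect_equal(row$low, length(intersect(s, groups$low)))
    expect_equal(row$absent, length(setdiff(s, prof$gene)))
  }
  row <- tab[tab$set == "all_high", ]
  expect_equal(row$low + row$absent, 0L)
  expect_equal(row$high_pct, 100)
})

test_that("a 4,957-gene set with 3,989 profiled genes has 968 absent", {
  genes <- sprintf("G%04d", 1:4957)
  prof <- profiles_from_levels(genes[1:3989], runif(3989, 6.5, 14))
  tab <- concordance_table(list(detected = genes), prof, 6)
  expect_equal(tab$absent, 968L)
  expect_equal(tab$absent_pct, format_percent(968, 4957))
  expect_equal(tab$high_pct, 80.47)
})
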