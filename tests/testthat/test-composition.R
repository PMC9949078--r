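test_that("compare_groups finds nothing when groups are copies", {
  g <- gaussian_test_matrix(1, n_null = 50, n_a = 4, n_b = 4)
  m <- g$matrix
  # make group B an exact copy of group A
  m[, paste0("S0", 5:8)] <- m[, paste0("S0", 1:4)]
  res <- compare_groups(m, g$groups)
  expect_false(any(res$significant))
  expect_true(all(res$p == 1))
})

test_that("an extreme separation is significant at q = 0.05", {
  set.seed(5)
  m <- tibble::tibble(transcript_id = "t1", gene_symbol = "G1")
  for (i in 1:3) m[[paste0("A", i)]] <- 100 + rnorm(1, 0, 0.1)
  for (i in 1:3) m[[paste0("B", i)]] <- 0 + abs(rnorm(1, 0, 0.01))
  groups <- make_groups(c(paste0("A", 1:3), paste0("B", 1:3)), c(3, 3))
  res <- compare_groups(m, groups)
  expect_true(res$significant)
  expect_lt(res$p, 1e-6)
})

test_that("per-transcript tests equal welch_t/student_t row by row", {
  g <- gaussian_test_matrix(33, n_null = 25, n_a = 5, n_b = 6)
  vals <- as.matrix(g$matrix[, -(1:2)])
  for (welch in c(FALSE, TRUE)) {
    res <- compare_groups(g$matrix, g$groups,
                          stats_config(welch = welch))
    f <- if (welch) welch_t else student_t
    for (i in c(1, 7, 25)) {
      o <- f(vals[i, 1:5], vals[i, 6:11])
      expect_equal(res$t[i], o$t, tolerance = 1e-12)
      expect_equal(res$df[i], unname(o$df), tolerance = 1e-12)
      expect_equal(res$p[i], o$p, tolerance = 1e-12)
    }
  }
})

test_that("compare_groups is invariant under within-group reordering", {
  g <- gaussian_test_matrix(12, n_null = 30)
  res1 <- compare_groups(g$matrix, g$groups)
  g2 <- g$groups[c(sample(1:8), sample(9:17)), ]
  res2 <- compare_groups(g$matrix, g2)
  expect_equal(res1$p, res2$p)
  expect_equal(res1$q_value, res2$q_value)
})

test_that("planted 3-SD effects are recovered with controlled FDR", {
  hits <- 0; total_fd <- 0; total_rej <- 0
  n_rep <- 25
  for (seed in seq_len(n_rep)) {
    g <- gaussian_test_matrix(seed, n_null = 200, n_diff = 10)
    res <- compare_groups(g$matrix, g$groups)
    called <- res$transcript_id[res$significant]
    hits <- hits + length(intersect(called, g$diff_ids))
    total_fd <- total_fd + length(setdiff(called, g$diff_ids))
    total_rej <- total_rej + length(called)
  }
  expect_gte(hits / (10 * n_rep), 0.9)
  expect_lte(total_fd / max(total_rej, 1), 0.1)
})

test_that("presence calls use a strict threshold on the group mean", {
  m <- tibble::tibble(
    transcript_id = c("t1", "t2"), gene_symbol = c("G1", "G2"),
    cell_type = c("floor_type", "real_type"),
    a1 = c(1, 1000), a2 = c(1, 900), b1 = c(1, 1100), b2 = c(1, 950))
  groups <- make_groups(c("a1", "a2", "b1", "b2"), c(2, 2))
  pres <- presence_table(m, groups, stats_config(presence_threshold = 1))
  floor_row <- pres[pres$cell_type == "floor_type", ]
  real_row <- pres[pres$cell_type == "real_type", ]
  expect_false(floor_row$present_A | floor_row$present_B)
  expect_true(real_row$present_A && real_row$present_B)
  expect_equal(attr(pres, "n_cell_types_detected"), 1)
})

test_that("raising the presence threshold never adds a present cell type", {
  g <- gaussian_test_matrix(77, n_null = 40, baseline = 20, sd = 10)
  m <- g$matrix
  m$cell_type <- rep(paste0("ct", 1:8), each = 5)
  prev_present <- NULL
  for (thr in c(0, 10, 30, 100)) {
    pres <- presence_table(m, g$groups,
                           stats_config(presence_threshold = thr))
    now <- pres$cell_type[pres$present_any]
    if (!is.null(prev_present)) expect_true(all(now %in% prev_present))
    prev_present <- now
  }
})

test_that("exclusive genes follow the all-vs-none and any-vs-none rules", {
  m <- tibble::tibble(
    transcript_id = paste0("t", 1:4),
    gene_symbol = c("BOTH", "AONLY", "PARTIAL_A", "NEITHER"),
    cell_type = "ct",
    a1 = c(10, 10, 10, 1), a2 = c(12, 12, 1, 1),
    b1 = c(11, 1, 1, 1), b2 = c(9, 1, 1, 1))
  groups <- make_groups(c("a1", "a2", "b1", "b2"), c(2, 2))
  strict <- exclusive_genes(m, groups, stats_config())
  expect_equal(strict$gene_symbol, "AONLY")
  expect_equal(strict$exclusive_to, "A")
  relaxed <- exclusive_genes(m, groups,
                             stats_config(exclusive_rule = "any-vs-none"))
  expect_setequal(relaxed$gene_symbol, c("AONLY", "PARTIAL_A"))
})

test_that("a gene exclusive via one isoform counts through the gene level", {
  m <- tibble::tibble(
    transcript_id = c("t1.1", "t1.2"),
    gene_symbol = c("G1", "G1"), cell_type = "ct",
    a1 = c(10, 1), a2 = c(1, 10), b1 = c(1, 1), b2 = c(1, 1))
  groups <- make_groups(c("a1", "a2", "b1", "b2"), c(2, 2))
  res <- exclusive_genes(m, groups, stats_config())
  expect_equal(res$gene_symbol, "G1")  # every A sample has some isoform on
})

test_that("QC comparison matches the Welch oracle and flags planted shifts", {
  set.seed(3)
  qc <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:17),
    total_reads = round(c(rnorm(8, 3e7, 2e6), rnorm(9, 3e7, 2e6))),
    avg_read_length = c(rnorm(8, 96, 1), rnorm(9, 86, 1)))
  groups <- make_groups(qc$sample_id, c(8, 9), c("F", "M"))
  res <- compare_qc_metrics(qc, groups)
  expect_equal(nrow(res), 2)
  rl <- res[res$metric == "avg_read_length", ]
  expect_lt(rl$p, 0.001)
  o <- welch_t(qc$avg_read_length[1:8], qc$avg_read_length[9:17])
  expect_equal(rl$p, o$p, tolerance = 1e-10)
  expect_equal(rl$t, o$t, tolerance = 1e-10)
  # identical tables per group -> p = 1
  qc2 <- tibble::tibble(sample_id = c(paste0("F", 1:3), paste0("M", 1:3)),
                        depth = c(4, 5, 6, 4, 5, 6))
  g2 <- make_groups(qc2$sample_id, c(3, 3))
  expect_equal(compare_qc_metrics(qc2, g2)$p, 1)
  # missing values: metric skipped with warning
  qc2$bad <- c(1, NA, 3, 4, 5, 6)
  expect_warning(res2 <- compare_qc_metrics(qc2, g2), "skipped")
  expect_false("bad" %in% res2$metric)
})
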