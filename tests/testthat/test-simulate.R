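small_cfg <- function(...) {
  defaults <- list(n_cell_types = 5, markers_per_type = 3,
                   n_shared_markers = 2, n_background_genes = 100,
                   group_sizes = c(4, 4), seed = 11)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("simulated marker files reproduce the ground-truth unique set", {
  d <- withr::local_tempdir()
  cfg <- sim_config(n_cell_types = 3, markers_per_type = 4,
                    n_shared_markers = 2, seed = 2)
  mk <- simulate_markers(cfg, d)
  expect_length(mk$files, 3)
  expect_equal(nrow(mk$truth$unique_marker_map), 12)
  recs <- load_marker_tables(mk$files)
  ref <- build_reference(recs)
  expect_setequal(ref$gene_symbol, mk$truth$unique_marker_map$gene_symbol)
  expect_length(mk$truth$shared_genes, 2)
  expect_false(any(mk$truth$shared_genes %in% ref$gene_symbol))
})

test_that("without shared markers every gene survives reference building", {
  d <- withr::local_tempdir()
  mk <- simulate_markers(small_cfg(n_shared_markers = 0), d)
  ref <- build_reference(load_marker_tables(mk$files))
  expect_equal(nrow(ref), 15)
})

test_that("the generator is deterministic byte-for-byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_cfg(n_exclusive_genes = c(1, 1), n_group_diff_genes = 2)
  ds1 <- simulate_dataset(cfg, d1)
  ds2 <- simulate_dataset(cfg, d2)
  for (f in c("counts.csv", "groups.csv", "qc.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  expect_identical(readLines(ds1$marker_files[1]),
                   readLines(ds2$marker_files[1]))
})

test_that("simulated files parse cleanly and match the manifest", {
  d <- withr::local_tempdir()
  ds <- simulate_dataset(small_cfg(), d)
  m <- read_matrix(ds$counts_path)
  expect_equal(nrow(m), ds$truth$n_transcripts)
  groups <- read_groups(ds$groups_path)
  expect_equal(nrow(groups), 8)
  expect_equal(sort(unique(groups$group)), c("F", "M"))
  qc <- readr::read_csv(ds$qc_path, show_col_types = FALSE)
  expect_equal(nrow(qc), 8)
  # isoform fan-out present: some symbols have 2 transcripts
  expect_gt(max(table(m$gene_symbol)), 1)
  # background tail exercises the low-expression filter
  attr(m, "normalized") <- TRUE
  expect_lt(nrow(filter_low_expression(m, threshold = 1)), nrow(m))
})

test_that("zero-weight cell types are absent downstream", {
  d <- withr::local_tempdir()
  w <- matrix(0, nrow = 5, ncol = 2)
  w[1:3, 1] <- c(0.5, 0.3, 0.2)
  w[1:3, 2] <- c(0.4, 0.4, 0.2)
  cfg <- small_cfg(proportions = w)
  ds <- simulate_dataset(cfg, d)
  m <- read_matrix(ds$counts_path)
  groups <- read_groups(ds$groups_path)
  norm <- tmm_normalize(m)
  ref <- build_reference(load_marker_tables(ds$marker_files))
  ann <- annotate_matrix(norm$matrix, ref)
  pres <- presence_table(ann, groups)
  absent <- paste0("cell_type_0", 4:5)
  expect_false(any(pres$present_any[pres$cell_type %in% absent]))
  present <- pres$cell_type[pres$present_any]
  expect_setequal(present, paste0("cell_type_0", 1:3))
})

test_that("a null dataset yields (almost) no significant transcripts", {
  d <- withr::local_tempdir()
  ds <- simulate_dataset(small_cfg(seed = 99), d)
  res <- run_pipeline(run_config(markers = file.path(d, "markers"),
                                 counts = ds$counts_path,
                                 groups = ds$groups_path,
                                 out_dir = file.path(d, "out")))
  expect_lte(sum(res$report$tests$significant), 1)
  expect_equal(nrow(res$report$exclusive), 0)
})

test_that("planted QC shifts are detected and nulls are not forced", {
  d <- withr::local_tempdir()
  cfg <- small_cfg(qc_group_means = list(avg_read_length = c(96, 86)))
  qc <- simulate_qc(cfg, d)
  groups <- tibble::tibble(sample_id = qc$sample_id,
                           group = rep(c("F", "M"), each = 4))
  res <- compare_qc_metrics(qc, groups)
  expect_lt(res$p[res$metric == "avg_read_length"], 0.001)
  expect_gt(min(res$p[res$metric != "avg_read_length"]), 0.001)
})
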