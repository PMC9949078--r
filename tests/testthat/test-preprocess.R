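test_that("identical samples get unit factors and equal columns", {
  m <- nb_fixture_matrix(1)[, 1:3]
  m$S2 <- m$S1
  norm <- tmm_normalize(m)
  expect_equal(unname(norm$factors), c(1, 1))
  expect_equal(norm$matrix$S1, norm$matrix$S2)
})

test_that("doubling every count leaves TMM factors at 1", {
  m <- nb_fixture_matrix(2)[, 1:3]
  m$S2 <- 2 * m$S1
  norm <- tmm_normalize(m)
  expect_equal(unname(norm$factors), c(1, 1), tolerance = 1e-10)
})

test_that("TMM factors match the frozen reference-implementation fixture", {
  fx <- readr::read_csv(system.file("extdata", "tmm_reference_factors.csv",
                                    package = "markerdecon"),
                        show_col_types = FALSE)
  for (seed in c(1, 5, 12, 20)) {
    m <- nb_fixture_matrix(seed)
    f <- tmm_normalize(m)$factors
    want <- fx |> dplyr::filter(seed == !!seed)
    expect_equal(unname(f[want$sample]), want$factor, tolerance = 1e-6,
                 info = paste("seed", seed))
  }
})

test_that("factor geometric mean is 1 and factors are scale invariant", {
  for (seed in 3:6) {
    m <- nb_fixture_matrix(seed)
    f <- tmm_normalize(m)$factors
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-8)
    m2 <- m
    m2$S3 <- m2$S3 * 7
    # M and A are proportion-based, so the trim window is unchanged; with
    # the unweighted mean the factor is exactly scale free, while the
    # precision weights depend on the raw counts and shift it slightly
    fu <- tmm_normalize(m, weighted = FALSE)$factors
    fu2 <- tmm_normalize(m2, weighted = FALSE)$factors
    expect_equal(unname(fu2), unname(fu), tolerance = 1e-8)
    f2 <- tmm_normalize(m2)$factors
    expect_equal(unname(f2), unname(f), tolerance = 0.05)
  }
})

test_that("offset puts unexpressed transcripts at the floor", {
  m <- nb_fixture_matrix(4)
  m[1, -(1:2)] <- as.list(rep(0, 6))
  norm <- tmm_normalize(m, offset = 1)
  expect_equal(as.numeric(norm$matrix[1, -(1:2)]), rep(1, 6))
  expect_true(all(as.matrix(norm$matrix[, -(1:2)]) >= 1))
})

test_that("zero library size and re-normalization are errors", {
  m <- nb_fixture_matrix(5)[, 1:4]
  m$S3 <- 0
  expect_error(tmm_normalize(m), "zero library size")
  norm <- tmm_normalize(nb_fixture_matrix(5))
  expect_error(tmm_normalize(norm$matrix), "already normalized")
})

test_that("sparse matrices fall back to the untrimmed mean with a warning", {
  m <- nb_fixture_matrix(9, n_genes = 12)
  w <- capture_warnings(tmm_normalize(m))
  expect_true(any(grepl("untrimmed mean", w)))
})

test_that("expression filter keeps rows at the boundary and drops below", {
  m <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                      gene_symbol = c("A", "B", "C"),
                      s1 = c(0, 1, 5), s2 = c(0, 1, 7))
  attr(m, "normalized") <- TRUE
  out <- filter_low_expression(m, threshold = 1)
  expect_equal(out$transcript_id, c("t2", "t3"))  # mean exactly 1 retained
})

test_that("filter row count matches the row-mean oracle and is monotone", {
  m <- nb_fixture_matrix(11, n_genes = 100)
  attr(m, "normalized") <- TRUE
  vals <- as.matrix(m[, -(1:2)])
  prev <- Inf
  for (thr in c(0, 5, 50, 500)) {
    out <- filter_low_expression(m, threshold = thr)
    expect_equal(nrow(out), sum(rowMeans(vals) >= thr))
    expect_lte(nrow(out), prev)
    prev <- nrow(out)
  }
  expect_error(filter_low_expression(m, threshold = 1e12), "below")
})

test_that("matrices round-trip through CSV within 1e-9", {
  m <- nb_fixture_matrix(13)
  norm <- tmm_normalize(m)$matrix
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix(norm, path)
  back <- read_matrix(path)
  expect_equal(back$transcript_id, norm$transcript_id)
  expect_equal(as.matrix(back[, -(1:2)]), as.matrix(norm[, -(1:2)]),
               tolerance = 1e-9)
})

test_that("duplicate transcript ids and non-numeric cells are format errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("transcript_id,gene_symbol,s1,s2",
               "t1,A,1,2", "t1,B,3,4"), path)
  expect_error(read_matrix(path), "Duplicate transcript_id")
  writeLines(c("transcript_id,gene_symbol,s1,s2",
               "t1,A,1,2", "t2,B,oops,4"), path)
  expect_error(read_matrix(path), "Non-numeric")
})
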