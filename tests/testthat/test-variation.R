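test_that("CV matches the hand calculation and basic identities", {
  m <- tibble::tibble(transcript_id = c("t1", "t2"),
                      gene_symbol = c("G1", "G2"),
                      a1 = c(1, 7), a2 = c(2, 7), a3 = c(3, 7),
                      b1 = c(2, 8), b2 = c(4, 8))
  attr(m, "normalized") <- TRUE
  groups <- make_groups(c("a1", "a2", "a3", "b1", "b2"), c(3, 2))
  cv <- cv_by_group(m, groups)
  expect_equal(cv$cv_A[1], 0.5)        # mean 2, sample SD 1
  expect_equal(cv$cv_A[2], 0)          # constant values
  expect_equal(cv$higher_group, c("B", "B"))
})

test_that("CV is invariant to positive scaling", {
  m <- nb_fixture_matrix(21, n_genes = 30)
  m[, -(1:2)] <- m[, -(1:2)] + 1
  attr(m, "normalized") <- TRUE
  groups <- make_groups(paste0("S", 1:6), c(3, 3))
  cv1 <- cv_by_group(m, groups)
  m2 <- m
  m2[, -(1:2)] <- m2[, -(1:2)] * 3.7
  attr(m2, "normalized") <- TRUE
  cv2 <- cv_by_group(m2, groups)
  expect_equal(cv2$cv_A, cv1$cv_A, tolerance = 1e-12)
  expect_equal(cv2$cv_B, cv1$cv_B, tolerance = 1e-12)
})

test_that("rank-1 data loads 100% on PC1 and variance sums to 100", {
  base <- c(1, 2, 3, 4, 5)
  m <- tibble::tibble(transcript_id = paste0("t", 1:10),
                      gene_symbol = paste0("G", 1:10))
  dirv <- seq(0.1, 1, length.out = 10)
  for (i in seq_along(base)) {
    m[[paste0("S", i)]] <- 10 + base[i] * dirv
  }
  attr(m, "normalized") <- TRUE
  groups <- make_groups(paste0("S", 1:5), c(2, 3))
  pca <- pca_expression(m, groups, n_components = 2)
  expect_equal(pca$explained_pct[1], 100, tolerance = 1e-8)
  expect_equal(sum(pca$explained_pct), 100, tolerance = 1e-6)
})

test_that("explained variance matches an eigen-decomposition oracle", {
  m <- nb_fixture_matrix(31, n_genes = 20)
  attr(m, "normalized") <- TRUE
  groups <- make_groups(paste0("S", 1:6), c(3, 3))
  pca <- pca_expression(m, groups, n_components = 3)
  x <- scale(t(as.matrix(m[, -(1:2)])), center = TRUE, scale = FALSE)
  ev <- eigen(cov(x), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(pca$explained_pct[seq_along(ev)],
               100 * ev / sum(ev), tolerance = 1e-8)
  expect_equal(sum(pca$explained_pct), 100, tolerance = 1e-6)
  # components orthonormal
  rot <- pca$rotation
  expect_equal(t(rot) %*% rot, diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("ellipsoid radii are exactly 2x the per-group score SD", {
  m <- nb_fixture_matrix(32, n_genes = 40)
  attr(m, "normalized") <- TRUE
  groups <- make_groups(paste0("S", 1:6), c(3, 3))
  pca <- pca_expression(m, groups, n_components = 2)
  for (g in c("A", "B")) {
    sc <- pca$scores[pca$scores$group == g, ]
    for (pc in c("PC1", "PC2")) {
      ell <- pca$ellipsoids[pca$ellipsoids$group == g &
                              pca$ellipsoids$component == pc, ]
      expect_equal(ell$center, mean(sc[[pc]]))
      expect_equal(ell$radius, 2 * sd(sc[[pc]]))
    }
  }
})

test_that("explained variance is invariant under sample reordering", {
  m <- nb_fixture_matrix(33, n_genes = 25)
  attr(m, "normalized") <- TRUE
  groups <- make_groups(paste0("S", 1:6), c(3, 3))
  p1 <- pca_expression(m, groups)
  perm <- c("transcript_id", "gene_symbol", paste0("S", c(4, 2, 6, 1, 3, 5)))
  m2 <- m[, perm]
  attr(m2, "normalized") <- TRUE
  p2 <- pca_expression(m2, groups)
  expect_equal(p1$explained_pct, p2$explained_pct, tolerance = 1e-10)
  expect_error(pca_expression(m[, 1:4], groups), "at least 3")
})

test_that("cv scatter writes a plot file and a CSV with one row per record", {
  m <- nb_fixture_matrix(34, n_genes = 15)
  m[, -(1:2)] <- m[, -(1:2)] + 1
  attr(m, "normalized") <- TRUE
  groups <- make_groups(paste0("S", 1:6), c(3, 3))
  cv <- cv_by_group(m, groups)
  img <- withr::local_tempfile(fileext = ".pdf")
  paths <- write_cv_scatter(cv, img)
  expect_true(file.exists(paths[1]))
  back <- readr::read_csv(paths[2], show_col_types = FALSE)
  expect_equal(nrow(back), nrow(cv))
  p <- plot_cv_scatter(cv)
  expect_s3_class(p, "ggplot")
})

test_that("pca and qc plots build", {
  m <- nb_fixture_matrix(35, n_genes = 20)
  attr(m, "normalized") <- TRUE
  groups <- make_groups(paste0("S", 1:6), c(3, 3))
  pca <- pca_expression(m, groups)
  expect_s3_class(autoplot(pca), "ggplot")
  qc <- tibble::tibble(sample_id = paste0("S", 1:6),
                       depth = c(30, 31, 29, 40, 41, 39))
  expect_s3_class(plot_qc_metrics(qc, groups), "ggplot")
})
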