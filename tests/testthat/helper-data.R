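# Shared generators for tests. Everything is built in code under fixed seeds;
# the only stored fixture is the frozen TMM factor table from the reference
# implementation (fixtures/tmm_edger_factors.csv).

# Negative binomial count matrix used for the TMM oracle comparison:
# 200 genes x 6 samples, lognormal baseline means, 10% of genes per sample
# up-regulated 4x so that true scaling factors differ from 1.
nb_fixture_matrix <- function(seed, n_genes = 200, n_samples = 6) {
  set.seed(seed)
  mu <- rlnorm(n_genes, log(100), 1.5)
  counts <- sapply(seq_len(n_samples), function(s) {
    bump <- sample(n_genes, round(0.1 * n_genes))
    m <- mu
    m[bump] <- m[bump] * 4
    rnbinom(n_genes, mu = m, size = 10)
  })
  colnames(counts) <- paste0("S", seq_len(n_samples))
  dplyr::bind_cols(
    tibble::tibble(transcript_id = sprintf("T%03d", seq_len(n_genes)),
                   gene_symbol = sprintf("G%03d", seq_len(n_genes))),
    tibble::as_tibble(counts))
}

# Random marker-record table with seeded cross-cell-type duplicates, for the
# reference-builder oracle.
random_marker_table <- function(seed, n_rows = 50, n_types = 6) {
  set.seed(seed)
  types <- paste0("ct", seq_len(n_types))
  genes <- paste0("g", sample(40, n_rows, replace = TRUE))
  tibble::tibble(gene_symbol = genes,
                 expression = round(runif(n_rows, 0, 100), 2),
                 cell_type = sample(types, n_rows, replace = TRUE))
}

# Set-algebra oracle for build_reference: symbols with exactly one distinct
# cell type survive.
reference_oracle_genes <- function(records) {
  sym <- toupper(trimws(records$gene_symbol))
  tab <- tapply(records$cell_type, sym, function(x) length(unique(x)))
  sort(names(tab)[tab == 1])
}

# Brute-force two-stage BKY enumerator, written against the procedure
# definition: both stages are explicit linear step-ups at q' = q/(1+q),
# stage 2 at level q' * m / (m - r1).
bky_oracle_reject <- function(p, q) {
  m <- length(p)
  bh_reject <- function(alpha) {
    o <- order(p)
    ok <- which(p[o] <= seq_len(m) * alpha / m)
    rej <- rep(FALSE, m)
    if (length(ok) > 0) rej[o[seq_len(max(ok))]] <- TRUE
    rej
  }
  q1 <- q / (1 + q)
  s1 <- bh_reject(q1)
  r1 <- sum(s1)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh_reject(q1 * m / (m - r1))
}

# Simple two-group Gaussian matrix on the normalized scale, with optional
# planted mean shifts (in units of the within-group SD), for the FDR and
# power benchmarks.
gaussian_test_matrix <- function(seed, n_null = 200, n_diff = 0,
                                 shift_sd = 3, n_a = 8, n_b = 9,
                                 baseline = 50, sd = 5) {
  set.seed(seed)
  n <- n_null + n_diff
  vals <- matrix(rnorm(n * (n_a + n_b), baseline, sd), nrow = n)
  if (n_diff > 0) {
    vals[seq_len(n_diff), seq_len(n_a) + n_b * 0] <-
      vals[seq_len(n_diff), seq_len(n_a)] + shift_sd * sd
  }
  colnames(vals) <- sprintf("S%02d", seq_len(n_a + n_b))
  m <- dplyr::bind_cols(
    tibble::tibble(transcript_id = sprintf("T%03d", seq_len(n)),
                   gene_symbol = sprintf("G%03d", seq_len(n))),
    tibble::as_tibble(vals))
  groups <- tibble::tibble(sample_id = colnames(vals),
                           group = rep(c("A", "B"), c(n_a, n_b)))
  list(matrix = m, groups = groups,
       diff_ids = if (n_diff > 0) m$transcript_id[seq_len(n_diff)]
                  else character())
}

make_groups <- function(sample_ids, sizes, labels = c("A", "B")) {
  tibble::tibble(sample_id = sample_ids, group = rep(labels, sizes))
}
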