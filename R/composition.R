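#' Statistical configuration for composition analysis
#'
#' @param fdr_q Target FDR level for the two-stage adjustment (default 0.05).
#' @param welch Use Welch's correction for the per-transcript multiple
#'   t-tests (default `FALSE`: pooled-variance unpaired t-test, the common
#'   default of commercial statistics software for "multiple unpaired
#'   t-tests"). Sequencing-QC comparisons always use Welch.
#' @param presence_threshold Abundance strictly above which a transcript
#'   counts as expressed (default 1, the normalization offset: any evidence
#'   above the unexpressed floor).
#' @param exclusive_rule `"all-vs-none"` (default): a gene is exclusive to a
#'   group only if every sample of that group expresses it and no sample of
#'   the other group does; `"any-vs-none"` relaxes "every" to "at least one".
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(fdr_q = 0.05, welch = FALSE, presence_threshold = 1,
                         exclusive_rule = c("all-vs-none", "any-vs-none")) {
  stopifnot(fdr_q > 0, fdr_q < 1, presence_threshold >= 0)
  structure(list(fdr_q = fdr_q, welch = isTRUE(welch),
                 presence_threshold = presence_threshold,
                 exclusive_rule = match.arg(exclusive_rule)),
            class = "stats_config")
}

#' Per-transcript group comparison with two-stage FDR
#'
#' Runs one unpaired t-test per annotated transcript (pooled-variance by
#' default, Welch with `cfg$welch`), then adjusts the p-values across all
#' transcripts with the Benjamini-Krieger-Yekutieli two-stage procedure at
#' level `cfg$fdr_q`. A transcript is `significant` if it is rejected by the
#' two-stage procedure; `p` is also reported so raw-p and FDR-adjusted
#' significance can be distinguished.
#'
#' @param a Annotated matrix (or any expression tibble; `cell_type` /
#'   `gene_symbol` columns are carried through when present).
#' @param groups Sample-to-group tibble (`sample_id`, `group`), exactly two
#'   groups with at least 2 samples each.
#' @param cfg A [stats_config()].
#' @return A tibble with one row per transcript: identifiers, per-group mean
#'   and SD, `t`, `df`, `p`, `q_value`, `significant`.
#' @export
compare_groups <- function(a, groups, cfg = stats_config()) {
  if (inherits(a, "tmm_norm")) a <- a$matrix
  sc <- sample_cols(a)
  groups <- check_groups(groups, sc)
  lv <- group_levels(groups)
  idx_a <- match(groups$sample_id[groups$group == lv[1]], sc)
  idx_b <- match(groups$sample_id[groups$group == lv[2]], sc)
  if (length(idx_a) < 2 || length(idx_b) < 2) {
    abort("Each group needs at least 2 samples.")
  }
  vals <- as.matrix(a[, sc])
  tt <- row_t_tests(vals, idx_a, idx_b, var_equal = !cfg$welch)
  adj <- bky_two_stage(tt$p, q = cfg$fdr_q)
  out <- tibble(transcript_id = a$transcript_id)
  if ("gene_symbol" %in% names(a)) out$gene_symbol <- a$gene_symbol
  if ("cell_type" %in% names(a)) out$cell_type <- a$cell_type
  out[[paste0("mean_", lv[1])]] <- tt$mean_a
  out[[paste0("sd_", lv[1])]] <- tt$sd_a
  out[[paste0("mean_", lv[2])]] <- tt$mean_b
  out[[paste0("sd_", lv[2])]] <- tt$sd_b
  out$t <- tt$t
  out$df <- tt$df
  out$p <- tt$p
  out$q_value <- adj$q_value
  out$significant <- adj$rejected
  out
}

#' Cell-type presence per group
#'
#' A cell type is called present in a group if at least one of its marker
#' transcripts has group-mean abundance strictly above
#' `cfg$presence_threshold` (with TMM+1 normalization, strictly above the
#' unexpressed floor of 1). Expression of a gene unique to one cell type is
#' taken as evidence that the cell type is present in the sampled tissue.
#'
#' @inheritParams compare_groups
#' @return A tibble with one row per cell type: `cell_type`,
#'   `present_<group>` and `n_markers_<group>` (supporting marker transcript
#'   counts) per group, and `present_any`. Attribute
#'   `n_cell_types_detected` counts cell types present in at least one group.
#' @export
presence_table <- function(a, groups, cfg = stats_config()) {
  if (!"cell_type" %in% names(a)) abort("`a` must be an annotated matrix.")
  if (nrow(a) == 0) abort("Annotated matrix is empty.")
  sc <- sample_cols(a)
  groups <- check_groups(groups, sc)
  lv <- group_levels(groups)
  vals <- as.matrix(a[, sc])
  out <- tibble(cell_type = sort(unique(a$cell_type)))
  for (g in lv) {
    gs <- groups$sample_id[groups$group == g]
    gmean <- rowMeans(vals[, gs, drop = FALSE])
    hits <- tibble(cell_type = a$cell_type,
                   hit = gmean > cfg$presence_threshold) |>
      group_by(.data$cell_type) |>
      summarise(n = sum(.data$hit), .groups = "drop")
    out[[paste0("present_", g)]] <-
      hits$n[match(out$cell_type, hits$cell_type)] > 0
    out[[paste0("n_markers_", g)]] <-
      hits$n[match(out$cell_type, hits$cell_type)]
  }
  out$present_any <- out[[paste0("present_", lv[1])]] |
    out[[paste0("present_", lv[2])]]
  attr(out, "n_cell_types_detected") <- sum(out$present_any)
  out
}

#' Group-exclusive genes
#'
#' Detects genes expressed in one group only. Under the default
#' `"all-vs-none"` rule a gene is exclusive to group G when *every* sample
#' of G has at least one of the gene's transcripts above
#' `cfg$presence_threshold` and *no* sample of the other group has any
#' transcript above it; `"any-vs-none"` relaxes the first condition to at
#' least one sample.
#'
#' @inheritParams compare_groups
#' @return A tibble with columns `gene_symbol`, `cell_type`,
#'   `exclusive_to` (group label). The per-group lists are disjoint by
#'   construction.
#' @export
exclusive_genes <- function(a, groups, cfg = stats_config()) {
  if (!"gene_symbol" %in% names(a)) abort("`a` must carry gene symbols.")
  sc <- sample_cols(a)
  groups <- check_groups(groups, sc)
  lv <- group_levels(groups)
  vals <- as.matrix(a[, sc]) > cfg$presence_threshold
  # per gene x sample: any transcript of the gene expressed in that sample
  expressed <- rowsum(vals + 0, group = a$gene_symbol) > 0
  ct_by_gene <- a |>
    distinct(.data$gene_symbol, .data$cell_type)
  res <- map_dfr(seq_along(lv), function(i) {
    g <- lv[i]; other <- lv[-i]
    gs <- groups$sample_id[groups$group == g]
    os <- groups$sample_id[groups$group == other]
    in_g <- if (cfg$exclusive_rule == "all-vs-none") {
      rowSums(expressed[, gs, drop = FALSE]) == length(gs)
    } else {
      rowSums(expressed[, gs, drop = FALSE]) >= 1
    }
    none_other <- rowSums(expressed[, os, drop = FALSE]) == 0
    tibble(gene_symbol = rownames(expressed)[in_g & none_other],
           exclusive_to = g)
  })
  res |>
    left_join(ct_by_gene, by = "gene_symbol") |>
    select("gene_symbol", "cell_type", "exclusive_to") |>
    arrange(.data$exclusive_to, .data$gene_symbol)
}

#' Compare sequencing-QC metrics between groups
#'
#' Runs an unpaired t-test with Welch's correction per QC metric (e.g. total
#' reads, average read length, mean Phred score, depth, coverage, percent
#' aligned), reporting group means and SDs. Raw per-metric p-values are
#' reported without multiplicity correction, matching the convention of
#' per-panel QC figures.
#'
#' @param qc Per-sample metrics tibble: a `sample_id` column plus one numeric
#'   column per metric.
#' @param groups Sample-to-group tibble.
#' @return Tibble with one row per metric: `metric`, per-group mean/SD, `t`,
#'   `df`, `p`.
#' @export
compare_qc_metrics <- function(qc, groups) {
  stopifnot(is.data.frame(qc))
  if (!"sample_id" %in% names(qc)) abort("`qc` needs a `sample_id` column.")
  groups <- check_groups(groups, as.character(qc$sample_id))
  lv <- group_levels(groups)
  metrics <- setdiff(names(qc), "sample_id")
  map_dfr(metrics, function(mname) {
    v <- qc[[mname]]
    if (!is.numeric(v) || anyNA(v)) {
      warn(paste0("QC metric `", mname,
                  "` skipped (non-numeric or missing values)."))
      return(tibble())
    }
    x <- v[match(groups$sample_id[groups$group == lv[1]], qc$sample_id)]
    y <- v[match(groups$sample_id[groups$group == lv[2]], qc$sample_id)]
    ht <- welch_t(x, y)
    out <- tibble(metric = mname)
    out[[paste0("mean_", lv[1])]] <- mean(x)
    out[[paste0("sd_", lv[1])]] <- sd(x)
    out[[paste0("mean_", lv[2])]] <- mean(y)
    out[[paste0("sd_", lv[2])]] <- sd(y)
    out$t <- ht$t; out$df <- ht$df; out$p <- ht$p
    out
  })
}

#' Full composition report
#'
#' Convenience wrapper bundling [compare_groups()], [presence_table()] and
#' [exclusive_genes()] for one annotated matrix.
#'
#' @inheritParams compare_groups
#' @return A list of class `composition_report` with elements `tests`,
#'   `presence`, `exclusive`, `n_cell_types_detected`, `config`. [tidy()]
#'   returns the per-transcript tests; [glance()] a one-row summary.
#' @export
composition_report <- function(a, groups, cfg = stats_config()) {
  tests <- compare_groups(a, groups, cfg)
  pres <- presence_table(a, groups, cfg)
  excl <- exclusive_genes(a, groups, cfg)
  structure(list(tests = tests,
                 presence = pres,
                 exclusive = excl,
                 n_cell_types_detected = attr(pres, "n_cell_types_detected"),
                 config = cfg),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat("Composition report\n")
  cat("  transcripts tested:   ", nrow(x$tests), "\n", sep = "")
  cat("  significant (q <= ", x$config$fdr_q, "): ",
      sum(x$tests$significant), "\n", sep = "")
  cat("  cell types detected:  ", x$n_cell_types_detected, "\n", sep = "")
  cat("  group-exclusive genes:", nrow(x$exclusive), "\n")
  invisible(x)
}

#' @describeIn composition_report Per-transcript test table.
#' @param x A `composition_report`.
#' @param ... Unused.
#' @method tidy composition_report
#' @export
tidy.composition_report <- function(x, ...) x$tests

#' @describeIn composition_report One-row summary.
#' @method glance composition_report
#' @export
glance.composition_report <- function(x, ...) {
  tibble(n_transcripts = nrow(x$tests),
         n_significant = sum(x$tests$significant),
         n_significant_raw_p = sum(x$tests$p < x$config$fdr_q),
         n_cell_types_detected = x$n_cell_types_detected,
         n_exclusive_genes = nrow(x$exclusive),
         fdr_q = x$config$fdr_q)
}
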