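#' Annotate a bulk expression matrix with cell types
#'
#' Inner-joins the quality-filtered bulk matrix to the unique-marker
#' reference on case-normalized official gene symbol. Every transcript
#' isoform of a matched gene yields its own annotated row carrying the
#' gene's single cell type; unmatched transcripts and unmatched reference
#' genes are excluded from the output but counted in the summary.
#'
#' @param m Normalized, filtered expression matrix tibble.
#' @param ref A `cell_type_reference` from [build_reference()] or
#'   [read_reference()].
#' @return An `annotated_matrix`: a tibble with columns `transcript_id`,
#'   `gene_symbol`, `cell_type`, `ref_expression` (the reference's source
#'   expression value, informational only), then the sample columns.
#'   Attribute `summary` holds `n_transcripts`, `n_genes`, `n_cell_types`,
#'   `n_unmatched_transcripts`, `n_unmatched_ref_genes`; [glance()] returns
#'   it as a one-row tibble.
#' @export
annotate_matrix <- function(m, ref) {
  if (inherits(m, "tmm_norm")) m <- m$matrix
  validate_matrix(m)
  validate_reference(ref)
  ref_tbl <- as_tibble(ref) |>
    select("gene_symbol", ref_expression = "expression", "cell_type")
  joined <- m |>
    mutate(gene_symbol = normalize_symbol(.data$gene_symbol)) |>
    inner_join(ref_tbl, by = "gene_symbol") |>
    relocate("transcript_id", "gene_symbol", "cell_type", "ref_expression")
  if (nrow(joined) == 0) {
    abort(paste0("No gene symbols in the matrix match the reference. ",
                 "Check that both use official gene symbols ",
                 "(symbols are compared upper-cased)."))
  }
  summary <- list(
    n_transcripts = nrow(joined),
    n_genes = n_distinct(joined$gene_symbol),
    n_cell_types = n_distinct(joined$cell_type),
    n_unmatched_transcripts = nrow(m) - nrow(joined),
    n_unmatched_ref_genes =
      sum(!ref_tbl$gene_symbol %in% joined$gene_symbol))
  structure(joined,
            summary = summary,
            normalized = attr(m, "normalized"),
            offset = attr(m, "offset"),
            class = c("annotated_matrix", class(joined)))
}

#' @export
print.annotated_matrix <- function(x, ...) {
  s <- attr(x, "summary")
  cat("Cell-type annotated matrix: ", s$n_transcripts, " transcripts / ",
      s$n_genes, " genes / ", s$n_cell_types, " cell types\n", sep = "")
  NextMethod()
}

#' @describeIn annotate_matrix Annotation summary counts as a one-row tibble.
#' @param x An `annotated_matrix`.
#' @param ... Unused.
#' @method glance annotated_matrix
#' @export
glance.annotated_matrix <- function(x, ...) {
  as_tibble(attr(x, "summary"))
}

#' Top expressed cell-type specific transcripts
#'
#' Ranks annotated transcripts by mean abundance across all samples
#' (descending; ties broken by `transcript_id` lexicographic order) and
#' reports per-group mean and standard deviation for the top `n`.
#'
#' @param a An `annotated_matrix`.
#' @param groups Sample-to-group mapping tibble (`sample_id`, `group`).
#' @param n Number of transcripts to report (default 40).
#' @return A tibble ranked by overall mean with per-group `mean_<group>` and
#'   `sd_<group>` columns.
#' @export
top_expressed <- function(a, groups, n = 40) {
  stopifnot(n >= 1)
  sc <- sample_cols(a)
  groups <- check_groups(groups, sc)
  vals <- as.matrix(a[, sc])
  overall <- rowMeans(vals)
  out <- tibble(cell_type = a$cell_type,
                gene_symbol = a$gene_symbol,
                transcript_id = a$transcript_id,
                mean_abundance = overall)
  for (g in group_levels(groups)) {
    gs <- groups$sample_id[groups$group == g]
    gv <- vals[, gs, drop = FALSE]
    out[[paste0("mean_", g)]] <- rowMeans(gv)
    out[[paste0("sd_", g)]] <- apply(gv, 1, sd)
  }
  out <- arrange(out, desc(.data$mean_abundance), .data$transcript_id)
  if (n > nrow(out)) {
    warn(paste0("Only ", nrow(out), " annotated transcripts available; ",
                "returning all."))
    n <- nrow(out)
  }
  head(out, n)
}
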