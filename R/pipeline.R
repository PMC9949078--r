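#' Default pipeline configuration
#'
#' @param markers Marker table paths (a directory of CSVs or a vector of
#'   files), or `NULL` if `reference` is given.
#' @param reference Optional pre-built reference CSV (skips reference
#'   building).
#' @param counts Raw count matrix CSV.
#' @param groups Sample-to-group CSV.
#' @param qc Optional per-sample QC metrics CSV.
#' @param out_dir Output directory.
#' @param labels Optional cell-type labels for marker files lacking a
#'   `cell_type` column.
#' @param offset Normalization offset (default 1, "TMM+1").
#' @param min_mean Expression-filter threshold on the pooled mean
#'   (default 1).
#' @param trim_m,trim_a TMM trim fractions (defaults 0.3, 0.05).
#' @param scale Normalized scale, `"libmean"` or `"cpm"`.
#' @param fdr_q FDR level (default 0.05).
#' @param welch Welch correction for the per-transcript tests
#'   (default FALSE).
#' @param presence_threshold Presence call threshold (default = `offset`).
#' @param exclusive_rule `"all-vs-none"` or `"any-vs-none"`.
#' @param top_n Size of the top-expressed report (default 40).
#' @param n_components PCA components to retain (default 3).
#' @param corr_pca Correlation instead of covariance PCA (default FALSE).
#' @param write_plots Also write PNG figures (default FALSE; the CSV tables
#'   always carry the plotted data).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(markers = NULL, reference = NULL, counts, groups,
                       qc = NULL, out_dir, labels = NULL,
                       offset = 1, min_mean = 1, trim_m = 0.3,
                       trim_a = 0.05, scale = "libmean",
                       fdr_q = 0.05, welch = FALSE,
                       presence_threshold = offset,
                       exclusive_rule = "all-vs-none",
                       top_n = 40, n_components = 3, corr_pca = FALSE,
                       write_plots = FALSE) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Every [run_config()] argument has a YAML key of the same name.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, y)
}

#' Run the full composition pipeline
#'
#' Executes reference building, TMM normalization, expression filtering,
#' cell-type annotation, group comparison with two-stage FDR, presence and
#' group-exclusive inference, QC comparison (when a QC table is given), and
#' variation analysis (per-group CV and PCA with 2-SD group ellipsoids),
#' writing every intermediate artifact plus a JSON manifest with input
#' checksums, parameter values and stage row counts. Re-running with
#' identical inputs and configuration reproduces identical outputs.
#'
#' @param cfg A `run_config` (or path to a YAML file).
#' @return Invisibly, a list with the `manifest` and the main result objects
#'   (`reference`, `norm`, `annotated`, `report`, `cv`, `pca`, `qc_tests`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  for (f in c("counts", "groups")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
      abort(paste0("Input file for `", f, "` is missing",
                   if (!is.null(cfg[[f]])) paste0(": ", cfg[[f]]), "."))
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)
  manifest <- list(parameters = cfg[setdiff(names(cfg),
                                            c("markers", "reference",
                                              "counts", "groups", "qc",
                                              "out_dir"))])

  # stage 1: reference
  stage <- "build-ref"
  res <- tryCatch({
    if (!is.null(cfg$reference)) {
      ref <- read_reference(cfg$reference)
      marker_files <- cfg$reference
    } else {
      marker_files <- cfg$markers
      if (length(marker_files) == 1 && dir.exists(marker_files)) {
        marker_files <- sort(list.files(marker_files, full.names = TRUE,
                                        pattern = "\\.(csv|tsv|txt)$"))
      }
      records <- load_marker_tables(marker_files, cfg$labels)
      ref <- build_reference(records)
    }
    write_reference(ref, out("reference.csv"))

    stage <- "preprocess"
    m <- read_matrix(cfg$counts)
    groups <- read_groups(cfg$groups)
    groups <- check_groups(groups, sample_cols(m))
    norm <- tmm_normalize(m, trim_m = cfg$trim_m, trim_a = cfg$trim_a,
                          offset = cfg$offset, scale = cfg$scale)
    filtered <- filter_low_expression(norm$matrix, threshold = cfg$min_mean)
    write_matrix(filtered, out("normalized.csv"))
    write_delim_plain(tidy(norm), out("tmm_factors.csv"))

    stage <- "annotate"
    ann <- annotate_matrix(filtered, ref)
    write_delim_plain(as_tibble(ann), out("annotated.csv"))
    top <- top_expressed(ann, groups, n = min(cfg$top_n, nrow(ann)))
    write_delim_plain(top, out(paste0("top", cfg$top_n, ".csv")))

    stage <- "compare"
    scfg <- stats_config(fdr_q = cfg$fdr_q, welch = cfg$welch,
                         presence_threshold = cfg$presence_threshold,
                         exclusive_rule = cfg$exclusive_rule)
    report <- composition_report(ann, groups, scfg)
    write_delim_plain(report$tests, out("transcript_tests.csv"))
    write_delim_plain(report$presence, out("presence.csv"))
    write_delim_plain(report$exclusive, out("exclusive_genes.csv"))

    qc_tests <- NULL
    if (!is.null(cfg$qc)) {
      qc <- read_delim_quiet(cfg$qc, delim_for(cfg$qc))
      qc_tests <- compare_qc_metrics(qc, groups)
      write_delim_plain(qc_tests, out("qc_tests.csv"))
    }

    stage <- "variation"
    cv <- cv_by_group(filtered, groups)
    write_delim_plain(cv, out("cv.csv"))
    pca <- pca_expression(filtered, groups, n_components = cfg$n_components,
                          scale. = cfg$corr_pca)
    write_delim_plain(pca$scores, out("pca_scores.csv"))
    write_delim_plain(glance(pca), out("pca_explained.csv"))
    write_delim_plain(pca$ellipsoids, out("pca_ellipsoids.csv"))

    if (isTRUE(cfg$write_plots)) {
      ggplot2::ggsave(out("pca.png"), autoplot(pca),
                      width = 6, height = 5, dpi = 150)
      ggplot2::ggsave(out("cv_scatter.png"), plot_cv_scatter(cv),
                      width = 6, height = 5, dpi = 150)
      ggplot2::ggsave(out(paste0("top", cfg$top_n, ".png")),
                      plot_top_expressed(top), width = 7,
                      height = 0.22 * nrow(top) + 1.5, dpi = 150)
      if (!is.null(cfg$qc)) {
        ggplot2::ggsave(out("qc_metrics.png"), plot_qc_metrics(qc, groups),
                        width = 8, height = 6, dpi = 150)
      }
    }

    list(ref = ref, norm = norm, filtered = filtered, ann = ann,
         report = report, cv = cv, pca = pca, qc_tests = qc_tests,
         groups = groups, m = m)
  }, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    abort(paste0("Pipeline failed at stage `", stage, "`: ",
                 conditionMessage(e)))
  })

  inputs <- c(counts = cfg$counts, groups = cfg$groups)
  if (!is.null(cfg$qc)) inputs <- c(inputs, qc = cfg$qc)
  manifest$input_md5 <- as.list(tools::md5sum(inputs))
  manifest$counts <- list(
    n_reference_genes = nrow(res$ref),
    n_reference_cell_types = length(unique(res$ref$cell_type)),
    n_input_transcripts = nrow(res$m),
    n_transcripts_pass_filter = nrow(res$filtered),
    n_annotated_transcripts = glance(res$ann)$n_transcripts,
    n_annotated_genes = glance(res$ann)$n_genes,
    n_cell_types_in_bulk = glance(res$ann)$n_cell_types,
    n_cell_types_detected = res$report$n_cell_types_detected,
    n_significant_transcripts = sum(res$report$tests$significant),
    n_exclusive_genes = nrow(res$report$exclusive))
  manifest$tmm <- list(reference_sample = res$norm$reference_sample,
                       factors = as.list(res$norm$factors))
  manifest$pca_explained_pct <-
    res$pca$explained_pct[seq_len(res$pca$n_components)]
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  invisible(list(manifest = manifest, reference = res$ref, norm = res$norm,
                 filtered = res$filtered, annotated = res$ann,
                 report = res$report, cv = res$cv, pca = res$pca,
                 qc_tests = res$qc_tests))
}
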