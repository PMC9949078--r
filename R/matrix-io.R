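#' Read / write a transcript-by-sample expression matrix
#'
#' Expression matrices are tibbles with one row per transcript: a transcript
#' identifier column, an official gene-symbol column, then one numeric column
#' per sample. Gene symbols are case-normalized on read.
#'
#' @param path Delimited file (CSV/TSV by extension).
#' @param id_col,symbol_col Names of the transcript-ID and gene-symbol
#'   columns in the file (renamed to `transcript_id` / `gene_symbol`).
#' @param delim Optional delimiter override.
#' @return A tibble with columns `transcript_id`, `gene_symbol`, and one
#'   numeric column per sample.
#' @export
read_matrix <- function(path, id_col = "transcript_id",
                        symbol_col = "gene_symbol", delim = NULL) {
  tab <- read_delim_quiet(path, delim_for(path, delim))
  if (!id_col %in% names(tab)) {
    abort(paste0("Column `", id_col, "` not found in ", path, "."))
  }
  if (!symbol_col %in% names(tab)) {
    abort(paste0("Column `", symbol_col, "` not found in ", path, "."))
  }
  names(tab)[names(tab) == id_col] <- "transcript_id"
  names(tab)[names(tab) == symbol_col] <- "gene_symbol"
  tab <- relocate(tab, "transcript_id", "gene_symbol")
  for (s in sample_cols(tab)) {
    v <- tab[[s]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        abort(paste0("Non-numeric value in sample column `", s,
                     "`, data row ", bad[1], " of ", path, "."))
      }
      tab[[s]] <- vn
    }
  }
  tab$transcript_id <- as.character(tab$transcript_id)
  tab$gene_symbol <- normalize_symbol(tab$gene_symbol)
  validate_matrix(tab)
  tab
}

#' @rdname read_matrix
#' @param m Expression matrix tibble to write.
#' @export
write_matrix <- function(m, path, delim = NULL) {
  validate_matrix(m)
  out <- m
  for (s in sample_cols(out)) {
    out[[s]] <- formatC(out[[s]], digits = 12, format = "g")
  }
  write_delim_plain(out, path, delim_for(path, delim))
  invisible(path)
}

validate_matrix <- function(m) {
  stopifnot(is.data.frame(m))
  if (!all(c("transcript_id", "gene_symbol") %in% names(m))) {
    abort("Matrix needs `transcript_id` and `gene_symbol` columns.")
  }
  sc <- sample_cols(m)
  if (length(sc) == 0) abort("Matrix has no sample columns.")
  dup <- m$transcript_id[duplicated(m$transcript_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate transcript_id rows: ",
                 paste(unique(dup), collapse = ", ")))
  }
  vals <- as.matrix(m[, sc])
  if (anyNA(vals)) abort("Matrix contains missing values.")
  if (any(vals < 0)) abort("Matrix contains negative values.")
  invisible(m)
}

#' Read a sample-to-group mapping
#'
#' @param path Delimited file with columns `sample_id` and `group`.
#' @param delim Optional delimiter override.
#' @return Tibble with character columns `sample_id`, `group`.
#' @export
read_groups <- function(path, delim = NULL) {
  tab <- read_delim_quiet(path, delim_for(path, delim))
  if (!all(c("sample_id", "group") %in% names(tab))) {
    abort(paste0("Groups file ", path,
                 " must have columns `sample_id` and `group`."))
  }
  tibble(sample_id = as.character(tab$sample_id),
         group = as.character(tab$group))
}
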