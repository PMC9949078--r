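# Internal helpers shared across modules.

#' Normalize gene symbols for cross-species matching
#'
#' Official gene symbols are shared by orthologous genes across species but
#' case conventions differ (rat `Lep`, primate `LEP`). All symbol comparisons
#' in the package go through this normalization: trim surrounding whitespace
#' and upper-case.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of trimmed, upper-cased symbols.
#' @export
#' @examples
#' normalize_symbol(c(" lep ", "Nphs2"))
normalize_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

# Delimiter from file extension; tab for .tsv/.txt, comma otherwise.
delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt", "tab")) "\t" else ","
}

read_delim_quiet <- function(path, delim) {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

write_delim_plain <- function(x, path, delim = ",") {
  readr::write_delim(x, path, delim = delim, progress = FALSE)
}

# Validate a sample->group mapping against a set of sample ids; returns the
# mapping as a tibble with character columns sample_id, group.
check_groups <- function(groups, sample_ids, require_two = TRUE) {
  stopifnot(is.data.frame(groups))
  if (!all(c("sample_id", "group") %in% names(groups))) {
    abort("`groups` must have columns `sample_id` and `group`.")
  }
  groups <- tibble(sample_id = as.character(groups$sample_id),
                   group = as.character(groups$group))
  missing <- setdiff(sample_ids, groups$sample_id)
  if (length(missing) > 0) {
    abort(paste0("No group assignment for sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  groups <- filter(groups, .data$sample_id %in% sample_ids)
  lv <- unique(groups$group)
  if (require_two && length(lv) != 2) {
    abort(paste0("Exactly two groups are required; found ",
                 length(lv), " (", paste(lv, collapse = ", "), ")."))
  }
  if (any(table(groups$group) < 1)) abort("Each group must be non-empty.")
  groups
}

# Sample (value) columns of an expression tibble: everything that is not
# metadata. Order preserved.
sample_cols <- function(m) {
  meta <- c("transcript_id", "gene_symbol", "cell_type", "ref_expression")
  setdiff(names(m), meta)
}

# group labels in stable order (first appearance in the groups table)
group_levels <- function(groups) unique(groups$group)
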