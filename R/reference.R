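#' Load per-cell-type marker tables
#'
#' Reads one or more delimited marker tables (one file per cell type, or any
#' mix of files that carry their own `cell_type` column) and concatenates them
#' into a single tibble of marker records. Gene symbols are case-normalized
#' (trimmed, upper-cased) so that rodent-style symbols (`Lep`) match primate
#' bulk data (`LEP`).
#'
#' Each file needs at least a gene-symbol column and an expression column.
#' If a file has no `cell_type` column the label is taken from
#' `cell_type_labels` (one label per file, in order).
#'
#' @param paths Character vector of file paths (CSV or TSV, auto-detected
#'   from the extension).
#' @param cell_type_labels Optional character vector, parallel to `paths`,
#'   supplying the cell-type label for files without a `cell_type` column.
#' @param delim Optional delimiter overriding extension-based detection.
#' @return A tibble of marker records with columns `gene_symbol`,
#'   `expression`, `cell_type`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("gene_symbol,expression", "Nphs2,120", "Lep,30"), f)
#' load_marker_tables(f, cell_type_labels = "podocyte")
load_marker_tables <- function(paths, cell_type_labels = NULL, delim = NULL) {
  stopifnot(length(paths) >= 1)
  if (!is.null(cell_type_labels) &&
      length(cell_type_labels) != length(paths)) {
    abort("`cell_type_labels` must have one label per file.")
  }
  recs <- map(seq_along(paths), function(i) {
    path <- paths[[i]]
    tab <- read_delim_quiet(path, delim_for(path, delim))
    if (nrow(tab) == 0) {
      warn(paste0("Marker file is empty: ", path))
      return(tibble(gene_symbol = character(), expression = double(),
                    cell_type = character()))
    }
    nm <- tolower(names(tab))
    sym_col <- match(TRUE, nm %in% c("gene_symbol", "gene", "symbol"))
    expr_col <- match(TRUE, nm %in% c("expression", "expr", "value",
                                      "abundance"))
    if (is.na(sym_col)) {
      abort(paste0("Marker file ", path, " lacks a gene-symbol column ",
                   "(expected one of: gene_symbol, gene, symbol)."))
    }
    if (is.na(expr_col)) {
      abort(paste0("Marker file ", path, " lacks an expression column ",
                   "(expected one of: expression, expr, value, abundance)."))
    }
    ct_col <- match(TRUE, nm == "cell_type")
    if (!is.na(ct_col)) {
      ct <- trimws(as.character(tab[[ct_col]]))
    } else if (!is.null(cell_type_labels)) {
      ct <- rep(cell_type_labels[[i]], nrow(tab))
    } else {
      abort(paste0("Marker file ", path, " has no cell_type column and no ",
                   "label was supplied for it."))
    }
    tibble(gene_symbol = normalize_symbol(tab[[sym_col]]),
           expression = as.numeric(tab[[expr_col]]),
           cell_type = ct)
  })
  out <- bind_rows(recs)
  validate_marker_records(out)
  out
}

validate_marker_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("gene_symbol", "expression", "cell_type")
  if (!all(need %in% names(records))) {
    abort("Marker records need columns gene_symbol, expression, cell_type.")
  }
  if (nrow(records) > 0) {
    if (any(records$gene_symbol == "" | is.na(records$gene_symbol))) {
      abort("Marker records contain empty gene symbols.")
    }
    if (any(records$cell_type == "" | is.na(records$cell_type))) {
      abort("Marker records contain empty cell-type labels.")
    }
    if (any(is.na(records$expression)) || any(records$expression < 0)) {
      abort("Marker expression values must be non-negative numbers.")
    }
  }
  invisible(records)
}

#' Build a unique-marker cell-type reference
#'
#' Reproduces, as a deterministic algorithm, the duplicate-removal step used
#' to turn per-cell-type single-cell marker lists into a reference of genes
#' uniquely assignable to one cell type: any gene symbol that appears under
#' two or more distinct cell types is removed entirely (all of its rows are
#' dropped), because its expression in a bulk sample cannot implicate a
#' single cell type. A gene listed more than once under the *same* cell type
#' is not ambiguous and is collapsed to one record, keeping the maximum
#' expression value.
#'
#' @param records A data frame of marker records (`gene_symbol`,
#'   `expression`, `cell_type`), e.g. from [load_marker_tables()].
#' @param provenance Free-text citation of the marker source, carried as an
#'   attribute of the result.
#' @return A `cell_type_reference`: a tibble with one row per unique marker
#'   gene (`gene_symbol`, `expression`, `cell_type`), the distinct cell-type
#'   labels in attribute `cell_types`, dropped ambiguous symbols in
#'   attribute `dropped_symbols`, and `provenance`.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   gene_symbol = c("A", "A", "B"),
#'   expression = c(1, 2, 3),
#'   cell_type = c("X", "Y", "X"))
#' build_reference(recs)  # gene A is ambiguous and dropped
build_reference <- function(records, provenance = "") {
  validate_marker_records(records)
  if (nrow(records) == 0) abort("Cannot build a reference from zero records.")
  records <- mutate(records, gene_symbol = normalize_symbol(.data$gene_symbol))
  ambig <- records |>
    distinct(.data$gene_symbol, .data$cell_type) |>
    count(.data$gene_symbol) |>
    filter(.data$n > 1) |>
    pull(.data$gene_symbol)
  if (all(records$gene_symbol %in% ambig)) {
    abort(paste0("Every gene is listed under multiple cell types; the ",
                 "reference would be empty. Dropped symbols: ",
                 paste(sort(ambig), collapse = ", ")))
  }
  kept <- records |>
    filter(!(.data$gene_symbol %in% ambig)) |>
    group_by(.data$gene_symbol, .data$cell_type) |>
    summarise(expression = max(.data$expression), .groups = "drop") |>
    select("gene_symbol", "expression", "cell_type") |>
    arrange(.data$gene_symbol)
  new_reference(kept, dropped = sort(ambig), provenance = provenance)
}

new_reference <- function(tbl, dropped = character(), provenance = "") {
  structure(as_tibble(tbl),
            cell_types = unique(tbl$cell_type),
            dropped_symbols = dropped,
            provenance = provenance,
            class = c("cell_type_reference", class(as_tibble(tbl))))
}

#' @export
print.cell_type_reference <- function(x, ...) {
  cat("Unique-marker cell-type reference: ", nrow(x), " genes, ",
      length(attr(x, "cell_types")), " cell types\n", sep = "")
  if (length(attr(x, "dropped_symbols")) > 0) {
    cat("Dropped as cross-cell-type duplicates: ",
        length(attr(x, "dropped_symbols")), " symbols\n", sep = "")
  }
  NextMethod()
}

validate_reference <- function(ref) {
  validate_marker_records(ref)
  dup <- ref$gene_symbol[duplicated(ref$gene_symbol)]
  if (length(dup) > 0) {
    abort(paste0("Reference violates one-cell-type-per-gene: ",
                 paste(unique(dup), collapse = ", ")))
  }
  invisible(ref)
}

#' Write / read a cell-type reference
#'
#' The reference is stored as a plain CSV with header
#' `gene_symbol,expression,cell_type`; `read_reference()` re-validates the
#' one-cell-type-per-gene invariant so a hand-edited file cannot silently
#' reintroduce ambiguous markers.
#'
#' @param ref A `cell_type_reference` from [build_reference()].
#' @param path Output (or input) CSV path.
#' @return `write_reference()` returns `path` invisibly; `read_reference()`
#'   returns a `cell_type_reference`.
#' @export
write_reference <- function(ref, path) {
  validate_reference(ref)
  if (length(unique(ref$cell_type)) == 0 || nrow(ref) == 0) {
    abort("Refusing to write an empty reference.")
  }
  write_delim_plain(as_tibble(ref)[, c("gene_symbol", "expression",
                                       "cell_type")], path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  tab <- read_delim_quiet(path, delim_for(path))
  need <- c("gene_symbol", "expression", "cell_type")
  if (!all(need %in% names(tab))) {
    abort(paste0("Reference file ", path, " must have columns ",
                 paste(need, collapse = ", "), "."))
  }
  bad <- which(is.na(tab$expression))
  if (length(bad) > 0) {
    abort(paste0("Malformed expression value in ", path, " at data line ",
                 bad[1], "."))
  }
  tab <- mutate(tab, gene_symbol = normalize_symbol(.data$gene_symbol),
                cell_type = trimws(.data$cell_type))
  ref <- new_reference(tab[, need])
  validate_reference(ref)
  ref
}
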