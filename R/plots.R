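# Plotting helpers. All plot_* functions return ggplot objects; file output
# goes through write_cv_scatter() / ggplot2::ggsave().

#' PCA score plot with 2-SD group ellipses
#'
#' Plots the first two retained components, one point per sample, with an
#' axis-aligned ellipse per group whose semi-axes are two standard
#' deviations of the group's scores along each component.
#'
#' @param object An `expression_pca` from [pca_expression()].
#' @param components Two component names to display (default
#'   `c("PC1", "PC2")`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot expression_pca
#' @export
autoplot.expression_pca <- function(object, components = c("PC1", "PC2"),
                                    ...) {
  stopifnot(length(components) == 2,
            all(components %in% names(object$scores)))
  sc <- object$scores
  ell <- object$ellipsoids |>
    filter(.data$component %in% components) |>
    pivot_wider(names_from = "component",
                values_from = c("center", "radius"))
  theta <- seq(0, 2 * pi, length.out = 120)
  cx <- paste0("center_", components[1]); cy <- paste0("center_", components[2])
  rx <- paste0("radius_", components[1]); ry <- paste0("radius_", components[2])
  paths <- ell |>
    rowwise() |>
    reframe(group = .data$group,
            x = .data[[cx]] + .data[[rx]] * cos(theta),
            y = .data[[cy]] + .data[[ry]] * sin(theta))
  lab <- function(pc) {
    i <- as.integer(sub("PC", "", pc))
    sprintf("%s (%.1f%%)", pc, object$explained_pct[i])
  }
  ggplot2::ggplot(sc, ggplot2::aes(.data[[components[1]]],
                                   .data[[components[2]]],
                                   colour = .data$group)) +
    ggplot2::geom_path(data = paths,
                       ggplot2::aes(.data$x, .data$y, colour = .data$group),
                       inherit.aes = FALSE, linetype = 2) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = lab(components[1]), y = lab(components[2]),
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Coefficient-of-variation scatter between groups
#'
#' One point per transcript: CV in the first group on the x axis, CV in the
#' second on the y axis, colored by which group has the higher mean
#' expression. Records with undefined CV (zero group mean) are dropped.
#'
#' @param records CV table from [cv_by_group()].
#' @return A ggplot object.
#' @export
plot_cv_scatter <- function(records) {
  stopifnot(nrow(records) > 0)
  cvs <- setdiff(grep("^cv_", names(records), value = TRUE), "cv_defined")
  stopifnot(length(cvs) == 2)
  dat <- records[records$cv_defined, , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(.data[[cvs[1]]], .data[[cvs[2]]],
                                    colour = .data$higher_group)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = sub("cv_", "CV in ", cvs[1]),
                  y = sub("cv_", "CV in ", cvs[2]),
                  colour = "higher mean") +
    ggplot2::theme_minimal()
}

#' Write the CV scatter plot and its underlying table
#'
#' Writes the scatter as an image (format from the file extension; `.png` or
#' `.pdf`) and the plotted table as a CSV next to it, so the figure is
#' reproducible data.
#'
#' @param records CV table from [cv_by_group()].
#' @param path Image output path.
#' @param csv_path CSV output path (default: `path` with a `.csv` extension).
#' @return Invisibly, `c(path, csv_path)`.
#' @export
write_cv_scatter <- function(records, path,
                             csv_path = paste0(tools::file_path_sans_ext(path),
                                               ".csv")) {
  p <- plot_cv_scatter(records)
  ggplot2::ggsave(path, p, width = 6, height = 5, dpi = 150)
  write_delim_plain(records, csv_path)
  invisible(c(path, csv_path))
}

#' Bar plot of top expressed cell-type specific transcripts
#'
#' @param top Table from [top_expressed()].
#' @return A ggplot object (per-group mean bars with SD error bars, labeled
#'   by cell type / gene / transcript).
#' @export
plot_top_expressed <- function(top) {
  lv <- sub("mean_", "", grep("^mean_(?!abundance)", names(top),
                              value = TRUE, perl = TRUE))
  dat <- top |>
    mutate(label = paste(.data$cell_type, .data$gene_symbol,
                         .data$transcript_id, sep = " / "),
           label = factor(.data$label, levels = rev(.data$label))) |>
    pivot_longer(cols = all_of(c(paste0("mean_", lv), paste0("sd_", lv))),
                 names_to = c(".value", "group"), names_sep = "_")
  ggplot2::ggplot(dat, ggplot2::aes(.data$label, .data$mean,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized abundance", fill = "group") +
    ggplot2::theme_minimal()
}

#' Per-metric QC comparison plot
#'
#' @param qc Per-sample QC metrics tibble (`sample_id` + numeric metrics).
#' @param groups Sample-to-group tibble.
#' @return A ggplot object: one facet per metric, points per sample, group
#'   mean bars with SD error bars.
#' @export
plot_qc_metrics <- function(qc, groups) {
  groups <- check_groups(groups, as.character(qc$sample_id))
  dat <- qc |>
    mutate(sample_id = as.character(.data$sample_id)) |>
    left_join(groups, by = "sample_id") |>
    pivot_longer(-c("sample_id", "group"),
                 names_to = "metric", values_to = "value")
  summ <- dat |>
    group_by(.data$metric, .data$group) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$group, .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(alpha = 0.4) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::geom_jitter(data = dat,
                         ggplot2::aes(.data$group, .data$value),
                         width = 0.1, inherit.aes = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
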