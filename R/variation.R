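#' Per-group coefficient of variation
#'
#' Computes, per transcript and group, the coefficient of variation
#' (sample standard deviation with the n-1 denominator, divided by the group
#' mean) over the normalized matrix, plus which group has the larger mean
#' expression. With the "+1" normalization offset group means are always
#' positive; should a group mean be zero the record is flagged undefined.
#'
#' @param m Normalized expression matrix tibble (all quality transcripts,
#'   not only annotated ones) or `tmm_norm` object.
#' @param groups Sample-to-group tibble; each group needs >= 2 samples.
#' @return A tibble with `transcript_id`, `cv_<group>` per group,
#'   `higher_group` (group with larger mean; `"equal"` on ties), and
#'   `cv_defined` (FALSE when a group mean is zero).
#' @export
cv_by_group <- function(m, groups) {
  if (inherits(m, "tmm_norm")) m <- m$matrix
  validate_matrix(m)
  sc <- sample_cols(m)
  groups <- check_groups(groups, sc)
  lv <- group_levels(groups)
  vals <- as.matrix(m[, sc])
  out <- tibble(transcript_id = m$transcript_id)
  means <- list()
  for (g in lv) {
    gs <- groups$sample_id[groups$group == g]
    if (length(gs) < 2) abort("Each group needs >= 2 samples for CV.")
    gv <- vals[, gs, drop = FALSE]
    mu <- rowMeans(gv)
    sdv <- apply(gv, 1, sd)
    out[[paste0("cv_", g)]] <- ifelse(mu == 0, NA_real_, sdv / mu)
    means[[g]] <- mu
  }
  out$higher_group <- case_when(
    means[[lv[1]]] > means[[lv[2]]] ~ lv[1],
    means[[lv[2]]] > means[[lv[1]]] ~ lv[2],
    TRUE ~ "equal")
  out$cv_defined <- !is.na(out[[paste0("cv_", lv[1])]]) &
    !is.na(out[[paste0("cv_", lv[2])]])
  out
}

#' Principal component analysis of samples with group ellipsoids
#'
#' PCA of the normalized matrix with samples as observations and transcripts
#' as features. Features are mean-centered; by default they are not scaled
#' to unit variance (covariance PCA, the usual default for expression data),
#' with correlation PCA available via `scale.`. Per-group ellipsoids are
#' axis-aligned in the retained component space: center at the group mean
#' score, radius two standard deviations of the group's scores along each
#' component.
#'
#' @param m Normalized expression matrix tibble or `tmm_norm`.
#' @param groups Sample-to-group tibble.
#' @param n_components Number of components to retain for scores/ellipsoids
#'   (default 3); explained variance is reported for all components.
#' @param scale. Scale features to unit variance (correlation PCA)?
#'   Default `FALSE`.
#' @return An `expression_pca` object: list with `scores` (tibble:
#'   `sample_id`, `group`, `PC1..PCk`), `explained_pct` (per-component % of
#'   total variance, all components), `ellipsoids` (tibble: `group`,
#'   `component`, `center`, `radius`), `rotation`, `n_components`.
#'   [tidy()] returns scores, [glance()] the variance summary, and
#'   [autoplot()] a score plot with the 2-SD ellipses.
#' @export
pca_expression <- function(m, groups, n_components = 3, scale. = FALSE) {
  if (inherits(m, "tmm_norm")) m <- m$matrix
  validate_matrix(m)
  sc <- sample_cols(m)
  if (length(sc) < 3) abort("PCA needs at least 3 samples.")
  groups <- check_groups(groups, sc)
  n_components <- min(n_components, length(sc) - 1, nrow(m))
  x <- t(as.matrix(m[, sc]))  # samples x transcripts
  if (isTRUE(scale.)) {
    keep <- apply(x, 2, var) > 0
    x <- x[, keep, drop = FALSE]
  }
  fit <- prcomp(x, center = TRUE, scale. = scale.)
  explained <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  grp <- groups$group[match(sc, groups$sample_id)]
  scores <- as_tibble(fit$x[, seq_len(n_components), drop = FALSE])
  scores <- bind_cols(tibble(sample_id = sc, group = grp), scores)
  ell <- scores |>
    pivot_longer(starts_with("PC"), names_to = "component",
                 values_to = "score") |>
    group_by(.data$group, .data$component) |>
    summarise(center = mean(.data$score),
              radius = 2 * sd(.data$score), .groups = "drop")
  structure(list(scores = scores,
                 explained_pct = explained,
                 ellipsoids = ell,
                 rotation = fit$rotation[, seq_len(n_components),
                                         drop = FALSE],
                 n_components = n_components),
            class = "expression_pca")
}

#' @export
print.expression_pca <- function(x, ...) {
  k <- min(3, length(x$explained_pct))
  cat("PCA of ", nrow(x$scores), " samples; top components explain ",
      paste0(round(x$explained_pct[seq_len(k)], 2), "%", collapse = ", "),
      " (total ", round(sum(x$explained_pct[seq_len(k)]), 2), "%)\n",
      sep = "")
  invisible(x)
}

#' @describeIn pca_expression Sample scores with group labels.
#' @param x An `expression_pca` object.
#' @param ... Unused.
#' @method tidy expression_pca
#' @export
tidy.expression_pca <- function(x, ...) x$scores

#' @describeIn pca_expression One row per component with `explained_pct` and
#'   the cumulative percentage.
#' @method glance expression_pca
#' @export
glance.expression_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$explained_pct)),
         explained_pct = x$explained_pct,
         cumulative_pct = cumsum(x$explained_pct))
}
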