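#' TMM normalization with an additive offset
#'
#' Normalizes a raw bulk count matrix by the trimmed mean of M-values (TMM):
#' per-sample scaling factors are estimated from doubly trimmed,
#' precision-weighted log2 expression ratios against a reference sample, then
#' counts are scaled and an additive offset (default 1) is applied so that
#' unexpressed transcripts sit at a floor of `offset` ("TMM+1").
#'
#' The algorithm:
#' * rows that are zero in every sample are ignored for factor estimation;
#' * the reference sample is the one whose upper-quartile count fraction is
#'   closest to the mean upper-quartile fraction across samples;
#' * for each sample, per-gene `M = log2((count/lib)/(ref_count/ref_lib))`
#'   and `A = (log2(count/lib) + log2(ref_count/ref_lib))/2` are computed
#'   over genes finite in both;
#' * the top and bottom `trim_m` of M and `trim_a` of A are trimmed, and the
#'   scaling factor is `2^` the precision-weighted mean of the surviving M
#'   (weights are inverse asymptotic binomial variances);
#' * factors are rescaled to geometric mean 1.
#'
#' Normalized values are `count / (lib_size * factor)` rescaled to the mean
#' library size (or to counts-per-million with `scale = "cpm"`), plus
#' `offset`.
#'
#' @param m Raw count matrix tibble (see [read_matrix()]).
#' @param trim_m,trim_a Trim fractions for M and A (defaults 0.3 and 0.05,
#'   the standard published values).
#' @param offset Additive constant applied after scaling (default 1).
#' @param scale `"libmean"` (default) rescales to the mean library size;
#'   `"cpm"` to counts per million.
#' @param weighted Precision weighting of M values (default `TRUE`).
#' @return An object of class `tmm_norm`: a list with `matrix` (the
#'   normalized tibble), `factors` (named per-sample scaling factors),
#'   `reference_sample`, `offset`, and `scale`. [tidy()] returns the
#'   per-sample factors; [glance()] a one-row summary.
#' @export
#' @examples
#' m <- tibble::tibble(transcript_id = paste0("t", 1:4),
#'                     gene_symbol = paste0("G", 1:4),
#'                     s1 = c(10, 20, 30, 0), s2 = c(20, 40, 60, 0))
#' norm <- tmm_normalize(m)
#' tidy(norm)
tmm_normalize <- function(m, trim_m = 0.3, trim_a = 0.05, offset = 1,
                          scale = c("libmean", "cpm"), weighted = TRUE) {
  validate_matrix(m)
  scale <- match.arg(scale)
  if (isTRUE(attr(m, "normalized"))) {
    abort("Matrix is already normalized.")
  }
  sc <- sample_cols(m)
  if (length(sc) < 2) abort("TMM needs at least 2 samples.")
  counts <- as.matrix(m[, sc])
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    abort(paste0("Sample(s) with zero library size: ",
                 paste(sc[lib <= 0], collapse = ", ")))
  }

  x <- counts[rowSums(counts > 0) > 0, , drop = FALSE]
  f75 <- apply(x, 2, function(col) quantile(col, probs = 0.75)) / lib
  ref_i <- if (median(f75) < 1e-20) {
    which.max(colSums(sqrt(x)))
  } else {
    which.min(abs(f75 - mean(f75)))
  }

  factors <- vapply(seq_along(sc), function(i) {
    tmm_pair_factor(x[, i], x[, ref_i], lib[i], lib[ref_i],
                    trim_m = trim_m, trim_a = trim_a, weighted = weighted,
                    sample_name = sc[i])
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  names(factors) <- sc

  target <- if (scale == "cpm") 1e6 else mean(lib)
  norm <- sweep(counts, 2, lib * factors, "/") * target + offset
  out <- m
  out[, sc] <- as_tibble(norm)
  attr(out, "normalized") <- TRUE
  attr(out, "offset") <- offset

  structure(list(matrix = out,
                 factors = factors,
                 reference_sample = sc[ref_i],
                 offset = offset,
                 scale = scale),
            class = "tmm_norm")
}

# Scaling factor of one sample against the reference (both on the count
# scale, with library sizes supplied). Falls back to the untrimmed mean when
# trimming leaves fewer than 10 genes.
tmm_pair_factor <- function(obs, ref, lib_obs, lib_ref, trim_m, trim_a,
                            weighted, sample_name = "?") {
  logR <- log2((obs / lib_obs) / (ref / lib_ref))
  absE <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / lib_obs / obs + (lib_ref - ref) / lib_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
  loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  if (sum(keep) < 10) {
    warn(paste0("Fewer than 10 genes survive TMM trimming for sample ",
                sample_name, "; using the untrimmed mean of M."))
    keep <- rep(TRUE, n)
  }
  f <- if (weighted) {
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(logR[keep], na.rm = TRUE)
  }
  if (is.na(f)) f <- 0
  2^f
}

#' @export
print.tmm_norm <- function(x, ...) {
  cat("TMM normalization (+", x$offset, " offset, scale = ", x$scale,
      ")\n", sep = "")
  cat("Reference sample:", x$reference_sample, "\n")
  cat("Factors:\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' @describeIn tmm_normalize Per-sample scaling factors and library sizes as
#'   a tibble.
#' @param x A `tmm_norm` object.
#' @param ... Unused.
#' @method tidy tmm_norm
#' @export
tidy.tmm_norm <- function(x, ...) {
  tibble(sample_id = names(x$factors), factor = unname(x$factors))
}

#' @describeIn tmm_normalize One-row summary (reference sample, offset,
#'   factor geometric mean).
#' @method glance tmm_norm
#' @export
glance.tmm_norm <- function(x, ...) {
  tibble(n_samples = length(x$factors),
         reference_sample = x$reference_sample,
         offset = x$offset,
         scale = x$scale,
         factor_geomean = exp(mean(log(x$factors))))
}

#' Filter transcripts by mean expression
#'
#' Retains transcripts whose mean normalized abundance across *all* samples
#' (both groups pooled) is at least `threshold`; rows with mean below the
#' threshold are removed. Row order is preserved.
#'
#' Note that with the default "+1" offset every normalized value is at least
#' `offset`, so a meaningful filter threshold must exceed the offset (or the
#' matrix must be normalized with `offset = 0`).
#'
#' @param m A normalized expression matrix tibble (or a `tmm_norm` object,
#'   whose `$matrix` is used).
#' @param threshold Minimum pooled mean (default 1); rows with mean strictly
#'   below it are dropped.
#' @return The filtered tibble.
#' @export
filter_low_expression <- function(m, threshold = 1) {
  if (inherits(m, "tmm_norm")) m <- m$matrix
  validate_matrix(m)
  stopifnot(threshold >= 0)
  if (!isTRUE(attr(m, "normalized"))) {
    warn("Filtering a matrix not flagged as normalized.")
  }
  sc <- sample_cols(m)
  means <- rowMeans(as.matrix(m[, sc]))
  keep <- means >= threshold
  if (!any(keep)) {
    abort("All transcripts fall below the expression filter.")
  }
  out <- m[keep, , drop = FALSE]
  attr(out, "normalized") <- attr(m, "normalized")
  attr(out, "offset") <- attr(m, "offset")
  out
}
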