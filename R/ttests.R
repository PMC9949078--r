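#' Two-sample t-tests
#'
#' `welch_t()` is the unpaired t-test with Welch's correction (no
#' equal-variance assumption, Welch-Satterthwaite degrees of freedom);
#' `student_t()` is the pooled-variance unpaired t-test with
#' `n_x + n_y - 2` degrees of freedom. Both are two-sided and return the
#' statistic, degrees of freedom and p-value as a one-row tibble.
#'
#' The degenerate case where both groups are constant and equal is reported
#' as `t = 0, p = 1` rather than an error, so that transcript-wise testing
#' over matrices with floor-valued rows does not abort.
#'
#' @param x,y Numeric vectors of at least 2 values each.
#' @return A tibble with columns `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t(c(10, 12, 11, 13), c(20, 19, 21, 22))
welch_t <- function(x, y) {
  t_two_sample(x, y, var_equal = FALSE)
}

#' @rdname welch_t
#' @export
student_t <- function(x, y) {
  t_two_sample(x, y, var_equal = TRUE)
}

t_two_sample <- function(x, y, var_equal) {
  if (length(x) < 2 || length(y) < 2) {
    abort("Each group needs at least 2 observations.")
  }
  if (var(x) == 0 && var(y) == 0) {
    if (x[1] == y[1]) {
      return(tibble(t = 0,
                    df = if (var_equal) length(x) + length(y) - 2 else NA_real_,
                    p = 1))
    }
    abort("Both groups are constant with different values; t is undefined.")
  }
  ht <- t.test(x, y, var.equal = var_equal)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = unname(ht$p.value))
}

# Vectorized two-sample t over matrix rows (columns split into two groups).
# Degenerate zero-variance rows: equal means -> t=0, p=1; unequal means with
# zero pooled variance -> t=Inf-like handled via p=0.
row_t_tests <- function(vals, idx_a, idx_b, var_equal) {
  xa <- vals[, idx_a, drop = FALSE]
  xb <- vals[, idx_b, drop = FALSE]
  na <- length(idx_a); nb <- length(idx_b)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, var); vb <- apply(xb, 1, var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  degenerate <- se == 0
  t[degenerate & ma == mb] <- 0
  df[degenerate] <- na + nb - 2
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[degenerate & ma == mb] <- 1
  p[degenerate & ma != mb] <- 0
  tibble(mean_a = ma, sd_a = sqrt(va), mean_b = mb, sd_b = sqrt(vb),
         t = t, df = df, p = p)
}
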