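#' Benjamini-Krieger-Yekutieli two-stage FDR procedure
#'
#' Adaptive two-stage linear step-up control of the false discovery rate.
#' With target level `q` and `q' = q / (1 + q)`:
#'
#' 1. Stage 1 applies the Benjamini-Hochberg linear step-up at level `q'`,
#'    giving `r1` rejections. If `r1 = 0` nothing is rejected; if `r1 = m`
#'    everything is rejected.
#' 2. Otherwise the number of true nulls is estimated as `m0 = m - r1` and
#'    stage 2 applies the linear step-up at level `q' * m / m0`.
#'
#' Adjusted q-values are the step-up cumulative minimum of
#' `p_(i) * m0 / i * (1 + q)` (clipped at 1), chosen so that
#' `q_value <= q` reproduces the two-stage rejection set exactly. Because the
#' procedure is adaptive, a q-value may be *smaller* than its p-value when
#' few true nulls are estimated; the rejection set, not the q-value, is the
#' primary quantity.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q Target FDR level (default 0.05).
#' @return A tibble with columns `p`, `q_value`, `rejected` in the input
#'   order. Zero-length input gives a zero-row tibble.
#' @export
#' @examples
#' bky_two_stage(c(0.001, 0.02, 0.4, 0.9), q = 0.05)
bky_two_stage <- function(p, q = 0.05) {
  if (length(p) == 0) {
    return(tibble(p = double(), q_value = double(), rejected = logical()))
  }
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  stopifnot(q > 0, q < 1)
  m <- length(p)
  q1 <- q / (1 + q)

  r1 <- bh_n_rejections(p, q1)
  if (r1 == 0) {
    m0 <- m
    rejected <- rep(FALSE, m)
  } else if (r1 == m) {
    m0 <- 0
    rejected <- rep(TRUE, m)
  } else {
    m0 <- m - r1
    r2 <- bh_n_rejections(p, q1 * m / m0)
    o <- order(p)
    rejected <- rep(FALSE, m)
    if (r2 > 0) rejected[o[seq_len(r2)]] <- TRUE
  }

  if (m0 == 0) {
    qv <- rep(0, m)
  } else {
    o <- order(p)
    ratios <- p[o] * m0 / seq_len(m) * (1 + q)
    qv_sorted <- rev(cummin(rev(pmin(ratios, 1))))
    qv <- numeric(m)
    qv[o] <- qv_sorted
  }
  tibble(p = p, q_value = qv, rejected = rejected)
}

# Number of rejections of the BH linear step-up at level alpha:
# max { i : p_(i) <= i * alpha / m }, 0 if none.
bh_n_rejections <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * alpha / m)
  if (length(ok) == 0) 0L else max(ok)
}
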