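#' One-sample t-test with Cohen's d and Bonferroni correction
#'
#' The group-level workhorse: a one- or two-sided one-sample t-test of
#' subject-level values against `mu`, reporting Cohen's d (mean difference
#' over the sample SD, n - 1 denominator) and a Bonferroni-corrected p-value.
#' One-sided tests are in the positive direction (values > mu), the direction
#' every above-chance / above-baseline hypothesis here takes.
#'
#' @param values numeric vector (n >= 2, nonzero variance).
#' @param mu null value (default 0).
#' @param tails "two" or "one".
#' @param bonferroni_m number of comparisons corrected for (default 1).
#' @return a `group_stat_result` list: `t`, `df`, `p_uncorrected`,
#'   `p_corrected`, `cohens_d`, `tails`, `bonferroni_m`, `mean`, `mu`.
#' @export
one_sample_t <- function(values, mu = 0, tails = c("two", "one"),
                         bonferroni_m = 1) {
  tails <- match.arg(tails)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("degenerate test: need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("degenerate test: zero sample variance")
  m <- mean(values)
  t <- (m - mu) / (s / sqrt(n))
  df <- n - 1L
  p <- if (tails == "two") 2 * stats::pt(abs(t), df, lower.tail = FALSE)
       else stats::pt(t, df, lower.tail = FALSE)
  structure(list(t = t, df = df, p_uncorrected = p,
                 p_corrected = bonferroni(p, bonferroni_m),
                 cohens_d = (m - mu) / s, tails = tails,
                 bonferroni_m = as.integer(bonferroni_m),
                 mean = m, mu = mu),
            class = "group_stat_result")
}

#' @export
print.group_stat_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g (%s-tailed%s), d = %.3f\n",
              x$df, x$t, x$p_corrected, x$tails,
              if (x$bonferroni_m > 1)
                paste0(", Bonferroni m = ", x$bonferroni_m) else ""),
      sep = "")
  invisible(x)
}

#' Bonferroni correction
#' @param p p-value(s) in (0, 1].
#' @param m number of comparisons (>= 1).
#' @return `min(1, m * p)`, vectorized over `p`.
#' @export
bonferroni <- function(p, m) {
  if (any(m < 1)) stop("m must be >= 1")
  pmin(1, p * m)
}
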