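# Method-comparison statistics between two algorithms measuring the
# same quantity on the same eyes: Pearson correlation, paired mean
# difference, and Bland-Altman 95% limits of agreement.

#' Construct a paired sample
#'
#' @param a,b Paired measurements (same subjects, micrometres),
#'   finite, equal length.
#' @param label Optional measure label (e.g. `"GCC"`, `"Cen"`).
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(a, b, label = "") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("paired measurements must be finite")
  structure(list(a = a, b = b, label = label), class = "paired_sample")
}

#' Pearson product-moment correlation of a paired sample
#'
#' @param s A [paired_sample] (or list with `a`, `b`); both vectors
#'   must be non-constant, otherwise `r` is undefined and `NA` is
#'   returned with a warning (never 0).
#' @return Correlation coefficient in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(s) {
  if (stats::sd(s$a) == 0 || stats::sd(s$b) == 0) {
    warning("correlation undefined for a constant vector; returning NA")
    return(NA_real_)
  }
  stats::cor(s$a, s$b, method = "pearson")
}

#' Paired mean difference with SD and p-value
#'
#' `bias = mean(a - b)` (which equals `mean(a) - mean(b)` exactly),
#' sample SD of the differences (n - 1 denominator), and the two-sided
#' paired t-test p-value.  With identical differences the t statistic
#' is undefined; by convention p = 1 when the bias is also 0, else 0
#' (the degenerate limit).
#'
#' @param s A [paired_sample] with `n >= 3`.
#' @param p_method `"t"` (paired t-test) or `"permutation"`
#'   (sign-flip permutation, 2000 resamples, seeded internally).
#' @return Named numeric: `bias`, `sd_diff`, `p`.
#' @export
mean_difference <- function(s, p_method = c("t", "permutation")) {
  p_method <- match.arg(p_method)
  d <- s$a - s$b
  n <- length(d)
  if (n < 3L) stop("paired statistics require n >= 3")
  bias <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    p <- if (bias == 0) 1 else 0
  } else if (p_method == "t") {
    p <- stats::t.test(s$a, s$b, paired = TRUE)$p.value
  } else {
    p <- run_with_seed(1L, {
      nres <- 2000L
      obs <- abs(mean(d))
      hits <- sum(vapply(seq_len(nres), function(i) {
        abs(mean(d * sample(c(-1, 1), n, replace = TRUE))) >= obs - 1e-12
      }, logical(1)))
      (hits + 1) / (nres + 1)
    })
  }
  c(bias = bias, sd_diff = sdd, p = p)
}

#' Bland-Altman agreement statistics
#'
#' Bias, SD of the paired differences, 95% limits of agreement
#' `bias +- 1.96 * SD` and their span `3.92 * SD`, plus the
#' (mean, difference) point pairs for plotting.
#'
#' @param s A [paired_sample] with `n >= 3`.
#' @return An object of class `agreement_stats`: list with `r`,
#'   `bias`, `sd_diff`, `p`, `loa_low`, `loa_high`, `span`, `n`,
#'   `label` and data frame `points` (columns `mean`, `diff`).
#' @export
bland_altman <- function(s) {
  md <- mean_difference(s)
  r <- suppressWarnings(pearson_r(s))
  structure(list(
    r = r, bias = unname(md["bias"]), sd_diff = unname(md["sd_diff"]),
    p = unname(md["p"]),
    loa_low = unname(md["bias"] - 1.96 * md["sd_diff"]),
    loa_high = unname(md["bias"] + 1.96 * md["sd_diff"]),
    span = unname(3.92 * md["sd_diff"]),
    n = length(s$a), label = s$label,
    points = data.frame(mean = (s$a + s$b) / 2, diff = s$a - s$b)
  ), class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "%s (n=%d): r=%.2f, bias=%.1f, SD=%.1f, LoA [%.1f, %.1f], span %.1f\n",
    if (nzchar(x$label)) x$label else "agreement", x$n,
    x$r, x$bias, x$sd_diff, x$loa_low, x$loa_high, x$span))
  invisible(x)
}

#' Method-comparison report table
#'
#' One row per measure: mean +- SD of each method, Pearson r, paired
#' mean difference +- SD, and p-value, with formatted columns rounded
#' to one decimal (r to two) in the conventional reporting style.  The
#' printed mean difference always equals the difference of the printed
#' group means up to rounding (the paired-difference identity).
#'
#' @param samples List of [paired_sample]s.
#' @return Data frame with numeric columns (`label`, `n`, `mean_a`,
#'   `sd_a`, `mean_b`, `sd_b`, `r`, `bias`, `sd_diff`, `p`) and
#'   formatted columns (`a_fmt`, `b_fmt`, `r_fmt`, `diff_fmt`,
#'   `p_fmt`).
#' @export
agreement_table <- function(samples) {
  if (length(samples) < 1L) stop("need at least one paired sample")
  rows <- lapply(samples, function(s) {
    md <- mean_difference(s)
    r <- suppressWarnings(pearson_r(s))
    data.frame(
      label = s$label, n = length(s$a),
      mean_a = mean(s$a), sd_a = stats::sd(s$a),
      mean_b = mean(s$b), sd_b = stats::sd(s$b),
      r = r, bias = unname(md["bias"]), sd_diff = unname(md["sd_diff"]),
      p = unname(md["p"]))
  })
  tab <- do.call(rbind, rows)
  fmt1 <- function(x) sprintf("%.1f", x)
  tab$a_fmt <- paste0(fmt1(tab$mean_a), "±", fmt1(tab$sd_a))
  tab$b_fmt <- paste0(fmt1(tab$mean_b), "±", fmt1(tab$sd_b))
  tab$r_fmt <- sprintf("%.2f", tab$r)
  tab$diff_fmt <- paste0(fmt1(tab$bias), "±", fmt1(tab$sd_diff))
  tab$p_fmt <- ifelse(tab$p < 0.01, "<0.01", sprintf("%.2f", tab$p))
  tab
}
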