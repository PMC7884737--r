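#' Paired Wilcoxon signed-rank comparison
#'
#' Reproduces the small-sample reporting convention common in invasive
#' physiology: zero differences are dropped, ties in `|post - pre|` get
#' mid-ranks, the statistic is `T = min(W+, W-)` (the sum of ranks of the
#' less frequent sign), and the default p-value is the asymptotic normal
#' approximation \emph{without} continuity correction,
#' \deqn{z = \frac{T - n(n+1)/4}{\sqrt{n(n+1)(2n+1)/24}},}
#' two-sided.  For n = 7 uniformly signed differences this gives
#' p = 0.018 (the exact sign-flip enumeration, available via
#' `method = "exact"`, gives 2/2^7 ~= 0.016).
#'
#' @param pre,post equal-length numeric vectors (n >= 5) of paired
#'   measurements.
#' @param method `"asymptotic"` (default) or `"exact"` (full enumeration
#'   of the 2^n sign assignments; n <= 20 after dropping zeros).
#' @param metric_name optional label carried into the result.
#' @return an object of class `paired_comparison`: `metric_name`,
#'   `mean_pre`, `se_pre`, `mean_post`, `se_post`, `n_used`,
#'   `w_statistic` (T), `z_value` (NA for exact), `p_two_sided`,
#'   `method`.
#' @export
wilcoxon_paired <- function(pre, post, method = c("asymptotic", "exact"),
                            metric_name = NA_character_) {
  method <- match.arg(method)
  if (length(pre) != length(post)) {
    stop("pre and post must have equal length", call. = FALSE)
  }
  if (length(pre) < 5L) {
    stop("paired comparison needs n >= 5 (got ", length(pre), ")",
         call. = FALSE)
  }
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("signed-rank test undefined: all paired differences are zero",
         call. = FALSE)
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  t_stat <- min(w_pos, w_neg)
  if (method == "asymptotic") {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- (t_stat - mu) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  } else {
    if (n > 20L) {
      stop("exact enumeration limited to n <= 20 nonzero differences",
           call. = FALSE)
    }
    z <- NA_real_
    p <- min(1, 2 * .signed_rank_cdf(t_stat, r))
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  structure(
    list(metric_name = metric_name,
         mean_pre = mean(pre), se_pre = se(pre),
         mean_post = mean(post), se_post = se(post),
         n_used = n, w_statistic = t_stat, z_value = z,
         p_two_sided = p, method = method),
    class = "paired_comparison")
}

# P(W+ <= t) under the sign-flip null, by enumeration of all 2^n
# assignments using the observed (possibly tied, mid-) ranks
.signed_rank_cdf <- function(t_stat, ranks) {
  n <- length(ranks)
  count <- 0L
  for (m in 0:(2^n - 1L)) {
    signs <- bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) != 0L
    if (sum(ranks[signs]) <= t_stat) count <- count + 1L
  }
  count / 2^n
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("paired_comparison%s: %.3g +/- %.2g vs %.3g +/- %.2g (n = %d)\n",
              if (is.na(x$metric_name)) "" else paste0(" [", x$metric_name, "]"),
              x$mean_pre, x$se_pre, x$mean_post, x$se_post, x$n_used))
  cat(sprintf("  T = %g, %s p = %.3f\n", x$w_statistic, x$method,
              x$p_two_sided))
  invisible(x)
}

#' Pearson correlation with t-distribution p-values
#'
#' Sample Pearson coefficient with `t = r sqrt(n-2) / sqrt(1-r^2)` on
#' `n - 2` degrees of freedom.  Both the one-sided p (tail in the
#' direction of the observed sign of r) and the two-sided p are
#' reported; one-sided is listed first because small invasive studies
#' commonly report directional correlations.
#'
#' @param x,y equal-length numeric vectors, n >= 3, each with nonzero
#'   variance.
#' @param x_name,y_name optional labels.
#' @return an object of class `correlation_result`: `x_name`, `y_name`,
#'   `r`, `n`, `t_value`, `p_one_sided`, `p_two_sided`, and `degenerate`
#'   (TRUE when |r| = 1 and the p-values hit the floor).
#' @export
pearson_correlation <- function(x, y, x_name = NA_character_,
                                y_name = NA_character_) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("correlation needs n >= 3 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate correlation: zero variance in x or y", call. = FALSE)
  }
  r <- stats::cor(x, y)
  pr <- pearson_p(r, n)
  structure(c(list(x_name = x_name, y_name = y_name, r = r, n = n), pr),
            class = "correlation_result")
}

#' t-statistic and p-values for a given Pearson r and sample size
#'
#' @param r Pearson coefficient in `[-1, 1]`.
#' @param n number of pairs (>= 3).
#' @return list with `t_value`, `p_one_sided` (tail in the direction of
#'   the sign of r), `p_two_sided`, `degenerate`.
#' @examples
#' pearson_p(0.707, 7)$p_one_sided  # ~0.038
#' @export
pearson_p <- function(r, n) {
  stopifnot(length(r) == 1L, is.finite(r), abs(r) <= 1, n >= 3)
  df <- n - 2
  if (abs(r) == 1) {
    return(list(t_value = Inf * sign(r), p_one_sided = 0,
                p_two_sided = 0, degenerate = TRUE))
  }
  t_val <- r * sqrt(df) / sqrt(1 - r^2)
  p_one <- stats::pt(abs(t_val), df, lower.tail = FALSE)
  list(t_value = t_val, p_one_sided = p_one,
       p_two_sided = min(1, 2 * p_one), degenerate = FALSE)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result%s: r = %.3f (n = %d), t = %.3f\n",
              if (is.na(x$x_name)) "" else
                paste0(" [", x$x_name, " vs ", x$y_name, "]"),
              x$r, x$n, x$t_value))
  cat(sprintf("  p one-sided = %.4f, two-sided = %.4f%s\n",
              x$p_one_sided, x$p_two_sided,
              if (x$degenerate) " (degenerate |r| = 1, floored)" else ""))
  invisible(x)
}

#' Build paired-comparison and correlation report tables
#'
#' Mirrors the reporting layout of invasive before/after studies: one
#' table of per-metric group means +/- SE with the paired signed-rank p,
#' and one table of correlations between a response metric and a set of
#' explanatory metrics in the post condition.
#'
#' @param metrics data frame with columns `subject_id`, `condition`, and
#'   one numeric column per metric.
#' @param pre_label,post_label values of `condition` identifying the two
#'   paired states.
#' @param correlations optional character vector of metric names to
#'   correlate against `correlate_with` (evaluated in the post
#'   condition).
#' @param correlate_with response metric name for the correlation table.
#' @return list with data frames `paired` (metric, mean_pre, se_pre,
#'   mean_post, se_post, w_statistic, p_two_sided) and `correlations`
#'   (x_name, y_name, r, n, p_one_sided, p_two_sided; NULL if not
#'   requested).
#' @export
build_report <- function(metrics, pre_label = "baseline",
                         post_label = "after_evar",
                         correlations = NULL, correlate_with = NULL) {
  need <- c("subject_id", "condition")
  if (!all(need %in% names(metrics))) {
    stop("metrics table must have 'subject_id' and 'condition' columns",
         call. = FALSE)
  }
  pre <- metrics[metrics$condition == pre_label, , drop = FALSE]
  post <- metrics[metrics$condition == post_label, , drop = FALSE]
  miss_post <- setdiff(pre$subject_id, post$subject_id)
  miss_pre <- setdiff(post$subject_id, pre$subject_id)
  if (length(miss_post) || length(miss_pre)) {
    stop("pairing error: subject(s) missing a condition: ",
         paste(unique(c(miss_post, miss_pre)), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(pre) < 5L) {
    stop("pairing error: need >= 5 paired subjects (got ", nrow(pre), ")",
         call. = FALSE)
  }
  post <- post[match(pre$subject_id, post$subject_id), , drop = FALSE]
  metric_cols <- setdiff(names(metrics), need)
  metric_cols <- metric_cols[vapply(metrics[metric_cols], is.numeric,
                                    logical(1))]
  rows <- lapply(metric_cols, function(m) {
    res <- tryCatch(wilcoxon_paired(pre[[m]], post[[m]], metric_name = m),
                    error = function(e) NULL)
    if (is.null(res)) {
      data.frame(metric = m, mean_pre = mean(pre[[m]]),
                 se_pre = stats::sd(pre[[m]]) / sqrt(nrow(pre)),
                 mean_post = mean(post[[m]]),
                 se_post = stats::sd(post[[m]]) / sqrt(nrow(post)),
                 w_statistic = NA_real_, p_two_sided = NA_real_)
    } else {
      data.frame(metric = m, mean_pre = res$mean_pre, se_pre = res$se_pre,
                 mean_post = res$mean_post, se_post = res$se_post,
                 w_statistic = res$w_statistic,
                 p_two_sided = res$p_two_sided)
    }
  })
  paired <- do.call(rbind, rows)

  corr <- NULL
  if (!is.null(correlations) && !is.null(correlate_with)) {
    bad <- setdiff(c(correlations, correlate_with), metric_cols)
    if (length(bad)) {
      stop("unknown metric(s) in correlation request: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    corr <- do.call(rbind, lapply(correlations, function(m) {
      cr <- pearson_correlation(post[[m]], post[[correlate_with]],
                                x_name = m, y_name = correlate_with)
      data.frame(x_name = m, y_name = correlate_with, r = cr$r, n = cr$n,
                 p_one_sided = cr$p_one_sided,
                 p_two_sided = cr$p_two_sided)
    }))
  }
  list(paired = paired, correlations = corr)
}
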