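#' Metabolome-wide two-sample t-tests
#'
#' Tests every feature for a mean difference between two groups, by default
#' with Welch's unequal-variance t statistic on log10 replicate-averaged
#' intensities (pooled-variance and raw-scale variants selectable). Tests
#' are two-sided; direction is reported as the sign of the group-2 minus
#' group-1 mean. Features are tested on pairwise-complete samples; a
#' feature with fewer than two usable samples in either group is flagged
#' untestable (`p = NA`), and a feature with zero variance in both groups
#' is flagged (`p = 1` when the means agree).
#'
#' @param table a `feature_table` (replicates are averaged internally).
#' @param meta sample metadata (`sample_id`, `group`).
#' @param g1,g2 the two group labels to compare.
#' @param on_log test on the log10 scale (default `TRUE`).
#' @param var_equal use the pooled-variance statistic (default `FALSE`,
#'   i.e. Welch).
#' @return data.frame (`univariate_table`): `feature_id`, `mean_g1`,
#'   `mean_g2`, `direction`, `t_stat`, `df`, `p_value`, `zero_variance`,
#'   `untestable`.
#' @export
two_sample_t <- function(table, meta, g1, g2, on_log = TRUE,
                         var_equal = FALSE) {
  x <- sample_matrix(table, log10 = on_log)
  grp <- meta$group[match(rownames(x), meta$sample_id)]
  x1 <- t(x[grp %in% g1, , drop = FALSE])
  x2 <- t(x[grp %in% g2, , drop = FALSE])
  if (ncol(x1) < 2 || ncol(x2) < 2)
    stop("both groups need at least 2 samples")

  msd <- function(m) {
    n <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    v <- rowSums((m - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
    list(n = n, mu = mu, v = v)
  }
  a <- msd(x1)
  b <- msd(x2)
  untestable <- a$n < 2 | b$n < 2
  diff <- b$mu - a$mu
  zero_var <- a$v == 0 & b$v == 0

  if (var_equal) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$v + (b$n - 1) * b$v) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    se2 <- a$v / a$n + b$v / b$n
    df <- se2^2 / ((a$v / a$n)^2 / (a$n - 1) + (b$v / b$n)^2 / (b$n - 1))
    se <- sqrt(se2)
  }
  t_stat <- diff / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  t_stat[zero_var & diff == 0] <- 0
  p[zero_var & diff == 0] <- 1
  p[zero_var & diff != 0] <- 0
  p[untestable] <- NA_real_
  t_stat[untestable] <- NA_real_
  if (any(zero_var & !untestable))
    warning(sum(zero_var & !untestable), " feature(s) with zero variance in both groups")

  out <- data.frame(feature_id = table$features$feature_id,
                    mean_g1 = a$mu, mean_g2 = b$mu,
                    direction = sign(diff), t_stat = t_stat, df = df,
                    p_value = p, zero_variance = zero_var,
                    untestable = untestable,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "groups") <- c(g1 = g1, g2 = g2)
  class(out) <- c("univariate_table", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at target FDR `q`: with the `m` p-values sorted
#' ascending, find the largest rank `i` with `p(i) <= (i/m) * q`; all
#' features at or below that rank are declared significant. Adjusted
#' q-values are the usual monotone-enforced `min over j >= i of (m/j) p(j)`
#' (computed via [stats::p.adjust()]), and a feature is significant exactly
#' when its q-value is at most `q`.
#'
#' @param p_values numeric p-values in `(0, 1]`; `NA` allowed (untestable
#'   features) and never declared significant.
#' @param q target false discovery rate (default 0.2).
#' @return list with `q_values`, `significant` (logical), `n_significant`
#'   and `max_significant_p` (largest p declared significant; `NA` if none).
#' @export
bh_fdr <- function(p_values, q = 0.2) {
  if (!length(p_values))
    return(list(q_values = numeric(0), significant = logical(0),
                n_significant = 0L, max_significant_p = NA_real_))
  qv <- stats::p.adjust(p_values, method = "BH")
  sig <- !is.na(qv) & qv <= q
  list(q_values = qv, significant = sig, n_significant = sum(sig),
       max_significant_p = if (any(sig)) max(p_values[sig]) else NA_real_)
}

#' Manhattan-plot data
#'
#' Emits `-log10 p` per feature with the BH significance flag and the
#' height of the horizontal FDR line: `-log10` of the largest p-value
#' declared significant at the stated `q` (absent when nothing is
#' significant).
#'
#' @param results a `univariate_table` from [two_sample_t()] (or any
#'   data.frame with `feature_id` and `p_value`).
#' @param q target FDR for the line (default 0.2).
#' @return data.frame with `index`, `feature_id`, `neg_log10_p`,
#'   `significant`; attribute `line_height` (numeric or `NA`).
#' @export
manhattan_data <- function(results, q = 0.2) {
  fdr <- bh_fdr(results$p_value, q)
  out <- data.frame(index = seq_len(nrow(results)),
                    feature_id = results$feature_id,
                    neg_log10_p = -log10(results$p_value),
                    significant = fdr$significant,
                    stringsAsFactors = FALSE)
  attr(out, "line_height") <-
    if (is.na(fdr$max_significant_p)) NA_real_
    else -log10(fdr$max_significant_p)
  attr(out, "q") <- q
  out
}

#' Univariate stage: t-tests plus FDR in one call
#'
#' @inheritParams two_sample_t
#' @param q target FDR (default 0.2).
#' @return the `univariate_table` with `q_value` and `significant_at_q`
#'   columns appended.
#' @export
univariate_analysis <- function(table, meta, g1, g2, q = 0.2,
                                on_log = TRUE, var_equal = FALSE) {
  res <- two_sample_t(table, meta, g1, g2, on_log, var_equal)
  fdr <- bh_fdr(res$p_value, q)
  res$q_value <- fdr$q_values
  res$significant_at_q <- fdr$significant
  attr(res, "q") <- q
  res
}
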