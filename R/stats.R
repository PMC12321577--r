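# Group statistics used throughout the figures: one-way ANOVA with
# Tukey's HSD multiple-comparison test (Tukey-Kramer for unbalanced
# groups), and mean +/- s.e.m. / five-number summaries.

as_group_data <- function(data) {
  if (is.data.frame(data)) {
    stopifnot(all(c("value", "group") %in% names(data)))
    data <- split(data$value, data$group)
  }
  if (!is.list(data) || is.null(names(data)) || any(names(data) == ""))
    stop("group data must be a named list of numeric vectors or a ",
         "data.frame with 'value' and 'group'")
  lapply(data, as.numeric)
}

#' One-way analysis of variance
#'
#' Fits the standard one-way fixed-effects model via [stats::aov()] and
#' returns the F statistic, degrees of freedom and p value.
#'
#' @param data named list of numeric vectors (one per group, each n >= 2),
#'   or a data.frame with columns `value` and `group`.
#' @return an `AnovaResult` list: `F`, `df_between`, `df_within`, `p_value`,
#'   `ms_within`, `group_n`, `group_means`.
#' @export
one_way_anova <- function(data) {
  g <- as_group_data(data)
  if (length(g) < 2) stop("need at least 2 groups")
  if (any(lengths(g) < 2)) stop("each group needs n >= 2")
  df <- data.frame(value = unlist(g, use.names = FALSE),
                   group = factor(rep(names(g), lengths(g))))
  if (stats::var(df$value) == 0)
    stop("ANOVA undefined: zero within-group and between-group variance")
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  structure(list(F = tab$`F value`[1],
                 df_between = tab$Df[1], df_within = tab$Df[2],
                 p_value = tab$`Pr(>F)`[1],
                 ms_within = tab$`Mean Sq`[2],
                 group_n = lengths(g),
                 group_means = vapply(g, mean, numeric(1))),
            class = "AnovaResult")
}

#' Tukey's HSD multiple-comparison test
#'
#' Pairwise comparisons after one-way ANOVA. For each pair the studentized
#' range statistic is
#' `q = |mean_i - mean_j| / sqrt(ms_within/2 * (1/n_i + 1/n_j))`
#' (the Tukey-Kramer form, exact for unbalanced groups), and the adjusted
#' p value is the upper tail of the studentized-range distribution with k
#' groups and `df_within` degrees of freedom ([stats::ptukey()]).
#'
#' @inheritParams one_way_anova
#' @return a `TukeyResult` data.frame: `group_i`, `group_j`, `mean_diff`
#'   (i minus j), `q`, `p_adj`.
#' @export
tukey_hsd <- function(data) {
  a <- one_way_anova(data)
  k <- length(a$group_means)
  nm <- names(a$group_means)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    diff <- a$group_means[i] - a$group_means[j]
    se <- sqrt(a$ms_within / 2 * (1 / a$group_n[i] + 1 / a$group_n[j]))
    q <- abs(diff) / se
    rows[[length(rows) + 1]] <- data.frame(
      group_i = nm[i], group_j = nm[j], mean_diff = unname(diff),
      q = unname(q),
      p_adj = stats::ptukey(q, nmeans = k, df = a$df_within,
                            lower.tail = FALSE))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("TukeyResult", "data.frame")
  out
}

#' Per-group summaries
#'
#' Mean, s.e.m. (sample s.d. with n-1 denominator over sqrt(n); `NA` for
#' single values), n, and box-plot five-number summaries with quartiles by
#' linear interpolation (quantile type 7).
#'
#' @param data named list of numeric vectors (each n >= 1), or a data.frame
#'   with `value` and `group`.
#' @return data.frame: `group`, `n`, `mean`, `sem`, `min`, `q1`, `median`,
#'   `q3`, `max`.
#' @export
summarize_groups <- function(data) {
  g <- as_group_data(data)
  if (any(lengths(g) < 1)) stop("each group needs n >= 1")
  do.call(rbind, lapply(names(g), function(nm) {
    v <- g[[nm]]
    qs <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    data.frame(group = nm, n = length(v), mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               min = qs[1], q1 = qs[2], median = qs[3], q3 = qs[4],
               max = qs[5])
  }))
}
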