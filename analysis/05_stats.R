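#!/usr/bin/env Rscript
# Group statistics over the measured tables: one-way ANOVA with Tukey's
# multiple-comparison test of morphometric metrics across septal regions,
# plus mean +/- s.e.m. summaries. Reads results/morphometry.csv (run
# analysis/02_morphometry.R first); writes results/stats.csv and
# results/summary.csv.

suppressPackageStartupMessages(library(septastro))

morph_path <- file.path("results", "morphometry.csv")
if (!file.exists(morph_path))
  stop("run analysis/02_morphometry.R first (missing ", morph_path, ")")
morph <- read_table(morph_path)
morph <- morph[!morph$border_touching, , drop = FALSE]

metrics <- c("longest_branch_um", "lw_ratio", "territory_area_um2")
stats_rows <- list()
summary_rows <- list()
for (met in metrics) {
  df <- data.frame(value = morph[[met]], group = morph$region_label)
  df <- df[!is.na(df$value), ]
  counts <- table(df$group)
  df <- df[df$group %in% names(counts)[counts >= 2], ]
  a <- one_way_anova(df)
  tk <- tukey_hsd(df)
  stats_rows[[length(stats_rows) + 1]] <- data.frame(
    metric = met, comparison = "omnibus", statistic = a$F,
    df1 = a$df_between, df2 = a$df_within, p = a$p_value)
  stats_rows[[length(stats_rows) + 1]] <- data.frame(
    metric = met, comparison = paste(tk$group_i, tk$group_j, sep = " vs "),
    statistic = tk$q, df1 = NA, df2 = a$df_within, p = tk$p_adj)
  s <- summarize_groups(df)
  s$metric <- met
  summary_rows[[length(summary_rows) + 1]] <- s
}

write_table(do.call(rbind, stats_rows), file.path("results", "stats.csv"))
write_table(do.call(rbind, summary_rows), file.path("results", "summary.csv"))

st <- do.call(rbind, stats_rows)
om <- st[st$comparison == "omnibus", ]
for (i in seq_len(nrow(om)))
  cat(sprintf("%-20s F(%d,%d) = %.2f, p = %.3g\n", om$metric[i],
              om$df1[i], om$df2[i], om$statistic[i], om$p[i]))
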