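#!/usr/bin/env Rscript
# Step 4 — nonparametric comparison of the outcome tables.
#
# Mirrors the study's statistical plan: Shapiro-Wilk-gated median/IQR
# summaries, Wilcoxon signed-rank on repeated threshold choices,
# Kruskal-Wallis across the four acquisition settings, and pairwise
# Mann-Whitney U with Bonferroni adjustment (m = 6 pairs) where the
# Kruskal-Wallis test is significant.

library(surfaccuracy)

repro <- read.csv("results/reproducibility.csv")
true_tab <- read.csv("results/trueness.csv")
if (nrow(repro) == 0 || nrow(true_tab) == 0)
  stop("run analysis/02 and 03 first")

summary_tab <- rbind(summarize_outcomes(repro), summarize_outcomes(true_tab))
write.csv(summary_tab, "results/stats_summary.csv", row.names = FALSE)
cat("Medians/IQRs per setting and outcome written to results/stats_summary.csv\n\n")

# threshold reproducibility: signed differences between the two sessions
thr <- repro$value[repro$outcome == "threshold_diff"]
w <- wilcoxon_signed_rank(thr)
cat(sprintf("Threshold differences: median |diff| %.2f grey values, Wilcoxon p = %.3f (%s)\n",
            median(abs(thr)), w$p, w$method))
kw_thr <- kruskal_wallis(split(thr, repro$setting[repro$outcome == "threshold_diff"]))
cat(sprintf("Threshold differences across settings: Kruskal-Wallis H = %.3f, p = %.3f\n\n",
            kw_thr$statistic, kw_thr$p))

compare_settings <- function(tab, outcome) {
  v <- tab$value[tab$outcome == outcome]
  g <- tab$setting[tab$outcome == outcome]
  kw <- kruskal_wallis(split(v, g))
  cat(sprintf("%-14s Kruskal-Wallis H = %6.3f, p = %.4f (%s)\n",
              outcome, kw$statistic, kw$p, kw$method))
  if (kw$p < 0.05) {
    settings <- unique(g)
    pairs <- combn(settings, 2)
    m <- ncol(pairs)
    for (j in seq_len(m)) {
      mw <- mann_whitney_u(v[g == pairs[1, j]], v[g == pairs[2, j]],
                           bonferroni_m = m)
      if (mw$p_adjusted < 0.05)
        cat(sprintf("    %s vs %s: U = %.1f, adjusted p = %.4f\n",
                    pairs[1, j], pairs[2, j], mw$statistic, mw$p_adjusted))
    }
  }
}

cat("Reproducibility outcomes across acquisition settings:\n")
for (o in c("mad_pre", "mad_post", "sdad_pre", "sdad_post"))
  compare_settings(repro, o)
cat("\nSuperimposition motions across acquisition settings:\n")
for (o in c("tx", "ty", "tz", "rx", "ry", "rz"))
  compare_settings(repro, o)
cat("\nTrueness outcomes across acquisition settings:\n")
for (o in c("trueness_mad", "trueness_sdad"))
  compare_settings(true_tab, o)
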