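#!/usr/bin/env Rscript
# Two sessions of two-way ANOVA (gender x emotion), one per feature family,
# on the per-segment feature values with channels as replicates. The design
# is unbalanced (4 female vs 6 male subjects), so Type II sums of squares
# are used.

suppressPackageStartupMessages(library(compen))
long <- readRDS("results/analysis/features_long.rds")

for (kind in c("hur", "aape")) {
  tab <- two_way_anova(long[[paste0("value_", kind)]], long$gender,
                       long$emotion)
  cat(sprintf("\nTwo-way ANOVA on %s (%s SS):\n", toupper(kind),
              attr(tab, "ss_type")))
  print(as.data.frame(tab), digits = 4)
  write.csv(as.data.frame(tab),
            sprintf("results/analysis/anova_%s.csv", kind), row.names = FALSE)
  sig <- tab$p[1] < attr(tab, "alpha")
  cat(sprintf("Gender effect %s at alpha = %.2f (p = %.3g).\n",
              if (sig) "significant" else "not significant",
              attr(tab, "alpha"), tab$p[1]))
}
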