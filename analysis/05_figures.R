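#!/usr/bin/env Rscript
# Step 5: proportion-vs-proportion scatter figures.
#
# One panel row per extraction window, one dot per covariate; departures
# from the diagonal are anchoring effects. Uses the scatter tables written
# by analysis/03_balance.R.

suppressPackageStartupMessages({
  library(anchorsim)
  library(data.table)
})
if (!requireNamespace("ggplot2", quietly = TRUE)) {
  stop("figures require the 'ggplot2' package")
}

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
for (preset in c("influenza_like", "covid_like")) {
  for (design in c("cohort_arbitrary_date", "cohort_visit",
                   "self_prior_date", "self_prior_visit")) {
    sc <- fread(sprintf("results/balance/%s_%s_scatter.csv", preset, design))
    p <- plot_covariate_scatter(sc, title = sprintf("%s - %s", preset, design))
    out <- sprintf("results/figures/%s_%s.pdf", preset, design)
    ggplot2::ggsave(out, p, width = 12, height = 3)
    cat("wrote", out, "\n")
  }
}
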