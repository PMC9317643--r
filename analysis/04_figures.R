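#!/usr/bin/env Rscript
# Figures for the factorial experiment: true-vs-imputed correlation
# scatterplots for one replicate, and box plots of bias and validity
# metrics across the grid. Writes PDFs under results/figures/ (requires
# ggplot2).

library(pairedimpute)

if (!requireNamespace("ggplot2", quietly = TRUE))
  stop("install ggplot2 to draw the figures")

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
res <- utils::read.csv("results/grid_results.csv")

## scatter: one replicate of the high-correlation profile at several levels
pf <- study_profile("gctof_like")
seed <- 20260930
st <- generate_paired_study(pf$design, pf$profile, pf$n_metabolites,
                            seed = derive_seed(seed, 1, 1))
logc <- log_transform_study(st)
recs <- list()
for (p in c(5, 20, 40, 60)) {
  ma <- induce_missingness(st$A, p, derive_seed(seed, "fig", p, 1))
  mb <- induce_missingness(st$B, p, derive_seed(seed, "fig", p, 2))
  masked <- log_transform_study(mask_study(st, ma, mb))
  for (me in imputation_methods()) {
    imp <- suppressWarnings(
      impute_study(masked, me, "separate",
                   imputer_settings(rf_trees = 20, seed = p)))
    rec <- correlation_records(logc, imp, ma, mb)
    rec$method <- me
    rec$p <- p
    recs[[length(recs) + 1]] <- rec
  }
}
sc <- plot_correlation_scatter(do.call(rbind, recs), facets = c("p", "method"))
ggplot2::ggsave("results/figures/correlation_scatter.pdf", sc,
                width = 10, height = 8)

## box plots across the grid
for (metric in c("mean_bias", "sensitivity", "specificity", "accuracy")) {
  gg <- plot_metric_boxes(res, metric)
  ggplot2::ggsave(sprintf("results/figures/%s_boxes.pdf", metric), gg,
                  width = 9, height = 6)
}
cat("figures written under results/figures/\n")
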