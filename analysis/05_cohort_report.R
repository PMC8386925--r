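#!/usr/bin/env Rscript
# Stage 5: between-sex comparison of the per-individual posterior medians
# (two-sided Wilcoxon rank-sum at 0.05) and the population summary tables,
# plus a simple credible-interval figure per model.

source(file.path("analysis", "00_config.R"))

truth <- read.csv(file.path(RESULTS_DIR, "truth.csv"))
sex_of <- unique(truth[, c("individual", "sex")])

as_stub <- function(df) {
  # rebuild minimal posterior objects from the stage-4 percentile tables
  out <- lapply(split(df, df$individual), function(d) {
    structure(list(percentiles = d[, c("source", "p2.5", "p16", "p50",
                                       "p84", "p97.5")]),
              class = "diet_posterior")
  })
  out[order(names(out))]
}

for (model in c("model1", "model2")) {
  f <- read.csv(file.path(RESULTS_DIR, paste0("fits_", model, ".csv")),
                check.names = FALSE)
  post <- as_stub(f)
  sexes <- sex_of$sex[match(names(post), sex_of$individual)]
  names(sexes) <- names(post)
  res <- summarize_cohort(post, sexes)
  write.csv(res$groups,
            file.path(RESULTS_DIR, paste0("cohort_", model, ".csv")),
            row.names = FALSE)
  scale_lab <- if (model == "model1") "dietary protein" else "whole diet"
  cat("\n==", model, "(fractions of", scale_lab, ") ==\n")
  print(res$groups[, c("source", "mean_male", "mean_female",
                       "ratio_male_female", "p_value", "significant")],
        digits = 3)
}

# figure: per-individual 68%/95% intervals by source and sex
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  f1 <- read.csv(file.path(RESULTS_DIR, "fits_model1.csv"),
                 check.names = FALSE)
  f1$sex <- sex_of$sex[match(f1$individual, sex_of$individual)]
  gg <- ggplot(f1, aes(individual, p50, colour = sex)) +
    geom_linerange(aes(ymin = `p2.5`, ymax = `p97.5`), linewidth = 0.3) +
    geom_pointrange(aes(ymin = p16, ymax = p84), size = 0.2,
                    linewidth = 0.9) +
    facet_wrap(~source, ncol = 1) +
    labs(y = "fraction of dietary protein", x = NULL,
         title = "Model 1 posteriors by individual") +
    theme_minimal(base_size = 9) +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
  dir.create(file.path(RESULTS_DIR, "figures"), showWarnings = FALSE)
  ggsave(file.path(RESULTS_DIR, "figures", "model1_posteriors.png"), gg,
         width = 6, height = 7, dpi = 150)
  cat("\nWrote figures/model1_posteriors.png\n")
}
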