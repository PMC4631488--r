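#!/usr/bin/env Rscript
# Step 4: combined-years repeated-measures models.
#
# Uses both measurement years per fraction. Model 1 takes sampling order
# nested in year as the fixed part; Model 2 takes the exact age at
# measurement as a covariate. Both carry the additive genetic term plus a
# permanent-environment term on animal identity, so repeatability
# R = (V_A + V_PE + V_C)/V_P is estimable alongside h2.

suppressPackageStartupMessages(library(immunoQG))

ds <- simulate_dataset(sim_config(seed = 2015L))
dir.create("results", showWarnings = FALSE)

fits <- list(); labels <- character(0)
for (model in c("Model 1", "Model 2")) {
  for (fr in unique(ds$phenotypes$fraction)) {
    r <- run_combined(ds, fr, model)
    fits[[length(fits) + 1L]] <- r$fit
    labels <- c(labels, sprintf("%s (%s)", fr, model))
    if (model == "Model 1") {
      w <- wald_f(r$fit, "factor(year):factor(order)")
      cat(sprintf("%-14s order-in-year Wald F(%d,%d) = %.2f, p = %.3g\n",
                  fr, w$ndf, w$ddf, w$F, w$p_value))
    } else {
      w <- wald_f(r$fit, "age")
      cat(sprintf("%-14s age covariate Wald F(%d,%d) = %.2f, p = %.3g\n",
                  fr, w$ndf, w$ddf, w$F, w$p_value))
    }
  }
}

tab2 <- parameter_table(fits, labels, with_repeatability = TRUE)
write_parameter_table(tab2, file.path("results", "table2.tsv"))
cat("\nCombined-years genetic estimates (results/table2.tsv):\n")
print(tab2[c("label", "n", "mean", "V_A", "V_PE", "V_R", "V_P", "R",
             "h2", "CV_A", "CV_R")], digits = 3, row.names = FALSE)
cat("\nR bounds h2 from above; both stay low when the permanent\n")
cat("between-individual variance is small, as in the emulated design.\n")
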