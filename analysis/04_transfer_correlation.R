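#!/usr/bin/env Rscript
# Link the two arms: transfer function between the downstream
# (band-pass) and upstream (low-pass) IPI tuning curves with propagated
# SEM, and the neural-versus-behavior correlation analysis (Pearson r,
# exhaustive permutation p, Meng's z for the dependent comparison).
# Reads the tables written by 02_behavior.R and 03_imaging.R.

suppressPackageStartupMessages(library(pulsetune))

need <- c("results/imaging_responses_vpn1_like.csv",
          "results/imaging_responses_pc1_like.csv",
          "results/behavior_ipi_summed_ci.csv")
if (!all(file.exists(need)))
  stop("run analysis/02_behavior.R and analysis/03_imaging.R first")

rebuild <- function(path) {
  long <- read.csv(path)
  agg <- aggregate(value ~ subject + condition, long, mean)
  normalize_per_subject(build_tuning(agg, axis = "ipi_ms"))
}
vpn1 <- rebuild(need[1])
pc1 <- rebuild(need[2])
behavior <- normalize_per_subject(
  build_tuning(read.csv(need[3]), axis = "ipi_ms"))

## --- transfer function ----------------------------------------------------
tf <- transfer_function(pc1, vpn1)
write.csv(data.frame(ipi_ms = tf$conditions, ratio = tf$ratio,
                     sem = tf$sem),
          "results/transfer_function.csv", row.names = FALSE)
cat("Downstream/upstream transfer function (ratio +/- SEM):\n")
print(data.frame(ipi_ms = tf$conditions, ratio = round(tf$ratio, 3),
                 sem = round(tf$sem, 3)))
r35 <- tf$ratio[tf$conditions == 35]
cat(sprintf("Band-pass check: ratio at 35 ms (%.2f) vs <=25 ms (max %.2f) and >=75 ms (max %.2f)\n",
            r35, max(tf$ratio[tf$conditions <= 25]),
            max(tf$ratio[tf$conditions >= 75])))

## --- neural-behavior correlations -----------------------------------------
report <- run_correlation_report(list(vpn1_like = vpn1, pc1_like = pc1),
                                 behavior, seed = 1)
cat("\nTuning-curve correlations with behavior (exhaustive permutation test):\n")
print(report$correlations)
cat(sprintf("\nMeng's z comparing the dependent correlations: z = %.3f, p = %.4f\n",
            report$meng$z, report$meng$p_value))

jsonlite::write_json(
  list(correlations = report$correlations,
       meng = report$meng[c("z", "p_value", "r1", "r2", "r_x", "n")],
       transfer = list(ipi_ms = tf$conditions, ratio = tf$ratio,
                       sem = tf$sem)),
  "results/correlation_report.json", auto_unbox = TRUE, digits = NA)
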