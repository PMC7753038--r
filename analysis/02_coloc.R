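#!/usr/bin/env Rscript
# Co-localization of the cytoskeletal (NESTIN) and endothelial-membrane
# (CD34/CD31) channels on capillary-like synthetic fields: Costes automatic
# thresholds, Pearson R and Manders M1/M2 above threshold, and the
# translated negative control (100 px on both axes, thresholds
# re-estimated), followed by a group comparison against segregated-signal
# control fields.

suppressPackageStartupMessages(library(marrowmorph))
dir.create("results", showWarnings = FALSE)

n_fields <- 20L
res <- lapply(seq_len(n_fields), function(s)
  coloc_analysis(simulate_coloc_pair(seed = s)))
coefs <- do.call(rbind, lapply(seq_along(res), function(i) {
  x <- res[[i]]
  data.frame(field = i, R = x$R, M1 = x$M1, M2 = x$M2,
             tR = x$tR, tM1 = x$tM1, tM2 = x$tM2,
             T_green = x$T_green, T_red = x$T_red, flagged = x$flagged)
}))
write.csv(coefs, "results/coloc_coefficients.csv", row.names = FALSE)

cat(sprintf("capillary-like fields (n = %d):\n", n_fields))
cat(sprintf("  R  = %.3f +- %.3f   (control tR  = %.3f +- %.3f)\n",
            mean(coefs$R), sd(coefs$R) / sqrt(n_fields),
            mean(coefs$tR), sd(coefs$tR) / sqrt(n_fields)))
cat(sprintf("  M1 = %.3f +- %.3f   (control tM1 = %.3f +- %.3f)\n",
            mean(coefs$M1), sd(coefs$M1) / sqrt(n_fields),
            mean(coefs$tM1), sd(coefs$tM1) / sqrt(n_fields)))
cat(sprintf("  M2 = %.3f +- %.3f\n", mean(coefs$M2),
            sd(coefs$M2) / sqrt(n_fields)))
wt <- wilcox.test(coefs$M1, coefs$M2, paired = TRUE, alternative = "greater")
cat(sprintf("  paired M1 > M2: p = %.2e — the asymmetric co-occurrence\n",
            wt$p.value))
cat("  signature: membrane signal sits inside cytoskeleton-positive area,\n")
cat("  the converse holds less, controls are near zero.\n")

# group comparison: correlated fields vs segregated-signal fields
seg <- vapply(seq_len(n_fields), function(s)
  coloc_analysis(simulate_coloc_pair(seed = 100L + s, segregated = TRUE))$M1,
  numeric(1))
gc <- compare_groups(list(capillary = coefs$M1, segregated = seg))
cat(sprintf("Kruskal-Wallis capillary vs segregated M1: H = %.1f, p = %.2e\n",
            gc$H, gc$p))
jsonlite::write_json(list(means = as.list(round(colMeans(coefs[, 2:7]), 4)),
                          m1_gt_m2_p = wt$p.value,
                          kw = gc[c("H", "df", "p")], dunn = gc$dunn),
                     "results/coloc_summary.json", auto_unbox = TRUE,
                     digits = NA)
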