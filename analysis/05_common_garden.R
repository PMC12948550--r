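#!/usr/bin/env Rscript
# Common-garden inference: provenance ANOVA with Tukey HSD on per-cutting
# NDAI, the northern/southern contrast on provenance means, the scaled and
# centered climate PCA, and the Pearson correlation matrix of pigment means
# with environmental variables.

suppressPackageStartupMessages(library(lightphen))

out <- "results"
pig <- read.csv(file.path(out, "provenance_ndai.csv"))
cl <- provenance_climate()

ot <- oneway_anova_tukey(pig$ndai, pig$provenance)
cat(sprintf("provenance effect on NDAI: F(%d, %d) = %.2f, p = %.2g\n",
            ot$model$df1, ot$model$df2, ot$model$statistic, ot$model$p_value))
lt <- attr(ot$pairwise, "letters")
cat("letters:", paste(names(lt), lt, sep = "=", collapse = " "), "\n")
write.csv(ot$pairwise, file.path(out, "provenance_tukey.csv"), row.names = FALSE)

means <- tapply(pig$ndai, pig$provenance, mean)
means <- means[cl$provenance]
reg <- region_means_test(means, cl$region)
cat(sprintf("northern vs southern provenance means: F(%d, %d) = %.2f, p = %.3f\n",
            reg$df1, reg$df2, reg$statistic, reg$p_value))

clim_vars <- c("solar_radiation", "elevation", "mat", "temp_seasonality",
               "annual_precip", "precip_seasonality")
pca <- pca_climate(cl[, clim_vars])
cat("climate PCA variance fractions:",
    paste(sprintf("%.1f%%", 100 * pca$variance_fraction), collapse = ", "), "\n")
write.csv(data.frame(provenance = cl$provenance, pca$scores),
          file.path(out, "climate_pca_scores.csv"), row.names = FALSE)

corr_in <- data.frame(cl[, clim_vars], pc1 = pca$scores[, 1],
                      pc2 = pca$scores[, 2], mean_ndai = as.vector(means))
cm <- correlation_matrix(corr_in)
write.csv(round(cm$r, 3), file.path(out, "correlation_r.csv"))
write.csv(signif(cm$p, 3), file.path(out, "correlation_p.csv"))
cat(sprintf("NDAI vs MAT: r = %.2f (p = %.3f); NDAI vs elevation: r = %.2f (p = %.3f)\n",
            cm$r["mean_ndai", "mat"], cm$p["mean_ndai", "mat"],
            cm$r["mean_ndai", "elevation"], cm$p["mean_ndai", "elevation"]))
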