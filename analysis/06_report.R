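#!/usr/bin/env Rscript
# Stage 6: assemble the coefficient table (per model, both likelihood parts)
# and the R2 / delta-R2 / proxy-correlation matrix from the stage artifacts.

source("analysis/00_config.R")

summaries <- read.csv(file.path(OUT, "model_summaries.csv"))
dr2 <- read.csv(file.path(OUT, "delta_r2.csv"))
proxies <- read.csv(file.path(OUT, "proxies.csv"))

fmt <- function(m, lo, hi) sprintf("%.3f [%.3f, %.3f]", m, lo, hi)

# coefficient table: rows = parameters, columns = models
keep <- summaries[grepl("^(beta|zi)_", summaries$parameter), ]
keep$cell <- fmt(keep$median, keep$ci_low, keep$ci_high)
tab1 <- reshape(keep[, c("model", "parameter", "cell")],
                idvar = "parameter", timevar = "model", direction = "wide")
names(tab1) <- sub("^cell\\.", "", names(tab1))
write.csv(tab1, file.path(OUT, "coefficient_table.csv"), row.names = FALSE)

# R2 matrix: proxy Pearson correlations above the diagonal, delta-R2 modes
# below, R2 per model on the diagonal (read from the summaries' companions)
prx <- c("lifespan", "lrs", "lrs_sa", "grandoffspring")
md <- proxies[proxies$eligible_model, ]
M <- matrix("", 4, 4, dimnames = list(prx, prx))
for (i in 1:4) for (j in 1:4) {
  if (i < j) M[i, j] <- sprintf("%.2f", cor(md[[prx[i]]], md[[prx[j]]],
                                            use = "complete.obs"))
  if (i > j) {
    row <- dr2[dr2$model_a == prx[i] & dr2$model_b == prx[j], ]
    if (nrow(row)) M[i, j] <- sprintf("%.1f%% [%.1f, %.1f]%s",
                                      100 * row$mode, 100 * row$ci_low,
                                      100 * row$ci_high,
                                      ifelse(row$significant, "*", ""))
  }
}
write.csv(as.data.frame(M), file.path(OUT, "r2_matrix.csv"))

cat("coefficient table:\n"); print(tab1, row.names = FALSE)
cat("\nR2 / delta-R2 / correlation matrix (delta-R2 below diagonal, r above):\n")
print(as.data.frame(M))
cat("\nAll tables written under", OUT, "\n")
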