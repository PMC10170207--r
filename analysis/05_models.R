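#!/usr/bin/env Rscript
# Stage 5: how well does each fitness proxy predict stabilized IGC?
# Hierarchical zero-inflated beta regressions (one per proxy, plus a null
# model), Bayesian R2 with pairwise differences, and the offspring-mean-IGC
# beta regression that tests whether LRS is a biased predictor.
#
# Pass --full for the long MCMC profile; the default profile keeps this
# stage at a few minutes.

source("analysis/00_config.R")

profile <- if ("--full" %in% commandArgs(trailingOnly = TRUE)) "full" else "fast"
mc <- mcmc_profile(profile)
cat("MCMC profile:", profile, "\n")

ped <- load_genealogy_stage()
statuses <- classify_migration(ped, SIM_CONFIG$parishes)
proxies <- read.csv(file.path(OUT, "proxies.csv"))

md <- proxies[proxies$eligible_model &
                complete.cases(proxies[, c("lifespan", "lrs", "lrs_sa",
                                           "grandoffspring", "igc")]), ]
cat("model rows:", nrow(md), "\n")

models <- c("lifespan", "lrs", "lrs_sa", "grandoffspring", "none")
fits <- list(); r2s <- list()
for (m in models) {
  fits[[m]] <- fit_zib(md, proxy = m, response = "igc", mcmc = mc,
                       seed = gencontrib:::split_seed(MASTER_SEED, m))
  r2s[[m]] <- bayes_r2(fits[[m]])
  cat(sprintf("  %-15s R2 = %.1f%% [%.1f, %.1f]\n", m, 100 * r2s[[m]]$median,
              100 * r2s[[m]]$ci_low, 100 * r2s[[m]]$ci_high))
}
summaries <- do.call(rbind, lapply(models, function(m)
  cbind(model = m, posterior_summary(fits[[m]]))))
write.csv(summaries, file.path(OUT, "model_summaries.csv"), row.names = FALSE)

prx <- setdiff(models, "none")
dr2 <- NULL
for (a in prx) for (b in prx) if (a != b) {
  d <- r2_difference(r2s[[a]], r2s[[b]])
  dr2 <- rbind(dr2, data.frame(model_a = a, model_b = b, mode = d$mode,
                               ci_low = d$ci_low, ci_high = d$ci_high,
                               significant = d$significant))
}
write.csv(dr2, file.path(OUT, "delta_r2.csv"), row.names = FALSE)

# bias test: mean offspring IGC ~ LRS + parental lifespan, beta regression
fin <- read.csv(file.path(OUT, "final_igc.csv"))
span <- c(min(ped$records$birth_year, na.rm = TRUE), FINAL_YEAR)
kid_igc <- numeric(0)
for (p in SIM_CONFIG$parishes) {
  pr <- build_presence(ped, statuses, p, span)
  kids <- unique(unlist(ped$child_index[md$id], use.names = FALSE))
  home <- setNames(statuses$home_parish, statuses$id)[kids]
  k <- kids[!is.na(home) & home == p]
  if (length(k)) kid_igc <- c(kid_igc, igc_at_year(ped, pr, FINAL_YEAR, k))
}
mo <- offspring_mean_igc(ped, kid_igc, md$id)
bd <- md[md$lrs > 0 & md$id %in% names(mo), ]
bd$mean_offspring_igc <- mo[bd$id] + 1e-10
bd$parent_lifespan <- bd$lifespan
bfit <- fit_zib(bd, proxy = "lrs", response = "mean_offspring_igc",
                zero_inflated = FALSE, covariates = "parent_lifespan",
                mcmc = mc, seed = gencontrib:::split_seed(MASTER_SEED, "bias"))
bsum <- posterior_summary(bfit)
write.csv(bsum, file.path(OUT, "bias_model_summary.csv"), row.names = FALSE)

sl <- bsum[bsum$parameter == "beta_proxy", ]
best <- prx[which.max(vapply(prx, function(m) r2s[[m]]$median, numeric(1)))]
n_pos <- sum(md$igc > 0)
cat(sprintf(
  "\nFinding: %s explains the most variation in stabilized IGC (%.0f%%) in this run;\nwith only %d surviving lineages among %d focals, the beta-part intervals are wide.\nThe slope of offspring-mean IGC on LRS is %.3f [%.3f, %.3f] (pd = %.3f): values near zero\nmean LRS ranks long-term contributions without systematic bias.\n",
  best, 100 * r2s[[best]]$median, n_pos, nrow(md),
  sl$median, sl$ci_low, sl$ci_high, sl$pd))
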