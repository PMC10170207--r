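#' End-to-end analysis pipeline
#'
#' Runs the full analysis over a genealogy: migration classification and
#' per-parish gene pools, per-year expected genetic contributions, cohort
#' stabilization, fitness proxies with lineage-fate accounting, and the
#' hierarchical (zero-inflated) beta regressions of stabilized IGC on each
#' proxy plus the offspring-mean-IGC bias model. Each stage writes plain CSV
#' or JSON artifacts plus a manifest into `out_dir`; rerunning with an
#' unchanged configuration skips completed stages.
#'
#' @param ped a [pedigree_table()] (or path to a genealogy readable by
#'   [load_genealogy()]).
#' @param parishes the two study parish labels.
#' @param out_dir output directory for stage artifacts.
#' @param final_year reference year for stabilized contributions.
#' @param year_range span of the presence tables; defaults to the data span.
#' @param cohort_width birth-cohort width in years.
#' @param threshold stabilization correlation threshold.
#' @param window_generations stabilization window in generations.
#' @param percentile_type quantile algorithm for the adulthood threshold.
#' @param models proxies to model (subset of `lifespan`, `lrs`, `lrs_sa`,
#'   `grandoffspring`, `none`).
#' @param bias_model also fit the beta regression of offspring-mean IGC on
#'   LRS and parental lifespan.
#' @param interaction_policy `"prune"` (fit sex-by-parish interaction, drop
#'   if non-significant), `"never"`, or `"always"`.
#' @param focal_selection `"cutoff"` keeps individuals born before the parish
#'   cutoff year (the latest decade closing an unbroken run of stabilized
#'   cohorts); `"stabilized_cohorts"` keeps members of every cohort that
#'   individually meets the stabilization criterion. The two coincide when
#'   stabilization is monotone in birth year; with small noisy cohorts the
#'   unbroken-run rule can discard almost everything, so the per-cohort rule
#'   is the robust choice for modest populations.
#' @param mcmc sampler settings (see [mcmc_profile()]).
#' @param zero_offset constant added to the bias-model response so that it is
#'   strictly positive (default 1e-10).
#' @param seed master seed; stage seeds are derived from it.
#' @param run_models set `FALSE` to stop after the proxy stage (no MCMC).
#' @param quiet suppress progress messages.
#' @return invisible list with every stage's in-memory results.
#' @export
run_pipeline <- function(ped, parishes, out_dir,
                         final_year = 1990L, year_range = NULL,
                         cohort_width = 10L, threshold = 0.95,
                         window_generations = 2, percentile_type = 7,
                         models = c("lifespan", "lrs", "lrs_sa",
                                    "grandoffspring", "none"),
                         bias_model = TRUE,
                         interaction_policy = c("prune", "never", "always"),
                         focal_selection = c("cutoff", "stabilized_cohorts"),
                         mcmc = mcmc_profile("fast"), zero_offset = 1e-10,
                         seed = 1L, run_models = TRUE, quiet = FALSE) {
  interaction_policy <- match.arg(interaction_policy)
  focal_selection <- match.arg(focal_selection)
  if (is.character(ped)) ped <- load_genealogy(ped)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  cfg <- list(parishes = parishes, final_year = final_year,
              cohort_width = cohort_width, threshold = threshold,
              window_generations = window_generations,
              percentile_type = percentile_type, models = models,
              bias_model = bias_model, interaction_policy = interaction_policy,
              focal_selection = focal_selection,
              mcmc = mcmc, zero_offset = zero_offset, seed = seed,
              n_records = nrow(ped$records))
  cfg_hash <- digest_config(cfg)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list(config_hash = cfg_hash, stages = character(0))
  if (!identical(manifest$config_hash, cfg_hash)) {
    manifest <- list(config_hash = cfg_hash, stages = character(0))
  }
  done <- function(stage, outputs) {
    identical(manifest$config_hash, cfg_hash) && stage %in% manifest$stages &&
      all(file.exists(file.path(out_dir, outputs)))
  }
  mark <- function(stage) {
    manifest$stages <<- union(manifest$stages, stage)
    manifest$config <<- cfg[setdiff(names(cfg), "mcmc")]
    manifest$versions <<- list(
      package = as.character(utils::packageVersion("gencontrib")),
      r = R.version.string)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  }
  res <- list(config = cfg)

  ## stage 1: normalized genealogy and summary -------------------------------
  say("stage genealogy: ", nrow(ped$records), " records")
  if (!done("genealogy", "genealogy.csv")) {
    write_genealogy(ped, file.path(out_dir, "genealogy.csv"))
    jsonlite::write_json(unclass(pedigree_summary(ped)),
                         file.path(out_dir, "pedigree_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    mark("genealogy")
  }
  res$summary <- pedigree_summary(ped)

  ## stage 2: migration and presence -----------------------------------------
  if (is.null(year_range)) {
    by <- ped$records$birth_year
    year_range <- c(min(by, na.rm = TRUE), final_year)
  }
  statuses <- classify_migration(ped, parishes)
  rates <- migration_rates(statuses)
  presence <- lapply(parishes, function(p)
    build_presence(ped, statuses, p, year_range))
  names(presence) <- parishes
  say("stage presence: pools of ",
      paste(vapply(presence, function(p) p$pop_size[[length(p$pop_size)]], integer(1)),
            collapse = " and "), " in ", year_range[2L])
  if (!done("presence", "migration_status.csv")) {
    utils::write.csv(statuses, file.path(out_dir, "migration_status.csv"), row.names = FALSE)
    utils::write.csv(rates, file.path(out_dir, "migration_rates.csv"), row.names = FALSE)
    pop <- do.call(rbind, lapply(parishes, function(p)
      data.frame(parish = p, year = presence[[p]]$years,
                 n = unname(presence[[p]]$pop_size))))
    utils::write.csv(pop, file.path(out_dir, "population_size.csv"), row.names = FALSE)
    win <- do.call(rbind, lapply(parishes, function(p)
      cbind(parish = p, presence[[p]]$windows)))
    utils::write.csv(win, file.path(out_dir, "presence_windows.csv"), row.names = FALSE)
    mark("presence")
  }
  res$statuses <- statuses; res$rates <- rates; res$presence <- presence

  ## stage 3: IGC series per parish ------------------------------------------
  series <- list()
  for (p in parishes) {
    series[[p]] <- igc_for_parish(ped, presence[[p]], statuses,
                                  end_year = final_year)
  }
  say("stage igc: ", sum(lengths(series)), " focal series")
  if (!done("igc", "igc_wide.csv")) {
    yr_cols <- year_range[1L]:final_year
    rows <- lapply(parishes, function(p) {
      t(vapply(series[[p]], function(s) {
        v <- rep(NA_real_, length(yr_cols))
        v[match(s$years, yr_cols)] <- s$igc
        v
      }, numeric(length(yr_cols))))
    })
    wide <- as.data.frame(do.call(rbind, rows))
    names(wide) <- yr_cols
    wide <- cbind(id = unlist(lapply(series, names), use.names = FALSE),
                  parish = rep(parishes, vapply(series, length, integer(1))),
                  wide)
    utils::write.csv(wide, file.path(out_dir, "igc_wide.csv"), row.names = FALSE)
    mark("igc")
  }
  res$series <- series

  ## stage 4: stabilization ---------------------------------------------------
  by <- stats::setNames(ped$records$birth_year, ped$records$id)
  stab <- list()
  for (p in parishes) {
    gt <- generation_time(ped, ids = presence[[p]]$windows$id)
    stab[[p]] <- cohort_stabilization(series[[p]], by, gt$mean, final_year,
                                      cohort_width, threshold, window_generations)
    stab[[p]]$generation_time <- gt
  }
  say("stage stabilization: cutoffs ",
      paste(vapply(stab, function(s) s$cutoff_birth_year %||% NA_integer_, integer(1)),
            collapse = " and "))
  if (!done("stabilization", "cohort_correlations.csv")) {
    corr <- do.call(rbind, lapply(parishes, function(p)
      cbind(parish = p, stab[[p]]$correlations)))
    utils::write.csv(corr, file.path(out_dir, "cohort_correlations.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(stab, function(s) list(cutoff_birth_year = s$cutoff_birth_year,
                                    window_years = s$window_years,
                                    threshold = s$threshold,
                                    generation_time = s$generation_time)),
      file.path(out_dir, "stabilization.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    mark("stabilization")
  }
  res$stabilization <- stab

  ## stage 5: proxies, lineage fates, offspring mean IGC ----------------------
  thresholds <- adulthood_threshold(ped, type = percentile_type)
  focal_igc <- numeric(0)
  for (p in parishes) {
    ids <- names(series[[p]])
    ids <- ids[!is.na(by[ids])]
    if (focal_selection == "cutoff") {
      cut <- stab[[p]]$cutoff_birth_year
      if (is.na(cut)) next
      ids <- ids[by[ids] < cut]
    } else {
      coh <- stab[[p]]$cohorts
      good <- coh$cohort[!is.na(coh$stabilized) & coh$stabilized]
      ids <- ids[((by[ids] %/% cohort_width) * cohort_width) %in% good]
    }
    focal_igc <- c(focal_igc, vapply(series[[p]][ids], function(s)
      s$final_value, numeric(1)))
  }
  say("stage proxies: ", length(focal_igc), " stabilized focals; adulthood ",
      round(thresholds$female, 1), "f/", round(thresholds$male, 1), "m")
  if (!length(focal_igc)) stop("no stabilized focal individuals; nothing to model")
  proxies <- compute_proxies(ped, thresholds, focal_igc, statuses, cohort_width)
  fates <- lineage_fates(ped, statuses, proxies, thresholds, final_year)

  # offspring final-year IGC for the bias response
  kids <- unique(unlist(ped$child_index[proxies$id], use.names = FALSE))
  kid_parish <- stats::setNames(statuses$home_parish, statuses$id)[kids]
  kid_igc <- numeric(0)
  for (p in parishes) {
    k <- kids[!is.na(kid_parish) & kid_parish == p]
    if (length(k)) kid_igc <- c(kid_igc, igc_at_year(ped, presence[[p]], final_year, k))
  }
  mean_off <- offspring_mean_igc(ped, kid_igc, proxies$id)
  if (!done("proxies", "proxies.csv")) {
    utils::write.csv(proxies, file.path(out_dir, "proxies.csv"), row.names = FALSE)
    utils::write.csv(fates$fates, file.path(out_dir, "lineage_fates.csv"), row.names = FALSE)
    jsonlite::write_json(list(prop_extinct = fates$prop_extinct,
                              stages = fates$stages,
                              adulthood_threshold = thresholds[c("female", "male", "pooled")]),
                         file.path(out_dir, "extinction_stages.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    mark("proxies")
  }
  res$thresholds <- thresholds; res$proxies <- proxies; res$fates <- fates
  res$offspring_mean_igc <- mean_off

  if (!run_models) return(invisible(res))

  ## stage 6: models -----------------------------------------------------------
  md <- proxies[proxies$eligible_model, ]
  md <- md[stats::complete.cases(md[, c("lifespan", "lrs", "lrs_sa",
                                        "grandoffspring", "igc")]), ]
  stopifnot(all(md$igc < 1))
  say("stage models: n = ", nrow(md), " (", paste(models, collapse = ", "), ")")
  fits <- list(); r2s <- list()
  for (m in models) {
    s <- split_seed(seed, paste0("model_", m))
    fits[[m]] <- switch(interaction_policy,
      never = fit_zib(md, proxy = m, response = "igc", mcmc = mcmc, seed = s),
      always = fit_zib(md, proxy = m, response = "igc", interaction = TRUE,
                       mcmc = mcmc, seed = s),
      prune = interaction_pruning(md, proxy = m, response = "igc",
                                  mcmc = mcmc, seed = s)$fit)
    r2s[[m]] <- bayes_r2(fits[[m]])
    say("  model ", m, ": R2 = ", round(r2s[[m]]$median, 3))
  }
  summaries <- do.call(rbind, lapply(names(fits), function(m)
    cbind(model = m, posterior_summary(fits[[m]]))))
  dr2 <- list()
  prx <- setdiff(models, "none")
  for (a in prx) for (b in prx) if (a != b) {
    dr2[[paste(a, b, sep = "_vs_")]] <- r2_difference(r2s[[a]], r2s[[b]])[
      c("mode", "ci_low", "ci_high", "significant")]
  }
  if (!done("models", "model_summaries.csv")) {
    utils::write.csv(summaries, file.path(out_dir, "model_summaries.csv"), row.names = FALSE)
    for (m in names(fits)) {
      utils::write.csv(as.data.frame(draw_matrix(fits[[m]])),
                       file.path(out_dir, paste0("draws_", m, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(r2 = lapply(r2s, function(r) r[c("median", "mode", "ci_low", "ci_high")]),
           delta_r2 = dr2, n = nrow(md)),
      file.path(out_dir, "r2.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
    mark("models")
  }
  res$fits <- fits; res$r2 <- r2s; res$delta_r2 <- dr2; res$model_data <- md

  ## stage 7: bias model --------------------------------------------------------
  if (bias_model) {
    bd <- md[md$lrs > 0 & md$id %in% names(mean_off), ]
    bd$mean_offspring_igc <- mean_off[bd$id] + zero_offset
    stopifnot(all(bd$mean_offspring_igc > 0), all(bd$mean_offspring_igc < 1))
    bd$parent_lifespan <- bd$lifespan
    say("stage bias model: n = ", nrow(bd), " reproducers")
    s <- split_seed(seed, "bias_model")
    bfit <- switch(interaction_policy,
      never = fit_zib(bd, proxy = "lrs", response = "mean_offspring_igc",
                      zero_inflated = FALSE, covariates = "parent_lifespan",
                      mcmc = mcmc, seed = s),
      always = fit_zib(bd, proxy = "lrs", response = "mean_offspring_igc",
                       zero_inflated = FALSE, interaction = TRUE,
                       covariates = "parent_lifespan", mcmc = mcmc, seed = s),
      prune = interaction_pruning(bd, proxy = "lrs",
                                  response = "mean_offspring_igc",
                                  zero_inflated = FALSE,
                                  covariates = "parent_lifespan",
                                  mcmc = mcmc, seed = s)$fit)
    bsum <- posterior_summary(bfit)
    if (!done("bias", "bias_model_summary.csv")) {
      utils::write.csv(bsum, file.path(out_dir, "bias_model_summary.csv"), row.names = FALSE)
      mark("bias")
    }
    res$bias_fit <- bfit; res$bias_summary <- bsum; res$bias_data <- bd
  }
  say("pipeline complete: ", out_dir)
  invisible(res)
}

digest_config <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  # small rolling hash; avoids a digest dependency
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 251)) %% .Machine$integer.max)
}
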