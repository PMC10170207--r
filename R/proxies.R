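#' Sex-specific adulthood thresholds
#'
#' Adulthood is defined as the sex-specific fifth percentile of
#' age-at-first-reproduction over the whole dataset: the age at which the
#' earliest five percent of reproducers had their first child. A pooled
#' threshold (both sexes together) is also returned for offspring of unknown
#' sex.
#'
#' @param ped a [pedigree_table()].
#' @param probs percentile (default 0.05).
#' @param type quantile algorithm passed to [stats::quantile()] (default 7,
#'   linear interpolation between order statistics).
#' @param min_reproducers minimum reproducers per sex required (default 20).
#' @return list with `female`, `male`, `pooled` (years) and `n` per group.
#' @export
adulthood_threshold <- function(ped, probs = 0.05, type = 7, min_reproducers = 20L) {
  afr <- age_first_reproduction(ped)
  sex <- stats::setNames(ped$records$sex, ped$records$id)[names(afr)]
  out <- list()
  for (s in c("female", "male")) {
    v <- afr[sex == s]
    if (length(v) < min_reproducers) {
      stop("fewer than ", min_reproducers, " reproducing ", s, "s with known birth years")
    }
    out[[s]] <- unname(stats::quantile(v, probs, type = type))
  }
  out$pooled <- unname(stats::quantile(afr, probs, type = type))
  out$n <- c(female = sum(sex == "female"), male = sum(sex == "male"))
  out
}

# age at first reproduction for every parent with known birth year
age_first_reproduction <- function(ped) {
  df <- ped$records
  by <- stats::setNames(df$birth_year, df$id)
  parents <- names(ped$child_index)
  afr <- vapply(parents, function(p) {
    kb <- by[ped$child_index[[p]]]
    if (all(is.na(kb)) || is.na(by[[p]])) return(NA_real_)
    min(kb, na.rm = TRUE) - by[[p]]
  }, numeric(1))
  afr[!is.na(afr)]
}

#' Fitness proxies and eligibility flags for focal individuals
#'
#' Computes, for each focal individual: lifespan (death year minus birth
#' year), LRS (number of offspring ever born), LRS_SA (offspring surviving to
#' the sex-specific adulthood threshold) and the number of grandoffspring
#' (total offspring of the focal's offspring, missing unless every offspring
#' has a complete life history). An offspring counts as surviving to
#' adulthood if its known lifespan reaches its sex's threshold, or if it
#' reproduced (first reproduction implies adulthood) when its death year is
#' missing. Eligibility flags mirror the analysis filters: `eligible_core`
#' (has an IGC estimate and known birth and death years, child deaths
#' included), `eligible_grand` (additionally every offspring has known birth
#' and death years) and `eligible_model` (informative for every model
#' predictor: core, grandoffspring available, known sex and parish).
#'
#' @param ped a [pedigree_table()].
#' @param thresholds output of [adulthood_threshold()].
#' @param igc_final named numeric of final-year IGC values; names define the
#'   focal set.
#' @param statuses output of [classify_migration()] (for parish assignment).
#' @param cohort_width width of birth cohorts in years (default 10).
#' @return data frame (`proxy_table`) with one row per focal.
#' @export
compute_proxies <- function(ped, thresholds, igc_final, statuses,
                            cohort_width = 10L) {
  df <- ped$records
  focals <- names(igc_final)
  ri <- match(focals, df$id)
  if (anyNA(ri)) stop("unknown focal id(s): ", paste(utils::head(focals[is.na(ri)], 5), collapse = ", "))
  by <- stats::setNames(df$birth_year, df$id)
  dy <- stats::setNames(df$death_year, df$id)
  sex <- stats::setNames(df$sex, df$id)
  nkids <- vapply(ped$child_index, length, integer(1))
  lrs_all <- stats::setNames(integer(nrow(df)), df$id)
  lrs_all[names(nkids)] <- nkids

  thr_for <- function(s) {
    ifelse(s == "female", thresholds$female,
           ifelse(s == "male", thresholds$male, thresholds$pooled))
  }
  survived_adult <- function(kid) {
    ls <- dy[[kid]] - by[[kid]]
    thr <- thr_for(sex[[kid]])
    if (!is.na(ls)) return(ls >= thr)
    lrs_all[[kid]] > 0  # reproduced, so reached adulthood; death unrecorded
  }

  n <- length(focals)
  lifespan <- rep(NA_real_, n); lrs <- integer(n); lrs_sa <- integer(n)
  grand <- rep(NA_real_, n); grand_ok <- logical(n)
  for (k in seq_len(n)) {
    f <- focals[k]
    lifespan[k] <- dy[[f]] - by[[f]]
    kids <- ped$child_index[[f]] %||% character(0)
    lrs[k] <- length(kids)
    if (length(kids)) {
      lrs_sa[k] <- sum(vapply(kids, survived_adult, logical(1)))
      complete <- all(!is.na(by[kids]) & !is.na(dy[kids]))
      grand_ok[k] <- complete
      if (complete) grand[k] <- sum(lrs_all[kids])
    } else {
      grand[k] <- 0
      grand_ok[k] <- TRUE
    }
  }

  st <- statuses[match(focals, statuses$id), ]
  parish <- st$home_parish
  cohort_start <- (by[focals] %/% cohort_width) * cohort_width
  cohort <- ifelse(is.na(parish) | is.na(cohort_start), NA_character_,
                   paste(parish, cohort_start, sep = ":"))

  eligible_core <- !is.na(by[focals]) & !is.na(dy[focals])
  eligible_grand <- eligible_core & grand_ok
  eligible_model <- eligible_grand & sex[focals] %in% c("female", "male") & !is.na(parish)

  out <- data.frame(
    id = focals, parish = parish, sex = unname(sex[focals]),
    birth_year = unname(by[focals]), cohort = cohort,
    lifespan = lifespan, lrs = lrs, lrs_sa = lrs_sa,
    grandoffspring = grand, igc = unname(igc_final),
    eligible_core = unname(eligible_core),
    eligible_grand = unname(eligible_grand),
    eligible_model = unname(eligible_model),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("proxy_table", "data.frame")
  out
}

#' Final-year IGC for a set of individuals
#'
#' The expected proportional contribution of each individual to the gene pool
#' of one year: the sum of its contribution coefficients over the individuals
#' present, divided by the population size.
#'
#' @param ped a [pedigree_table()].
#' @param presence a [build_presence()] table.
#' @param year the reference year.
#' @param ids individuals to evaluate.
#' @return named numeric vector (NA if the pool is empty).
#' @export
igc_at_year <- function(ped, presence, year, ids) {
  pool <- presence$by_year[[as.character(year)]]
  npool <- length(pool)
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  if (npool == 0L) return(out)
  for (f in ids) {
    coeff <- contribution_vector(ped, f)
    hit <- pool[pool %in% names(coeff)]
    out[[f]] <- sum(coeff[hit]) / npool
  }
  out
}

#' Descendant fates and lineage extinction accounting
#'
#' For each focal individual, classifies every descendant as having
#' reproduced in the study population (continuing the lineage), being alive
#' at the final year without having reproduced, or having failed to continue
#' the lineage (died or emigrated without reproducing locally); emigrants'
#' recorded offspring are born outside, so a descendant classified as an
#' emigrant counts as reproducing outside the population. Also tallies the
#' life stage at which extinct lineages failed.
#'
#' @param ped a [pedigree_table()].
#' @param statuses output of [classify_migration()].
#' @param proxies output of [compute_proxies()] (supplies the focal set,
#'   their proxies and final IGC).
#' @param thresholds output of [adulthood_threshold()] (pooled threshold used
#'   for the died-before-reproductive-age stage).
#' @param final_year reference year.
#' @return list with `fates` (data frame per focal: percentages of
#'   descendants that reproduced, are alive unreproduced, failed, and the
#'   emigration share of failures; `extinct` flag) and `stages` (extinction
#'   stage tallies, both conditional on reaching the stage and as shares of
#'   extinct / of all focals).
#' @export
lineage_fates <- function(ped, statuses, proxies, thresholds, final_year) {
  df <- ped$records
  dy <- stats::setNames(df$death_year, df$id)
  status <- stats::setNames(statuses$status, statuses$id)
  nkids <- vapply(ped$child_index, length, integer(1))
  lrs_all <- stats::setNames(integer(nrow(df)), df$id)
  lrs_all[names(nkids)] <- nkids

  focals <- proxies$id
  n <- length(focals)
  pr <- pa <- pf <- pe <- rep(NA_real_, n)
  ndesc <- integer(n)
  for (k in seq_len(n)) {
    desc <- descendants(ped, focals[k])
    ndesc[k] <- length(desc)
    if (!length(desc)) next
    emi <- status[desc] == "emigrant"
    reproduced <- lrs_all[desc] > 0 & !emi
    alive <- !reproduced & !emi & (is.na(dy[desc]) | dy[desc] > final_year)
    failed <- !reproduced & !alive
    pr[k] <- 100 * mean(reproduced)
    pa[k] <- 100 * mean(alive)
    pf[k] <- 100 * mean(failed)
    pe[k] <- if (any(failed)) 100 * sum(failed & emi) / sum(failed) else NA_real_
  }
  extinct <- proxies$igc == 0
  fates <- data.frame(
    id = focals, n_descendants = ndesc,
    pct_descendants_reproduced = pr,
    pct_descendants_alive_unreproduced = pa,
    pct_failed = pf, pct_failed_by_emigration = pe,
    extinct = extinct, stringsAsFactors = FALSE)

  # extinction stages, successive-conditional and unconditional
  ex <- proxies[extinct & proxies$eligible_core, ]
  died_young <- !is.na(ex$lifespan) & ex$lifespan < thresholds$pooled
  no_off <- !died_young & ex$lrs == 0
  no_sa <- !died_young & ex$lrs > 0 & ex$lrs_sa == 0
  no_grand <- !died_young & ex$lrs_sa > 0 & !is.na(ex$grandoffspring) & ex$grandoffspring == 0
  later <- !died_young & ex$lrs_sa > 0 & !is.na(ex$grandoffspring) & ex$grandoffspring > 0
  n_ex <- nrow(ex)
  at_risk <- c(n_ex, n_ex - sum(died_young),
               n_ex - sum(died_young) - sum(no_off),
               sum(no_grand) + sum(later))
  counts <- c(sum(died_young), sum(no_off), sum(no_sa), sum(no_grand))
  stages <- data.frame(
    stage = c("died_before_reproductive_age", "no_offspring",
              "no_adult_surviving_offspring", "no_grandoffspring"),
    n = counts,
    prop_conditional = ifelse(at_risk > 0, counts / at_risk, NA_real_),
    prop_of_extinct = if (n_ex > 0) counts / n_ex else NA_real_,
    prop_of_all = counts / max(nrow(proxies), 1L),
    stringsAsFactors = FALSE)

  list(fates = fates, stages = stages,
       prop_extinct = mean(extinct, na.rm = TRUE))
}

#' Mean final-year IGC of each focal's offspring
#'
#' For reproducing focal individuals, the arithmetic mean of their
#' offspring's own final-year IGC. Used as the response of the bias test: a
#' slope of offspring-mean IGC on the parent's LRS different from zero means
#' LRS systematically over- or under-estimates long-term contributions.
#'
#' @param ped a [pedigree_table()].
#' @param igc_offspring named numeric of final-year IGC covering the
#'   offspring of the focal set (see [igc_at_year()]).
#' @param focals focal ids; non-reproducers are dropped.
#' @return named numeric vector of offspring-mean IGC per reproducing focal.
#' @export
offspring_mean_igc <- function(ped, igc_offspring, focals) {
  out <- numeric(0)
  for (f in focals) {
    kids <- ped$child_index[[f]]
    if (is.null(kids) || !length(kids)) next
    v <- igc_offspring[kids[kids %in% names(igc_offspring)]]
    v <- v[!is.na(v)]
    if (!length(v)) next
    out[f] <- mean(v)
  }
  out
}
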