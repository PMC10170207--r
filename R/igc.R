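#' Expected genetic contribution of a focal individual to each descendant
#'
#' Propagates Mendelian expectations down the focal's descendant subgraph:
#' the focal contributes 1 to itself and each descendant receives half of
#' each parent's coefficient, with non-descendant parents contributing 0.
#' The focal is treated as a founder (its own parents are severed), so only
#' direct-descent contributions are counted — kin contributions through
#' siblings or parents are excluded by construction. The result equals the
#' focal's row of the additive (numerator) relationship matrix computed with
#' the focal's parent links removed.
#'
#' @param ped a [pedigree_table()].
#' @param focal individual id.
#' @return named numeric vector over `c(focal, descendants(ped, focal))`,
#'   values in `[0, 1]`, with `coeff[focal] == 1`.
#' @export
contribution_vector <- function(ped, focal) {
  df <- ped$records
  if (!focal %in% df$id) stop("unknown focal id: ", focal)
  desc <- descendants(ped, focal)
  ids <- c(focal, desc)
  coeff <- c(1, numeric(length(desc)))
  names(coeff) <- ids
  if (!length(desc)) return(coeff)
  # records are topologically ordered; walk descendants in that order
  sub <- df[df$id %in% desc, c("id", "sire", "dam")]
  pos <- match(sub$id, ids)
  si <- match(sub$sire, ids)  # NA for parents outside focal + descendants
  di <- match(sub$dam, ids)
  for (i in seq_len(nrow(sub))) {
    v <- 0
    if (!is.na(si[i])) v <- v + 0.5 * coeff[si[i]]
    if (!is.na(di[i])) v <- v + 0.5 * coeff[di[i]]
    coeff[pos[i]] <- v
  }
  coeff
}

#' Additive relationship matrix by the tabular method
#'
#' Dense numerator relationship matrix A over all individuals, built with the
#' classical recursion in topological order: diagonal `1 + F` (inbreeding from
#' the parents' relatedness) and off-diagonal `a(i,j) = (a(j, sire_i) +
#' a(j, dam_i)) / 2` for `j` preceding `i`. Optionally severs the parent links
#' of one individual first, which makes that individual's row the expected
#' direct-descent genetic contribution to every other individual. Quadratic in
#' pedigree size; intended for validation and small pedigrees — use
#' [contribution_vector()] for per-focal work at scale.
#'
#' @param ped a [pedigree_table()].
#' @param sever optional id whose parent links are removed before building.
#' @return numeric matrix with dimnames equal to the individual ids.
#' @export
relationship_matrix <- function(ped, sever = NULL) {
  df <- ped$records
  n <- nrow(df)
  idx <- seq_len(n); names(idx) <- df$id
  si <- unname(idx[df$sire]); di <- unname(idx[df$dam])
  if (!is.null(sever)) {
    k <- idx[[sever]]
    si[k] <- NA_integer_; di[k] <- NA_integer_
  }
  A <- matrix(0, n, n, dimnames = list(df$id, df$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[j, s]
      if (!is.na(d)) row <- row + 0.5 * A[j, d]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Per-year individual genetic contribution series
#'
#' Converts a focal's expected contributions into proportional contributions
#' to a parish gene pool: for each year, the sum of the focal's coefficients
#' over the individuals present (the focal's own coefficient of 1 counts while
#' it is present) divided by the population size that year. Years with an
#' empty gene pool yield `NA`.
#'
#' @param coeff named coefficient vector from [contribution_vector()].
#' @param presence a [build_presence()] table for one parish.
#' @param start_year first year of the series; typically the focal's birth
#'   year, or arrival year for an immigrant.
#' @param end_year last year (the reference "final" year of the analysis).
#' @return object of class `igc_series`: list with `focal`, `parish`, `years`,
#'   `igc` (numeric, same length as `years`) and `final_value`.
#' @export
igc_series <- function(coeff, presence, start_year, end_year) {
  years <- start_year:end_year
  focal <- names(coeff)[1L]
  py0 <- presence$years[1L]
  npy <- length(presence$years)

  # presence windows are single closed intervals, so the summed coefficient
  # present in each year is a difference array followed by a cumulative sum
  w <- presence$windows
  hit <- match(w$id, names(coeff))
  rows <- which(!is.na(hit))
  delta <- numeric(npy + 1L)
  for (r in rows) {
    v <- coeff[hit[r]]
    s <- w$start[r] - py0 + 1L
    e <- w$end[r] - py0 + 1L
    delta[s] <- delta[s] + v
    delta[e + 1L] <- delta[e + 1L] - v
  }
  tot <- cumsum(delta[seq_len(npy)])
  at <- match(years, presence$years)
  vals <- rep(NA_real_, length(years))
  ok <- !is.na(at)
  pool_n <- presence$pop_size[at[ok]]
  vals[ok] <- ifelse(pool_n > 0L, tot[at[ok]] / pool_n, NA_real_)
  structure(list(focal = focal, parish = presence$parish, years = years,
                 igc = vals, final_value = vals[length(vals)]),
            class = "igc_series")
}

#' IGC series for a set of focal individuals
#'
#' Convenience wrapper: computes [contribution_vector()] and [igc_series()]
#' for each focal. Residents and emigrants start at birth year, immigrants at
#' arrival year.
#'
#' @param ped a [pedigree_table()].
#' @param presence a [build_presence()] table.
#' @param statuses migration status table from [classify_migration()].
#' @param focals ids; default all individuals with a presence window in this
#'   parish and a known start year.
#' @param end_year final year of the series.
#' @return named list of `igc_series`.
#' @export
igc_for_parish <- function(ped, presence, statuses, focals = NULL, end_year) {
  win <- presence$windows
  if (is.null(focals)) focals <- win$id[win$start <= end_year]
  win_start <- stats::setNames(win$start, win$id)
  out <- vector("list", length(focals))
  names(out) <- focals
  for (f in focals) {
    s <- win_start[[f]]
    if (is.null(s) || is.na(s) || s > end_year) next
    out[[f]] <- igc_series(contribution_vector(ped, f), presence, s, end_year)
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Mean parental age at offspring birth
#'
#' Generation time as the mean, over all parent-offspring pairs with known
#' birth years, of the parent's age when the offspring was born; both sexes
#' pooled. Optionally restricted to parents belonging to one parish.
#'
#' @param ped a [pedigree_table()].
#' @param ids optional parent ids to restrict to (e.g. one parish's
#'   individuals).
#' @return list with `mean`, `se` and `n` (number of pairs).
#' @export
generation_time <- function(ped, ids = NULL) {
  df <- ped$records
  by <- stats::setNames(df$birth_year, df$id)
  pars <- c(df$sire, df$dam)
  kids <- c(df$id, df$id)
  keep <- !is.na(pars)
  pars <- pars[keep]; kids <- kids[keep]
  if (!is.null(ids)) {
    keep <- pars %in% ids
    pars <- pars[keep]; kids <- kids[keep]
  }
  ages <- by[kids] - by[pars]
  ages <- ages[!is.na(ages)]
  if (!length(ages)) stop("no parent-offspring pairs with known birth years")
  list(mean = mean(ages),
       se = if (length(ages) > 1L) stats::sd(ages) / sqrt(length(ages)) else NA_real_,
       n = length(ages))
}

#' Detect stabilization of cohort genetic contributions
#'
#' Groups focal individuals into parish-specific birth cohorts (default
#' 10-year bins keyed by decade start) and, for each cohort and year,
#' computes the Pearson correlation across cohort members between that year's
#' IGC and the final-year IGC. A cohort is stabilized when the correlation
#' stays at or above `threshold` throughout the window of
#' `ceiling(window_generations * generation_time)` years ending at
#' `final_year`. Cohorts with fewer than two members are excluded; years with
#' zero variance in either vector (correlation undefined) count as failing
#' the threshold.
#'
#' @param series list of `igc_series` for one parish (see [igc_for_parish()]).
#' @param birth_years named vector of focal birth years (names = ids).
#' @param gen_time generation time in years (see [generation_time()]).
#' @param final_year reference year.
#' @param cohort_width cohort bin width in years (default 10).
#' @param threshold correlation threshold (default 0.95).
#' @param window_generations window length in generations (default 2).
#' @return list with `cohorts` (data frame: cohort, n, stabilized),
#'   `correlations` (long data frame: cohort, year, r, n), and
#'   `cutoff_birth_year` (first year of the earliest decade that breaks the
#'   run of stabilized cohorts; individuals born before the end of the last
#'   stabilized decade in that run are "stabilized focals"), plus the window
#'   used.
#' @export
cohort_stabilization <- function(series, birth_years, gen_time, final_year,
                                 cohort_width = 10L, threshold = 0.95,
                                 window_generations = 2) {
  ids <- names(series)
  by <- birth_years[ids]
  ok <- !is.na(by)
  ids <- ids[ok]; by <- by[ok]
  if (!length(ids)) stop("no focal individuals with known birth years")
  dec <- (by %/% cohort_width) * cohort_width
  window_years <- as.integer(ceiling(window_generations * gen_time))
  win_lo <- final_year - window_years

  # year x individual IGC matrix (rows = all years up to final)
  all_years <- min(vapply(series[ids], function(s) s$years[1L], numeric(1))):final_year
  M <- matrix(NA_real_, length(all_years), length(ids),
              dimnames = list(all_years, ids))
  for (j in seq_along(ids)) {
    s <- series[[ids[j]]]
    M[as.character(s$years), j] <- s$igc
  }

  cor_rows <- list()
  cohorts <- sort(unique(dec))
  stab <- logical(length(cohorts))
  names(stab) <- cohorts
  n_coh <- integer(length(cohorts))
  for (k in seq_along(cohorts)) {
    members <- ids[dec == cohorts[k]]
    n_coh[k] <- length(members)
    if (length(members) < 2L) { stab[k] <- NA; next }
    fin <- M[as.character(final_year), members]
    yrs <- all_years[all_years >= cohorts[k]]
    r <- rep(NA_real_, length(yrs))
    for (t in seq_along(yrs)) {
      v <- M[as.character(yrs[t]), members]
      use <- !is.na(v) & !is.na(fin)
      if (sum(use) < 2L) next
      if (stats::sd(v[use]) == 0 || stats::sd(fin[use]) == 0) next  # undefined -> NA
      r[t] <- stats::cor(v[use], fin[use])
    }
    cor_rows[[k]] <- data.frame(cohort = cohorts[k], year = yrs, r = r,
                                n = length(members))
    in_win <- yrs >= win_lo & yrs <= final_year
    rw <- r[in_win]
    stab[k] <- length(rw) > 0L && all(!is.na(rw)) && all(rw >= threshold)
  }

  # latest decade such that it and every earlier (evaluable) decade stabilized
  cutoff <- NA_integer_
  for (k in seq_along(cohorts)) {
    if (is.na(stab[k])) next  # too small to evaluate; does not break the run
    if (stab[k]) cutoff <- as.integer(cohorts[k]) else break
  }
  list(
    cohorts = data.frame(cohort = cohorts, n = n_coh, stabilized = unname(stab)),
    correlations = if (length(cor_rows)) do.call(rbind, cor_rows) else
      data.frame(cohort = integer(), year = integer(), r = numeric(), n = integer()),
    cutoff_birth_year = if (is.na(cutoff)) NA_integer_ else cutoff + cohort_width,
    window_years = window_years,
    threshold = threshold
  )
}
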