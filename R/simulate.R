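#' Configuration for the two-parish demographic simulator
#'
#' Defaults emulate a pre-industrial Alpine two-parish population: high
#' childhood mortality (about a quarter dead by age 5), marriage in the
#' mid-twenties, a median of about four offspring among reproducers, a
#' generation time near 32 years, and appreciable marriage-driven migration
#' (roughly one in six individuals an immigrant and one in five an emigrant).
#'
#' @param parishes labels of the two parishes.
#' @param founding_size founding population per parish.
#' @param years integer `c(start, end)` calendar span.
#' @param mortality data frame `age_min`, `age_max`, `rate`: annual death
#'   probability by age band.
#' @param marriage_age_mean,marriage_age_sd marriage-age distribution (years).
#' @param celibacy_prob probability of never entering the marriage market.
#' @param fertility annual birth probability for a married couple with the
#'   wife aged between `fertile_ages[1]` and `fertile_ages[2]`.
#' @param fertile_ages female fertile age range.
#' @param emigration_prob probability that an individual reaching marriage
#'   age marries outside and leaves.
#' @param immigration_rate expected immigrant arrivals per resident per year.
#' @param sex_ratio probability a newborn is male.
#' @param remarriage_age_max widowed individuals below this age re-enter the
#'   marriage market.
#' @param density_dependence exponent of the compensatory-fertility term
#'   `(founding_size / current_size)^density_dependence`, emulating the
#'   household-capacity constraints on reproduction in historical parishes;
#'   keeps parish sizes near their founding values. 0 disables.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(parishes = c("parish_a", "parish_b"),
                       founding_size = c(1000L, 520L),
                       years = c(1560L, 1990L),
                       mortality = default_mortality(),
                       marriage_age_mean = 22, marriage_age_sd = 3,
                       celibacy_prob = 0.15,
                       fertility = 0.25, fertile_ages = c(17L, 42L),
                       emigration_prob = 0.45,
                       immigration_rate = 0.0055,
                       sex_ratio = 0.5,
                       remarriage_age_max = 45L,
                       density_dependence = 0.5) {
  stopifnot(length(parishes) == 2L, length(founding_size) == 2L,
            years[2L] > years[1L], fertility >= 0, fertility <= 1,
            emigration_prob >= 0, emigration_prob <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_mortality <- function() {
  data.frame(
    age_min = c(0L, 1L, 5L, 15L, 50L, 70L),
    age_max = c(0L, 4L, 14L, 49L, 69L, 120L),
    rate    = c(0.17, 0.035, 0.007, 0.011, 0.028, 0.115)
  )
}

#' Simulate a two-parish genealogical population
#'
#' Individual-based yearly simulation of aging, mortality, marriage (with
#' emigration at marriage and immigrant arrivals), and reproduction, emitting
#' records in the genealogy schema accepted by [pedigree_table()]. Immigrants
#' arrive at marriage with no local ancestors (pedigree founders); emigrants
#' keep their death year recorded but reproduce outside the study
#' populations, so none of their offspring enter the pedigree. Monogamous;
#' widowed individuals may remarry. Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return list with `ped` (a `pedigree_table`), `records` (the raw data
#'   frame), `config` and `seed`.
#' @export
simulate_population <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  y0 <- cfg$years[1L]; y1 <- cfg$years[2L]

  cap <- sum(cfg$founding_size) * 2L + as.integer((y1 - y0 + 1L) * sum(cfg$founding_size) * 0.06) + 1000L
  id <- integer(0)
  n <- 0L
  sex <- character(cap); birth <- integer(cap); death <- rep(NA_integer_, cap)
  sire <- rep(NA_integer_, cap); dam <- rep(NA_integer_, cap)
  bplace <- character(cap); mplace <- rep(NA_character_, cap)
  myear <- rep(NA_integer_, cap)
  loc <- character(cap)            # current location: parish label or "away"
  alive <- logical(cap)
  spouse <- rep(NA_integer_, cap)
  marr_age <- rep(NA_real_, cap)   # target marriage age; NA = never marries
  emig <- logical(cap)             # emigrates when reaching marriage age

  grow <- function(k) {
    if (n + k <= length(sex)) return(invisible())
    add <- max(k, length(sex))
    sex <<- c(sex, character(add)); birth <<- c(birth, integer(add))
    death <<- c(death, rep(NA_integer_, add))
    sire <<- c(sire, rep(NA_integer_, add)); dam <<- c(dam, rep(NA_integer_, add))
    bplace <<- c(bplace, character(add)); mplace <<- c(mplace, rep(NA_character_, add))
    myear <<- c(myear, rep(NA_integer_, add)); loc <<- c(loc, character(add))
    alive <<- c(alive, logical(add)); spouse <<- c(spouse, rep(NA_integer_, add))
    marr_age <<- c(marr_age, rep(NA_real_, add)); emig <<- c(emig, logical(add))
    invisible()
  }

  draw_marr_age <- function(k) {
    a <- stats::rnorm(k, cfg$marriage_age_mean, cfg$marriage_age_sd)
    a <- pmin(pmax(a, 19), 60)
    a[stats::runif(k) < cfg$celibacy_prob] <- NA
    a
  }

  add_individuals <- function(k, sex_v, birth_v, bplace_v, loc_v,
                              sire_v = NA_integer_, dam_v = NA_integer_,
                              mplace_v = NA_character_, myear_v = NA_integer_,
                              can_emigrate = TRUE) {
    grow(k)
    i <- n + seq_len(k)
    sex[i] <<- sex_v; birth[i] <<- birth_v; bplace[i] <<- bplace_v
    loc[i] <<- loc_v; alive[i] <<- TRUE
    sire[i] <<- sire_v; dam[i] <<- dam_v
    mplace[i] <<- mplace_v; myear[i] <<- myear_v
    marr_age[i] <<- draw_marr_age(k)
    emig[i] <<- can_emigrate & stats::runif(k) < cfg$emigration_prob
    n <<- n + k
    i
  }

  # founding populations: age structure 0-59, founders born in their parish
  for (p in 1:2) {
    k <- cfg$founding_size[p]
    ages <- sample(0:59, k, replace = TRUE,
                   prob = exp(-0.025 * (0:59)))
    i <- add_individuals(k,
      sex_v = sample(c("female", "male"), k, TRUE),
      birth_v = y0 - ages, bplace_v = cfg$parishes[p], loc_v = cfg$parishes[p])
    # founders past their marriage age are married residents already
    m <- i[!is.na(marr_age[i]) & ages >= marr_age[i] & !emig[i]]
    if (length(m)) {
      mplace[m] <- cfg$parishes[p]
      myear[m] <- pmin(birth[m] + as.integer(marr_age[m]), y0)
      f <- m[sex[m] == "female"]; ma <- m[sex[m] == "male"]
      np <- min(length(f), length(ma))
      if (np) { spouse[f[seq_len(np)]] <- ma[seq_len(np)]; spouse[ma[seq_len(np)]] <- f[seq_len(np)] }
    }
  }

  mort_rate <- function(age) {
    r <- numeric(length(age))
    for (b in seq_len(nrow(cfg$mortality))) {
      in_b <- age >= cfg$mortality$age_min[b] & age <= cfg$mortality$age_max[b]
      r[in_b] <- cfg$mortality$rate[b]
    }
    r[age > max(cfg$mortality$age_max)] <- cfg$mortality$rate[nrow(cfg$mortality)]
    r
  }

  for (year in y0:y1) {
    for (p in 1:2) {
      par <- cfg$parishes[p]
      here <- which(alive[seq_len(n)] & loc[seq_len(n)] == par)
      if (!length(here)) {
        stop("population of ", par, " went extinct in ", year,
             "; increase founding_size or fertility")
      }
      age <- year - birth[here]

      # immigrant arrivals: founders born away, married into the parish now
      n_imm <- stats::rpois(1L, cfg$immigration_rate * length(here))
      if (n_imm > 0L) {
        ia <- pmin(pmax(round(stats::rnorm(n_imm, cfg$marriage_age_mean, cfg$marriage_age_sd)), 19), 45)
        add_individuals(n_imm,
          sex_v = sample(c("female", "male"), n_imm, TRUE),
          birth_v = as.integer(year - ia), bplace_v = "away", loc_v = par,
          mplace_v = par, myear_v = year, can_emigrate = FALSE)
      }

      # marriage-age transitions: emigrate or enter the market
      here <- which(alive[seq_len(n)] & loc[seq_len(n)] == par)
      age <- year - birth[here]
      due <- here[is.na(spouse[here]) & is.na(mplace[here]) &
                    !is.na(marr_age[here]) & age >= marr_age[here]]
      if (length(due)) {
        leaving <- due[emig[due]]
        if (length(leaving)) {
          mplace[leaving] <- "away"; myear[leaving] <- year
          loc[leaving] <- "away"
        }
        due <- setdiff(due, leaving)
      }
      # market: unmarried locals at/above marriage age plus waiting immigrants
      mk <- which(alive[seq_len(n)] & loc[seq_len(n)] == par &
                    is.na(spouse[seq_len(n)]) &
                    ((is.na(mplace[seq_len(n)]) & !is.na(marr_age[seq_len(n)]) &
                        (year - birth[seq_len(n)]) >= marr_age[seq_len(n)] &
                        (year - birth[seq_len(n)]) <= cfg$remarriage_age_max & !emig[seq_len(n)]) |
                       (!is.na(mplace[seq_len(n)]) & mplace[seq_len(n)] == par &
                          (year - birth[seq_len(n)]) <= cfg$remarriage_age_max)))
      f <- mk[sex[mk] == "female"]; m <- mk[sex[mk] == "male"]
      np <- min(length(f), length(m))
      if (np > 0L) {
        f <- f[sample.int(length(f), np)]
        m <- m[sample.int(length(m), np)]
        spouse[f] <- m; spouse[m] <- f
        new_f <- is.na(mplace[f]); new_m <- is.na(mplace[m])
        mplace[f[new_f]] <- par; myear[f[new_f]] <- year
        mplace[m[new_m]] <- par; myear[m[new_m]] <- year
      }

      # reproduction: married couples with a fertile wife, both present
      wives <- which(alive[seq_len(n)] & loc[seq_len(n)] == par &
                       sex[seq_len(n)] == "female" & !is.na(spouse[seq_len(n)]))
      if (length(wives)) {
        wage <- year - birth[wives]
        h <- spouse[wives]
        ok <- wage >= cfg$fertile_ages[1L] & wage <= cfg$fertile_ages[2L] &
          alive[h] & loc[h] == par
        wives <- wives[ok]
        fert <- cfg$fertility
        if (cfg$density_dependence > 0) {
          fert <- fert * (cfg$founding_size[p] / length(here))^cfg$density_dependence
          fert <- min(max(fert, 0.4 * cfg$fertility), 1.8 * cfg$fertility)
        }
        births <- wives[stats::runif(length(wives)) < fert]
        if (length(births)) {
          add_individuals(length(births),
            sex_v = sample(c("male", "female"), length(births), TRUE,
                           prob = c(cfg$sex_ratio, 1 - cfg$sex_ratio)),
            birth_v = year, bplace_v = par, loc_v = par,
            sire_v = spouse[births], dam_v = births)
        }
      }
    }

    # mortality applies everywhere, including to emigrants living away
    liv <- which(alive[seq_len(n)])
    dies <- liv[stats::runif(length(liv)) < mort_rate(year - birth[liv])]
    if (length(dies)) {
      alive[dies] <- FALSE
      death[dies] <- year
      widowed <- spouse[dies]
      widowed <- widowed[!is.na(widowed)]
      spouse[widowed] <- NA_integer_
      spouse[dies] <- NA_integer_
    }
  }

  i <- seq_len(n)
  rec <- data.frame(
    id = paste0("i", i),
    sire = ifelse(is.na(sire[i]), NA_character_, paste0("i", sire[i])),
    dam = ifelse(is.na(dam[i]), NA_character_, paste0("i", dam[i])),
    sex = sex[i], birth_year = birth[i], death_year = death[i],
    birth_place = bplace[i], marriage_place = mplace[i],
    marriage_year = myear[i], stringsAsFactors = FALSE)
  list(ped = pedigree_table(rec), records = rec, config = cfg, seed = seed)
}

#' Gene-dropping Monte-Carlo oracle for expected contributions
#'
#' Realizes the Mendelian expectation that [contribution_vector()] computes:
#' the focal carries two distinguishable alleles, every other founder carries
#' null alleles, and alleles are dropped down the pedigree by fair Mendelian
#' sampling (each child receives one allele drawn at random from each
#' parent's pair; the focal's own parents are severed). The realized
#' contribution in a year is the proportion of focal allele copies among the
#' `2 * pop_size` allele slots of that year's gene pool.
#'
#' @param ped a [pedigree_table()].
#' @param focal individual id.
#' @param presence a [build_presence()] table.
#' @param year calendar year inside the presence table.
#' @param reps Monte-Carlo replicates (at least 2).
#' @param seed RNG seed.
#' @return list with `focal`, `year`, `reps`, `realized` (per-rep
#'   proportions), `mean` and `mc_se`.
#' @export
gene_drop <- function(ped, focal, presence, year, reps = 1e4, seed = 1L) {
  if (reps < 2L) stop("reps must be at least 2")
  if (!year %in% presence$years) stop("year outside the presence table")
  set.seed(seed)
  desc <- descendants(ped, focal)
  ids <- c(focal, desc)
  pool <- presence$by_year[[as.character(year)]]
  npool <- length(pool)
  if (npool == 0L) stop("empty gene pool in ", year)

  # focal-allele copy counts per rep and individual; transmission from a
  # parent with k copies is Bernoulli(k / 2) per meiosis
  copies <- matrix(0L, nrow = reps, ncol = length(ids),
                   dimnames = list(NULL, ids))
  copies[, 1L] <- 2L
  if (length(desc)) {
    sub <- ped$records[ped$records$id %in% desc, c("id", "sire", "dam")]
    pos <- match(sub$id, ids)
    si <- match(sub$sire, ids)
    di <- match(sub$dam, ids)
    for (r in seq_len(nrow(sub))) {
      v <- integer(reps)
      if (!is.na(si[r])) v <- v + stats::rbinom(reps, 1L, copies[, si[r]] / 2)
      if (!is.na(di[r])) v <- v + stats::rbinom(reps, 1L, copies[, di[r]] / 2)
      copies[, pos[r]] <- v
    }
  }
  carriers <- intersect(pool, ids)
  tot <- if (length(carriers)) rowSums(copies[, carriers, drop = FALSE]) else numeric(reps)
  realized <- tot / (2 * npool)
  list(focal = focal, year = year, reps = reps, realized = realized,
       mean = mean(realized), mc_se = stats::sd(realized) / sqrt(reps))
}

#' Simulate model-ready data from the zero-inflated beta likelihood
#'
#' Draws a design (parish, sex, parish-specific birth cohort, proxy counts)
#' and simulates responses from exactly the hierarchical zero-inflated beta
#' likelihood fitted by [fit_zib()], with supplied ground-truth parameters.
#'
#' @param n rows (at least 100).
#' @param coef list with elements `bz`, `bb` (named fixed-effect vectors over
#'   `intercept`, `proxy`, `parish_b`, `sex_male`, optionally
#'   `parish_b:sex_male`), `phi` (beta precision, > 0), `sd_z`, `sd_b`
#'   (length-2: random intercept and slope SDs for each part).
#' @param n_cohorts cohorts per parish.
#' @param proxy_lambda Poisson mean of the proxy counts.
#' @param zero_inflated simulate zeros (`TRUE`) or beta-only (`FALSE`).
#' @param seed RNG seed.
#' @return list with `data` (data frame: `y`, `proxy`, `parish`, `sex`,
#'   `cohort`), `truth` (the coefficients and realized random effects).
#' @export
simulate_regression_data <- function(n, coef, n_cohorts = 8L,
                                     proxy_lambda = 4, zero_inflated = TRUE,
                                     seed = 1L) {
  if (n < 100L) stop("n must be at least 100")
  if (coef$phi <= 0) stop("phi must be positive")
  set.seed(seed)
  parish <- sample(c("parish_a", "parish_b"), n, TRUE)
  sex <- sample(c("female", "male"), n, TRUE)
  cohort <- paste(parish, sample.int(n_cohorts, n, TRUE), sep = ":")
  proxy <- stats::rpois(n, proxy_lambda)
  g <- match(cohort, sort(unique(cohort)))
  G <- max(g)
  X <- cbind(intercept = 1, proxy = proxy,
             parish_b = as.numeric(parish == "parish_b"),
             sex_male = as.numeric(sex == "male"))
  if ("parish_b:sex_male" %in% names(coef$bb)) {
    X <- cbind(X, `parish_b:sex_male` = X[, "parish_b"] * X[, "sex_male"])
  }
  stopifnot(all(names(coef$bb) %in% colnames(X)))
  uz <- cbind(stats::rnorm(G, 0, coef$sd_z[1L]), stats::rnorm(G, 0, coef$sd_z[2L]))
  ub <- cbind(stats::rnorm(G, 0, coef$sd_b[1L]), stats::rnorm(G, 0, coef$sd_b[2L]))
  eta_b <- drop(X[, names(coef$bb), drop = FALSE] %*% coef$bb) +
    ub[g, 1L] + ub[g, 2L] * proxy
  mu <- invlogit(eta_b)
  y <- stats::rbeta(n, mu * coef$phi, (1 - mu) * coef$phi)
  # guard against numerical 0/1 from rbeta at extreme mu
  eps <- 1e-12
  y <- pmin(pmax(y, eps), 1 - eps)
  if (zero_inflated) {
    eta_z <- drop(X[, names(coef$bz), drop = FALSE] %*% coef$bz) +
      uz[g, 1L] + uz[g, 2L] * proxy
    z <- stats::rbinom(n, 1L, invlogit(eta_z))
    y[z == 1L] <- 0
  }
  list(data = data.frame(y = y, proxy = proxy, parish = parish, sex = sex,
                         cohort = cohort, stringsAsFactors = FALSE),
       truth = list(coef = coef, uz = if (zero_inflated) uz else NULL, ub = ub))
}
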