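#' Classify individuals as residents, immigrants, emigrants or movers
#'
#' Applies the marriage-based classification: born and married in a study
#' parish (or born there and never married) = resident; born outside but
#' married in a parish = immigrant, arriving at the marriage year; born in a
#' parish but married outside = emigrant, departing at the marriage year;
#' born in one study parish and married in the other = inter-parish mover.
#' Individuals with no usable place information are unclassifiable.
#'
#' @param ped a [pedigree_table()].
#' @param parishes character vector of study parish labels.
#' @return data frame with columns `id`, `status`, `home_parish`,
#'   `birth_parish`, `arrival_year`, `departure_year`.
#' @export
classify_migration <- function(ped, parishes) {
  df <- ped$records
  bp <- df$birth_place
  mp <- df$marriage_place
  my <- df$marriage_year
  born_in <- !is.na(bp) & bp %in% parishes
  married <- !is.na(mp)
  married_in <- married & mp %in% parishes

  status <- rep("unclassifiable", nrow(df))
  home <- rep(NA_character_, nrow(df))
  arrival <- rep(NA_integer_, nrow(df))
  departure <- rep(NA_integer_, nrow(df))

  res <- born_in & ((married_in & mp == bp) | !married)
  status[res] <- "resident"; home[res] <- bp[res]

  imm <- !born_in & married_in
  status[imm] <- "immigrant"; home[imm] <- mp[imm]; arrival[imm] <- my[imm]

  emi <- born_in & married & !married_in
  status[emi] <- "emigrant"; home[emi] <- bp[emi]; departure[emi] <- my[emi]

  mov <- born_in & married_in & mp != bp
  status[mov] <- "inter_parish_mover"; home[mov] <- mp[mov]
  arrival[mov] <- my[mov]; departure[mov] <- my[mov]

  data.frame(id = df$id, status = status, home_parish = home,
             birth_parish = ifelse(born_in, bp, NA_character_),
             arrival_year = arrival, departure_year = departure,
             stringsAsFactors = FALSE)
}

#' Proportion of each migration class per parish
#'
#' Proportions are over classifiable individuals. Residents and emigrants
#' count toward their birth parish, immigrants toward their marriage parish,
#' and inter-parish movers toward their birth (origin) parish.
#'
#' @param statuses output of [classify_migration()].
#' @return data frame: `parish`, `status`, `n`, `prop`; proportions sum to 1
#'   within each parish.
#' @export
migration_rates <- function(statuses) {
  s <- statuses[statuses$status != "unclassifiable", ]
  parish <- ifelse(s$status == "immigrant", s$home_parish, s$birth_parish)
  tab <- as.data.frame(table(parish = parish, status = s$status),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0 | TRUE, ]
  tot <- stats::ave(tab$n, tab$parish, FUN = sum)
  tab$prop <- tab$n / tot
  tab[order(tab$parish, -tab$n), ]
}

#' Per-parish, per-year local gene pool membership
#'
#' Determines each individual's presence window in one parish from its
#' migration status and life dates, then materializes the year-by-year gene
#' pool. Residents are present from birth to death; immigrants from arrival
#' (marriage) to death; emigrants from birth to departure (marriage);
#' inter-parish movers from birth to marriage in the origin parish and from
#' marriage to death in the destination parish, with the transition year
#' assigned to the destination. Individuals with a missing death year remain
#' present until their last recorded event (own marriage or last offspring
#' birth) plus `censor_horizon` years. Year intervals are closed; the pool of
#' year `y` is everyone whose window covers `y`.
#'
#' @param ped a [pedigree_table()].
#' @param statuses output of [classify_migration()].
#' @param parish parish label.
#' @param year_range integer vector `c(start, end)`.
#' @param censor_horizon extra presence years after the last recorded event
#'   when the death year is missing (default 0).
#' @return object of class `presence_table`: list with `parish`, `years`,
#'   `by_year` (named list year -> ids), `pop_size` (named integer) and
#'   `windows` (data frame id/start/end).
#' @export
build_presence <- function(ped, statuses, parish, year_range,
                           censor_horizon = 0L) {
  df <- ped$records
  st <- statuses[match(df$id, statuses$id), ]

  # last recorded event per individual, for death-censored windows
  kid_by <- stats::setNames(df$birth_year, df$id)
  last_kid <- rep(NA_real_, nrow(df))
  for (p in names(ped$child_index)) {
    yrs <- kid_by[ped$child_index[[p]]]
    if (any(!is.na(yrs))) last_kid[match(p, df$id)] <- max(yrs, na.rm = TRUE)
  }
  end_alive <- ifelse(!is.na(df$death_year), df$death_year,
                      pmax(df$birth_year, df$marriage_year, last_kid,
                           na.rm = TRUE) + censor_horizon)

  start <- rep(NA_real_, nrow(df))
  end <- rep(NA_real_, nrow(df))
  in_home <- !is.na(st$home_parish) & st$home_parish == parish
  is_res <- st$status == "resident" & in_home
  is_imm <- st$status == "immigrant" & in_home
  is_emi <- st$status == "emigrant" & !is.na(st$birth_parish) & st$birth_parish == parish
  is_mov_dest <- st$status == "inter_parish_mover" & in_home
  is_mov_orig <- st$status == "inter_parish_mover" &
    !is.na(st$birth_parish) & st$birth_parish == parish

  start[is_res] <- df$birth_year[is_res]
  end[is_res] <- end_alive[is_res]
  start[is_imm] <- st$arrival_year[is_imm]
  end[is_imm] <- end_alive[is_imm]
  start[is_emi] <- df$birth_year[is_emi]
  end[is_emi] <- st$departure_year[is_emi]
  start[is_mov_dest] <- st$arrival_year[is_mov_dest]
  end[is_mov_dest] <- end_alive[is_mov_dest]
  start[is_mov_orig] <- df$birth_year[is_mov_orig]
  end[is_mov_orig] <- st$departure_year[is_mov_orig] - 1L  # transition year goes to destination

  ok <- !is.na(start) & !is.na(end) & end >= start
  win <- data.frame(id = df$id[ok], start = as.integer(start[ok]),
                    end = as.integer(end[ok]), stringsAsFactors = FALSE)
  win$start <- pmax(win$start, year_range[1L])
  win$end <- pmin(win$end, year_range[2L])
  win <- win[win$end >= win$start, ]

  years <- year_range[1L]:year_range[2L]
  by_year <- vector("list", length(years))
  names(by_year) <- years
  if (nrow(win)) {
    reps <- win$end - win$start + 1L
    long_year <- sequence(reps) - 1L + rep(win$start, reps)
    long_id <- rep(win$id, reps)
    sp <- split(long_id, long_year)
    by_year[names(sp)] <- sp
  }
  empty <- vapply(by_year, is.null, logical(1))
  by_year[empty] <- list(character(0))
  pop_size <- vapply(by_year, length, integer(1))

  structure(list(parish = parish, years = years, by_year = by_year,
                 pop_size = pop_size, windows = win),
            class = "presence_table")
}

#' @export
print.presence_table <- function(x, ...) {
  cat(sprintf("<presence_table: %s, %d-%d, pop %d-%d>\n", x$parish,
              min(x$years), max(x$years), min(x$pop_size), max(x$pop_size)))
  invisible(x)
}
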