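test_that("expected contributions follow Mendelian halving with severed parents", {
  ped <- diamond_pedigree()
  cv <- contribution_vector(ped, "a")
  expect_equal(cv[["a"]], 1)
  expect_equal(cv[["c"]], 0.5)   # offspring
  expect_equal(cv[["d"]], 0.5)
  # grandchild through a mating of two of the focal's children: 0.25 + 0.25
  expect_equal(cv[["e"]], 0.5)
  # grandchild through a single child
  ped2 <- pedigree_table(data.frame(
    id = c("a", "c", "g"), sire = c(NA, "a", "c"), dam = NA_character_))
  expect_equal(contribution_vector(ped2, "a")[["g"]], 0.25)
  # non-descendants are absent from the coefficient vector
  expect_false("b" %in% names(contribution_vector(ped, "a")))
  expect_error(contribution_vector(ped, "zz"), "unknown focal")
})

test_that("propagation equals the severed-parent relationship matrix rows", {
  for (seed in 1:6) {
    ped <- random_pedigree(sample(60:150, 1L), seed)
    ids <- sample(ped$records$id, 4L)
    for (f in ids) {
      A <- relationship_matrix(ped, sever = f)
      cv <- contribution_vector(ped, f)
      expect_lt(max(abs(cv - A[f, names(cv)])), 1e-12)
      # and zero relatedness to every non-descendant through descent
      others <- setdiff(ped$records$id, names(cv))
      desc_of_others <- others[vapply(others, function(o) f %in% ancestors(ped, o), logical(1))]
      expect_length(desc_of_others, 0L)
    }
  }
})

test_that("founder contributions to a fully-pedigreed individual sum to one", {
  sim <- small_sim()
  ped <- sim$ped
  founders <- ped$records$id[is.na(ped$records$sire) & is.na(ped$records$dam)]
  total <- setNames(numeric(nrow(ped$records)), ped$records$id)
  for (f in founders) {
    cv <- contribution_vector(ped, f)
    total[names(cv)] <- total[names(cv)] + cv
  }
  non_founders <- setdiff(ped$records$id, founders)
  expect_lt(max(abs(total[non_founders] - 1)), 1e-9)
})

test_that("IGC divides the present coefficient mass by the pool size", {
  tp <- toy_parish()
  cv <- contribution_vector(tp$ped, "f")
  s <- igc_series(cv, tp$presence, 1700L, 1790L)
  at <- function(y) s$igc[match(y, s$years)]
  # 1750: pool = {focal, child, 2 unrelated} -> (1 + 0.5) / 4
  expect_equal(at(1750L), 0.375)
  # 1710: focal + the two unrelated: 1/3
  expect_equal(at(1710L), 1 / 3)
  # focal dead, child still present: 0.5 / 3
  expect_equal(at(1770L), 0.5 / 3)
  expect_equal(s$final_value, 0.5 / 3)

  # focal alone in the pool -> exactly 1; dead with no descendants -> 0
  solo <- pedigree_table(data.frame(
    id = c("x", "y"), sire = NA_character_, dam = NA_character_,
    birth_place = "elmwood", marriage_place = NA_character_,
    birth_year = c(1700L, 1720L), death_year = c(1710L, 1750L),
    sex = "male"))
  stx <- classify_migration(solo, "elmwood")
  prx <- build_presence(solo, stx, "elmwood", c(1700L, 1750L))
  sx <- igc_series(contribution_vector(solo, "x"), prx, 1700L, 1750L)
  expect_equal(sx$igc[match(1705L, sx$years)], 1)   # pool = {x}
  expect_equal(sx$igc[match(1730L, sx$years)], 0)   # x dead, unrelated y present
})

test_that("adding unrelated present individuals dilutes IGC", {
  tp <- toy_parish()
  cv <- contribution_vector(tp$ped, "f")
  base <- igc_series(cv, tp$presence, 1700L, 1790L)
  more <- tp$ped$records
  extra <- data.frame(id = c("u3", "u4"), sire = NA, dam = NA, sex = "male",
                      birth_year = 1700L, death_year = 1790L,
                      birth_place = "elmwood", marriage_place = NA,
                      marriage_year = NA)
  more <- rbind(more[, names(extra)], extra)
  ped2 <- pedigree_table(more)
  st2 <- classify_migration(ped2, "elmwood")
  pr2 <- build_presence(ped2, st2, "elmwood", c(1700L, 1790L))
  diluted <- igc_series(contribution_vector(ped2, "f"), pr2, 1700L, 1790L)
  pre <- base$igc[base$igc > 0 & !is.na(base$igc)]
  post <- diluted$igc[base$igc > 0 & !is.na(base$igc)]
  expect_true(all(post < pre))
})

test_that("generation time is the mean parental age at offspring birth", {
  ped <- pedigree_table(data.frame(
    id = c("p", "k"), sire = c(NA, "p"), dam = NA_character_,
    birth_year = c(1700L, 1732L)))
  gt <- generation_time(ped)
  expect_equal(gt$mean, 32)
  expect_equal(gt$n, 1L)
  ped2 <- pedigree_table(data.frame(
    id = c("p", "k1", "k2"), sire = c(NA, "p", "p"), dam = NA_character_,
    birth_year = c(1700L, 1730L, 1734L)))
  gt2 <- generation_time(ped2)
  expect_equal(gt2$mean, 32)
  expect_equal(gt2$se, 2)
  expect_error(generation_time(pedigree_table(data.frame(
    id = "solo", sire = NA_character_, dam = NA_character_))), "no parent")
})

test_that("cohort stabilization applies the correlation-window criterion", {
  # hand-built series: two cohorts of three; cohort 1700 frozen over the
  # whole window, cohort 1710 dips below the threshold inside it
  years <- 1700:1800
  mk <- function(focal, vals) {
    structure(list(focal = focal, parish = "elmwood", years = years,
                   igc = vals, final_value = vals[length(vals)]),
              class = "igc_series")
  }
  frozen <- lapply(1:3, function(i) mk(paste0("a", i), rep(i / 100, length(years))))
  names(frozen) <- paste0("a", 1:3)
  wobble <- lapply(1:3, function(i) {
    v <- rep(i / 100, length(years))
    if (i == 3) v[years == 1770] <- 0.0001  # rank flip well inside the window
    mk(paste0("b", i), v)
  })
  names(wobble) <- paste0("b", 1:3)
  lone <- list(c1 = mk("c1", rep(0.01, length(years))))
  series <- c(frozen, wobble, lone)
  births <- setNames(c(1700L, 1701L, 1705L, 1710L, 1711L, 1712L, 1720L),
                     names(series))
  st <- cohort_stabilization(series, births, gen_time = 20, final_year = 1800L)
  coh <- st$cohorts
  expect_true(coh$stabilized[coh$cohort == 1700])
  expect_false(coh$stabilized[coh$cohort == 1710])
  # single-member cohort is excluded, not failed
  expect_true(is.na(coh$stabilized[coh$cohort == 1720]))
  expect_equal(st$window_years, 40L)
  # run of stabilized cohorts ends before 1710
  expect_equal(st$cutoff_birth_year, 1710L)
  # final-year correlation is exactly 1 for a non-constant cohort
  cc <- st$correlations
  expect_equal(cc$r[cc$cohort == 1700 & cc$year == 1800], 1)
})

test_that("a sub-threshold correlation year blocks stabilization", {
  years <- 1900:1950
  base <- matrix(c(1, 2, 4, 8), 4, length(years))
  noise <- base
  noise[, years == 1940] <- c(8, 4, 2, 1)  # r < 0.95 in one window year
  mk_set <- function(M, prefix) {
    out <- lapply(seq_len(nrow(M)), function(i)
      structure(list(focal = paste0(prefix, i), parish = "p", years = years,
                     igc = M[i, ] / 100, final_value = M[i, length(years)] / 100),
                class = "igc_series"))
    setNames(out, paste0(prefix, seq_len(nrow(M))))
  }
  births <- setNames(rep(1900L, 4L), paste0("x", 1:4))
  ok <- cohort_stabilization(mk_set(base, "x"), births, 10, 1950L)
  bad <- cohort_stabilization(mk_set(noise, "x"), births, 10, 1950L)
  expect_true(ok$cohorts$stabilized)
  expect_false(bad$cohorts$stabilized)
})
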