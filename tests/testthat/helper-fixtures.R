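# shared fixtures; everything is built in code at test time

# five individuals: founders a, b; full sibs c, d; e the child of the sib
# mating (inbred diamond)
diamond_pedigree <- function() {
  pedigree_table(data.frame(
    id = c("a", "b", "c", "d", "e"),
    sire = c(NA, NA, "a", "a", "c"),
    dam = c(NA, NA, "b", "b", "d"),
    sex = c("male", "female", "male", "female", "male"),
    stringsAsFactors = FALSE))
}

# random multi-generation pedigree with complete parentage below the founders
random_pedigree <- function(n, seed, n_gen = 5L) {
  set.seed(seed)
  per_gen <- diff(round(seq(0, n, length.out = n_gen + 1L)))
  id <- paste0("p", seq_len(n))
  sex <- sample(c("female", "male"), n, TRUE)
  sire <- dam <- rep(NA_character_, n)
  gen <- rep(seq_len(n_gen), per_gen)
  for (g in 2:n_gen) {
    prev <- which(gen == g - 1L)
    males <- prev[sex[prev] == "male"]
    females <- prev[sex[prev] == "female"]
    if (!length(males) || !length(females)) next
    cur <- which(gen == g)
    sire[cur] <- id[sample(males, length(cur), TRUE)]
    dam[cur] <- id[sample(females, length(cur), TRUE)]
  }
  pedigree_table(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                            birth_year = 1600L + 30L * (gen - 1L),
                            stringsAsFactors = FALSE))
}

# brute-force descendant closure by repeated one-step expansion
bfs_descendants <- function(ped, focal) {
  out <- character(0)
  repeat {
    step <- unique(unlist(ped$child_index[c(focal, out)], use.names = FALSE))
    step <- setdiff(step, c(out, focal))
    if (!length(step)) break
    out <- c(out, step)
  }
  out
}

# four residents of one parish with fixed life spans, for IGC arithmetic
toy_parish <- function() {
  rec <- data.frame(
    id = c("f", "kid", "u1", "u2"),
    sire = c(NA, "f", NA, NA),
    dam = c(NA, NA, NA, NA),
    sex = c("male", "female", "male", "female"),
    birth_year = c(1700L, 1730L, 1700L, 1700L),
    death_year = c(1760L, 1790L, 1790L, 1790L),
    birth_place = "elmwood",
    marriage_place = c("elmwood", "elmwood", NA, NA),
    marriage_year = c(1725L, 1755L, NA, NA),
    stringsAsFactors = FALSE)
  ped <- pedigree_table(rec)
  st <- classify_migration(ped, "elmwood")
  list(ped = ped, statuses = st,
       presence = build_presence(ped, st, "elmwood", c(1700L, 1790L)))
}

# small cached two-parish simulation shared across test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(founding_size = c(220L, 140L), years = c(1650L, 1850L))
      cache <<- c(simulate_population(cfg, seed = 424L), list(cfg = cfg))
    }
    cache
  }
})

# zib_fit skeleton with externally supplied posterior draws, to exercise the
# posterior functionals on exactly known inputs
manual_zib_fit <- function(draws, X, w, g, y, zero_inflated = TRUE,
                           random_slope = TRUE) {
  structure(list(
    samples = coda::as.mcmc.list(list(coda::mcmc(draws))),
    X = X, w = w, g = g, G = max(g), y = y, pos = which(y > 0),
    zero_inflated = zero_inflated, random_slope = random_slope,
    proxy = "proxy", response = "y", interaction = FALSE,
    covariates = character(0), cohort_levels = as.character(seq_len(max(g))),
    data_n = length(y), mcmc = list(chains = 1L), seed = 1L
  ), class = "zib_fit")
}

# draw matrix column names for a manual fit
zib_draw_names <- function(P, G, zero_inflated = TRUE) {
  nm <- c(paste0("bb[", seq_len(P), "]"), "lphi",
          paste0("sd_ub[", 1:2, "]"),
          paste0("ub[", seq_len(G), ",1]"), paste0("ub[", seq_len(G), ",2]"))
  if (zero_inflated) {
    nm <- c(nm, paste0("bz[", seq_len(P), "]"), paste0("sd_uz[", 1:2, "]"),
            paste0("uz[", seq_len(G), ",1]"), paste0("uz[", seq_len(G), ",2]"))
  }
  nm
}

# standard generative setting used by the recovery and R2 checks
recovery_coefs <- function(interaction = FALSE) {
  bz <- c(intercept = 1.0, proxy = -0.5, parish_b = 0.3, sex_male = 0.1)
  bb <- c(intercept = -3.0, proxy = 0.08, parish_b = -0.3, sex_male = 0.05)
  if (interaction) {
    bz <- c(bz, "parish_b:sex_male" = 1.0)
    bb <- c(bb, "parish_b:sex_male" = 0.5)
  }
  list(bz = bz, bb = bb, phi = 30, sd_z = c(0.3, 0.05), sd_b = c(0.2, 0.02))
}
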