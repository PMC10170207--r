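test_that("probability of direction summarizes posterior sign agreement", {
  expect_equal(prob_direction(rep(c(1, 2), 60))$pd, 1)
  expect_equal(prob_direction(rep(c(1, 2), 60))$class, "highly significant")
  half <- c(rep(1, 100), rep(-1, 100))
  expect_equal(prob_direction(half)$pd, 0.5)
  expect_equal(prob_direction(half)$class, "not significant")
  x <- c(rep(1, 96), rep(-1, 4))
  expect_equal(prob_direction(x)$pd, 0.96)
  expect_equal(prob_direction(x)$class, "trend effect")
  expect_equal(prob_direction(c(rep(1, 98), rep(-1, 2)))$class, "significant")
  expect_error(prob_direction(rep(0, 200)), "all-zero")
  expect_error(prob_direction(1:50), "100 draws")
  # invariant to monotone reparameterization
  set.seed(1)
  d <- rnorm(500, 1, 1)
  expect_equal(prob_direction(d)$pd, prob_direction(d^3)$pd)
  expect_equal(prob_direction(d)$pd, prob_direction(sign(d) * sqrt(abs(d)))$pd)
})

test_that("Bayesian R2 reaches its analytic limits on controlled draws", {
  # deterministic design: two cohorts, strong separation
  n <- 400L
  x <- rep(c(0, 10), each = n / 2)
  X <- cbind(intercept = 1, proxy = x, parish_b = 0, sex_male = 0)
  g <- rep(1:2, each = n / 2)
  y <- rep(0.5, n)
  P <- ncol(X); G <- 2L
  nm <- zib_draw_names(P, G)
  mk_draws <- function(bb, lphi, bz) {
    M <- matrix(0, 150, length(nm), dimnames = list(NULL, nm))
    M[, paste0("bb[", 1:P, "]")] <- matrix(bb, 150, P, byrow = TRUE)
    M[, "lphi"] <- lphi
    M[, paste0("bz[", 1:P, "]")] <- matrix(bz, 150, P, byrow = TRUE)
    M
  }
  # noiseless limit: huge precision, extinction deterministic in the proxy
  fit_lim <- manual_zib_fit(mk_draws(c(-2, 0.3, 0, 0), log(1e8), c(30, -6, 0, 0)),
                            X, x, g, y)
  r2 <- bayes_r2(fit_lim)
  expect_gt(r2$median, 0.999)
  # no predictor variation at all: R2 collapses to zero
  fit0 <- manual_zib_fit(mk_draws(c(-2, 0, 0, 0), log(30), c(0.5, 0, 0, 0)),
                         X, x, g, y)
  expect_lt(bayes_r2(fit0)$median, 1e-10)
  # every draw stays inside [0, 1]
  expect_true(all(r2$draws >= 0 & r2$draws <= 1))
})

test_that("an intercept-only fit recovers the zero fraction and a flat R2", {
  co <- recovery_coefs()
  co$bz[] <- c(logit(0.3), 0, 0, 0)
  co$bb[] <- c(-3, 0, 0, 0)
  co$sd_z <- c(0, 0); co$sd_b <- c(0, 0)
  sim <- simulate_regression_data(1000L, co, seed = 21L)
  fit <- fit_zib(sim$data, proxy = "none", mcmc = mcmc_profile("fast"), seed = 4L)
  s <- posterior_summary(fit)
  # closed-form Bernoulli estimate of the zero probability
  phat <- mean(sim$data$y == 0)
  est <- s$median[s$parameter == "zi_intercept"]
  expect_lt(abs(invlogit(est) - phat), 0.05)
  expect_lt(bayes_r2(fit)$median, 0.05)
})

test_that("R2 differences pair draws and demand identical data", {
  co <- recovery_coefs()
  sim <- simulate_regression_data(600L, co, seed = 31L)
  fit <- fit_zib(sim$data, proxy = "proxy", mcmc = mcmc_profile("fast"), seed = 7L)
  r2 <- bayes_r2(fit)
  self <- r2_difference(r2, r2)
  expect_equal(self$mode, 0, tolerance = 1e-12)
  expect_false(self$significant)
  null_fit <- fit_zib(sim$data, proxy = "none", mcmc = mcmc_profile("fast"), seed = 8L)
  d <- r2_difference(fit, null_fit)
  expect_gt(d$mode, 0)   # true-signal model explains more
  other <- bayes_r2(fit)
  other$data_n <- 99L
  expect_error(r2_difference(r2, other), "different numbers")
})

test_that("permuted proxies carry no direction signal", {
  co <- recovery_coefs()
  sig <- 0L
  pds <- numeric(4)
  for (r in seq_len(4)) {
    sim <- simulate_regression_data(600L, co, seed = 40L + r)
    sim$data$proxy <- sample(sim$data$proxy)  # break the association
    fit <- fit_zib(sim$data, proxy = "proxy", mcmc = mcmc_profile("fast"),
                   seed = 50L + r)
    pds[r] <- prob_direction(fit, "beta_proxy")$pd
    if (pds[r] > 0.975) sig <- sig + 1L
  }
  # under the null pd is uniform on [0.5, 1]; significance should be rare
  expect_lte(sig, 1L)
  expect_lt(mean(pds), 0.95)
})

test_that("the sex-by-parish interaction is pruned only when absent", {
  co0 <- recovery_coefs()          # generator without interaction
  sim0 <- simulate_regression_data(800L, co0, seed = 61L)
  pr0 <- interaction_pruning(sim0$data, proxy = "proxy",
                             mcmc = mcmc_profile("fast"), seed = 11L)
  expect_true(pr0$dropped)
  expect_false(pr0$fit$interaction)

  co1 <- recovery_coefs(interaction = TRUE)  # logit shift 1.0 in the zero part
  sim1 <- simulate_regression_data(800L, co1, seed = 62L)
  pr1 <- interaction_pruning(sim1$data, proxy = "proxy",
                             mcmc = mcmc_profile("fast"), seed = 12L)
  expect_false(pr1$dropped)

  # single-parish data: the interaction cannot be estimated
  one <- sim0$data[sim0$data$parish == "parish_a", ]
  expect_error(fit_zib(one, proxy = "proxy", interaction = TRUE, seed = 1L),
               "single level")
})

test_that("the fit is reproducible given seed and validates its inputs", {
  co <- recovery_coefs()
  sim <- simulate_regression_data(300L, co, seed = 71L)
  prof <- list(chains = 2L, adapt = 150L, burn = 100L, iter = 200L, thin = 1L)
  f1 <- fit_zib(sim$data, proxy = "proxy", mcmc = prof, seed = 3L)
  f2 <- fit_zib(sim$data, proxy = "proxy", mcmc = prof, seed = 3L)
  expect_equal(gencontrib:::draw_matrix(f1), gencontrib:::draw_matrix(f2))
  bad <- sim$data; bad$y[1] <- 1.2
  expect_error(fit_zib(bad, proxy = "proxy", seed = 1L), "\\[0, 1\\)")
  bad2 <- sim$data; bad2$y[bad2$y > 0][1] <- 0
  expect_error(fit_zib(bad2, proxy = "proxy", zero_inflated = FALSE, seed = 1L),
               "strictly positive")
})

test_that("posterior medians agree with an independent maximum-likelihood fit", {
  skip_if_not_installed("glmmTMB")
  co <- recovery_coefs()
  sim <- simulate_regression_data(1500L, co, seed = 91L)
  fit <- fit_zib(sim$data, proxy = "proxy", mcmc = mcmc_profile("fast"), seed = 92L)
  s <- posterior_summary(fit)

  d <- sim$data
  d$parish <- factor(d$parish); d$sex <- factor(d$sex); d$cohort <- factor(d$cohort)
  tmb <- glmmTMB::glmmTMB(
    y ~ proxy + parish + sex + (1 + proxy || cohort),
    ziformula = ~ proxy + parish + sex + (1 + proxy || cohort),
    family = glmmTMB::beta_family(), data = d)
  fx <- glmmTMB::fixef(tmb)
  se <- sqrt(diag(stats::vcov(tmb)$cond))
  sez <- sqrt(diag(stats::vcov(tmb)$zi))

  pairs <- rbind(
    data.frame(p = "beta_intercept", est = fx$cond[["(Intercept)"]], se = se[["(Intercept)"]]),
    data.frame(p = "beta_proxy", est = fx$cond[["proxy"]], se = se[["proxy"]]),
    data.frame(p = "beta_parish_parish_b", est = fx$cond[["parishparish_b"]], se = se[["parishparish_b"]]),
    data.frame(p = "zi_intercept", est = fx$zi[["(Intercept)"]], se = sez[["zi~(Intercept)"]]),
    data.frame(p = "zi_proxy", est = fx$zi[["proxy"]], se = sez[["zi~proxy"]]),
    data.frame(p = "zi_parish_parish_b", est = fx$zi[["parishparish_b"]], se = sez[["zi~parishparish_b"]]))
  for (k in seq_len(nrow(pairs))) {
    med <- s$median[s$parameter == pairs$p[k]]
    expect_lt(abs(med - pairs$est[k]), 4 * pairs$se[k] + 0.05)
  }
})

test_that("a single-cohort null model fits and summarizes cleanly", {
  co <- recovery_coefs()
  co$sd_z <- c(0, 0); co$sd_b <- c(0, 0)
  sim <- simulate_regression_data(300L, co, n_cohorts = 1L, seed = 95L)
  sim$data$cohort <- "only"   # one cohort across both parishes
  prof <- list(chains = 2L, adapt = 150L, burn = 150L, iter = 300L, thin = 1L)
  fit <- fit_zib(sim$data, proxy = "none", mcmc = prof, seed = 96L)
  expect_equal(fit$G, 1L)
  r2 <- bayes_r2(fit)            # exercises the collapsed ub/uz monitors
  expect_true(is.finite(r2$median))
  s <- posterior_summary(fit)
  expect_true(all(is.finite(s$median)))
})
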