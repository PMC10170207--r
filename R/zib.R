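#' MCMC sampler settings
#'
#' The `"full"` profile mirrors the headline analysis settings (four chains,
#' long warm-up, thinning by 10); `"fast"` is a short profile for tests and
#' simulation studies with the same number of retained draws.
#'
#' @param profile `"full"` or `"fast"`, or a list with elements `chains`,
#'   `adapt`, `burn`, `iter`, `thin`.
#' @return list of sampler settings.
#' @export
mcmc_profile <- function(profile = "fast") {
  if (is.list(profile)) return(profile)
  switch(profile,
    full = list(chains = 4L, adapt = 1000L, burn = 2000L, iter = 4000L, thin = 10L),
    fast = list(chains = 2L, adapt = 400L, burn = 400L, iter = 800L, thin = 1L),
    stop("unknown mcmc profile: ", profile))
}

build_design <- function(data, proxy, interaction, covariates) {
  n <- nrow(data)
  if (!"parish" %in% names(data) || !"sex" %in% names(data) || !"cohort" %in% names(data)) {
    stop("data must contain parish, sex and cohort columns")
  }
  parish <- factor(data$parish)
  sex <- factor(data$sex, levels = c("female", "male"))
  if (anyNA(sex)) stop("sex must be female/male for model rows")
  X <- cbind(intercept = rep(1, n))
  w <- rep(0, n)
  if (proxy != "none") {
    if (!proxy %in% names(data)) stop("proxy column not found: ", proxy)
    w <- as.numeric(data[[proxy]])
    if (anyNA(w)) stop("missing values in proxy ", proxy)
    X <- cbind(X, proxy = w)
  }
  if (nlevels(parish) > 1L) {
    for (lv in levels(parish)[-1L]) {
      X <- cbind(X, stats::setNames(list(as.numeric(parish == lv)), paste0("parish_", lv))[[1]])
      colnames(X)[ncol(X)] <- paste0("parish_", lv)
    }
  }
  # a factor with one observed level carries no information and would make
  # the design rank deficient
  if (length(unique(sex)) > 1L) {
    X <- cbind(X, sex_male = as.numeric(sex == "male"))
  }
  if (interaction) {
    if (nlevels(parish) < 2L || !"sex_male" %in% colnames(X)) {
      stop("sex x parish interaction inestimable: parish or sex has a single level")
    }
    for (lv in levels(parish)[-1L]) {
      X <- cbind(X, stats::setNames(list(as.numeric(parish == lv) * X[, "sex_male"]),
                                    paste0("parish_", lv, ":sex_male"))[[1]])
      colnames(X)[ncol(X)] <- paste0("parish_", lv, ":sex_male")
    }
  }
  for (cv in covariates) {
    if (!cv %in% names(data)) stop("covariate column not found: ", cv)
    v <- as.numeric(data[[cv]])
    if (anyNA(v)) stop("missing values in covariate ", cv)
    X <- cbind(X, stats::setNames(list(v), cv)[[1]])
    colnames(X)[ncol(X)] <- cv
  }
  g <- as.integer(factor(data$cohort))
  list(X = X, w = w, g = g, G = max(g), cohort_levels = levels(factor(data$cohort)))
}

zib_model_string <- function(zero_inflated, random_slope, P) {
  # explicit sums instead of inprod(): markedly faster in JAGS
  lin <- function(b, Xname, row) {
    paste(sprintf("%s[%d] * %s[%s,%d]", b, seq_len(P), Xname, row, seq_len(P)),
          collapse = " + ")
  }
  zi_re <- if (random_slope) "uz[g[i],1] + uz[g[i],2] * w[i]" else "uz[g[i],1]"
  be_re <- if (random_slope) "ub[gp[k],1] + ub[gp[k],2] * wp[k]" else "ub[gp[k],1]"
  nre <- if (random_slope) 2L else 1L
  zi_block <- if (zero_inflated) paste0("
  for (i in 1:n) {
    z[i] ~ dbern(pz[i])
    logit(pz[i]) <- ", lin("bz", "X", "i"), " + ", zi_re, "
  }
  for (j in 1:G) { for (m in 1:", nre, ") { uz[j,m] ~ dnorm(0, tau_uz[m]) } }
  for (m in 1:", nre, ") {
    sd_uz[m] ~ dt(0, 0.16, 3) T(0,)
    tau_uz[m] <- pow(sd_uz[m], -2)
  }
  for (p in 1:P) { bz[p] ~ dnorm(0, 1.0E-4) }
") else ""
  paste0("model {", zi_block, "
  for (k in 1:npos) {
    y[k] ~ dbeta(a1[k], a2[k])
    a1[k] <- mu[k] * phi
    a2[k] <- (1 - mu[k]) * phi
    logit(mu[k]) <- ", lin("bb", "Xp", "k"), " + ", be_re, "
  }
  for (j in 1:G) { for (m in 1:", nre, ") { ub[j,m] ~ dnorm(0, tau_ub[m]) } }
  for (m in 1:", nre, ") {
    sd_ub[m] ~ dt(0, 0.16, 3) T(0,)
    tau_ub[m] <- pow(sd_ub[m], -2)
  }
  for (p in 1:P) { bb[p] ~ dnorm(0, 1.0E-4) }
  lphi ~ dnorm(0, 1.0E-4)
  phi <- exp(lphi)
}")
}

#' Fit a hierarchical (zero-inflated) beta regression
#'
#' The likelihood is a mixture of a point mass at zero, whose probability is
#' logit-linear in the predictors (lineage extinction), and a beta
#' distribution for the nonzero proportions, with a logit link on the mean
#' and an intercept-only log-linked precision. Both parts share the same
#' fixed-effect structure (proxy, parish, sex, optional sex-by-parish
#' interaction, optional extra covariates) and each part has its own random
#' intercept and random proxy slope by parish-specific birth cohort. Priors
#' are weakly informative: wide normal (sd 100) on fixed effects and
#' half-Student-t(3, scale 2.5) on random-effect standard deviations.
#' Sampled with JAGS; reproducible given `seed`.
#'
#' @param data data frame with the response column, the proxy column, and
#'   `parish`, `sex`, `cohort` (plus any extra covariate columns).
#' @param proxy name of the proxy column, or `"none"` for the null model.
#' @param response name of the response column (values in `[0, 1)`).
#' @param zero_inflated model the zeros (`TRUE`) or require a strictly
#'   positive response (`FALSE`, beta regression).
#' @param interaction include the sex-by-parish interaction.
#' @param covariates extra numeric fixed-effect columns (e.g. parental
#'   lifespan in the bias model).
#' @param mcmc sampler settings from [mcmc_profile()].
#' @param seed integer seed (fans out to per-chain RNG seeds).
#' @param quiet suppress JAGS progress output.
#' @return object of class `zib_fit`: posterior draws (coda `mcmc.list`),
#'   the design, and bookkeeping used by [bayes_r2()], [posterior_summary()]
#'   and [prob_direction()].
#' @export
fit_zib <- function(data, proxy, response = "y", zero_inflated = TRUE,
                    interaction = FALSE, covariates = character(),
                    mcmc = mcmc_profile("fast"), seed = 1L, quiet = TRUE) {
  y <- as.numeric(data[[response]])
  if (anyNA(y) || any(y < 0) || any(y >= 1)) {
    stop("response must lie in [0, 1) with no missing values")
  }
  if (!zero_inflated && any(y == 0)) {
    stop("beta regression requires a strictly positive response; add an offset to zero values")
  }
  des <- build_design(data, proxy, interaction, covariates)
  X <- des$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear term(s): ", paste(bad, collapse = ", "))
  }
  pos <- which(y > 0)
  random_slope <- proxy != "none"

  # centre numeric predictors for the sampler; draws are mapped back to the
  # raw scale afterwards (exact affine identity), so reported coefficients
  # stay per-unit on the original scales
  num_cols <- intersect(c("proxy", covariates), colnames(X))
  ctr <- stats::setNames(numeric(length(num_cols)), num_cols)
  Xc <- X
  for (cn in num_cols) {
    ctr[cn] <- mean(X[, cn])
    Xc[, cn] <- X[, cn] - ctr[cn]
  }

  jd <- list(y = y[pos], Xp = Xc[pos, , drop = FALSE], gp = des$g[pos],
             wp = des$w[pos], npos = length(pos), G = des$G, P = ncol(X))
  if (zero_inflated) {
    jd$z <- as.integer(y == 0)
    jd$X <- Xc
    jd$g <- des$g
    jd$w <- des$w
    jd$n <- length(y)
  }
  if (!random_slope) jd$wp <- NULL
  if (!random_slope && zero_inflated) jd$w <- NULL

  model <- zib_model_string(zero_inflated, random_slope, ncol(X))

  # cheap working estimates give the sampler a sane starting point
  yp <- pmin(pmax(y[pos], 1e-6), 1 - 1e-6)
  bb0 <- tryCatch(unname(stats::coef(stats::lm.fit(Xc[pos, , drop = FALSE], logit(yp)))),
                  error = function(e) numeric(ncol(X)))
  bb0[!is.finite(bb0)] <- 0
  mu0 <- invlogit(drop(Xc[pos, , drop = FALSE] %*% bb0))
  rv <- stats::var(yp - mu0)
  phi0 <- min(max(mean(mu0 * (1 - mu0)) / max(rv, 1e-8) - 1, 1), 1e4)
  inits <- lapply(seq_len(mcmc$chains), function(c) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = split_seed(seed, paste0("chain", c)),
                bb = bb0, lphi = log(phi0))
    if (zero_inflated) {
      bz0 <- tryCatch(unname(stats::coef(stats::glm.fit(Xc, as.integer(y == 0),
                                                        family = stats::binomial()))),
                      error = function(e) numeric(ncol(X)))
      bz0[!is.finite(bz0)] <- 0
      ini$bz <- bz0
    }
    ini
  })
  monitors <- c("bb", "lphi", "sd_ub", "ub")
  if (zero_inflated) monitors <- c(monitors, "bz", "sd_uz", "uz")
  jm <- rjags::jags.model(textConnection(model), data = jd, inits = inits,
                          n.chains = mcmc$chains, n.adapt = mcmc$adapt,
                          quiet = quiet)
  update(jm, mcmc$burn, progress.bar = "none")
  samples <- rjags::coda.samples(jm, monitors, n.iter = mcmc$iter,
                                 thin = mcmc$thin, progress.bar = "none")

  # map intercept draws back to the raw predictor scale
  if (length(num_cols)) {
    ic <- match(num_cols, colnames(X))
    samples <- coda::as.mcmc.list(lapply(samples, function(ch) {
      M <- as.matrix(ch)
      shift <- drop(M[, paste0("bb[", ic, "]"), drop = FALSE] %*% ctr)
      M[, "bb[1]"] <- M[, "bb[1]"] - shift
      if (zero_inflated) {
        shiftz <- drop(M[, paste0("bz[", ic, "]"), drop = FALSE] %*% ctr)
        M[, "bz[1]"] <- M[, "bz[1]"] - shiftz
      }
      coda::mcmc(M, start = stats::start(ch), thin = coda::thin(ch))
    }))
  }

  structure(list(
    samples = samples, X = X, w = des$w, g = des$g, G = des$G,
    y = y, pos = pos, zero_inflated = zero_inflated,
    random_slope = random_slope, proxy = proxy, response = response,
    interaction = interaction, covariates = covariates,
    cohort_levels = des$cohort_levels, data_n = length(y),
    mcmc = mcmc, seed = seed
  ), class = "zib_fit")
}

#' @export
print.zib_fit <- function(x, ...) {
  cat(sprintf("<zib_fit: %s model, proxy = %s, n = %d, %d cohorts, %d draws>\n",
              if (x$zero_inflated) "zero-inflated beta" else "beta",
              x$proxy, x$data_n, x$G,
              coda::niter(x$samples) * coda::nchain(x$samples)))
  invisible(x)
}

# draws as one matrix, columns named as in JAGS monitors
draw_matrix <- function(fit) {
  do.call(rbind, lapply(fit$samples, as.matrix))
}

# human-readable parameter names for the fixed effects and scales
fixed_param_names <- function(fit) {
  p <- colnames(fit$X)
  # JAGS drops the index on length-1 monitored arrays
  sd_b <- if (fit$random_slope) paste0("sd_ub[", 1:2, "]") else "sd_ub"
  sd_z <- if (fit$random_slope) paste0("sd_uz[", 1:2, "]") else "sd_uz"
  lab <- if (fit$random_slope) c("intercept", "slope") else "intercept"
  out <- c(stats::setNames(paste0("bb[", seq_along(p), "]"), paste0("beta_", p)),
           phi = "lphi",
           stats::setNames(sd_b, paste0("sd_beta_", lab)))
  if (fit$zero_inflated) {
    out <- c(out,
             stats::setNames(paste0("bz[", seq_along(p), "]"), paste0("zi_", p)),
             stats::setNames(sd_z, paste0("sd_zi_", lab)))
  }
  out
}

#' Posterior summary table
#'
#' Median, 95 percent credible interval, probability of direction and
#' split-chain R-hat for every fixed effect and random-effect scale.
#'
#' @param fit a [fit_zib()] result.
#' @return data frame with one row per parameter.
#' @export
posterior_summary <- function(fit) {
  nm <- fixed_param_names(fit)
  M <- draw_matrix(fit)
  rhat <- rep(NA_real_, length(nm))
  if (coda::nchain(fit$samples) > 1L) {
    gd <- try(coda::gelman.diag(fit$samples[, unname(nm), drop = FALSE],
                                multivariate = FALSE, autoburnin = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) rhat <- gd$psrf[, 1L]
  }
  D <- M[, unname(nm), drop = FALSE]
  D[, which(nm == "lphi")] <- exp(D[, which(nm == "lphi")])  # report precision, not log
  out <- data.frame(
    parameter = names(nm),
    median = apply(D, 2, stats::median),
    ci_low = apply(D, 2, stats::quantile, 0.025),
    ci_high = apply(D, 2, stats::quantile, 0.975),
    pd = apply(D, 2, function(v) prob_direction(v)$pd),
    rhat = rhat,
    stringsAsFactors = FALSE)
  # scales and phi have a fixed sign; pd is not meaningful there
  out$pd[grepl("^sd_|^phi$", out$parameter)] <- NA_real_
  rownames(out) <- NULL
  out
}

# random-effect columns; JAGS drops the indices on a 1x1 monitored array
re_cols <- function(M, base, G, col) {
  nm <- paste0(base, "[", seq_len(G), ",", col, "]")
  if (all(nm %in% colnames(M))) return(M[, nm, drop = FALSE])
  if (G == 1L && base %in% colnames(M)) return(M[, base, drop = FALSE])
  stop("monitored columns not found for ", base)
}

# per-draw linear predictors over all observations
predictor_draws <- function(fit) {
  M <- draw_matrix(fit)
  P <- ncol(fit$X)
  bb <- M[, paste0("bb[", seq_len(P), "]"), drop = FALSE]
  eta_b <- bb %*% t(fit$X)
  ub0 <- re_cols(M, "ub", fit$G, 1L)
  eta_b <- eta_b + ub0[, fit$g, drop = FALSE]
  if (fit$random_slope) {
    ub1 <- re_cols(M, "ub", fit$G, 2L)
    eta_b <- eta_b + sweep(ub1[, fit$g, drop = FALSE], 2, fit$w, `*`)
  }
  out <- list(mu = invlogit(eta_b), phi = exp(M[, "lphi"]))
  if (fit$zero_inflated) {
    bz <- M[, paste0("bz[", seq_len(P), "]"), drop = FALSE]
    eta_z <- bz %*% t(fit$X)
    uz0 <- re_cols(M, "uz", fit$G, 1L)
    eta_z <- eta_z + uz0[, fit$g, drop = FALSE]
    if (fit$random_slope) {
      uz1 <- re_cols(M, "uz", fit$G, 2L)
      eta_z <- eta_z + sweep(uz1[, fit$g, drop = FALSE], 2, fit$w, `*`)
    }
    out$pi <- invlogit(eta_z)
  }
  out
}

#' Bayesian R-squared
#'
#' Per posterior draw, the variance of the model-implied expected response
#' across observations divided by that variance plus the mean model-implied
#' residual variance. For the zero-inflated model the expected response is
#' `(1 - pi) * mu` and the residual variance is the variance of the mixture
#' of the point mass at zero and the beta component; for the plain beta model
#' they are `mu` and the beta variance.
#'
#' @param fit a [fit_zib()] result.
#' @return object of class `r2_posterior`: list with `draws`, `median`,
#'   `mode` and the 95 percent credible interval.
#' @export
bayes_r2 <- function(fit) {
  pd <- predictor_draws(fit)
  mu <- pd$mu
  phi <- pd$phi
  # phi is per-draw (rows); expand explicitly before mixing with mu
  beta_var <- mu * (1 - mu) / (1 + matrix(phi, nrow(mu), ncol(mu)))
  if (fit$zero_inflated) {
    pi_ <- pd$pi
    pred <- (1 - pi_) * mu
    resid <- (1 - pi_) * (beta_var + mu^2) - pred^2
  } else {
    pred <- mu
    resid <- beta_var
  }
  n <- ncol(pred)
  varfit <- (rowMeans(pred^2) - rowMeans(pred)^2) * n / (n - 1)
  draws <- varfit / (varfit + rowMeans(resid))
  structure(list(draws = draws, median = stats::median(draws),
                 mode = density_mode(draws),
                 ci_low = unname(stats::quantile(draws, 0.025)),
                 ci_high = unname(stats::quantile(draws, 0.975)),
                 data_n = fit$data_n),
            class = "r2_posterior")
}

#' @export
print.r2_posterior <- function(x, ...) {
  cat(sprintf("Bayesian R2: median %.3f [%.3f, %.3f]\n", x$median, x$ci_low, x$ci_high))
  invisible(x)
}

#' Difference between two Bayesian R-squared posteriors
#'
#' Pairs the posterior draws of two models fitted to the same observations
#' and summarizes `R2(A) - R2(B)` by its kernel-density mode and 95 percent
#' credible interval; the difference is called significant when the interval
#' excludes zero.
#'
#' @param r2a,r2b [bayes_r2()] results (or [fit_zib()] results, which are
#'   converted).
#' @return list with `mode`, `ci_low`, `ci_high`, `significant`, `draws`.
#' @export
r2_difference <- function(r2a, r2b) {
  if (inherits(r2a, "zib_fit")) r2a <- bayes_r2(r2a)
  if (inherits(r2b, "zib_fit")) r2b <- bayes_r2(r2b)
  if (r2a$data_n != r2b$data_n) {
    stop("models were fitted to different numbers of observations")
  }
  S <- min(length(r2a$draws), length(r2b$draws))
  d <- r2a$draws[seq_len(S)] - r2b$draws[seq_len(S)]
  ci <- stats::quantile(d, c(0.025, 0.975))
  list(mode = density_mode(d), ci_low = unname(ci[1L]), ci_high = unname(ci[2L]),
       significant = ci[1L] > 0 || ci[2L] < 0, draws = d)
}

#' Probability of direction
#'
#' The share of posterior draws sharing the sign of the posterior median,
#' with the conventional significance reading: below 0.95 not significant,
#' 0.95-0.975 a trend effect, 0.975-0.99 significant, above 0.99 highly
#' significant.
#'
#' @param draws numeric vector of posterior draws (at least 100), or a
#'   `zib_fit` plus `parameter` name from [posterior_summary()].
#' @param parameter parameter name when `draws` is a fit.
#' @return list with `pd` and `class`.
#' @export
prob_direction <- function(draws, parameter = NULL) {
  if (inherits(draws, "zib_fit")) {
    nm <- fixed_param_names(draws)
    if (is.null(parameter) || !parameter %in% names(nm)) {
      stop("parameter must be one of: ", paste(names(nm), collapse = ", "))
    }
    draws <- draw_matrix(draws)[, unname(nm[parameter])]
  }
  if (length(draws) < 100L) stop("at least 100 draws required")
  if (all(draws == 0)) stop("probability of direction undefined for an all-zero posterior")
  m <- stats::median(draws)
  s <- if (m >= 0) 1 else -1
  pd <- mean(sign(draws) == s)
  cls <- if (pd < 0.95) "not significant" else if (pd < 0.975) "trend effect"
         else if (pd < 0.99) "significant" else "highly significant"
  list(pd = pd, class = cls)
}

#' Fit with the sex-by-parish interaction and prune it if non-significant
#'
#' Fits the model including the two-way sex-by-parish interaction; if the
#' interaction's probability of direction stays below 0.975 in every part of
#' the model, refits without it and returns the reduced fit.
#'
#' @inheritParams fit_zib
#' @return list with `fit` (the retained model), `dropped` (logical) and
#'   `interaction_pd` (pd per part).
#' @export
interaction_pruning <- function(data, proxy, response = "y",
                                zero_inflated = TRUE, covariates = character(),
                                mcmc = mcmc_profile("fast"), seed = 1L) {
  fit1 <- fit_zib(data, proxy, response, zero_inflated, interaction = TRUE,
                  covariates = covariates, mcmc = mcmc, seed = seed)
  nm <- fixed_param_names(fit1)
  int_pars <- names(nm)[grepl(":sex_male$", names(nm))]
  pds <- vapply(int_pars, function(p) prob_direction(fit1, p)$pd, numeric(1))
  if (all(pds < 0.975)) {
    fit0 <- fit_zib(data, proxy, response, zero_inflated, interaction = FALSE,
                    covariates = covariates, mcmc = mcmc, seed = seed)
    list(fit = fit0, dropped = TRUE, interaction_pd = pds)
  } else {
    list(fit = fit1, dropped = FALSE, interaction_pd = pds)
  }
}
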