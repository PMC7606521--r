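test_that("multiplicative proposals preserve positivity with the stated moments", {
  cur <- c(mu = 1e-6, nu = 1e-7, s = 1e-4)
  # degenerate scale: identity proposal, zero correction
  pr <- propose_params(cur, lambda = 0)
  expect_equal(pr$proposal, cur)
  expect_equal(pr$log_hastings_correction, 0)

  set.seed(30)
  steps <- replicate(1e5, {
    out <- propose_params(cur["mu"], lambda = 0.05)
    log(out$proposal / cur["mu"])
  })
  expect_equal(mean(steps), 0, tolerance = 3 * 0.05 / sqrt(1e5))
  expect_equal(sd(steps), 0.05, tolerance = 0.01)
  set.seed(31)
  props <- replicate(2000, propose_params(cur, 0.5)$proposal)
  expect_true(all(props > 0))
})

test_that("prior-only chains sample the exponential priors; dropping the Hastings correction is biased", {
  fit <- run_mcmc(NULL, prior_spec(),
                  mcmc_config(n_iter = 1e5, thin = 50, seed = 1, ne = 5e4),
                  likelihood = FALSE)
  expect_equal(mean(fit$samples[, "mu"]), 1e-5, tolerance = 0.05)
  expect_equal(mean(fit$samples[, "nu"]), 1e-5, tolerance = 0.05)
  expect_equal(mean(fit$samples[, "s"]), 1e-2, tolerance = 0.05)

  # regression oracle: the same multiplicative walk without the
  # log(proposed/current) correction targets density proportional to
  # pi(theta)/theta, which is improper at 0 -- the chain collapses toward
  # zero instead of sampling the exponential prior
  set.seed(2)
  rate <- 1e5
  cur <- 1 / rate
  keep <- numeric(2000)
  for (i in 1:1e5) {
    stp <- rnorm(1, 0, 0.5)
    prop <- cur * exp(stp)
    if (log(runif(1)) < -rate * (prop - cur)) cur <- prop  # correction omitted
    if (i %% 50 == 0) keep[i / 50] <- cur
  }
  biased_mean <- mean(keep[(length(keep) / 5):length(keep)])
  expect_lt(biased_mean, 0.25 / rate)   # far below the true prior mean 1/rate
})

test_that("chains are deterministic given the seed and the accounting matches", {
  sp <- msfs(10, c(40, 8, 3, 2, 1, 1, 1, 2, 3, 9, 30))
  cfg <- mcmc_config(n_iter = 2000, thin = 10, seed = 99, ne = 5e4)
  f1 <- run_mcmc(sp, prior_spec(), cfg)
  f2 <- run_mcmc(sp, prior_spec(), cfg)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$acceptance_rate, f2$acceptance_rate)
  expect_equal(nrow(f1$samples), retained_samples(cfg))
  expect_equal(retained_samples(mcmc_config()), 1600L)
  # burnin/thin bookkeeping on an odd configuration
  cfg2 <- mcmc_config(n_iter = 1001, burnin_frac = 0.3, thin = 7, seed = 1)
  expect_equal(retained_samples(cfg2), as.integer(floor(1001 * 0.7 / 7)))
})

test_that("posterior summaries have the closed-form moments", {
  samples <- cbind(mu = c(1, 2, 3, 4), nu = rep(2, 4), s = c(1, 1, 2, 2))
  s <- posterior_summary(samples, ne = 10)
  expect_equal(s$mean[s$parameter == "mu"], 2.5)
  expect_equal(s$sd[s$parameter == "mu"], sd(c(1, 2, 3, 4)))
  expect_equal(s$sd[s$parameter == "nu"], 0)
  expect_equal(s$q2.5[s$parameter == "nu"], 2)
  expect_equal(s$q97.5[s$parameter == "nu"], 2)
  # ne_s: mean is linear in ne, quantiles computed on per-sample products
  expect_equal(s$mean[s$parameter == "ne_s"],
               10 * s$mean[s$parameter == "s"])
  expect_equal(s$q2.5[s$parameter == "ne_s"],
               unname(quantile(10 * samples[, "s"], 0.025)))
})

test_that("parameters are recovered from synthetic spectra at reduced scale", {
  # truth: alpha 0.72, beta 0.036, Ne*s = 2 at Ne = 50,000
  p <- cg_truth_params()
  for (r in 1:3) {
    q <- simulate_tile_frequencies(p, 20000, seed = 300 + r)
    set.seed(400 + r)
    k <- rbinom(20000, 40, q)
    sp <- msfs(40, tabulate(k + 1, nbins = 41))
    fit <- run_mcmc(sp, prior_spec(),
                    mcmc_config(n_iter = 60000, thin = 50, seed = 500 + r,
                                ne = 5e4))
    s <- fit$summary
    expect_equal(s$mean[s$parameter == "alpha"], 0.72, tolerance = 0.25)
    expect_equal(s$mean[s$parameter == "beta"], 0.036, tolerance = 0.25)
    expect_equal(s$mean[s$parameter == "ne_s"], 2.0, tolerance = 0.25)
  }
})

test_that("acceptance rates stay in a workable band across the published lambda grid", {
  p <- cg_truth_params()
  q <- simulate_tile_frequencies(p, 2000, seed = 310)
  set.seed(410)
  k <- rbinom(2000, 40, q)
  sp <- msfs(40, tabulate(k + 1, nbins = 41))
  for (lam in c(0.01, 0.05, 0.1)) {
    fit <- run_mcmc(sp, prior_spec(),
                    mcmc_config(n_iter = 20000, thin = 20, lambda = lam,
                                seed = 600, ne = 5e4))
    expect_gt(fit$acceptance_rate, 0.05)
    expect_lt(fit$acceptance_rate, 0.8)
  }
})

test_that("the Ne grid leaves scaled parameters invariant while s scales as 1/Ne", {
  p <- cg_truth_params()
  q <- simulate_tile_frequencies(p, 20000, seed = 320)
  set.seed(420)
  k <- rbinom(20000, 40, q)
  sp <- msfs(40, tabulate(k + 1, nbins = 41))
  cfg <- mcmc_config(n_iter = 60000, thin = 50, seed = 7, ne = 5e4)
  grid <- ne_grid_fit(sp, prior_spec(), cfg, ne_grid = c(5e4, 1e6))
  tb <- grid$table
  nes <- tb$mean[tb$parameter == "ne_s"]
  expect_equal(nes[1], nes[2], tolerance = 0.25)
  alphas <- tb$mean[tb$parameter == "alpha"]
  expect_equal(alphas[1], alphas[2], tolerance = 0.2)
  ss <- tb$mean[tb$parameter == "s"]
  expect_equal(ss[1] / ss[2], 20, tolerance = 0.25)
  # a one-point grid is just run_mcmc with the derived seed
  g1 <- ne_grid_fit(sp, prior_spec(), cfg, ne_grid = 5e4)
  cfg1 <- cfg
  cfg1$seed <- epimsfs:::.child_seed(cfg$seed, 1L)
  expect_identical(g1$fits[[1]]$samples, run_mcmc(sp, prior_spec(), cfg1)$samples)
})

test_that("signed selection support explores both signs under the prior", {
  fit <- run_mcmc(NULL, prior_spec(s_support = "signed"),
                  mcmc_config(n_iter = 4e4, thin = 20, seed = 5, ne = 5e4),
                  likelihood = FALSE)
  s <- fit$samples[, "s"]
  expect_gt(mean(s > 0), 0.2)
  expect_gt(mean(s < 0), 0.2)
  expect_equal(mean(abs(s)), 1e-2, tolerance = 0.15)
})

test_that("posterior serialization echoes the configuration", {
  sp <- msfs(4, c(5, 1, 1, 1, 5))
  fit <- run_mcmc(sp, prior_spec(),
                  mcmc_config(n_iter = 500, thin = 5, seed = 3, ne = 1e4))
  p <- tempfile(fileext = ".json")
  write_posterior(fit, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$config$n_iter, 500)
  expect_equal(back$config$ne, 1e4)
  expect_equal(nrow(back$samples), nrow(fit$samples))
})
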