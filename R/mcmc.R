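# Metropolis-Hastings sampler for (mu, nu, s) given a fixed Ne and one or
# more observed mSFS. Proposals are multiplicative log-normal random walks
# (each rate multiplied by exp(lambda * z), z standard normal), which keep
# the rates positive; the Hastings correction for this asymmetric proposal
# is sum(log(proposed/current)). Priors are exponential with user-set
# rates. The published chain design -- 1,000,000 iterations, first 20%
# burnin, 1600 retained samples (thin 500) -- is the default configuration.

#' Exponential prior specification
#'
#' Prior rates, not means: `rate = 1e5` puts the prior mean at `1e-5`.
#' Defaults place the epimutation-rate priors near the genome-wide
#' estimates and leave selection weakly constrained.
#'
#' @param rate_mu,rate_nu,rate_s Positive exponential rates.
#' @param s_support `"nonnegative"` (exponential prior on s) or `"signed"`
#'   (symmetric two-sided exponential with a sign-flip proposal move).
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(rate_mu = 1e5, rate_nu = 1e5, rate_s = 1e2,
                       s_support = c("nonnegative", "signed")) {
  s_support <- match.arg(s_support)
  stopifnot(rate_mu > 0, rate_nu > 0, rate_s > 0)
  structure(list(rate_mu = rate_mu, rate_nu = rate_nu, rate_s = rate_s,
                 s_support = s_support),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' @param n_iter Chain length (default 1,000,000).
#' @param burnin_frac Fraction of the chain discarded as burnin (default
#'   0.2).
#' @param thin Keep every `thin`-th post-burnin iteration (default 500;
#'   with the default chain length this retains exactly 1600 samples).
#' @param lambda Scale of the multiplicative proposal (sd of the log-step).
#' @param seed Integer seed; identical seeds give bit-identical chains.
#' @param ne Effective population size fixed during the fit.
#' @return An `mcmc_config` object.
#' @export
mcmc_config <- function(n_iter = 1e6, burnin_frac = 0.2, thin = 500L,
                        lambda = 0.05, seed = 1L, ne = 50000) {
  stopifnot(n_iter >= 1, burnin_frac >= 0, burnin_frac < 1, thin >= 1,
            lambda >= 0, ne > 0)
  structure(list(n_iter = as.integer(n_iter), burnin_frac = burnin_frac,
                 thin = as.integer(thin), lambda = lambda,
                 seed = as.integer(seed), ne = ne),
            class = "mcmc_config")
}

#' Number of samples a configuration retains
#'
#' `floor(n_iter * (1 - burnin_frac) / thin)`; 1600 for the default
#' configuration.
#'
#' @param config An `mcmc_config`.
#' @return Integer count.
#' @export
retained_samples <- function(config) {
  as.integer(floor(config$n_iter * (1 - config$burnin_frac) / config$thin))
}

#' One multiplicative random-walk proposal
#'
#' Each rate is multiplied by `exp(lambda * z)` with independent standard
#' normal `z`; the log Hastings correction `sum(log(proposed/current))`
#' must be added to the log acceptance ratio.
#'
#' @param current Named numeric vector `c(mu, nu, s)`, all positive.
#' @param lambda Proposal scale.
#' @param z Optional fixed standard-normal vector (for reproducibility in
#'   tests); drawn internally when `NULL`.
#' @return List with `proposal` and `log_hastings_correction`.
#' @export
propose_params <- function(current, lambda, z = NULL) {
  stopifnot(all(current > 0), lambda >= 0)
  if (is.null(z)) z <- stats::rnorm(length(current))
  step <- lambda * z
  list(proposal = current * exp(step), log_hastings_correction = sum(step))
}

#' Run the Metropolis--Hastings sampler
#'
#' Log target = mSFS log-likelihood (via the exact series evaluation of the
#' sampling probabilities) + exponential log-priors. The chain starts at
#' the prior means; if the target is not finite there, it re-initializes
#' from prior draws (up to 100 attempts). Deterministic given
#' `config$seed`.
#'
#' @param msfs_obs An `msfs` or list of `msfs` sharing parameters.
#' @param prior A `prior_spec`.
#' @param config An `mcmc_config`.
#' @param likelihood If `FALSE`, sample the prior only (used to validate
#'   the proposal/correction machinery).
#' @return An `mcmc_posterior`: retained `samples` matrix (columns mu, nu,
#'   s), `acceptance_rate`, `config`, `prior`, and the `summary` table from
#'   [posterior_summary()].
#' @export
run_mcmc <- function(msfs_obs, prior = prior_spec(), config = mcmc_config(),
                     likelihood = TRUE) {
  stopifnot(inherits(prior, "prior_spec"), inherits(config, "mcmc_config"))
  if (inherits(msfs_obs, "msfs")) msfs_obs <- list(msfs_obs)
  if (likelihood) {
    stopifnot(length(msfs_obs) > 0,
              all(vapply(msfs_obs, inherits, TRUE, "msfs")))
    counts_list <- lapply(msfs_obs, `[[`, "counts")
    m_list <- lapply(msfs_obs, `[[`, "m")
  }
  ne <- config$ne
  rates <- c(prior$rate_mu, prior$rate_nu, prior$rate_s)
  signed <- prior$s_support == "signed"

  log_prior <- function(p) {
    # exponential on mu, nu; exponential or symmetric two-sided on s
    lp <- log(rates[1]) - rates[1] * p[1] + log(rates[2]) - rates[2] * p[2]
    if (signed) {
      lp + log(rates[3] / 2) - rates[3] * abs(p[3])
    } else {
      lp + log(rates[3]) - rates[3] * p[3]
    }
  }
  log_lik <- function(p) {
    total <- 0
    for (i in seq_along(counts_list)) {
      m <- m_list[[i]]
      k <- 0:m
      a <- 4 * ne * p[1]
      b <- 4 * ne * p[2]
      g <- 4 * ne * p[3]
      lpk <- lchoose(m, k) + lbeta(b + k, a + m - k) +
        .log_kummer(b + k, a + b + m, g) -
        (lbeta(b, a) + .log_kummer(b, a + b, g))
      lpk[!is.finite(lpk)] <- -1e10
      cnt <- counts_list[[i]]
      nz <- cnt > 0
      total <- total + sum(cnt[nz] * lpk[nz])
    }
    total
  }
  log_target <- if (likelihood) {
    function(p) log_lik(p) + log_prior(p)
  } else {
    log_prior
  }

  n_iter <- config$n_iter
  n_burn <- floor(n_iter * config$burnin_frac)
  n_keep <- retained_samples(config)

  res <- .with_seed(config$seed, {
    cur <- c(1 / rates[1], 1 / rates[2],
             if (signed) 1 / rates[3] else 1 / rates[3])
    cur_lt <- log_target(cur)
    attempts <- 0L
    while (!is.finite(cur_lt) && attempts < 100L) {
      cur <- c(stats::rexp(1, rates[1]), stats::rexp(1, rates[2]),
               stats::rexp(1, rates[3]))
      cur_lt <- log_target(cur)
      attempts <- attempts + 1L
    }
    if (!is.finite(cur_lt)) {
      stop("could not find a finite-target initial state in 100 attempts")
    }
    Z <- matrix(stats::rnorm(n_iter * 3L), n_iter, 3L)
    log_u <- log(stats::runif(n_iter))
    flip <- if (signed) stats::runif(n_iter) < 0.1 else rep(FALSE, n_iter)
    keep <- matrix(NA_real_, n_keep, 3L,
                   dimnames = list(NULL, c("mu", "nu", "s")))
    ki <- 0L
    n_acc <- 0L
    lambda <- config$lambda
    thin <- config$thin
    for (i in seq_len(n_iter)) {
      step <- lambda * Z[i, ]
      prop <- cur * exp(step)
      if (flip[i]) prop[3] <- -prop[3]   # symmetric move; no extra correction
      prop_lt <- log_target(prop)
      if (log_u[i] < prop_lt - cur_lt + sum(step)) {
        cur <- prop
        cur_lt <- prop_lt
        n_acc <- n_acc + 1L
      }
      if (i > n_burn && (i - n_burn) %% thin == 0L && ki < n_keep) {
        ki <- ki + 1L
        keep[ki, ] <- cur
      }
    }
    list(keep = keep[seq_len(ki), , drop = FALSE], acc = n_acc / n_iter)
  })

  out <- structure(list(samples = res$keep, acceptance_rate = res$acc,
                        config = config, prior = prior),
                   class = "mcmc_posterior")
  out$summary <- posterior_summary(out, ne)
  out
}

#' Posterior summaries of retained samples
#'
#' Means, SDs and central 95% credible intervals for each rate parameter
#' and for the scaled parameters `4*ne*mu`, `4*ne*nu` and `ne*s` (products
#' computed per sample, then summarized).
#'
#' @param samples An `mcmc_posterior` or a numeric matrix with columns mu,
#'   nu, s.
#' @param ne Effective population size used for the scaled parameters.
#' @return Data frame, one row per (scaled) parameter.
#' @export
posterior_summary <- function(samples, ne) {
  if (inherits(samples, "mcmc_posterior")) samples <- samples$samples
  stopifnot(is.matrix(samples), ncol(samples) == 3L, nrow(samples) >= 2L)
  mat <- cbind(mu = samples[, 1], nu = samples[, 2], s = samples[, 3],
               alpha = 4 * ne * samples[, 1], beta = 4 * ne * samples[, 2],
               ne_s = ne * samples[, 3])
  data.frame(
    parameter = colnames(mat),
    mean = apply(mat, 2, mean),
    sd = apply(mat, 2, stats::sd),
    q2.5 = apply(mat, 2, stats::quantile, probs = 0.025),
    q97.5 = apply(mat, 2, stats::quantile, probs = 0.975),
    row.names = NULL)
}

#' @export
print.mcmc_posterior <- function(x, ...) {
  cat(sprintf("MCMC posterior: %d retained samples (Ne = %g, acceptance %.3f)\n",
              nrow(x$samples), x$config$ne, x$acceptance_rate))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Fit the same spectrum across a grid of effective population sizes
#'
#' Runs an independent chain per `ne` value with seeds derived as
#' `config$seed + index`. Because only the scaled parameters are
#' identifiable, posterior `4*ne*mu`, `4*ne*nu` and `ne*s` should agree
#' across the grid while the raw rates scale as `1/ne`.
#'
#' @param msfs_obs An `msfs` or list of them.
#' @param prior A `prior_spec`.
#' @param config An `mcmc_config`; its `ne` and `seed` are overridden per
#'   grid point.
#' @param ne_grid Numeric vector of Ne values.
#' @return List with `fits` (one `mcmc_posterior` per Ne) and `table`
#'   (row-bound summaries with an `ne` column).
#' @export
ne_grid_fit <- function(msfs_obs, prior = prior_spec(), config = mcmc_config(),
                        ne_grid = c(5e4, 1e5, 5e5, 1e6)) {
  stopifnot(length(ne_grid) >= 1)
  fits <- vector("list", length(ne_grid))
  names(fits) <- format(ne_grid, scientific = FALSE, trim = TRUE)
  rows <- list()
  for (i in seq_along(ne_grid)) {
    cfg <- config
    cfg$ne <- ne_grid[i]
    cfg$seed <- .child_seed(config$seed, i)
    fits[[i]] <- run_mcmc(msfs_obs, prior, cfg)
    rows[[i]] <- cbind(ne = ne_grid[i], fits[[i]]$summary)
  }
  list(fits = fits, table = do.call(rbind, rows))
}

#' Serialize a posterior (config echo + retained samples) to JSON
#'
#' @param x An `mcmc_posterior`.
#' @param path File path.
#' @export
write_posterior <- function(x, path) {
  stopifnot(inherits(x, "mcmc_posterior"))
  jsonlite::write_json(
    list(config = unclass(x$config), prior = unclass(x$prior),
         acceptance_rate = x$acceptance_rate,
         summary = x$summary,
         samples = as.data.frame(x$samples)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
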