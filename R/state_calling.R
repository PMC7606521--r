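# Discrete epigenotype calling. Pooled tile methylation levels are modelled
# as a normal mixture -- unmethylated, heterozygous, methylated components
# for outbred diploids (k = 3), unmethylated/methylated for inbred lines
# (k = 2) -- fitted by EM. Classification thresholds come either from the
# crossing points of adjacent weighted component densities or from the
# fixed cutoffs used in the maize analysis (0.3/0.7 outbred, 0.5 inbred).

#' Fit a k-component normal mixture by EM
#'
#' Means are initialized at spread quantiles (5/50/95th for k = 3, 5/95th
#' for k = 2), weights equal, all component sds at half the sample sd.
#' Variances are floored at `var_floor` to prevent collapse onto single
#' points. Convergence when the log-likelihood gain drops below `tol`.
#'
#' @param levels Numeric vector of methylation levels in `[0, 1]`; missing
#'   values are dropped. At least `10 * k` finite values required.
#' @param k Number of components (1, 2 or 3).
#' @param seed Seed controlling optional random restarts.
#' @param n_restarts Additional random-initialization restarts; the best
#'   log-likelihood wins. Default 1.
#' @param max_iter,tol EM stopping rule.
#' @param var_floor Minimum component variance.
#' @return A `mixture_fit`: list with `k`, `weights`, `means` (ascending),
#'   `sds`, `loglik`, `loglik_trace`, `converged`, `n_iter`.
#' @export
fit_mixture <- function(levels, k, seed = 1L, n_restarts = 1L,
                        max_iter = 1000L, tol = 1e-6, var_floor = 1e-4) {
  x <- levels[is.finite(levels)]
  stopifnot(k >= 1L, k <= 3L)
  if (length(x) < 10L * k) {
    stop("need at least ", 10L * k, " finite values to fit ", k, " components")
  }
  degenerate <- stats::sd(x) < sqrt(var_floor) / 10 || length(unique(x)) == 1L
  if (k == 1L) {
    m <- mean(x)
    v <- max(stats::var(x) * (length(x) - 1) / length(x), var_floor)
    fit <- list(k = 1L, weights = 1, means = m, sds = sqrt(v),
                loglik = sum(stats::dnorm(x, m, sqrt(v), log = TRUE)),
                loglik_trace = numeric(), converged = !degenerate,
                n_iter = 0L)
    class(fit) <- "mixture_fit"
    return(fit)
  }
  if (degenerate) {
    m <- rep(mean(x), k)
    fit <- list(k = k, weights = rep(1 / k, k), means = m,
                sds = rep(sqrt(var_floor), k), loglik = NA_real_,
                loglik_trace = numeric(), converged = FALSE, n_iter = 0L)
    class(fit) <- "mixture_fit"
    return(fit)
  }
  probs <- if (k == 3L) c(0.05, 0.50, 0.95) else c(0.05, 0.95)
  inits <- list(list(means = as.numeric(stats::quantile(x, probs)),
                     sds = rep(max(stats::sd(x) / 2, sqrt(var_floor)), k),
                     weights = rep(1 / k, k)))
  if (n_restarts > 0L) {
    restart_means <- .with_seed(seed, {
      lapply(seq_len(n_restarts), function(r) sort(stats::runif(k)))
    })
    for (r in seq_len(n_restarts)) {
      inits[[r + 1L]] <- list(
        means = restart_means[[r]],
        sds = rep(max(stats::sd(x) / 2, sqrt(var_floor)), k),
        weights = rep(1 / k, k))
    }
  }
  best <- NULL
  for (init in inits) {
    fit <- .em_normal(x, init, max_iter, tol, var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$k <- k
  class(best) <- "mixture_fit"
  best
}

# Core EM loop; responsibilities in log space for stability.
.em_normal <- function(x, init, max_iter, tol, var_floor) {
  n <- length(x)
  k <- length(init$means)
  mu <- init$means
  sd_ <- init$sds
  w <- init$weights
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    lg <- vapply(seq_len(k), function(j) {
      log(w[j]) + stats::dnorm(x, mu[j], sd_[j], log = TRUE)
    }, numeric(n))
    mrow <- apply(lg, 1L, max)
    lse <- mrow + log(rowSums(exp(lg - mrow)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    resp <- exp(lg - lse)
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- colSums(resp * (outer(x, mu, "-")^2)) / nk
    sd_ <- sqrt(pmax(v, var_floor))
  }
  o <- order(mu)
  list(weights = w[o], means = mu[o], sds = sd_[o], loglik = trace[length(trace)],
       loglik_trace = trace, converged = converged, n_iter = it)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("%d-component normal mixture (%s, %d EM iterations, loglik %.3f)\n",
              x$k, if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$loglik))
  print(round(rbind(weight = x$weights, mean = x$means, sd = x$sds), 4))
  invisible(x)
}

#' Derive classification thresholds from a mixture fit
#'
#' Thresholds are the crossing points of adjacent weighted component
#' densities, located by a grid scan plus `uniroot` refinement on each
#' interval between consecutive component means. When the fit has not
#' converged, or a crossing is absent or falls outside `(0, 1)`, the
#' thresholds fall back to the fixed values 0.3/0.7 (outbred) and 0.5
#' (inbred) used in the published analysis.
#'
#' @param fit A `mixture_fit` with `k` of 2 or 3.
#' @return A `calling_thresholds`: list with `t_low`, `t_high`,
#'   `inbred_cut`, `source` (`"em"` or `"fallback"`).
#' @export
derive_thresholds <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!fit$k %in% c(2L, 3L)) stop("thresholds require a 2- or 3-component fit")
  fallback <- structure(list(t_low = 0.3, t_high = 0.7, inbred_cut = 0.5,
                             source = "fallback"),
                        class = "calling_thresholds")
  if (!isTRUE(fit$converged)) {
    warning("mixture fit did not converge; using fixed fallback thresholds")
    return(fallback)
  }
  crossings <- vapply(seq_len(fit$k - 1L), function(j) {
    .density_crossing(fit$weights[j], fit$means[j], fit$sds[j],
                      fit$weights[j + 1L], fit$means[j + 1L], fit$sds[j + 1L])
  }, numeric(1))
  if (any(!is.finite(crossings) | crossings <= 0 | crossings >= 1)) {
    warning("no density crossing inside (0, 1); using fixed fallback thresholds")
    return(fallback)
  }
  if (fit$k == 3L) {
    structure(list(t_low = crossings[1], t_high = crossings[2],
                   inbred_cut = 0.5, source = "em"),
              class = "calling_thresholds")
  } else {
    structure(list(t_low = 0.3, t_high = 0.7, inbred_cut = crossings[1],
                   source = "em"),
              class = "calling_thresholds")
  }
}

# Crossing of two weighted normal densities between their means: grid scan
# for a sign change of the log-density difference, then uniroot.
.density_crossing <- function(w1, m1, s1, w2, m2, s2) {
  if (m2 <= m1) return(NA_real_)
  f <- function(x) {
    (log(w1) + stats::dnorm(x, m1, s1, log = TRUE)) -
      (log(w2) + stats::dnorm(x, m2, s2, log = TRUE))
  }
  grid <- seq(m1, m2, length.out = 512L)
  fx <- f(grid)
  sgn <- which(fx[-length(fx)] > 0 & fx[-1L] <= 0)
  if (!length(sgn)) return(NA_real_)
  i <- sgn[1]
  stats::uniroot(f, c(grid[i], grid[i + 1L]), tol = 1e-10)$root
}

#' Fixed calling thresholds
#'
#' @param t_low,t_high Outbred cutoffs, `0 < t_low < t_high < 1`.
#' @param inbred_cut Inbred cutoff in `(0, 1)`.
#' @return A `calling_thresholds` object.
#' @export
calling_thresholds <- function(t_low = 0.3, t_high = 0.7, inbred_cut = 0.5) {
  stopifnot(t_low > 0, t_high < 1, t_low < t_high,
            inbred_cut > 0, inbred_cut < 1)
  structure(list(t_low = t_low, t_high = t_high, inbred_cut = inbred_cut,
                 source = "fixed"),
            class = "calling_thresholds")
}

#' Call discrete epigenotypes from tile levels
#'
#' Outbred diploids: level `> t_high` is a methylated call (2), `< t_low`
#' unmethylated (0), otherwise heterozygous (1). Inbred lines: level
#' `> inbred_cut` is methylated (1), else unmethylated (0). Inequalities
#' are strict, so boundary values fall to the middle/unmethylated class;
#' missing levels propagate to missing calls.
#'
#' @param tiles A `tile_matrix`.
#' @param thr A `calling_thresholds` object.
#' @param ploidy_mode `"outbred"` or `"inbred"`.
#' @return A `call_matrix`: list with `tiles`, `calls` (integer matrix,
#'   0/1/2 or 0/1 with NA), `ploidy_mode`, `context`.
#' @export
call_states <- function(tiles, thr = calling_thresholds(),
                        ploidy_mode = c("outbred", "inbred")) {
  ploidy_mode <- match.arg(ploidy_mode)
  stopifnot(inherits(tiles, "tile_matrix"), inherits(thr, "calling_thresholds"))
  lev <- tiles$levels
  calls <- matrix(NA_integer_, nrow(lev), ncol(lev), dimnames = dimnames(lev))
  ok <- is.finite(lev)
  if (ploidy_mode == "outbred") {
    calls[ok] <- 1L
    calls[ok & lev > thr$t_high] <- 2L
    calls[ok & lev < thr$t_low] <- 0L
  } else {
    calls[ok] <- 0L
    calls[ok & lev > thr$inbred_cut] <- 1L
  }
  call_matrix(tiles$tiles, calls, ploidy_mode, tiles$context)
}

#' Epigenotype call matrix
#'
#' @param tiles Tile coordinate data frame (chrom, start, end).
#' @param calls Integer matrix of calls; 0/1/2 (+NA) for outbred,
#'   0/1 (+NA) for inbred.
#' @param ploidy_mode `"outbred"` or `"inbred"`.
#' @param context Methylation context label.
#' @return An object of class `call_matrix`.
#' @export
call_matrix <- function(tiles, calls, ploidy_mode = c("outbred", "inbred"),
                        context = "CG") {
  ploidy_mode <- match.arg(ploidy_mode)
  stopifnot(is.matrix(calls), nrow(calls) == nrow(tiles))
  vals <- calls[!is.na(calls)]
  allowed <- if (ploidy_mode == "outbred") 0:2 else 0:1
  if (length(vals) && !all(vals %in% allowed)) {
    stop("calls must be in {", paste(allowed, collapse = ","), "} or NA")
  }
  structure(list(tiles = tiles, calls = calls, ploidy_mode = ploidy_mode,
                 context = context),
            class = "call_matrix")
}

#' @export
print.call_matrix <- function(x, ...) {
  cat(sprintf("call_matrix: %d tiles x %d individuals (%s, %s, %.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls), x$ploidy_mode, x$context,
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Sensitivity of the mSFS to the calling cutoffs
#'
#' Re-calls states under each cutoff pair, rebuilds the (normalized) mSFS,
#' and reports pairwise total-variation distances
#' \eqn{TV(p, q) = \frac{1}{2}\sum_k |p_k - q_k|}. Small distances mean the
#' spectrum is insensitive to the exact thresholds.
#'
#' @param tiles A `tile_matrix` (outbred interpretation).
#' @param cutoff_grid List of `c(t_low, t_high)` pairs (at least 2).
#' @param missing_policy Passed to [build_msfs()].
#' @return Symmetric matrix of TV distances with zero diagonal, labelled by
#'   cutoff pair.
#' @export
cutoff_sensitivity <- function(tiles, cutoff_grid,
                               missing_policy = "drop") {
  stopifnot(length(cutoff_grid) >= 2L)
  spectra <- lapply(cutoff_grid, function(co) {
    thr <- calling_thresholds(t_low = co[1], t_high = co[2])
    sp <- build_msfs(call_states(tiles, thr, "outbred"),
                     missing_policy = missing_policy)
    sp$counts / sum(sp$counts)
  })
  labs <- vapply(cutoff_grid, function(co) {
    sprintf("(%g,%g)", co[1], co[2])
  }, "")
  n <- length(spectra)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- 0.5 * sum(abs(spectra[[i]] - spectra[[j]]))
    }
  }
  d
}
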