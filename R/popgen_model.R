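# Stationary distribution of the methylated-epiallele frequency q at a
# hypermutable locus under forward epimutation (gain, rate mu), backward
# epimutation (loss, rate nu), genic selection s, and drift at effective
# population size Ne:
#
#   phi(q) = C e^{gamma q} (1-q)^(alpha-1) q^(beta-1),
#   alpha = 4 Ne mu,  beta = 4 Ne nu,  gamma = 4 Ne s,
#
# with C chosen so phi integrates to 1 on (0,1). Only the scaled parameters
# (alpha, beta, gamma) are identifiable from frequency data; Ne is fixed by
# the analyst. Note the exponent assignment is kept exactly as used for the
# maize analysis this package re-implements: the gain rate scales the
# exponent on (1-q) and the loss rate the exponent on q. `swap_exponents`
# selects the conventional mutation-drift assignment instead.

#' Model parameters for the stationary epiallele-frequency density
#'
#' @param mu Forward epimutation rate (methylation gain) per tile per
#'   generation; `> 0`.
#' @param nu Backward epimutation rate (methylation loss); `> 0`.
#' @param s Selection coefficient per methylated tile (can be negative).
#' @param ne Effective population size; `> 0`.
#' @param swap_exponents If `TRUE`, use the conventional assignment in which
#'   `alpha = 4*ne*mu` scales the exponent on `q` rather than on `1 - q`.
#'   Default `FALSE` reproduces the published form.
#' @return An object of class `model_params`. The scaled parameters are
#'   always derived on access via [scaled_params()], never stored.
#' @seealso [params_from_scaled()], [log_density()], [expected_sfs()]
#' @examples
#' p <- model_params(mu = 3.6e-6, nu = 1.8e-7, s = 4e-5, ne = 5e4)
#' scaled_params(p)  # alpha 0.72, beta 0.036, gamma 8
#' @export
model_params <- function(mu, nu, s, ne, swap_exponents = FALSE) {
  stopifnot(is.numeric(mu), is.numeric(nu), is.numeric(s), is.numeric(ne),
            length(mu) == 1L, length(nu) == 1L, length(s) == 1L,
            length(ne) == 1L)
  if (!(mu > 0) || !(nu > 0)) stop("epimutation rates mu and nu must be > 0")
  if (!(ne > 0)) stop("ne must be > 0")
  structure(list(mu = mu, nu = nu, s = s, ne = ne,
                 swap_exponents = isTRUE(swap_exponents)),
            class = "model_params")
}

#' Construct model parameters from scaled values
#'
#' Inverse of [scaled_params()]: given `(alpha, beta, gamma)` and an assumed
#' `ne`, returns the per-generation rates `mu = alpha/(4 ne)` etc.
#'
#' @param alpha,beta Scaled epimutation rates, `> 0`.
#' @param gamma Scaled selection coefficient `4*ne*s`.
#' @inheritParams model_params
#' @return A `model_params` object.
#' @export
params_from_scaled <- function(alpha, beta, gamma, ne, swap_exponents = FALSE) {
  model_params(mu = alpha / (4 * ne), nu = beta / (4 * ne),
               s = gamma / (4 * ne), ne = ne, swap_exponents = swap_exponents)
}

#' Scaled parameters (alpha, beta, gamma)
#'
#' @param params A `model_params` object.
#' @return Named numeric vector `c(alpha, beta, gamma)` with
#'   `alpha = 4*ne*mu`, `beta = 4*ne*nu`, `gamma = 4*ne*s`.
#' @export
scaled_params <- function(params) {
  stopifnot(inherits(params, "model_params"))
  c(alpha = 4 * params$ne * params$mu,
    beta  = 4 * params$ne * params$nu,
    gamma = 4 * params$ne * params$s)
}

#' @export
print.model_params <- function(x, ...) {
  sp <- scaled_params(x)
  cat(sprintf("Stationary-model parameters (Ne = %g%s)\n", x$ne,
              if (x$swap_exponents) ", swapped exponents" else ""))
  cat(sprintf("  mu = %.4g  nu = %.4g  s = %.4g\n", x$mu, x$nu, x$s))
  cat(sprintf("  alpha = %.4g  beta = %.4g  gamma = %.4g  (Ne x s = %.4g)\n",
              sp[1], sp[2], sp[3], x$ne * x$s))
  invisible(x)
}

# Density exponents on (1-q) and q respectively, honouring swap_exponents.
.density_exponents <- function(params) {
  sp <- scaled_params(params)
  if (params$swap_exponents) {
    c(one_minus_q = sp[["beta"]], q = sp[["alpha"]], gamma = sp[["gamma"]])
  } else {
    c(one_minus_q = sp[["alpha"]], q = sp[["beta"]], gamma = sp[["gamma"]])
  }
}

# log of Kummer's confluent hypergeometric function M(b; c; g), vectorized
# over b. Exact power series with overflow renormalization, valid for any
# real g (Kummer transform for g < 0); used both by the series likelihood
# and for cross-checking the quadrature path.
.log_kummer <- function(b, c, g) {
  stopifnot(all(b > 0), c > 0)
  if (g == 0) return(rep(0, length(b)))
  if (g < 0) return(g + .log_kummer(c - b, c, -g))
  if (g > 5e5) stop("gamma too large for series evaluation (", g, ")")
  t <- rep(1, length(b))
  s <- rep(1, length(b))
  off <- 0
  j <- 0
  jmax <- max(1000, ceiling(g + 12 * sqrt(g) + 50))
  repeat {
    t <- t * (b + j) / ((c + j) * (j + 1)) * g
    s <- s + t
    j <- j + 1
    if (max(s) > 1e280) {
      s <- s * 1e-280
      t <- t * 1e-280
      off <- off + 280 * log(10)
    }
    if (j > g && max(t) < max(s) * 1e-17) break
    if (j >= jmax) break
  }
  log(s) + off
}

# log integral  log \int_0^1 e^{g q} (1-q)^(a-1) q^(b-1) dq  (a = exponent
# base on 1-q, b on q), by Gauss-Jacobi quadrature in log space.
.log_norm_integral_quad <- function(a, b, g, order = 128L) {
  if (abs(g) > 50) order <- 256L
  rule <- .unit_jacobi(a, b, order)
  .logsumexp(rule$logw + g * rule$q)
}

#' Normalization constant of the stationary density
#'
#' Computes \eqn{C = 1 / \int_0^1 e^{\gamma q} (1-q)^{\alpha-1} q^{\beta-1}
#' dq} by fixed-order Gauss--Jacobi quadrature: the endpoint singularities
#' are absorbed exactly into the quadrature weight and only the smooth
#' factor \eqn{e^{\gamma q}} is approximated. Order 128 by default (256 when
#' \eqn{|\gamma| > 50}).
#'
#' @param params A `model_params` object.
#' @param order Quadrature order.
#' @return The constant `C` (positive, finite).
#' @examples
#' # gamma = 0 reduces to the beta-function closed form 1/B(beta, alpha)
#' p <- params_from_scaled(0.72, 0.036, 0, ne = 5e4)
#' normalization_constant(p) * beta(0.036, 0.72)  # 1
#' @export
normalization_constant <- function(params, order = 128L) {
  ex <- .density_exponents(params)
  lZ <- .log_norm_integral_quad(ex[["one_minus_q"]], ex[["q"]],
                                ex[["gamma"]], order)
  C <- exp(-lZ)
  if (!is.finite(C) || C <= 0) {
    stop("normalization constant is not finite for these parameters")
  }
  C
}

#' Normalized log density of the methylated-epiallele frequency
#'
#' @param q Frequencies strictly inside `(0, 1)`.
#' @param params A `model_params` object.
#' @return `log(C) + gamma*q + (alpha-1)*log(1-q) + (beta-1)*log(q)`
#'   (exponents swapped if the params say so), vectorized over `q`.
#' @export
log_density <- function(q, params) {
  stopifnot(is.numeric(q))
  if (any(q <= 0 | q >= 1)) {
    stop("q must lie strictly inside (0, 1); the density can be singular at the endpoints")
  }
  ex <- .density_exponents(params)
  lZ <- .log_norm_integral_quad(ex[["one_minus_q"]], ex[["q"]], ex[["gamma"]])
  -lZ + ex[["gamma"]] * q + (ex[["one_minus_q"]] - 1) * log1p(-q) +
    (ex[["q"]] - 1) * log(q)
}

# log expected sampling probabilities log p_k, k = 0..m, by either route.
# quadrature: binomial kernel folded into the smooth factor of the same
#   Gauss-Jacobi rule used for C.
# series: exact confluent-hypergeometric form
#   p_k = C(m,k) B(b+k, a+m-k) M(b+k; a+b+m; g) / [B(b, a) M(b; a+b; g)].
.log_expected_sfs <- function(params, m, method = c("quadrature", "series"),
                              order = 128L) {
  method <- match.arg(method)
  ex <- .density_exponents(params)
  a <- ex[["one_minus_q"]]
  b <- ex[["q"]]
  g <- ex[["gamma"]]
  k <- 0:m
  if (method == "series") {
    lpk <- lchoose(m, k) + lbeta(b + k, a + m - k) +
      .log_kummer(b + k, a + b + m, g) -
      (lbeta(b, a) + .log_kummer(b, a + b, g))
  } else {
    if (abs(g) > 50) order <- 256L
    rule <- .unit_jacobi(a, b, order)
    lZ <- .logsumexp(rule$logw + g * rule$q)
    base <- rule$logw + g * rule$q
    lq <- log(rule$q)
    l1q <- log1p(-rule$q)
    lpk <- vapply(k, function(kk) {
      lchoose(m, kk) + .logsumexp(base + kk * lq + (m - kk) * l1q) - lZ
    }, numeric(1))
  }
  lpk
}

#' Expected site frequency spectrum under binomial sampling
#'
#' Probability that `k` of `m` sampled epialleles at a tile are methylated,
#' \eqn{p_k = \int_0^1 \binom{m}{k} q^k (1-q)^{m-k} \phi(q) dq}, for
#' `k = 0..m`.
#'
#' @param params A `model_params` object.
#' @param m Allele sample size (`2n` for `n` outbred diploids).
#' @param method `"quadrature"` (Gauss--Jacobi, the reference scheme) or
#'   `"series"` (exact confluent-hypergeometric evaluation; faster for
#'   repeated calls, used internally by [run_mcmc()]). Both agree to
#'   near machine precision.
#' @return Numeric probability vector of length `m + 1` summing to 1.
#' @examples
#' p <- params_from_scaled(1, 1, 0, ne = 1e4)
#' expected_sfs(p, m = 5)  # uniform: 1/6 each
#' @export
expected_sfs <- function(params, m, method = c("quadrature", "series")) {
  stopifnot(m >= 1)
  p <- exp(.log_expected_sfs(params, m, method))
  p / sum(p)
}

#' Multinomial log-likelihood of one or more observed mSFS
#'
#' \eqn{\sum_k n_k \log p_k} (up to the multinomial constant), summed over
#' cohorts when `msfs` is a list of spectra sharing the same parameters.
#' Bins with `n_k = 0` contribute 0; a true `-Inf` log-probability is
#' clamped to a large finite penalty so the sampler can always compare
#' states.
#'
#' @param msfs An `msfs` object (see [build_msfs()]) or list of them.
#' @param params A `model_params` object.
#' @param method Passed to [expected_sfs()]; the sampler uses `"series"`.
#' @return Scalar log-likelihood.
#' @export
msfs_loglik <- function(msfs, params, method = c("series", "quadrature")) {
  method <- match.arg(method)
  if (inherits(msfs, "msfs")) msfs <- list(msfs)
  stopifnot(length(msfs) > 0, all(vapply(msfs, inherits, TRUE, "msfs")))
  total <- 0
  for (sp in msfs) {
    lpk <- .log_expected_sfs(params, sp$m, method)
    lpk[!is.finite(lpk)] <- -1e10
    nz <- sp$counts > 0
    total <- total + sum(sp$counts[nz] * lpk[nz])
  }
  total
}
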