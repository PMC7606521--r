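# Gauss-Jacobi quadrature via Golub-Welsch, used to integrate the stationary
# density, whose weight (1-q)^(alpha-1) q^(beta-1) is singular at both
# endpoints whenever alpha or beta < 1. The Jacobi weight absorbs the
# singularities exactly, so only the smooth factor e^{gamma q} (times a
# polynomial when computing sampling probabilities) is approximated.

#' Gauss--Jacobi quadrature rule
#'
#' Nodes and weights for \eqn{\int_{-1}^{1} f(x)\,(1-x)^a (1+x)^b \, dx},
#' computed by the Golub--Welsch eigenvalue method.
#'
#' @param n Number of nodes (rule is exact for polynomials up to degree
#'   \eqn{2n-1}).
#' @param a,b Weight exponents; must be \eqn{> -1}.
#' @return List with `nodes` (ascending, in \eqn{(-1,1)}) and `weights`
#'   (positive, summing to the weight-function integral).
#' @examples
#' gj <- gauss_jacobi(16, 0, 0)       # Gauss-Legendre
#' sum(gj$weights)                    # 2
#' @export
gauss_jacobi <- function(n, a, b) {
  stopifnot(n >= 1, a > -1, b > -1)
  mu0 <- exp((a + b + 1) * log(2) + lgamma(a + 1) + lgamma(b + 1) -
               lgamma(a + b + 2))
  if (n == 1L) {
    return(list(nodes = (b - a) / (a + b + 2), weights = mu0))
  }
  ab <- a + b
  d <- numeric(n)
  e <- numeric(n - 1)
  d[1] <- (b - a) / (ab + 2)
  e[1] <- sqrt(4 * (1 + a) * (1 + b) / ((ab + 2)^2 * (ab + 3)))
  if (n > 2) {
    i <- 2:(n - 1)
    abi <- ab + 2 * i
    d[i] <- (b^2 - a^2) / ((abi - 2) * abi)
    e[i] <- sqrt(4 * i * (i + a) * (i + b) * (i + ab) / ((abi^2 - 1) * abi^2))
  }
  abn <- ab + 2 * n
  d[n] <- (b^2 - a^2) / ((abn - 2) * abn)
  J <- matrix(0, n, n)
  diag(J) <- d
  J[cbind(seq_len(n - 1), 2:n)] <- e
  J[cbind(2:n, seq_len(n - 1))] <- e
  es <- eigen(J, symmetric = TRUE)
  list(nodes = rev(es$values), weights = rev(es$vectors[1, ]^2) * mu0)
}

# Cache of rules on the unit interval, keyed by (alpha, beta, order).
.quad_cache <- new.env(parent = emptyenv())

# Rule for \int_0^1 g(q) (1-q)^(alpha-1) q^(beta-1) dq  ==  sum(w * g(q)).
# The 2^-(alpha+beta-1) change-of-variable factor is folded into the weights.
.unit_jacobi <- function(alpha, beta, order = 128L) {
  key <- paste(format(alpha, digits = 17), format(beta, digits = 17), order,
               sep = "|")
  hit <- get0(key, envir = .quad_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  gj <- gauss_jacobi(order, alpha - 1, beta - 1)
  rule <- list(q = (gj$nodes + 1) / 2,
               w = gj$weights * 2^(-(alpha + beta - 1)),
               logw = log(gj$weights) - (alpha + beta - 1) * log(2))
  if (length(ls(.quad_cache)) > 256L) {
    rm(list = ls(.quad_cache), envir = .quad_cache)
  }
  assign(key, rule, envir = .quad_cache)
  rule
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
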