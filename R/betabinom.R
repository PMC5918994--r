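#' Beta-binomial distribution in the (mu, sigma) parameterization
#'
#' The number of true positives Y among N calls is modeled as Beta-binomial
#' with mean probability `mu` (the expected PPV) and dispersion `sigma`:
#' \deqn{E[Y] = N\mu, \quad Var[Y] = N\mu(1-\mu)\frac{1 + N\sigma}{1 + \sigma}.}
#' `sigma = 0` is the Binomial limit; for `sigma > 0` the distribution is the
#' Beta-binomial with shape parameters `alpha = mu/sigma` and
#' `beta = (1 - mu)/sigma`, so that `sigma = 1/(alpha + beta)`.
#'
#' @param y Vector of counts, each in `0..n`.
#' @param n Number of trials (call-list size), positive integer.
#' @param mu Mean probability in (0, 1).
#' @param sigma Dispersion, non-negative real. `sigma = 0` gives the Binomial.
#' @param log Return log-density?
#' @return `dbetabinom` returns (log-)probabilities; `pbetabinom` lower-tail
#'   probabilities; `rbetabinom` random counts.
#' @examples
#' dbetabinom(3, 10, mu = 0.3, sigma = 0.5)
#' bb_moments(0.5, 1, 10) # variance 13.75
#' @export
dbetabinom <- function(y, n, mu, sigma, log = FALSE) {
  k <- max(length(y), length(n), length(mu), length(sigma))
  y <- rep_len(y, k); n <- rep_len(n, k)
  mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  stopifnot(all(mu > 0 & mu < 1), all(sigma >= 0), all(n >= 1))
  if (any(y < 0 | y > n)) {
    stop("'y' must lie in [0, n]")
  }
  out <- numeric(k)
  bin <- sigma == 0
  if (any(bin)) {
    out[bin] <- stats::dbinom(y[bin], n[bin], mu[bin], log = TRUE)
  }
  if (any(!bin)) {
    a <- mu[!bin] / sigma[!bin]
    b <- (1 - mu[!bin]) / sigma[!bin]
    yy <- y[!bin]; nn <- n[!bin]
    # grouped lgamma differences limit cancellation for large shapes
    out[!bin] <- lchoose(nn, yy) +
      (lgamma(yy + a) - lgamma(a)) +
      (lgamma(nn - yy + b) - lgamma(b)) -
      (lgamma(nn + a + b) - lgamma(a + b))
  }
  if (log) out else exp(out)
}

#' @rdname dbetabinom
#' @param q Vector of quantiles (counts).
#' @export
pbetabinom <- function(q, n, mu, sigma) {
  k <- max(length(q), length(n), length(mu), length(sigma))
  q <- rep_len(q, k); n <- rep_len(n, k)
  mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  vapply(seq_len(k), function(i) {
    qi <- floor(q[i])
    if (qi < 0) return(0)
    if (qi >= n[i]) return(1)
    # sum the shorter tail
    if (qi <= n[i] / 2) {
      sum(dbetabinom(0:qi, n[i], mu[i], sigma[i]))
    } else {
      1 - sum(dbetabinom((qi + 1):n[i], n[i], mu[i], sigma[i]))
    }
  }, numeric(1))
}

#' @rdname dbetabinom
#' @param m Number of draws.
#' @export
rbetabinom <- function(m, n, mu, sigma) {
  n <- rep_len(n, m); mu <- rep_len(mu, m); sigma <- rep_len(sigma, m)
  stopifnot(all(mu > 0 & mu < 1), all(sigma >= 0))
  p <- mu
  pos <- sigma > 0
  if (any(pos)) {
    ab <- ab_from_musigma(mu[pos], sigma[pos])
    p[pos] <- stats::rbeta(sum(pos), ab$alpha, ab$beta)
  }
  stats::rbinom(m, n, p)
}

#' Mean and variance of the Beta-binomial count
#'
#' @inheritParams dbetabinom
#' @return List with elements `mean = n * mu` and
#'   `variance = n * mu * (1 - mu) * (1 + n * sigma) / (1 + sigma)`.
#' @export
bb_moments <- function(mu, sigma, n) {
  stopifnot(all(mu > 0 & mu < 1), all(sigma >= 0), all(n >= 1))
  list(mean = n * mu,
       variance = n * mu * (1 - mu) * (1 + n * sigma) / (1 + sigma))
}

#' Convert (mu, sigma) to Beta shape parameters
#'
#' `alpha = mu/sigma`, `beta = (1 - mu)/sigma`. The inverse is
#' `mu = alpha/(alpha + beta)`, `sigma = 1/(alpha + beta)`.
#'
#' @inheritParams dbetabinom
#' @return List with `alpha` and `beta`.
#' @export
ab_from_musigma <- function(mu, sigma) {
  stopifnot(all(mu > 0 & mu < 1))
  if (any(sigma <= 0)) {
    stop("'sigma' must be > 0; use the Binomial limit for sigma = 0")
  }
  list(alpha = mu / sigma, beta = (1 - mu) / sigma)
}

#' Inverse link functions for the mean and dispersion parts
#'
#' The mean uses the logistic link, `mu = exp(eta)/(1 + exp(eta))`. The
#' dispersion uses either the log link, `sigma = exp(eta)`, or a Box-Cox
#' family `sigma = eta^(1/lambda)` (valid for `eta > 0`); as `lambda -> 0`
#' the Box-Cox family approaches the log link.
#'
#' @param eta Linear predictor value(s).
#' @param link For `link_sigma`: `"log"` or a numeric Box-Cox `lambda > 0`.
#' @return `link_mu` a probability; `link_sigma` a non-negative dispersion
#'   (`NA` where a Box-Cox predictor is non-positive, i.e. infeasible).
#' @export
link_mu <- function(eta) stats::plogis(eta)

#' @rdname link_mu
#' @export
link_sigma <- function(eta, link = "log") {
  if (identical(link, "log")) return(exp(eta))
  lambda <- as.numeric(link)
  if (!is.finite(lambda) || lambda <= 0) {
    stop("Box-Cox dispersion link requires a positive numeric lambda")
  }
  out <- rep(NA_real_, length(eta))
  ok <- eta > 0
  out[ok] <- eta[ok]^(1 / lambda)
  out
}

#' Akaike weights
#'
#' Transforms a vector of AIC values into relative model weights
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with
#' `Delta_i = AIC_i - min(AIC)`.
#'
#' @param aic Numeric vector of AIC values (length >= 2).
#' @return Numeric vector of weights summing to 1.
#' @examples
#' akaike_weights(c(7219.47, 7230.74)) # first weight > 0.99
#' @export
akaike_weights <- function(aic) {
  stopifnot(is.numeric(aic), length(aic) >= 2, all(is.finite(aic)))
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}
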