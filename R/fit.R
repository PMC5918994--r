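#' Fit a Beta-binomial regression with covariate-dependent dispersion
#'
#' Maximizes the exact Beta-binomial log-likelihood jointly over the mean
#' coefficients `beta` (logit link for mu, the expected PPV) and dispersion
#' coefficients `gamma` (log link for sigma by default, or a Box-Cox link
#' `sigma = (z'gamma)^(1/lambda)`). Optimization is quasi-Newton (BFGS) on
#' the unconstrained scale with analytic gradients for the log link, warm
#' started from a Binomial logistic regression of `y/n` on the mean design
#' and a method-of-moments dispersion estimate. Wald standard errors come
#' from the inverse observed information at the optimum.
#'
#' @param table Data frame with columns `y` (TP count), `n` (call-list
#'   size), and the covariates referenced by `spec` (`titv`, `hethom`,
#'   `med_dp`, `dp_lt5`, `wes_indicator`, optional factor labels).
#' @param spec A [bb_spec()] or a name accepted by [named_spec()].
#' @param start Optional warm start: list with numeric vectors `beta`,
#'   `gamma` matching the spec's column counts.
#' @param control List: `maxit` (default 500), `reltol` (default 1e-10).
#' @param se Compute Wald standard errors from the numeric observed
#'   information (default `TRUE`)? Skipping it speeds up repeated refits
#'   that only need point estimates (leave-one-out, link scans).
#' @return Object of class `bbfit`: coefficients, standard errors, Wald
#'   p-values, `loglik`, `aic = -2*loglik + 2*(p+q)`, the design matrices,
#'   stored centering constants, and a `converged` flag.
#' @examples
#' tab <- simulate_training_table(sim_config(n_obs = 80, seed = 1))
#' fit <- bbfit(tab, named_spec("m11_1"))
#' summary(fit)
#' @export
bbfit <- function(table, spec, start = NULL,
                  control = list(maxit = 500, reltol = 1e-10), se = TRUE) {
  if (is.character(spec)) spec <- named_spec(spec)
  stopifnot(inherits(spec, "bb_spec"))
  if (!all(c("y", "n") %in% names(table))) {
    stop("table must contain columns 'y' and 'n'")
  }
  y <- as.numeric(table$y); n <- as.numeric(table$n)
  if (any(y < 0 | y > n) || any(n < 1)) stop("need 0 <= y <= n, n >= 1")
  d <- build_design(table, spec)
  X <- d$X; Z <- d$Z
  p <- ncol(X); q <- ncol(Z)
  if (nrow(X) < p + q + 1) {
    stop("need at least p + q + 1 = ", p + q + 1, " observations")
  }
  check_rank(X, "mean")
  check_rank(Z, "dispersion")
  link <- spec$dispersion_link
  boxcox <- !identical(link, "log")

  # optimize on column-scaled designs so BFGS and the numeric Hessian see
  # comparably sized parameters (squares of raw depths span ~1e4)
  sx <- sqrt(colMeans(X^2)); sz <- sqrt(colMeans(Z^2))
  Xs <- sweep(X, 2, sx, "/"); Zs <- sweep(Z, 2, sz, "/")
  SIGMA_FLOOR <- 1e-8  # smooth lower bound; keeps lgamma differences accurate

  nll <- function(theta) {
    beta <- theta[seq_len(p)]
    gamma <- theta[p + seq_len(q)]
    eta <- pmin(pmax(drop(Xs %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    zg <- drop(Zs %*% gamma)
    if (boxcox) {
      if (any(zg <= 0)) {
        # infeasible Box-Cox region: penalized, not fatal
        return(1e8 * (1 + sum(pmax(0, -zg))))
      }
      sigma <- zg^(1 / link)
    } else {
      sigma <- exp(pmin(zg, 20)) + SIGMA_FLOOR
    }
    ll <- sum(dbetabinom(y, n, mu, sigma, log = TRUE))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  grad <- NULL
  if (!boxcox) {
    grad <- function(theta) {
      beta <- theta[seq_len(p)]
      gamma <- theta[p + seq_len(q)]
      eta <- pmin(pmax(drop(Xs %*% beta), -30), 30)
      mu <- stats::plogis(eta)
      zg <- pmin(drop(Zs %*% gamma), 20)
      ezg <- exp(zg)
      sigma <- ezg + SIGMA_FLOOR
      a <- mu / sigma; b <- (1 - mu) / sigma
      dab <- digamma(n + a + b) - digamma(a + b)
      dla <- digamma(y + a) - digamma(a) - dab
      dlb <- digamma(n - y + b) - digamma(b) - dab
      dmu <- (dla - dlb) / sigma * mu * (1 - mu)
      dsg <- -(a * dla + b * dlb) / sigma * ezg
      -c(drop(crossprod(Xs, dmu)), drop(crossprod(Zs, dsg)))
    }
  }

  st0 <- fit_start(start, X, Z, y, n, link, p, q)
  theta0 <- c(st0[seq_len(p)] * sx, st0[p + seq_len(q)] * sz)
  opt <- stats::optim(theta0, nll, gr = grad, method = "BFGS",
                      control = list(maxit = control$maxit %||% 500,
                                     reltol = control$reltol %||% 1e-10))
  # polish once if the first pass hit the iteration cap
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, nll, gr = grad, method = "BFGS",
                         control = list(maxit = control$maxit %||% 500,
                                        reltol = control$reltol %||% 1e-10))
    if (opt2$value <= opt$value) opt <- opt2
  }
  opt_converged <- opt$convergence == 0

  vc <- NULL; se_vec <- rep(NA_real_, p + q)
  scl <- c(sx, sz)
  se_ok <- NA
  if (se) {
    hess <- tryCatch(stats::optimHess(opt$par, nll, gr = grad),
                     error = function(e) NULL)
    if (!is.null(hess)) {
      vc <- tryCatch(solve(hess), error = function(e) NULL)
      if (!is.null(vc)) {
        dg <- diag(vc)
        if (any(dg <= 0)) { vc <- NULL } else {
          vc <- vc / tcrossprod(scl)  # back to the unscaled parameterization
          se_vec <- sqrt(diag(vc))
        }
      }
    }
    se_ok <- !is.null(vc)
  }
  converged <- opt_converged && !isFALSE(se_ok)
  est <- opt$par / scl
  zval <- est / se_vec
  pval <- 2 * stats::pnorm(-abs(zval))
  nm <- c(colnames(X), colnames(Z))
  names(est) <- names(se_vec) <- names(zval) <- names(pval) <- nm

  structure(list(
    spec = spec, X = X, Z = Z, y = y, n = n, table = table,
    design_info = d$design_info,
    beta = est[seq_len(p)], gamma = est[p + seq_len(q)],
    se = se_vec, vcov = vc, zval = zval, pval = pval,
    loglik = -opt$value, aic = 2 * opt$value + 2 * (p + q),
    p = p, q = q, converged = converged, opt_converged = opt_converged,
    counts = opt$counts),
    class = "bbfit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_rank <- function(M, part) {
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop("rank-deficient ", part, " design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
}

fit_start <- function(start, X, Z, y, n, link, p, q) {
  if (!is.null(start)) {
    stopifnot(length(start$beta) == p, length(start$gamma) == q)
    return(c(start$beta, start$gamma))
  }
  # stage 1: Binomial logistic regression for the mean part
  g <- suppressWarnings(stats::glm.fit(X, cbind(y, n - y),
                                       family = stats::binomial()))
  beta0 <- g$coefficients
  beta0[!is.finite(beta0)] <- 0
  mu0 <- pmin(pmax(stats::plogis(drop(X %*% beta0)), 1e-10), 1 - 1e-10)
  # stage 2: method-of-moments dispersion from Pearson overdispersion
  phi <- sum((y - n * mu0)^2 / (n * mu0 * (1 - mu0))) / max(length(y) - p, 1)
  sigma0 <- max((phi - 1) / mean(n), 1e-8)
  gamma0 <- if (identical(link, "log")) {
    c(log(sigma0), rep(0, q - 1))
  } else {
    c(max(sigma0^as.numeric(link), 1e-6), rep(0, q - 1))
  }
  c(beta0, gamma0)
}

#' @method coef bbfit
#' @export
coef.bbfit <- function(object, ...) c(object$beta, object$gamma)

#' @method logLik bbfit
#' @export
logLik.bbfit <- function(object, ...) {
  structure(object$loglik, df = object$p + object$q,
            nobs = length(object$y), class = "logLik")
}

#' Fitted mean and dispersion values
#'
#' @param object A [bbfit()] object.
#' @param what `"mu"` (expected PPV per row) or `"sigma"` (dispersion).
#' @param ... Unused.
#' @export
fitted.bbfit <- function(object, what = c("mu", "sigma"), ...) {
  what <- match.arg(what)
  if (what == "mu") {
    link_mu(drop(object$X %*% object$beta))
  } else {
    link_sigma(drop(object$Z %*% object$gamma), object$spec$dispersion_link)
  }
}

#' @method print bbfit
#' @export
print.bbfit <- function(x, ...) {
  cat("Beta-binomial regression (", x$p, ", ", x$q, ")",
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  cat("  log-likelihood: ", format(x$loglik), "   AIC: ", format(x$aic),
      "\n", sep = "")
  invisible(x)
}

#' @method summary bbfit
#' @export
summary.bbfit <- function(object, ...) {
  tab <- function(idx) {
    data.frame(Estimate = coef(object)[idx], `Std.Error` = object$se[idx],
               `z.value` = object$zval[idx], `p.value` = object$pval[idx],
               check.names = FALSE)
  }
  out <- list(mean = tab(seq_len(object$p)),
              dispersion = tab(object$p + seq_len(object$q)),
              loglik = object$loglik, aic = object$aic,
              converged = object$converged, p = object$p, q = object$q)
  class(out) <- "summary.bbfit"
  out
}

#' @method print summary.bbfit
#' @export
print.summary.bbfit <- function(x, ...) {
  cat("Beta-binomial regression (", x$p, ", ", x$q, ")\n\n", sep = "")
  cat("Mean part (logit link for mu):\n")
  stats::printCoefmat(as.matrix(x$mean), has.Pvalue = TRUE)
  cat("\nDispersion part:\n")
  stats::printCoefmat(as.matrix(x$dispersion), has.Pvalue = TRUE)
  cat("\nlog-likelihood: ", format(x$loglik), "   AIC: ", format(x$aic),
      if (!x$converged) "   [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}
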