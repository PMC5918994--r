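#' Randomized quantile residuals
#'
#' For each observation, draws `u` uniformly between the fitted
#' Beta-binomial CDF at `y - 1` and at `y` and returns the standard-Normal
#' quantile of `u`. On a well-specified model these residuals have mean
#' approximately 0 and standard deviation approximately 1, which is what
#' makes them usable for spotting gross irregularities in a discrete-response
#' regression.
#'
#' @param fit A converged [bbfit()].
#' @param seed Integer seed fixing the randomization (default 423).
#' @return Numeric vector of residuals, one per training row.
#' @export
weighted_residuals <- function(fit, seed = 423) {
  stopifnot(inherits(fit, "bbfit"))
  mu <- fitted(fit, "mu")
  sigma <- pmax(fitted(fit, "sigma"), 0)
  m <- length(fit$y)
  lo <- pbetabinom(fit$y - 1, fit$n, mu, sigma)
  hi <- pbetabinom(fit$y, fit$n, mu, sigma)
  u <- withr_seed(seed, stats::runif(m, min = lo, max = hi))
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  stats::qnorm(u)
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Binomial hat values for the mean part
#'
#' Leverage of each observation in the mean-part covariate space, using the
#' Binomial working weights `w_i = N_i mu_i (1 - mu_i)` under the logit
#' link: the diagonal of
#' `H = W^{1/2} X (X'WX)^{-1} X' W^{1/2}`. These are approximate for the
#' Beta-binomial model (an exact Beta-binomial leverage is not defined
#' here), but they identify covariate-space outliers.
#'
#' @param fit A converged [bbfit()].
#' @return Vector of hat values in `[0, 1]` summing to `p`.
#' @export
hat_values <- function(fit) {
  stopifnot(inherits(fit, "bbfit"))
  mu <- fitted(fit, "mu")
  w <- fit$n * mu * (1 - mu)
  Xs <- fit$X * sqrt(w)
  XtWX <- crossprod(Xs)
  R <- tryCatch(chol(XtWX), error = function(e)
    stop("singular weighted cross-product X'WX"))
  B <- Xs %*% chol2inv(R)
  pmin(pmax(rowSums(B * Xs), 0), 1)
}

#' Cook's distances under the Binomial working model
#'
#' One-step GLM influence: `D_i = r_i^2 h_i / (p (1 - h_i)^2)` with `r_i`
#' the Binomial Pearson residual `(y_i - N_i mu_i)/sqrt(N_i mu_i (1-mu_i))`
#' and `h_i` the Binomial hat value. Large values point to observations
#' exerting strong influence on the fitted mean surface.
#'
#' @param fit A converged [bbfit()].
#' @return Vector of non-negative distances (`Inf`, with a warning, where
#'   `h_i = 1`).
#' @export
cooks_distances <- function(fit) {
  stopifnot(inherits(fit, "bbfit"))
  h <- hat_values(fit)
  mu <- fitted(fit, "mu")
  r <- (fit$y - fit$n * mu) / sqrt(fit$n * mu * (1 - mu))
  d <- r^2 * h / (fit$p * (1 - h)^2)
  if (any(h >= 1 - 1e-12)) {
    warning("hat value of 1 encountered; Cook's distance reported as Inf")
    d[h >= 1 - 1e-12] <- Inf
  }
  d
}

#' Per-row diagnostic report
#'
#' Combines randomized quantile residuals, Binomial hat values and Cook's
#' distances, flagging rows beyond the usual rules of thumb.
#'
#' @param fit A converged [bbfit()].
#' @param seed Seed for the residual randomization.
#' @param resid_cut,hat_mult,cook_mult Flag thresholds: `|residual| >
#'   resid_cut` (default 3), `hat > hat_mult * p / n_obs` (default 2),
#'   `cook > cook_mult / n_obs` (default 4).
#' @param refit_without_top Integer; if positive, additionally refits the
#'   model without the `refit_without_top` highest-Cook rows and reports the
#'   largest change in fitted mu (`refit_max_mu_shift` attribute).
#' @return Data frame with `residual`, `hat`, `cook` and logical flag
#'   columns.
#' @export
diagnose <- function(fit, seed = 423, resid_cut = 3, hat_mult = 2,
                     cook_mult = 4, refit_without_top = 0) {
  r <- weighted_residuals(fit, seed = seed)
  h <- hat_values(fit)
  d <- cooks_distances(fit)
  m <- length(r)
  out <- data.frame(residual = r, hat = h, cook = d,
                    flag_residual = abs(r) > resid_cut,
                    flag_hat = h > hat_mult * fit$p / m,
                    flag_cook = d > cook_mult / m)
  if (refit_without_top > 0) {
    drop_idx <- order(d, decreasing = TRUE)[seq_len(min(refit_without_top, m))]
    refit <- bbfit(fit$table[-drop_idx, , drop = FALSE], fit$spec,
                   start = list(beta = fit$beta, gamma = fit$gamma))
    dd <- build_design(fit$table, fit$spec, design_info = refit$design_info)
    mu_new <- link_mu(drop(dd$X %*% refit$beta))
    attr(out, "refit_dropped") <- drop_idx
    attr(out, "refit_max_mu_shift") <- max(abs(mu_new - fitted(fit, "mu")))
  }
  out
}
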