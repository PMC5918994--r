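#' 95% prediction interval for the observed PPV of a call set
#'
#' For a future call set with covariates `newdata` and size `n`, the
#' observed proportion `Y/N` is approximated as Normal with mean `mu` and
#' variance `mu (1 - mu) (1 + N sigma) / (N (1 + sigma))` (the Beta-binomial
#' variance divided by `N^2`), where `mu` and `sigma` come from the fitted
#' linear predictors. The interval is `mu +/- z_{0.975} * sd`, truncated to
#' `[0, 1]`; coefficient-estimation uncertainty is deliberately ignored.
#'
#' @param fit A converged [bbfit()].
#' @param newdata One-or-more-row data frame with the covariates the model
#'   uses (raw scale; stored training centers are applied).
#' @param n Call-list size(s) for the new set(s).
#' @param level Coverage level (default 0.95).
#' @param envelope Multiplier on the training covariate range beyond which a
#'   covariate triggers an extrapolation warning (default 1.1; `Inf`
#'   disables).
#' @return Data frame with columns `point`, `lower`, `upper`, `length_pct`
#'   (interval length in percent, post-truncation).
#' @examples
#' tab <- simulate_training_table(sim_config(n_obs = 80, seed = 1))
#' fit <- bbfit(tab, named_spec("m11_1"))
#' predict_interval(fit, tab[1, ], n = tab$n[1])
#' @export
predict_interval <- function(fit, newdata, n, level = 0.95, envelope = 1.1) {
  stopifnot(inherits(fit, "bbfit"))
  if (!fit$opt_converged) stop("model did not converge; refusing to predict")
  n <- rep_len(as.numeric(n), nrow(newdata))
  if (any(n < 1)) stop("'n' must be >= 1")
  check_envelope(fit, newdata, envelope)
  d <- build_design(newdata, fit$spec, design_info = fit$design_info)
  mu <- link_mu(drop(d$X %*% fit$beta))
  sigma <- link_sigma(drop(d$Z %*% fit$gamma), fit$spec$dispersion_link)
  v <- mu * (1 - mu) * (1 + n * sigma) / (n * (1 + sigma))
  zq <- stats::qnorm((1 + level) / 2)
  lower <- pmax(mu - zq * sqrt(v), 0)
  upper <- pmin(mu + zq * sqrt(v), 1)
  data.frame(point = mu, lower = lower, upper = upper,
             length_pct = (upper - lower) * 100)
}

check_envelope <- function(fit, newdata, envelope) {
  if (!is.finite(envelope)) return(invisible())
  for (v in names(fit$design_info$centers)) {
    if (!v %in% names(newdata)) next
    rng <- range(fit$table[[v]])
    pad <- (envelope - 1) * diff(rng)
    out <- newdata[[v]] < rng[1] - pad | newdata[[v]] > rng[2] + pad
    if (any(out)) {
      warning("covariate '", v, "' outside the training envelope for ",
              sum(out), " row(s); prediction is an extrapolation")
    }
  }
  invisible()
}

#' Leave-one-out prediction intervals
#'
#' For each training row, refits the model on the remaining rows (warm
#' started from the full-data fit) and predicts an interval for the held-out
#' observed proportion. Rows whose refit does not converge are flagged and
#' excluded from coverage.
#'
#' @param table Training table (columns `y`, `n`, covariates).
#' @param spec A [bb_spec()] or [named_spec()] name.
#' @param level Coverage level (default 0.95).
#' @return Data frame of class `bb_loo` with `point`, `lower`, `upper`,
#'   `length_pct`, `observed` (= y/n), `covered`, `converged`; the number of
#'   excluded rows is attached as attribute `n_excluded`.
#' @export
loo_intervals <- function(table, spec, level = 0.95) {
  if (is.character(spec)) spec <- named_spec(spec)
  m <- nrow(table)
  full <- bbfit(table, spec)
  if (m < full$p + full$q + 2) {
    stop("need at least p + q + 2 = ", full$p + full$q + 2,
         " rows for leave-one-out")
  }
  warm <- list(beta = full$beta, gamma = full$gamma)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    f <- tryCatch(bbfit(table[-i, , drop = FALSE], spec, start = warm,
                        se = FALSE),
                  error = function(e) NULL)
    if (is.null(f) || !f$opt_converged) {
      rows[[i]] <- data.frame(point = NA_real_, lower = NA_real_,
                              upper = NA_real_, length_pct = NA_real_,
                              observed = table$y[i] / table$n[i],
                              covered = NA, converged = FALSE)
      next
    }
    pi <- predict_interval(f, table[i, , drop = FALSE], n = table$n[i],
                           level = level, envelope = Inf)
    obs <- table$y[i] / table$n[i]
    rows[[i]] <- cbind(pi, observed = obs,
                       covered = obs >= pi$lower & obs <= pi$upper,
                       converged = TRUE)
  }
  out <- do.call(rbind, rows)
  n_excl <- sum(!out$converged)
  if (n_excl > 0) {
    message(n_excl, " leave-one-out refit(s) failed to converge; ",
            "excluded from coverage")
  }
  attr(out, "n_excluded") <- n_excl
  class(out) <- c("bb_loo", class(out))
  out
}

#' Five-number summary of prediction-interval lengths
#'
#' Summarizes interval lengths (in percent) with type-7 quartiles, and the
#' observed coverage when the intervals carry held-out observations.
#' Optionally restricts to intervals whose point estimate of PPV exceeds a
#' threshold (the high-confidence regime where intervals tighten).
#'
#' @param intervals Data frame from [loo_intervals()] or
#'   [predict_interval()] (needs `length_pct`; `observed`/`covered` for
#'   coverage).
#' @param restrict_point_above Optional proportion; keep only rows with
#'   `point >` this value before summarizing lengths.
#' @return List with `min`, `q1`, `median`, `q3`, `max` (percent) and
#'   `coverage_pct` (percent, `NA` if no coverage information).
#' @export
summarize_lengths <- function(intervals, restrict_point_above = NULL) {
  keep <- intervals[!is.na(intervals$length_pct), , drop = FALSE]
  cov_pct <- if ("covered" %in% names(keep) && nrow(keep) > 0) {
    100 * mean(keep$covered)
  } else NA_real_
  if (!is.null(restrict_point_above)) {
    keep <- keep[keep$point > restrict_point_above, , drop = FALSE]
  }
  if (nrow(keep) == 0) stop("no intervals left to summarize")
  qs <- stats::quantile(keep$length_pct, c(0, 0.25, 0.5, 0.75, 1),
                        type = 7, names = FALSE)
  list(min = qs[1], q1 = qs[2], median = qs[3], q3 = qs[4], max = qs[5],
       coverage_pct = cov_pct)
}
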