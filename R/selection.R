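#' Backward elimination with an AIC stopping rule
#'
#' Iteratively drops terms from one part of the model. At each step the
#' removable term with the largest Wald p-value is tried first: it is
#' dropped only if the refitted model's AIC is lower; otherwise the next
#' largest is tried, and the procedure stops when no removal lowers the AIC.
#' Removable terms exclude the intercept, any main effect still referenced
#' by a square or interaction in the same part (marginality), and — when
#' eliminating from the mean part — any term also present in the dispersion
#' part (the dispersion terms must stay a subset of the mean terms). Ties in
#' p-value are broken by dropping the higher-order term first, then
#' alphabetically.
#'
#' @param table Training table.
#' @param start_spec A [bb_spec()] or [named_spec()] name.
#' @param part `"mean"` or `"dispersion"`.
#' @return List with `fit` (final [bbfit()]), `spec` (final spec) and
#'   `trace` (data frame: step, dropped term, its p-value, AIC before and
#'   after each accepted removal).
#' @export
backward_eliminate <- function(table, start_spec, part = c("mean", "dispersion")) {
  part <- match.arg(part)
  if (is.character(start_spec)) start_spec <- named_spec(start_spec)
  spec <- start_spec
  fit <- bbfit(table, spec)
  if (!fit$converged) stop("starting model did not converge")
  trace <- data.frame(step = integer(), dropped = character(),
                      p_value = numeric(), aic_before = numeric(),
                      aic_after = numeric())
  step <- 0
  repeat {
    cand <- removal_candidates(fit, spec, part)
    if (nrow(cand) == 0) break
    accepted <- FALSE
    for (j in seq_len(nrow(cand))) {
      new_spec <- drop_term(spec, part, cand$key[j])
      new_fit <- tryCatch(
        bbfit(table, new_spec,
              start = warm_without(fit, part, cand$key[j])),
        error = function(e) NULL)
      if (is.null(new_fit) || !new_fit$converged) next
      if (new_fit$aic < fit$aic) {
        step <- step + 1
        trace <- rbind(trace, data.frame(
          step = step, dropped = cand$label[j], p_value = cand$p[j],
          aic_before = fit$aic, aic_after = new_fit$aic))
        spec <- new_spec; fit <- new_fit; accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  list(fit = fit, spec = spec, trace = trace)
}

# terms eligible for removal, ordered: largest p first, ties -> higher order
# first, then alphabetical label
removal_candidates <- function(fit, spec, part) {
  terms <- if (part == "mean") spec$mean_terms else spec$disp_terms
  keys <- vapply(terms, term_key, character(1))
  labels <- vapply(terms, term_label, character(1))
  kinds <- vapply(terms, `[[`, character(1), "kind")
  # marginality: a main effect is pinned while any higher-order term in the
  # same part references its covariate
  pinned <- vapply(seq_along(terms), function(i) {
    if (kinds[i] == "intercept") return(TRUE)
    if (kinds[i] == "main") {
      v <- terms[[i]]$vars
      return(any(vapply(terms, function(t)
        t$kind %in% c("square", "interaction") && v %in% t$vars,
        logical(1))))
    }
    FALSE
  }, logical(1))
  if (part == "mean") {
    dkeys <- vapply(spec$disp_terms, term_key, character(1))
    pinned <- pinned | keys %in% dkeys
  }
  pv <- term_pvalues(fit, spec, part)
  ord_rank <- ifelse(kinds %in% c("square", "interaction"), 0, 1)
  keep <- which(!pinned)
  keep <- keep[order(-pv[keep], ord_rank[keep], labels[keep])]
  data.frame(key = keys[keep], label = labels[keep], p = pv[keep],
             stringsAsFactors = FALSE)
}

# per-term Wald p-value; a multi-column (factor) term takes its smallest
# column p-value, so the term is judged by its strongest component
term_pvalues <- function(fit, spec, part) {
  terms <- if (part == "mean") spec$mean_terms else spec$disp_terms
  info <- fit$design_info
  row1 <- fit$table[1, , drop = FALSE]
  ncols <- vapply(terms, function(t) ncol(term_columns(row1, t, info)),
                  integer(1))
  offset <- if (part == "mean") 0 else fit$p
  pv_all <- fit$pval[offset + seq_len(if (part == "mean") fit$p else fit$q)]
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1
  vapply(seq_along(terms), function(i) min(pv_all[starts[i]:ends[i]]),
         numeric(1))
}

drop_term <- function(spec, part, key) {
  slot <- if (part == "mean") "mean_terms" else "disp_terms"
  keys <- vapply(spec[[slot]], term_key, character(1))
  spec[[slot]] <- spec[[slot]][keys != key]
  bb_spec(spec$mean_terms, spec$disp_terms, spec$dispersion_link)
}

warm_without <- function(fit, part, key) {
  spec <- fit$spec
  terms <- if (part == "mean") spec$mean_terms else spec$disp_terms
  info <- fit$design_info
  row1 <- fit$table[1, , drop = FALSE]
  ncols <- vapply(terms, function(t) ncol(term_columns(row1, t, info)),
                  integer(1))
  keys <- vapply(terms, term_key, character(1))
  drop_cols <- unlist(mapply(function(k, s, n) if (k == key) s:(s + n - 1),
                             keys, cumsum(ncols) - ncols + 1, ncols))
  if (part == "mean") {
    list(beta = fit$beta[-drop_cols], gamma = fit$gamma)
  } else {
    list(beta = fit$beta, gamma = fit$gamma[-drop_cols])
  }
}

#' Scan Box-Cox dispersion links by AIC
#'
#' Refits the model under the Box-Cox dispersion link
#' `sigma = (z'gamma)^(1/lambda)` for each `lambda = 1/k`, `k` in
#' `inv_lambdas`, alongside the log link (reported as `lambda = 0`, its
#' limiting case). The AIC per link indicates which dispersion link the data
#' support.
#'
#' @param table Training table.
#' @param spec A [bb_spec()] with `q > 1` dispersion terms.
#' @param inv_lambdas Positive integers `k` (default `2:10`).
#' @return Data frame with `lambda`, `inv_lambda`, `aic`, `converged`; the
#'   best (lowest-AIC) lambda among converged fits is attached as attribute
#'   `best_lambda`.
#' @export
lambda_scan <- function(table, spec, inv_lambdas = 2:10) {
  if (is.character(spec)) spec <- named_spec(spec)
  if (length(spec$disp_terms) < 2) {
    stop("lambda scan requires a dispersion part with q > 1")
  }
  stopifnot(all(inv_lambdas == floor(inv_lambdas)), all(inv_lambdas >= 1))
  log_fit <- bbfit(table, spec, se = FALSE)
  sig_hat <- pmax(fitted(log_fit, "sigma"), 1e-12)
  rows <- list(data.frame(lambda = 0, inv_lambda = Inf, aic = log_fit$aic,
                          converged = log_fit$opt_converged))
  for (k in inv_lambdas) {
    lam <- 1 / k
    bspec <- bb_spec(spec$mean_terms, spec$disp_terms, dispersion_link = lam)
    # warm start: least-squares gamma reproducing sigma-hat on the new scale
    g0 <- tryCatch(qr.solve(log_fit$Z, sig_hat^lam), error = function(e) NULL)
    st <- if (!is.null(g0) && all(drop(log_fit$Z %*% g0) > 0)) {
      list(beta = log_fit$beta, gamma = g0)
    } else NULL
    f <- tryCatch(bbfit(table, bspec, start = st, se = FALSE),
                  error = function(e) NULL)
    rows[[length(rows) + 1]] <- data.frame(
      lambda = lam, inv_lambda = k,
      aic = if (is.null(f)) NA_real_ else f$aic,
      converged = !is.null(f) && f$opt_converged)
  }
  out <- do.call(rbind, rows)
  ok <- out$converged & is.finite(out$aic)
  if (!any(ok[-1])) {
    warning("all Box-Cox fits were infeasible; only the log link is reported")
    out <- out[1, , drop = FALSE]
    ok <- ok[1]
  }
  attr(out, "best_lambda") <- out$lambda[ok][which.min(out$aic[ok])]
  out
}
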