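#' @title Model terms and named specifications
#' @description
#' A model specification holds an ordered list of terms for the mean part
#' (logit link for mu) and for the dispersion part (log or Box-Cox link for
#' sigma). Terms are intercept, main effects, squares of quantitative
#' covariates, or pairwise interactions, all built on mean-centered
#' quantitative covariates; the WES indicator and factor labels are never
#' centered. The dispersion term list must be a subset of the mean term list.
#' @name bb_spec
NULL

# covariates treated as quantitative (centered before second-order terms)
QUANT_COVARS <- c("titv", "hethom", "med_dp", "dp_lt5")

bb_term <- function(kind, vars = character(0)) {
  kind <- match.arg(kind, c("intercept", "main", "square", "interaction"))
  if (kind == "intercept") vars <- character(0)
  if (kind == "main" && length(vars) != 1) stop("main term needs 1 covariate")
  if (kind == "square") {
    if (length(vars) != 1) stop("square term needs 1 covariate")
    if (!vars %in% QUANT_COVARS) {
      stop("square terms are only defined for quantitative covariates, not '",
           vars, "'")
    }
  }
  if (kind == "interaction" &&
      (length(vars) != 2 || vars[1] == vars[2])) {
    stop("interaction term needs 2 distinct covariates")
  }
  structure(list(kind = kind, vars = vars), class = "bb_term")
}

term_label <- function(t) {
  switch(t$kind,
         intercept = "(Intercept)",
         main = t$vars,
         square = paste0("I(", t$vars, "^2)"),
         interaction = paste(t$vars, collapse = ":"))
}

term_key <- function(t) {
  # canonical identity: interactions are order-free
  switch(t$kind,
         intercept = "1",
         main = t$vars,
         square = paste0(t$vars, "^2"),
         interaction = paste(sort(t$vars), collapse = ":"))
}

#' Parse term strings into term descriptors
#'
#' Accepted forms: `"1"` (intercept), `"titv"` (main effect),
#' `"titv^2"` or `"I(titv^2)"` (square), `"wes_indicator:titv"`
#' (interaction).
#'
#' @param x Character vector of term strings.
#' @return List of term descriptors.
#' @export
parse_terms <- function(x) {
  lapply(x, function(s) {
    s <- gsub("\\s", "", s)
    if (s %in% c("1", "(Intercept)", "Intercept")) return(bb_term("intercept"))
    m <- regmatches(s, regexec("^I\\((\\w+)\\^2\\)$|^(\\w+)\\^2$", s))[[1]]
    if (length(m) && any(nzchar(m[-1]))) {
      return(bb_term("square", m[-1][nzchar(m[-1])][1]))
    }
    if (grepl(":", s, fixed = TRUE)) {
      return(bb_term("interaction", strsplit(s, ":", fixed = TRUE)[[1]]))
    }
    bb_term("main", s)
  })
}

#' Construct a Beta-binomial model specification
#'
#' @param mean_terms,disp_terms Character vectors of term strings (see
#'   [parse_terms()]) or lists of term descriptors. Both must contain an
#'   intercept; `disp_terms` must be a subset of `mean_terms`.
#' @param dispersion_link `"log"` or a positive Box-Cox `lambda`.
#' @return An object of class `bb_spec` with elements `mean_terms`,
#'   `disp_terms`, `dispersion_link`.
#' @examples
#' bb_spec(c("1", "titv", "titv^2"), "1")
#' @export
bb_spec <- function(mean_terms, disp_terms = "1", dispersion_link = "log") {
  as_terms <- function(x) {
    if (is.character(x)) parse_terms(x)
    else if (is.list(x) && all(vapply(x, inherits, logical(1), "bb_term"))) x
    else stop("terms must be strings or bb_term descriptors")
  }
  mt <- as_terms(mean_terms)
  dt <- as_terms(disp_terms)
  mk <- vapply(mt, term_key, character(1))
  dk <- vapply(dt, term_key, character(1))
  if (anyDuplicated(mk) || anyDuplicated(dk)) stop("duplicate terms in spec")
  if (!"1" %in% mk || !"1" %in% dk) {
    stop("both term lists must include an intercept ('1')")
  }
  if (!all(dk %in% mk)) {
    stop("dispersion terms must be a subset of mean terms; offending: ",
         paste(setdiff(dk, mk), collapse = ", "))
  }
  if (!identical(dispersion_link, "log")) {
    lam <- as.numeric(dispersion_link)
    if (!is.finite(lam) || lam <= 0) stop("dispersion_link must be 'log' or lambda > 0")
    dispersion_link <- lam
  }
  structure(list(mean_terms = mt, disp_terms = dt,
                 dispersion_link = dispersion_link),
            class = "bb_spec")
}

#' @method print bb_spec
#' @export
print.bb_spec <- function(x, ...) {
  cat("Beta-binomial model specification\n")
  cat("  mean part  (p = ", length(x$mean_terms), "): ",
      paste(vapply(x$mean_terms, term_label, character(1)), collapse = " + "),
      "\n", sep = "")
  cat("  dispersion (q = ", length(x$disp_terms), "): ",
      paste(vapply(x$disp_terms, term_label, character(1)), collapse = " + "),
      "\n", sep = "")
  lnk <- x$dispersion_link
  cat("  dispersion link: ",
      if (identical(lnk, "log")) "log" else paste0("Box-Cox (lambda = ", lnk, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Named model specifications
#'
#' Pre-registered specifications of the candidate PPV models:
#' \describe{
#'   \item{`m11_6`}{11 mean terms (intercept, WES indicator, Ti/Tv, MedDp,
#'     DpLt5, Ti/Tv^2, MedDp^2, WES:Ti/Tv, WES:MedDp, WES:DpLt5,
#'     Ti/Tv:MedDp) and 6 dispersion terms (intercept, WES indicator, Ti/Tv,
#'     DpLt5, Ti/Tv^2, WES:Ti/Tv).}
#'   \item{`m11_1`}{The `m11_6` mean part with intercept-only dispersion.}
#'   \item{`m15_1`}{The `m11_1` mean part plus the four Het/Hom-related
#'     terms (Het/Hom, Het/Hom^2, WES:Het/Hom, MedDp:Het/Hom);
#'     intercept-only dispersion.}
#'   \item{`global_mean_18`}{The full second-order pool: intercept, the five
#'     main effects, four squares, four WES interactions, MedDp:Het/Hom,
#'     Ti/Tv:MedDp, Ti/Tv:DpLt5, and a configurable 18th slot (default
#'     Ti/Tv:Het/Hom); intercept-only dispersion.}
#' }
#'
#' @param name One of `"m11_6"`, `"m11_1"`, `"m15_1"`, `"global_mean_18"`.
#' @param extra_term Term string filling the 18th slot of the global model.
#' @return A [bb_spec()].
#' @export
named_spec <- function(name, extra_term = "titv:hethom") {
  mean11 <- c("1", "wes_indicator", "titv", "med_dp", "dp_lt5",
              "titv^2", "med_dp^2",
              "wes_indicator:titv", "wes_indicator:med_dp",
              "wes_indicator:dp_lt5", "titv:med_dp")
  disp6 <- c("1", "wes_indicator", "titv", "dp_lt5", "titv^2",
             "wes_indicator:titv")
  hethom4 <- c("hethom", "hethom^2", "wes_indicator:hethom", "med_dp:hethom")
  switch(name,
    m11_6 = bb_spec(mean11, disp6),
    m11_1 = bb_spec(mean11, "1"),
    m15_1 = bb_spec(c(mean11, hethom4), "1"),
    global_mean_18 = bb_spec(
      c("1", "wes_indicator", "titv", "hethom", "med_dp", "dp_lt5",
        "titv^2", "hethom^2", "med_dp^2", "dp_lt5^2",
        "wes_indicator:titv", "wes_indicator:hethom",
        "wes_indicator:med_dp", "wes_indicator:dp_lt5",
        "med_dp:hethom", "titv:med_dp", "titv:dp_lt5", extra_term),
      "1"),
    stop("unknown spec '", name,
         "'; known: m11_6, m11_1, m15_1, global_mean_18"))
}

#' Center quantitative covariates
#'
#' Subtracts the mean from each quantitative covariate; the centering
#' constants are stored so new observations can be placed on the training
#' scale. The WES indicator and factor labels are left untouched.
#'
#' @param table Data frame of training observations.
#' @param covariates Covariate names to center (defaults to the quantitative
#'   covariates present in `table`).
#' @return List with `table` (centered) and `centers` (named numeric).
#' @export
center_covariates <- function(table, covariates = intersect(QUANT_COVARS,
                                                            names(table))) {
  missing_cov <- setdiff(covariates, names(table))
  if (length(missing_cov)) {
    stop("covariates absent from table: ", paste(missing_cov, collapse = ", "))
  }
  centers <- vapply(covariates, function(v) mean(table[[v]]), numeric(1))
  for (v in covariates) table[[v]] <- table[[v]] - centers[[v]]
  list(table = table, centers = centers)
}

# design info bundles everything needed to rebuild a design row at serve time
make_design_info <- function(table, spec) {
  vars <- unique(unlist(lapply(c(spec$mean_terms, spec$disp_terms),
                               `[[`, "vars")))
  missing_cov <- setdiff(vars, names(table))
  if (length(missing_cov)) {
    stop("spec references covariates absent from table: ",
         paste(missing_cov, collapse = ", "))
  }
  quant <- intersect(vars, QUANT_COVARS)
  centers <- vapply(quant, function(v) mean(table[[v]]), numeric(1))
  fac <- vars[vapply(vars, function(v)
    is.character(table[[v]]) || is.factor(table[[v]]), logical(1))]
  levels <- lapply(fac, function(v) sort(unique(as.character(table[[v]]))))
  names(levels) <- fac
  list(centers = centers, factor_levels = levels)
}

# one covariate -> matrix of columns (1 col, or k-1 treatment dummies)
covar_columns <- function(table, v, info) {
  x <- table[[v]]
  if (!is.null(info$factor_levels[[v]])) {
    lev <- info$factor_levels[[v]]
    x <- as.character(x)
    bad <- setdiff(unique(x), lev)
    if (length(bad)) {
      stop("unseen level(s) in '", v, "': ", paste(bad, collapse = ", "))
    }
    cols <- vapply(lev[-1], function(l) as.numeric(x == l),
                   numeric(length(x)))
    cols <- matrix(cols, nrow = length(x),
                   dimnames = list(NULL, paste0(v, lev[-1])))
    return(cols)
  }
  x <- as.numeric(x)
  if (v %in% names(info$centers)) x <- x - info$centers[[v]]
  matrix(x, ncol = 1, dimnames = list(NULL, v))
}

term_columns <- function(table, t, info) {
  n <- nrow(table)
  switch(t$kind,
    intercept = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
    main = covar_columns(table, t$vars, info),
    square = {
      m <- covar_columns(table, t$vars, info)
      matrix(m[, 1]^2, ncol = 1, dimnames = list(NULL, term_label(t)))
    },
    interaction = {
      a <- covar_columns(table, t$vars[1], info)
      b <- covar_columns(table, t$vars[2], info)
      out <- do.call(cbind, lapply(colnames(a), function(ca)
        vapply(colnames(b), function(cb) a[, ca] * b[, cb], numeric(n))))
      out <- matrix(out, nrow = n)
      colnames(out) <- as.vector(outer(colnames(a), colnames(b), paste,
                                       sep = ":"))
      out
    })
}

#' Build design matrices for the mean and dispersion parts
#'
#' Quantitative covariates are centered (training means, or the stored means
#' in `design_info` when scoring new data) before any square or interaction
#' is formed; factor labels expand to treatment-coded dummies.
#'
#' @param table Data frame of raw (uncentered) observations.
#' @param spec A [bb_spec()].
#' @param design_info Centering constants and factor levels from a previous
#'   call (for scoring new data); `NULL` to compute from `table`.
#' @return List with matrices `X` (mean part), `Z` (dispersion part) and the
#'   `design_info` used.
#' @export
build_design <- function(table, spec, design_info = NULL) {
  stopifnot(inherits(spec, "bb_spec"))
  if (is.null(design_info)) design_info <- make_design_info(table, spec)
  vars <- unique(unlist(lapply(c(spec$mean_terms, spec$disp_terms),
                               `[[`, "vars")))
  missing_cov <- setdiff(vars, names(table))
  if (length(missing_cov)) {
    stop("spec references covariates absent from table: ",
         paste(missing_cov, collapse = ", "))
  }
  X <- do.call(cbind, lapply(spec$mean_terms, term_columns,
                             table = table, info = design_info))
  Z <- do.call(cbind, lapply(spec$disp_terms, term_columns,
                             table = table, info = design_info))
  list(X = X, Z = Z, design_info = design_info)
}
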