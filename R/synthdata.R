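#' Configuration for the synthetic training-table generator
#'
#' The generator emulates a gold-standard-derived training set: covariates
#' drawn over realistic call-set ranges, and TP counts drawn Beta-binomially
#' from the logit-mean / log-dispersion regression structure. Coefficient
#' defaults are the fitted (11, 6) model of the WGS/WES study the package
#' implements; covariate ranges default to realistic human call-set values
#' (Ti/Tv 1-3.5, Het/Hom 1-7, median depth 5-150, DpLt5 0-0.5, an even
#' WGS/WES mix, call-list sizes 5000-60000).
#'
#' @param n_obs Number of observations (call sets) to simulate.
#' @param spec A [bb_spec()] or [named_spec()] name (default `"m11_6"`).
#' @param beta,gamma Generating coefficient vectors for the mean and
#'   dispersion parts (lengths p and q of `spec`); defaults are the fitted
#'   (11, 6) coefficients when `spec` is `"m11_6"`-shaped, and must be
#'   supplied otherwise.
#' @param titv_range,hethom_range,med_dp_range,dp_lt5_range Uniform draw
#'   ranges for the quantitative covariates.
#' @param wes_prob Probability an observation is WES (`wes_indicator = 1`).
#' @param n_range Range of call-list sizes N (drawn uniformly, rounded).
#' @param titv_hethom_cor In `[0, 1]`: strength of the negative Ti/Tv vs
#'   Het/Hom association (0 = independent draws).
#' @param seed Integer seed; fixes the whole table.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_obs = 500, spec = "m11_6",
                       beta = NULL, gamma = NULL,
                       titv_range = c(1, 3.5), hethom_range = c(1, 7),
                       med_dp_range = c(5, 150), dp_lt5_range = c(0, 0.5),
                       wes_prob = 0.5, n_range = c(5000, 60000),
                       titv_hethom_cor = 0, seed = 1) {
  if (is.character(spec)) spec <- named_spec(spec)
  stopifnot(inherits(spec, "bb_spec"), n_obs >= 1,
            titv_hethom_cor >= 0, titv_hethom_cor <= 1)
  p <- length(spec$mean_terms); q <- length(spec$disp_terms)
  if (is.null(beta)) {
    if (p != 11) stop("no default beta for this spec; supply one of length ", p)
    beta <- c(5.02, -1.42, 5.15, -1.96e-2, -1.79,
              -1.75e-1, -1.40e-4, -4.47, 4.72e-2, 1.76, -1.91e-2)
  }
  if (is.null(gamma)) {
    if (q == 1) gamma <- -6.81047
    else if (q == 6) {
      gamma <- c(-6.81047, 3.00998, -10.04787, -0.33822, -6.32795, 9.01236)
    } else stop("no default gamma for this spec; supply one of length ", q)
  }
  stopifnot(length(beta) == p, length(gamma) == q)
  structure(list(n_obs = n_obs, spec = spec, beta = beta, gamma = gamma,
                 titv_range = titv_range, hethom_range = hethom_range,
                 med_dp_range = med_dp_range, dp_lt5_range = dp_lt5_range,
                 wes_prob = wes_prob, n_range = n_range,
                 titv_hethom_cor = titv_hethom_cor, seed = seed),
            class = "sim_config")
}

#' Simulate a training table from the Beta-binomial regression model
#'
#' Draws covariates, centers them (sample means, exactly as the fitter
#' will), forms `mu` via the logit link and `sigma` via the spec's
#' dispersion link, and draws `y ~ BetaBinomial(n, mu, sigma)` by Beta-then-
#' Binomial composition. Linear predictors pushed outside the numerically
#' representable range are clamped, with a warning giving the count.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `y`, `n`, `titv`, `hethom`, `med_dp`,
#'   `dp_lt5`, `wes_indicator` — the training-table format.
#' @examples
#' tab <- simulate_training_table(sim_config(n_obs = 50, seed = 7))
#' head(tab)
#' @export
simulate_training_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, {
    m <- config$n_obs
    u <- stats::runif(m)
    titv <- config$titv_range[1] + u * diff(config$titv_range)
    rho <- config$titv_hethom_cor
    v <- rho * (1 - u) + (1 - rho) * stats::runif(m)
    hethom <- config$hethom_range[1] + v * diff(config$hethom_range)
    tab <- data.frame(
      titv = titv,
      hethom = hethom,
      med_dp = stats::runif(m, config$med_dp_range[1], config$med_dp_range[2]),
      dp_lt5 = stats::runif(m, config$dp_lt5_range[1], config$dp_lt5_range[2]),
      wes_indicator = stats::rbinom(m, 1, config$wes_prob))
    n <- round(stats::runif(m, config$n_range[1], config$n_range[2]))
    d <- build_design(tab, config$spec)
    eta <- drop(d$X %*% config$beta)
    n_clamp <- sum(abs(eta) > 30)
    if (n_clamp > 0) {
      warning(n_clamp, " linear predictor(s) clamped to keep mu inside (0, 1)")
    }
    mu <- link_mu(pmin(pmax(eta, -30), 30))
    zg <- drop(d$Z %*% config$gamma)
    sigma <- if (identical(config$spec$dispersion_link, "log")) {
      exp(pmin(pmax(zg, -20), 20))
    } else {
      s <- link_sigma(zg, config$spec$dispersion_link)
      if (anyNA(s)) stop("Box-Cox dispersion predictor non-positive for ",
                         sum(is.na(s)), " row(s); adjust gamma")
      s
    }
    cbind(data.frame(y = rbetabinom(m, n, mu, sigma), n = n), tab)
  })
}

#' Simulate a matching truth/call VCF record pair
#'
#' Builds a truth set of `n_true` SNVs and a call set consisting of the
#' truth plus `n_false` fabricated false-positive records, with substitution
#' types chosen so the two components hit the requested Ti/Tv ratios (false
#' calls typically depress Ti/Tv). Validating the pair returns exactly
#' `tp = n_true`, `fp = n_false`.
#'
#' @param n_true,n_false Record counts (non-negative).
#' @param titv_true,titv_false Target Ti/Tv of the truth and FP components.
#' @param depth_mean Mean of the (shifted Poisson) per-record depth model.
#' @param het_frac Fraction of heterozygous genotypes.
#' @param contig Contig name for all records.
#' @param seed Integer seed.
#' @return List with `truth` and `calls` (variant record data frames) and
#'   `confident` (a region data frame covering all records).
#' @export
simulate_vcf_pair <- function(n_true, n_false, titv_true = 2.1,
                              titv_false = 0.5, depth_mean = 30,
                              het_frac = 0.6, contig = "1", seed = 1) {
  stopifnot(n_true >= 0, n_false >= 0, n_true + n_false >= 1)
  withr_seed(seed, {
    total <- n_true + n_false
    span <- 10L * total + 1000L
    pos <- sort(sample.int(span, total))
    make <- function(k, pos_k, titv, qual) {
      if (k == 0) return(parse_vcf_records_empty())
      ti_pairs <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"),
                         ncol = 2, byrow = TRUE)
      tv_pairs <- matrix(c("A", "C", "C", "A", "A", "T", "T", "A",
                           "C", "G", "G", "C", "G", "T", "T", "G"),
                         ncol = 2, byrow = TRUE)
      n_ti <- round(k * titv / (1 + titv))
      is_ti <- sample(rep(c(TRUE, FALSE), c(n_ti, k - n_ti)))
      pick <- function(mat, n) mat[sample.int(nrow(mat), n, replace = TRUE), ,
                                   drop = FALSE]
      sub <- matrix(NA_character_, k, 2)
      if (n_ti > 0) sub[is_ti, ] <- pick(ti_pairs, n_ti)
      if (k - n_ti > 0) sub[!is_ti, ] <- pick(tv_pairs, k - n_ti)
      n_het <- max(min(round(k * het_frac), k - 1), 1)
      gt <- sample(rep(c("het", "hom_alt"), c(n_het, k - n_het)))
      if (k == 1) gt <- "het"
      data.frame(contig = contig, pos = pos_k, ref = sub[, 1], alt = sub[, 2],
                 genotype = gt, qual = qual,
                 depth = stats::rpois(k, depth_mean - 1) + 1)
    }
    truth_idx <- if (n_true > 0) sort(sample.int(total, n_true)) else integer(0)
    truth <- make(n_true, pos[truth_idx], titv_true, qual = 60)
    fps <- make(n_false, pos[setdiff(seq_len(total), truth_idx)],
                titv_false, qual = 15)
    list(truth = truth, calls = rbind(truth, fps),
         confident = data.frame(contig = contig, start = 0L,
                                end = span + 1L))
  })
}

parse_vcf_records_empty <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), genotype = character(), qual = numeric(),
             depth = numeric())
}

#' Write variant records as a minimal VCF v4.2 file
#'
#' Fixture writer for toy call/truth sets produced by
#' [simulate_vcf_pair()]; emits one sample with GT and DP.
#'
#' @param records Variant record data frame.
#' @param path Output path.
#' @param sample Sample column name.
#' @export
write_vcf <- function(records, path, sample = "SAMPLE") {
  gt_map <- c(het = "0/1", hom_alt = "1/1", hom_ref = "0/0",
              missing = "./.")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  ord <- order(records$contig, records$pos)
  records <- records[ord, , drop = FALSE]
  body <- if (nrow(records)) {
    paste(records$contig, records$pos, ".", records$ref, records$alt,
          format(records$qual, trim = TRUE), "PASS", ".", "GT:DP",
          paste(gt_map[records$genotype], records$depth, sep = ":"),
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write regions as a BED3 file
#'
#' @param regions Region data frame (`contig`, `start`, `end`).
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  writeLines(if (nrow(regions)) {
    paste(regions$contig, regions$start, regions$end, sep = "\t")
  } else character(0), path)
  invisible(path)
}
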