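# a minimal hand-built fit whose mu and sigma are known exactly lets the
# interval arithmetic be checked in closed form
stub_fit <- function(beta, gamma) {
  spec <- bb_spec("1", "1")
  structure(list(spec = spec, beta = beta, gamma = gamma,
                 design_info = list(centers = numeric(0),
                                    factor_levels = list()),
                 table = data.frame(dummy = 1),
                 opt_converged = TRUE, converged = TRUE),
            class = "bbfit")
}

test_that("the Binomial-limit interval matches the closed form", {
  f <- stub_fit(beta = 0, gamma = -30) # mu = 0.5, sigma ~ 1e-13
  pi <- predict_interval(f, data.frame(dummy = 1), n = 100)
  z <- qnorm(0.975)
  expect_equal(pi$point, 0.5)
  expect_equal(pi$lower, 0.5 - z * 0.05, tolerance = 1e-6)
  expect_equal(pi$upper, 0.5 + z * 0.05, tolerance = 1e-6)
  expect_equal(pi$length_pct, 19.6, tolerance = 1e-3)
})

test_that("intervals truncate to [0,1] and shrink as mu approaches 1", {
  f <- stub_fit(beta = qlogis(0.99), gamma = log(0.5))
  pi <- predict_interval(f, data.frame(dummy = 1), n = 50)
  expect_equal(pi$upper, 1) # untruncated upper would exceed 1
  expect_lte(pi$lower, pi$point)

  lengths <- vapply(c(0.9, 0.99, 0.999, 0.9999), function(m) {
    predict_interval(stub_fit(qlogis(m), -30),
                     data.frame(dummy = 1), n = 1e6)$length_pct
  }, numeric(1))
  expect_true(all(diff(lengths) < 0))
})

test_that("interval length grows with the dispersion at fixed mu and N", {
  lens <- vapply(c(-8, -6, -4, -2), function(g) {
    predict_interval(stub_fit(qlogis(0.9), g),
                     data.frame(dummy = 1), n = 1000)$length_pct
  }, numeric(1))
  expect_true(all(diff(lens) > 0))
})

test_that("out-of-envelope covariates warn but still predict", {
  tab <- simulate_training_table(small_config(n_obs = 120, seed = 41))
  f <- bbfit(tab, bb_spec(c("1", "titv", "med_dp"), "1"))
  new <- tab[1, ]
  new$titv <- max(tab$titv) + 2
  expect_warning(predict_interval(f, new, n = 1e4), "envelope")
  expect_silent(predict_interval(f, tab[1, ], n = 1e4))
})

test_that("leave-one-out intervals are deterministic and need enough rows", {
  tab <- simulate_training_table(small_config(n_obs = 60, seed = 12))
  spec <- bb_spec(c("1", "titv", "med_dp"), "1")
  a <- loo_intervals(tab, spec)
  b <- loo_intervals(tab, spec)
  expect_equal(a, b)
  expect_equal(nrow(a), 60)
  expect_true(all(a$converged))
  expect_error(loo_intervals(tab[1, , drop = FALSE], spec), "at least")
})

test_that("length summaries use type-7 quartiles and honor restriction", {
  iv <- data.frame(point = seq(0.90, 0.98, by = 0.02),
                   lower = 0, upper = 1,
                   length_pct = c(1, 2, 3, 4, 5))
  s <- summarize_lengths(iv)
  expect_equal(unlist(s[c("min", "q1", "median", "q3", "max")]),
               c(min = 1, q1 = 2, median = 3, q3 = 4, max = 5))
  expect_equal(summarize_lengths(iv, restrict_point_above = 0)[1:5],
               s[1:5])
  r <- summarize_lengths(iv, restrict_point_above = 0.95)
  expect_lte(r$max, s$max)
  expect_error(summarize_lengths(iv, restrict_point_above = 1), "left")
})

test_that("restricting to high point estimates never lengthens the maximum", {
  tab <- simulate_training_table(small_config(n_obs = 80, seed = 19))
  f <- bbfit(tab, bb_spec(c("1", "titv", "med_dp"), "1"))
  pi <- predict_interval(f, tab, n = tab$n)
  s_all <- summarize_lengths(pi)
  s_hi <- summarize_lengths(pi, restrict_point_above = 0.95)
  expect_gte(s_all$max, s_hi$max)
})
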