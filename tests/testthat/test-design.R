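test_that("centering subtracts means, stores constants, and is idempotent", {
  tab <- data.frame(titv = c(2, 3, 4), hethom = c(1, 2, 3),
                    med_dp = c(10, 20, 30), dp_lt5 = c(0, 0.1, 0.2),
                    wes_indicator = c(0, 1, 1))
  c1 <- center_covariates(tab)
  expect_equal(c1$table$titv, c(-1, 0, 1))
  expect_equal(c1$centers[["titv"]], 3)
  expect_equal(c1$table$wes_indicator, tab$wes_indicator) # never centered
  c2 <- center_covariates(c1$table)
  expect_equal(c2$table, c1$table) # already mean-zero
  expect_error(center_covariates(tab, "missing_cov"), "absent")
})

test_that("stored centering reproduces training-scale values on new data", {
  set.seed(4)
  tab <- simulate_training_table(sim_config(n_obs = 40, seed = 4))
  spec <- named_spec("m11_6")
  d <- build_design(tab, spec)
  one <- build_design(tab[7, , drop = FALSE], spec,
                      design_info = d$design_info)
  expect_equal(one$X[1, ], d$X[7, ])
  expect_equal(one$Z[1, ], d$Z[7, ])
})

test_that("named specs have the registered shapes and nested dispersion", {
  expect_equal(length(named_spec("m11_6")$mean_terms), 11)
  expect_equal(length(named_spec("m11_6")$disp_terms), 6)
  expect_equal(length(named_spec("m11_1")$mean_terms), 11)
  expect_equal(length(named_spec("m11_1")$disp_terms), 1)
  expect_equal(length(named_spec("m15_1")$mean_terms), 15)
  expect_equal(length(named_spec("global_mean_18")$mean_terms), 18)
  expect_error(named_spec("nope"), "known")
  for (nm in c("m11_6", "m11_1", "m15_1", "global_mean_18")) {
    sp <- named_spec(nm)
    mk <- vapply(sp$mean_terms, snvppv:::term_key, character(1))
    dk <- vapply(sp$disp_terms, snvppv:::term_key, character(1))
    expect_true(all(dk %in% mk))
  }
})

test_that("spec construction rejects invalid term sets", {
  expect_error(bb_spec(c("1", "titv"), c("1", "med_dp")), "subset")
  expect_error(bb_spec(c("titv"), "1"), "intercept")
  expect_error(bb_spec(c("1", "titv", "titv"), "1"), "duplicate")
  expect_error(bb_spec(c("1", "wes_indicator^2"), "1"), "quantitative")
  expect_error(bb_spec(c("1", "titv:titv"), "1"), "distinct")
})

test_that("design columns follow spec order with centered second-order terms", {
  tab <- data.frame(y = 1, n = 2,
                    titv = c(2, 3), hethom = c(1, 3), med_dp = c(10, 30),
                    dp_lt5 = c(0, 0.2), wes_indicator = c(0, 1))
  d <- build_design(tab, named_spec("m11_6"))
  expect_equal(ncol(d$X), 11)
  expect_equal(ncol(d$Z), 6)
  # row 2: centered titv = 0.5, wes = 1 -> interaction 0.5, square 0.25
  expect_equal(unname(d$X[2, "wes_indicator:titv"]), 0.5)
  expect_equal(unname(d$X[2, "I(titv^2)"]), 0.25)
  # a mean-value row leaves only intercept and WES-derived entries nonzero
  tab3 <- rbind(tab, data.frame(y = 1, n = 2, titv = 2.5, hethom = 2,
                                med_dp = 20, dp_lt5 = 0.1,
                                wes_indicator = 1))
  d3 <- build_design(tab3, named_spec("m11_6"))
  nz <- d3$X[3, d3$X[3, ] != 0]
  expect_equal(sort(names(nz)), sort(c("(Intercept)", "wes_indicator")))
})

test_that("factor labels expand to treatment-coded columns", {
  tab <- data.frame(y = c(5, 6, 7), n = 10,
                    titv = c(2, 2.5, 3),
                    kit_label = c("WGS", "WES-Nextera", "WES-TrueSeq"))
  sp <- bb_spec(c("1", "titv", "kit_label"), "1")
  d <- build_design(tab, sp)
  expect_equal(ncol(d$X), 4) # intercept + titv + 2 dummies (3 levels)
  expect_true(all(c("kit_labelWES-TrueSeq", "kit_labelWGS") %in%
                  colnames(d$X)))
  new <- build_design(tab[2, , drop = FALSE], sp, design_info = d$design_info)
  expect_equal(new$X[1, ], d$X[2, ])
  tab$kit_label[1] <- "WES-Agilent"
  expect_error(build_design(tab, sp, design_info = d$design_info), "unseen")
})

test_that("term strings round-trip through the parser", {
  ts <- parse_terms(c("1", "titv", "I(med_dp^2)", "dp_lt5^2",
                      "wes_indicator:titv"))
  expect_equal(vapply(ts, function(t) t$kind, character(1)),
               c("intercept", "main", "square", "square", "interaction"))
})
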