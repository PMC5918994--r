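test_that("the generator is fully reproducible under a fixed seed", {
  cfg <- sim_config(n_obs = 60, seed = 14)
  expect_equal(simulate_training_table(cfg), simulate_training_table(cfg))
  cfg2 <- sim_config(n_obs = 60, seed = 15)
  expect_false(isTRUE(all.equal(simulate_training_table(cfg),
                                simulate_training_table(cfg2))))
})

test_that("covariates respect the configured ranges and WES mix", {
  tab <- simulate_training_table(sim_config(n_obs = 400, seed = 16))
  expect_true(all(tab$titv >= 1 & tab$titv <= 3.5))
  expect_true(all(tab$hethom >= 1 & tab$hethom <= 7))
  expect_true(all(tab$med_dp >= 5 & tab$med_dp <= 150))
  expect_true(all(tab$dp_lt5 >= 0 & tab$dp_lt5 <= 0.5))
  expect_true(all(tab$wes_indicator %in% 0:1))
  expect_gt(mean(tab$wes_indicator), 0.4)
  expect_lt(mean(tab$wes_indicator), 0.6)
  expect_true(all(tab$y >= 0 & tab$y <= tab$n))
})

test_that("a deeply negative dispersion intercept reproduces Binomial noise", {
  spec <- bb_spec("1", "1")
  # fixed covariate pattern: every row shares mu; N fixed
  cfg <- sim_config(n_obs = 4000, spec = spec, beta = qlogis(0.9),
                    gamma = -12, n_range = c(2000, 2000), seed = 18)
  tab <- simulate_training_table(cfg)
  v_emp <- var(tab$y)
  v_bin <- 2000 * 0.9 * 0.1
  expect_equal(v_emp, v_bin, tolerance = 0.08)
})

test_that("simulated Y matches the Beta-binomial moments at fixed covariates", {
  spec <- bb_spec("1", "1")
  cfg <- sim_config(n_obs = 10000, spec = spec, beta = qlogis(0.8),
                    gamma = log(0.002), n_range = c(1000, 1000), seed = 20)
  tab <- simulate_training_table(cfg)
  m <- bb_moments(0.8, 0.002, 1000)
  expect_equal(mean(tab$y), m$mean, tolerance = 0.005)
  expect_equal(var(tab$y), m$variance, tolerance = 0.05)
})

test_that("the negative Ti/Tv-Het/Hom association knob works", {
  t0 <- simulate_training_table(sim_config(n_obs = 400, seed = 22,
                                           titv_hethom_cor = 0))
  t1 <- simulate_training_table(sim_config(n_obs = 400, seed = 22,
                                           titv_hethom_cor = 0.9))
  expect_lt(cor(t1$titv, t1$hethom), -0.5)
  expect_gt(cor(t0$titv, t0$hethom), -0.2)
})

test_that("truth/call pairs round-trip through validation exactly", {
  pair <- simulate_vcf_pair(100, 0, seed = 26)
  r <- match_variants(pair$calls, pair$truth, pair$confident)
  expect_equal(r$ppv, 1)
  pair <- simulate_vcf_pair(100, 100, seed = 27)
  r <- match_variants(pair$calls, pair$truth, pair$confident)
  expect_equal(r$ppv, 0.5)
  expect_equal(r$tp, 100); expect_equal(r$fp, 100)
  # combined call-set Ti/Tv sits between the component targets
  st <- compute_stats(pair$calls, 0)
  expect_gt(st$titv, 0.5)
  expect_lt(st$titv, 2.1)
})

test_that("a simulated pair flows end-to-end into a fittable training row", {
  pair <- simulate_vcf_pair(400, 60, seed = 28)
  td <- tempfile(); dir.create(td)
  write_vcf(pair$calls, file.path(td, "calls.vcf"))
  write_vcf(pair$truth, file.path(td, "truth.vcf"))
  write_bed(pair$confident, file.path(td, "conf.bed"))
  calls <- read_snvs(file.path(td, "calls.vcf"),
                     filter_spec(require_nonref = TRUE))
  truth <- read_snvs(file.path(td, "truth.vcf"),
                     filter_spec(require_nonref = TRUE))
  conf <- read_regions(file.path(td, "conf.bed"))
  rep <- match_variants(calls, truth, conf,
                        stats = compute_stats(calls, wes_indicator = 0))
  row <- as_training_row(rep)
  expect_equal(row$y, 400)
  expect_equal(row$n, 460)
  # the row drops straight into a training table and prediction
  tab <- simulate_training_table(sim_config(n_obs = 80, seed = 29))
  f <- bbfit(tab, named_spec("m11_1"))
  pi <- suppressWarnings(predict_interval(f, row, n = row$n))
  expect_true(pi$lower >= 0 && pi$upper <= 1)
})
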