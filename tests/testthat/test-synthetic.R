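test_that("zero noise reproduces the deterministic latent trajectory exactly", {
  cfg <- synthetic_config(treatments = "control", conditions = "ambient",
                          noise = list(moisture_cv = 0, aw_sd = 0,
                                       attribute_cv = 0), seed = 3)
  syn <- generate_storage_experiment(cfg)
  traj <- integrate_uptake(cfg$isotherms$control, cfg$pkg,
                           cfg$environments$ambient, cfg$powder,
                           horizon = 180, times = cfg$sampling_days)
  expect_equal(syn$moisture_pct_wb, dry_to_wet(traj$moisture_db),
               tolerance = 1e-10)
  expect_equal(syn$aw, traj$water_activity, tolerance = 1e-10)
})

test_that("identical seeds give bit-identical experiments", {
  s1 <- generate_storage_experiment(synthetic_config(seed = 42))
  s2 <- generate_storage_experiment(synthetic_config(seed = 42))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  s3 <- generate_storage_experiment(synthetic_config(seed = 43))
  expect_false(identical(s1$moisture_pct_wb, s3$moisture_pct_wb))
})

test_that("generated values do not depend on series order or subsetting", {
  full <- generate_storage_experiment(synthetic_config(seed = 9))
  sub <- generate_storage_experiment(
    synthetic_config(treatments = c("TCP", "control"),
                     conditions = "ambient", seed = 9))
  for (nm in c("control.ambient", "TCP.ambient")) {
    expect_identical(split_series(sub)[[nm]]$moisture_pct_wb,
                     split_series(full)[[nm]]$moisture_pct_wb, label = nm)
  }
})

test_that("generated tables satisfy the storage schema", {
  syn <- generate_storage_experiment(synthetic_config(seed = 5))
  expect_s3_class(validate_storage(as.data.frame(syn)), "storage_experiment")
  expect_true(all(syn$aw >= 0 & syn$aw < 1))
  expect_true(all(syn$moisture_pct_wb >= 0 & syn$moisture_pct_wb < 100))
  expect_true(all(syn$tpc_cfu_per_g >= 661))
  expect_true(all(syn$caking_pct >= 0 & syn$caking_pct <= 100))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(rnorm(1))
  invisible(generate_storage_experiment(synthetic_config(seed = 77)))
  after <- rnorm(2)
  expect_identical(before[2:3], after)
})

test_that("drier true isotherms (anticaking) never shorten the true shelf life", {
  cfg <- synthetic_config(seed = 1)
  truth <- attr(generate_storage_experiment(cfg), "ground_truth")$true_theta
  for (cond in c("ambient", "accelerated")) {
    expect_gt(truth[[paste0("TCP.", cond)]], truth[[paste0("SiO2.", cond)]])
    expect_gt(truth[[paste0("SiO2.", cond)]], truth[[paste0("control.", cond)]])
  }
})

test_that("treated series cross the critical moisture later than control in nearly all replicates", {
  later <- vapply(1:100, function(r) {
    syn <- generate_storage_experiment(
      synthetic_config(treatments = c("control", "TCP"),
                       conditions = "ambient", seed = 1000 + r))
    s <- split_series(syn)
    cross <- vapply(s, function(d) {
      experimental_shelf_life(d$day, wet_to_dry(d$moisture_pct_wb),
                              0.006)$theta_days
    }, numeric(1))
    cross[["TCP.ambient"]] > cross[["control.ambient"]]
  }, logical(1))
  expect_gte(mean(later), 0.95)
})

test_that("noiseless recovery is exact and noisy recovery is accurate", {
  quiet <- synthetic_config(treatments = "control", conditions = "ambient",
                            noise = list(moisture_cv = 0, aw_sd = 0,
                                         attribute_cv = 0))
  rec <- recovery_experiment(quiet, n_replicates = 1, seed = 2)
  expect_lt(rec$summary$param_bias_rel, 1e-6)
  expect_lt(abs(rec$results$predicted_error), 0.01)
  expect_identical(rec$n_fit_failures, 0L)
})

test_that("a critical moisture above equilibrium yields zero finite recoveries", {
  cfg <- synthetic_config(treatments = "TCP", conditions = "ambient",
                          powder = powder_spec(0.0192, 0.004, 0.05))
  rec <- recovery_experiment(cfg, n_replicates = 3, seed = 4)
  expect_identical(rec$summary$n_finite, 0L)
  expect_true(all(!is.finite(rec$results$predicted_theta)))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(sampling_days = c(10, 20)), "start at 0")
  expect_error(synthetic_config(noise = list(moisture_cv = -1, aw_sd = 0,
                                             attribute_cv = 0)), ">= 0")
  expect_error(synthetic_config(treatments = "butter"), "'arg'")
})
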