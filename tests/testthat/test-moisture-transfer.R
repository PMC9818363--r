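test_that("spec constructors validate their invariants", {
  expect_equal(package_spec(5.4e-8, width = 0.155, height = 0.193)$area,
               2 * 0.155 * 0.193)
  expect_error(package_spec(0, area = 0.06), "permeability")
  expect_error(package_spec(5.4e-8, area = -1), "area")
  expect_error(environment_spec(25, 0), "rel_humidity")
  expect_error(powder_spec(0.02, 0.006, 0.004), "x_critical")
})

test_that("saturation pressure returns steam-table values and a correlation elsewhere", {
  expect_identical(saturation_pressure(25), 3173.027)
  expect_identical(saturation_pressure(40), 7380.726)
  p30 <- saturation_pressure(30)
  expect_lt(abs(p30 - 4246) / 4246, 0.02)
  expect_true(attr(p30, "interpolated"))
  expect_error(saturation_pressure(0), "\\(0, 100\\)")
  expect_error(saturation_pressure(100), "\\(0, 100\\)")
})

test_that("uptake rate reproduces the published hand arithmetic", {
  # aw fixed at 0.28 at the initial state via a near-flat linear isotherm
  fit <- isotherm_fit("linear", c(a = 0.28, b = 1e-9))
  r_amb <- uptake_rate(0, fit, study_pkg(), study_env_ambient(), study_powder())
  expect_equal(r_amb, 5.4e-8 * 0.06 * 3173.027 / 0.0192 * (0.60 - 0.28),
               tolerance = 1e-12)
  expect_equal(r_amb, 1.7134e-4, tolerance = 1e-4)
  r_acc <- uptake_rate(0, fit, study_pkg(), study_env_accel(), study_powder())
  expect_equal(r_acc, 5.4e-8 * 0.06 * 7380.726 / 0.0192 * (0.90 - 0.28),
               tolerance = 1e-12)
  expect_equal(r_acc, 7.722e-4, tolerance = 2e-4)
})

test_that("uptake rate is zero at equilibrium and signed by the driving force", {
  fit <- isotherm_fit("linear", c(a = 0.1, b = 25))
  x_eq <- (0.6 - 0.1) / 25
  env <- study_env_ambient()
  expect_equal(uptake_rate(x_eq, fit, study_pkg(), env, study_powder()), 0)
  expect_gt(uptake_rate(x_eq / 2, fit, study_pkg(), env, study_powder()), 0)
  expect_lt(uptake_rate(x_eq * 1.5, fit, study_pkg(), env, study_powder()), 0)
})

test_that("integration matches the closed-form solution for a linear isotherm", {
  a <- 0.1; b <- 25
  fit <- isotherm_fit("linear", c(a = a, b = b))
  pkg <- study_pkg(); env <- study_env_ambient(); powder <- study_powder()
  cc <- pkg$permeability * pkg$area * env$sat_pressure / powder$dry_mass
  x_eq <- (env$rel_humidity - a) / b
  times <- seq(0, 200, by = 0.5)
  closed <- x_eq + (powder$x_initial - x_eq) * exp(-cc * b * times)
  traj <- integrate_uptake(fit, pkg, env, powder, horizon = 200, times = times)
  expect_equal(traj$moisture_db, closed, tolerance = 1e-8)
})

test_that("starting at equilibrium yields a constant trajectory", {
  fit <- gab_example()
  env <- study_env_ambient()
  x_eq <- equilibrium_moisture(fit, env)
  powder <- powder_spec(0.0192, x_eq, x_eq * 2)
  traj <- integrate_uptake(fit, study_pkg(), env, powder, horizon = 100)
  expect_equal(traj$moisture_db, rep(x_eq, nrow(traj)), tolerance = 1e-9)
})

test_that("trajectories never overshoot the equilibrium moisture", {
  pars <- random_gab_params(6, seed = 303)
  for (i in seq_len(nrow(pars))) {
    fit <- isotherm_fit("gab", unlist(pars[i, ]))
    env <- study_env_ambient()
    x_star <- equilibrium_moisture(fit, env)
    powder <- powder_spec(0.0192, x_star / 10, x_star)
    traj <- integrate_uptake(fit, study_pkg(), env, powder, horizon = 2000)
    expect_true(all(traj$moisture_db <= x_star * (1 + 1e-8)))
    expect_true(all(diff(traj$moisture_db) > -1e-12))
    expect_equal(traj$water_activity,
                 sapply(traj$moisture_db, function(x) isotherm_aw(fit, x)),
                 tolerance = 1e-9)
  }
})

test_that("adaptive integration agrees with fixed-step RK4 to 1e-6 relative", {
  fit <- gab_example()
  pkg <- study_pkg(); env <- study_env_ambient()
  powder <- study_powder(xi = 0.004, xc = 0.02)
  oracle <- rk4_uptake(fit, pkg, env, powder, horizon = 200, h = 0.01)
  at <- seq(0, 200, by = 10)
  traj <- integrate_uptake(fit, pkg, env, powder, horizon = 200, times = at)
  expect_equal(traj$moisture_db,
               oracle$moisture_db[match(at, oracle$time)],
               tolerance = 1e-6)
})

test_that("moisture response is monotone in Rh, p*, K and Ap", {
  fit <- gab_example()
  base <- list(K = 5.4e-8, Ap = 0.06, Rh = 0.5, pstar = 3173.027)
  at <- c(5, 20, 60, 150)
  xat <- function(cfg) {
    integrate_uptake(fit, package_spec(cfg$K, area = cfg$Ap),
                     environment_spec(25, cfg$Rh, sat_pressure = cfg$pstar),
                     study_powder(), horizon = 150,
                     times = c(0, at))$moisture_db[-1]
  }
  x0 <- xat(base)
  set.seed(404)
  for (nm in names(base)) {
    for (rep in 1:3) {
      up <- base
      up[[nm]] <- base[[nm]] * (1 + runif(1, 0.05, 0.5))
      if (nm == "Rh") up$Rh <- min(up$Rh, 0.95)
      expect_true(all(xat(up) >= x0 - 1e-10),
                  label = sprintf("monotone in %s", nm))
    }
  }
})

test_that("trajectory containers validate their shape", {
  expect_error(moisture_trajectory(c(1, 2), c(0.1, 0.2), c(0.2, 0.3)),
               "from 0")
  expect_error(moisture_trajectory(c(0, 1), c(0.1), c(0.2, 0.3)),
               "equal length")
  tr <- moisture_trajectory(c(0, 1), c(0.1, 0.2), c(0.2, 0.3), "synthetic")
  expect_identical(attr(tr, "provenance"), "synthetic")
})
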