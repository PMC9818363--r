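test_that("moisture basis conversions are mutually inverse", {
  expect_equal(wet_to_dry(5.613), 5.613 / 94.387)
  expect_equal(dry_to_wet(wet_to_dry(5.613)), 5.613)
  m <- seq(0, 40, by = 2.5)
  expect_equal(dry_to_wet(wet_to_dry(m)), m)
  expect_error(wet_to_dry(100), "\\[0, 100\\)")
  expect_error(dry_to_wet(-0.1), "non-negative")
})

test_that("GAB evaluation matches hand arithmetic and degenerates correctly", {
  fit <- gab_example()
  # u = k aw = 0.4: X = 0.05 * 10 * 0.4 / ((1 - 0.4) * (1 - 0.4 + 10 * 0.4))
  #              = 0.2 / (0.6 * 4.6) = 0.2 / 2.76
  expect_equal(isotherm_moisture(fit, 0.5), 0.2 / 2.76, tolerance = 1e-12)
  expect_equal(isotherm_aw(fit, 0.2 / 2.76), 0.5, tolerance = 1e-9)
  expect_identical(isotherm_moisture(fit, 0), 0)
  expect_error(isotherm_moisture(fit, 1), "below")
  expect_warning(isotherm_moisture(fit, 0.95), "0.94")
})

test_that("linear isotherm handles the intercept and inverts in closed form", {
  fit <- isotherm_fit("linear", c(a = 0.2, b = 50))
  expect_equal(isotherm_moisture(fit, 0.2), 0)
  expect_error(isotherm_moisture(fit, 0.1), "intercept")
  expect_equal(isotherm_aw(fit, 0.004), 0.4)
})

test_that("isotherm evaluation is strictly increasing for admissible parameters", {
  aw <- seq(0.01, 0.9, by = 0.01)
  pars <- random_gab_params(25)
  for (i in seq_len(nrow(pars))) {
    fit <- isotherm_fit("gab", unlist(pars[i, ]))
    expect_true(all(diff(isotherm_moisture(fit, aw)) > 0),
                label = sprintf("monotone GAB case %d", i))
  }
  for (fam in c("halsey", "oswin", "iglesias_chirife")) {
    fit <- isotherm_fit(fam, setNames(c(0.02, 1.2), c("a", "b")))
    expect_true(all(diff(isotherm_moisture(fit, aw)) > 0), label = fam)
  }
})

test_that("inversion round-trips to 1e-9 relative over the working range", {
  aw <- seq(0.01, 0.9, by = 0.045)
  pars <- random_gab_params(12, seed = 202)
  for (i in seq_len(nrow(pars))) {
    fit <- isotherm_fit("gab", unlist(pars[i, ]))
    x <- isotherm_moisture(fit, aw)
    expect_equal(isotherm_aw(fit, x), aw, tolerance = 1e-9)
    expect_equal(isotherm_moisture(fit, isotherm_aw(fit, x)), x,
                 tolerance = 1e-9)
  }
  for (fam in c("halsey", "oswin", "iglesias_chirife")) {
    fit <- isotherm_fit(fam, setNames(c(0.02, 1.2), c("a", "b")))
    x <- isotherm_moisture(fit, aw)
    expect_equal(isotherm_aw(fit, x), aw, tolerance = 1e-9)
  }
})

test_that("moisture above the isotherm range raises a range error", {
  fit <- gab_example()
  xmax <- suppressWarnings(isotherm_moisture(fit, 1 - 1e-9))
  expect_error(isotherm_aw(fit, xmax * 1.01), "exceeds")
})

test_that("noiseless GAB points are recovered to 1e-6 relative", {
  true <- gab_example()
  aw <- seq(0.1, 0.9, by = 0.1)
  pts <- sorption_points(isotherm_moisture(true, aw), aw, temperature = 25)
  fit <- fit_isotherm(pts, "gab")
  expect_lt(max(abs(fit$params - true$params) / true$params), 1e-6)
  expect_lt(fit$rss, 1e-16)
  expect_identical(fit$n_points, 9L)
  expect_identical(fit$temperature, 25)
})

test_that("1 percent multiplicative noise at n = 20 recovers GAB within 10 percent", {
  true <- gab_example()
  set.seed(11)
  aw <- seq(0.04, 0.92, length.out = 20)
  x <- isotherm_moisture(true, aw) * (1 + 0.01 * rnorm(20))
  fit <- fit_isotherm(sorption_points(x, aw), "gab")
  expect_lt(max(abs(fit$params - true$params) / true$params), 0.10)
})

test_that("under-determined fits are refused with an informative error", {
  pts <- sorption_points(c(0.02, 0.04, 0.06), c(0.2, 0.4, 0.6))
  expect_error(fit_isotherm(pts, "gab"), "insufficient data")
  expect_error(fit_isotherm(pts[1:2, ], "oswin"), "insufficient data")
})

test_that("GAB beats a straight line on the bundled control-ambient series", {
  s <- split_series(apricot_storage())[["control.ambient"]]
  pts <- data.frame(moisture_db = wet_to_dry(s$moisture_pct_wb),
                    water_activity = s$aw)
  gab <- fit_isotherm(pts, "gab")
  lin <- fit_isotherm(pts, "linear")
  expect_lt(gab$rss, lin$rss)
})

test_that("alternative families fit their own data back", {
  aw <- seq(0.05, 0.9, length.out = 12)
  for (fam in c("halsey", "oswin", "iglesias_chirife")) {
    true <- isotherm_fit(fam, setNames(c(0.03, 1.4), c("a", "b")))
    fit <- fit_isotherm(sorption_points(isotherm_moisture(true, aw), aw), fam)
    expect_equal(unname(fit$params), unname(true$params), tolerance = 1e-4,
                 label = fam)
  }
})

test_that("isotherm JSON serialization round-trips", {
  fit <- fit_isotherm(sorption_points(
    isotherm_moisture(gab_example(), seq(0.1, 0.9, 0.1)),
    seq(0.1, 0.9, 0.1), temperature = 25), "gab")
  path <- withr::local_tempfile(fileext = ".json")
  write_isotherm_json(fit, path)
  back <- read_isotherm_json(path)
  expect_equal(back$params, fit$params)
  expect_equal(back$family, fit$family)
  expect_equal(back$rss, fit$rss)
})

test_that("invalid parameter vectors are rejected at construction", {
  expect_error(isotherm_fit("gab", c(Xm = 0.05, C = 10, k = 1.2)), "k < 1")
  expect_error(isotherm_fit("gab", c(Xm = -1, C = 10, k = 0.5)), "Xm > 0")
  expect_error(isotherm_fit("gab", c(a = 1, b = 2)), "needs parameters")
})
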