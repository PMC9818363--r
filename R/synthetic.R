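# canonical series ordering used to derive per-series RNG substreams, so that
# generated values do not depend on the order treatments/conditions are listed
.series_codes <- c(control.ambient = 1L, TCP.ambient = 2L, SiO2.ambient = 3L,
                   control.accelerated = 4L, TCP.accelerated = 5L,
                   SiO2.accelerated = 6L)

# default true isotherms: GAB parameters emulating the calibrated study --
# same energy constant and correction factor, equilibrium moisture ordered
# control > SiO2 > TCP so anticaking treatments equilibrate drier
.default_true_isotherms <- function(temperature = NA_real_) {
  mk <- function(xm) isotherm_fit("gab", c(Xm = xm, C = 5, k = 0.95),
                                  temperature = temperature)
  list(control = mk(0.012), SiO2 = mk(0.009), TCP = mk(0.007))
}

# least-squares slope of each quality attribute on dry-basis moisture gain in
# the transcribed study (pooled over series), used as generator defaults
.default_attribute_slopes <- function() {
  storage <- apricot_storage()
  x <- wet_to_dry(storage$moisture_pct_wb)
  gain <- x - min(x)
  slope_of <- function(col, log10scale = FALSE) {
    y <- storage[[col]]
    if (log10scale) y <- log10(y)
    unname(coef(lm(y ~ gain))[2])
  }
  c(caking_pct = slope_of("caking_pct"),
    carr_index_pct = slope_of("carr_index_pct"),
    hygroscopicity = slope_of("hygroscopicity"),
    prt_min = slope_of("prt_min"),
    rr = slope_of("rr"),
    L = slope_of("L"),
    a = slope_of("a"),
    b = slope_of("b"),
    log10_tpc = slope_of("tpc_cfu_per_g", log10scale = TRUE))
}

# day-0 baselines of the transcribed study
.default_baselines <- c(moisture = NA, caking_pct = 10.191,
                        carr_index_pct = 22.356, hygroscopicity = 23.041,
                        prt_min = 1.423, rr = 6.047, L = 57.337, a = 5.463,
                        b = 27.128, tpc_cfu_per_g = 661)

#' Configuration for a synthetic storage experiment
#'
#' Describes a simulated storage study with the design of the bundled
#' apricot-powder study: a set of treatments and storage conditions sampled
#' on a fixed schedule, a true sorption isotherm per treatment, the package /
#' environment / powder constants, and a noise model (multiplicative Gaussian
#' on moisture and quality attributes, additive Gaussian on water activity).
#' Quality attributes drift linearly in the latent moisture gain; the total
#' plate count drifts on the log10 scale and is floored at its day-0
#' baseline.
#'
#' @param treatments Subset of `c("control", "TCP", "SiO2")`.
#' @param conditions Subset of `c("ambient", "accelerated")`.
#' @param sampling_days Strictly increasing sampling schedule starting at 0
#'   (default: the study's monthly-then-20-day schedule).
#' @param isotherms Named list (by treatment) of true [isotherm_fit()]s.
#' @param pkg,powder Package and powder constants ([package_spec()],
#'   [powder_spec()]).
#' @param environments Named list (by condition) of [environment_spec()]s.
#' @param noise List with `moisture_cv` (multiplicative CV on wet-basis
#'   moisture), `aw_sd` (additive SD on water activity), `attribute_cv`
#'   (multiplicative CV on quality attributes).
#' @param baselines,slopes Day-0 attribute baselines and attribute-vs-moisture
#'   slopes; defaults are the bundled study's day-0 values and pooled
#'   least-squares slopes.
#' @param seed Integer seed; identical seeds give bit-identical experiments.
#' @return A list of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' @export
synthetic_config <- function(treatments = c("control", "TCP", "SiO2"),
                             conditions = c("ambient", "accelerated"),
                             sampling_days = c(0, 30, 60, 90, 120, 140, 160, 180),
                             isotherms = .default_true_isotherms(),
                             pkg = package_spec(5.4e-8, area = 0.0600),
                             environments = list(
                               ambient = environment_spec(25, 0.60,
                                                          sat_pressure = 3173.027),
                               accelerated = environment_spec(40, 0.90,
                                                              sat_pressure = 7380.726)),
                             powder = powder_spec(0.0192, 0.004, 0.006),
                             noise = list(moisture_cv = 0.01, aw_sd = 0.01,
                                          attribute_cv = 0.02),
                             baselines = .default_baselines,
                             slopes = .default_attribute_slopes(),
                             seed = 1L) {
  treatments <- match.arg(treatments, c("control", "TCP", "SiO2"),
                          several.ok = TRUE)
  conditions <- match.arg(conditions, c("ambient", "accelerated"),
                          several.ok = TRUE)
  if (sampling_days[1] != 0 || any(diff(sampling_days) <= 0)) {
    stop("sampling_days must be strictly increasing and start at 0",
         call. = FALSE)
  }
  if (!all(treatments %in% names(isotherms))) {
    stop("isotherms must be named by treatment", call. = FALSE)
  }
  if (!all(conditions %in% names(environments))) {
    stop("environments must be named by condition", call. = FALSE)
  }
  for (v in noise) {
    if (!is.finite(v) || v < 0) stop("noise levels must be >= 0",
                                     call. = FALSE)
  }
  structure(list(treatments = treatments, conditions = conditions,
                 sampling_days = sampling_days, isotherms = isotherms,
                 pkg = pkg, environments = environments, powder = powder,
                 noise = noise, baselines = baselines, slopes = slopes,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# run code with a private RNG stream, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic storage experiment
#'
#' For each treatment x condition series, the latent moisture trajectory is
#' integrated from the package moisture balance under the treatment's true
#' isotherm, sampled at the configured days, and observed with the
#' configured noise.  The output uses the same long schema as
#' [read_storage_csv()] and carries the ground truth (true isotherms and
#' true crossing times of the critical moisture) as attribute
#' `"ground_truth"`.
#'
#' @param cfg A [synthetic_config()].
#' @return A `storage_experiment` data.frame.
#' @examples
#' syn <- generate_storage_experiment(synthetic_config(seed = 7))
#' head(syn)
#' attr(syn, "ground_truth")$true_theta
#' @export
generate_storage_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  combos <- expand.grid(treatment = cfg$treatments, condition = cfg$conditions,
                        stringsAsFactors = FALSE)
  out <- list()
  truth <- list(isotherms = list(), true_theta = c())
  for (i in seq_len(nrow(combos))) {
    tr <- combos$treatment[i]
    cd <- combos$condition[i]
    nm <- paste(tr, cd, sep = ".")
    fit <- cfg$isotherms[[tr]]
    env <- cfg$environments[[cd]]
    traj <- integrate_uptake(fit, cfg$pkg, env, cfg$powder,
                             horizon = max(cfg$sampling_days),
                             times = cfg$sampling_days)
    x_lat <- traj$moisture_db
    aw_lat <- traj$water_activity
    theta <- predict_shelf_life(fit, cfg$pkg, env, cfg$powder)$theta_days
    n <- length(cfg$sampling_days)
    series_seed <- (cfg$seed %% 2000000L) * 1000L + .series_codes[[nm]]
    obs <- .with_seed(series_seed, {
      zm <- rnorm(n); za <- rnorm(n)
      zattr <- matrix(rnorm(n * length(cfg$slopes)), nrow = n)
      list(zm = zm, za = za, zattr = zattr)
    })
    gain <- x_lat - cfg$powder$x_initial
    d <- data.frame(treatment = tr, condition = cd, day = cfg$sampling_days)
    d$moisture_pct_wb <- dry_to_wet(x_lat) *
      (1 + cfg$noise$moisture_cv * obs$zm)
    d$aw <- pmin(pmax(aw_lat + cfg$noise$aw_sd * obs$za, 0), 0.999)
    attr_mean <- function(col) {
      cfg$baselines[[col]] + cfg$slopes[[col]] * gain
    }
    j <- 0
    noisy <- function(mu) {
      j <<- j + 1
      mu * (1 + cfg$noise$attribute_cv * obs$zattr[, j])
    }
    d$caking_pct <- pmin(pmax(noisy(attr_mean("caking_pct")), 0), 100)
    d$carr_index_pct <- pmin(pmax(noisy(attr_mean("carr_index_pct")), 0), 99.9)
    d$hygroscopicity <- pmax(noisy(attr_mean("hygroscopicity")), 0)
    d$prt_min <- pmax(noisy(attr_mean("prt_min")), 0)
    d$rr <- pmax(noisy(attr_mean("rr")), 0)
    d$L <- pmax(noisy(attr_mean("L")), 0)
    d$a <- noisy(attr_mean("a"))
    d$b <- pmax(noisy(attr_mean("b")), 0)
    log_tpc <- log10(cfg$baselines[["tpc_cfu_per_g"]]) +
      cfg$slopes[["log10_tpc"]] * gain
    j <- j + 1
    log_tpc <- log_tpc + cfg$noise$attribute_cv * obs$zattr[, j]
    d$tpc_cfu_per_g <- pmax(10^log_tpc, cfg$baselines[["tpc_cfu_per_g"]])
    out[[nm]] <- d
    truth$isotherms[[nm]] <- fit
    truth$true_theta[nm] <- theta
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res <- validate_storage(res)
  attr(res, "ground_truth") <- truth
  res
}

#' Parameter- and shelf-life-recovery experiment
#'
#' Monte-Carlo check of the full pipeline on data the model itself generated:
#' for each replicate, generate a synthetic experiment, refit the isotherm of
#' each series from its observed (moisture, water-activity) pairs, predict
#' the time to critical moisture from the refitted isotherm, extract the
#' experimental first-crossing time from the observed moisture, and compare
#' both against the true crossing time.
#'
#' @param cfg A [synthetic_config()]; its seed is replaced per replicate.
#' @param n_replicates Number of replicates (>= 1).
#' @param seed Base seed for the replicate streams.
#' @return A list with `results` (one row per replicate x series: recovered
#'   GAB parameters, true/predicted/experimental crossing times and their
#'   errors), `summary` (per-series relative parameter bias and RMSE, median
#'   absolute shelf-life error, counts of non-finite results) and
#'   `n_fit_failures`.
#' @examples
#' rec <- recovery_experiment(synthetic_config(treatments = "control",
#'                                             conditions = "ambient"),
#'                            n_replicates = 2, seed = 1)
#' rec$summary
#' @export
recovery_experiment <- function(cfg, n_replicates, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"), n_replicates >= 1)
  rows <- list()
  n_fail <- 0L
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- (seed + 7919L * (r - 1L)) %% 2147483647L
    syn <- generate_storage_experiment(cfg_r)
    truth <- attr(syn, "ground_truth")
    for (nm in names(split_series(syn))) {
      s <- split_series(syn)[[nm]]
      true_fit <- truth$isotherms[[nm]]
      x_obs <- wet_to_dry(s$moisture_pct_wb)
      fit <- tryCatch(
        fit_isotherm(data.frame(moisture_db = x_obs, water_activity = s$aw),
                     true_fit$family),
        error = function(e) NULL)
      if (is.null(fit)) {
        n_fail <- n_fail + 1L
        next
      }
      env <- cfg$environments[[s$condition[1]]]
      pred <- predict_shelf_life(fit, cfg$pkg, env, cfg$powder)$theta_days
      expm <- experimental_shelf_life(s$day, x_obs,
                                      cfg$powder$x_critical)$theta_days
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, series = nm,
        t(setNames(fit$params, paste0("est_", names(fit$params)))),
        t(setNames(true_fit$params, paste0("true_", names(true_fit$params)))),
        true_theta = truth$true_theta[[nm]], predicted_theta = pred,
        experimental_theta = expm,
        predicted_error = pred - truth$true_theta[[nm]],
        pred_vs_exp = pred - expm)
    }
  }
  results <- do.call(rbind, c(rows, make.row.names = FALSE))
  summ <- NULL
  if (!is.null(results)) {
    par_names <- names(cfg$isotherms[[1]]$params)
    summ <- do.call(rbind, lapply(split(results, results$series), function(d) {
      rel <- sapply(par_names, function(p) {
        (d[[paste0("est_", p)]] - d[[paste0("true_", p)]]) /
          d[[paste0("true_", p)]]
      })
      rel <- matrix(rel, nrow = nrow(d))
      fin <- is.finite(d$predicted_error)
      data.frame(series = d$series[1], n = nrow(d),
                 n_finite = sum(fin),
                 param_bias_rel = mean(abs(colMeans(rel))),
                 param_rmse_rel = sqrt(mean(rel^2)),
                 shelf_rmse = if (any(fin)) {
                   sqrt(mean(d$predicted_error[fin]^2))
                 } else NA_real_,
                 shelf_median_abs_rel = if (any(fin)) {
                   median(abs(d$predicted_error[fin] / d$true_theta[fin]))
                 } else NA_real_)
    }))
    rownames(summ) <- NULL
  }
  list(results = results, summary = summ, n_fit_failures = n_fail)
}
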