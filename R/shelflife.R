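#' Shelf-life results
#'
#' A shelf life is the storage time (days) at which the powder moisture
#' first reaches its critical value `x_critical`.  It may be infinite
#' (`finite = FALSE`) when the critical moisture lies at or above the
#' equilibrium moisture for the storage environment, in which case the powder
#' never reaches it.
#'
#' @param theta_days Time to critical moisture, days (`Inf` allowed).
#' @param basis `"predicted"` (model) or `"experimental"` (measured series).
#' @param x_initial,x_critical Initial and critical dry-basis moisture.
#' @param treatment,condition Optional labels (e.g. `"TCP"`, `"ambient"`).
#' @param trajectory Optional [moisture_trajectory()] backing the result.
#' @return An object of class `shelf_life`.
#' @export
shelf_life <- function(theta_days, basis = c("predicted", "experimental"),
                       x_initial = NA_real_, x_critical = NA_real_,
                       treatment = NA_character_, condition = NA_character_,
                       trajectory = NULL) {
  basis <- match.arg(basis)
  if (is.na(theta_days) || theta_days < 0) {
    stop("theta_days must be >= 0 (possibly Inf)", call. = FALSE)
  }
  structure(list(theta_days = theta_days, finite = is.finite(theta_days),
                 basis = basis, x_initial = x_initial,
                 x_critical = x_critical, treatment = treatment,
                 condition = condition, trajectory = trajectory),
            class = "shelf_life")
}

#' @export
print.shelf_life <- function(x, ...) {
  lbl <- paste(stats::na.omit(c(x$treatment, x$condition)), collapse = " / ")
  if (nzchar(lbl)) lbl <- paste0(" [", lbl, "]")
  if (x$finite) {
    cat(sprintf("<shelf_life%s: %.3f days (%s), Xi = %.4g -> Xc = %.4g>\n",
                lbl, x$theta_days, x$basis, x$x_initial, x$x_critical))
  } else {
    cat(sprintf("<shelf_life%s: never reaches Xc = %.4g (%s; critical moisture at or above equilibrium)>\n",
                lbl, x$x_critical, x$basis))
  }
  invisible(x)
}

#' Predict time to critical moisture from the package moisture balance
#'
#' Integrates the moisture balance with event detection: the crossing of
#' `x_critical` is located by the solver's root finder
#' ([deSolve::lsodar()]) to about `1e-6` day.  If the critical moisture is at
#' or above the equilibrium moisture for the environment, the result is
#' flagged infinite rather than an error.
#'
#' @inheritParams uptake_rate
#' @param horizon Maximum time searched, days.
#' @param keep_trajectory Attach the dense trajectory up to the crossing (or
#'   horizon) to the result.
#' @return A [shelf_life()] with basis `"predicted"`.
#' @examples
#' fit <- isotherm_fit("linear", c(a = 0.1, b = 25))
#' predict_shelf_life(fit, package_spec(5.4e-8, area = 0.06),
#'                    environment_spec(25, 0.6),
#'                    powder_spec(0.0192, 0.004, 0.006))
#' @export
predict_shelf_life <- function(fit, pkg, env, powder, horizon = 1e5,
                               keep_trajectory = FALSE) {
  stopifnot(inherits(fit, "isotherm_fit"), inherits(powder, "powder_spec"))
  xi <- powder$x_initial
  xc <- powder$x_critical
  if (xc < xi) stop("x_critical must be >= x_initial", call. = FALSE)
  traj <- NULL
  if (xc == xi) {
    theta <- 0
  } else {
    xstar <- equilibrium_moisture(fit, env)
    if (xc >= xstar) {
      theta <- Inf
    } else {
      cc <- .rate_coef(pkg, env, powder)
      rhs <- function(t, y, parms) {
        list(cc * (env$rel_humidity - .safe_aw(fit, y[1])))
      }
      rootfun <- function(t, y, parms) y[1] - xc
      sol <- deSolve::lsodar(c(X = xi), times = c(0, horizon), func = rhs,
                             rootfunc = rootfun, rtol = 1e-10, atol = 1e-12)
      troot <- attr(sol, "troot")
      theta <- if (length(troot) >= 1) troot[1] else Inf
    }
  }
  if (keep_trajectory) {
    hor <- if (is.finite(theta) && theta > 0) theta * 1.2 else
      min(horizon, 10 / .rate_coef(pkg, env, powder))
    traj <- integrate_uptake(fit, pkg, env, powder, horizon = max(hor, 1))
  }
  shelf_life(theta, basis = "predicted", x_initial = xi, x_critical = xc,
             trajectory = traj)
}

#' Extract experimental shelf life from a measured storage series
#'
#' First crossing of the critical moisture by linear interpolation between
#' adjacent sampling days.  A measurement exactly at the critical value on a
#' sampling day resolves to that day.  If the series crosses more than once
#' (non-monotone data), the first crossing is returned and the others are
#' reported in a message.  A series that never reaches the critical moisture
#' yields a flagged infinite result.
#'
#' @param days Sampling days (>= 2, strictly increasing).
#' @param moisture_db Measured dry-basis moisture at each day.
#' @param x_critical Critical dry-basis moisture, kg/kg.
#' @return A [shelf_life()] with basis `"experimental"`.
#' @examples
#' experimental_shelf_life(c(0, 10), c(0.004, 0.008), 0.006)  # 5 days
#' @export
experimental_shelf_life <- function(days, moisture_db, x_critical) {
  if (length(days) < 2 || length(days) != length(moisture_db)) {
    stop("need >= 2 (day, moisture) observations of equal length",
         call. = FALSE)
  }
  if (any(diff(days) <= 0)) stop("days must be strictly increasing",
                                 call. = FALSE)
  above <- moisture_db >= x_critical
  crossings <- which(!above[-length(above)] & above[-1])
  exact <- which(moisture_db == x_critical)
  cross_times <- numeric(0)
  if (length(exact)) cross_times <- days[exact]
  for (i in crossings) {
    if (moisture_db[i + 1] == x_critical) next  # already counted as exact
    cross_times <- c(cross_times,
                     days[i] + (x_critical - moisture_db[i]) /
                       (moisture_db[i + 1] - moisture_db[i]) *
                       (days[i + 1] - days[i]))
  }
  cross_times <- sort(unique(cross_times))
  if (length(cross_times) == 0) {
    if (above[1]) {
      theta <- days[1]  # starts at/above critical
    } else {
      theta <- Inf
    }
  } else {
    theta <- cross_times[1]
    if (length(cross_times) > 1) {
      message(sprintf("series crosses the critical moisture %d times; using the first (others at %s days)",
                      length(cross_times),
                      paste(signif(cross_times[-1], 5), collapse = ", ")))
    }
  }
  shelf_life(theta, basis = "experimental", x_initial = moisture_db[1],
             x_critical = x_critical)
}

#' Compare a predicted trajectory with observed moisture
#'
#' Evaluates the predicted trajectory at the observed sampling days by
#' interpolation on its dense output, and reports the Pearson correlation and
#' root-mean-square error over the pairs, plus the paired table.
#'
#' @param predicted A [moisture_trajectory()] whose time range covers the
#'   observed days.
#' @param days Observed sampling days.
#' @param moisture_db Observed dry-basis moisture at those days.
#' @return A list with `pearson_r`, `rmse` (kg/kg) and `pairs` (a data.frame
#'   with day, observed and predicted moisture).
#' @examples
#' fit <- isotherm_fit("linear", c(a = 0.1, b = 25))
#' traj <- integrate_uptake(fit, package_spec(5.4e-8, area = 0.06),
#'                          environment_spec(25, 0.6),
#'                          powder_spec(0.0192, 0.004, 0.02), horizon = 100)
#' compare_trajectories(traj, c(0, 20, 50), c(0.004, 0.008, 0.012))
#' @export
compare_trajectories <- function(predicted, days, moisture_db) {
  stopifnot(inherits(predicted, "moisture_trajectory"))
  if (length(days) != length(moisture_db) || length(days) < 3) {
    stop("insufficient data: need at least 3 (day, moisture) pairs",
         call. = FALSE)
  }
  if (max(days) > max(predicted$time) || min(days) < min(predicted$time)) {
    stop("observed days fall outside the predicted horizon", call. = FALSE)
  }
  pred <- approx(predicted$time, predicted$moisture_db, xout = days)$y
  pairs <- data.frame(day = days, observed = moisture_db, predicted = pred)
  list(pearson_r = cor(moisture_db, pred),
       rmse = sqrt(mean((moisture_db - pred)^2)),
       pairs = pairs)
}

#' Closed-form lower bound on predicted shelf life
#'
#' With the water activity frozen at its initial value the driving force is
#' maximal, so \eqn{(X_c - X_i) W_s / (K A_p p^* (R_h - a_w(X_i)))} bounds the
#' time to critical moisture from below for any increasing isotherm.
#'
#' @inheritParams uptake_rate
#' @return Days (may be `Inf` when the initial state is at/above equilibrium).
#' @export
shelf_life_lower_bound <- function(fit, pkg, env, powder) {
  aw0 <- pmin(pmax(isotherm_aw(fit, powder$x_initial), 0), 0.9999)
  drive <- env$rel_humidity - aw0
  if (drive <= 0) return(Inf)
  (powder$x_critical - powder$x_initial) / (.rate_coef(pkg, env, powder) * drive)
}
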