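#' Package, environment and powder specifications
#'
#' Value constructors for the constants of the package moisture balance
#' \eqn{W_s \, dX/d\theta = K A_p p^* (R_h - a_w)}.
#'
#' @param permeability Water-vapour permeability `K` of the film,
#'   kg water / m^2 / day / Pa (> 0).
#' @param area Package surface area `Ap` in m^2; alternatively give `width`,
#'   `height` (m) and `faces` and the area is derived as
#'   `faces * width * height`.
#' @param width,height,faces Pouch dimensions used when `area` is missing.
#' @return A list of class `package_spec`.
#' @examples
#' package_spec(permeability = 5.4e-8, area = 0.06)
#' package_spec(permeability = 5.4e-8, width = 0.155, height = 0.193)
#' @export
package_spec <- function(permeability, area = NULL, width = NULL,
                         height = NULL, faces = 2) {
  if (is.null(area)) {
    if (is.null(width) || is.null(height)) {
      stop("give either area or width and height", call. = FALSE)
    }
    area <- faces * width * height
  }
  if (!is.finite(permeability) || permeability <= 0) {
    stop("permeability must be > 0", call. = FALSE)
  }
  if (!is.finite(area) || area <= 0) stop("area must be > 0", call. = FALSE)
  structure(list(permeability = permeability, area = area),
            class = "package_spec")
}

#' @rdname package_spec
#' @param temperature Storage temperature, degrees Celsius.
#' @param rel_humidity Storage relative humidity as a fraction in (0, 1].
#' @param sat_pressure Saturation vapour pressure of water `p*` in Pa at
#'   `temperature`; defaults to [saturation_pressure()] of the temperature.
#' @export
environment_spec <- function(temperature, rel_humidity, sat_pressure = NULL) {
  if (!is.finite(rel_humidity) || rel_humidity <= 0 || rel_humidity > 1) {
    stop("rel_humidity must be a fraction in (0, 1]", call. = FALSE)
  }
  if (is.null(sat_pressure)) sat_pressure <- saturation_pressure(temperature)
  if (!is.finite(sat_pressure) || sat_pressure <= 0) {
    stop("sat_pressure must be > 0", call. = FALSE)
  }
  structure(list(temperature = temperature, rel_humidity = rel_humidity,
                 sat_pressure = sat_pressure),
            class = "environment_spec")
}

#' @rdname package_spec
#' @param dry_mass Dry solids mass `Ws` inside the package, kg (> 0).
#' @param x_initial Initial dry-basis moisture `Xi`, kg/kg.
#' @param x_critical Critical dry-basis moisture `Xc`, kg/kg (> `x_initial`
#'   or equal for a degenerate zero-shelf-life case).
#' @export
powder_spec <- function(dry_mass, x_initial, x_critical) {
  if (!is.finite(dry_mass) || dry_mass <= 0) {
    stop("dry_mass must be > 0", call. = FALSE)
  }
  if (!is.finite(x_initial) || x_initial < 0) {
    stop("x_initial must be >= 0", call. = FALSE)
  }
  if (!is.finite(x_critical) || x_critical < x_initial) {
    stop("x_critical must be >= x_initial", call. = FALSE)
  }
  structure(list(dry_mass = dry_mass, x_initial = x_initial,
                 x_critical = x_critical),
            class = "powder_spec")
}

#' Saturation vapour pressure of water
#'
#' Returns the steam-table values used throughout the bundled storage study at
#' exactly 25 and 40 degrees Celsius (3173.027 and 7380.726 Pa) and the
#' Arden Buck correlation elsewhere, flagged with attribute
#' `interpolated = TRUE`.
#'
#' @param temperature Temperature in degrees Celsius, in (0, 100).
#' @return Saturation pressure in Pa.
#' @examples
#' saturation_pressure(25)
#' saturation_pressure(30)
#' @export
saturation_pressure <- function(temperature) {
  if (any(!is.finite(temperature)) || any(temperature <= 0) ||
      any(temperature >= 100)) {
    stop("temperature must be in (0, 100) degrees Celsius", call. = FALSE)
  }
  tabulated <- c(`25` = 3173.027, `40` = 7380.726)
  out <- vapply(temperature, function(t) {
    key <- as.character(t)
    if (key %in% names(tabulated)) return(tabulated[[key]])
    # Arden Buck correlation (Pa)
    611.21 * exp((18.678 - t / 234.5) * (t / (257.14 + t)))
  }, numeric(1))
  interp <- !(as.character(temperature) %in% names(tabulated))
  if (any(interp)) attr(out, "interpolated") <- interp
  out
}

# K * Ap * pstar / Ws, the rate scale of the moisture balance (1/day per unit
# driving force)
.rate_coef <- function(pkg, env, powder) {
  pkg$permeability * pkg$area * env$sat_pressure / powder$dry_mass
}

#' Instantaneous moisture uptake rate
#'
#' Evaluates the right-hand side of the package moisture balance
#' \eqn{dX/d\theta = (K A_p p^* / W_s)(R_h - a_w(X))} at moisture `x`.
#' The water activity from the isotherm is clamped to `[0, 0.9999]` before
#' computing the driving force.
#'
#' @param x Dry-basis moisture, kg/kg.
#' @param fit Sorption isotherm ([isotherm_fit()]) of the powder.
#' @param pkg A [package_spec()].
#' @param env An [environment_spec()].
#' @param powder A [powder_spec()].
#' @return Uptake rate in kg water / kg dry solids / day.  Positive while the
#'   powder is drier than its equilibrium with the environment, zero at
#'   equilibrium, negative above it.
#' @examples
#' fit <- isotherm_fit("linear", c(a = 0.2, b = 5))
#' pkg <- package_spec(5.4e-8, area = 0.06)
#' env <- environment_spec(25, 0.6)
#' pow <- powder_spec(0.0192, 0.004, 0.006)
#' uptake_rate(0.02, fit, pkg, env, pow)
#' @export
uptake_rate <- function(x, fit, pkg, env, powder) {
  stopifnot(inherits(pkg, "package_spec"), inherits(env, "environment_spec"),
            inherits(powder, "powder_spec"))
  aw <- pmin(pmax(isotherm_aw(fit, x), 0), 0.9999)
  .rate_coef(pkg, env, powder) * (env$rel_humidity - aw)
}

#' Construct a moisture trajectory
#'
#' @param times Strictly increasing times in days, starting at 0.
#' @param moisture_db Dry-basis moisture at each time.
#' @param water_activity Water activity at each time.
#' @param provenance One of `"predicted"`, `"synthetic"`, `"experimental"`.
#' @return A `data.frame` of class `moisture_trajectory`.
#' @export
moisture_trajectory <- function(times, moisture_db, water_activity,
                                provenance = c("predicted", "synthetic",
                                               "experimental")) {
  provenance <- match.arg(provenance)
  if (length(times) != length(moisture_db) ||
      length(times) != length(water_activity)) {
    stop("times, moisture_db and water_activity must have equal length",
         call. = FALSE)
  }
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing from 0", call. = FALSE)
  }
  out <- data.frame(time = times, moisture_db = moisture_db,
                    water_activity = water_activity)
  attr(out, "provenance") <- provenance
  class(out) <- c("moisture_trajectory", "data.frame")
  out
}

#' Integrate the package moisture balance
#'
#' Solves \eqn{dX/d\theta = (K A_p p^* / W_s)(R_h - a_w(X))} from the powder's
#' initial moisture with an adaptive stiff/non-stiff solver
#' ([deSolve::lsoda()]).  The trajectory approaches the equilibrium moisture
#' \eqn{X^*} with \eqn{a_w(X^*) = R_h} and never overshoots it beyond solver
#' tolerance.
#'
#' @inheritParams uptake_rate
#' @param horizon Integration horizon in days (> 0).
#' @param times Optional explicit output times (must start at 0); by default
#'   401 evenly spaced points over the horizon.
#' @param rtol,atol Solver tolerances on moisture.
#' @return A [moisture_trajectory()] with provenance `"predicted"`.
#' @examples
#' fit <- isotherm_fit("linear", c(a = 0.1, b = 25))
#' traj <- integrate_uptake(fit, package_spec(5.4e-8, area = 0.06),
#'                          environment_spec(25, 0.6),
#'                          powder_spec(0.0192, 0.004, 0.006), horizon = 100)
#' head(traj)
#' @export
integrate_uptake <- function(fit, pkg, env, powder, horizon, times = NULL,
                             rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(fit, "isotherm_fit"))
  if (!is.finite(horizon) || horizon <= 0) {
    stop("horizon must be > 0", call. = FALSE)
  }
  if (is.null(times)) times <- seq(0, horizon, length.out = 401L)
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing from 0", call. = FALSE)
  }
  cc <- .rate_coef(pkg, env, powder)
  rhs <- function(t, y, parms) {
    aw <- .safe_aw(fit, y[1])
    list(cc * (env$rel_humidity - aw))
  }
  sol <- deSolve::lsoda(c(X = powder$x_initial), times, rhs, rtol = rtol,
                        atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("moisture integration failed at t = %.4g days (last X = %.6g)",
                 max(sol[, "time"]), sol[nrow(sol), "X"]), call. = FALSE)
  }
  x <- pmax(sol[, "X"], 0)
  moisture_trajectory(sol[, "time"], unname(x),
                      vapply(x, function(v) .safe_aw(fit, v), numeric(1)),
                      provenance = "predicted")
}

# isotherm_aw clamped into [0, 0.9999]; moisture above the isotherm range is
# treated as saturated (driving force from above)
.safe_aw <- function(fit, x) {
  aw <- tryCatch(isotherm_aw(fit, max(x, 0)), error = function(e) 0.9999)
  min(max(aw, 0), 0.9999)
}

#' Equilibrium moisture content of a powder in an environment
#'
#' The moisture \eqn{X^*} at which the powder's water activity equals the
#' storage relative humidity; the asymptote of [integrate_uptake()].
#' Returns `Inf` when the isotherm never reaches the storage humidity.
#'
#' @inheritParams uptake_rate
#' @return Dry-basis moisture, kg/kg (possibly `Inf`).
#' @export
equilibrium_moisture <- function(fit, env) {
  stopifnot(inherits(fit, "isotherm_fit"), inherits(env, "environment_spec"))
  sup <- .aw_supremum(fit)
  if (env$rel_humidity >= sup) return(Inf)
  # an environment drier than the powder at X = 0 (possible for families with
  # an aw intercept) gives a zero equilibrium moisture
  suppressWarnings(
    tryCatch(isotherm_moisture(fit, env$rel_humidity), error = function(e) 0))
}
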