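# shared fixtures: published study constants and small builders

study_pkg <- function() package_spec(permeability = 5.4e-8, area = 0.0600)
study_env_ambient <- function() environment_spec(25, 0.60, sat_pressure = 3173.027)
study_env_accel <- function() environment_spec(40, 0.90, sat_pressure = 7380.726)
study_powder <- function(xi = 0.004, xc = 0.006) powder_spec(0.0192, xi, xc)

gab_example <- function() isotherm_fit("gab", c(Xm = 0.05, C = 10, k = 0.8))

# seeded admissible GAB parameter sets for property-style loops
random_gab_params <- function(n, seed = 101) {
  set.seed(seed)
  data.frame(Xm = runif(n, 0.005, 0.5),
             C = exp(runif(n, log(0.2), log(500))),
             k = runif(n, 0.1, 0.98))
}

# fixed-step classical Runge-Kutta integration of the moisture balance,
# an independent oracle for the adaptive solver
rk4_uptake <- function(fit, pkg, env, powder, horizon, h) {
  cc <- pkg$permeability * pkg$area * env$sat_pressure / powder$dry_mass
  f <- function(x) {
    aw <- min(max(isotherm_aw(fit, max(x, 0)), 0), 0.9999)
    cc * (env$rel_humidity - aw)
  }
  n <- ceiling(horizon / h)
  x <- numeric(n + 1)
  x[1] <- powder$x_initial
  for (i in seq_len(n)) {
    k1 <- f(x[i])
    k2 <- f(x[i] + h / 2 * k1)
    k3 <- f(x[i] + h / 2 * k2)
    k4 <- f(x[i] + h * k3)
    x[i + 1] <- x[i] + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  data.frame(time = h * (0:n), moisture_db = x)
}
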