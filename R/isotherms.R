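#' Construct a table of sorption observations
#'
#' A set of equilibrium (moisture, water activity) pairs measured at one
#' temperature, the raw material for isotherm fitting.
#'
#' @param moisture_db Dry-basis moisture contents, kg water / kg dry solids
#'   (non-negative).
#' @param water_activity Water activities, dimensionless, in `[0, 1)`.
#' @param temperature Temperature in degrees Celsius (single value, recycled).
#' @return A `data.frame` of class `sorption_points` with columns
#'   `moisture_db`, `water_activity`, `temperature`.
#' @examples
#' sorption_points(c(0.05, 0.07, 0.09), c(0.2, 0.4, 0.6), temperature = 25)
#' @export
sorption_points <- function(moisture_db, water_activity, temperature = NA_real_) {
  if (length(moisture_db) != length(water_activity)) {
    stop("moisture_db and water_activity must have equal length", call. = FALSE)
  }
  if (any(!is.finite(moisture_db)) || any(moisture_db < 0)) {
    stop("moisture_db must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(water_activity)) ||
      any(water_activity < 0) || any(water_activity >= 1)) {
    stop("water_activity must be in [0, 1)", call. = FALSE)
  }
  temperature <- rep_len(as.numeric(temperature), length(moisture_db))
  if (length(unique(temperature[!is.na(temperature)])) > 1) {
    stop("all sorption points must share one temperature", call. = FALSE)
  }
  out <- data.frame(moisture_db = as.numeric(moisture_db),
                    water_activity = as.numeric(water_activity),
                    temperature = temperature)
  class(out) <- c("sorption_points", "data.frame")
  out
}

# family metadata: parameter names and box constraints used by the fitter
.isotherm_families <- list(
  gab = list(params = c("Xm", "C", "k"),
             lower = c(1e-8, 1e-8, 1e-3),
             upper = c(1, 1e4, 0.999)),
  halsey = list(params = c("a", "b"),
                lower = c(1e-10, 1e-3),
                upper = c(1e4, 50)),
  oswin = list(params = c("a", "b"),
               lower = c(1e-10, 1e-3),
               upper = c(10, 10)),
  iglesias_chirife = list(params = c("a", "b"),
                          lower = c(0, 1e-10),
                          upper = c(10, 10)),
  linear = list(params = c("a", "b"),
                lower = c(-Inf, 1e-12),
                upper = c(Inf, Inf))
)

#' Create an isotherm fit object
#'
#' Bundles an isotherm family with its parameter vector.  Usually produced by
#' [fit_isotherm()]; construct directly to evaluate a known isotherm.
#'
#' Families and their moisture predictions \eqn{X(a_w)}:
#' \describe{
#'   \item{gab}{\eqn{X = X_m C k a_w / [(1 - k a_w)(1 - k a_w + C k a_w)]},
#'     the three-parameter Guggenheim-Anderson-de Boer multilayer model with
#'     monolayer moisture \eqn{X_m > 0}, energy constant \eqn{C > 0} and
#'     correction factor \eqn{0 < k < 1}; the canonical description of food
#'     powders up to \eqn{a_w \approx 0.94}.}
#'   \item{halsey}{\eqn{X = (a / (-\ln a_w))^{1/b}}.}
#'   \item{oswin}{\eqn{X = a \, (a_w / (1 - a_w))^{b}}.}
#'   \item{iglesias_chirife}{\eqn{X = a + b \, a_w / (1 - a_w)}.}
#'   \item{linear}{\eqn{a_w = a + b X}, i.e. \eqn{X = (a_w - a)/b}.}
#' }
#'
#' @param family One of `"gab"`, `"halsey"`, `"oswin"`, `"iglesias_chirife"`,
#'   `"linear"`.
#' @param params Named numeric vector of family parameters (see Details).
#' @param temperature Temperature label in degrees Celsius.
#' @param rss Residual sum of squares of the fit (moisture units), if known.
#' @param n_points Number of points the fit used, if known.
#' @return An object of class `isotherm_fit`.
#' @examples
#' fit <- isotherm_fit("gab", c(Xm = 0.05, C = 10, k = 0.8))
#' isotherm_moisture(fit, 0.5)
#' @export
isotherm_fit <- function(family, params, temperature = NA_real_,
                         rss = NA_real_, n_points = NA_integer_) {
  family <- match.arg(tolower(family), names(.isotherm_families))
  meta <- .isotherm_families[[family]]
  if (is.null(names(params)) || !setequal(names(params), meta$params)) {
    stop(sprintf("family '%s' needs parameters: %s", family,
                 paste(meta$params, collapse = ", ")), call. = FALSE)
  }
  params <- params[meta$params]
  bad <- params < meta$lower | params > meta$upper | !is.finite(params)
  if (family == "gab") {
    if (params[["Xm"]] <= 0 || params[["C"]] <= 0 ||
        params[["k"]] <= 0 || params[["k"]] >= 1) {
      stop("GAB parameters must satisfy Xm > 0, C > 0, 0 < k < 1",
           call. = FALSE)
    }
  } else if (any(bad)) {
    stop(sprintf("parameter(s) out of range for family '%s': %s", family,
                 paste(meta$params[bad], collapse = ", ")), call. = FALSE)
  }
  structure(list(family = family, params = params,
                 temperature = as.numeric(temperature),
                 rss = as.numeric(rss), n_points = as.integer(n_points)),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("<isotherm_fit: %s>\n", x$family))
  print(signif(x$params, 5))
  if (!is.na(x$temperature)) cat("temperature:", x$temperature, "degC\n")
  if (!is.na(x$rss)) {
    cat(sprintf("rss: %.4g on %s points\n", x$rss,
                ifelse(is.na(x$n_points), "?", x$n_points)))
  }
  invisible(x)
}

# upper end of the admissible water-activity interval for a fit
.aw_supremum <- function(fit) {
  switch(fit$family,
         gab = min(1 - 1e-9, 1 / fit$params[["k"]] - 1e-9),
         1 - 1e-9)
}

#' Evaluate an isotherm: moisture at a given water activity
#'
#' @param fit An [isotherm_fit()].
#' @param aw Water activities in `[0, 0.94]`; values above 0.94 trigger a
#'   warning (beyond the usual validity range of food sorption models) and
#'   values at or above the family's singularity (e.g. `1/k` for GAB) are
#'   rejected.
#' @return Dry-basis moisture content(s), kg/kg.
#' @examples
#' fit <- isotherm_fit("gab", c(Xm = 0.05, C = 10, k = 0.8))
#' isotherm_moisture(fit, c(0, 0.5))
#' @export
isotherm_moisture <- function(fit, aw) {
  stopifnot(inherits(fit, "isotherm_fit"))
  if (any(!is.finite(aw)) || any(aw < 0)) {
    stop("water activity must be finite and >= 0", call. = FALSE)
  }
  sup <- .aw_supremum(fit)
  if (any(aw >= sup + 1e-9)) {
    stop(sprintf("water activity must be below %.6g for this %s fit",
                 sup, fit$family), call. = FALSE)
  }
  if (any(aw > 0.94)) {
    warning("water activity above 0.94 is outside the usual validity range of sorption models",
            call. = FALSE)
  }
  p <- fit$params
  x <- switch(fit$family,
    gab = {
      u <- p[["k"]] * aw
      p[["Xm"]] * p[["C"]] * u / ((1 - u) * (1 - u + p[["C"]] * u))
    },
    halsey = ifelse(aw == 0, 0, (p[["a"]] / (-log(aw)))^(1 / p[["b"]])),
    oswin = p[["a"]] * (aw / (1 - aw))^p[["b"]],
    iglesias_chirife = p[["a"]] + p[["b"]] * aw / (1 - aw),
    linear = {
      if (any(aw < p[["a"]] - 1e-12)) {
        stop(sprintf("water activity below the linear-isotherm intercept a = %.6g",
                     p[["a"]]), call. = FALSE)
      }
      pmax(0, (aw - p[["a"]]) / p[["b"]])
    })
  unname(x)
}

#' Invert an isotherm: water activity at a given moisture content
#'
#' Closed-form inverses are used where available (halsey, oswin,
#' iglesias_chirife, linear); the GAB family is inverted by monotone
#' bracketing (Brent root finding to a `1e-12` tolerance on water activity).
#'
#' @param fit An [isotherm_fit()].
#' @param x Dry-basis moisture content(s), kg/kg, non-negative and within the
#'   invertible range of the family (a range error is thrown for moisture
#'   above the isotherm's supremum on its admissible water-activity domain).
#' @return Water activities in `[0, 1)`.
#' @examples
#' fit <- isotherm_fit("gab", c(Xm = 0.05, C = 10, k = 0.8))
#' isotherm_aw(fit, isotherm_moisture(fit, 0.5))  # 0.5
#' @export
isotherm_aw <- function(fit, x) {
  stopifnot(inherits(fit, "isotherm_fit"))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("moisture must be finite and >= 0", call. = FALSE)
  }
  p <- fit$params
  aw <- switch(fit$family,
    halsey = ifelse(x == 0, 0, exp(-p[["a"]] / x^p[["b"]])),
    oswin = {
      r <- (x / p[["a"]])^(1 / p[["b"]])
      r / (1 + r)
    },
    iglesias_chirife = {
      if (any(x < p[["a"]] - 1e-12)) {
        stop("moisture below the iglesias_chirife intercept is not invertible",
             call. = FALSE)
      }
      r <- pmax(0, (x - p[["a"]])) / p[["b"]]
      r / (1 + r)
    },
    linear = p[["a"]] + p[["b"]] * x,
    gab = vapply(x, .gab_invert_one, numeric(1), fit = fit))
  if (any(aw >= 1)) {
    stop("moisture exceeds the isotherm's range on water activity < 1",
         call. = FALSE)
  }
  unname(aw)
}

.gab_invert_one <- function(x, fit) {
  if (x == 0) return(0)
  sup <- .aw_supremum(fit)
  xmax <- suppressWarnings(isotherm_moisture(fit, sup))
  if (x > xmax) {
    stop(sprintf("moisture %.6g exceeds the GAB supremum %.6g on the admissible domain",
                 x, xmax), call. = FALSE)
  }
  f <- function(a) suppressWarnings(isotherm_moisture(fit, a)) - x
  uniroot(f, c(0, sup), tol = 1e-13, maxiter = 200)$root
}

# deterministic multi-start sets per family (dispersed over the box)
.isotherm_starts <- function(family, x) {
  xm <- max(max(x), 1e-4)
  switch(family,
    gab = rbind(c(mean(x), 10, 0.7),
                c(xm * 0.5, 5, 0.5),
                c(xm * 0.2, 100, 0.9),
                c(xm, 1, 0.95),
                c(xm * 0.05, 1000, 0.99),
                c(xm * 0.8, 0.1, 0.3)),
    halsey = rbind(c(0.001, 1.5), c(0.01, 1), c(1e-4, 2), c(0.1, 0.8),
                   c(0.001, 3)),
    oswin = rbind(c(mean(x), 0.5), c(xm, 0.2), c(xm * 0.5, 1), c(0.05, 0.4),
                  c(0.2, 0.8)),
    iglesias_chirife = rbind(c(min(x), xm), c(0, mean(x)), c(min(x) / 2, 0.1),
                             c(min(x), 0.01), c(0, 1)))
}

#' Fit a moisture sorption isotherm
#'
#' Least-squares fit of moisture on water activity.  Nonlinear families are
#' fitted by bounded quasi-Newton (L-BFGS-B) optimisation from several
#' dispersed deterministic starting points, keeping the best converged
#' solution; the linear family has a closed-form solution.  Bounds:
#' GAB `Xm` in (0, 1], `C` in (0, 1e4], `k` in (1e-3, 0.999).
#'
#' @param points A [sorption_points()] table (or a data.frame with columns
#'   `moisture_db` and `water_activity`).
#' @param family Isotherm family; see [isotherm_fit()].
#' @param n_starts Number of starting points to use (up to the size of the
#'   deterministic start set).
#' @return An [isotherm_fit()] with `rss` and `n_points` filled in.
#' @examples
#' true <- isotherm_fit("gab", c(Xm = 0.05, C = 10, k = 0.8))
#' aw <- seq(0.1, 0.9, by = 0.1)
#' pts <- sorption_points(isotherm_moisture(true, aw), aw)
#' fit_isotherm(pts, "gab")
#' @export
fit_isotherm <- function(points, family = c("gab", "halsey", "oswin",
                                            "iglesias_chirife", "linear"),
                         n_starts = 5) {
  family <- match.arg(family)
  if (!all(c("moisture_db", "water_activity") %in% names(points))) {
    stop("points must have columns moisture_db and water_activity",
         call. = FALSE)
  }
  x <- points$moisture_db
  aw <- points$water_activity
  temp <- if ("temperature" %in% names(points)) points$temperature[1] else NA_real_
  if (!is.na(temp) && "temperature" %in% names(points) &&
      length(unique(points$temperature[!is.na(points$temperature)])) > 1) {
    stop("all sorption points must share one temperature", call. = FALSE)
  }
  npar <- length(.isotherm_families[[family]]$params)
  if (length(x) < npar + 1) {
    stop(sprintf("insufficient data: family '%s' has %d parameters and needs at least %d points (got %d)",
                 family, npar, npar + 1, length(x)), call. = FALSE)
  }

  if (family == "linear") {
    # aw = a + b X  <=>  X = -a/b + aw/b; regress X on aw, transform back
    fit <- lm(x ~ aw)
    slope <- unname(coef(fit)[2])
    if (!is.finite(slope) || slope <= 0) {
      stop("fit failure: linear isotherm requires moisture increasing in water activity",
           call. = FALSE)
    }
    b <- 1 / slope
    a <- -unname(coef(fit)[1]) * b
    rss <- sum(fit$residuals^2)
    return(isotherm_fit("linear", c(a = a, b = b), temperature = temp,
                        rss = rss, n_points = length(x)))
  }

  meta <- .isotherm_families[[family]]
  predfun <- switch(family,
    gab = function(p, aw) {
      u <- p[3] * aw
      p[1] * p[2] * u / ((1 - u) * (1 - u + p[2] * u))
    },
    halsey = function(p, aw) ifelse(aw == 0, 0, (p[1] / (-log(aw)))^(1 / p[2])),
    oswin = function(p, aw) p[1] * (aw / (1 - aw))^p[2],
    iglesias_chirife = function(p, aw) p[1] + p[2] * aw / (1 - aw))
  obj <- function(p) {
    pred <- predfun(p, aw)
    if (any(!is.finite(pred))) return(1e10)
    sum((x - pred)^2)
  }
  starts <- .isotherm_starts(family, x)
  starts <- starts[seq_len(min(n_starts + 1, nrow(starts))), , drop = FALSE]
  best <- NULL
  diagnostics <- character(0)
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(starts[i, ], meta$lower * 1.01 + 1e-12), meta$upper * 0.99)
    o <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B", lower = meta$lower,
            upper = meta$upper,
            control = list(maxit = 2000, factr = 1e4)),
      error = function(e) {
        diagnostics <<- c(diagnostics, conditionMessage(e))
        NULL
      })
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    stop(sprintf("fit failure: no start converged for family '%s' (%s)",
                 family, paste(unique(diagnostics), collapse = "; ")),
         call. = FALSE)
  }
  # polish the best solution: finer finite-difference steps, then a
  # derivative-free pass to squeeze out the last digits
  polished <- tryCatch(
    optim(best$par, obj, method = "L-BFGS-B", lower = meta$lower,
          upper = meta$upper,
          control = list(maxit = 5000, factr = 10, pgtol = 1e-14,
                         ndeps = rep(1e-7, length(best$par)))),
    error = function(e) best)
  if (polished$value <= best$value) best <- polished
  box <- function(p) pmin(pmax(p, meta$lower), meta$upper)
  nm_polish <- tryCatch(
    optim(best$par, function(p) obj(box(p)), method = "Nelder-Mead",
          control = list(maxit = 5000, reltol = 1e-15)),
    error = function(e) best)
  if (nm_polish$value < best$value) {
    nm_polish$par <- box(nm_polish$par)
    best <- nm_polish
  }
  params <- setNames(best$par, meta$params)
  isotherm_fit(family, params, temperature = temp, rss = best$value,
               n_points = length(x))
}

#' Serialize an isotherm fit to JSON (and back)
#'
#' @param fit An [isotherm_fit()].
#' @param path File path.
#' @return `read_isotherm_json()` returns an [isotherm_fit()];
#'   `write_isotherm_json()` returns `path` invisibly.
#' @export
write_isotherm_json <- function(fit, path) {
  stopifnot(inherits(fit, "isotherm_fit"))
  jsonlite::write_json(
    list(family = fit$family, params = as.list(fit$params),
         temperature = fit$temperature, rss = fit$rss,
         n_points = fit$n_points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_isotherm_json
#' @export
read_isotherm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  isotherm_fit(obj$family, unlist(obj$params),
               temperature = obj$temperature %||% NA_real_,
               rss = obj$rss %||% NA_real_,
               n_points = obj$n_points %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
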