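#' Convert between wet-basis and dry-basis moisture content
#'
#' Storage tables report moisture as a wet-basis percentage \eqn{m} (g water
#' per 100 g product); the moisture-transfer model works in dry-basis moisture
#' \eqn{X} (kg water per kg dry solids).  The two are related by
#' \eqn{X = m / (100 - m)} and \eqn{m = 100 X / (1 + X)}.
#'
#' @param moisture_pct_wb Wet-basis moisture content in percent, in `[0, 100)`.
#' @param moisture_db Dry-basis moisture content, kg water / kg dry solids,
#'   non-negative.
#' @return `wet_to_dry()` returns dry-basis moisture (kg/kg); `dry_to_wet()`
#'   returns wet-basis percent.
#' @examples
#' wet_to_dry(5.613)   # ~0.0595 kg/kg
#' dry_to_wet(wet_to_dry(5.613))
#' @export
wet_to_dry <- function(moisture_pct_wb) {
  if (any(!is.finite(moisture_pct_wb)) ||
      any(moisture_pct_wb < 0) || any(moisture_pct_wb >= 100)) {
    stop("wet-basis moisture must be in [0, 100) percent", call. = FALSE)
  }
  moisture_pct_wb / (100 - moisture_pct_wb)
}

#' @rdname wet_to_dry
#' @export
dry_to_wet <- function(moisture_db) {
  if (any(!is.finite(moisture_db)) || any(moisture_db < 0)) {
    stop("dry-basis moisture must be non-negative", call. = FALSE)
  }
  100 * moisture_db / (1 + moisture_db)
}
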