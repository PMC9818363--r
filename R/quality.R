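#' Degree of caking
#'
#' Percentage of powder retained on a fine sieve after shaking,
#' `DC = c / d * 100`, where `d` is the amount of powder sieved and `c` the
#' amount left on the sieve.
#'
#' @param retained Mass retained on the sieve, g (`c`).
#' @param sieved Mass of powder used for sieving, g (`d`, > 0).
#' @return Degree of caking in percent, in `[0, 100]`.
#' @examples
#' degree_of_caking(2.5, 5)  # 50
#' @export
degree_of_caking <- function(retained, sieved) {
  if (any(sieved <= 0)) stop("sieved mass must be > 0", call. = FALSE)
  if (any(retained < 0) || any(retained > sieved)) {
    stop("retained mass must be in [0, sieved]", call. = FALSE)
  }
  retained / sieved * 100
}

#' Carr's compressibility index
#'
#' `CI = (rho_tapped - rho_bulk) / rho_tapped * 100`; higher values mean
#' poorer flowability.
#'
#' @param rho_bulk Bulk density (must not exceed `rho_tapped`).
#' @param rho_tapped Tapped density (> 0), same units as `rho_bulk`.
#' @return Carr index in percent, in `[0, 100)`.
#' @examples
#' carr_index(0.4, 0.5)  # 20
#' @export
carr_index <- function(rho_bulk, rho_tapped) {
  if (any(rho_tapped <= 0)) stop("tapped density must be > 0", call. = FALSE)
  if (any(rho_bulk < 0) || any(rho_bulk > rho_tapped)) {
    stop("bulk density must be in [0, tapped density]", call. = FALSE)
  }
  (rho_tapped - rho_bulk) / rho_tapped * 100
}

#' Flowability class from the Carr index
#'
#' Standard powder-flow classes with closed-left boundaries:
#' `[0, 15)` very good, `[15, 20)` good, `[20, 35)` fair, `[35, 45)` bad,
#' `>= 45` very bad.
#'
#' @param ci Carr index in percent (>= 0).
#' @return A factor with levels `very good < good < fair < bad < very bad`.
#' @examples
#' classify_flow(c(10, 22.356, 36.98, 50))
#' @export
classify_flow <- function(ci) {
  if (any(!is.finite(ci)) || any(ci < 0)) {
    stop("Carr index must be finite and >= 0", call. = FALSE)
  }
  cut(ci, breaks = c(0, 15, 20, 35, 45, Inf), right = FALSE,
      labels = c("very good", "good", "fair", "bad", "very bad"),
      ordered_result = TRUE)
}

#' Rehydration ratio
#'
#' Mass of the rehydrated sample divided by the mass of the dried sample.
#'
#' @param w_rehydrated Weight of rehydrated sample, g (>= 0).
#' @param w_dried Weight of dried sample, g (> 0).
#' @return Dimensionless ratio >= 0.
#' @examples
#' rehydration_ratio(12.094, 2)  # 6.047
#' @export
rehydration_ratio <- function(w_rehydrated, w_dried) {
  if (any(w_dried <= 0)) stop("dried weight must be > 0", call. = FALSE)
  if (any(w_rehydrated < 0)) stop("rehydrated weight must be >= 0",
                                  call. = FALSE)
  w_rehydrated / w_dried
}

#' Water-activity stability class
#'
#' Two-threshold scheme: powders at water activity at or below 0.60 are
#' microbiologically and physically stable, between 0.60 and 0.65 marginal,
#' and above 0.65 unstable.
#'
#' @param aw Water activity in `[0, 1)`.
#' @return A factor with levels `stable < marginal < unstable`.
#' @examples
#' classify_aw_stability(c(0.28, 0.601, 0.881))
#' @export
classify_aw_stability <- function(aw) {
  if (any(!is.finite(aw)) || any(aw < 0) || any(aw >= 1)) {
    stop("water activity must be in [0, 1)", call. = FALSE)
  }
  cut(aw, breaks = c(-Inf, 0.60, 0.65, Inf),
      labels = c("stable", "marginal", "unstable"), ordered_result = TRUE)
}

#' Total-aerobic-bacteria count within the regulatory limit
#'
#' The FSSAI limit for fruit powders is 40,000 CFU/g (inclusive).
#'
#' @param count Total plate count, CFU/g (>= 0).
#' @param limit Regulatory limit, CFU/g.
#' @return Logical: `TRUE` when the count is within the limit.
#' @examples
#' tab_within_limit(c(7980, 40000, 40001))
#' @export
tab_within_limit <- function(count, limit = 40000) {
  if (any(!is.finite(count)) || any(count < 0)) {
    stop("count must be finite and >= 0", call. = FALSE)
  }
  count <= limit
}

#' Augment a storage table with quality classifications
#'
#' Adds `flow_class` (from `carr_index_pct`), `aw_stability` (from `aw`) and
#' `tab_safe` (from `tpc_cfu_per_g`) columns, row-wise.  Columns that are
#' absent are skipped.
#'
#' @param storage A storage table as returned by [read_storage_csv()] or
#'   [generate_storage_experiment()].
#' @return The table with the classification columns appended.
#' @export
augment_quality <- function(storage) {
  stopifnot(is.data.frame(storage))
  if ("carr_index_pct" %in% names(storage)) {
    storage$flow_class <- classify_flow(storage$carr_index_pct)
  }
  if ("aw" %in% names(storage)) {
    storage$aw_stability <- classify_aw_stability(storage$aw)
  }
  if ("tpc_cfu_per_g" %in% names(storage)) {
    storage$tab_safe <- tab_within_limit(storage$tpc_cfu_per_g)
  }
  storage
}
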