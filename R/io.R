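# long-format storage-table schema
.storage_required <- c("treatment", "condition", "day", "moisture_pct_wb", "aw")
.storage_optional <- c("caking_pct", "carr_index_pct", "hygroscopicity",
                       "prt_min", "rr", "L", "a", "b", "tpc_cfu_per_g")

#' Read a long-format storage-experiment CSV
#'
#' The schema has one row per treatment x condition x sampling day with
#' mandatory columns `treatment`, `condition`, `day`, `moisture_pct_wb`
#' (wet-basis percent) and `aw`, plus optional quality-attribute columns
#' (`caking_pct`, `carr_index_pct`, `hygroscopicity`, `prt_min`, `rr`, `L`,
#' `a`, `b`, `tpc_cfu_per_g`) and per-cell `*_sd` columns.  Unknown columns
#' are kept with a warning.  Rows are sorted by day within each series (with
#' a warning if they were out of order); malformed numeric cells are reported
#' with their row and column.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of class `storage_experiment`.
#' @export
read_storage_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
                  error = function(e) {
                    stop("schema error: cannot parse ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    stop("schema error: empty storage file: ", path, call. = FALSE)
  }
  validate_storage(raw)
}

#' Validate (and normalize) a storage table
#'
#' @param storage A data.frame in the long storage schema.
#' @return The validated table, sorted by treatment, condition and day, with
#'   class `storage_experiment`.
#' @export
validate_storage <- function(storage) {
  missing <- setdiff(.storage_required, names(storage))
  if (length(missing)) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  known <- c(.storage_required, .storage_optional,
             paste0(c("moisture_pct_wb", "aw", .storage_optional), "_sd"),
             c("flow_class", "aw_stability", "tab_safe"))
  extra <- setdiff(names(storage), known)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  num_cols <- intersect(names(storage),
                        c("day", "moisture_pct_wb", "aw", .storage_optional,
                          paste0(c("moisture_pct_wb", "aw", .storage_optional),
                                 "_sd")))
  for (cl in num_cols) {
    v <- storage[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "")
      if (length(bad)) {
        stop(sprintf("malformed numeric cell(s) in column '%s' at row(s) %s",
                     cl, paste(bad, collapse = ", ")), call. = FALSE)
      }
      storage[[cl]] <- conv
    }
  }
  if (any(!is.finite(storage$moisture_pct_wb)) ||
      any(storage$moisture_pct_wb < 0) || any(storage$moisture_pct_wb >= 100)) {
    stop("moisture_pct_wb must be in [0, 100)", call. = FALSE)
  }
  if (any(!is.finite(storage$aw)) || any(storage$aw < 0) ||
      any(storage$aw >= 1)) {
    stop("aw must be in [0, 1)", call. = FALSE)
  }
  key <- interaction(storage$treatment, storage$condition, drop = TRUE)
  for (k in levels(key)) {
    d <- storage$day[key == k]
    if (anyDuplicated(d)) {
      stop("duplicate sampling days in series ", k, call. = FALSE)
    }
    if (is.unsorted(d)) {
      warning("sampling days out of order in series ", k, "; rows sorted",
              call. = FALSE)
    }
  }
  storage <- storage[order(storage$treatment, storage$condition, storage$day), ,
                     drop = FALSE]
  rownames(storage) <- NULL
  class(storage) <- c("storage_experiment", "data.frame")
  storage
}

#' @rdname read_storage_csv
#' @param storage A storage table.
#' @export
write_storage_csv <- function(storage, path) {
  stopifnot(is.data.frame(storage))
  write.csv(storage, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a storage table into its treatment x condition series
#'
#' @param storage A storage table.
#' @return A named list of data.frames, names `"<treatment>.<condition>"`,
#'   each sorted by day.
#' @export
split_series <- function(storage) {
  stopifnot(is.data.frame(storage))
  key <- interaction(storage$treatment, storage$condition, drop = TRUE,
                     lex.order = TRUE)
  lapply(split(as.data.frame(storage), key), function(d) {
    d[order(d$day), , drop = FALSE]
  })
}

#' The bundled 180-day apricot-powder storage study
#'
#' Transcription of the published storage tables for spray-dried apricot
#' powder: three treatments (untreated `control`, tricalcium phosphate `TCP`,
#' silicon dioxide `SiO2`) under two storage conditions (`ambient`,
#' 25 degC / 60\% RH and `accelerated`, 40 degC / 90\% RH), sampled on days
#' 0, 30, 60, 90, 120, 140, 160 and 180.  Columns follow the long schema of
#' [read_storage_csv()]; `*_sd` columns hold the reported standard
#' deviations.  Total plate counts are in CFU/g.
#'
#' @return A `storage_experiment` data.frame with 48 rows.
#' @examples
#' head(apricot_storage())
#' @export
apricot_storage <- function() {
  path <- system.file("extdata", "apricot_storage.csv",
                      package = "powdershelf", mustWork = TRUE)
  suppressWarnings(read_storage_csv(path))
}
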