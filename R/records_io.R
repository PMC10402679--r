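#' QC item catalog
#'
#' Constructs a catalog of monitored machine parameters. Each item has an
#' integer index, a name, a tolerance (the allowed deviation magnitude before
#' the parameter counts as failed), a tolerance unit, and a free-text
#' description of the error modeled when assessing dose severity.
#'
#' @param item_id integer vector of unique item indices.
#' @param name character vector of item labels.
#' @param tolerance_value positive numeric vector of tolerances.
#' @param tolerance_unit character vector, each \code{"degrees"} or
#'   \code{"mm"}.
#' @param modeled_error character vector describing the dose-perturbation
#'   used for severity assessment.
#' @return A data frame with class \code{"qc_catalog"}.
#' @export
qc_catalog <- function(item_id, name, tolerance_value, tolerance_unit,
                       modeled_error = NA_character_) {
  cat <- data.frame(
    item_id = as.integer(item_id),
    name = as.character(name),
    tolerance_value = as.numeric(tolerance_value),
    tolerance_unit = as.character(tolerance_unit),
    modeled_error = as.character(modeled_error),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(cat$item_id)) {
    stop("item_id must be unique within a catalog", call. = FALSE)
  }
  if (any(!is.finite(cat$tolerance_value)) || any(cat$tolerance_value <= 0)) {
    stop("tolerance_value must be positive", call. = FALSE)
  }
  bad <- !cat$tolerance_unit %in% c("degrees", "mm")
  if (any(bad)) {
    stop("tolerance_unit must be 'degrees' or 'mm' (item ",
         paste(cat$item_id[bad], collapse = ", "), ")", call. = FALSE)
  }
  class(cat) <- c("qc_catalog", "data.frame")
  cat
}

#' Default catalog of six monthly mechanical QC items for an MR-linac
#'
#' The six routinely monitored items with the institutional tolerances used
#' throughout the package examples: gantry angle indicator (0.2 degrees),
#' collimator-couch coincidence (0.2 degrees), jaw position indicator
#' (1.0 mm), couch position precision (1.0 mm), radiation isocenter size
#' (0.5 mm), and MR-to-MV fit (1.0 mm).
#'
#' @return A \code{qc_catalog} with six rows.
#' @export
#' @examples
#' default_catalog()
default_catalog <- function() {
  qc_catalog(
    item_id = 1:6,
    name = c("Gantry angle indicator",
             "Coincidence collimator-couch",
             "Jaw position indicator",
             "Couch position precision",
             "Radiation isocenter size",
             "MR to MV fit"),
    tolerance_value = c(0.2, 0.2, 1.0, 1.0, 0.5, 1.0),
    tolerance_unit = c("degrees", "degrees", "mm", "mm", "mm", "mm"),
    modeled_error = c("0.2 degree change in gantry angle",
                      "0.2 degree change in gantry angle",
                      "1.0 mm shift in jaws",
                      "1.0 mm shift in AP direction",
                      "0.5 mm translational shift in three axes",
                      "1.0 mm translational shift in three axes")
  )
}

#' Grid of candidate QC test intervals
#'
#' @param intervals strictly increasing integer vector of test intervals in
#'   days, all at least 1.
#' @param labels optional character labels; defaults to \code{"D<interval>"}.
#' @return A data frame with class \code{"interval_grid"} and columns
#'   \code{interval_days} and \code{label}.
#' @export
#' @examples
#' interval_grid()  # the default daily-to-bimonthly grid
interval_grid <- function(intervals = c(1L, 7L, 14L, 21L, 30L, 60L),
                          labels = paste0("D", intervals)) {
  intervals <- as.integer(intervals)
  if (length(intervals) == 0L || any(intervals < 1L)) {
    stop("intervals must all be >= 1 day", call. = FALSE)
  }
  if (any(diff(intervals) <= 0L)) {
    stop("intervals must be strictly increasing", call. = FALSE)
  }
  if (length(labels) != length(intervals)) {
    stop("labels must parallel intervals", call. = FALSE)
  }
  structure(
    data.frame(interval_days = intervals, label = as.character(labels),
               stringsAsFactors = FALSE),
    class = c("interval_grid", "data.frame")
  )
}

## ---- internal validation helpers -------------------------------------------

parse_iso_date <- function(x, file, column) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(as.character(x)))
  if (any(is.na(d))) {
    row <- if (length(bad)) bad[1] else which(is.na(d))[1]
    stop("unparseable date in ", file, " column '", column, "', row ", row,
         " ('", x[row], "'); expected ISO-8601 YYYY-MM-DD", call. = FALSE)
  }
  d
}

check_item_ids <- function(ids, catalog, file) {
  unknown <- which(!ids %in% catalog$item_id)
  if (length(unknown) > 0L) {
    stop("unknown item_id ", ids[unknown[1]], " in ", file, ", row ",
         unknown[1], " (not in catalog)", call. = FALSE)
  }
  invisible(ids)
}

check_header <- function(df, expected, file) {
  if (!all(expected %in% names(df))) {
    stop(file, ": header must contain columns ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Decide whether deviations are within tolerance
#'
#' A measurement is within tolerance exactly when its absolute deviation does
#' not exceed the item's tolerance; the boundary counts as within tolerance
#' because tolerances are stated as inclusive limits.
#'
#' @param deviation numeric vector of measured deviations.
#' @param tolerance positive numeric vector (recycled) of tolerances.
#' @return logical vector.
#' @export
within_tolerance <- function(deviation, tolerance) {
  abs(deviation) <= tolerance
}

## ---- readers ---------------------------------------------------------------

#' Read a QC measurement log
#'
#' Reads a CSV with columns \code{date,item_id,measured_deviation}. The
#' within-tolerance flag is recomputed from the catalog tolerances; any flag
#' stored in the file is ignored.
#'
#' @param path path to the CSV file.
#' @param catalog a \code{qc_catalog}.
#' @return A data frame of measurements with columns \code{date} (Date),
#'   \code{item_id}, \code{measured_deviation}, \code{within_tolerance}.
#' @export
read_qc_log <- function(path, catalog = default_catalog()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_header(df, c("date", "item_id", "measured_deviation"), path)
  if (nrow(df) == 0L) {
    return(data.frame(date = as.Date(character()), item_id = integer(),
                      measured_deviation = numeric(),
                      within_tolerance = logical()))
  }
  date <- parse_iso_date(df$date, path, "date")
  item_id <- as.integer(df$item_id)
  check_item_ids(item_id, catalog, path)
  dev <- as.numeric(df$measured_deviation)
  if (any(!is.finite(dev))) {
    stop("non-numeric measured_deviation in ", path, ", row ",
         which(!is.finite(dev))[1], call. = FALSE)
  }
  tol <- catalog$tolerance_value[match(item_id, catalog$item_id)]
  data.frame(date = date, item_id = item_id, measured_deviation = dev,
             within_tolerance = within_tolerance(dev, tol))
}

#' Write a QC measurement log
#'
#' @param log a measurement data frame as returned by [read_qc_log()].
#' @param path output CSV path.
#' @export
write_qc_log <- function(log, path) {
  out <- data.frame(date = format(log$date, "%Y-%m-%d"),
                    item_id = log$item_id,
                    measured_deviation = log$measured_deviation)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a service/failure event log
#'
#' Reads a CSV with columns
#' \code{item_id,onset_date,found_date,repaired_date,found_by_qc}.
#' \code{onset_date} is the date the failure is judged to have begun, or the
#' last QC test that missed it; \code{found_date} is when it was discovered;
#' \code{repaired_date} is when function was restored. Events are returned
#' sorted by \code{found_date} and the ordering invariant
#' onset <= found <= repaired is enforced.
#'
#' @inheritParams read_qc_log
#' @return A data frame of service events.
#' @export
read_service_log <- function(path, catalog = default_catalog()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_header(df, c("item_id", "onset_date", "found_date", "repaired_date",
                     "found_by_qc"), path)
  if (nrow(df) == 0L) {
    return(data.frame(item_id = integer(), onset_date = as.Date(character()),
                      found_date = as.Date(character()),
                      repaired_date = as.Date(character()),
                      found_by_qc = logical()))
  }
  item_id <- as.integer(df$item_id)
  check_item_ids(item_id, catalog, path)
  onset <- parse_iso_date(df$onset_date, path, "onset_date")
  found <- parse_iso_date(df$found_date, path, "found_date")
  repaired <- parse_iso_date(df$repaired_date, path, "repaired_date")
  bad <- which(onset > found | found > repaired)
  if (length(bad) > 0L) {
    stop("service event dates out of order in ", path, ", row ", bad[1],
         " (need onset <= found <= repaired)", call. = FALSE)
  }
  fbq <- as.logical(df$found_by_qc)
  if (any(is.na(fbq))) {
    stop("found_by_qc must be TRUE/FALSE in ", path, ", row ",
         which(is.na(fbq))[1], call. = FALSE)
  }
  ev <- data.frame(item_id = item_id, onset_date = onset, found_date = found,
                   repaired_date = repaired, found_by_qc = fbq)
  ev[order(ev$found_date, ev$item_id), , drop = FALSE]
}

#' Write a service event log
#'
#' @param events a service event data frame as returned by
#'   [read_service_log()].
#' @param path output CSV path.
#' @export
write_service_log <- function(events, path) {
  out <- data.frame(item_id = events$item_id,
                    onset_date = format(events$onset_date, "%Y-%m-%d"),
                    found_date = format(events$found_date, "%Y-%m-%d"),
                    repaired_date = format(events$repaired_date, "%Y-%m-%d"),
                    found_by_qc = events$found_by_qc)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dose-metric table
#'
#' Reads per-patient, per-item, per-interval dose deviations produced
#' externally by a treatment planning system: the change in the percentage
#' of PTV covered by the prescription dose (percentage points) and the
#' change in the maximum spinal-cord dose (cGy), both absolute magnitudes.
#' CSV columns:
#' \code{patient_id,item_id,interval_days,delta_ptv_pct,delta_cord_cgy}.
#'
#' @inheritParams read_qc_log
#' @param grid an \code{interval_grid}; every \code{interval_days} in the
#'   file must be a member.
#' @return A data frame of dose-metric records.
#' @export
read_dose_metrics <- function(path, catalog = default_catalog(),
                              grid = interval_grid()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_header(df, c("patient_id", "item_id", "interval_days",
                     "delta_ptv_pct", "delta_cord_cgy"), path)
  if (nrow(df) == 0L) {
    return(data.frame(patient_id = character(), item_id = integer(),
                      interval_days = integer(), delta_ptv_pct = numeric(),
                      delta_cord_cgy = numeric()))
  }
  item_id <- as.integer(df$item_id)
  check_item_ids(item_id, catalog, path)
  iv <- as.integer(df$interval_days)
  bad <- which(!iv %in% grid$interval_days)
  if (length(bad) > 0L) {
    stop("interval_days ", iv[bad[1]], " in ", path, ", row ", bad[1],
         " is not on the tested grid {",
         paste(grid$interval_days, collapse = ","), "}", call. = FALSE)
  }
  ptv <- as.numeric(df$delta_ptv_pct)
  cord <- as.numeric(df$delta_cord_cgy)
  neg <- which(!is.finite(ptv) | !is.finite(cord) | ptv < 0 | cord < 0)
  if (length(neg) > 0L) {
    stop("dose deviations must be non-negative magnitudes in ", path,
         ", row ", neg[1], call. = FALSE)
  }
  data.frame(patient_id = as.character(df$patient_id), item_id = item_id,
             interval_days = iv, delta_ptv_pct = ptv, delta_cord_cgy = cord)
}

#' Write a dose-metric table
#'
#' @param metrics a dose-metric data frame as returned by
#'   [read_dose_metrics()].
#' @param path output CSV path.
#' @export
write_dose_metrics <- function(metrics, path) {
  utils::write.csv(
    metrics[, c("patient_id", "item_id", "interval_days", "delta_ptv_pct",
                "delta_cord_cgy")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an analysis/catalog configuration file
#'
#' Reads a YAML (or JSON) configuration holding the QC item catalog and the
#' interval grid, plus optional analysis settings.
#'
#' @param path path to a YAML file with top-level keys \code{catalog} (list
#'   of items with \code{item_id}, \code{name}, \code{tolerance_value},
#'   \code{tolerance_unit}, optional \code{modeled_error}) and
#'   \code{intervals} (integer vector); other keys are passed through.
#' @return A list with elements \code{catalog} (a \code{qc_catalog}),
#'   \code{grid} (an \code{interval_grid}), and any remaining settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  out <- cfg
  if (!is.null(cfg$catalog)) {
    items <- cfg$catalog
    out$catalog <- qc_catalog(
      item_id = vapply(items, function(x) as.integer(x$item_id), integer(1)),
      name = vapply(items, function(x) as.character(x$name), character(1)),
      tolerance_value = vapply(items, function(x)
        as.numeric(x$tolerance_value), numeric(1)),
      tolerance_unit = vapply(items, function(x)
        as.character(x$tolerance_unit), character(1)),
      modeled_error = vapply(items, function(x)
        if (is.null(x$modeled_error)) NA_character_
        else as.character(x$modeled_error), character(1))
    )
  } else {
    out$catalog <- default_catalog()
  }
  out$grid <- if (!is.null(cfg$intervals)) {
    interval_grid(as.integer(unlist(cfg$intervals)))
  } else {
    interval_grid()
  }
  out
}
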