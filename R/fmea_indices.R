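#' Round half away from zero
#'
#' Unlike [round()], which rounds half to even, values exactly halfway
#' between integers move away from zero (2.5 becomes 3). This is the
#' convention used when converting a mean severity rank to an integer rank.
#'
#' @param x numeric vector.
#' @return numeric vector of integers.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Occurrence index of a QC item
#'
#' The occurrence quantity is the fraction of the observation period a
#' parameter spent out of tolerance, in percent. An out-of-tolerance QC
#' measurement marks the state "failed" from its date until the next
#' in-tolerance measurement or the item's repair, whichever comes first;
#' each failed calendar day is counted once. Items that never failed receive
#' rank 2, not rank 1: a rank-1 occurrence would assert a failure rate below
#' one part in 10^4, which a finite clean record cannot support.
#'
#' @param log a QC measurement data frame (see [read_qc_log()]).
#' @param item a single-row \code{qc_catalog} entry, or an item_id present
#'   in \code{log}.
#' @param period_days length of the observation period in days; must cover
#'   all log dates for the item.
#' @param service optional service event data frame; repairs end a failed
#'   state if they precede the next in-tolerance measurement.
#' @param period_start first day of the observation window; defaults to the
#'   earliest date in \code{log}.
#' @param tables ranking tables (see [rank_tables()]).
#' @return A list of class \code{"occurrence_result"} with elements
#'   \code{item_id}, \code{quantity} (percent), \code{ever_failed},
#'   \code{rank}, \code{failed_days}.
#' @export
occurrence_index <- function(log, item, period_days, service = NULL,
                             period_start = NULL, tables = rank_tables()) {
  id <- if (is.data.frame(item)) item$item_id[1] else as.integer(item)
  if (!is.numeric(period_days) || period_days <= 0) {
    stop("period_days must be a positive number of days", call. = FALSE)
  }
  rows <- log[log$item_id == id, , drop = FALSE]
  if (nrow(rows) == 0L || all(rows$within_tolerance)) {
    return(structure(list(item_id = id, quantity = 0, ever_failed = FALSE,
                          rank = 2L, failed_days = 0L),
                     class = "occurrence_result"))
  }
  rows <- rows[order(rows$date), , drop = FALSE]
  if (is.null(period_start)) period_start <- min(log$date)
  window_end <- period_start + period_days - 1L
  if (any(rows$date < period_start) || any(rows$date > window_end)) {
    stop("period does not cover all log dates for item ", id, call. = FALSE)
  }
  repairs <- if (!is.null(service)) {
    sort(service$repaired_date[service$item_id == id])
  } else {
    as.Date(character())
  }
  failed <- as.Date(character())
  oot <- which(!rows$within_tolerance)
  for (i in oot) {
    start <- rows$date[i]
    later_ok <- rows$date[rows$within_tolerance & rows$date > start]
    later_rep <- repairs[repairs > start]
    end <- min(c(later_ok, later_rep, window_end + 1L))
    failed <- c(failed, seq(start, end - 1L, by = "day"))
  }
  n_failed <- length(unique(failed))
  quantity <- n_failed / period_days * 100
  structure(list(item_id = id, quantity = quantity, ever_failed = TRUE,
                 rank = rank_from_table(quantity, "occurrence", tables),
                 failed_days = n_failed),
            class = "occurrence_result")
}

#' Detection index of a QC item
#'
#' The detection quantity is the fraction of the observation period during
#' which failures persisted undetected, in percent. A failure caught by the
#' QC test itself contributes nothing. A failure missed by QC and found
#' later (by service or at a subsequent test) contributes half the time
#' between the last QC test that missed it and its discovery: the true onset
#' is only known to lie inside that gap, and half the gap is its expected
#' position.
#'
#' @param service a service event data frame (see [read_service_log()]).
#' @param item a single-row \code{qc_catalog} entry or an item_id.
#' @param period_days observation period in days (the same period used for
#'   the occurrence index, so that O and D are commensurable).
#' @param interval_days optional test interval this index is associated
#'   with; carried through to the result.
#' @param tables ranking tables.
#' @return A list of class \code{"detection_result"} with elements
#'   \code{item_id}, \code{interval_days}, \code{quantity} (percent),
#'   \code{rank}, \code{undetected_days}.
#' @export
detection_index <- function(service, item, period_days, interval_days = NA,
                            tables = rank_tables()) {
  id <- if (is.data.frame(item)) item$item_id[1] else as.integer(item)
  if (!is.numeric(period_days) || period_days <= 0) {
    stop("period_days must be a positive number of days", call. = FALSE)
  }
  rows <- service[service$item_id == id, , drop = FALSE]
  contrib <- if (nrow(rows) == 0L) {
    numeric(0)
  } else {
    ifelse(rows$found_by_qc, 0,
           as.numeric(rows$found_date - rows$onset_date) / 2)
  }
  undetected <- sum(contrib)
  quantity <- undetected / period_days * 100
  structure(list(item_id = id, interval_days = interval_days,
                 quantity = quantity,
                 rank = rank_from_table(quantity, "detection", tables),
                 undetected_days = undetected),
            class = "detection_result")
}

#' Severity index of a failure mode
#'
#' Severity is assessed from per-patient dose perturbations observed when
#' the item's modeled error persists for a given test interval: the change
#' in PTV coverage (percent of volume) and the change in maximum spinal-cord
#' dose (cGy). Each patient's two quantities are converted to ranks on their
#' respective scales and combined per \code{aggregation} (default: the worst
#' of the two, a conservative choice). The cohort is pooled either as the
#' mean of per-patient ranks (default, which yields fractional mean ranks)
#' or as the rank of the mean quantities.
#'
#' @param metrics a dose-metric data frame (see [read_dose_metrics()]), one
#'   row per patient for the requested item and interval.
#' @param item a single-row \code{qc_catalog} entry or an item_id.
#' @param interval_days the test interval in days.
#' @param aggregation how a patient's PTV and cord ranks combine:
#'   \code{"max_of_criteria"} (default), \code{"ptv_only"},
#'   \code{"cord_only"}.
#' @param pooling \code{"mean_of_ranks"} (default) or
#'   \code{"rank_of_means"}.
#' @param tables ranking tables.
#' @return A list of class \code{"severity_result"} with elements
#'   \code{item_id}, \code{interval_days}, \code{per_patient_ranks},
#'   \code{mean_rank}, \code{mean_delta_ptv_pct}, \code{mean_delta_cord_cgy}.
#' @export
severity_index <- function(metrics, item, interval_days,
                           aggregation = c("max_of_criteria", "ptv_only",
                                           "cord_only"),
                           pooling = c("mean_of_ranks", "rank_of_means"),
                           tables = rank_tables()) {
  aggregation <- match.arg(aggregation)
  pooling <- match.arg(pooling)
  id <- if (is.data.frame(item)) item$item_id[1] else as.integer(item)
  rows <- metrics[metrics$item_id == id &
                    metrics$interval_days == interval_days, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no dose-metric records for item ", id, " at interval ",
         interval_days, " days", call. = FALSE)
  }
  ptv_ranks <- rank_from_table(rows$delta_ptv_pct, "severity_ptv", tables)
  cord_ranks <- rank_from_table(rows$delta_cord_cgy, "severity_cord", tables)
  combine <- function(p, co) {
    switch(aggregation,
           max_of_criteria = pmax(p, co),
           ptv_only = p,
           cord_only = co)
  }
  per_patient <- combine(ptv_ranks, cord_ranks)
  mean_ptv <- mean(rows$delta_ptv_pct)
  mean_cord <- mean(rows$delta_cord_cgy)
  mean_rank <- if (pooling == "mean_of_ranks") {
    mean(per_patient)
  } else {
    combine(rank_from_table(mean_ptv, "severity_ptv", tables),
            rank_from_table(mean_cord, "severity_cord", tables))
  }
  structure(list(item_id = id, interval_days = interval_days,
                 per_patient_ranks = as.integer(per_patient),
                 mean_rank = as.numeric(mean_rank),
                 mean_delta_ptv_pct = mean_ptv,
                 mean_delta_cord_cgy = mean_cord),
            class = "severity_result")
}

#' Assemble the (S, O, D) rank profile of a failure mode
#'
#' A failure mode is one QC item paired with one test interval. The mean
#' severity rank is converted to an integer per the configured rounding
#' (default: nearest, half away from zero); occurrence and detection ranks
#' are passed through.
#'
#' @param item a single-row \code{qc_catalog} entry or an item_id.
#' @param interval_days the test interval in days.
#' @param S a \code{severity_result} or a numeric mean severity rank.
#' @param O an \code{occurrence_result} or an integer occurrence rank.
#' @param D a \code{detection_result} or an integer detection rank.
#' @param rounding \code{"nearest"} (half away from zero, the default),
#'   \code{"floor"}, or \code{"ceiling"}.
#' @return A one-row data frame with class \code{"rank_profile"} and columns
#'   \code{item_id}, \code{interval_days}, \code{S}, \code{O}, \code{D}.
#' @export
rank_profile <- function(item, interval_days, S, O, D,
                         rounding = c("nearest", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  id <- if (is.data.frame(item)) item$item_id[1] else as.integer(item)
  s_mean <- if (inherits(S, "severity_result")) S$mean_rank else as.numeric(S)
  o_rank <- if (inherits(O, "occurrence_result")) O$rank else as.integer(O)
  d_rank <- if (inherits(D, "detection_result")) D$rank else as.integer(D)
  if (inherits(S, "severity_result") && S$item_id != id ||
      inherits(O, "occurrence_result") && O$item_id != id ||
      inherits(D, "detection_result") && D$item_id != id) {
    stop("S, O, and D must refer to item ", id, call. = FALSE)
  }
  s_rank <- switch(rounding,
                   nearest = round_half_away(s_mean),
                   floor = floor(s_mean),
                   ceiling = ceiling(s_mean))
  if (s_rank < 1 || s_rank > 10) {
    warning("rounded severity rank ", s_rank, " clamped to [1, 10]",
            call. = FALSE)
    s_rank <- min(max(s_rank, 1), 10)
  }
  if (!o_rank %in% 1:10 || !d_rank %in% 1:10) {
    stop("O and D ranks must be integers in 1-10", call. = FALSE)
  }
  structure(
    data.frame(item_id = id, interval_days = as.integer(interval_days),
               S = as.integer(s_rank), O = as.integer(o_rank),
               D = as.integer(d_rank)),
    class = c("rank_profile", "data.frame")
  )
}
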