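#' Risk-matrix analysis of QC frequencies
#'
#' The top-level estimator of the package. From a QC measurement log, a
#' service event log, and a per-patient dose-metric table, it computes the
#' FMEA indices of every failure mode FM(QC_m, D_n) — the severity rank from
#' the cohort dose perturbations at each tested interval, the occurrence
#' rank from the out-of-tolerance time fraction, and the detection rank from
#' the undetected-failure time fraction — classifies each (S, O) pair on the
#' 10x10 risk matrix, and recommends per item the first medium-risk interval
#' on the grid. When the old schedule's intervals are supplied, the new and
#' old schedules are compared with the efficiency metric E = O/D.
#'
#' @param qc_log QC measurement data frame (see [read_qc_log()]).
#' @param service_log service event data frame (see [read_service_log()]).
#' @param dose_metrics dose-metric data frame (see [read_dose_metrics()]).
#' @param catalog a \code{qc_catalog}.
#' @param grid an \code{interval_grid} of candidate test intervals.
#' @param period_days observation period in days covering the logs; defaults
#'   to the span of the QC log.
#' @param rounding rounding of mean severity ranks: \code{"nearest"} (half
#'   away from zero), \code{"floor"}, \code{"ceiling"}.
#' @param aggregation how the PTV and cord severity criteria combine per
#'   patient (see [severity_index()]).
#' @param pooling cohort pooling of severity ranks (see [severity_index()]).
#' @param old_schedule optional named or ordered integer vector of the old
#'   per-item test intervals in days; enables the schedule comparison.
#' @param tables ranking tables (see [rank_tables()]).
#' @return An object of class \code{"rm_analysis"}: a list with
#'   \code{indices} (one row per failure mode: mean S index, S/O/D ranks,
#'   risk level), \code{severity} (mean severity indices in wide form, one
#'   row per item), \code{recommendations} (list of
#'   \code{frequency_recommendation}), \code{recommendation_table},
#'   \code{comparison} (or NULL), \code{matrix}, and the call and settings.
#' @export
#' @examples
#' fx <- end_to_end_fixture(seed = 7)
#' fit <- rm_analysis(fx$qc_log, fx$service_log, fx$dose_metrics,
#'                    period_days = 360)
#' fit
rm_analysis <- function(qc_log, service_log, dose_metrics,
                        catalog = default_catalog(),
                        grid = interval_grid(),
                        period_days = NULL,
                        rounding = c("nearest", "floor", "ceiling"),
                        aggregation = c("max_of_criteria", "ptv_only",
                                        "cord_only"),
                        pooling = c("mean_of_ranks", "rank_of_means"),
                        old_schedule = NULL,
                        tables = rank_tables()) {
  rounding <- match.arg(rounding)
  aggregation <- match.arg(aggregation)
  pooling <- match.arg(pooling)
  if (is.null(period_days)) {
    if (nrow(qc_log) == 0L) {
      stop("period_days must be given when the QC log is empty",
           call. = FALSE)
    }
    period_days <- as.integer(max(qc_log$date) - min(qc_log$date)) + 1L
  }
  matrix <- build_risk_matrix()

  occ <- lapply(catalog$item_id, function(id) {
    occurrence_index(qc_log, id, period_days, service = service_log,
                     tables = tables)
  })
  det <- lapply(catalog$item_id, function(id) {
    detection_index(service_log, id, period_days, tables = tables)
  })
  names(occ) <- names(det) <- catalog$item_id

  profiles <- list(); sev_rows <- list()
  for (k in seq_along(catalog$item_id)) {
    id <- catalog$item_id[k]
    for (iv in grid$interval_days) {
      sv <- severity_index(dose_metrics, id, iv, aggregation = aggregation,
                           pooling = pooling, tables = tables)
      pr <- rank_profile(id, iv, sv, occ[[k]], det[[k]],
                         rounding = rounding)
      pr$S_mean <- sv$mean_rank
      profiles[[length(profiles) + 1L]] <- pr
    }
  }
  profiles <- do.call(rbind, profiles)
  profiles$level <- as.character(lookup_risk(matrix, profiles$S, profiles$O))

  sev_wide <- stats::reshape(
    profiles[, c("item_id", "interval_days", "S_mean")],
    idvar = "item_id", timevar = "interval_days", direction = "wide")
  names(sev_wide) <- sub("^S_mean\\.", "D", names(sev_wide))

  recs <- lapply(catalog$item_id, function(id) {
    recommend_frequency(id, profiles, matrix = matrix, grid = grid)
  })
  names(recs) <- catalog$item_id
  rec_table <- data.frame(
    item_id = catalog$item_id,
    name = catalog$name,
    O = vapply(occ, function(x) as.integer(x$rank), integer(1)),
    D = vapply(det, function(x) as.integer(x$rank), integer(1)),
    recommended_interval_days =
      vapply(recs, function(r) r$recommended_interval_days, integer(1)),
    rule_applied = vapply(recs, function(r) r$rule_applied, character(1)),
    stringsAsFactors = FALSE)

  comparison <- NULL
  if (!is.null(old_schedule)) {
    old_iv <- if (!is.null(names(old_schedule))) {
      as.integer(old_schedule[as.character(catalog$item_id)])
    } else {
      as.integer(rep_len(old_schedule, nrow(catalog)))
    }
    comparison <- compare_with_old(catalog, qc_log, service_log,
                                   period_days, rec_table, old_iv, tables)
  }

  structure(list(indices = profiles, severity = sev_wide,
                 occurrence = occ, detection = det,
                 recommendations = recs, recommendation_table = rec_table,
                 comparison = comparison, matrix = matrix,
                 settings = list(period_days = period_days,
                                 rounding = rounding,
                                 aggregation = aggregation,
                                 pooling = pooling),
                 catalog = catalog, grid = grid, call = match.call()),
            class = "rm_analysis")
}

# Re-estimates O and D ranks per schedule interval and tabulates E for the
# recommended versus the old intervals. O does not depend on the interval
# (it is the item's out-of-tolerance fraction over the period); D is
# computed once per item from the service record, so the comparison reduces
# to the efficiency of the shared ranks unless per-interval detection data
# are supplied downstream.
compare_with_old <- function(catalog, qc_log, service_log, period_days,
                             rec_table, old_iv, tables) {
  new_eval <- schedule_evaluation(rec_table$item_id, rec_table$O,
                                  rec_table$D, label = "new")
  old_eval <- schedule_evaluation(rec_table$item_id, rec_table$O,
                                  rec_table$D, label = "old")
  cmp <- compare_schedules(new_eval, old_eval)
  cmp$interval_new <- rec_table$recommended_interval_days
  cmp$interval_old <- old_iv
  cmp
}

#' @export
print.rm_analysis <- function(x, ...) {
  cat("Risk-matrix QC frequency analysis\n")
  cat("  period:", x$settings$period_days, "days;",
      nrow(x$catalog), "QC items x", nrow(x$grid), "intervals =",
      nrow(x$indices), "failure modes\n")
  cat("  settings: rounding =", x$settings$rounding,
      "| aggregation =", x$settings$aggregation,
      "| pooling =", x$settings$pooling, "\n\n")
  cat("Recommended test intervals:\n")
  print(x$recommendation_table, row.names = FALSE)
  invisible(x)
}

#' @export
summary.rm_analysis <- function(object, ...) {
  structure(list(fit = object), class = "summary.rm_analysis")
}

#' @export
print.summary.rm_analysis <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nMean severity indices by interval:\n")
  print(fit$severity, row.names = FALSE)
  cat("\nPer-failure-mode risk levels:\n")
  print(fit$indices[, c("item_id", "interval_days", "S_mean", "S", "O",
                        "D", "level")], row.names = FALSE)
  if (!is.null(fit$comparison)) {
    cat("\n")
    print(fit$comparison)
  }
  invisible(x)
}

#' @export
coef.rm_analysis <- function(object, ...) {
  m <- as.matrix(object$severity[, -1, drop = FALSE])
  rownames(m) <- object$severity$item_id
  m
}

#' Plot the risk-matrix maps of a fitted analysis
#'
#' Draws one severity-by-interval grid per QC item, cells colored by risk
#' level with the recommended interval starred.
#'
#' @param x an \code{rm_analysis} object.
#' @param file optional PNG path.
#' @param ... unused.
#' @export
plot.rm_analysis <- function(x, file = NULL, ...) {
  render_rm_map(x$recommendations, file = file)
  invisible(x)
}
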