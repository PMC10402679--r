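#' Configuration for the machine-log simulator
#'
#' Describes the data-generating reality behind a QC record set: a machine
#' whose monitored parameters drift within tolerance while healthy, fail as
#' a memoryless process, stay out of tolerance until repaired, and are
#' checked by QC tests on a fixed working-day interval that flag a true
#' exceedance with a given sensitivity. A failure missed by QC is found by
#' service staff after a delay. All days are working days (20 per month, 240
#' per year), so a 360-day period corresponds to 1.5 calendar years.
#'
#' @param seed integer random seed.
#' @param period_days length of the simulated period in working days.
#' @param items a \code{qc_catalog}.
#' @param failure_rate expected failures per working year (240 days) per
#'   item; recycled over items.
#' @param drift_sd standard deviation of the healthy daily deviation, in the
#'   item's unit; recycled. Defaults to a quarter of each tolerance.
#' @param repair_delay_days whole days from discovery to restored function.
#' @param qc_interval_days working days between QC tests.
#' @param detection_sensitivity probability a QC test flags a true
#'   exceedance.
#' @param service_delay_days days from true failure onset to discovery by
#'   service, when QC has not flagged it first.
#' @param failure_excess multiple of tolerance at which a failed parameter
#'   sits; must exceed 1.
#' @param scripted_onsets optional data frame (\code{item_id}, \code{day})
#'   of forced failure-onset days for deterministic scenarios; combined with
#'   any random onsets.
#' @return A list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(seed = 1L,
                              period_days = 360L,
                              items = default_catalog(),
                              failure_rate = c(2 / 3, 0, 0, 0, 0, 0),
                              drift_sd = items$tolerance_value / 4,
                              repair_delay_days = 1L,
                              qc_interval_days = 20L,
                              detection_sensitivity = 1,
                              service_delay_days = 6L,
                              failure_excess = 1.5,
                              scripted_onsets = NULL) {
  n <- nrow(items)
  failure_rate <- rep_len(failure_rate, n)
  drift_sd <- rep_len(drift_sd, n)
  if (period_days < 1) stop("period_days must be >= 1", call. = FALSE)
  if (period_days < qc_interval_days) {
    stop("period_days must be at least one QC interval", call. = FALSE)
  }
  if (any(failure_rate < 0)) stop("failure rates must be >= 0", call. = FALSE)
  if (detection_sensitivity < 0 || detection_sensitivity > 1) {
    stop("detection_sensitivity must be a probability", call. = FALSE)
  }
  if (failure_excess <= 1) stop("failure_excess must exceed 1", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 period_days = as.integer(period_days), items = items,
                 failure_rate = failure_rate, drift_sd = drift_sd,
                 repair_delay_days = as.integer(repair_delay_days),
                 qc_interval_days = as.integer(qc_interval_days),
                 detection_sensitivity = detection_sensitivity,
                 service_delay_days = as.integer(service_delay_days),
                 failure_excess = failure_excess,
                 scripted_onsets = scripted_onsets),
            class = "simulation_config")
}

# Simulation epoch: working day d maps to this date + d - 1, so that date
# differences equal working-day differences.
sim_epoch <- function() as.Date("2020-06-01")

#' Simulate a machine's QC and service logs with ground truth
#'
#' Runs the day-by-day state machine described in [simulation_config()] for
#' every catalog item and returns the QC measurement log, the service event
#' log, and exhaustive ground-truth bookkeeping per item:
#' \describe{
#'   \item{latent_out_days / latent_out_frac}{days the parameter was truly
#'     out of tolerance (percent of the period)}
#'   \item{observed_out_days / observed_out_frac}{days attributable to an
#'     out-of-tolerance state from the QC records alone, counted day by day
#'     (the estimand of [occurrence_index()])}
#'   \item{undetected_half_days / undetected_frac}{half-interval undetected
#'     failure durations accumulated at discovery time (the estimand of
#'     [detection_index()])}
#'   \item{latent_undetected_days}{days truly failed and not yet found}
#'   \item{n_failures}{number of failure onsets}
#' }
#'
#' A QC test that misses a true exceedance records a healthy-looking
#' deviation (the measurement failed to reveal the fault); a flagging test
#' records the true out-of-tolerance deviation. Service events record as
#' onset the last QC test that did not report the failure.
#'
#' @param config a \code{simulation_config}.
#' @return A list with elements \code{qc_log}, \code{service_log},
#'   \code{truth} (one row per item), and \code{config}.
#' @export
simulate_machine_log <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  epoch <- sim_epoch()
  period <- config$period_days
  qc_days <- seq(1L, period, by = config$qc_interval_days)
  p_day <- config$failure_rate / 240

  qc_rows <- list(); ev_rows <- list(); truth_rows <- list()
  for (k in seq_len(nrow(config$items))) {
    item <- config$items[k, ]
    tol <- item$tolerance_value
    scripted <- if (is.null(config$scripted_onsets)) integer(0) else {
      so <- config$scripted_onsets
      as.integer(so$day[so$item_id == item$item_id])
    }
    state <- "ok"            # ok | failed_undetected | failed_detected
    onset_true <- NA_integer_
    service_day <- NA_integer_
    repair_day <- NA_integer_
    latent_out <- 0L; latent_undet <- 0L
    undet_half <- 0; n_fail <- 0L
    meas_day <- integer(0); meas_dev <- numeric(0)
    ev <- list()

    healthy_dev <- function() {
      d <- stats::rnorm(1, 0, config$drift_sd[k])
      max(min(d, tol), -tol)
    }
    last_silent_qc <- function(d) {
      prior <- qc_days[qc_days < d]
      if (length(prior)) max(prior) else 1L
    }

    for (d in seq_len(period)) {
      if (state == "failed_detected" && d >= repair_day) state <- "ok"
      if (state == "ok" &&
          (d %in% scripted || stats::runif(1) < p_day[k])) {
        state <- "failed_undetected"
        onset_true <- d
        service_day <- d + config$service_delay_days
        n_fail <- n_fail + 1L
      }
      if (d %in% qc_days) {
        if (state == "failed_undetected") {
          if (stats::runif(1) < config$detection_sensitivity) {
            # flagged by the test itself: recorded deviation is the true
            # exceedance; undetected duration contributes nothing
            meas_day <- c(meas_day, d)
            meas_dev <- c(meas_dev, tol * config$failure_excess)
            repair_day <- d + config$repair_delay_days
            ev[[length(ev) + 1L]] <- data.frame(
              item_id = item$item_id,
              onset_date = epoch + last_silent_qc(d) - 1L,
              found_date = epoch + d - 1L,
              repaired_date = epoch + repair_day - 1L,
              found_by_qc = TRUE)
            state <- "failed_detected"
          } else {
            # missed: the record looks healthy
            meas_day <- c(meas_day, d)
            meas_dev <- c(meas_dev, healthy_dev())
          }
        } else if (state == "failed_detected") {
          meas_day <- c(meas_day, d)
          meas_dev <- c(meas_dev, tol * config$failure_excess)
        } else {
          meas_day <- c(meas_day, d)
          meas_dev <- c(meas_dev, healthy_dev())
        }
      }
      if (state == "failed_undetected" && d >= service_day) {
        lsq <- last_silent_qc(d)
        repair_day <- d + config$repair_delay_days
        ev[[length(ev) + 1L]] <- data.frame(
          item_id = item$item_id,
          onset_date = epoch + lsq - 1L,
          found_date = epoch + d - 1L,
          repaired_date = epoch + repair_day - 1L,
          found_by_qc = FALSE)
        undet_half <- undet_half + (d - lsq) / 2
        state <- "failed_detected"
      }
      if (state != "ok") latent_out <- latent_out + 1L
      if (state == "failed_undetected") latent_undet <- latent_undet + 1L
    }

    item_qc <- data.frame(date = epoch + meas_day - 1L,
                          item_id = item$item_id,
                          measured_deviation = meas_dev)
    item_qc$within_tolerance <- within_tolerance(item_qc$measured_deviation,
                                                 tol)
    item_ev <- if (length(ev)) do.call(rbind, ev) else NULL
    observed_out <- brute_force_observed_days(item_qc, item_ev, period)

    qc_rows[[k]] <- item_qc
    ev_rows[[k]] <- item_ev
    truth_rows[[k]] <- data.frame(
      item_id = item$item_id,
      n_failures = n_fail,
      latent_out_days = latent_out,
      latent_out_frac = latent_out / period * 100,
      observed_out_days = observed_out,
      observed_out_frac = observed_out / period * 100,
      undetected_half_days = undet_half,
      undetected_frac = undet_half / period * 100,
      latent_undetected_days = latent_undet)
  }

  qc_log <- do.call(rbind, qc_rows)
  qc_log <- qc_log[order(qc_log$date, qc_log$item_id), , drop = FALSE]
  rownames(qc_log) <- NULL
  ev_rows <- ev_rows[!vapply(ev_rows, is.null, logical(1))]
  service_log <- if (length(ev_rows)) {
    ev <- do.call(rbind, ev_rows)
    ev <- ev[order(ev$found_date, ev$item_id), , drop = FALSE]
    rownames(ev) <- NULL
    ev
  } else {
    data.frame(item_id = integer(), onset_date = as.Date(character()),
               found_date = as.Date(character()),
               repaired_date = as.Date(character()), found_by_qc = logical())
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(qc_log = qc_log, service_log = service_log, truth = truth,
       config = config)
}

# Day-by-day count of days attributable to an out-of-tolerance state from
# the records alone: day d counts when some out-of-tolerance measurement at
# t <= d has no in-tolerance measurement and no repair in (t, d]. This is
# the independent brute-force oracle for occurrence_index().
brute_force_observed_days <- function(item_qc, item_ev, period) {
  if (nrow(item_qc) == 0L) return(0L)
  epoch <- sim_epoch()
  m_day <- as.integer(item_qc$date - epoch) + 1L
  m_ok <- item_qc$within_tolerance
  rep_day <- if (is.null(item_ev)) integer(0) else {
    as.integer(item_ev$repaired_date - epoch) + 1L
  }
  count <- 0L
  for (d in seq_len(period)) {
    oot <- m_day[!m_ok & m_day <= d]
    hit <- FALSE
    for (t in oot) {
      clears <- c(m_day[m_ok & m_day > t & m_day <= d],
                  rep_day[rep_day > t & rep_day <= d])
      if (length(clears) == 0L) { hit <- TRUE; break }
    }
    if (hit) count <- count + 1L
  }
  count
}

#' Dose-effect model for the synthetic dose-metric generator
#'
#' An explicit stand-in for the mechanism by which the dose impact of a
#' sustained parameter error grows with the QC test interval: the expected
#' deviation scales as \code{base_effect * (interval / shortest)^exponent},
#' with lognormal patient-to-patient variability of unit mean and the given
#' coefficient of variation.
#'
#' @param item_id integer vector of items.
#' @param base_ptv_effect expected change in PTV coverage (percent) at the
#'   shortest interval.
#' @param base_cord_effect expected change in maximum cord dose (cGy) at
#'   the shortest interval.
#' @param interval_scaling_exponent exponent of the interval scaling.
#' @param patient_variability_cv coefficient of variation of the lognormal
#'   patient multiplier.
#' @return A data frame of class \code{"dose_effect_model"}.
#' @export
dose_effect_model <- function(item_id,
                              base_ptv_effect,
                              base_cord_effect,
                              interval_scaling_exponent = 1,
                              patient_variability_cv = 0.3) {
  m <- data.frame(item_id = as.integer(item_id),
                  base_ptv_effect = as.numeric(base_ptv_effect),
                  base_cord_effect = as.numeric(base_cord_effect),
                  interval_scaling_exponent =
                    rep_len(interval_scaling_exponent, length(item_id)),
                  patient_variability_cv =
                    rep_len(patient_variability_cv, length(item_id)))
  if (any(m$base_ptv_effect < 0) || any(m$base_cord_effect < 0) ||
      any(m$patient_variability_cv < 0)) {
    stop("effects and cv must be non-negative", call. = FALSE)
  }
  class(m) <- c("dose_effect_model", "data.frame")
  m
}

#' Default dose-effect model for the six-item catalog
#'
#' Calibrated so that cohort mean severity ranks rise from about 1 at the
#' daily interval to 8-9 at the bimonthly interval, the qualitative pattern
#' of sustained mechanical errors on an MR-linac.
#'
#' @return A \code{dose_effect_model} for items 1-6.
#' @export
default_dose_model <- function() {
  dose_effect_model(
    item_id = 1:6,
    base_ptv_effect = c(0.8, 0.8, 0.7, 1.0, 1.6, 1.2),
    base_cord_effect = c(30, 30, 25, 40, 60, 45),
    interval_scaling_exponent = 0.75,
    patient_variability_cv = 0.3
  )
}

#' Simulate a per-patient dose-metric table
#'
#' For each item, interval, and patient, draws the PTV-coverage change and
#' the maximum-cord-dose change around the model's interval-scaled expected
#' effect with independent lognormal patient multipliers of unit mean.
#' Expected effects are monotone non-decreasing in the interval whenever the
#' scaling exponent is non-negative.
#'
#' @param model a \code{dose_effect_model}.
#' @param grid an \code{interval_grid}.
#' @param n_patients number of patients in the cohort.
#' @param seed integer random seed.
#' @return A dose-metric data frame (see [read_dose_metrics()]).
#' @export
simulate_dose_metrics <- function(model, grid = interval_grid(),
                                  n_patients = 10L, seed = 1L) {
  stopifnot(inherits(model, "dose_effect_model"), n_patients >= 1L)
  set.seed(seed)
  shortest <- min(grid$interval_days)
  rows <- list()
  for (k in seq_len(nrow(model))) {
    mk <- model[k, ]
    cv <- mk$patient_variability_cv
    sdlog <- sqrt(log(1 + cv^2))
    for (iv in grid$interval_days) {
      scale <- (iv / shortest)^mk$interval_scaling_exponent
      mult_ptv <- if (cv > 0) {
        stats::rlnorm(n_patients, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, n_patients)
      mult_cord <- if (cv > 0) {
        stats::rlnorm(n_patients, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, n_patients)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("P%02d", seq_len(n_patients)),
        item_id = mk$item_id,
        interval_days = iv,
        delta_ptv_pct = mk$base_ptv_effect * scale * mult_ptv,
        delta_cord_cgy = mk$base_cord_effect * scale * mult_cord)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a self-consistent synthetic input bundle with ground truth
#'
#' Generates one machine-log simulation and one dose-metric cohort, writes
#' the three CSV inputs plus a ground-truth JSON and a catalog/grid YAML
#' config to \code{dir}, and returns the expected (S, O, D) rank profiles
#' computed from the generator's own exhaustive bookkeeping. Identical seeds
#' produce byte-identical files.
#'
#' @param seed integer seed driving both generators.
#' @param dir output directory (created if needed).
#' @param config a \code{simulation_config}; its seed is replaced by
#'   \code{seed}.
#' @param model a \code{dose_effect_model}.
#' @param grid an \code{interval_grid}.
#' @param n_patients cohort size for the dose table.
#' @return A list with \code{paths} (named file paths), \code{truth},
#'   \code{expected_profiles} (data frame of item_id, interval_days, S, O,
#'   D), and the in-memory \code{qc_log}, \code{service_log},
#'   \code{dose_metrics}.
#' @export
end_to_end_fixture <- function(seed = 42L, dir = tempfile("fixture"),
                               config = simulation_config(),
                               model = default_dose_model(),
                               grid = interval_grid(),
                               n_patients = 10L) {
  config$seed <- as.integer(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_machine_log(config)
  metrics <- simulate_dose_metrics(model, grid, n_patients,
                                   seed = seed + 1L)
  paths <- c(qc_log = file.path(dir, "qc_log.csv"),
             service_log = file.path(dir, "service_log.csv"),
             dose_metrics = file.path(dir, "dose_metrics.csv"),
             ground_truth = file.path(dir, "ground_truth.json"),
             config = file.path(dir, "config.yaml"))
  write_qc_log(sim$qc_log, paths[["qc_log"]])
  write_service_log(sim$service_log, paths[["service_log"]])
  write_dose_metrics(metrics, paths[["dose_metrics"]])
  jsonlite::write_json(sim$truth, paths[["ground_truth"]], digits = NA,
                       dataframe = "rows")
  yaml::write_yaml(list(
    period_days = config$period_days,
    intervals = as.integer(grid$interval_days),
    catalog = lapply(seq_len(nrow(config$items)), function(i) {
      it <- config$items[i, ]
      list(item_id = it$item_id, name = it$name,
           tolerance_value = it$tolerance_value,
           tolerance_unit = it$tolerance_unit,
           modeled_error = it$modeled_error)
    })), paths[["config"]])

  # expected ranks from the generator's own bookkeeping, not the estimators
  profiles <- list()
  for (k in seq_len(nrow(config$items))) {
    tr <- sim$truth[k, ]
    o_rank <- if (tr$observed_out_days == 0L) 2L else {
      rank_from_table(tr$observed_out_frac, "occurrence")
    }
    d_rank <- rank_from_table(tr$undetected_frac, "detection")
    for (iv in grid$interval_days) {
      sv <- severity_index(metrics, config$items$item_id[k], iv)
      profiles[[length(profiles) + 1L]] <- data.frame(
        item_id = config$items$item_id[k], interval_days = iv,
        S = as.integer(round_half_away(sv$mean_rank)),
        O = o_rank, D = d_rank)
    }
  }
  expected <- do.call(rbind, profiles)
  list(paths = paths, truth = sim$truth, expected_profiles = expected,
       qc_log = sim$qc_log, service_log = sim$service_log,
       dose_metrics = metrics, config = config)
}
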