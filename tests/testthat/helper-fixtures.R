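# Shared fixture builders; everything is generated in code at test time.

epoch <- as.Date("2020-06-01")

# A flat QC log for one item: all-clear except out-of-tolerance on the given
# zero-based day offsets.
make_flat_log <- function(item_id = 1L, n_days = 360L, oot_days = integer(0),
                          tolerance = 0.2) {
  dev <- rep(0, n_days)
  dev[oot_days + 1L] <- tolerance * 1.5
  data.frame(date = epoch + seq_len(n_days) - 1L,
             item_id = item_id,
             measured_deviation = dev,
             within_tolerance = abs(dev) <= tolerance)
}

make_service_event <- function(item_id = 1L, onset_day, found_day,
                               repaired_day = found_day, found_by_qc = FALSE) {
  data.frame(item_id = item_id,
             onset_date = epoch + onset_day,
             found_date = epoch + found_day,
             repaired_date = epoch + repaired_day,
             found_by_qc = found_by_qc)
}

empty_service_log <- function() {
  data.frame(item_id = integer(), onset_date = as.Date(character()),
             found_date = as.Date(character()),
             repaired_date = as.Date(character()), found_by_qc = logical())
}

# Dose-metric rows at one (item, interval) with explicit per-patient values.
make_dose_rows <- function(item_id = 1L, interval_days = 7L,
                           ptv, cord = rep(0, length(ptv))) {
  data.frame(patient_id = sprintf("P%02d", seq_along(ptv)),
             item_id = item_id, interval_days = interval_days,
             delta_ptv_pct = ptv, delta_cord_cgy = cord)
}

# Build rank profiles for one item across the default grid from mean S
# indices (as printed per-interval severity means) and a shared O rank.
profiles_from_means <- function(s_means, o_rank, item_id = 1L,
                                intervals = c(1L, 7L, 14L, 21L, 30L, 60L),
                                rounding = "nearest") {
  do.call(rbind, lapply(seq_along(s_means), function(i) {
    rank_profile(item_id, intervals[i], s_means[i], o_rank, 1L,
                 rounding = rounding)
  }))
}

# Independent day-by-day occurrence oracle: walks every calendar day of the
# window and asks whether the most recent state-setting record marks it
# failed. Written as a direct transcription of the state-holding rule, not
# shared with the package internals.
oracle_occurrence_days <- function(log, item_id, period_days,
                                   period_start = min(log$date),
                                   repairs = as.Date(character())) {
  rows <- log[log$item_id == item_id, , drop = FALSE]
  rows <- rows[order(rows$date), , drop = FALSE]
  failed <- 0L
  for (off in seq_len(period_days) - 1L) {
    day <- period_start + off
    oot <- rows$date[!rows$within_tolerance & rows$date <= day]
    is_failed <- FALSE
    for (t in oot) {
      ended <- any(rows$date[rows$within_tolerance] > t &
                     rows$date[rows$within_tolerance] <= day) ||
        any(repairs > t & repairs <= day)
      if (!ended) { is_failed <- TRUE; break }
    }
    if (is_failed) failed <- failed + 1L
  }
  failed
}
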