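test_that("one out-of-tolerance day in 360 gives 0.278% and rank 6", {
  log <- make_flat_log(n_days = 360L, oot_days = 99L)
  res <- occurrence_index(log, 1L, 360)
  expect_equal(res$quantity, 100 / 360, tolerance = 1e-12)
  expect_equal(round(res$quantity, 3), 0.278)
  expect_identical(res$rank, 6L)
  expect_true(res$ever_failed)
})

test_that("items that never failed get rank 2, not rank 1", {
  log <- make_flat_log(n_days = 360L)
  res <- occurrence_index(log, 1L, 360)
  expect_identical(res$rank, 2L)
  expect_false(res$ever_failed)
  expect_equal(res$quantity, 0)
  # an item with no records at all behaves the same way
  res2 <- occurrence_index(log, 3L, 360)
  expect_identical(res2$rank, 2L)
})

test_that("half the period out of tolerance gives 50% and rank 10", {
  log <- make_flat_log(n_days = 360L, oot_days = 0:179)
  res <- occurrence_index(log, 1L, 360)
  expect_equal(res$quantity, 50)
  expect_identical(res$rank, 10L)
})

test_that("a repair ends a failed state before the next clean measurement", {
  # out of tolerance on day 10, next measurement only on day 20, but the
  # item was repaired on day 13: days 10-12 count, not 10-19
  log <- rbind(make_flat_log(n_days = 1L),
               data.frame(date = epoch + c(10, 20), item_id = 1L,
                          measured_deviation = c(0.3, 0),
                          within_tolerance = c(FALSE, TRUE)))
  sv <- make_service_event(1L, onset_day = 10, found_day = 10,
                           repaired_day = 13)
  res <- occurrence_index(log, 1L, 30, service = sv)
  expect_equal(res$failed_days, 3L)
  expect_equal(res$quantity, 10)
})

test_that("occurrence matches a day-by-day oracle on random small logs", {
  set.seed(23)
  for (rep in 1:20) {
    n <- 60L
    n_oot <- sample(0:6, 1)
    oot <- sort(sample(0:(n - 1L), n_oot))
    # sprinkle some explicit clean measurements between failures
    clean <- sort(sample(setdiff(0:(n - 1L), oot),
                         sample(3:10, 1)))
    log <- data.frame(date = epoch + c(oot, clean), item_id = 1L,
                      measured_deviation = c(rep(0.3, length(oot)),
                                             rep(0.05, length(clean))),
                      within_tolerance = rep(c(FALSE, TRUE),
                                             c(length(oot), length(clean))))
    log <- log[order(log$date), ]
    res <- occurrence_index(log, 1L, n, period_start = epoch)
    expect_equal(res$failed_days,
                 oracle_occurrence_days(log, 1L, n, period_start = epoch),
                 info = paste("rep", rep))
  }
})

test_that("detection sums half-interval contributions of missed failures", {
  # last clean QC on day 100, failure found on day 106: 3 undetected days
  sv <- make_service_event(1L, onset_day = 100, found_day = 106,
                           repaired_day = 107)
  res <- detection_index(sv, 1L, 360)
  expect_equal(res$quantity, 3 / 360 * 100, tolerance = 1e-12)
  expect_equal(round(res$quantity, 3), 0.833)
  expect_identical(res$rank, 4L)

  # hand-enumerated multi-event scenario: (206-200)/2 + (64-50)/2 = 10 days;
  # the QC-found event contributes nothing
  sv3 <- rbind(
    make_service_event(1L, 200, 206, 210),
    make_service_event(1L, 50, 64, 70),
    make_service_event(1L, 300, 305, 306, found_by_qc = TRUE))
  res3 <- detection_index(sv3, 1L, 360)
  expect_equal(res3$quantity, 10 / 360 * 100, tolerance = 1e-12)
})

test_that("no service events and QC-found failures give rank 1", {
  expect_identical(detection_index(empty_service_log(), 1L, 360)$rank, 1L)
  sv <- make_service_event(1L, 10, 16, 17, found_by_qc = TRUE)
  res <- detection_index(sv, 1L, 360)
  expect_equal(res$quantity, 0)
  expect_identical(res$rank, 1L)
})

test_that("severity pools per-patient ranks as their arithmetic mean", {
  # PTV values chosen inside the rank-1 and rank-2 bands; cord negligible
  m <- make_dose_rows(ptv = c(0.5, 0.8, 0.9, 1.5))
  res <- severity_index(m, 1L, 7L)
  expect_equal(res$per_patient_ranks, c(1L, 1L, 1L, 2L))
  expect_equal(res$mean_rank, 1.25)

  single <- make_dose_rows(ptv = 0.5, cord = 30)
  res1 <- severity_index(single, 1L, 7L)
  expect_equal(res1$per_patient_ranks, 1L)
  expect_equal(res1$mean_rank, 1)
})

test_that("a cohort built to average 2.95 reproduces that mean rank", {
  # 20 patients: 1 in the rank-2 PTV band, 19 in the rank-3 band
  ptv <- c(1.5, seq(2.05, 2.95, length.out = 19))
  stopifnot(mean(c(2L, rep(3L, 19))) == 2.95)
  m <- make_dose_rows(ptv = ptv)
  res <- severity_index(m, 1L, 7L)
  expect_equal(res$mean_rank, 2.95)
})

test_that("severity aggregation and pooling modes behave as documented", {
  m <- make_dose_rows(ptv = c(0.5, 2.5), cord = c(100, 40))
  # ptv ranks 1,3; cord ranks 3,1; max-of-criteria 3,3
  expect_equal(severity_index(m, 1L, 7L)$mean_rank, 3)
  expect_equal(severity_index(m, 1L, 7L, aggregation = "ptv_only")$mean_rank,
               2)
  expect_equal(severity_index(m, 1L, 7L, aggregation = "cord_only")$mean_rank,
               2)
  # rank_of_means: mean ptv 1.5 (rank 2), mean cord 70 (rank 2) -> 2
  expect_equal(severity_index(m, 1L, 7L,
                              pooling = "rank_of_means")$mean_rank, 2)
  expect_error(severity_index(m, 1L, 60L), "no dose-metric records")
})

test_that("mean-of-ranks pooling lies within the per-patient rank range", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:15, 1)
    m <- make_dose_rows(ptv = stats::runif(n, 0, 30),
                        cord = stats::runif(n, 0, 1200))
    res <- severity_index(m, 1L, 7L)
    expect_gte(res$mean_rank, min(res$per_patient_ranks))
    expect_lte(res$mean_rank, max(res$per_patient_ranks))
  }
})

test_that("rank profiles round the mean severity per the configured mode", {
  expect_identical(rank_profile(1L, 7L, 2.950, 6L, 1L)$S, 3L)
  expect_identical(rank_profile(1L, 14L, 6.556, 2L, 1L,
                                rounding = "floor")$S, 6L)
  expect_identical(rank_profile(1L, 14L, 6.556, 2L, 1L)$S, 7L)
  expect_identical(rank_profile(1L, 14L, 6.556, 2L, 1L,
                                rounding = "ceiling")$S, 7L)
  for (r in c("nearest", "floor", "ceiling")) {
    expect_identical(rank_profile(1L, 1L, 1.0, 2L, 1L, rounding = r)$S, 1L)
  }
  # half away from zero, not banker's rounding
  expect_identical(rank_profile(1L, 7L, 2.5, 2L, 1L)$S, 3L)
  expect_warning(p <- rank_profile(1L, 7L, 0.2, 2L, 1L), "clamped")
  expect_identical(p$S, 1L)
})

test_that("rank profiles refuse mismatched items and bad ranks", {
  sv <- severity_index(make_dose_rows(item_id = 2L, ptv = 1), 2L, 7L)
  expect_error(rank_profile(1L, 7L, sv, 2L, 1L), "refer to item")
  expect_error(rank_profile(1L, 7L, 3, 0L, 1L), "1-10")
  expect_error(rank_profile(1L, 7L, 3, 2L, 11L), "1-10")
})
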