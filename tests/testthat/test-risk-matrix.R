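# Independent rule-table oracle, transcribed clause by clause from the
# band definitions: S=1 or O=1 are low except that O=1 with S of 9 or 10 is
# medium; for S 2-5 the medium band is O+S 9-10 and the high band 11-15;
# for S 6-10 the medium band is O+S 9-11 and the high band 12-20.
oracle_level <- function(s, o) {
  if (s == 1) return("low")
  if (o == 1) return(if (s %in% c(9, 10)) "medium" else "low")
  bands <- if (s <= 5) list(medium = 9:10, high = 11:15)
           else list(medium = 9:11, high = 12:20)
  if ((o + s) %in% bands$medium) return("medium")
  if ((o + s) %in% bands$high) return("high")
  "low"
}

test_that("quoted band-rule examples classify correctly", {
  expect_equal(as.character(classify_risk(1, 10)), "low")
  expect_equal(as.character(classify_risk(9, 1)), "medium")
  expect_equal(as.character(classify_risk(10, 1)), "medium")
  expect_equal(as.character(classify_risk(8, 1)), "low")
  expect_equal(as.character(classify_risk(3, 6)), "medium")
  expect_equal(as.character(classify_risk(8, 6)), "high")
  expect_equal(as.character(classify_risk(6, 2)), "low")
  expect_error(classify_risk(0, 5), "1-10")
  expect_error(classify_risk(5, 11), "1-10")
})

test_that("the 100-cell matrix matches the oracle and partitions 32/19/49", {
  m <- build_risk_matrix()
  expect_equal(dim(m), c(10L, 10L))
  for (s in 1:10) for (o in 1:10) {
    expect_equal(unclass(m)[o, s], oracle_level(s, o),
                 info = sprintf("S=%d O=%d", s, o))
  }
  counts <- table(factor(unclass(m), levels = c("low", "medium", "high")))
  expect_equal(unname(counts[["low"]]), 32L)
  expect_equal(unname(counts[["medium"]]), 19L)
  expect_equal(unname(counts[["high"]]), 49L)
  expect_equal(sum(counts), 100L)
  # the O=1 row: low up to S=8, medium for S 9-10
  expect_equal(unname(unclass(m)[1, ]),
               c(rep("low", 8), "medium", "medium"))
})

test_that("risk is monotone non-decreasing in S and in O", {
  m <- build_risk_matrix()
  ord <- c(low = 1L, medium = 2L, high = 3L)
  num <- matrix(ord[unclass(m)], nrow = 10)
  for (o in 1:10) expect_true(all(diff(num[o, ]) >= 0), info = paste("O", o))
  for (s in 1:10) expect_true(all(diff(num[, s]) >= 0), info = paste("S", s))
})

test_that("published per-item mean S traces give the published intervals", {
  cases <- list(
    list(s = c(1.200, 2.950, 4.350, 4.950, 5.800, 7.500), o = 6L, d = 7L),
    list(s = c(1.200, 2.950, 4.350, 4.950, 5.800, 7.500), o = 2L, d = 60L),
    list(s = c(1.125, 2.188, 3.938, 4.875, 5.688, 7.438), o = 2L, d = 60L),
    list(s = c(1.412, 3.647, 5.471, 5.941, 7.294, 8.647), o = 2L, d = 30L),
    list(s = c(1.615, 4.308, 6.462, 7.538, 8.308, 9.308), o = 2L, d = 21L))
  for (cs in cases) {
    rec <- recommend_frequency(1L, profiles_from_means(cs$s, cs$o))
    expect_identical(rec$recommended_interval_days, cs$d,
                     info = paste(cs$s, collapse = ","))
    expect_equal(rec$rule_applied, "first_medium")
  }
})

test_that("a low-low-medium-medium-high-high trace recommends the third
           interval and candidates exclude the high cells", {
  # S ranks chosen so that with O = 3 the trace is L L M M H H
  pr <- profiles_from_means(c(1, 5, 6, 7, 9, 10), 3L)
  rec <- recommend_frequency(1L, pr)
  expect_identical(rec$recommended_interval_days, 14L)
  expect_equal(rec$per_interval_levels$level,
               c("low", "low", "medium", "medium", "high", "high"))
  expect_equal(rec$candidates, c(1L, 7L, 14L, 21L))
})

test_that("fallback rules cover traces with no medium cell", {
  # all low: the longest interval wins
  rec <- recommend_frequency(1L, profiles_from_means(rep(1, 6), 1L))
  expect_identical(rec$recommended_interval_days, 60L)
  expect_equal(rec$rule_applied, "longest_all_low")

  # low straight to high: last interval before the first high
  pr <- profiles_from_means(c(2, 2, 2, 2, 10, 10), 5L)
  rec2 <- recommend_frequency(1L, pr)
  expect_equal(rec2$per_interval_levels$level[5], "high")
  expect_identical(rec2$recommended_interval_days, 21L)
  expect_equal(rec2$rule_applied, "last_before_high")

  # already high at the shortest interval: escalation needed
  expect_error(recommend_frequency(1L, profiles_from_means(rep(10, 6), 8L)),
               "escalation")
})

test_that("appending high intervals after the first medium changes nothing", {
  set.seed(47)
  base_grid <- interval_grid(c(1L, 7L, 14L, 21L))
  ext_grid <- interval_grid(c(1L, 7L, 14L, 21L, 30L, 60L))
  for (rep in 1:10) {
    o <- sample(2:6, 1)
    s <- sort(sample(1:7, 4, replace = TRUE))
    pr <- profiles_from_means(s, o, intervals = base_grid$interval_days)
    lev <- as.character(classify_risk(pr$S, pr$O))
    if (!"medium" %in% lev || "high" %in% lev) next
    rec <- recommend_frequency(1L, pr, grid = base_grid)
    # extend with two intervals forced into the high band
    s_hi <- rep(10, 2)
    pr_ext <- rbind(pr, profiles_from_means(s_hi, o,
                                            intervals = c(30L, 60L)))
    rec_ext <- recommend_frequency(1L, pr_ext, grid = ext_grid)
    expect_identical(rec_ext$recommended_interval_days,
                     rec$recommended_interval_days)
  }
})

test_that("recommendation input contracts are enforced", {
  pr <- profiles_from_means(c(1, 2, 3, 4, 5, 6), 2L)
  expect_error(recommend_frequency(1L, pr[-2, ]), "every grid interval")
  pr2 <- pr
  pr2$O[3] <- 5L
  expect_error(recommend_frequency(1L, pr2), "share one O rank")
  # non-monotone level sequences are scanned in order with a warning
  pr3 <- profiles_from_means(c(1, 7, 1, 7, 7, 7), 3L)
  expect_warning(rec <- recommend_frequency(1L, pr3), "not monotone")
  expect_identical(rec$recommended_interval_days, 7L)
})

test_that("risk maps render one grid per item", {
  pr1 <- profiles_from_means(c(1, 3, 4, 5, 6, 8), 6L, item_id = 1L)
  pr2 <- profiles_from_means(c(1, 3, 4, 5, 6, 8), 2L, item_id = 2L)
  recs <- list(recommend_frequency(1L, pr1), recommend_frequency(2L, pr2))
  txt <- render_rm_map(recs, draw = FALSE)
  expect_equal(sum(grepl("^QC item", txt)), 2L)
  expect_equal(sum(grepl("<-$", txt)), 2L)
  expect_error(render_rm_map(list()), "no recommendations")
})
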