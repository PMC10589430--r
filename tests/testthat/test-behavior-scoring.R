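test_that("daily performance is percent retrieved and validates counts", {
  rec <- behavior_record("A1", c(-2, -1, 2), c(10, 0, 20), c(20, 20, 20))
  dp <- daily_performance(rec)
  right <- dp$pct[dp$side == "right"]
  expect_equal(right, c(50, 0, 100))
  bad <- rec
  bad$pellets_retrieved[1] <- 25L
  expect_error(daily_performance(bad), "exceeds")
})

test_that("baseline normalization divides by the baseline-window mean", {
  # baseline days -3..-1 present, one day missing from the window
  rec <- behavior_record("A1", c(-3, -2, 2, 3),
                         paretic = c(12, 12, 6, 12),
                         nonparetic = c(12, 12, 12, 12))
  dp <- daily_performance(rec)
  norm <- baseline_normalize(dp, baseline_window = c(-3, -1))
  # baseline mean over the two available days = 60%; day 2 raw 30% -> 50
  r <- norm[norm$side == "right", ]
  expect_equal(r$pct_of_baseline[r$day == 2], 50)
  expect_equal(r$pct_of_baseline[r$day == 3], 100)
  base <- attr(norm, "baselines")
  expect_equal(base$baseline_pct[base$side == "right"], 60)

  # constant series normalizes to a constant 100
  cst <- behavior_record("A2", c(-3, -2, -1, 2, 5), rep(10, 5), rep(10, 5))
  nc <- baseline_normalize(daily_performance(cst), c(-3, -1))
  expect_true(all(nc$pct_of_baseline == 100))

  # zero baseline flags the animal unusable
  z <- behavior_record("A3", c(-2, -1, 2), c(0, 0, 5), c(10, 10, 10))
  nz <- baseline_normalize(daily_performance(z), c(-2, -1))
  expect_true("A3" %in% attr(nz, "unusable"))
  expect_equal(nrow(nz), 0L)
})

test_that("phase means average available days and ignore out-of-window rows", {
  df <- data.frame(animal_id = "A1", day = c(2, 3, 9, 12),
                   side = "right", pct_of_baseline = c(40, 60, 999, 70))
  pm <- phase_mean(df, c(2, 6))
  expect_equal(pm$mean_pct, 50)
  expect_equal(pm$n_days, 2L)
  # row order does not matter
  pm2 <- phase_mean(df[c(4, 3, 1, 2), ], c(2, 6))
  expect_equal(pm2$mean_pct, 50)
  # animal with no data in the window is flagged, not zero-filled
  pm3 <- phase_mean(df, c(4, 6))
  expect_identical(attr(pm3, "empty"), "A1")
  expect_equal(nrow(pm3), 0L)
})

test_that("severity grades follow the 20-point bins and are monotone", {
  expect_equal(severity_grade(100), 0)
  expect_equal(severity_grade(80), 0)
  expect_equal(severity_grade(79.9), 1)
  expect_equal(severity_grade(60), 1)
  expect_equal(severity_grade(59.9), 2)
  expect_equal(severity_grade(40), 2)
  expect_equal(severity_grade(20), 3)
  expect_equal(severity_grade(19.9), 4)
  expect_equal(severity_grade(0), 4)
  expect_equal(severity_grade(130), 0)   # above-baseline performance allowed

  # non-increasing in performance over a fine grid
  g <- severity_grade(seq(120, 0, by = -0.5))
  expect_true(all(diff(g) >= 0))

  expect_error(severity_grade(50, thresholds = c(80, 80, 40, 20)),
               "decreasing")
})

test_that("deficit summaries and the transition matrix count animals correctly", {
  # six animals with designed subacute/residual performance of the paretic paw
  design <- data.frame(
    id = paste0("A", 1:6),
    sub = c(10, 10, 30, 50, 70, 90),     # grades 4 4 3 2 1 0
    res = c(10, 50, 50, 90, 90, 90)      # grades 4 2 2 0 0 0
  )
  recs <- do.call(rbind, lapply(seq_len(6), function(i) {
    days <- c(-7:-1, 2:6, 12:21)
    pellets <- round(c(rep(20, 7), rep(design$sub[i] / 100 * 20, 5),
                       rep(design$res[i] / 100 * 20, 10)))
    behavior_record(design$id[i], days, pellets, rep(20, length(days)))
  }))
  summ <- summarize_deficits(recs, paretic_side = "right")
  expect_equal(nrow(summ), 6L)
  expect_equal(summ$subacute_grade, c(4, 4, 3, 2, 1, 0))
  expect_equal(summ$residual_grade, c(4, 2, 2, 0, 0, 0))
  expect_equal(summ$n_days_subacute, rep(5L, 6))
  expect_equal(summ$n_days_residual, rep(10L, 6))

  tm <- transition_matrix(summ)
  expect_equal(sum(tm), 6L)
  # hand-counted cells
  expect_equal(tm["4", "4"], 1L)
  expect_equal(tm["4", "2"], 1L)
  expect_equal(tm["3", "2"], 1L)
  expect_equal(tm["2", "0"], 1L)
  expect_equal(tm["1", "0"], 1L)
  expect_equal(tm["0", "0"], 1L)
  expect_equal(rowSums(tm), c(`0` = 1L, `1` = 1L, `2` = 1L, `3` = 1L,
                              `4` = 2L))

  # all animals in one cell
  one <- summ
  one$subacute_grade <- 4
  one$residual_grade <- 4
  tm1 <- transition_matrix(one)
  expect_equal(tm1["4", "4"], 6L)
  expect_equal(sum(tm1 != 0), 1L)
})
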