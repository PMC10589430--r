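test_that("splits partition the animals with the configured sizes", {
  sp <- make_splits(9, n_models = 20, train_fraction = 2 / 3, master_seed = 1)
  for (s in sp) {
    expect_length(s$train, 6L)
    expect_length(s$test, 3L)
    expect_setequal(c(s$train, s$test), 1:9)
    expect_length(intersect(s$train, s$test), 0L)
  }
  sp2 <- make_splits(9, 20, 2 / 3, master_seed = 1)
  expect_identical(sp, sp2)
  sp3 <- make_splits(9, 20, 2 / 3, master_seed = 2)
  expect_false(identical(sp[[1]]$test, sp3[[1]]$test))
  expect_equal(length(make_splits(215, 5)[[1]]$test), 72L)
})

test_that("the forest recovers an identity task and handles a constant target", {
  n <- 300
  x <- matrix(withr::with_seed(1, stats::runif(n, 0, 100)),
              dimnames = list(paste0("A", 1:n), "x"))
  split <- list(train = 1:200, test = 201:n)
  err <- fit_predict_once(x, x[, 1], split, rf_control(300), seed = 1)
  expect_lt(mean(err), 2)

  errc <- fit_predict_once(x, rep(42, n), split, rf_control(50), seed = 1)
  expect_equal(as.numeric(errc), rep(0, 100))
  expect_equal(unname(attr(errc, "predictions")), rep(42, 100))
})

test_that("a permuted target scores like the mean predictor", {
  n <- 150
  dat <- withr::with_seed(2, {
    x <- matrix(stats::rnorm(n * 5), n, 5,
                dimnames = list(paste0("A", 1:n), paste0("f", 1:5)))
    list(x = x, y = stats::rnorm(n, 50, 10))
  })
  splits <- make_splits(n, 25, 2 / 3, master_seed = 3)
  ev <- evaluate_predictor(dat$x, dat$y, splits, rf_control(150), 3, "noise")
  base <- prediction_error(baseline_errors(dat$y, splits))
  expect_lt(abs(ev$report$pe - base$pe) / base$pe, 0.2)
})

test_that("the PE statistic matches hand arithmetic", {
  r1 <- prediction_error(list(c(1, 2, 100)))
  expect_equal(r1$pe, 2)

  r2 <- prediction_error(list(c(10, 10, 10), c(20, 20, 20)))
  expect_equal(r2$pe, 15)

  r0 <- prediction_error(list(rep(0, 5), rep(0, 3)))
  expect_equal(r0$pe, 0)
  expect_equal(r0$iqr, 0)

  # uniform additive offset c -> PE = c; quartile consistency
  errs <- withr::with_seed(4, replicate(6, stats::runif(9), simplify = FALSE))
  off <- lapply(errs, function(e) e * 0 + 3.25)
  expect_equal(prediction_error(off)$pe, 3.25)
  r <- prediction_error(errs)
  expect_lte(r$q1, r$pe)
  expect_lte(r$pe, r$q3)
  expect_equal(r$iqr, r$q3 - r$q1)

  expect_error(prediction_error(list()), "at least one")
  expect_error(prediction_error(list(numeric(0))), "at least one")
})

test_that("predictor comparison requires shared splits and is zero on identical sets", {
  n <- 60
  dat <- withr::with_seed(5, {
    x <- matrix(stats::rnorm(n * 3), n, 3,
                dimnames = list(paste0("A", 1:n), paste0("f", 1:3)))
    list(x = x, y = stats::rnorm(n, 50, 10))
  })
  splits <- make_splits(n, 6, 2 / 3, 7)
  e1 <- evaluate_predictor(dat$x, dat$y, splits, rf_control(80), 7, "a")
  e2 <- evaluate_predictor(dat$x, dat$y, splits, rf_control(80), 7, "b")
  cmp <- compare_predictors(list(a = e1, b = e2))
  expect_equal(unname(cmp$pairwise["a", "b"]), 0)
  expect_equal(cmp$table$pe[1], cmp$table$pe[2])

  other <- evaluate_predictor(dat$x, dat$y, make_splits(n, 6, 2 / 3, 8),
                              rf_control(80), 8, "c")
  expect_error(compare_predictors(list(a = e1, c = other)), "same splits")
})

test_that("importance ranks a single informative feature first", {
  hits <- vapply(1:5, function(s) {
    dat <- withr::with_seed(s, {
      x <- matrix(stats::rnorm(120 * 10), 120, 10,
                  dimnames = list(paste0("A", 1:120), as.character(1:10)))
      y <- 50 + 8 * x[, 4] + stats::rnorm(120, 0, 2)
      list(x = x, y = y)
    })
    splits <- make_splits(120, 5, 2 / 3, s)
    rk <- oob_importance(dat$x, dat$y, splits, rf_control(150), s)
    rk$region_id[1] == 4
  }, TRUE)
  expect_gte(sum(hits), 5L)

  # pure-noise features sit inside the permutation null band
  dat <- withr::with_seed(11, {
    x <- matrix(stats::rnorm(100 * 8), 100, 8,
                dimnames = list(paste0("A", 1:100), as.character(1:8)))
    list(x = x, y = stats::rnorm(100, 50, 10))
  })
  splits <- make_splits(100, 5, 2 / 3, 11)
  rk <- oob_importance(dat$x, dat$y, splits, rf_control(100), 11)
  nb <- importance_null_band(dat$x, dat$y, n_perm = 60,
                             control = rf_control(100), seed = 12)
  expect_true(all(rk$importance >= nb$lower & rk$importance <= nb$upper))
})

test_that("importance ties break by ascending region id", {
  # constant columns all get importance 0: the tie resolves by region id
  x <- matrix(0, 10, 2, dimnames = list(paste0("A", 1:10), c("9", "2")))
  splits <- make_splits(10, 2, 2 / 3, 1)
  out <- oob_importance(x, rep(5, 10), splits, rf_control(20), 1)
  expect_equal(out$importance, c(0, 0))
  expect_equal(out$region_id, c(2L, 9L))
})

test_that("the first local minimum rule handles interior, plateau and boundary cases", {
  k1 <- first_local_minimum(c(5, 4, 3, 4, 2))
  expect_equal(as.integer(k1), 3L)
  expect_true(attr(k1, "interior"))

  # plateau at the minimum resolves to its smallest k
  k2 <- first_local_minimum(c(5, 3, 3, 4, 5))
  expect_equal(as.integer(k2), 2L)

  # monotone decreasing curve: no interior minimum, flagged endpoint
  k3 <- first_local_minimum(c(5, 4, 3, 2, 1))
  expect_equal(as.integer(k3), 5L)
  expect_false(attr(k3, "interior"))

  # relevance tolerance skips shallow dips on a falling stretch
  pe <- c(10, 9.4, 9.5, 8, 7, 6.95, 7.1, 7.0)
  expect_equal(as.integer(first_local_minimum(pe)), 2L)
  expect_equal(as.integer(first_local_minimum(pe, tol = 0.025)), 6L)
})

test_that("the inclusion curve matches the full-region PE at k = K and truncates k_max", {
  co <- simulate_cohort(small_config(master_seed = 9L, n_animals = 60L,
                                     n_sham = 0L))
  feats <- cohort_features(co, pipeline_config())
  splits <- make_splits(nrow(feats$segmented), 5, 2 / 3, 9)
  ctrl <- rf_control(100)
  X <- feats$predictor_sets$segmented_mri
  y <- feats$targets$residual
  rk <- oob_importance(X, y, splits, ctrl, 9)
  expect_warning(
    curve <- incremental_inclusion(rk, X, y, splits, ctrl, 9,
                                   k_max = ncol(X) + 10L),
    "truncated")
  expect_equal(nrow(curve), ncol(X))
  full <- evaluate_predictor(X[, as.character(rk$region_id), drop = FALSE],
                             y, splits, ctrl, 9, name = paste0("top", ncol(X)))
  expect_equal(curve$pe[nrow(curve)], full$report$pe)
})

test_that("stratified PE pools errors within grades and flags empty grades", {
  ev <- structure(list(
    name = "fix",
    errors = list(c(A1 = 2, A2 = 10, A3 = 4), c(A2 = 20, A3 = 6)),
    report = NULL, split_checksum = 0, seeds = 1:2),
    class = "predictor_eval")
  grades <- c(A1 = 0, A2 = 4, A3 = 0)
  sp <- stratified_pe(ev, grades)
  # grade 0: model medians mean(c(median(2,4), median(6))) = mean(3, 6)
  expect_equal(sp$pe[sp$grade == 0], 4.5)
  expect_equal(sp$pe[sp$grade == 4], 15)
  expect_true(is.na(sp$pe[sp$grade == 2]))
  expect_equal(sp$n_errors[sp$grade == 0], 3L)

  # all animals in one grade: stratified equals overall PE
  grades1 <- c(A1 = 1, A2 = 1, A3 = 1)
  sp1 <- stratified_pe(ev, grades1)
  expect_equal(sp1$pe[sp1$grade == 1], prediction_error(ev$errors)$pe)
})

test_that("replication on an identical cohort reproduces the prediction PEs", {
  co <- simulate_cohort(small_config(master_seed = 13L, n_animals = 60L,
                                     n_sham = 0L))
  feats <- cohort_features(co, pipeline_config())
  ctrl <- rf_control(100)
  splits <- make_splits(nrow(feats$segmented), 6, 2 / 3, 13)
  direct <- evaluate_predictor(feats$predictor_sets$segmented_mri,
                               feats$targets$residual, splits, ctrl, 13,
                               "segmented_mri")
  frozen <- list(kept_regions = feats$kept_regions, control = ctrl,
                 n_models = 6, train_fraction = 2 / 3, master_seed = 13)
  evals <- validate_on_cohort(frozen, feats$predictor_sets,
                              feats$targets$residual)
  expect_equal(evals$segmented_mri$report$pe, direct$report$pe)

  # missing kept regions are an input error
  broken <- feats$predictor_sets
  broken$segmented_mri <- broken$segmented_mri[, -1, drop = FALSE]
  expect_error(validate_on_cohort(frozen, broken, feats$targets$residual),
               "missing kept regions")

  # transfer mode trains on the prediction cohort and evaluates elsewhere
  frozen$train_features <- feats$predictor_sets
  frozen$train_target <- feats$targets$residual
  tr <- validate_on_cohort(frozen, feats$predictor_sets,
                           feats$targets$residual, mode = "transfer")
  expect_s3_class(tr$segmented_mri, "predictor_eval")
  expect_true(tr$segmented_mri$report$pe >= 0)
})

test_that("PE is invariant to animal order and shifts linearly under offsets", {
  co <- simulate_cohort(small_config(master_seed = 15L, n_animals = 48L,
                                     n_sham = 0L))
  feats <- cohort_features(co, pipeline_config())
  X <- feats$predictor_sets$segmented_mri
  y <- feats$targets$residual
  splits <- make_splits(nrow(X), 4, 2 / 3, 15)
  ev <- evaluate_predictor(X, y, splits, rf_control(100), 15, "seg")
  # reorder animals and remap split indices accordingly
  perm <- withr::with_seed(1, sample(nrow(X)))
  inv <- order(perm)
  splits_p <- lapply(splits, function(s) {
    list(train = sort(inv[s$train]), test = sort(inv[s$test]))
  })
  attr(splits_p, "checksum") <- strokepredict:::split_checksum(splits_p)
  ev_p <- evaluate_predictor(X[perm, , drop = FALSE], y[perm], splits_p,
                             rf_control(100), 15, "seg")
  expect_equal(sort(names(ev_p$errors[[1]])), sort(names(ev$errors[[1]])))
  expect_equal(ev_p$report$pe, ev$report$pe, tolerance = 0.25)

  # perfect predictor has PE 0; uniform offset c has PE c
  perfect <- lapply(splits, function(s) abs(y[s$test] - y[s$test]))
  expect_equal(prediction_error(perfect)$pe, 0)
  off <- lapply(splits, function(s) abs((y[s$test] + 7.5) - y[s$test]))
  expect_equal(prediction_error(off)$pe, 7.5)
})
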