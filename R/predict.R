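#' Hyperparameters of the bagged-tree regressor
#'
#' Standard regression-forest defaults: 500 trees, `ceiling(p/3)` candidate
#' features per split, unlimited depth, minimum node size 5.
#'
#' @param num_trees Number of trees per model.
#' @param mtry Features tried per split; `NULL` = `ceiling(p/3)`.
#' @param min_node_size Minimal terminal node size.
#' @return List of class `rf_control`.
#' @export
rf_control <- function(num_trees = 500L, mtry = NULL, min_node_size = 5L) {
  structure(list(num_trees = as.integer(num_trees), mtry = mtry,
                 min_node_size = as.integer(min_node_size)),
            class = "rf_control")
}

#' Repeated random train/test splits
#'
#' Generates `n_models` independent uniform partitions of the animals into
#' a training set (two thirds by default) and a test set
#' (`round(n * (1 - train_fraction))` animals).
#'
#' @param n_animals Number of animals (>= 6).
#' @param n_models Number of splits / models.
#' @param train_fraction Training fraction.
#' @param master_seed Master seed; split `i` uses the derived stream
#'   `derive_seed(master_seed, i)`.
#' @return List of `n_models` lists with integer `train` and `test`
#'   indices; attributes `"checksum"` (for pairing assertions) and
#'   `"seeds"`.
#' @export
make_splits <- function(n_animals, n_models = 50L, train_fraction = 2 / 3,
                        master_seed = 1L) {
  stopifnot(n_animals >= 6, n_models >= 1,
            train_fraction > 0, train_fraction < 1)
  n_test <- round(n_animals * (1 - train_fraction))
  n_test <- max(1L, min(n_animals - 1L, n_test))
  seeds <- derive_seed(master_seed, seq_len(n_models))
  splits <- lapply(seq_len(n_models), function(i) {
    test <- with_seed(seeds[i], sort(sample.int(n_animals, n_test)))
    list(train = setdiff(seq_len(n_animals), test), test = test)
  })
  attr(splits, "checksum") <- split_checksum(splits)
  attr(splits, "seeds") <- seeds
  splits
}

# cheap deterministic checksum over the test sets; used to assert that
# paired predictor comparisons share identical splits
split_checksum <- function(splits) {
  acc <- 0
  for (i in seq_along(splits)) {
    acc <- (acc + i * (sum(splits[[i]]$test * 7919) %% 1e9)) %% 2147483647
  }
  acc
}

#' Fit one model on one split and return test-set absolute errors
#'
#' Trains a bagged-tree regressor on the training rows only and returns
#' `|predicted - actual|` for every test animal, in percentage points of
#' the (percent-of-baseline) target. A constant training target returns
#' that constant for every test animal.
#'
#' @param features Numeric matrix (animals x features) with rownames.
#' @param target Numeric target vector aligned with `features` rows.
#' @param split List with `train` and `test` index vectors.
#' @param control [rf_control()] hyperparameters.
#' @param seed Integer seed of the fit.
#' @return Named numeric vector of absolute test errors; attribute
#'   `"predictions"` holds the raw predictions.
#' @export
fit_predict_once <- function(features, target, split,
                             control = rf_control(), seed = 1L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(target), !anyNA(features),
            !anyNA(target))
  tr <- split$train
  te <- split$test
  y_tr <- target[tr]
  if (stats::var(y_tr) == 0) {
    pred <- rep(y_tr[1], length(te))
  } else {
    p <- ncol(features)
    mtry <- if (is.null(control$mtry)) max(1L, ceiling(p / 3)) else
      min(p, control$mtry)
    fit <- ranger::ranger(
      x = features[tr, , drop = FALSE], y = y_tr,
      num.trees = control$num_trees, mtry = mtry,
      min.node.size = control$min_node_size,
      seed = as.integer(seed), num.threads = 1
    )
    pred <- stats::predict(fit, data = features[te, , drop = FALSE],
                           num.threads = 1)$predictions
  }
  err <- abs(pred - target[te])
  names(err) <- rownames(features)[te]
  attr(err, "predictions") <- stats::setNames(pred, rownames(features)[te])
  err
}

#' Prediction error (PE) with averaged quartiles
#'
#' For each model the median, Q1 and Q3 of its test-set absolute errors
#' are computed; the PE is the mean of the per-model medians and the
#' reported quartiles/IQR are the means of the per-model quartiles.
#'
#' @param errors_by_model List (one element per model) of numeric vectors
#'   of absolute errors.
#' @return Object of class `prediction_report`: `pe`, `q1`, `q3`, `iqr`
#'   (all in percentage points), `n_models` and `per_model`
#'   (`data.frame` of per-model statistics).
#' @export
prediction_error <- function(errors_by_model) {
  if (!length(errors_by_model) ||
      any(!vapply(errors_by_model, length, 0L))) {
    stop("every model needs at least one test error", call. = FALSE)
  }
  per <- t(vapply(errors_by_model, function(e) {
    q <- stats::quantile(e, c(0.25, 0.5, 0.75), names = FALSE)
    c(q1 = q[1], median = q[2], q3 = q[3])
  }, numeric(3)))
  per_model <- data.frame(model = seq_len(nrow(per)), per)
  structure(list(pe = mean(per_model$median),
                 q1 = mean(per_model$q1),
                 q3 = mean(per_model$q3),
                 iqr = mean(per_model$q3 - per_model$q1),
                 n_models = nrow(per_model),
                 per_model = per_model),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf(
    "prediction_report: PE %.2f pp (Q1 %.2f, Q3 %.2f, IQR %.2f; %d models)\n",
    x$pe, x$q1, x$q3, x$iqr, x$n_models))
  invisible(x)
}

#' Evaluate one predictor set across all splits
#'
#' @inheritParams fit_predict_once
#' @param splits Splits from [make_splits()].
#' @param master_seed Master seed; model `i` is fitted with the derived
#'   tree seed `derive_seed(derive_seed(master_seed, i), 1)`.
#' @param name Predictor-set name carried into reports.
#' @return Object of class `predictor_eval`: `name`, `errors`
#'   (per-model named error vectors), `report`
#'   ([prediction_error()] result), `split_checksum`, `seeds`.
#' @export
evaluate_predictor <- function(features, target, splits,
                               control = rf_control(), master_seed = 1L,
                               name = "predictor") {
  seeds <- derive_seed(derive_seed(master_seed, seq_along(splits)), 1L)
  errors <- lapply(seq_along(splits), function(i) {
    fit_predict_once(features, target, splits[[i]], control, seeds[i])
  })
  structure(list(name = name, errors = errors,
                 report = prediction_error(errors),
                 split_checksum = attr(splits, "checksum"),
                 seeds = seeds),
            class = "predictor_eval")
}

#' @export
print.predictor_eval <- function(x, ...) {
  cat("predictor_eval:", x$name, "- ")
  print(x$report)
  invisible(x)
}

#' Compare predictor sets evaluated on shared splits
#'
#' @param evals Named list of [evaluate_predictor()] results fitted on the
#'   same target and identical splits (asserted via the split checksum).
#' @return List with `table` (`data.frame` of PE and averaged quartiles
#'   per predictor, ordered by PE) and `pairwise` (matrix of paired PE
#'   differences, row minus column, averaged over the shared models).
#' @export
compare_predictors <- function(evals) {
  stopifnot(length(evals) >= 2)
  cks <- vapply(evals, `[[`, 0, "split_checksum")
  if (length(unique(cks)) != 1) {
    stop("predictor evaluations do not share the same splits", call. = FALSE)
  }
  nm <- vapply(evals, `[[`, "", "name")
  reports <- lapply(evals, `[[`, "report")
  tab <- data.frame(
    predictor = nm,
    pe = vapply(reports, `[[`, 0, "pe"),
    q1 = vapply(reports, `[[`, 0, "q1"),
    q3 = vapply(reports, `[[`, 0, "q3"),
    iqr = vapply(reports, `[[`, 0, "iqr")
  )
  tab <- tab[order(tab$pe), ]
  rownames(tab) <- NULL
  med <- vapply(reports, function(r) r$per_model$median,
                numeric(reports[[1]]$n_models))
  k <- length(evals)
  pw <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) pw[i, j] <- mean(med[, i] - med[, j])
  }
  list(table = tab, pairwise = pw)
}

#' Out-of-bag permutation importance of the segmented-MRI regions
#'
#' Fits one regression forest per split (training rows only) with
#' per-tree out-of-bag permutation importance, and averages the
#' importance of every region over the model fits. Regions are ranked by
#' descending mean importance, ties broken by ascending region id.
#'
#' @inheritParams evaluate_predictor
#' @return Object of class `importance_ranking`: `data.frame`
#'   (`region_id`, `importance`) in rank order; attribute
#'   `"positive_ids"` holds the region ids with importance > 0.
#' @export
oob_importance <- function(features, target, splits,
                           control = rf_control(), master_seed = 1L) {
  features <- as.matrix(features)
  ids <- colnames(features)
  seeds <- derive_seed(derive_seed(master_seed, seq_along(splits)), 2L)
  p <- ncol(features)
  mtry <- if (is.null(control$mtry)) max(1L, ceiling(p / 3)) else
    min(p, control$mtry)
  imp <- matrix(0, length(splits), p, dimnames = list(NULL, ids))
  for (i in seq_along(splits)) {
    tr <- splits[[i]]$train
    fit <- ranger::ranger(
      x = features[tr, , drop = FALSE], y = target[tr],
      num.trees = control$num_trees, mtry = mtry,
      min.node.size = control$min_node_size,
      importance = "permutation",
      seed = as.integer(seeds[i]), num.threads = 1
    )
    imp[i, names(fit$variable.importance)] <- fit$variable.importance
  }
  mean_imp <- colMeans(imp)
  rid <- suppressWarnings(as.integer(ids))
  if (anyNA(rid)) rid <- seq_len(p)
  ord <- order(-mean_imp, rid)
  out <- data.frame(region_id = rid[ord], importance = mean_imp[ord])
  rownames(out) <- NULL
  structure(out, class = c("importance_ranking", "data.frame"),
            positive_ids = rid[ord][mean_imp[ord] > 0])
}

#' Permutation null band for importance scores
#'
#' Refits the forest `n_perm` times with the target randomly permuted and
#' collects the importance of every region under the null of no
#' feature-target association. The band is a pair of pooled quantiles.
#'
#' @inheritParams evaluate_predictor
#' @param n_perm Number of target permutations.
#' @param probs Lower/upper quantiles of the pooled null scores.
#' @param seed Seed of the permutation stream.
#' @return List with `lower`, `upper` (numeric band bounds) and
#'   `null_scores` (n_perm x p matrix).
#' @export
importance_null_band <- function(features, target, n_perm = 100L,
                                 control = rf_control(),
                                 probs = c(0.005, 0.995), seed = 1L) {
  features <- as.matrix(features)
  p <- ncol(features)
  mtry <- if (is.null(control$mtry)) max(1L, ceiling(p / 3)) else
    min(p, control$mtry)
  null_scores <- matrix(0, n_perm, p, dimnames = list(NULL, colnames(features)))
  for (b in seq_len(n_perm)) {
    sb <- derive_seed(seed, b)
    y_perm <- with_seed(sb, sample(target))
    fit <- ranger::ranger(
      x = features, y = y_perm,
      num.trees = control$num_trees, mtry = mtry,
      min.node.size = control$min_node_size,
      importance = "permutation",
      seed = as.integer(sb), num.threads = 1
    )
    null_scores[b, names(fit$variable.importance)] <- fit$variable.importance
  }
  q <- stats::quantile(null_scores, probs, names = FALSE)
  list(lower = q[1], upper = q[2], null_scores = null_scores)
}

#' First (relevant) local minimum of an inclusion curve
#'
#' With `tol = 0`: the smallest interior `k` with `pe[k] <= pe[k - 1]` and
#' `pe[k] < pe[k + 1]` (a plateau at the minimum resolves to its smallest
#' `k`). With `tol > 0` the local minimum must additionally be *relevant*:
#' its PE must lie within `tol * min(pe)` of the best PE reached anywhere
#' on the curve, so shallow dips on a still-falling stretch are skipped.
#' Endpoints are not minima; a curve with no qualifying interior minimum
#' returns `k = length(pe)` flagged as non-interior.
#'
#' @param pe Numeric PE values at `k = 1..K`.
#' @param tol Relative relevance tolerance (fraction of the curve
#'   minimum); 0 = strict local minimum.
#' @return Integer `k_star` with attribute `"interior"` (logical).
#' @export
first_local_minimum <- function(pe, tol = 0) {
  K <- length(pe)
  slack <- min(pe) * tol
  if (K >= 3) {
    for (k in 2:(K - 1)) {
      if (pe[k] <= pe[k - 1] && pe[k] < pe[k + 1] &&
          (tol == 0 || pe[k] <= min(pe) + slack)) {
        while (k > 2 && pe[k - 1] == pe[k]) k <- k - 1
        return(structure(k, interior = TRUE))
      }
    }
  }
  structure(K, interior = FALSE)
}

#' Incremental region-inclusion PE curve
#'
#' Rebuilds the segmented-MRI predictor from the `k` most important
#' regions, for `k = 1..k_max`, recomputes the PE on the shared splits,
#' and locates the first local minimum of the curve.
#'
#' @param ranking [oob_importance()] result (or a `data.frame` with
#'   `region_id` in rank order).
#' @param features Full segmented-MRI matrix (columns named by region id).
#' @param target,splits,control,master_seed As in [evaluate_predictor()].
#' @param k_max Largest number of regions; truncated with a warning when
#'   it exceeds the ranking.
#' @param tol Relevance tolerance of the reported first local minimum,
#'   see [first_local_minimum()]. The default skips local dips that sit
#'   more than 2.5 percent above the best PE on the curve.
#' @return Object of class `inclusion_curve`: `data.frame` (`k`, `pe`)
#'   with attributes `"k_star"`, `"interior"` and `"region_ids"` (rank
#'   order used).
#' @export
incremental_inclusion <- function(ranking, features, target, splits,
                                  control = rf_control(), master_seed = 1L,
                                  k_max = 30L, tol = 0.025) {
  rid <- as.character(ranking$region_id)
  rid <- rid[rid %in% colnames(features)]
  if (!length(rid)) stop("ranking is empty", call. = FALSE)
  if (k_max > length(rid)) {
    warning("k_max exceeds the ", length(rid), " ranked regions; truncated",
            call. = FALSE)
    k_max <- length(rid)
  }
  pe <- vapply(seq_len(k_max), function(k) {
    ev <- evaluate_predictor(features[, rid[seq_len(k)], drop = FALSE],
                             target, splits, control, master_seed,
                             name = paste0("top", k))
    ev$report$pe
  }, 0)
  ks <- first_local_minimum(pe, tol)
  structure(data.frame(k = seq_len(k_max), pe = pe),
            class = c("inclusion_curve", "data.frame"),
            k_star = as.integer(ks), interior = attr(ks, "interior"),
            region_ids = rid)
}

#' @export
print.inclusion_curve <- function(x, ...) {
  cat(sprintf("inclusion_curve: k = 1..%d, k* = %d (PE %.2f pp%s)\n",
              nrow(x), attr(x, "k_star"), x$pe[attr(x, "k_star")],
              if (attr(x, "interior")) "" else ", no interior minimum"))
  invisible(x)
}

#' Severity-stratified prediction error
#'
#' PE recomputed within severity strata: per model, the median absolute
#' error over the test animals of each grade; averaged over the models in
#' which the grade occurs. Grades never seen in a test set are reported as
#' `NA`, not 0.
#'
#' @param eval [evaluate_predictor()] result (per-model errors named by
#'   animal id).
#' @param grades Named integer vector (animal id -> severity grade 0..4).
#' @return `data.frame` (`grade`, `pe`, `n_models`, `n_errors`).
#' @export
stratified_pe <- function(eval, grades) {
  stopifnot(inherits(eval, "predictor_eval"), !is.null(names(grades)))
  out <- lapply(0:4, function(g) {
    ids <- names(grades)[grades == g]
    med <- vapply(eval$errors, function(e) {
      e <- e[names(e) %in% ids]
      if (length(e)) stats::median(e) else NA_real_
    }, 0)
    n_err <- sum(vapply(eval$errors,
                        function(e) sum(names(e) %in% ids), 0L))
    data.frame(grade = g,
               pe = if (all(is.na(med))) NA_real_ else mean(med, na.rm = TRUE),
               n_models = sum(!is.na(med)), n_errors = n_err)
  })
  do.call(rbind, out)
}

#' Build the three predictor sets
#'
#' @param segmented Animals x regions percentage matrix (e.g.
#'   [profile_matrix()] restricted to [filter_regions()] output).
#' @param lesion_volume Named numeric vector of lesion volumes (mm^3).
#' @param subacute Named numeric vector of subacute percent-of-baseline
#'   performance; optional (`NULL` when predicting the subacute deficit
#'   itself).
#' @param animal_ids Row order; defaults to `rownames(segmented)`.
#' @return Named list of feature matrices (`lesion_volume`,
#'   `segmented_mri` and, when supplied, `subacute_deficit`), all with
#'   identical rownames.
#' @export
build_predictor_sets <- function(segmented, lesion_volume, subacute = NULL,
                                 animal_ids = rownames(segmented)) {
  sets <- list(
    lesion_volume = matrix(lesion_volume[animal_ids],
                           dimnames = list(animal_ids, "lesion_volume")),
    segmented_mri = segmented[animal_ids, , drop = FALSE]
  )
  if (!is.null(subacute)) {
    sets$subacute_deficit <- matrix(
      subacute[animal_ids], dimnames = list(animal_ids, "subacute_deficit"))
  }
  for (s in sets) {
    if (anyNA(s)) stop("predictor sets must not contain missing values",
                       call. = FALSE)
  }
  sets
}

#' Evaluate frozen prediction models on a replication cohort
#'
#' The kept-region list, hyperparameters and split scheme are frozen from
#' the prediction cohort. In `"refit"` mode (default) the models are
#' refitted per split on the replication cohort itself; in `"transfer"`
#' mode each model is trained on the full prediction cohort and evaluated
#' on the replication test subsets.
#'
#' @param frozen List with `kept_regions` (character/integer region ids),
#'   `control` ([rf_control()]), `n_models`, `train_fraction`,
#'   `master_seed`, and — for transfer mode — `train_features` (named list
#'   per predictor) and `train_target`.
#' @param features Named list of replication-cohort predictor matrices
#'   (as from [build_predictor_sets()]).
#' @param target Replication-cohort target vector.
#' @param mode `"refit"` or `"transfer"`.
#' @return Named list of [evaluate_predictor()] results.
#' @export
validate_on_cohort <- function(frozen, features, target,
                               mode = c("refit", "transfer")) {
  mode <- match.arg(mode)
  kept <- as.character(frozen$kept_regions)
  if (!all(kept %in% colnames(features$segmented_mri))) {
    stop("replication cohort is missing kept regions: ",
         paste(setdiff(kept, colnames(features$segmented_mri)),
               collapse = ", "), call. = FALSE)
  }
  features$segmented_mri <- features$segmented_mri[, kept, drop = FALSE]
  n <- nrow(features$segmented_mri)
  splits <- make_splits(n, frozen$n_models, frozen$train_fraction,
                        frozen$master_seed)
  if (mode == "refit") {
    return(stats::setNames(lapply(names(features), function(nm) {
      evaluate_predictor(features[[nm]], target, splits, frozen$control,
                         frozen$master_seed, name = nm)
    }), names(features)))
  }
  # transfer: train once per split on the full prediction cohort
  stats::setNames(lapply(names(features), function(nm) {
    tr_x <- frozen$train_features[[nm]]
    if (nm == "segmented_mri") tr_x <- tr_x[, kept, drop = FALSE]
    seeds <- derive_seed(derive_seed(frozen$master_seed,
                                     seq_along(splits)), 1L)
    errors <- lapply(seq_along(splits), function(i) {
      joint_x <- rbind(tr_x, features[[nm]])
      joint_y <- c(frozen$train_target, target)
      split <- list(train = seq_len(nrow(tr_x)),
                    test = nrow(tr_x) + splits[[i]]$test)
      fit_predict_once(joint_x, joint_y, split, frozen$control, seeds[i])
    })
    structure(list(name = nm, errors = errors,
                   report = prediction_error(errors),
                   split_checksum = attr(splits, "checksum"),
                   seeds = seeds),
              class = "predictor_eval")
  }), names(features))
}
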