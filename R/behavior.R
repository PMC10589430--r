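#' Per-day, per-side retrieval performance
#'
#' @param record Long-format staircase `data.frame` with columns
#'   `animal_id`, `day`, `side`, `pellets_retrieved`, `pellets_presented`.
#' @return `data.frame` (`animal_id`, `day`, `side`, `pct`) with the
#'   percentage of presented pellets retrieved; missing days stay absent.
#' @export
daily_performance <- function(record) {
  req <- c("animal_id", "day", "side", "pellets_retrieved",
           "pellets_presented")
  if (!all(req %in% names(record))) {
    stop("record must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(record$pellets_retrieved > record$pellets_presented)) {
    stop("pellets_retrieved exceeds pellets_presented", call. = FALSE)
  }
  if (any(record$pellets_presented <= 0)) {
    stop("pellets_presented must be positive", call. = FALSE)
  }
  data.frame(animal_id = record$animal_id, day = record$day,
             side = record$side,
             pct = 100 * record$pellets_retrieved / record$pellets_presented)
}

#' Normalize daily performance to the pre-stroke baseline
#'
#' Each animal's and side's performance is expressed as a percentage of its
#' mean performance over the baseline window (missing days within the
#' window are simply averaged over). Animals whose baseline window holds no
#' data, or whose baseline mean is 0, on any side are flagged unusable and
#' dropped from the output.
#'
#' @param daily Output of [daily_performance()].
#' @param baseline_window Closed integer day window, default `c(-7, -1)`.
#' @return `data.frame` (`animal_id`, `day`, `side`, `pct_of_baseline`)
#'   for post-baseline days, with attributes `"baselines"` (per
#'   animal/side baseline means) and `"unusable"` (flagged animal ids).
#' @export
baseline_normalize <- function(daily, baseline_window = c(-7, -1)) {
  in_base <- daily$day >= baseline_window[1] & daily$day <= baseline_window[2]
  key <- paste(daily$animal_id, daily$side, sep = "\r")
  base <- tapply(daily$pct[in_base], key[in_base], mean)
  parts <- strsplit(names(base), "\r", fixed = TRUE)
  baselines <- data.frame(
    animal_id = vapply(parts, `[`, "", 1),
    side = vapply(parts, `[`, "", 2),
    baseline_pct = as.numeric(base)
  )
  bad <- unique(c(
    setdiff(daily$animal_id, baselines$animal_id),
    baselines$animal_id[is.na(baselines$baseline_pct) |
                          baselines$baseline_pct <= 0]
  ))
  post <- daily[daily$day > baseline_window[2] & !daily$animal_id %in% bad, ]
  idx <- match(paste(post$animal_id, post$side),
               paste(baselines$animal_id, baselines$side))
  out <- data.frame(animal_id = post$animal_id, day = post$day,
                    side = post$side,
                    pct_of_baseline = 100 * post$pct /
                      baselines$baseline_pct[idx])
  attr(out, "baselines") <- baselines
  attr(out, "unusable") <- bad
  out
}

#' Mean performance over a phase window
#'
#' Arithmetic mean of the available days within a closed integer day
#' window, per animal and side.
#'
#' @param normalized Output of [baseline_normalize()] (or any data frame
#'   with `animal_id`, `day`, `side` and a value column).
#' @param window Closed integer window, e.g. `c(2, 6)` for the subacute
#'   phase or `c(12, 21)` for the residual phase.
#' @param value Name of the value column.
#' @return `data.frame` (`animal_id`, `side`, `mean_pct`, `n_days`);
#'   animals with no data in the window are absent (flagged via the
#'   `"empty"` attribute).
#' @export
phase_mean <- function(normalized, window, value = "pct_of_baseline") {
  inw <- normalized$day >= window[1] & normalized$day <= window[2]
  sub <- normalized[inw, ]
  if (!nrow(sub)) {
    out <- data.frame(animal_id = character(), side = character(),
                      mean_pct = numeric(), n_days = integer())
    attr(out, "empty") <- unique(normalized$animal_id)
    return(out)
  }
  key <- paste(sub$animal_id, sub$side, sep = "\r")
  m <- tapply(sub[[value]], key, mean)
  n <- tapply(sub[[value]], key, length)
  parts <- strsplit(names(m), "\r", fixed = TRUE)
  out <- data.frame(animal_id = vapply(parts, `[`, "", 1),
                    side = vapply(parts, `[`, "", 2),
                    mean_pct = as.numeric(m), n_days = as.integer(n))
  rownames(out) <- NULL
  attr(out, "empty") <- setdiff(unique(normalized$animal_id), out$animal_id)
  out[order(out$animal_id, out$side), ]
}

#' mRS-like severity grade from phase performance
#'
#' The deficit is `100 - phase_pct`, floored at 0; the grade counts how
#' many severity thresholds the deficit exceeds. With the default
#' performance thresholds (80, 60, 40, 20 percent of baseline) this yields
#' five 20-point bins: performance >= 80 -> grade 0, [60, 80) -> 1,
#' [40, 60) -> 2, [20, 40) -> 3, < 20 -> 4.
#'
#' @param phase_pct Numeric vector of phase-mean performance
#'   (percent of baseline).
#' @param thresholds Strictly decreasing length-4 vector of performance
#'   thresholds.
#' @return Integer grades 0..4.
#' @export
severity_grade <- function(phase_pct, thresholds = c(80, 60, 40, 20)) {
  if (length(thresholds) != 4 || any(diff(thresholds) >= 0)) {
    stop("thresholds must be 4 strictly decreasing values", call. = FALSE)
  }
  deficit <- pmax(0, 100 - phase_pct)
  deficit_cuts <- 100 - thresholds
  rowSums(outer(deficit, deficit_cuts, `>`))
}

#' Per-animal deficit summary
#'
#' Scores a cohort's staircase records end to end: daily performance,
#' baseline normalization, subacute and residual phase means for both
#' sides, and severity grades of the paretic side.
#'
#' @param record Long-format staircase records (several animals).
#' @param paretic_side Named character vector (animal id -> `"left"`/
#'   `"right"`), or a single value recycled to all animals.
#' @param baseline_window,subacute_window,residual_window Closed integer
#'   day windows.
#' @param thresholds Severity thresholds, see [severity_grade()].
#' @return `data.frame`, one row per usable animal: per-side baselines and
#'   phase means, `subacute_pct` / `residual_pct` (paretic side),
#'   `subacute_grade`, `residual_grade`, `n_days_subacute`,
#'   `n_days_residual`. Attribute `"excluded"` lists animals flagged
#'   unusable at any step.
#' @export
summarize_deficits <- function(record, paretic_side = "right",
                               baseline_window = c(-7, -1),
                               subacute_window = c(2, 6),
                               residual_window = c(12, 21),
                               thresholds = c(80, 60, 40, 20)) {
  daily <- daily_performance(record)
  norm <- baseline_normalize(daily, baseline_window)
  sub <- phase_mean(norm, subacute_window)
  res <- phase_mean(norm, residual_window)
  baselines <- attr(norm, "baselines")

  animals <- sort(unique(norm$animal_id))
  if (length(paretic_side) == 1 && is.null(names(paretic_side))) {
    paretic <- stats::setNames(rep(paretic_side, length(animals)), animals)
  } else {
    paretic <- paretic_side
  }

  pick <- function(df, id, side, col) {
    v <- df[[col]][df$animal_id == id & df$side == side]
    if (length(v)) v else NA_real_
  }
  rows <- lapply(animals, function(id) {
    ps <- paretic[[id]]
    if (is.null(ps) || is.na(ps)) {
      stop("no paretic side recorded for animal ", id, call. = FALSE)
    }
    ns <- setdiff(c("left", "right"), ps)
    data.frame(
      animal_id = id, paretic_side = ps,
      baseline_paretic = pick(baselines, id, ps, "baseline_pct"),
      baseline_nonparetic = pick(baselines, id, ns, "baseline_pct"),
      subacute_pct = pick(sub, id, ps, "mean_pct"),
      subacute_nonparetic_pct = pick(sub, id, ns, "mean_pct"),
      residual_pct = pick(res, id, ps, "mean_pct"),
      residual_nonparetic_pct = pick(res, id, ns, "mean_pct"),
      n_days_subacute = pick(sub, id, ps, "n_days"),
      n_days_residual = pick(res, id, ps, "n_days")
    )
  })
  out <- do.call(rbind, rows)
  usable <- !is.na(out$subacute_pct) & !is.na(out$residual_pct)
  excluded <- c(attr(norm, "unusable"), out$animal_id[!usable])
  out <- out[usable, ]
  out$subacute_grade <- severity_grade(out$subacute_pct, thresholds)
  out$residual_grade <- severity_grade(out$residual_pct, thresholds)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Recovery-transition matrix
#'
#' Cross-tabulates subacute vs residual severity grades: entry (i, j)
#' counts animals with subacute grade i and residual grade j (the data
#' behind a recovery chord diagram).
#'
#' @param summaries Output of [summarize_deficits()] (needs
#'   `subacute_grade`, `residual_grade`).
#' @return 5x5 integer matrix, rows = subacute grade 0..4, columns =
#'   residual grade 0..4.
#' @export
transition_matrix <- function(summaries) {
  if (any(is.na(summaries$subacute_grade)) ||
      any(is.na(summaries$residual_grade))) {
    stop("every animal needs both grades", call. = FALSE)
  }
  tab <- table(factor(summaries$subacute_grade, levels = 0:4),
               factor(summaries$residual_grade, levels = 0:4))
  m <- matrix(as.integer(tab), 5, 5,
              dimnames = list(subacute = 0:4, residual = 0:4))
  m
}
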