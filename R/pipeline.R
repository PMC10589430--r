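#' Pipeline configuration
#'
#' @param input_dir Cohort directory ([write_cohort()] layout), or `NULL`
#'   when an in-memory cohort is passed to [run_pipeline()].
#' @param out_dir Output directory.
#' @param master_seed Master seed of every stochastic stage.
#' @param n_models,train_fraction Split scheme, see [make_splits()].
#' @param num_trees,min_node_size Forest hyperparameters, see
#'   [rf_control()].
#' @param k_max Largest region count of the inclusion curve.
#' @param baseline_window,subacute_window,residual_window,thresholds
#'   Behavior-scoring settings, see [summarize_deficits()].
#' @param edema_correction `"hemisphere_ratio"` or `"none"`.
#' @param cohort_role `"prediction"` or `"replication"` (recorded in the
#'   report).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = "pipeline_out",
                            master_seed = 1L, n_models = 50L,
                            train_fraction = 2 / 3, num_trees = 500L,
                            min_node_size = 5L, k_max = 30L,
                            baseline_window = c(-7, -1),
                            subacute_window = c(2, 6),
                            residual_window = c(12, 21),
                            thresholds = c(80, 60, 40, 20),
                            edema_correction = "hemisphere_ratio",
                            cohort_role = "prediction") {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Quantify, score and assemble the model inputs of a cohort
#'
#' Runs the imaging and behavioral stages: per-animal region lesion
#' profiles, kept-region filter (regions lesioned in at least one MCAO
#' animal), deficit summaries and the target/feature alignment used by the
#' prediction stage. Animals excluded by behavior scoring are dropped from
#' the feature matrices.
#'
#' @param cohort An `mcao_cohort` or the list returned by [read_cohort()].
#' @param config A [pipeline_config()].
#' @return List with `profiles`, `kept_regions`, `segmented` (MCAO
#'   animals x kept regions), `volumes`, `summaries` (all animals),
#'   `mcao_summaries`, `predictor_sets`, `targets` (list with `subacute`,
#'   `residual`) and `incidence` ([incidence_map()] over MCAO animals).
#' @export
cohort_features <- function(cohort, config = pipeline_config()) {
  atlas <- cohort$atlas
  masks <- cohort$masks
  cov <- cohort$covariates
  profiles <- lapply(names(masks), function(id) {
    region_lesion_percentages(masks[[id]], atlas,
                              edema_correction = config$edema_correction)
  })
  names(profiles) <- names(masks)

  paretic <- stats::setNames(cov$paretic_side, cov$animal_id)
  summaries <- summarize_deficits(cohort$behavior, paretic,
                                  config$baseline_window,
                                  config$subacute_window,
                                  config$residual_window,
                                  config$thresholds)

  mcao_ids <- cov$animal_id[cov$group == "MCAO"]
  mcao_ids <- intersect(mcao_ids, summaries$animal_id)
  kept <- filter_regions(profiles[mcao_ids])
  segmented <- profile_matrix(profiles[mcao_ids], kept)
  volumes <- vapply(profiles[mcao_ids], `[[`, 0, "corrected_volume_mm3")
  names(volumes) <- mcao_ids
  ms <- summaries[match(mcao_ids, summaries$animal_id), ]
  subacute <- stats::setNames(ms$subacute_pct, mcao_ids)
  residual <- stats::setNames(ms$residual_pct, mcao_ids)

  list(profiles = profiles, kept_regions = kept, segmented = segmented,
       volumes = volumes, summaries = summaries, mcao_summaries = ms,
       predictor_sets = build_predictor_sets(segmented, volumes, subacute),
       targets = list(subacute = subacute, residual = residual),
       incidence = incidence_map(cohort$masks[mcao_ids]))
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

# md5 of the canonical JSON form of the analysis configuration
# (provenance); the output location does not influence results and is
# excluded, so reruns into different directories hash identically
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes quantify -> score -> predict -> select-regions -> report on a
#' cohort and writes every artifact (CSV/JSON/NIfTI) to
#' `config$out_dir`. Idempotent for a fixed configuration; the report
#' carries the configuration hash, master seed and package version.
#'
#' @param config A [pipeline_config()]; `config$input_dir` must point to a
#'   cohort directory unless `cohort` is given.
#' @param cohort Optional in-memory cohort (skips reading
#'   `config$input_dir`).
#' @return Invisibly, the report list (also written as `report.json` and
#'   `report.md`).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) {
    if (is.null(config$input_dir)) {
      stop("config$input_dir is NULL and no cohort was given", call. = FALSE)
    }
    cohort <- pipeline_stage("read", read_cohort(config$input_dir))
  }
  missing <- setdiff(cohort$covariates$animal_id, names(cohort$masks))
  if (length(missing)) {
    stop("pipeline stage 'read' failed: no lesion mask for animal(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  feats <- pipeline_stage("quantify", cohort_features(cohort, config))
  write_profiles(feats$profiles, file.path(out, "region_profiles.csv"))
  write_incidence_map(feats$incidence, file.path(out, "incidence_map.nii.gz"),
                      cohort$atlas$voxel_size_mm)
  utils::write.csv(data.frame(region_id = feats$kept_regions),
                   file.path(out, "kept_regions.csv"), row.names = FALSE)

  pipeline_stage("score", {
    utils::write.csv(feats$summaries, file.path(out, "deficit_summaries.csv"),
                     row.names = FALSE)
    tm <- transition_matrix(feats$mcao_summaries)
    utils::write.csv(as.data.frame(tm), file.path(out, "transition_matrix.csv"))
  })

  control <- rf_control(config$num_trees, min_node_size = config$min_node_size)
  n <- nrow(feats$segmented)
  splits <- make_splits(n, config$n_models, config$train_fraction,
                        config$master_seed)
  sets <- feats$predictor_sets

  evals <- pipeline_stage("predict", {
    res <- lapply(names(sets), function(nm) {
      evaluate_predictor(sets[[nm]], feats$targets$residual, splits, control,
                         config$master_seed, name = nm)
    })
    names(res) <- names(sets)
    sub <- lapply(c("lesion_volume", "segmented_mri"), function(nm) {
      evaluate_predictor(sets[[nm]], feats$targets$subacute, splits, control,
                         config$master_seed, name = nm)
    })
    names(sub) <- c("lesion_volume", "segmented_mri")
    list(residual = res, subacute = sub)
  })

  selection <- pipeline_stage("select-regions", {
    ranking <- oob_importance(sets$segmented_mri, feats$targets$residual,
                              splits, control, config$master_seed)
    curve <- incremental_inclusion(
      ranking, sets$segmented_mri, feats$targets$residual, splits, control,
      config$master_seed, k_max = min(config$k_max, length(feats$kept_regions)))
    utils::write.csv(as.data.frame(ranking),
                     file.path(out, "importance_ranking.csv"),
                     row.names = FALSE)
    cdf <- as.data.frame(curve)
    cdf$k_star <- attr(curve, "k_star")
    utils::write.csv(cdf, file.path(out, "inclusion_curve.csv"),
                     row.names = FALSE)
    list(ranking = ranking, curve = curve)
  })

  report <- pipeline_stage("report", {
    per_model <- do.call(rbind, lapply(names(evals), function(tg) {
      do.call(rbind, lapply(evals[[tg]], function(ev) {
        cbind(target = tg, predictor = ev$name, ev$report$per_model)
      }))
    }))
    utils::write.csv(per_model, file.path(out, "per_model_errors.csv"),
                     row.names = FALSE)
    grades <- stats::setNames(feats$mcao_summaries$residual_grade,
                              feats$mcao_summaries$animal_id)
    strat <- stratified_pe(evals$residual$segmented_mri, grades)
    rep <- list(
      package_version = as.character(utils::packageVersion("strokepredict")),
      config_hash = config_hash(config),
      master_seed = config$master_seed,
      cohort_role = config$cohort_role,
      n_animals = n,
      n_kept_regions = length(feats$kept_regions),
      pe = lapply(evals, function(tg) {
        lapply(tg, function(ev) ev$report[c("pe", "q1", "q3", "iqr")])
      }),
      stratified_pe_residual = strat,
      n_positive_importance = length(attr(selection$ranking, "positive_ids")),
      k_star = attr(selection$curve, "k_star"),
      k_star_interior = attr(selection$curve, "interior"),
      pe_at_k_star = selection$curve$pe[attr(selection$curve, "k_star")]
    )
    jsonlite::write_json(rep, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    md <- c(
      "# Outcome-prediction pipeline report", "",
      sprintf("- package version: %s", rep$package_version),
      sprintf("- config hash: %s (master seed %d, %s cohort)",
              rep$config_hash, rep$master_seed, rep$cohort_role),
      sprintf("- animals: %d; kept regions: %d", rep$n_animals,
              rep$n_kept_regions), "",
      "## Prediction error (pp)", "",
      unlist(lapply(names(evals), function(tg) {
        c(sprintf("### target: %s deficit", tg),
          vapply(evals[[tg]], function(ev) {
            sprintf("- %s: PE %.2f (Q1 %.2f, Q3 %.2f, IQR %.2f)",
                    ev$name, ev$report$pe, ev$report$q1, ev$report$q3,
                    ev$report$iqr)
          }, ""), "")
      })),
      sprintf("## Region selection"), "",
      sprintf("- regions with positive OOB importance: %d",
              rep$n_positive_importance),
      sprintf("- inclusion-curve first local minimum: k* = %d (PE %.2f pp%s)",
              rep$k_star, rep$pe_at_k_star,
              if (rep$k_star_interior) "" else "; no interior minimum"))
    writeLines(md, file.path(out, "report.md"))
    rep
  })
  invisible(report)
}
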