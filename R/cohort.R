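#' Configuration of a synthetic MCAO cohort
#'
#' Collects every parameter of the cohort generator. All randomness flows
#' from `master_seed`; per-animal streams are derived with [derive_seed()],
#' so the cohort is a pure function of its configuration.
#'
#' @param master_seed Integer master seed.
#' @param n_animals Number of MCAO animals.
#' @param n_sham Number of sham animals (appended after the MCAO animals).
#' @param occlusion_minutes Occlusion time(s) in minutes (30, 45 or 60);
#'   recycled over MCAO animals.
#' @param atlas_shape,voxel_size_mm,n_regions Toy-atlas geometry, see
#'   [build_toy_atlas()].
#' @param atlas_seed Seed of the atlas partition.
#' @param lesion_hemisphere Side of the occlusion; the paretic paw is the
#'   contralateral one.
#' @param informative_region_ids Region ids driving the deficit; `NULL`
#'   selects `n_informative` default regions (see
#'   [default_informative_regions()]; lesioned hemisphere).
#' @param n_informative Number of informative regions when
#'   `informative_region_ids` is `NULL`.
#' @param deficit_weights Non-negative weights, one per informative region
#'   (recycled). Default gives the striatal core double weight.
#' @param recovery_rate,residual_noise_sd,acute_noise_sd See
#'   [ground_truth_params()].
#' @param anisotropy_kappa Directional growth preference of the lesions,
#'   see [simulate_lesion()].
#' @param lesion_options Named list of further [simulate_lesion()]
#'   arguments (e.g. `shell_weight_open = 0` for strictly subcortical
#'   lesions); they override the defaults and `anisotropy_kappa`.
#' @param genotype_labels,surgeon_labels Covariate levels.
#' @param genotype_effect_sd SD (mm^3) of per-genotype additive lesion
#'   volume offsets.
#' @param surgeon_effect_mm3 Total additive lesion-volume spread between
#'   surgeons (mm^3); surgeons get equally spaced offsets centred on 0.
#' @param ... Further overrides passed to [ground_truth_params()].
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(master_seed = 1L,
                              n_animals = 215L,
                              n_sham = 15L,
                              occlusion_minutes = 45,
                              atlas_shape = c(32L, 32L, 32L),
                              voxel_size_mm = 0.2,
                              n_regions = 60L,
                              atlas_seed = 99L,
                              lesion_hemisphere = "left",
                              informative_region_ids = NULL,
                              n_informative = 14L,
                              deficit_weights = NULL,
                              recovery_rate = 0.15,
                              residual_noise_sd = 0.08,
                              acute_noise_sd = 0.35,
                              anisotropy_kappa = 3.5,
                              lesion_options = list(),
                              genotype_labels = c("WT", sprintf("G%02d", 1:14)),
                              surgeon_labels = c("S1", "S2"),
                              genotype_effect_sd = 2,
                              surgeon_effect_mm3 = 2,
                              ...) {
  stopifnot(n_animals >= 1, n_sham >= 0,
            all(occlusion_minutes %in% c(30, 45, 60)),
            recovery_rate > 0, residual_noise_sd >= 0, acute_noise_sd >= 0,
            genotype_effect_sd >= 0)
  cfg <- list(master_seed = as.integer(master_seed),
              n_animals = as.integer(n_animals),
              n_sham = as.integer(n_sham),
              occlusion_minutes = occlusion_minutes,
              atlas_shape = as.integer(atlas_shape),
              voxel_size_mm = voxel_size_mm,
              n_regions = as.integer(n_regions),
              atlas_seed = as.integer(atlas_seed),
              lesion_hemisphere = lesion_hemisphere,
              informative_region_ids = informative_region_ids,
              n_informative = as.integer(n_informative),
              deficit_weights = deficit_weights,
              recovery_rate = recovery_rate,
              residual_noise_sd = residual_noise_sd,
              acute_noise_sd = acute_noise_sd,
              anisotropy_kappa = anisotropy_kappa,
              lesion_options = lesion_options,
              genotype_labels = genotype_labels,
              surgeon_labels = surgeon_labels,
              genotype_effect_sd = genotype_effect_sd,
              surgeon_effect_mm3 = surgeon_effect_mm3,
              extra = list(...))
  class(cfg) <- "simulation_config"
  cfg
}

#' Default informative regions of a toy atlas
#'
#' Picks the deficit-driving regions of the lesioned hemisphere: the
#' peripheral deep regions (external-capsule-like structures at the edge
#' of the infarct core, whose involvement varies between animals) plus the
#' cortical-shell regions nearest the core. This yields a mixed
#' subcortical/cortical set, emulating the caudoputamen-border /
#' somatosensory-cortex / white-matter regions that carry outcome
#' information after MCAO.
#'
#' @param atlas Atlas from [build_toy_atlas()].
#' @param n Number of regions.
#' @param hemisphere Lesioned hemisphere.
#' @return Integer vector of region ids.
#' @export
default_informative_regions <- function(atlas, n = 14L,
                                        hemisphere = "left") {
  ont <- atlas$ontology
  hemi <- ont[ont$hemisphere == hemisphere, ]
  core_id <- attr(atlas, "core_regions")[[hemisphere]]
  d <- dim(atlas$labels)
  cen_of <- function(id) colMeans(arrayInd(which(atlas$labels == id), d))
  cens <- t(vapply(hemi$region_id, cen_of, numeric(3)))
  core_cen <- cens[match(core_id, hemi$region_id), ]
  dist2 <- rowSums(sweep(cens, 2, core_cen)^2)
  # peripheral deep regions first (the infarct-core centre is lesioned in
  # essentially every animal and thus carries little between-animal
  # information), then the shell regions nearest the core
  deep <- hemi$region_id[hemi$type == "deep"][order(-dist2[hemi$type == "deep"])]
  shell <- hemi$region_id[hemi$type == "shell"][order(dist2[hemi$type == "shell"])]
  n_deep <- min(length(deep), max(1L, round(n * 0.15)))
  sort(c(deep[seq_len(n_deep)], shell[seq_len(n - n_deep)]))
}

#' Simulate a full synthetic MCAO cohort
#'
#' Generates the atlas, per-animal covariates (genotype, surgeon,
#' occlusion time, paretic side), lesion masks, staircase behavior records
#' and the ground-truth table. Deterministic given the configuration.
#'
#' @param config A [simulation_config()].
#' @return Object of class `mcao_cohort`: list with `atlas`, `masks`
#'   (named list of [lesion_mask()]), `behavior` (long `data.frame`),
#'   `covariates` (`data.frame`), `ground_truth` (`data.frame` with latent
#'   severity, acute/residual deficits and the deterministic subacute /
#'   residual phase deficits, in fractions), `weights` (named informative
#'   region weights) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  cfg <- config
  atlas <- build_toy_atlas(cfg$n_regions, cfg$atlas_shape, cfg$voxel_size_mm,
                           seed = cfg$atlas_seed)
  inf_ids <- cfg$informative_region_ids
  if (is.null(inf_ids)) {
    inf_ids <- default_informative_regions(atlas, cfg$n_informative,
                                           cfg$lesion_hemisphere)
  }
  w <- cfg$deficit_weights
  if (is.null(w)) {
    # striatal core gets double weight, mirroring the outsized role of the
    # caudoputamen in MCAO outcome
    core_id <- attr(atlas, "core_regions")[[cfg$lesion_hemisphere]]
    w <- rep(1, length(inf_ids))
    w[inf_ids == core_id] <- 2
  } else {
    w <- rep_len(w, length(inf_ids))
  }
  stopifnot(all(w >= 0), all(inf_ids %in% atlas$ontology$region_id))
  names(w) <- as.character(inf_ids)

  params <- do.call(ground_truth_params,
                    c(list(weights = w,
                           recovery_rate = cfg$recovery_rate,
                           residual_noise_sd = cfg$residual_noise_sd,
                           acute_noise_sd = cfg$acute_noise_sd),
                      cfg$extra))

  n_total <- cfg$n_animals + cfg$n_sham
  ids <- sprintf("M%03d", seq_len(n_total))
  group <- c(rep("MCAO", cfg$n_animals), rep("sham", cfg$n_sham))
  occl <- rep(NA_real_, n_total)
  occl[group == "MCAO"] <- rep_len(cfg$occlusion_minutes, cfg$n_animals)
  paretic <- if (cfg$lesion_hemisphere == "left") "right" else "left"

  # covariate assignment and per-genotype volume offsets from dedicated
  # streams of the master seed
  cov_seed <- derive_seed(cfg$master_seed, 0L)
  assign <- with_seed(cov_seed, {
    list(genotype = sample(cfg$genotype_labels, n_total, replace = TRUE),
         surgeon = sample(cfg$surgeon_labels, n_total, replace = TRUE),
         genotype_offsets = stats::rnorm(length(cfg$genotype_labels), 0,
                                         cfg$genotype_effect_sd),
         severity = stats::runif(n_total))
  })
  names(assign$genotype_offsets) <- cfg$genotype_labels
  n_surg <- length(cfg$surgeon_labels)
  surgeon_offsets <- if (n_surg > 1) {
    (seq_len(n_surg) - (n_surg + 1) / 2) / (n_surg - 1) * cfg$surgeon_effect_mm3
  } else {
    0
  }
  names(surgeon_offsets) <- cfg$surgeon_labels

  covariates <- data.frame(
    animal_id = ids, group = group, genotype = assign$genotype,
    surgeon = assign$surgeon, occlusion_min = occl,
    paretic_side = paretic
  )

  nbr <- neighbour_table(dim(atlas$labels))
  masks <- vector("list", n_total)
  names(masks) <- ids
  behavior <- vector("list", n_total)
  truth <- vector("list", n_total)
  empty_mask <- lesion_mask(array(FALSE, dim(atlas$labels)))

  for (i in seq_len(n_total)) {
    sham <- group[i] == "sham"
    sev <- if (sham) 0 else assign$severity[i]
    offset <- surgeon_offsets[[assign$surgeon[i]]] +
      assign$genotype_offsets[[assign$genotype[i]]]
    masks[[i]] <- if (sham) {
      lesion_mask(empty_mask$mask, ids[i])
    } else {
      args <- list(atlas = atlas, occlusion_minutes = occl[i],
                   latent_severity = sev,
                   seed = derive_seed(cfg$master_seed, 2L * i),
                   hemisphere = cfg$lesion_hemisphere,
                   volume_offset_mm3 = offset,
                   anisotropy_kappa = cfg$anisotropy_kappa,
                   animal_id = ids[i], nbr = nbr)
      args[names(cfg$lesion_options)] <- cfg$lesion_options
      do.call(simulate_lesion, args)
    }
    prof <- region_lesion_percentages(masks[[i]], atlas)
    rec <- simulate_behavior(prof, params, is_sham = sham,
                             paretic_side = paretic,
                             seed = derive_seed(cfg$master_seed, 2L * i + 1L),
                             animal_id = ids[i])
    behavior[[i]] <- rec
    tr <- attr(rec, "truth")
    truth[[i]] <- data.frame(
      animal_id = ids[i], latent_severity = sev, damage = tr$damage,
      acute_deficit = tr$acute_deficit,
      residual_deficit = tr$residual_deficit,
      true_subacute_deficit = tr$true_subacute_deficit,
      true_residual_deficit = tr$true_residual_deficit
    )
  }

  structure(list(atlas = atlas, masks = masks,
                 behavior = do.call(rbind, behavior),
                 covariates = covariates,
                 ground_truth = do.call(rbind, truth),
                 weights = w, params = params, config = cfg),
            class = "mcao_cohort")
}

#' @export
print.mcao_cohort <- function(x, ...) {
  cat("mcao_cohort:", sum(x$covariates$group == "MCAO"), "MCAO +",
      sum(x$covariates$group == "sham"), "sham animals,",
      nrow(x$atlas$ontology), "atlas regions\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the deposit-style layout: atlas NIfTI + ontology CSV, one lesion
#' mask NIfTI per animal, behavior and covariate CSVs, ground-truth JSON
#' and a config echo JSON.
#'
#' @param cohort An `mcao_cohort`.
#' @param dir Output directory (created if missing).
#' @param gzip Write `.nii.gz` (default) or plain `.nii`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask_dir <- file.path(dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  write_atlas(cohort$atlas, file.path(dir, paste0("atlas", ext)),
              file.path(dir, "ontology.csv"))
  vox <- cohort$atlas$voxel_size_mm
  for (id in names(cohort$masks)) {
    img <- RNifti::asNifti(cohort$masks[[id]]$mask + 0L)
    RNifti::pixdim(img) <- rep_len(vox, 3L)
    RNifti::writeNifti(img, file.path(mask_dir, paste0(id, ext)))
  }
  utils::write.csv(cohort$behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(ground_truth = cohort$ground_truth,
         weights = as.list(cohort$weights)),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  cfg <- cohort$config
  cfg$informative_region_ids <- as.integer(names(cohort$weights))
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List with `atlas`, `masks`, `behavior`, `covariates` (ground
#'   truth, when present, under `ground_truth`).
#' @export
read_cohort <- function(dir) {
  label_path <- dir(dir, pattern = "^atlas\\.nii(\\.gz)?$", full.names = TRUE)
  atlas <- read_atlas(label_path[1], file.path(dir, "ontology.csv"))
  mask_files <- dir(file.path(dir, "masks"), pattern = "\\.nii(\\.gz)?$",
                    full.names = TRUE)
  masks <- lapply(mask_files, function(f) {
    id <- sub("\\.nii(\\.gz)?$", "", basename(f))
    img <- RNifti::readNifti(f)
    lesion_mask(array(as.vector(img) > 0.5, dim = dim(img)), id)
  })
  names(masks) <- vapply(masks, `[[`, "", "animal_id")
  out <- list(atlas = atlas, masks = masks,
              behavior = utils::read.csv(file.path(dir, "behavior.csv")),
              covariates = utils::read.csv(file.path(dir, "covariates.csv")))
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) out$ground_truth <- jsonlite::read_json(gt)
  out
}
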