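#' Per-region lesion percentages ("segmented MRI")
#'
#' Expresses the lesioned volume of every atlas region as a percentage of
#' that region's total volume. Counting is done in exact integer voxel
#' arithmetic before the division. Regions untouched by the lesion get 0.
#'
#' @param mask A [lesion_mask()].
#' @param atlas An [atlas_volume()] on the same grid.
#' @param edema_correction `"hemisphere_ratio"` (default) corrects the
#'   lesion volume by the contralateral/ipsilateral hemisphere volume
#'   ratio; `"none"` skips the correction.
#' @param tie_side Hemisphere assumed ipsilateral when a lesion straddles
#'   the midline exactly evenly.
#' @return Object of class `region_lesion_profile`: list with `animal_id`,
#'   `pct` (named numeric, one entry per ontology region, percent in
#'   `[0, 100]`), `lesion_volume_mm3` (lesion within atlas foreground) and
#'   `corrected_volume_mm3`.
#' @export
region_lesion_percentages <- function(mask, atlas,
                                      edema_correction = c("hemisphere_ratio",
                                                           "none"),
                                      tie_side = "left") {
  edema_correction <- match.arg(edema_correction)
  check_same_grid(mask, atlas)
  ids <- atlas$ontology$region_id
  nb <- max(ids)
  region_n <- tabulate(atlas$labels, nbins = nb)[ids]
  lesion_n <- tabulate(atlas$labels[mask$mask], nbins = nb)[ids]
  pct <- ifelse(region_n > 0L, 100 * lesion_n / region_n, 0)
  names(pct) <- as.character(ids)
  vol <- sum(lesion_n) * voxel_volume_mm3(atlas)
  corrected <- if (edema_correction == "none") {
    vol
  } else {
    edema_corrected_volume(mask, atlas, tie_side = tie_side)
  }
  structure(list(animal_id = mask$animal_id, pct = pct,
                 lesion_volume_mm3 = vol,
                 corrected_volume_mm3 = corrected),
            class = "region_lesion_profile")
}

#' @export
print.region_lesion_profile <- function(x, ...) {
  cat("region_lesion_profile:", x$animal_id, "-",
      sum(x$pct > 0), "regions lesioned,",
      signif(x$lesion_volume_mm3, 4), "mm^3 (corrected",
      paste0(signif(x$corrected_volume_mm3, 4), ")\n"))
  invisible(x)
}

#' Lesion volume within atlas coordinates
#'
#' Counts lesion voxels carrying a nonzero atlas label (lesion voxels
#' outside the atlas foreground are excluded) and converts to mm^3.
#'
#' @inheritParams region_lesion_percentages
#' @return Volume in mm^3.
#' @export
lesion_volume_in_atlas <- function(mask, atlas) {
  check_same_grid(mask, atlas)
  sum(atlas$labels[mask$mask] > 0L) * voxel_volume_mm3(atlas)
}

#' Edema-corrected lesion volume (hemisphere-ratio method)
#'
#' Scales the in-atlas lesion volume by the ratio of contralateral to
#' ipsilateral hemisphere foreground volume, compensating ipsilateral
#' swelling. The ipsilateral side is the hemisphere holding the majority of
#' lesion voxels; an exact tie is broken to `tie_side` with a warning.
#'
#' @inheritParams region_lesion_percentages
#' @return Corrected volume in mm^3 (0 for an empty lesion).
#' @export
edema_corrected_volume <- function(mask, atlas, tie_side = "left") {
  check_same_grid(mask, atlas)
  vol <- lesion_volume_in_atlas(mask, atlas)
  if (vol == 0) {
    return(0)
  }
  left <- hemisphere_slab(atlas, "left")
  n_left <- sum(mask$mask & left)
  n_right <- sum(mask$mask & !left)
  if (n_left == n_right) {
    warning("lesion straddles the midline with an exact tie; ",
            "ipsilateral side taken as ", tie_side, call. = FALSE)
    ipsi <- tie_side
  } else {
    ipsi <- if (n_left > n_right) "left" else "right"
  }
  hemi <- hemisphere_foreground(atlas)
  contra <- setdiff(c("left", "right"), ipsi)
  vol * hemi[[contra]] / hemi[[ipsi]]
}

#' Keep regions lesioned in at least one animal
#'
#' Dimensionality reduction of the segmented MRI: a region is retained iff
#' its lesion percentage is positive in at least one animal of the cohort.
#'
#' @param profiles List of [region_lesion_percentages()] profiles.
#' @return Integer vector of kept region ids, ascending.
#' @export
filter_regions <- function(profiles) {
  if (!length(profiles)) stop("need at least one profile", call. = FALSE)
  ids <- as.integer(names(profiles[[1]]$pct))
  mx <- Reduce(pmax, lapply(profiles, `[[`, "pct"))
  sort(ids[mx > 0])
}

#' Stack profiles into an animals x regions percentage matrix
#'
#' @param profiles List of `region_lesion_profile` objects.
#' @param region_ids Regions (columns) to keep, e.g. from
#'   [filter_regions()]; default all ontology regions.
#' @return Numeric matrix, rownames = animal ids, colnames = region ids.
#' @export
profile_matrix <- function(profiles, region_ids = NULL) {
  if (is.null(region_ids)) region_ids <- as.integer(names(profiles[[1]]$pct))
  m <- t(vapply(profiles,
                function(p) p$pct[as.character(region_ids)],
                numeric(length(region_ids))))
  rownames(m) <- vapply(profiles, `[[`, "", "animal_id")
  colnames(m) <- as.character(region_ids)
  m
}

#' Voxelwise lesion incidence map
#'
#' @param masks List of [lesion_mask()] objects on a shared grid.
#' @return Object of class `incidence_map`: list with `freq` (3D array of
#'   voxelwise lesion frequencies in `[0, 1]`) and `n_animals`.
#' @export
incidence_map <- function(masks) {
  if (!length(masks)) stop("need at least one mask", call. = FALSE)
  d <- dim(masks[[1]]$mask)
  acc <- array(0, dim = d)
  for (m in masks) {
    if (!identical(dim(m$mask), d)) {
      stop("masks are on different voxel grids", call. = FALSE)
    }
    acc <- acc + m$mask
  }
  structure(list(freq = acc / length(masks), n_animals = length(masks)),
            class = "incidence_map")
}

#' @export
print.incidence_map <- function(x, ...) {
  cat("incidence_map:", x$n_animals, "animals, max frequency",
      signif(max(x$freq), 3), "\n")
  invisible(x)
}

#' Individual deviation from the group-mean volume
#'
#' The heterogeneity statistic: each animal's absolute deviation from the
#' group mean, expressed in percent of that mean.
#'
#' @param volumes Numeric vector of lesion volumes (mm^3).
#' @return Numeric vector of deviations in percent.
#' @export
deviation_from_group_mean <- function(volumes) {
  if (!length(volumes)) stop("no volumes supplied", call. = FALSE)
  m <- mean(volumes)
  if (m <= 0) {
    stop("group mean volume must be positive", call. = FALSE)
  }
  100 * abs(volumes - m) / m
}

#' Write lesion profiles as a cohort CSV
#'
#' One row per animal: `animal_id`, `lesion_volume_mm3`,
#' `corrected_volume_mm3`, then one `region_<id>` percentage column per
#' ontology region.
#'
#' @param profiles List of `region_lesion_profile` objects.
#' @param path Output CSV path.
#' @export
write_profiles <- function(profiles, path) {
  m <- profile_matrix(profiles)
  df <- data.frame(
    animal_id = rownames(m),
    lesion_volume_mm3 = vapply(profiles, `[[`, 0, "lesion_volume_mm3"),
    corrected_volume_mm3 = vapply(profiles, `[[`, 0, "corrected_volume_mm3")
  )
  colnames(m) <- paste0("region_", colnames(m))
  utils::write.csv(cbind(df, m), path, row.names = FALSE)
  invisible(path)
}

#' Write an incidence map as NIfTI
#'
#' @param im An [incidence_map()].
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param voxel_size_mm Voxel size recorded in the header.
#' @export
write_incidence_map <- function(im, path, voxel_size_mm = 1) {
  img <- RNifti::asNifti(im$freq)
  RNifti::pixdim(img) <- rep_len(voxel_size_mm, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
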