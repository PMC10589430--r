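#' Lesion mask container
#'
#' A binary 3D mask on the same voxel grid as its atlas.
#'
#' @param mask 3D logical (or 0/1) array.
#' @param animal_id Animal identifier.
#' @return Object of class `lesion_mask`.
#' @export
lesion_mask <- function(mask, animal_id = "animal") {
  stopifnot(length(dim(mask)) == 3)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, animal_id = as.character(animal_id)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("lesion_mask:", x$animal_id, "-", sum(x$mask), "voxels lesioned\n")
  invisible(x)
}

check_same_grid <- function(mask, atlas) {
  if (!identical(dim(mask$mask), dim(atlas$labels))) {
    stop("lesion mask and atlas are on different voxel grids (",
         paste(dim(mask$mask), collapse = "x"), " vs ",
         paste(dim(atlas$labels), collapse = "x"), ")", call. = FALSE)
  }
}

# 6-connectivity neighbour lookup for a 3D grid: N x 6 integer matrix of
# linear indices, NA outside the grid. Built once per atlas and reused.
neighbour_table <- function(d) {
  n <- prod(d)
  co <- arrayInd(seq_len(n), d)
  shift <- function(axis, by) {
    cc <- co
    cc[, axis] <- cc[, axis] + by
    ok <- cc[, axis] >= 1L & cc[, axis] <= d[axis]
    out <- rep(NA_integer_, n)
    out[ok] <- cc[ok, 1] + (cc[ok, 2] - 1L) * d[1] +
      (cc[ok, 3] - 1L) * d[1] * d[2]
    out
  }
  cbind(shift(1L, -1L), shift(1L, 1L), shift(2L, -1L),
        shift(2L, 1L), shift(3L, -1L), shift(3L, 1L))
}

# Defaults of the lesion-size calibration: mean lesioned fraction of the
# ipsilateral hemisphere and coefficient of variation by occlusion time.
# Longer occlusions give larger and relatively more homogeneous lesions.
.LESION_SIZE_TABLE <- data.frame(
  occlusion_min = c(30, 45, 60),
  mean_fraction = c(0.15, 0.32, 0.50),
  cv = c(0.75, 0.50, 0.30)
)

lesion_size_params <- function(occlusion_minutes,
                               size_table = .LESION_SIZE_TABLE) {
  i <- match(occlusion_minutes, size_table$occlusion_min)
  if (is.na(i)) {
    stop("occlusion_minutes must be one of ",
         paste(size_table$occlusion_min, collapse = ", "), call. = FALSE)
  }
  size_table[i, ]
}

#' Simulate one MCAO-like lesion by stochastic region growing
#'
#' Grows a connected lesion from the striatal-core seed of one hemisphere by
#' weighted voxel accretion. Deep (striatum-like) voxels are strongly
#' preferred; cortical-shell voxels only become accessible once the lesion
#' exceeds a volume gate, so any lesion that touches cortex also carries
#' striatal damage (nested topology). The target lesion size is the quantile
#' of a lognormal size distribution at `latent_severity`, with occlusion-time
#' dependent mean and spread: longer occlusions produce larger lesions with
#' smaller relative spread.
#'
#' @param atlas Atlas from [build_toy_atlas()] (needs the `core_regions`
#'   attribute and the ontology `type` column).
#' @param occlusion_minutes One of 30, 45, 60.
#' @param latent_severity Severity quantile in `[0, 1]`; 0 gives an empty
#'   mask.
#' @param seed Integer seed for the growth randomness.
#' @param hemisphere `"left"` or `"right"`; side of the occlusion.
#' @param volume_offset_mm3 Additive covariate offset (surgeon/genotype) on
#'   the target volume, in mm^3.
#' @param animal_id Identifier stored in the returned mask.
#' @param shell_gate_fraction Lesion size (fraction of hemisphere
#'   foreground) above which the cortical shell becomes reachable.
#' @param shell_weight_closed,shell_weight_open Accretion weight of shell
#'   voxels below/above the gate (deep voxels have weight 1).
#' @param anisotropy_kappa Strength of the per-animal directional growth
#'   preference (0 = isotropic). Each animal draws a random preferred
#'   direction; voxel accretion is up-weighted along it, so lesions of
#'   equal volume differ in which regions they reach — the
#'   direction-dependent territory variability of the MCAO model.
#' @param size_table Calibration table (`occlusion_min`, `mean_fraction`,
#'   `cv`); override to change the size model.
#' @param nbr Optional precomputed [neighbour table][build_toy_atlas]
#'   (internal, reused across animals).
#' @return A [lesion_mask()].
#' @export
simulate_lesion <- function(atlas, occlusion_minutes = 45,
                            latent_severity = 0.5, seed = 1L,
                            hemisphere = c("left", "right"),
                            volume_offset_mm3 = 0,
                            animal_id = "animal",
                            shell_gate_fraction = 0.18,
                            shell_weight_closed = 0.03,
                            shell_weight_open = 0.6,
                            anisotropy_kappa = 3.5,
                            size_table = .LESION_SIZE_TABLE,
                            nbr = NULL) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(latent_severity >= 0, latent_severity <= 1)
  d <- dim(atlas$labels)
  mask <- array(FALSE, dim = d)
  if (latent_severity == 0) {
    return(lesion_mask(mask, animal_id))
  }

  sp <- lesion_size_params(occlusion_minutes, size_table)
  sdlog <- sqrt(log(1 + sp$cv^2))
  # lognormal with mean sp$mean_fraction; latent_severity is the quantile
  frac <- sp$mean_fraction *
    stats::qlnorm(latent_severity, meanlog = -sdlog^2 / 2, sdlog = sdlog)

  hemi_fg <- hemisphere_foreground(atlas)[[hemisphere]]
  vox_mm3 <- voxel_volume_mm3(atlas)
  n_target <- round(frac * hemi_fg + volume_offset_mm3 / vox_mm3)
  n_target <- as.integer(clamp(n_target, 0, floor(0.95 * hemi_fg)))
  if (n_target <= 0L) {
    return(lesion_mask(mask, animal_id))
  }

  side_ok <- hemisphere_slab(atlas, hemisphere)
  eligible <- atlas$labels > 0L & side_ok
  shell_ids <- atlas$ontology$region_id[atlas$ontology$type == "shell"]
  is_shell <- array(atlas$labels %in% shell_ids, dim = d)

  core_id <- attr(atlas, "core_regions")[[hemisphere]]
  core_vox <- which(atlas$labels == core_id)
  core_xyz <- arrayInd(core_vox, d)
  cen <- colMeans(core_xyz)
  seed_voxel <- core_vox[which.min(rowSums(sweep(core_xyz, 2, cen)^2))]

  gate <- shell_gate_fraction * hemi_fg
  if (is.null(nbr)) nbr <- neighbour_table(d)

  with_seed(seed, {
    # per-animal preferred growth direction (unit vector)
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    dir_weight <- function(vox) {
      if (anisotropy_kappa == 0) return(rep(1, length(vox)))
      xyz <- arrayInd(vox, d)
      v <- sweep(xyz, 2, cen)
      nv <- sqrt(rowSums(v^2))
      nv[nv == 0] <- 1
      exp(anisotropy_kappa * as.vector(v %*% u) / nv)
    }
    in_lesion <- logical(prod(d))
    in_frontier <- logical(prod(d))
    in_lesion[seed_voxel] <- TRUE
    size <- 1L
    nb <- nbr[seed_voxel, ]
    nb <- nb[!is.na(nb)]
    frontier <- nb[eligible[nb] & !in_lesion[nb]]
    in_frontier[frontier] <- TRUE
    while (size < n_target && length(frontier) > 0L) {
      shell_w <- if (size < gate) shell_weight_closed else shell_weight_open
      w <- ifelse(is_shell[frontier], shell_w, 1) * dir_weight(frontier)
      reachable <- which(w > 0)
      if (!length(reachable)) break  # nothing left (e.g. strictly subcortical)
      batch <- min(n_target - size, length(reachable),
                   max(1L, as.integer(ceiling(0.25 * length(frontier)))))
      pick <- if (length(reachable) == 1L) {
        frontier[reachable]
      } else {
        frontier[reachable[sample.int(length(reachable), batch,
                                      prob = w[reachable])]]
      }
      in_lesion[pick] <- TRUE
      in_frontier[pick] <- FALSE
      size <- size + length(pick)
      nb <- as.vector(nbr[pick, ])
      nb <- nb[!is.na(nb)]
      nb <- unique(nb[eligible[nb] & !in_lesion[nb] & !in_frontier[nb]])
      in_frontier[nb] <- TRUE
      frontier <- c(frontier[in_frontier[frontier]], nb)
    }
    mask[in_lesion] <- TRUE
  })
  lesion_mask(mask, animal_id)
}
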