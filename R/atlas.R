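#' Atlas volume container
#'
#' Bundles a 3D integer label image with its voxel size and region ontology.
#' Label 0 is background; every nonzero label must appear in the ontology.
#' The hemisphere split is a plane perpendicular to the first array axis:
#' voxel index `i <= midline_index` is the left hemisphere.
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @param voxel_size_mm Isotropic voxel edge length in mm, or a length-3
#'   numeric vector of per-axis sizes.
#' @param ontology `data.frame` with columns `region_id`, `acronym`, `name`,
#'   `hemisphere` (`"left"`/`"right"`) and optionally `type`
#'   (`"deep"`/`"shell"`).
#' @param midline_index Last voxel index (along the first axis) belonging to
#'   the left hemisphere. Defaults to `dim(labels)[1] / 2`.
#' @return An object of class `atlas_volume`.
#' @export
atlas_volume <- function(labels, voxel_size_mm, ontology,
                         midline_index = floor(dim(labels)[1] / 2)) {
  stopifnot(length(dim(labels)) == 3)
  if (!is.integer(labels)) {
    storage.mode(labels) <- "integer"
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (!length(voxel_size_mm) %in% c(1L, 3L) || any(voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be one or three positive numbers", call. = FALSE)
  }
  req <- c("region_id", "acronym", "name", "hemisphere")
  if (!all(req %in% names(ontology))) {
    stop("ontology must have columns region_id, acronym, name, hemisphere",
         call. = FALSE)
  }
  present <- sort(unique(labels[labels > 0L]))
  missing <- setdiff(present, ontology$region_id)
  if (length(missing)) {
    stop("labels contain region ids absent from the ontology: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(
    list(labels = labels,
         voxel_size_mm = voxel_size_mm,
         ontology = ontology[order(ontology$region_id), , drop = FALSE],
         midline_index = as.integer(midline_index)),
    class = "atlas_volume"
  )
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat("atlas_volume:", paste(dim(x$labels), collapse = " x "), "voxels,",
      nrow(x$ontology), "regions,",
      "voxel", paste(signif(x$voxel_size_mm, 3), collapse = "x"), "mm\n")
  invisible(x)
}

# volume of a single voxel in mm^3
voxel_volume_mm3 <- function(atlas) {
  prod(rep_len(atlas$voxel_size_mm, 3L))
}

#' Per-region voxel counts and volumes
#'
#' @param atlas An [atlas_volume()].
#' @return `data.frame` with `region_id`, `n_voxels`, `volume_mm3` for every
#'   ontology region (regions absent from the labels get 0).
#' @export
region_volumes <- function(atlas) {
  ids <- atlas$ontology$region_id
  counts <- tabulate(atlas$labels, nbins = max(ids))
  n <- counts[ids]
  data.frame(region_id = ids, n_voxels = n,
             volume_mm3 = n * voxel_volume_mm3(atlas))
}

# logical mask of left-hemisphere voxel positions
hemisphere_slab <- function(atlas, side = c("left", "right")) {
  side <- match.arg(side)
  d <- dim(atlas$labels)
  xs <- slice.index(atlas$labels, 1L)
  if (side == "left") xs <= atlas$midline_index else xs > atlas$midline_index
}

# foreground voxel counts per hemisphere
hemisphere_foreground <- function(atlas) {
  fg <- atlas$labels > 0L
  left <- hemisphere_slab(atlas, "left")
  c(left = sum(fg & left), right = sum(fg & !left))
}

#' Build a toy two-hemisphere brain atlas
#'
#' Constructs a mirror-symmetric ellipsoidal "brain" partitioned into
#' `n_regions` labelled regions, half per hemisphere. Each hemisphere has a
#' central set of deep, striatum-like regions and an outer shell of
#' cortex-like regions, emulating the nested subcortical-core /
#' cortical-shell topology of the transient MCAO lesion territory. The
#' region with the most central centroid in each hemisphere is designated
#' the striatal core (recorded in the `core_regions` attribute) and serves
#' as the seed for lesion growth.
#'
#' @param n_regions Even number of regions, at least 20.
#' @param atlas_shape Length-3 integer vector of array dimensions (each
#'   at least 16).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param seed Integer seed controlling the (deterministic) region
#'   partition.
#' @param deep_fraction Fraction of each hemisphere's regions placed in the
#'   deep compartment.
#' @return An [atlas_volume()]; attribute `core_regions` names the striatal
#'   core region id of each hemisphere.
#' @export
build_toy_atlas <- function(n_regions = 60L, atlas_shape = c(32L, 32L, 32L),
                            voxel_size_mm = 0.2, seed = 1L,
                            deep_fraction = 1 / 3) {
  n_regions <- as.integer(n_regions)
  atlas_shape <- as.integer(atlas_shape)
  if (n_regions < 20L || n_regions %% 2L != 0L) {
    stop("n_regions must be an even integer >= 20", call. = FALSE)
  }
  if (length(atlas_shape) != 3L || any(atlas_shape < 16L)) {
    stop("atlas_shape must be three integers, each >= 16", call. = FALSE)
  }
  d <- atlas_shape
  centre <- (d + 1) / 2
  semi <- 0.45 * d
  co <- arrayInd(seq_len(prod(d)), d)
  u2 <- ((co[, 1] - centre[1]) / semi[1])^2 +
    ((co[, 2] - centre[2]) / semi[2])^2 +
    ((co[, 3] - centre[3]) / semi[3])^2
  fg <- u2 <= 1
  deep <- fg & u2 <= 0.62^2          # central, striatum-like compartment
  mid <- floor(d[1] / 2)
  left <- co[, 1] <= mid

  n_half <- n_regions %/% 2L
  n_deep <- max(1L, round(deep_fraction * n_half))
  n_shell <- n_half - n_deep

  left_deep <- which(left & deep)
  left_shell <- which(left & fg & !deep)
  if (length(left_deep) < n_deep || length(left_shell) < n_shell) {
    stop("atlas_shape too small to place n_regions regions", call. = FALSE)
  }

  part <- function(voxels, k, km_seed) {
    # k-means on voxel coordinates gives compact, contiguous-ish parcels;
    # clusters are relabelled by centroid position for determinism
    xy <- co[voxels, , drop = FALSE]
    km <- with_seed(km_seed, stats::kmeans(xy, centers = k, nstart = 5,
                                           iter.max = 100))
    cen <- km$centers
    ord <- order(rowSums((cen - matrix(centre, k, 3, byrow = TRUE))^2),
                 cen[, 1], cen[, 2], cen[, 3])
    relab <- integer(k)
    relab[ord] <- seq_len(k)
    relab[km$cluster]
  }

  lab <- integer(prod(d))
  lab[left_deep] <- part(left_deep, n_deep, derive_seed(seed, 1L))
  lab[left_shell] <- n_deep + part(left_shell, n_shell, derive_seed(seed, 2L))

  # mirror the left hemisphere onto the right, offsetting the region ids
  lab3 <- array(lab, dim = d)
  mirror <- lab3[d[1]:1, , , drop = FALSE]
  right_side <- array(slice.index(lab3, 1L) > mid, dim = d)
  lab3[right_side & mirror > 0L] <- mirror[right_side & mirror > 0L] + n_half
  lab3[right_side & mirror == 0L] <- 0L

  type_half <- c(rep("deep", n_deep), rep("shell", n_shell))
  acro_half <- c(sprintf("STRd%02d", seq_len(n_deep)),
                 sprintf("CTX%02d", seq_len(n_shell)))
  ontology <- data.frame(
    region_id = seq_len(n_regions),
    acronym = c(paste0("L_", acro_half), paste0("R_", acro_half)),
    name = c(paste("left", type_half, "region", seq_len(n_half)),
             paste("right", type_half, "region", seq_len(n_half))),
    hemisphere = rep(c("left", "right"), each = n_half),
    type = rep(type_half, 2L)
  )
  atlas <- atlas_volume(lab3, voxel_size_mm, ontology, midline_index = mid)
  attr(atlas, "core_regions") <- c(left = 1L, right = n_half + 1L)
  atlas
}

#' Write / read an atlas as NIfTI + ontology CSV
#'
#' @param atlas An [atlas_volume()].
#' @param label_path Path of the NIfTI label image (`.nii` or `.nii.gz`).
#' @param ontology_path Path of the ontology CSV.
#' @return `write_atlas` returns the paths invisibly; `read_atlas` returns
#'   an [atlas_volume()].
#' @export
write_atlas <- function(atlas, label_path, ontology_path) {
  img <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(img) <- rep_len(atlas$voxel_size_mm, 3L)
  RNifti::writeNifti(img, label_path)
  utils::write.csv(atlas$ontology, ontology_path, row.names = FALSE)
  invisible(c(label_path, ontology_path))
}

#' @rdname write_atlas
#' @param midline_index See [atlas_volume()].
#' @export
read_atlas <- function(label_path, ontology_path, midline_index = NULL) {
  img <- RNifti::readNifti(label_path)
  labels <- array(as.integer(round(as.vector(img))), dim = dim(img))
  vox <- RNifti::pixdim(img)[seq_len(3L)]
  ontology <- utils::read.csv(ontology_path, stringsAsFactors = FALSE)
  if (is.null(midline_index)) midline_index <- floor(dim(labels)[1] / 2)
  atlas_volume(labels, vox, ontology, midline_index = midline_index)
}
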