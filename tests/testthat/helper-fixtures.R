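# Shared fixtures and independent brute-force oracles.

# Small toy atlas, built once per test session.
tiny_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_toy_atlas(20L, c(20L, 20L, 20L), 0.1,
                                                  seed = 7L)
    cache
  }
})

# Random label volume + random mask on a small grid (for oracle tests);
# labels 0..n_regions, mask independent Bernoulli.
random_instance <- function(seed, d = c(20L, 20L, 20L), n_regions = 6L,
                            p_mask = 0.3) {
  withr::with_seed(seed, {
    labels <- array(sample(0:n_regions, prod(d), replace = TRUE), dim = d)
    mask <- array(stats::runif(prod(d)) < p_mask, dim = d)
    ids <- sort(unique(labels[labels > 0]))
    ontology <- data.frame(region_id = ids,
                           acronym = paste0("R", ids),
                           name = paste("region", ids),
                           hemisphere = "left")
    list(atlas = atlas_volume(labels, 0.1, ontology),
         mask = lesion_mask(mask, paste0("A", seed)))
  })
}

# Brute-force per-region lesion voxel counts via explicit triple loops
# (independent of the vectorised implementation).
brute_region_counts <- function(mask, labels, ids) {
  d <- dim(labels)
  lesion <- stats::setNames(numeric(length(ids)), as.character(ids))
  total <- stats::setNames(numeric(length(ids)), as.character(ids))
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        lab <- labels[i, j, k]
        if (lab > 0) {
          key <- as.character(lab)
          total[key] <- total[key] + 1
          if (mask[i, j, k]) lesion[key] <- lesion[key] + 1
        }
      }
    }
  }
  list(lesion = lesion, total = total)
}

# Brute-force in-foreground lesion voxel count.
brute_inatlas_count <- function(mask, labels) {
  d <- dim(labels)
  n <- 0L
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        if (mask[i, j, k] && labels[i, j, k] > 0) n <- n + 1L
      }
    }
  }
  n
}

# A hand-buildable asymmetric two-region atlas: left slab fully labelled
# (n_left voxels), right slab partially labelled (n_right voxels).
asymmetric_atlas <- function(n_left = 1100L, n_right = 1000L) {
  d <- c(22L, 10L, 10L)
  labels <- array(0L, dim = d)
  labels[1:11, , ] <- 1L
  right <- which(slice.index(labels, 1) > 11)
  labels[right[seq_len(n_right)]] <- 2L
  ontology <- data.frame(region_id = 1:2, acronym = c("L", "R"),
                         name = c("left", "right"),
                         hemisphere = c("left", "right"))
  atlas_volume(labels, 0.1, ontology, midline_index = 11L)
}

# Long-format staircase record for one animal from per-day retrieval
# counts (20 pellets presented per side).
behavior_record <- function(animal_id, days, paretic, nonparetic,
                            paretic_side = "right") {
  other <- setdiff(c("left", "right"), paretic_side)
  rbind(
    data.frame(animal_id = animal_id, day = days, side = paretic_side,
               pellets_retrieved = paretic, pellets_presented = 20L),
    data.frame(animal_id = animal_id, day = days, side = other,
               pellets_retrieved = nonparetic, pellets_presented = 20L)
  )
}

# Small cohort configuration used by module-level tests (kept light; the
# acceptance suite exercises the full default size).
small_config <- function(master_seed = 1L, n_animals = 60L, n_sham = 6L, ...) {
  simulation_config(master_seed = master_seed, n_animals = n_animals,
                    n_sham = n_sham, ...)
}

# One reproducible uniform severity draw.
runif_severity <- function(seed) withr::with_seed(seed, stats::runif(1))

# Mean-predictor baseline errors on the same splits.
baseline_errors <- function(target, splits) {
  lapply(splits, function(s) {
    abs(target[s$test] - mean(target[s$train]))
  })
}
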