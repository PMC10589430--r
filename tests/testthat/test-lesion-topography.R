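test_that("region percentages, in-atlas volume and incidence match brute-force loops", {
  freq_acc <- NULL
  masks <- list()
  for (s in 1:8) {
    inst <- random_instance(s)
    ids <- inst$atlas$ontology$region_id
    oracle <- brute_region_counts(inst$mask$mask, inst$atlas$labels, ids)
    prof <- region_lesion_percentages(inst$mask, inst$atlas,
                                      edema_correction = "none")
    expect_equal(prof$pct,
                 100 * oracle$lesion / oracle$total[names(prof$pct)])
    n_in <- brute_inatlas_count(inst$mask$mask, inst$atlas$labels)
    expect_equal(lesion_volume_in_atlas(inst$mask, inst$atlas), n_in * 0.1^3)
    expect_equal(prof$lesion_volume_mm3, n_in * 0.1^3)
    masks[[s]] <- inst$mask
    freq_acc <- if (is.null(freq_acc)) inst$mask$mask + 0 else
      freq_acc + inst$mask$mask
  }
  im <- incidence_map(masks)
  expect_equal(im$freq, freq_acc / length(masks))
  expect_equal(im$n_animals, 8L)
})

test_that("profile conservation: region percentages reproduce the in-atlas volume", {
  a <- tiny_atlas()
  rv <- region_volumes(a)
  for (s in 1:10) {
    m <- simulate_lesion(a, 45, runif_severity(s), seed = 100 + s)
    prof <- region_lesion_percentages(m, a)
    reconstructed <- sum(prof$pct / 100 * rv$volume_mm3)
    expect_equal(reconstructed, prof$lesion_volume_mm3, tolerance = 1e-9)
  }
})

test_that("full, empty and monotone lesions behave as required", {
  a <- tiny_atlas()
  # mask covering one region entirely -> pct 100 there
  rid <- a$ontology$region_id[3]
  full <- lesion_mask(array(a$labels == rid, dim(a$labels)), "full")
  prof <- region_lesion_percentages(full, a)
  expect_equal(unname(prof$pct[as.character(rid)]), 100)

  empty <- lesion_mask(array(FALSE, dim(a$labels)), "empty")
  pe <- region_lesion_percentages(empty, a)
  expect_true(all(pe$pct == 0))
  expect_equal(pe$lesion_volume_mm3, 0)

  # adding lesion voxels never decreases any percentage or the volume
  m1 <- simulate_lesion(a, 30, 0.4, seed = 9L)
  grown <- m1$mask
  grown[which(!grown & a$labels > 0)[1:50]] <- TRUE
  p1 <- region_lesion_percentages(m1, a)
  p2 <- region_lesion_percentages(lesion_mask(grown, "grown"), a)
  expect_true(all(p2$pct >= p1$pct))
  expect_gte(p2$lesion_volume_mm3, p1$lesion_volume_mm3)

  # grid mismatch is an input error
  bad <- lesion_mask(array(FALSE, c(4, 4, 4)), "bad")
  expect_error(region_lesion_percentages(bad, a), "grids")
  expect_error(lesion_volume_in_atlas(bad, a), "grids")
})

test_that("edema correction applies the hemisphere volume ratio", {
  a <- asymmetric_atlas(n_left = 1100L, n_right = 1000L)
  mask <- array(FALSE, dim(a$labels))
  mask[2:6, 2:6, 2:6] <- TRUE          # 125 voxels, all left, all labelled
  m <- lesion_mask(mask, "A1")
  vol <- lesion_volume_in_atlas(m, a)
  expect_equal(vol, 125 * 0.1^3)
  # ipsilateral (left) 10% larger than contralateral -> divide by 1.1
  expect_equal(edema_corrected_volume(m, a), vol / 1.1)

  # symmetric toy atlas: correction is the identity
  b <- tiny_atlas()
  mb <- simulate_lesion(b, 45, 0.5, seed = 2L)
  expect_equal(edema_corrected_volume(mb, b), lesion_volume_in_atlas(mb, b))

  # empty lesion -> 0
  expect_equal(edema_corrected_volume(lesion_mask(array(FALSE, dim(a$labels))),
                                      a), 0)

  # exact midline tie -> warning, tie side used
  tie <- array(FALSE, dim(a$labels))
  tie[11, 2, 2] <- TRUE
  tie[12, 2, 2] <- TRUE
  expect_warning(edema_corrected_volume(lesion_mask(tie), a), "tie")
})

test_that("region filtering keeps exactly the regions lesioned somewhere", {
  a <- tiny_atlas()
  profs <- lapply(1:6, function(s) {
    region_lesion_percentages(simulate_lesion(a, 45, runif_severity(s),
                                              seed = 200 + s), a)
  })
  kept <- filter_regions(profs)
  mx <- Reduce(pmax, lapply(profs, `[[`, "pct"))
  expect_identical(kept, sort(as.integer(names(mx)[mx > 0])))
  expect_false(any(diff(kept) <= 0))
  # invariant to animal order
  expect_identical(filter_regions(rev(profs)), kept)

  # single animal with one lesioned region -> exactly that region
  rid <- a$ontology$region_id[5]
  one <- lesion_mask(array(a$labels == rid, dim(a$labels)), "one")
  expect_identical(filter_regions(list(region_lesion_percentages(one, a))),
                   rid)
})

test_that("deviation from the group mean is the absolute percent deviation", {
  expect_equal(deviation_from_group_mean(c(10, 10, 10)), c(0, 0, 0))
  expect_equal(deviation_from_group_mean(c(5, 15)), c(50, 50))
  expect_error(deviation_from_group_mean(c(0, 0)), "positive")
})

test_that("incidence map handles identical masks and grid mismatch", {
  a <- tiny_atlas()
  m <- simulate_lesion(a, 45, 0.5, seed = 4L)
  im <- incidence_map(list(m, m, m))
  expect_true(all(im$freq %in% c(0, 1)))
  m2 <- lesion_mask(array(FALSE, c(4, 4, 4)))
  expect_error(incidence_map(list(m, m2)), "grids")
})
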