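test_that("otsu separates two-level images and rejects constant ones", {
  x <- array(c(rep(20, 500), rep(200, 100)), c(6, 10, 10))
  t <- otsu_threshold(x)
  expect_gt(t, 20)
  expect_lt(t, 200)
  expect_error(otsu_threshold(array(7, c(2, 2, 2))), "constant")
})

test_that("absolute thresholding matches the generator mask exactly", {
  # constant-0 marker with absolute 10: empty mask (threshold outside range)
  s0 <- tiny_stack(array(0, c(3, 4, 4)))
  expect_warning(m0 <- threshold_marker(s0, "absolute", 10), "outside")
  expect_false(any(m0))
  # noiseless shell at 200 over background 20, absolute 100: mask voxel count
  # equals the ground-truth cytoplasm voxel count exactly
  syn <- generate_stack(one_cell_profile(radius = 5), c(24, 24, 24),
                        voxel_spacing(0.5, 0.5, 0.5))
  m <- threshold_marker(syn$stack, "absolute", 100)
  expect_equal(sum(m), sum(syn$label_mask$labels > 0L))
  expect_equal(attr(m, "threshold"), 100)
  expect_error(threshold_marker(syn$stack, "absolute"), "absolute_value")
})

test_that("connectivity semantics: diagonal contact merges only under 26", {
  m <- array(FALSE, c(2, 2, 2))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE
  sp <- voxel_spacing(1, 1, 1)
  expect_equal(max(label_components(m, 26L, sp)$labels), 1L)
  expect_equal(max(label_components(m, 6L, sp)$labels), 2L)
  # edge (not corner) contact merges under 18 but not 6
  m2 <- array(FALSE, c(2, 2, 1))
  m2[1, 1, 1] <- TRUE
  m2[2, 2, 1] <- TRUE
  expect_equal(max(label_components(m2, 18L, sp)$labels), 1L)
  expect_equal(max(label_components(m2, 6L, sp)$labels), 2L)
  # empty mask
  expect_equal(max(label_components(array(FALSE, c(3, 3, 3)), 26L, sp)$labels), 0L)
})

test_that("labeling agrees with the brute-force flood-fill oracle", {
  sp <- voxel_spacing(1, 1, 1)
  withr::with_seed(42, {
    for (i in 1:30) {
      d <- sample(2:6, 3, replace = TRUE)
      m <- array(runif(prod(d)) < 0.4, d)
      for (conn in c(6L, 26L)) {
        got <- label_components(m, conn, sp)$labels
        want <- oracle_labels(m, conn)
        expect_identical(canonical_labels(got), canonical_labels(want))
      }
    }
  })
})

test_that("component volumes are exact physical volumes with border flags", {
  sp <- voxel_spacing(0.5, 0.5, 0.5)
  lab <- array(0L, c(10, 10, 10))
  lab[2:6, 2:6, 3:6] <- 1L            # 100 voxels, interior
  lab[1, 9:10, 9:10] <- 2L            # touches the z = 1 face
  comps <- component_volumes(label_mask(lab, sp))
  expect_equal(comps$volume_um3[1], 12.5)     # 100 x 0.125
  expect_equal(comps$voxel_count[1], 100L)
  expect_false(comps$border_touching[1])
  expect_true(comps$border_touching[2])
  # conservation: total volume = positive voxels x voxel volume
  expect_equal(sum(comps$volume_um3), sum(lab > 0L) * voxel_volume(sp))
})

test_that("artifact cutoff is (1 + margin) x largest control object", {
  sp <- voxel_spacing(1, 1, 1)
  marker <- array(0, c(8, 12, 12))
  marker[2:3, 2:4, 2:3] <- 200        # 12 voxels -> 12.0 um^3
  marker[6, 8:9, 8:9] <- 200          # 4 voxels
  ctrl <- tiny_stack(marker, sp)
  expect_equal(estimate_artifact_cutoff(ctrl, "absolute", 110, margin = 0.10),
               13.2)
  expect_equal(estimate_artifact_cutoff(ctrl, "absolute", 110, margin = 0),
               12.0)
  # control with zero supra-threshold voxels: cutoff 0
  empty <- tiny_stack(array(5, c(4, 4, 4)), sp)
  expect_warning(c0 <- estimate_artifact_cutoff(empty, "absolute", 110))
  expect_equal(c0, 0)
})

test_that("remove_small_objects removes, relabels and conserves volume", {
  sp <- voxel_spacing(1, 1, 1)
  lab <- array(0L, c(6, 12, 12))
  lab[2:4, 2:5, 2:5] <- 1L            # 48 voxels
  lab[2, 8, 8] <- 2L                  # 1 voxel
  lab[5, 9:10, 9:10] <- 3L            # 4 voxels
  lm <- label_mask(lab, sp)
  # cutoff 0 is the identity
  id <- remove_small_objects(lm, 0)
  expect_identical(id$labels$labels, lm$labels)
  expect_equal(nrow(id$removed), 0L)
  # cutoff 5 removes the two small ones and relabels survivors 1..K'
  f <- remove_small_objects(lm, 5)
  expect_equal(sort(unique(as.vector(f$labels$labels))), c(0L, 1L))
  expect_equal(nrow(f$removed), 2L)
  expect_true(all(f$removed$cls == "REMOVED"))
  # conservation: retained + removed voxels = original positive voxels
  expect_equal(sum(f$labels$labels > 0L) + sum(f$removed$voxel_count),
               sum(lab > 0L))
  # cutoff above everything empties the mask
  all_gone <- remove_small_objects(lm, 1e9)
  expect_equal(max(all_gone$labels$labels), 0L)
})

test_that("nucleus exclusion is exact set subtraction", {
  a <- array(FALSE, c(2, 2, 2))
  b <- array(FALSE, c(2, 2, 2))
  a[1, 1, 1] <- TRUE; a[1, 2, 1] <- TRUE; a[2, 1, 1] <- TRUE; a[2, 2, 1] <- TRUE
  b[1, 1, 1] <- TRUE; b[2, 1, 1] <- TRUE
  out <- exclude_nucleus_voxels(a, b)
  expect_equal(sum(out), 2L)
  expect_true(out[1, 2, 1] && out[2, 2, 1])
  # disjoint masks leave the marker unchanged
  expect_identical(unname(exclude_nucleus_voxels(a, array(FALSE, c(2, 2, 2)))),
                   unname(a))
  # nucleus superset empties the result
  expect_false(any(exclude_nucleus_voxels(a, a)))
  expect_error(exclude_nucleus_voxels(a, array(FALSE, c(2, 2, 1))),
               "identical shape")
})

test_that("raising the absolute threshold never increases segmented volume", {
  withr::with_seed(31, {
    s <- tiny_stack(array(round(runif(4000, 0, 255)), c(10, 20, 20)))
  })
  vols <- vapply(c(20, 60, 100, 140, 180, 220), function(t) {
    sum(suppressWarnings(threshold_marker(s, "absolute", t)))
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("noiseless segmentation recovers per-cell volume exactly", {
  p <- synthetic_profile(n_cells = 4L, radius_mean = 4, radius_sd = 0.3,
                         noise_sd = 0, seed = 17L)
  sp <- voxel_spacing(0.5, 0.5, 0.5)
  syn <- generate_stack(p, c(30, 60, 60), sp)
  mask <- threshold_marker(syn$stack, "absolute", 110)
  labs <- label_components(mask, 26L, sp)
  comps <- component_volumes(labs)
  expect_equal(nrow(comps), 4L)
  # match each ground-truth cell to its component via a representative voxel
  for (i in syn$cells$cell_id) {
    vox <- which(syn$label_mask$labels == i)[1]
    got <- comps$volume_um3[comps$label == labs$labels[vox]]
    expect_equal(got, syn$cells$voxel_cytoplasm_volume[i])
  }
})
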