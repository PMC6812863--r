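test_that("shell volume closed form and radius calibration invert each other", {
  expect_equal(shell_volume_um3(6, 3), (4 / 3) * pi * (216 - 27))
  expect_equal(shell_volume_um3(6, 3), 791.68, tolerance = 1e-4)
  expect_error(shell_volume_um3(3, 6))
  # E[(4/3) pi (1 - f^3) r^3] with r ~ N(mu, sigma) equals the requested mean
  rr <- radius_for_mean_volume(1335, cv = 0.2, nucleus_fraction = 0.6)
  cc <- (4 / 3) * pi * (1 - 0.6^3)
  expect_equal(cc * (rr$radius_mean^3 + 3 * rr$radius_mean * rr$radius_sd^2),
               1335, tolerance = 1e-9)
  expect_equal(rr$radius_sd / rr$radius_mean, 0.2 / 3)
})

test_that("profile validation rejects inconsistent parameters", {
  expect_error(synthetic_profile(network_size_distribution = c("1" = 0.5)),
               "sum to 1")
  expect_error(synthetic_profile(network_size_distribution = c(a = 1)),
               "integer aggregate sizes")
  expect_error(synthetic_profile(nucleus_fraction = 1.2))
  # artifact separability: speckles must stay below the smallest cell volume
  expect_error(synthetic_profile(radius_mean = 2, radius_sd = 0,
                                 n_artifacts = 5L, artifact_radius_max = 1.9),
               "strictly below")
})

test_that("generation is bit-identical under a fixed seed", {
  p <- synthetic_profile(n_cells = 4L, radius_mean = 4, radius_sd = 0.3,
                         n_artifacts = 3L, noise_sd = 15, seed = 7L)
  sp <- voxel_spacing(0.5, 0.5, 0.5)
  a <- generate_stack(p, c(24, 80, 80), sp)
  b <- generate_stack(p, c(24, 80, 80), sp)
  expect_identical(a$stack$marker_channel, b$stack$marker_channel)
  expect_identical(a$stack$nucleus_channel, b$stack$nucleus_channel)
  expect_identical(a$cells, b$cells)
  expect_identical(a$label_mask$labels, b$label_mask$labels)
  ca <- generate_control_stack(p, c(24, 80, 80), sp)
  cb <- generate_control_stack(p, c(24, 80, 80), sp)
  expect_identical(ca$marker_channel, cb$marker_channel)
  # a different seed changes the render
  p2 <- synthetic_profile(n_cells = 4L, radius_mean = 4, radius_sd = 0.3,
                          n_artifacts = 3L, noise_sd = 15, seed = 8L)
  expect_false(identical(generate_stack(p2, c(24, 80, 80), sp)$stack$marker_channel,
                         a$stack$marker_channel))
})

test_that("nucleus voxels are never marker-positive in the noiseless render", {
  p <- synthetic_profile(n_cells = 5L, radius_mean = 4, radius_sd = 0.2,
                         noise_sd = 0, seed = 3L)
  syn <- generate_stack(p, c(30, 60, 60), voxel_spacing(0.5, 0.5, 0.5))
  fg <- p$foreground_level
  nuc_pos <- syn$stack$nucleus_channel == fg
  expect_gt(sum(nuc_pos), 0)
  expect_true(all(syn$stack$marker_channel[nuc_pos] == p$background_level))
  # and the ground-truth label mask never overlaps nuclei either
  expect_true(all(syn$label_mask$labels[nuc_pos] == 0L))
})

test_that("network members form one component; distinct aggregates never touch", {
  p <- synthetic_profile(n_cells = 10L, radius_mean = 4, radius_sd = 0.2,
                         network_size_distribution = c("1" = 0.25, "3" = 0.75),
                         protrusion_probability = 0.5, noise_sd = 0, seed = 21L)
  sp <- voxel_spacing(0.5, 0.5, 0.5)
  syn <- generate_stack(p, c(36, 100, 100), sp)
  cells <- syn$cells
  nets <- setdiff(unique(cells$network_id), 0L)
  expect_gt(length(nets), 0)
  for (nid in nets) {
    ids <- cells$cell_id[cells$network_id == nid]
    m <- array(syn$label_mask$labels %in% ids, dim(syn$label_mask$labels))
    lab <- label_components(m, 26L, sp)
    expect_equal(max(lab$labels), 1L)
  }
  # component count of the whole ground truth = #aggregates
  m_all <- syn$label_mask$labels > 0L
  lab_all <- label_components(m_all, 26L, sp)
  expect_equal(max(lab_all$labels), length(nets) + sum(cells$network_id == 0L))
})

test_that("voxelized shell volume converges to the closed form", {
  analytic <- shell_volume_um3(6, 3)
  errs <- vapply(c(0.8, 0.4, 0.2), function(h) {
    sp <- voxel_spacing(h, h, h)
    n <- ceiling(13.5 / h)
    syn <- generate_stack(one_cell_profile(radius = 6, nucleus_fraction = 0.5),
                          shape = rep(n, 3), spacing = sp)
    abs(syn$cells$voxel_cytoplasm_volume - analytic) / analytic
  }, numeric(1))
  expect_lt(errs[3], 0.02)
  expect_lt(errs[3], errs[1])
  # spec'd accuracy regime: radius >= 8 voxels, untruncated -> within 10%
  expect_true(all(errs < 0.10))
})

test_that("target volume fraction drives the realized cytoplasm budget", {
  p <- entity_preset("NScHL", seed = 4)
  sp <- study_spacing()
  syn <- generate_stack(p, c(study_Z, 160, 160), sp)
  realized <- 100 * sum(syn$cells$voxel_cytoplasm_volume) /
    stack_volume_um3(syn$stack)
  expect_gte(realized, 5.39)
  expect_lte(realized, 6.59)
})

test_that("entity presets encode the reported tissue values", {
  expect_equal(entity_preset("NScHL")$target_volume_fraction, 5.99)
  expect_equal(entity_preset("MCcHL_EBV")$cell_volume_mean_um3, 1335)
  expect_equal(entity_preset("LAD")$cell_volume_mean_um3, 464)
  expect_lt(profile_network_share(entity_preset("LAD")),
            profile_network_share(entity_preset("NScHL")))
  expect_equal(profile_network_share(entity_preset("NScHL")), 75)
  fr <- vapply(c("LAD", "AD", "NScHL", "MCcHL", "MCcHL_EBV"),
               function(e) entity_preset(e)$target_volume_fraction, numeric(1))
  expect_equal(unname(fr), c(1.51, 1.99, 5.99, 3.13, 2.23))
  expect_error(entity_preset("XYZ"))
})

test_that("control stacks contain exactly the artifacts and nothing else", {
  p <- synthetic_profile(n_cells = 5L, radius_mean = 5, radius_sd = 0.3,
                         n_artifacts = 20L, artifact_radius_max = 1.5,
                         noise_sd = 0, seed = 9L)
  sp <- voxel_spacing(0.5, 0.5, 0.5)
  ctrl <- generate_control_stack(p, c(30, 80, 80), sp)
  mask <- ctrl$marker_channel > p$background_level
  lab <- label_components(mask, 26L, sp)
  expect_equal(max(lab$labels), 20L)
  # no nuclei in a control
  expect_true(all(ctrl$nucleus_channel == p$background_level))
  # every artifact volume below the smallest cytoplasm volume of the profile
  arts <- attr(ctrl, "artifacts")
  vv <- voxel_volume(sp)
  r_min <- p$radius_mean - 2 * p$radius_sd
  expect_true(all(arts$voxel_count * vv <
                  shell_volume_um3(r_min, p$nucleus_fraction * r_min)))
  # with zero artifacts and zero noise the channel is flat background
  p0 <- synthetic_profile(n_cells = 1L, radius_mean = 5, n_artifacts = 0L,
                          noise_sd = 0, seed = 2L)
  c0 <- generate_control_stack(p0, c(16, 32, 32), sp)
  expect_equal(max(c0$marker_channel), p0$background_level)
})

test_that("truncated cells and multinucleated cells are rendered as requested", {
  p <- synthetic_profile(n_cells = 6L, radius_mean = 4, radius_sd = 0.2,
                         p_truncated = 0.5, noise_sd = 0, seed = 13L)
  sp <- voxel_spacing(0.5, 0.5, 0.5)
  syn <- generate_stack(p, c(30, 70, 70), sp)
  expect_equal(sum(syn$cells$truncated), 3L)
  d <- dim(syn$label_mask$labels)
  for (i in syn$cells$cell_id[syn$cells$truncated]) {
    m <- syn$label_mask$labels == i
    on_face <- any(m[1, , ]) || any(m[d[1], , ]) || any(m[, 1, ]) ||
      any(m[, d[2], ]) || any(m[, , 1]) || any(m[, , d[3]])
    expect_true(on_face)
  }
  # nuclei_per_cell = 2 renders two DAPI blobs per cell
  p2 <- synthetic_profile(n_cells = 3L, radius_mean = 5, radius_sd = 0,
                          nuclei_per_cell = 2L, noise_sd = 0, seed = 5L)
  syn2 <- generate_stack(p2, c(30, 60, 60), sp)
  nmask <- syn2$stack$nucleus_channel == p2$foreground_level
  lab <- label_components(nmask, 26L, sp)
  expect_equal(max(lab$labels), 6L)
})

test_that("stacks too small for the cells are rejected, not silently clipped", {
  p <- one_cell_profile(radius = 6)
  expect_error(generate_stack(p, c(8, 8, 8), voxel_spacing(0.5, 0.5, 0.5)),
               "too small")
})
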