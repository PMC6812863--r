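test_that("voxel spacing and volumes are exact physical quantities", {
  sp <- voxel_spacing(0.36, 0.37, 0.13)
  expect_equal(voxel_volume(sp), 0.36 * 0.37 * 0.13)
  expect_equal(voxel_volume(sp), 0.017316, tolerance = 1e-6)
  expect_error(voxel_spacing(0, 1, 1), "strictly positive")
  expect_error(voxel_spacing(1, -1, 1), "strictly positive")
  expect_error(voxel_spacing(1, 1, Inf), "strictly positive")
  ds <- default_spacing()
  expect_equal(ds$dx, 365 / 1024)
  expect_equal(ds$dy, 375 / 1024)
  expect_equal(ds$dz, 0.13)
})

test_that("image_stack validates geometry and intensities", {
  a <- array(1, c(2, 3, 4))
  sp <- voxel_spacing(1, 1, 1)
  s <- image_stack(a, a, sp, name = "s")
  expect_s3_class(s, "image_stack")
  expect_equal(stack_volume_um3(s), 24)
  expect_error(image_stack(a, array(1, c(2, 3, 5)), sp), "identical shape")
  expect_error(image_stack(matrix(1, 2, 2), a, sp), "3D array")
  b <- a; b[1] <- -1
  expect_error(image_stack(b, a, sp), ">= 0")
  b <- a; b[1] <- NA
  expect_error(image_stack(b, a, sp), "finite")
})

test_that("stack round-trips through TIFF + sidecar voxel-identically", {
  withr::with_seed(11, {
    nuc <- array(sample(0:500, 4 * 16 * 16, replace = TRUE), c(4, 16, 16))
    mrk <- array(sample(0:500, 4 * 16 * 16, replace = TRUE), c(4, 16, 16))
  })
  sp <- voxel_spacing(0.357, 0.366, 0.13)
  s <- image_stack(nuc, mrk, sp, name = "rt")
  path <- file.path(withr::local_tempdir(), "rt.tif")
  write_stack(s, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  r <- read_stack(path)
  expect_identical(dim(r$marker_channel), dim(mrk))
  expect_true(all(r$nucleus_channel == nuc))
  expect_true(all(r$marker_channel == mrk))
  # spacing survives to at least 6 significant digits
  expect_equal(r$spacing$dx, 0.357, tolerance = 1e-7)
  expect_equal(r$spacing$dy, 0.366, tolerance = 1e-7)
  expect_equal(r$spacing$dz, 0.13, tolerance = 1e-7)
  expect_equal(r$name, "rt")
  expect_equal(stack_volume_um3(r), prod(dim(mrk)) * voxel_volume(sp))
})

test_that("read_stack fails loudly on bad inputs", {
  td <- withr::local_tempdir()
  expect_error(read_stack(file.path(td, "missing.tif")), "no such file")
  # a TIFF with no sidecar and no override: spacing must not be defaulted
  p <- file.path(td, "bare.tif")
  tiff::writeTIFF(list(matrix(0.1, 8, 8), matrix(0.2, 8, 8)), p,
                  bits.per.sample = 16L)
  expect_error(read_stack(p), "spacing")
  # channel_map must name both roles
  expect_error(read_stack(p, channel_map = c(marker = 1)), "nucleus")
  # page count not divisible by the channel count
  p3 <- file.path(td, "odd.tif")
  tiff::writeTIFF(list(matrix(0, 4, 4), matrix(0, 4, 4), matrix(0, 4, 4)),
                  p3, bits.per.sample = 16L)
  expect_error(read_stack(p3, spacing = voxel_spacing(1, 1, 1)),
               "not a multiple")
})

test_that("spacing override wins over file metadata, with a >1% warning", {
  s <- tiny_stack(array(5, c(2, 4, 4)), voxel_spacing(0.5, 0.5, 0.5))
  path <- file.path(withr::local_tempdir(), "ov.tif")
  write_stack(s, path)
  ov <- voxel_spacing(1, 1, 1)
  expect_warning(r <- read_stack(path, spacing = ov), "disagrees")
  expect_equal(r$spacing$dx, 1)
  # within 1% there is no warning
  ov2 <- voxel_spacing(0.5005, 0.5, 0.5)
  expect_no_warning(r2 <- read_stack(path, spacing = ov2))
  expect_equal(r2$spacing$dx, 0.5005)
})

test_that("write_stack rejects out-of-range and rounds non-integer intensities", {
  td <- withr::local_tempdir()
  s <- tiny_stack(array(70000, c(1, 2, 2)))
  expect_error(write_stack(s, file.path(td, "o.tif")), "16-bit")
  s2 <- tiny_stack(array(1.5, c(1, 2, 2)))
  expect_warning(write_stack(s2, file.path(td, "f.tif")), "rounded")
  r <- read_stack(file.path(td, "f.tif"))
  expect_true(all(r$marker_channel == 2))
})

test_that("write_results emits the 11-column schema and reconstructable shares", {
  comps <- data.frame(label = 1:3, voxel_count = c(100L, 50L, 30L),
                      volume_um3 = c(100, 50, 30),
                      border_touching = c(FALSE, FALSE, TRUE),
                      nuclei_count = c(3L, 1L, 0L),
                      cls = c("NW", "SC", "UD"))
  s <- tiny_stack(array(0, c(10, 10, 10)))
  q <- quantify_stack(comps, s, entity = "E", artifact_cutoff_um3 = 2)
  path <- file.path(withr::local_tempdir(), "res.csv")
  write_results(q, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 1L)
  expect_named(df, c("stack", "entity", "total_fraction_pct", "nw_share_pct",
                     "sc_share_pct", "ud_share_pct", "n_single_cells",
                     "single_cell_mean_um3", "single_cell_sd_um3",
                     "n_networks", "artifact_cutoff_um3"))
  expect_equal(df$nw_share_pct + df$sc_share_pct + df$ud_share_pct, 100,
               tolerance = 0.01)
  expect_error(write_results(list(), path), "non-empty")
})

test_that("ground truth round-trips through JSON", {
  syn <- generate_stack(one_cell_profile(radius = 4),
                        shape = c(20, 20, 20), spacing = voxel_spacing(0.5, 0.5, 0.5))
  path <- file.path(withr::local_tempdir(), "gt.json")
  write_ground_truth(syn, path)
  gt <- read_ground_truth(path)
  expect_equal(gt$cells$outer_radius, syn$cells$outer_radius)
  expect_equal(gt$cells$voxel_cytoplasm_volume, syn$cells$voxel_cytoplasm_volume)
})

test_that("label masks round-trip through 16-bit TIFF", {
  sp <- voxel_spacing(0.5, 0.5, 0.5)
  lab <- array(0L, c(3, 6, 6))
  lab[1, 1:2, 1:2] <- 1L
  lab[3, 5:6, 5:6] <- 2L
  lm <- label_mask(lab, sp)
  path <- file.path(withr::local_tempdir(), "lab.tif")
  write_label_mask(lm, path)
  pages <- tiff::readTIFF(path, all = TRUE)
  back <- array(0L, dim(lab))
  for (z in 1:3) back[z, , ] <- as.integer(round(pages[[z]] * 65535))
  expect_identical(back, lab)
})
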