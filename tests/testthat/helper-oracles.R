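# Shared oracles and fixtures for the test suite.

# Brute-force flood-fill labeling over explicitly enumerated neighbor offsets.
# Labels components 1..K in linear-index scan order (z fastest), the same
# canonical order label_components() uses, so label arrays compare exactly.
oracle_labels <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  ord <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  offs <- switch(as.character(connectivity),
                 "6" = offs[ord == 1, ],
                 "18" = offs[ord <= 2, ],
                 "26" = offs)
  lab <- array(0L, d)
  nxt <- 0L
  # scan in linear-index order: z fastest, then y, then x
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (!mask[z, y, x] || lab[z, y, x] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(z, y, x))
    lab[z, y, x] <- nxt
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        w <- v + c(offs$dz[k], offs$dy[k], offs$dx[k])
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- nxt
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
  }
  lab
}

# Relabel a label array canonically: labels numbered by first appearance in
# linear-index order. Makes partitions comparable regardless of labeling order.
canonical_labels <- function(lab) {
  attributes(lab) <- list(dim = dim(lab))
  pos <- which(lab > 0L)
  if (length(pos) == 0) return(lab)
  first <- !duplicated(lab[pos])
  map <- integer(max(lab))
  map[lab[pos][first]] <- seq_len(sum(first))
  out <- lab
  out[pos] <- map[lab[pos]]
  out
}

# Paint a solid sphere of a given value into a (Z, Y, X) array; voxel centers
# at (i - 0.5) * spacing; center in um.
paint_sphere <- function(arr, center, radius, spacing, value) {
  d <- dim(arr)
  zc <- (seq_len(d[1]) - 0.5) * spacing$dz
  yc <- (seq_len(d[2]) - 0.5) * spacing$dy
  xc <- (seq_len(d[3]) - 0.5) * spacing$dx
  d2 <- outer(outer((zc - center[1])^2, (yc - center[2])^2, "+"),
              (xc - center[3])^2, "+")
  arr[d2 <= radius^2] <- value
  arr
}

# A tiny two-channel stack around a given marker array (background nucleus
# channel) for unit tests.
tiny_stack <- function(marker, spacing = voxel_spacing(1, 1, 1),
                       nucleus = NULL, name = "tiny") {
  if (is.null(nucleus)) nucleus <- array(0, dim(marker))
  image_stack(nucleus, marker, spacing, name = name)
}

# One-cell noiseless profile used by several tests.
one_cell_profile <- function(radius = 6, nucleus_fraction = 0.5, seed = 1L) {
  synthetic_profile(name = "one", n_cells = 1L, radius_mean = radius,
                    radius_sd = 0, nucleus_fraction = nucleus_fraction,
                    network_size_distribution = c("1" = 1),
                    n_artifacts = 0L, noise_sd = 0, seed = seed)
}

# The confocal-style acquisition grid used by end-to-end studies: lateral spacing
# from a 365x375 um field at 1024 px, 0.48 um z-step, 48 planes.
study_spacing <- function() voxel_spacing(365 / 1024, 375 / 1024, 0.48)
study_Z <- 48L

# Side length (multiple of 16) so that n cells of the profile's mean volume
# fill the target volume fraction of the stack.
study_side <- function(profile, n_cells = 20L) {
  sp <- study_spacing()
  zext <- study_Z * sp$dz
  area <- n_cells * profile$cell_volume_mean_um3 /
    (profile$target_volume_fraction / 100) / zext
  as.integer(round(sqrt(area / (sp$dx * sp$dy)) / 16) * 16)
}

# Midpoint absolute threshold of a profile's imaging model (the faithful
# absolute-intensity mode).
study_threshold <- function(profile) {
  (profile$background_level + profile$foreground_level) / 2
}
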