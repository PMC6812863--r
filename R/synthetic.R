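#' Analytic volume of a spherical shell
#'
#' Closed-form cytoplasm volume of the shell model: a marker-positive shell
#' between the nucleus radius and the outer cell radius,
#' `(4/3) * pi * (outer^3 - inner^3)`.
#'
#' @param outer_radius,inner_radius Radii in micrometres,
#'   `outer_radius > inner_radius >= 0`.
#' @return Volume in cubic micrometres.
#' @export
shell_volume_um3 <- function(outer_radius, inner_radius = 0) {
  stopifnot(all(outer_radius > inner_radius), all(inner_radius >= 0))
  (4 / 3) * pi * (outer_radius^3 - inner_radius^3)
}

#' Solve the outer-radius distribution from a target mean cytoplasm volume
#'
#' Given a target mean single-cell cytoplasm volume, a within-stack volume
#' coefficient of variation and the nucleus/outer radius ratio, returns the
#' normal radius parameters such that `E[(4/3) pi (1 - f^3) r^3]` equals the
#' target (using `E[r^3] = mu^3 + 3 mu sigma^2`, with `sigma = cv/3 * mu` from
#' the first-order volume CV).
#'
#' @param volume_mean_um3 Target mean cytoplasm volume in um^3.
#' @param cv Volume coefficient of variation (default 0.2).
#' @param nucleus_fraction Ratio nucleus radius / outer radius.
#' @return List with `radius_mean` and `radius_sd` in um.
#' @export
radius_for_mean_volume <- function(volume_mean_um3, cv = 0.2,
                                   nucleus_fraction = 0.6) {
  stopifnot(volume_mean_um3 > 0, cv >= 0, nucleus_fraction > 0,
            nucleus_fraction < 1)
  cc <- (4 / 3) * pi * (1 - nucleus_fraction^3)
  mu <- (volume_mean_um3 / (cc * (1 + cv^2 / 3)))^(1 / 3)
  list(radius_mean = mu, radius_sd = cv / 3 * mu)
}

#' Synthetic stack profile
#'
#' Parameter set for the synthetic confocal-stack generator: sphere-shell
#' cells (marker-positive cytoplasm surrounding an unstained-in-the-marker,
#' DAPI-like nucleus), multi-cell aggregates joined by overlap or by
#' cylindrical protrusions, nucleus-free speckle artifacts, and additive
#' Gaussian noise on a constant background.
#'
#' @param name Entity label.
#' @param n_cells Number of cells (ignored when `target_volume_fraction`
#'   drives the cell budget).
#' @param radius_mean,radius_sd Outer-radius distribution in um (draws are
#'   clamped to mean +/- 2 sd).
#' @param nucleus_fraction Nucleus radius / outer radius, in (0, 1).
#' @param network_size_distribution Named numeric vector of probabilities over
#'   aggregate sizes (names are sizes: `"1"` solitary, `"3"` a 3-cell network,
#'   ...); must sum to 1. Realized compositions use a deterministic
#'   largest-remainder quota on the cell-weighted shares, so a stack's
#'   composition equals the nominal distribution as closely as the cell count
#'   allows.
#' @param protrusion_probability Probability that a network neighbour is
#'   attached at a distance bridged by a protrusion cylinder instead of by
#'   direct shell overlap.
#' @param protrusion_radius Protrusion cylinder radius in um.
#' @param target_volume_fraction Optional percentage of the stack volume that
#'   should be cytoplasm; when set it overrides `n_cells` and the drawn radii
#'   are rescaled (bounded) so the analytic cytoplasm total matches the
#'   budget.
#' @param n_artifacts Number of marker-only speckles. The first artifact is
#'   always rendered at exactly `artifact_radius_max`, so a control generated
#'   from the same profile bounds the artifact sizes of any paired sample
#'   stack.
#' @param artifact_radius_max Largest artifact radius in um; must keep all
#'   artifact volumes strictly below the smallest cell cytoplasm volume
#'   (separability by size, which is what makes the control-based cutoff
#'   work).
#' @param background_level,foreground_level,noise_sd Intensity units of the
#'   constant background, the stained voxels, and the additive Gaussian noise.
#' @param p_truncated Fraction of solitary cells deliberately placed with
#'   centers within `outer_radius` of a stack face, so the undefined
#'   edge-fragment class is exercised (0 by default).
#' @param nuclei_per_cell 1 (default) or 2: with 2, each nucleus compartment
#'   holds two smaller DAPI spheres, emulating multinucleated cells.
#' @param seed Integer seed; identical seed + profile give bit-identical
#'   output.
#' @param max_retries Placement rejection-sampling cap per cell.
#' @return An object of class `synthetic_profile`.
#' @export
synthetic_profile <- function(name = "custom",
                              n_cells = 20L,
                              radius_mean = 5.5,
                              radius_sd = 0.37,
                              nucleus_fraction = 0.6,
                              network_size_distribution = c("1" = 1),
                              protrusion_probability = 0.3,
                              protrusion_radius = 0.6,
                              target_volume_fraction = NULL,
                              n_artifacts = 0L,
                              artifact_radius_max = 1.5,
                              background_level = 20,
                              foreground_level = 200,
                              noise_sd = 0,
                              p_truncated = 0,
                              nuclei_per_cell = 1L,
                              seed = 1L,
                              max_retries = 1000L) {
  nsd <- network_size_distribution
  if (is.null(names(nsd)) || any(is.na(suppressWarnings(as.integer(names(nsd))))))
    stop("network_size_distribution must be named by integer aggregate sizes")
  if (abs(sum(nsd) - 1) > 1e-8)
    stop("network_size_distribution probabilities must sum to 1")
  if (any(nsd < 0)) stop("network size probabilities must be >= 0")
  stopifnot(radius_mean > 0, radius_sd >= 0, nucleus_fraction > 0,
            nucleus_fraction < 1, protrusion_probability >= 0,
            protrusion_probability <= 1, n_cells >= 1,
            p_truncated >= 0, p_truncated <= 1,
            nuclei_per_cell %in% c(1L, 2L),
            foreground_level > background_level, background_level >= 0,
            noise_sd >= 0, n_artifacts >= 0)
  if (!is.null(target_volume_fraction))
    stopifnot(target_volume_fraction > 0, target_volume_fraction < 100)
  if (n_artifacts > 0) {
    r_min <- max(0.5, radius_mean - 2 * radius_sd)
    min_cell_vol <- shell_volume_um3(r_min, nucleus_fraction * r_min)
    art_vol_max <- (4 / 3) * pi * artifact_radius_max^3
    if (art_vol_max >= min_cell_vol)
      stop(sprintf(
        "artifact_radius_max %.3g um gives artifact volumes (%.4g um^3) not strictly below the smallest cell cytoplasm volume (%.4g um^3)",
        artifact_radius_max, art_vol_max, min_cell_vol))
  }
  structure(list(name = name, n_cells = as.integer(n_cells),
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 nucleus_fraction = nucleus_fraction,
                 network_size_distribution = nsd,
                 protrusion_probability = protrusion_probability,
                 protrusion_radius = protrusion_radius,
                 target_volume_fraction = target_volume_fraction,
                 n_artifacts = as.integer(n_artifacts),
                 artifact_radius_max = artifact_radius_max,
                 background_level = background_level,
                 foreground_level = foreground_level,
                 noise_sd = noise_sd,
                 p_truncated = p_truncated,
                 nuclei_per_cell = as.integer(nuclei_per_cell),
                 seed = as.integer(seed),
                 max_retries = as.integer(max_retries),
                 cell_volume_mean_um3 = shell_volume_um3(
                   radius_mean, nucleus_fraction * radius_mean)),
            class = "synthetic_profile")
}

#' Expected network volume share of a profile
#'
#' Cell-weighted share of cells living in aggregates of at least three:
#' `sum_{k>=3} k p_k / sum_k k p_k`. Since all cells draw radii from the same
#' distribution, this is also the expected marker-volume share of networks.
#'
#' @param profile A [synthetic_profile()].
#' @return Share in percent.
#' @export
profile_network_share <- function(profile) {
  stopifnot(inherits(profile, "synthetic_profile"))
  k <- as.integer(names(profile$network_size_distribution))
  p <- profile$network_size_distribution
  100 * sum(k[k >= 3] * p[k >= 3]) / sum(k * p)
}

#' Entity presets calibrated to reported tissue measurements
#'
#' Fully populated generator profiles for the five studied entities:
#' lymphadenitis (LAD), adenoids (AD), nodular-sclerosis classical Hodgkin
#' lymphoma (NScHL), mixed-cellularity cHL without (MCcHL) and with
#' (MCcHL_EBV) EBV infection. Target volume fractions are the reported means
#' (1.51 / 1.99 / 5.99 / 3.13 / 2.23 percent), the outer-radius distribution
#' is solved from the reported single-cell cytoplasm volume means (464 / 458 /
#' 672 / 978 / 1335 um^3) at a 20% within-stack volume CV, and the network
#' volume shares encode the qualitative network dominance per entity (NScHL
#' network-dominated at 75%, the others single-cell-dominated at 30-35%).
#' Aggregate-size distributions beyond that are ad hoc: no quantitative
#' network-size data exist for these tissues.
#'
#' @param name One of `"LAD"`, `"AD"`, `"NScHL"`, `"MCcHL"`, `"MCcHL_EBV"`.
#' @param seed Seed stored in the profile.
#' @return A [synthetic_profile()] with field `cell_volume_mean_um3` equal to
#'   the calibrated single-cell mean.
#' @export
entity_preset <- function(name = c("LAD", "AD", "NScHL", "MCcHL", "MCcHL_EBV"),
                          seed = 1L) {
  name <- match.arg(name)
  # fraction %, single-cell mean um^3, aggregate-size probs, protrusion prob
  presets <- list(
    LAD = list(frac = 1.51, scv = 464,
               nsd = c("1" = 14 / 16, "3" = 2 / 16), pp = 0.2),
    AD = list(frac = 1.99, scv = 458,
              nsd = c("1" = 13 / 15, "3" = 1 / 15, "4" = 1 / 15), pp = 0.5),
    NScHL = list(frac = 5.99, scv = 672,
                 nsd = c("1" = 5 / 8, "5" = 3 / 8), pp = 0.3),
    MCcHL = list(frac = 3.13, scv = 978,
                 nsd = c("1" = 14 / 16, "3" = 2 / 16), pp = 0.6),
    MCcHL_EBV = list(frac = 2.23, scv = 1335,
                     nsd = c("1" = 13 / 15, "3" = 1 / 15, "4" = 1 / 15),
                     pp = 0.6))
  p <- presets[[name]]
  rr <- radius_for_mean_volume(p$scv, cv = 0.2, nucleus_fraction = 0.6)
  prof <- synthetic_profile(name = name, n_cells = 20L,
                            radius_mean = rr$radius_mean,
                            radius_sd = rr$radius_sd,
                            nucleus_fraction = 0.6,
                            network_size_distribution = p$nsd,
                            protrusion_probability = p$pp,
                            protrusion_radius = 0.6,
                            target_volume_fraction = p$frac,
                            n_artifacts = 15L, artifact_radius_max = 1.5,
                            background_level = 20, foreground_level = 200,
                            noise_sd = 20, seed = seed)
  prof$cell_volume_mean_um3 <- p$scv
  prof
}

# Deterministic largest-remainder realization of the aggregate-size
# distribution: returns a vector of group sizes whose cell-weighted
# composition matches the nominal shares as closely as n_cells allows.
realize_composition <- function(n_cells, nsd) {
  sizes <- as.integer(names(nsd))
  p <- as.numeric(nsd)
  share <- sizes * p / sum(sizes * p)  # cell-weighted share per size
  ord <- order(sizes, decreasing = TRUE)
  groups <- integer(0)
  used <- 0L
  for (i in ord) {
    k <- sizes[i]
    if (k == 1L) next
    g <- round(n_cells * share[i] / k)
    while (g > 0L && used + g * k > n_cells) g <- g - 1L
    if (g > 0L) {
      groups <- c(groups, rep(k, g))
      used <- used + g * k
    }
  }
  c(groups, rep(1L, n_cells - used))
}

rand_direction <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# linear (1-based) index into a (Z, Y, X) array
lin_index <- function(z, y, x, d) z + d[1] * (y - 1) + d[1] * d[2] * (x - 1)

#' Generate a synthetic two-channel confocal stack with ground truth
#'
#' Renders sphere-shell cells (marker channel), solid nuclei (nucleus
#' channel), network aggregates connected by shell overlap or protrusion
#' cylinders, nucleus-free speckle artifacts, and additive Gaussian noise.
#' Nucleus-compartment voxels are never marker-positive in the noiseless
#' render, so "the nuclear stain is not included in the volumes" holds by
#' construction. Cells sharing a network form one connected marker component
#' (verified and, if a digitized protrusion pinches off, repaired by widening
#' it); cells of different aggregates never touch (enforced by a 2 um
#' clearance during placement). All randomness comes from `profile$seed`.
#'
#' @param profile A [synthetic_profile()].
#' @param shape Integer vector `(Z, Y, X)` in voxels.
#' @param spacing A [voxel_spacing()].
#' @return An object of class `synthetic_stack`: list with
#'   \describe{
#'   \item{stack}{the rendered [image_stack()];}
#'   \item{cells}{ground-truth data frame: `cell_id`, center `z`/`y`/`x` (um),
#'     `nucleus_radius`, `outer_radius`, `network_id` (0 = solitary),
#'     `truncated`, `analytic_cytoplasm_volume` (closed form, untruncated),
#'     `voxel_cytoplasm_volume` (rendered voxels x voxel volume);}
#'   \item{label_mask}{[label_mask()] labeling each cell's cytoplasm voxels by
#'     `cell_id`;}
#'   \item{artifacts}{data frame of speckles (`id`, center, `radius`,
#'     `voxel_count`);}
#'   \item{artifact_mask}{integer array labeling artifact voxels.}
#'   }
#' @export
generate_stack <- function(profile, shape, spacing) {
  stopifnot(inherits(profile, "synthetic_profile"),
            inherits(spacing, "voxel_spacing"), length(shape) == 3)
  shape <- as.integer(shape)
  ext <- c(shape[1] * spacing$dz, shape[2] * spacing$dy, shape[3] * spacing$dx)
  r_hi <- profile$radius_mean + 2 * profile$radius_sd
  if (any(ext < 2 * r_hi + 1))
    stop(sprintf("stack extent (%.1f x %.1f x %.1f um) too small for cells of radius up to %.1f um",
                 ext[1], ext[2], ext[3], r_hi))
  withr::with_seed(profile$seed, generate_stack_impl(profile, shape, spacing, ext))
}

generate_stack_impl <- function(profile, shape, spacing, ext) {
  clearance <- 2.0   # um between cells of different aggregates
  r_lo <- max(0.5, profile$radius_mean - 2 * profile$radius_sd)
  r_hi <- profile$radius_mean + 2 * profile$radius_sd
  f <- profile$nucleus_fraction
  cc <- (4 / 3) * pi * (1 - f^3)

  # --- composition -----------------------------------------------------
  if (!is.null(profile$target_volume_fraction)) {
    budget <- profile$target_volume_fraction / 100 *
      prod(shape) * voxel_volume(spacing)
    ev <- cc * (profile$radius_mean^3 +
                3 * profile$radius_mean * profile$radius_sd^2)
    n_eff <- max(1L, as.integer(round(budget / ev)))
  } else {
    budget <- NULL
    n_eff <- profile$n_cells
  }
  groups <- realize_composition(n_eff, profile$network_size_distribution)

  radii <- pmin(pmax(rnorm(n_eff, profile$radius_mean, profile$radius_sd),
                     r_lo), r_hi)
  if (!is.null(budget)) {
    s <- (budget / sum(cc * radii^3))^(1 / 3)
    s <- min(max(s, 0.8), 1.25)
    radii <- radii * s
  }

  # assign radii to groups in order
  cells <- data.frame(cell_id = seq_len(n_eff),
                      z = NA_real_, y = NA_real_, x = NA_real_,
                      outer_radius = radii,
                      nucleus_radius = f * radii,
                      network_id = 0L, truncated = FALSE)
  gstart <- cumsum(c(1L, groups))[seq_along(groups)]
  net_id <- 0L
  for (gi in seq_along(groups)) {
    if (groups[gi] >= 2L) {
      net_id <- net_id + 1L
      cells$network_id[gstart[gi]:(gstart[gi] + groups[gi] - 1L)] <- net_id
    }
  }
  # deliberate edge truncation of some solitary cells
  solo <- which(cells$network_id == 0L)
  n_trunc <- round(profile$p_truncated * length(solo))
  if (n_trunc > 0) {
    cells$truncated[solo[sample.int(length(solo), n_trunc)]] <- TRUE
  }

  # --- placement (rejection sampling) ----------------------------------
  place_interior <- function(r) {
    lo <- r + 0.25
    hi <- c(ext[1], ext[2], ext[3]) - r - 0.25
    if (any(hi <= lo)) stop("stack too small to place a cell of radius ", r)
    c(runif(1, lo, hi[1]), runif(1, lo, hi[2]), runif(1, lo, hi[3]))
  }
  place_truncated <- function(r) {
    ctr <- place_interior(r)
    axis <- sample(3L, 1L)
    side <- sample(c(TRUE, FALSE), 1L)
    d <- runif(1, f * r + 0.2, 0.9 * r)  # nucleus stays inside
    ctr[axis] <- if (side) d else ext[axis] - d
    ctr
  }
  conflict <- function(ctr, r, own_group) {
    placed <- which(!is.na(cells$z))
    for (j in placed) {
      dd <- sqrt(sum((ctr - c(cells$z[j], cells$y[j], cells$x[j]))^2))
      rj <- cells$outer_radius[j]
      same <- own_group > 0L && cells$network_id[j] == own_group
      lim <- if (same) 0.9 * (r + rj) else r + rj + clearance
      if (dd < lim) return(TRUE)
    }
    FALSE
  }

  protrusions <- list()
  for (gi in seq_along(groups)) {
    ids <- gstart[gi]:(gstart[gi] + groups[gi] - 1L)
    for (m in seq_along(ids)) {
      i <- ids[m]
      r <- cells$outer_radius[i]
      placed_ok <- FALSE
      for (try in seq_len(profile$max_retries)) {
        if (m == 1L) {
          ctr <- if (cells$truncated[i]) place_truncated(r) else place_interior(r)
          if (!conflict(ctr, r, 0L)) { placed_ok <- TRUE; break }
        } else {
          anchor <- ids[sample(m - 1L, 1L)]
          ra <- cells$outer_radius[anchor]
          prot <- runif(1) < profile$protrusion_probability
          dd <- if (prot) 1.15 * (r + ra) else 0.95 * (r + ra)
          dir <- rand_direction()
          ctr <- c(cells$z[anchor], cells$y[anchor], cells$x[anchor]) + dd * dir
          lo <- r + 0.25
          if (any(ctr < lo) || any(ctr > ext - lo)) next
          if (!conflict(ctr, r, cells$network_id[i])) {
            if (prot) protrusions[[length(protrusions) + 1L]] <-
                c(a = anchor, b = i)
            placed_ok <- TRUE
            break
          }
        }
      }
      if (!placed_ok)
        stop(sprintf("overcrowding: could not place cell %d (group of %d) after %d retries",
                     i, groups[gi], profile$max_retries))
      cells$z[i] <- ctr[1]; cells$y[i] <- ctr[2]; cells$x[i] <- ctr[3]
    }
  }

  # --- artifacts --------------------------------------------------------
  arts <- place_artifacts(profile, ext, cells)

  # --- rasterization ----------------------------------------------------
  render <- rasterize_scene(profile, shape, spacing, cells, protrusions, arts)
  gt <- render$gt
  nuc_lab <- render$nuc_lab
  art_lab <- render$art_lab
  vv <- voxel_volume(spacing)

  counts <- tabulate(gt[gt > 0L], nbins = n_eff)
  cells$analytic_cytoplasm_volume <-
    shell_volume_um3(cells$outer_radius, cells$nucleus_radius)
  cells$voxel_cytoplasm_volume <- counts * vv
  if (nrow(arts) > 0) {
    arts$voxel_count <- tabulate(art_lab[art_lab > 0L], nbins = nrow(arts))
  }

  marker <- array(profile$background_level, shape)
  marker[gt > 0L | art_lab > 0L] <- profile$foreground_level
  nucleus <- array(profile$background_level, shape)
  nucleus[nuc_lab > 0L] <- profile$foreground_level
  if (profile$noise_sd > 0) {
    n <- length(marker)
    marker <- marker + rnorm(n, 0, profile$noise_sd)
    nucleus <- nucleus + rnorm(n, 0, profile$noise_sd)
  }
  marker <- round(pmax(marker, 0))
  nucleus <- round(pmax(nucleus, 0))
  dim(marker) <- shape
  dim(nucleus) <- shape

  stack <- image_stack(nucleus, marker, spacing,
                       name = sprintf("%s_seed%d", profile$name, profile$seed))
  structure(list(stack = stack,
                 cells = cells,
                 label_mask = label_mask(gt, spacing),
                 artifacts = arts,
                 artifact_mask = art_lab),
            class = "synthetic_stack")
}

place_artifacts <- function(profile, ext, cells) {
  n_art <- profile$n_artifacts
  if (n_art == 0)
    return(data.frame(id = integer(0), z = numeric(0), y = numeric(0),
                      x = numeric(0), radius = numeric(0),
                      voxel_count = integer(0)))
  amax <- profile$artifact_radius_max
  # the first artifact is always the worst-case speckle at amax, so a control
  # from this profile bounds the artifact size of any paired sample stack
  rad <- c(amax, runif(n_art - 1, 0.5 * amax, amax))
  arts <- data.frame(id = seq_len(n_art), z = NA_real_, y = NA_real_,
                     x = NA_real_, radius = rad, voxel_count = 0L)
  has_cells <- nrow(cells) > 0 && !anyNA(cells$z)
  for (i in seq_len(n_art)) {
    a <- arts$radius[i]
    ok <- FALSE
    for (try in seq_len(profile$max_retries)) {
      ctr <- c(runif(1, a + 0.25, ext[1] - a - 0.25),
               runif(1, a + 0.25, ext[2] - a - 0.25),
               runif(1, a + 0.25, ext[3] - a - 0.25))
      bad <- FALSE
      if (has_cells) {
        dd <- sqrt((ctr[1] - cells$z)^2 + (ctr[2] - cells$y)^2 +
                   (ctr[3] - cells$x)^2)
        if (any(dd < cells$outer_radius + a + 1.5)) bad <- TRUE
      }
      if (!bad && i > 1) {
        j <- seq_len(i - 1L)
        dd <- sqrt((ctr[1] - arts$z[j])^2 + (ctr[2] - arts$y[j])^2 +
                   (ctr[3] - arts$x[j])^2)
        if (any(dd < arts$radius[j] + a + 1.0)) bad <- TRUE
      }
      if (!bad) { ok <- TRUE; break }
    }
    if (!ok) stop("overcrowding: could not place artifact ", i)
    arts$z[i] <- ctr[1]; arts$y[i] <- ctr[2]; arts$x[i] <- ctr[3]
  }
  arts
}

# voxel-center coordinates of a bounding box around center +/- reach, clipped
# to the stack; returns NULL if empty
bbox_grid <- function(center, reach, shape, spacing) {
  sp <- c(spacing$dz, spacing$dy, spacing$dx)
  lo <- pmax(1L, as.integer(ceiling((center - reach) / sp + 0.5)))
  hi <- pmin(shape, as.integer(floor((center + reach) / sp + 0.5)))
  if (any(hi < lo)) return(NULL)
  list(zi = lo[1]:hi[1], yi = lo[2]:hi[2], xi = lo[3]:hi[3],
       zc = ((lo[1]:hi[1]) - 0.5) * sp[1],
       yc = ((lo[2]:hi[2]) - 0.5) * sp[2],
       xc = ((lo[3]:hi[3]) - 0.5) * sp[3])
}

# squared distance of every bbox voxel center to a point
bbox_dist2 <- function(g, center) {
  outer(outer((g$zc - center[1])^2, (g$yc - center[2])^2, "+"),
        (g$xc - center[3])^2, "+")
}

bbox_lin <- function(g, which_idx, shape) {
  nz <- length(g$zi); ny <- length(g$yi)
  a <- ((which_idx - 1L) %% nz) + 1L
  b <- (((which_idx - 1L) %/% nz) %% ny) + 1L
  cx <- ((which_idx - 1L) %/% (nz * ny)) + 1L
  lin_index(g$zi[a], g$yi[b], g$xi[cx], shape)
}

rasterize_scene <- function(profile, shape, spacing, cells, protrusions, arts) {
  gt <- array(0L, shape)
  nuc_lab <- array(0L, shape)
  f <- profile$nucleus_fraction

  centers <- cbind(cells$z, cells$y, cells$x)
  # shells, with nearest-center ownership where network partners overlap
  for (i in seq_len(nrow(cells))) {
    r <- cells$outer_radius[i]; rn <- cells$nucleus_radius[i]
    g <- bbox_grid(centers[i, ], r, shape, spacing)
    if (is.null(g)) next
    d2 <- bbox_dist2(g, centers[i, ])
    sel <- which(d2 <= r^2 & d2 > rn^2)
    if (length(sel) == 0) next
    lin <- bbox_lin(g, sel, shape)
    cur <- gt[lin]
    free <- cur == 0L
    gt[lin[free]] <- i
    clash <- which(!free & cur != i)
    if (length(clash) > 0) {
      # contested voxels go to the nearer center
      for (o in unique(cur[clash])) {
        cl <- clash[cur[clash] == o]
        d2_new <- d2[sel[cl]]
        # recover voxel coords from linear index to measure against owner o
        li <- lin[cl]
        zz <- ((li - 1L) %% shape[1]) + 1L
        yy <- (((li - 1L) %/% shape[1]) %% shape[2]) + 1L
        xx <- ((li - 1L) %/% (shape[1] * shape[2])) + 1L
        pz <- (zz - 0.5) * spacing$dz
        py <- (yy - 0.5) * spacing$dy
        px <- (xx - 0.5) * spacing$dx
        d2_old <- (pz - centers[o, 1])^2 + (py - centers[o, 2])^2 +
          (px - centers[o, 3])^2
        take <- d2_new < d2_old
        gt[li[take]] <- i
      }
    }
  }

  # nuclei (solid spheres inside the nucleus compartment)
  for (i in seq_len(nrow(cells))) {
    rn <- cells$nucleus_radius[i]
    if (profile$nuclei_per_cell == 1L) {
      sub_centers <- centers[i, , drop = FALSE]
      sub_r <- rn
    } else {
      dir <- rand_direction()
      # two well-separated sub-nuclei inside the compartment (gap ~0.26 rn so
      # digitization never merges them)
      sub_centers <- rbind(centers[i, ] + 0.55 * rn * dir,
                           centers[i, ] - 0.55 * rn * dir)
      sub_r <- rep(0.42 * rn, 2)
    }
    for (s in seq_len(nrow(sub_centers))) {
      g <- bbox_grid(sub_centers[s, ], sub_r[s], shape, spacing)
      if (is.null(g)) next
      d2 <- bbox_dist2(g, sub_centers[s, ])
      sel <- which(d2 <= sub_r[s]^2)
      if (length(sel) > 0) nuc_lab[bbox_lin(g, sel, shape)] <- i
    }
  }

  paint_bridge <- function(a, b, prad) {
    pa <- centers[a, ]; pb <- centers[b, ]
    lo <- pmin(pa, pb) - prad; hi <- pmax(pa, pb) + prad
    g <- bbox_grid((lo + hi) / 2, (hi - lo) / 2, shape, spacing)
    if (is.null(g)) return(invisible(NULL))
    u <- pb - pa
    L2 <- sum(u^2)
    nz <- length(g$zc); ny <- length(g$yc); nx <- length(g$xc)
    pz <- array(g$zc, c(nz, ny, nx))
    py <- array(rep(g$yc, each = nz), c(nz, ny, nx))
    px <- array(rep(g$xc, each = nz * ny), c(nz, ny, nx))
    t <- ((pz - pa[1]) * u[1] + (py - pa[2]) * u[2] + (px - pa[3]) * u[3]) / L2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (pz - (pa[1] + t * u[1]))^2 + (py - (pa[2] + t * u[2]))^2 +
      (px - (pa[3] + t * u[3]))^2
    # keep bridges out of the nucleus compartments of both endpoints
    d2a <- bbox_dist2(g, pa); d2b <- bbox_dist2(g, pb)
    sel <- which(d2 <= prad^2 &
                 d2a > cells$nucleus_radius[a]^2 &
                 d2b > cells$nucleus_radius[b]^2)
    if (length(sel) == 0) return(invisible(NULL))
    lin <- bbox_lin(g, sel, shape)
    free <- gt[lin] == 0L
    owner <- ifelse(d2a[sel[free]] <= d2b[sel[free]], a, b)
    gt[lin[free]] <<- owner
    invisible(NULL)
  }
  for (p in protrusions) paint_bridge(p[["a"]], p[["b"]], profile$protrusion_radius)

  # carve out all nucleus compartments: nucleus voxels are never
  # marker-positive, by construction
  for (i in seq_len(nrow(cells))) {
    rn <- cells$nucleus_radius[i]
    g <- bbox_grid(centers[i, ], rn, shape, spacing)
    if (is.null(g)) next
    d2 <- bbox_dist2(g, centers[i, ])
    sel <- which(d2 <= rn^2)
    if (length(sel) > 0) gt[bbox_lin(g, sel, shape)] <- 0L
  }

  # verify each aggregate is one connected component; widen pinched
  # protrusions if digitization broke them
  nets <- setdiff(unique(cells$network_id), 0L)
  for (nid in nets) {
    ids <- which(cells$network_id == nid)
    prad <- profile$protrusion_radius
    for (attempt in 0:3) {
      pad <- 1
      lo <- pmin(apply(centers[ids, , drop = FALSE], 2, min) -
                   max(cells$outer_radius[ids]) - pad, Inf)
      hi <- apply(centers[ids, , drop = FALSE], 2, max) +
        max(cells$outer_radius[ids]) + pad
      g <- bbox_grid((lo + hi) / 2, (hi - lo) / 2, shape, spacing)
      sub <- gt[g$zi, g$yi, g$xi, drop = FALSE]
      m <- array(sub %in% ids, dim(sub))
      lab <- label_components_cpp(as.logical(m), dim(m), 26L)
      if (attr(lab, "n_labels") <= 1L) break
      if (attempt == 3L)
        stop("could not connect aggregate ", nid, " after widening protrusions")
      prad <- prad * 1.6
      for (m2 in 2:length(ids)) paint_bridge(ids[m2 - 1L], ids[m2], prad)
      # re-carve compartments potentially touched by widened bridges
      for (i in ids) {
        rn <- cells$nucleus_radius[i]
        gg <- bbox_grid(centers[i, ], rn, shape, spacing)
        if (is.null(gg)) next
        d2 <- bbox_dist2(gg, centers[i, ])
        sel <- which(d2 <= rn^2)
        if (length(sel) > 0) gt[bbox_lin(gg, sel, shape)] <- 0L
      }
    }
  }

  art_lab <- array(0L, shape)
  for (i in seq_len(nrow(arts))) {
    actr <- c(arts$z[i], arts$y[i], arts$x[i])
    g <- bbox_grid(actr, arts$radius[i], shape, spacing)
    if (is.null(g)) next
    d2 <- bbox_dist2(g, actr)
    sel <- which(d2 <= arts$radius[i]^2)
    if (length(sel) > 0) art_lab[bbox_lin(g, sel, shape)] <- i
  }

  list(gt = gt, nuc_lab = nuc_lab, art_lab = art_lab)
}

#' Generate a negative-control stack
#'
#' A stack containing only speckle artifacts, background and noise — no cells,
#' no nuclei — emulating an identically processed negative control. Used to
#' calibrate the artifact-size cutoff (see [estimate_artifact_cutoff()]).
#' Because every profile renders its first artifact at exactly
#' `artifact_radius_max`, a control from the same profile always bounds the
#' speckle sizes of its paired sample stack.
#'
#' @param profile A [synthetic_profile()].
#' @param shape Integer `(Z, Y, X)` in voxels.
#' @param spacing A [voxel_spacing()].
#' @return An [image_stack()] with attribute `"artifacts"` (ground-truth
#'   speckle table).
#' @export
generate_control_stack <- function(profile, shape, spacing) {
  stopifnot(inherits(profile, "synthetic_profile"),
            inherits(spacing, "voxel_spacing"), length(shape) == 3)
  shape <- as.integer(shape)
  ext <- c(shape[1] * spacing$dz, shape[2] * spacing$dy, shape[3] * spacing$dx)
  withr::with_seed(profile$seed + 1L, {
    no_cells <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                           outer_radius = numeric(0))
    arts <- place_artifacts(profile, ext, no_cells)
    art_lab <- array(0L, shape)
    for (i in seq_len(nrow(arts))) {
      actr <- c(arts$z[i], arts$y[i], arts$x[i])
      g <- bbox_grid(actr, arts$radius[i], shape, spacing)
      if (is.null(g)) next
      d2 <- bbox_dist2(g, actr)
      sel <- which(d2 <= arts$radius[i]^2)
      if (length(sel) > 0) art_lab[bbox_lin(g, sel, shape)] <- i
    }
    arts$voxel_count <- if (nrow(arts) > 0)
      tabulate(art_lab[art_lab > 0L], nbins = nrow(arts)) else integer(0)
    marker <- array(profile$background_level, shape)
    marker[art_lab > 0L] <- profile$foreground_level
    nucleus <- array(profile$background_level, shape)
    if (profile$noise_sd > 0) {
      marker <- marker + rnorm(length(marker), 0, profile$noise_sd)
      nucleus <- nucleus + rnorm(length(nucleus), 0, profile$noise_sd)
    }
    marker <- round(pmax(marker, 0)); dim(marker) <- shape
    nucleus <- round(pmax(nucleus, 0)); dim(nucleus) <- shape
    out <- image_stack(nucleus, marker, spacing,
                       name = sprintf("%s_control_seed%d", profile$name,
                                      profile$seed))
    attr(out, "artifacts") <- arts
    out
  })
}
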