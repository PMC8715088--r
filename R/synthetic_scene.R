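# Synthetic FIB/SEM-like scenes: rasterized dendrites with ground-truth
# particles and synapse patches, so every analysis stage is testable without
# microscopy data.
#
# Default geometry mimics the scale of reconstructed CA1 dendrites: a shaft
# ~4 um long and ~0.5 um in radius (volume ~3 um^3), spine heads of
# ~0.15 um radius (volume ~0.014 um^3) on cylindrical necks, synaptic patches
# ~0.1 um in radius. Surface particles follow either complete spatial
# randomness (area-weighted over boundary nodes) or a Thomas-like
# parent-offspring process with geodesic offspring spread; intracellular
# particles follow a 3D Poisson draw over the compartment interior.

#' Configuration for a synthetic dendrite scene
#'
#' @param kind `"pyramidal"` (spiny shaft) or `"interneuron"` (smooth shaft).
#' @param spacing_nm Isotropic voxel spacing in nm (default 20).
#' @param shaft_radius_nm,shaft_length_nm Shaft cylinder dimensions.
#' @param curve_amplitude_nm Amplitude of the gentle sinusoidal bend of the
#'   shaft axis.
#' @param n_spines Number of spines (forced to 0 for interneurons).
#' @param spine_head_radius_nm,spine_neck_length_nm,spine_neck_radius_nm
#'   Spine geometry.
#' @param n_asym_synapses Asymmetric patches. For pyramidal scenes one patch
#'   is placed on every spine head (this argument is ignored); for
#'   interneurons they are placed on the shaft.
#' @param n_sym_synapses Symmetric patches on the shaft.
#' @param synapse_radius_nm Patch radius (nm) on the membrane.
#' @param particle_model `"clustered_surface"` (parent-offspring) or
#'   `"csr_surface"` (complete spatial randomness).
#' @param lambda_pm Surface particle intensity, gold/um^2 (csr model).
#' @param n_parents,offspring_per_parent,offspring_spread_nm Clustered-model
#'   parameters: parents are allocated across compartment surfaces
#'   area-weighted; each contributes `offspring_per_parent` particles with
#'   geodesic Gaussian spread `offspring_spread_nm`.
#' @param lambda_intra Intracellular intensity, gold/um^3.
#' @param place_particles Set `FALSE` to generate geometry only.
#' @param seed Integer seed; the whole scene is deterministic given the seed.
#' @return A `scene_config` list.
#' @export
scene_config <- function(kind = c("pyramidal", "interneuron"),
                         spacing_nm = 20,
                         shaft_radius_nm = 500, shaft_length_nm = 4000,
                         curve_amplitude_nm = 150,
                         n_spines = 13,
                         spine_head_radius_nm = 150,
                         spine_neck_length_nm = 200,
                         spine_neck_radius_nm = 60,
                         n_asym_synapses = 5, n_sym_synapses = 3,
                         synapse_radius_nm = 100,
                         particle_model = c("clustered_surface", "csr_surface"),
                         lambda_pm = 8,
                         n_parents = 10, offspring_per_parent = 5,
                         offspring_spread_nm = 30,
                         lambda_intra = 120,
                         place_particles = TRUE,
                         seed = 1L) {
  kind <- match.arg(kind)
  particle_model <- match.arg(particle_model)
  if (kind == "interneuron") n_spines <- 0L
  cfg <- list(
    kind = kind, spacing_nm = spacing_nm,
    shaft_radius_nm = shaft_radius_nm, shaft_length_nm = shaft_length_nm,
    curve_amplitude_nm = curve_amplitude_nm,
    n_spines = as.integer(n_spines),
    spine_head_radius_nm = spine_head_radius_nm,
    spine_neck_length_nm = spine_neck_length_nm,
    spine_neck_radius_nm = spine_neck_radius_nm,
    n_asym_synapses = as.integer(n_asym_synapses),
    n_sym_synapses = as.integer(n_sym_synapses),
    synapse_radius_nm = synapse_radius_nm,
    particle_model = particle_model,
    lambda_pm = lambda_pm,
    n_parents = as.integer(n_parents),
    offspring_per_parent = as.integer(offspring_per_parent),
    offspring_spread_nm = offspring_spread_nm,
    lambda_intra = lambda_intra,
    place_particles = isTRUE(place_particles),
    seed = as.integer(seed)
  )
  geom <- unlist(cfg[c("spacing_nm", "shaft_radius_nm", "shaft_length_nm",
                       "spine_head_radius_nm", "spine_neck_length_nm",
                       "spine_neck_radius_nm", "synapse_radius_nm",
                       "offspring_spread_nm")])
  if (any(geom <= 0)) stop("geometric parameters must be positive", call. = FALSE)
  structure(cfg, class = "scene_config")
}

# shaft axis center (x, y) at height z (nm)
shaft_axis <- function(cfg, z, cx, cy) {
  cbind(cx + cfg$curve_amplitude_nm * sin(2 * pi * z / cfg$shaft_length_nm), cy)
}

# sample spine attachment sites (z, theta) with non-overlapping heads
sample_spine_sites <- function(cfg, cx, cy) {
  min_sep <- 2 * cfg$spine_head_radius_nm + 2 * cfg$spacing_nm
  reach <- cfg$shaft_radius_nm + cfg$spine_neck_length_nm + cfg$spine_head_radius_nm
  zlim <- c(cfg$spine_head_radius_nm + cfg$spacing_nm,
            cfg$shaft_length_nm - cfg$spine_head_radius_nm - cfg$spacing_nm)
  for (attempt in seq_len(200)) {
    z <- runif(cfg$n_spines, zlim[1], zlim[2])
    th <- runif(cfg$n_spines, 0, 2 * pi)
    ax <- shaft_axis(cfg, z, cx, cy)
    hx <- ax[, 1] + reach * cos(th); hy <- ax[, 2] + reach * sin(th)
    hz <- z
    ok <- TRUE
    if (cfg$n_spines > 1) {
      dd <- as.matrix(stats::dist(cbind(hx, hy, hz)))
      diag(dd) <- Inf
      ok <- min(dd) > min_sep
    }
    if (ok) {
      if (attempt > 1) warning("spine placement regenerated (", attempt - 1,
                               " overlapping draw(s) rejected)", call. = FALSE)
      return(tibble::tibble(z = z, theta = th))
    }
  }
  stop("could not place ", cfg$n_spines, " non-overlapping spines", call. = FALSE)
}

# area-weighted sample of n surface nodes (without replacement)
sample_surface_nodes <- function(surface, n, replace = FALSE) {
  sample.int(nrow(surface$nodes), n, replace = replace,
             prob = surface$nodes$area_nm2)
}

# deposit particles at nodes with uniform jitter inside the voxel
jitter_at_nodes <- function(surface, node_idx) {
  s <- surface$spacing
  nd <- surface$nodes[node_idx, ]
  tibble::tibble(
    x_nm = nd$x + runif(length(node_idx), -s / 2, s / 2),
    y_nm = nd$y + runif(length(node_idx), -s / 2, s / 2),
    z_nm = nd$z + runif(length(node_idx), -s / 2, s / 2),
    node = nd$node
  )
}

#' Build a synthetic labeled scene with ground-truth particles
#'
#' Rasterizes a capped-cylinder shaft along a gently curved axis (plus sphere
#' head / cylinder neck spines for pyramidal scenes), paints synapse patches
#' on the membrane (one asymmetric patch per spine head; symmetric patches on
#' the shaft), then deposits plasma-membrane particles on the boundary
#' surface under the configured point process and intracellular particles in
#' the deep interior. Deterministic given `cfg$seed`.
#'
#' @param cfg A [scene_config()].
#' @return A list of class `synthetic_scene`: `volume` ([label_volume()],
#'   shaft = label 1, spines = labels 2..), `synapses` (patch label volume in
#'   the same frame), `synapse_meta`, `compartments` (label_id, kind,
#'   parent_id), `surfaces` (named list of `surface_graph`s), `particles`
#'   (particle table in nm), `ground_truth` (true compartment, localization,
#'   parent cluster id, surface node), and `config`.
#' @export
build_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  withr::with_seed(cfg$seed, build_scene_impl(cfg))
}

build_scene_impl <- function(cfg) {
  s <- cfg$spacing_nm
  reach <- if (cfg$n_spines > 0) {
    cfg$spine_neck_length_nm + 2 * cfg$spine_head_radius_nm
  } else 0
  margin <- 3 * s
  half_xy <- cfg$shaft_radius_nm + cfg$curve_amplitude_nm + reach + margin
  nx <- as.integer(ceiling(2 * half_xy / s))
  ny <- nx
  nz <- as.integer(ceiling(cfg$shaft_length_nm / s))
  cx <- nx * s / 2; cy <- ny * s / 2
  xc <- (seq_len(nx) - 0.5) * s
  yc <- (seq_len(ny) - 0.5) * s
  zc <- (seq_len(nz) - 0.5) * s

  labels <- array(0L, dim = c(ny, nx, nz))
  # shaft (label 1), slice by slice around the curved axis
  r2 <- cfg$shaft_radius_nm^2
  ax_all <- shaft_axis(cfg, zc, cx, cy)
  for (k in seq_len(nz)) {
    d2 <- outer((yc - ax_all[k, 2])^2, (xc - ax_all[k, 1])^2, "+")
    sl <- labels[, , k]
    sl[d2 <= r2] <- 1L
    labels[, , k] <- sl
  }

  compartments <- tibble::tibble(
    label_id = 1L,
    kind = if (cfg$kind == "pyramidal") "pyramidal_shaft" else "interneuron_shaft",
    parent_id = NA_integer_
  )

  spine_sites <- NULL
  spine_poles <- NULL
  if (cfg$n_spines > 0) {
    spine_sites <- sample_spine_sites(cfg, cx, cy)
    spine_poles <- matrix(0, cfg$n_spines, 3)
    for (i in seq_len(cfg$n_spines)) {
      zs <- spine_sites$z[i]; th <- spine_sites$theta[i]
      ax <- shaft_axis(cfg, zs, cx, cy)
      u <- c(cos(th), sin(th), 0)
      b <- c(ax[1, 1] + cfg$shaft_radius_nm * u[1],
             ax[1, 2] + cfg$shaft_radius_nm * u[2], zs)
      h <- b + (cfg$spine_neck_length_nm + cfg$spine_head_radius_nm) * u
      spine_poles[i, ] <- h + cfg$spine_head_radius_nm * u
      lab <- 1L + i
      # bounding box of neck + head
      lo <- pmin(b, h) - cfg$spine_head_radius_nm - s
      hi <- pmax(b, h) + cfg$spine_head_radius_nm + s
      ix <- which(xc >= lo[1] & xc <= hi[1])
      iy <- which(yc >= lo[2] & yc <= hi[2])
      iz <- which(zc >= lo[3] & zc <= hi[3])
      px <- rep(xc[ix], each = length(iy))
      py <- rep(yc[iy], times = length(ix))
      grid2 <- cbind(py, px)  # (iy, ix) pairs, column-major over the box
      for (k in iz) {
        p <- cbind(grid2[, 2], grid2[, 1], zc[k])
        rel <- sweep(p, 2, b)
        t_par <- rel %*% u
        perp2 <- rowSums(rel^2) - as.vector(t_par)^2
        in_neck <- t_par >= 0 & t_par <= cfg$spine_neck_length_nm &
          perp2 <= cfg$spine_neck_radius_nm^2
        in_head <- rowSums(sweep(p, 2, h)^2) <= cfg$spine_head_radius_nm^2
        hit <- which(in_neck | in_head)
        if (length(hit)) {
          sl <- labels[, , k]
          idx <- cbind(rep(iy, times = length(ix)), rep(ix, each = length(iy)))[hit, , drop = FALSE]
          cur <- sl[idx]
          idx <- idx[cur == 0L, , drop = FALSE]  # never overwrite the shaft
          sl[idx] <- lab
          labels[, , k] <- sl
        }
      }
      compartments <- dplyr::bind_rows(compartments, tibble::tibble(
        label_id = lab, kind = "spine", parent_id = 1L
      ))
    }
  }

  vol <- label_volume(labels, voxel_spacing(s, s, s))

  # synapse patches: boundary voxels of the target compartment within
  # synapse_radius_nm of an anchor point on the membrane
  syn <- array(0L, dim = dim(labels))
  syn_meta <- tibble::tibble(patch_id = integer(0), type = character(0),
                             compartment_id = integer(0))
  patch_id <- 0L
  paint_patch <- function(comp_id, anchor, type) {
    patch_id <<- patch_id + 1L
    mask <- labels == comp_id
    bidx <- which(exposed_faces(mask) > 0L)
    ai <- arrayInd(bidx, dim(labels))
    px <- (ai[, 2] - 0.5) * s; py <- (ai[, 1] - 0.5) * s; pz <- (ai[, 3] - 0.5) * s
    near <- (px - anchor[1])^2 + (py - anchor[2])^2 + (pz - anchor[3])^2 <=
      cfg$synapse_radius_nm^2
    sel <- bidx[near]
    sel <- sel[syn[sel] == 0L]
    syn[sel] <<- patch_id
    syn_meta <<- dplyr::bind_rows(syn_meta, tibble::tibble(
      patch_id = patch_id, type = type, compartment_id = comp_id
    ))
  }
  if (cfg$kind == "pyramidal" && cfg$n_spines > 0) {
    for (i in seq_len(cfg$n_spines)) {
      paint_patch(1L + i, spine_poles[i, ], "asymmetric")
    }
  } else if (cfg$kind == "interneuron" && cfg$n_asym_synapses > 0) {
    z <- runif(cfg$n_asym_synapses, margin, cfg$shaft_length_nm - margin)
    th <- runif(cfg$n_asym_synapses, 0, 2 * pi)
    ax <- shaft_axis(cfg, z, cx, cy)
    for (i in seq_along(z)) {
      anchor <- c(ax[i, 1] + cfg$shaft_radius_nm * cos(th[i]),
                  ax[i, 2] + cfg$shaft_radius_nm * sin(th[i]), z[i])
      paint_patch(1L, anchor, "asymmetric")
    }
  }
  if (cfg$n_sym_synapses > 0) {
    z <- runif(cfg$n_sym_synapses, margin, cfg$shaft_length_nm - margin)
    th <- runif(cfg$n_sym_synapses, 0, 2 * pi)
    ax <- shaft_axis(cfg, z, cx, cy)
    for (i in seq_along(z)) {
      anchor <- c(ax[i, 1] + cfg$shaft_radius_nm * cos(th[i]),
                  ax[i, 2] + cfg$shaft_radius_nm * sin(th[i]), z[i])
      paint_patch(1L, anchor, "symmetric")
    }
  }
  syn_vol <- label_volume(syn, voxel_spacing(s, s, s))

  surfaces <- lapply(compartments$label_id, function(id) extract_surface(vol, id))
  names(surfaces) <- as.character(compartments$label_id)

  particles <- tibble::tibble(
    particle_id = integer(0), x_nm = numeric(0), y_nm = numeric(0), z_nm = numeric(0)
  )
  truth <- tibble::tibble(
    particle_id = integer(0), compartment_id = integer(0),
    localization = character(0), parent_cluster = integer(0), node = integer(0)
  )
  if (cfg$place_particles) {
    pm <- place_pm_particles(cfg, surfaces, compartments)
    intra <- place_intra_particles(cfg, vol, compartments)
    all_p <- dplyr::bind_rows(pm, intra)
    if (nrow(all_p)) {
      all_p$particle_id <- seq_len(nrow(all_p))
      particles <- all_p[, c("particle_id", "x_nm", "y_nm", "z_nm")]
      truth <- all_p[, c("particle_id", "compartment_id", "localization",
                         "parent_cluster", "node")]
    }
  }

  structure(
    list(volume = vol, synapses = syn_vol, synapse_meta = syn_meta,
         compartments = compartments, surfaces = surfaces,
         particles = particles, ground_truth = truth, config = cfg),
    class = "synthetic_scene"
  )
}

# unseeded cores shared by build_scene and simulate_surface_pattern ---------

draw_pattern_csr <- function(surface, lambda_pm) {
  n <- rpois(1, lambda_pm * surface_area_nm2(surface) / 1e6)
  n <- min(n, nrow(surface$nodes))
  if (n == 0) {
    return(tibble::tibble(node = integer(0), parent = integer(0)))
  }
  tibble::tibble(node = sample_surface_nodes(surface, n), parent = NA_integer_)
}

draw_pattern_clustered <- function(surface, n_parents, offspring_per_parent,
                                   spread_nm, parent_offset = 0L) {
  w_area <- surface$nodes$area_nm2
  parent_nodes <- sample_surface_nodes(surface, n_parents)
  out <- vector("list", n_parents)
  for (j in seq_along(parent_nodes)) {
    dg <- as.numeric(igraph::distances(surface$graph, v = parent_nodes[j],
                                       to = surface$nodes$node))
    w <- w_area * exp(-dg^2 / (2 * spread_nm^2))
    w[!is.finite(w)] <- 0
    k <- min(offspring_per_parent, sum(w > 0))
    out[[j]] <- tibble::tibble(node = sample.int(length(w), k, prob = w),
                               parent = parent_offset + j)
  }
  dplyr::bind_rows(out)
}

#' Simulate a surface point pattern on an existing membrane surface
#'
#' Draws plasma-membrane particle positions (as surface node ids) on a
#' boundary-surface graph under either complete spatial randomness (nodes
#' sampled area-weighted, count `Poisson(lambda_pm x area)`) or the
#' Thomas-like clustered process (`n_parents` area-weighted parents, each with
#' `offspring_per_parent` offspring placed with geodesic Gaussian weight of
#' scale `offspring_spread_nm`). This is the same process [build_scene()] uses
#' for surface particles; exposing it lets power and calibration studies
#' redraw patterns on a fixed surface.
#'
#' @param surface A `surface_graph`.
#' @param model `"csr_surface"` or `"clustered_surface"`.
#' @param lambda_pm CSR intensity, gold/um^2.
#' @param n_parents,offspring_per_parent,offspring_spread_nm Clustered-model
#'   parameters.
#' @param seed Integer seed.
#' @return Tibble with `node` (surface node id) and `parent` (generating
#'   parent id, `NA` under CSR).
#' @export
simulate_surface_pattern <- function(surface,
                                     model = c("clustered_surface", "csr_surface"),
                                     lambda_pm = 8, n_parents = 10,
                                     offspring_per_parent = 5,
                                     offspring_spread_nm = 30, seed = 1L) {
  model <- match.arg(model)
  withr::with_seed(seed, {
    if (model == "csr_surface") {
      draw_pattern_csr(surface, lambda_pm)
    } else {
      draw_pattern_clustered(surface, n_parents, offspring_per_parent,
                             offspring_spread_nm)
    }
  })
}

# surface particles: CSR (area-weighted Poisson) or Thomas-like clusters with
# geodesic offspring spread
place_pm_particles <- function(cfg, surfaces, compartments) {
  areas_um2 <- vapply(surfaces, surface_area_nm2, numeric(1)) / 1e6
  out <- list()
  if (cfg$particle_model == "csr_surface") {
    for (i in seq_along(surfaces)) {
      drawn <- draw_pattern_csr(surfaces[[i]], cfg$lambda_pm)
      if (nrow(drawn) == 0) next
      pts <- jitter_at_nodes(surfaces[[i]], drawn$node)
      pts$compartment_id <- compartments$label_id[i]
      pts$localization <- "PM"
      pts$parent_cluster <- NA_integer_
      out[[length(out) + 1]] <- pts
    }
  } else {
    alloc <- as.vector(stats::rmultinom(1, cfg$n_parents, prob = areas_um2))
    parent_offset <- 0L
    for (i in seq_along(surfaces)) {
      if (alloc[i] == 0) next
      drawn <- draw_pattern_clustered(surfaces[[i]], alloc[i],
                                      cfg$offspring_per_parent,
                                      cfg$offspring_spread_nm, parent_offset)
      parent_offset <- parent_offset + alloc[i]
      pts <- jitter_at_nodes(surfaces[[i]], drawn$node)
      pts$compartment_id <- compartments$label_id[i]
      pts$localization <- "PM"
      pts$parent_cluster <- drawn$parent
      out[[length(out) + 1]] <- pts
    }
  }
  dplyr::bind_rows(out)
}

# intracellular particles: Poisson over the deep interior (voxels whose whole
# 26-neighborhood shares the label, so a jittered point stays > one voxel
# from every boundary node)
place_intra_particles <- function(cfg, vol, compartments) {
  s <- vol$spacing[["dx"]]
  out <- list()
  for (i in seq_len(nrow(compartments))) {
    id <- compartments$label_id[i]
    mask <- vol$labels == id
    vol_um3 <- sum(mask) * s^3 / 1e9
    n <- rpois(1, cfg$lambda_intra * vol_um3)
    if (n == 0) next
    boundary <- exposed_faces(mask) > 0L
    deep <- mask & !boundary
    for (oz in -1:1) for (oy in -1:1) for (ox in -1:1) {
      if (oz == 0 && oy == 0 && ox == 0) next
      deep <- deep & !shift_logical(boundary, oy, ox, oz)
    }
    idx <- which(deep)
    if (!length(idx)) {
      warning("compartment ", id, " has no deep interior; skipping ",
              "intracellular particles", call. = FALSE)
      next
    }
    pick <- idx[sample.int(length(idx), n, replace = TRUE)]
    ai <- arrayInd(pick, dim(mask))
    out[[length(out) + 1]] <- tibble::tibble(
      x_nm = (ai[, 2] - 0.5) * s + runif(n, -s / 2, s / 2),
      y_nm = (ai[, 1] - 0.5) * s + runif(n, -s / 2, s / 2),
      z_nm = (ai[, 3] - 0.5) * s + runif(n, -s / 2, s / 2),
      node = NA_integer_,
      compartment_id = id,
      localization = "intracellular",
      parent_cluster = NA_integer_
    )
  }
  dplyr::bind_rows(out)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %s dendrite: %d compartment(s), %d synapse patch(es), %d particle(s)\n",
              x$config$kind, nrow(x$compartments), nrow(x$synapse_meta),
              nrow(x$particles)))
  invisible(x)
}

#' Write a synthetic scene to disk in the pipeline's input formats
#'
#' Emits `volume.tif`, `synapses.tif`, `particles.csv`, `synapse_meta.csv`,
#' `compartments.csv` and `ground_truth.csv` under `dir`.
#'
#' @param scene A [build_scene()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_label_volume(scene$volume, file.path(dir, "volume.tif"))
  write_label_volume(scene$synapses, file.path(dir, "synapses.tif"))
  write_particle_table(scene$particles, file.path(dir, "particles.csv"))
  readr::write_csv(scene$synapse_meta, file.path(dir, "synapse_meta.csv"))
  readr::write_csv(scene$compartments, file.path(dir, "compartments.csv"))
  readr::write_csv(scene$ground_truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Simulate a spine population with particle counts proportional to volume
#'
#' Draws spine volumes from a lognormal distribution spanning the typical
#' 0.005-0.03 um^3 range of CA1 spines and particle counts from
#' `Poisson(lambda * volume)`, the generative model behind the observed
#' volume-count correlation and the excess of empty small spines.
#'
#' @param n Number of spines (default 84).
#' @param meanlog,sdlog Lognormal parameters of the volume distribution
#'   (defaults give a median of ~0.012 um^3).
#' @param lambda Particle intensity, gold/um^3 (default 312, the scale of
#'   per-spine densities in CA1 pyramidal cells).
#' @param seed Integer seed.
#' @return Tibble: `spine_id, volume_um3, n_gold`.
#' @export
simulate_spines <- function(n = 84, meanlog = log(0.012), sdlog = 0.6,
                            lambda = 312, seed = 1L) {
  withr::with_seed(seed, {
    vols <- stats::rlnorm(n, meanlog, sdlog)
    tibble::tibble(
      spine_id = seq_len(n),
      volume_um3 = vols,
      n_gold = rpois(n, lambda * vols)
    )
  })
}

#' Reference per-dendrite SK2 immunogold measurements
#'
#' Bundled per-dendrite measurements of SK2 immunogold labeling on six
#' 3D-reconstructed spiny (pyramidal-cell) dendrites and six smooth
#' (interneuron) dendrites from mouse CA1 stratum radiatum: plasma-membrane
#' (PM) and intracellular particle counts, compartment volumes, spine counts
#' and per-spine density summaries, together with the published group mean
#' densities and spine/synapse summary counts. These tables feed the worked
#' examples and validate the accounting functions against known printed
#' values.
#'
#' @return A named list of tibbles:
#' \describe{
#'   \item{pyramidal}{Per-dendrite shaft and spine counts, volumes and spine
#'     density summaries (6 dendrites).}
#'   \item{interneuron}{Per-dendrite counts and volumes for smooth dendrites
#'     (6 dendrites).}
#'   \item{group_densities}{Comparative group mean densities (gold/um^3) with
#'     SEM by compartment and localization.}
#'   \item{spine_summary}{Spine population counts and mean volumes of
#'     immunopositive vs immunonegative spines.}
#'   \item{synapse_counts}{Particles analyzed per synapse type and how many
#'     fell within / beyond the 660-nm profile limit.}
#' }
#' @export
sk2_dendrite_data <- function() {
  list(
    pyramidal = tibble::tibble(
      dendrite = 1:6,
      n_sections_shaft = c(147L, 115L, 171L, 156L, 79L, 155L),
      shaft_pm = c(444L, 353L, 167L, 48L, 48L, 152L),
      shaft_intra = c(778L, 217L, 550L, 1156L, 84L, 363L),
      shaft_volume_um3 = c(6.67, 3.76, 4.67, 3.74, 1.81, 4.24),
      n_spines = c(13L, 11L, 27L, 6L, 6L, 21L),
      spine_pm = c(98L, 49L, 118L, 14L, 14L, 105L),
      spine_intra = c(4L, 5L, 2L, 1L, 1L, 4L),
      spine_volume_um3 = c(0.25, 0.14, 0.35, 0.07, 0.06, 0.26),
      spine_density_mean = c(416.85, 354.45, 304.14, 119.52, 95.79, 352.94),
      spine_density_sem = c(30.77, 24.47, 45.46, 76.45, 60.80, 51.63)
    ),
    interneuron = tibble::tibble(
      dendrite = 1:6,
      n_sections = c(88L, 104L, 115L, 106L, 98L, 147L),
      volume_um3 = c(3.15, 3.46, 3.81, 3.77, 3.49, 5.24),
      pm = c(27L, 31L, 35L, 32L, 30L, 49L),
      intra = c(194L, 213L, 221L, 219L, 222L, 301L)
    ),
    group_densities = tibble::tibble(
      group = c("spine", "pyramidal_shaft", "interneuron_shaft",
                "spine", "pyramidal_shaft", "interneuron_shaft"),
      localization = c("PM", "PM", "PM",
                       "intracellular", "intracellular", "intracellular"),
      mean_density = c(423.1, 102.4, 8.9, 17.5, 125.6, 60.0),
      sem = c(15.13, 46.43, 0.1, 4.1, 38.2, 1.0),
      n = c(62L, 6L, 6L, NA_integer_, NA_integer_, NA_integer_)
    ),
    spine_summary = tibble::tibble(
      n_spines = 84L, n_immunonegative = 22L,
      mean_volume_positive_um3 = 0.0152, sem_volume_positive_um3 = 0.001,
      mean_volume_negative_um3 = 0.0079, sem_volume_negative_um3 = 0.001
    ),
    synapse_counts = tibble::tibble(
      type = c("asymmetric", "symmetric"),
      n_analyzed = c(1631L, 610L),
      n_within_660 = c(771L, 154L),
      n_beyond_660 = c(860L, 456L)
    )
  )
}
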