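# Particle-to-compartment assignment and PM/intracellular classification.
#
# "Contact with the plasma membrane" is operationalized as lying within
# pm_contact_radius (default 20 nm, one isotropic voxel) of the nearest
# boundary-surface node. The criterion in the source imaging workflow is
# visual; 20 nm matches both the z-resolution and the scale of a
# silver-enhanced gold particle.

#' Assign particles to compartments by containing voxel
#'
#' Each particle is assigned the label of the voxel containing its (x, y, z)
#' position. Particles falling in background are assigned the label of the
#' nearest labeled voxel within `pm_contact_radius` (ties broken toward the
#' closer voxel center, then the lower label id); otherwise they are left
#' unassigned (`NA`) and counted in a message.
#'
#' @param particles Tibble with `particle_id, x_nm, y_nm, z_nm`.
#' @param vol An isotropic [label_volume()].
#' @param pm_contact_radius Search radius for background particles, nm.
#' @return `particles` with a `compartment_id` column added/overwritten.
#' @export
assign_compartments <- function(particles, vol, pm_contact_radius = 20) {
  d <- dim(vol$labels)
  s <- vol$spacing
  ext <- volume_extent(vol)
  out_of_bounds <- particles$x_nm < 0 | particles$x_nm > ext[["x"]] |
    particles$y_nm < 0 | particles$y_nm > ext[["y"]] |
    particles$z_nm < 0 | particles$z_nm > ext[["z"]]
  if (any(out_of_bounds)) {
    stop(sum(out_of_bounds), " particle(s) outside the volume's physical bounds",
         call. = FALSE)
  }
  ix <- pmin(floor(particles$x_nm / s[["dx"]]), d[2] - 1) + 1
  iy <- pmin(floor(particles$y_nm / s[["dy"]]), d[1] - 1) + 1
  iz <- pmin(floor(particles$z_nm / s[["dz"]]), d[3] - 1) + 1
  lab <- vol$labels[cbind(iy, ix, iz)]
  comp <- ifelse(lab > 0L, lab, NA_integer_)

  # rescue background particles within the contact radius
  bg <- which(lab == 0L)
  if (length(bg)) {
    rx <- ceiling(pm_contact_radius / s[["dx"]])
    ry <- ceiling(pm_contact_radius / s[["dy"]])
    rz <- ceiling(pm_contact_radius / s[["dz"]])
    offs <- expand.grid(oy = -ry:ry, ox = -rx:rx, oz = -rz:rz)
    for (i in bg) {
      jy <- iy[i] + offs$oy; jx <- ix[i] + offs$ox; jz <- iz[i] + offs$oz
      ok <- jy >= 1 & jy <= d[1] & jx >= 1 & jx <= d[2] & jz >= 1 & jz <= d[3]
      if (!any(ok)) next
      cand_lab <- vol$labels[cbind(jy[ok], jx[ok], jz[ok])]
      pos <- cand_lab > 0L
      if (!any(pos)) next
      cx <- (jx[ok][pos] - 0.5) * s[["dx"]]
      cy <- (jy[ok][pos] - 0.5) * s[["dy"]]
      cz <- (jz[ok][pos] - 0.5) * s[["dz"]]
      dist <- sqrt((cx - particles$x_nm[i])^2 + (cy - particles$y_nm[i])^2 +
                     (cz - particles$z_nm[i])^2)
      within <- dist <= pm_contact_radius
      if (!any(within)) next
      cand <- tibble::tibble(lab = cand_lab[pos][within], dist = dist[within])
      cand <- cand[order(cand$dist, cand$lab), ]
      comp[i] <- cand$lab[1]
    }
  }
  n_un <- sum(is.na(comp))
  if (n_un > 0) message(n_un, " particle(s) unassigned (background beyond contact radius)")
  particles$compartment_id <- as.integer(comp)
  particles
}

#' Classify particles as plasma-membrane-bound or intracellular
#'
#' A particle is `PM` iff its distance to the nearest node of its
#' compartment's boundary surface is at most `pm_contact_radius`; otherwise it
#' is `intracellular`. The nearest surface node (the particle's projection for
#' geodesic work) and the distance are stored for every particle.
#'
#' @param particles Tibble with `particle_id, x_nm, y_nm, z_nm,
#'   compartment_id`; every row must belong to `surface$compartment_id`.
#' @param surface A [extract_surface()] result for that compartment.
#' @param pm_contact_radius Contact radius in nm (default 20, one voxel).
#' @return `particles` with columns `localization`, `nearest_surface_node`,
#'   `dist_to_surface_nm` added.
#' @export
classify_localization <- function(particles, surface, pm_contact_radius = 20) {
  if (pm_contact_radius < 0) stop("pm_contact_radius must be >= 0", call. = FALSE)
  if (!"compartment_id" %in% names(particles)) {
    stop("particles must be assigned to compartments first", call. = FALSE)
  }
  if (!all(particles$compartment_id == surface$compartment_id, na.rm = FALSE)) {
    stop("all particles must belong to compartment ", surface$compartment_id,
         call. = FALSE)
  }
  np <- nrow(particles)
  nn_node <- integer(np); nn_dist <- numeric(np)
  nx <- surface$nodes$x; ny <- surface$nodes$y; nz <- surface$nodes$z
  chunk <- max(1L, floor(2e7 / length(nx)))
  for (start in seq(1, np, by = chunk)) {
    rows <- start:min(np, start + chunk - 1)
    dx <- outer(particles$x_nm[rows], nx, "-")
    dy <- outer(particles$y_nm[rows], ny, "-")
    dz <- outer(particles$z_nm[rows], nz, "-")
    d2 <- dx * dx + dy * dy + dz * dz
    j <- max.col(-d2, ties.method = "first")
    nn_node[rows] <- j
    nn_dist[rows] <- sqrt(d2[cbind(seq_along(rows), j)])
  }
  particles$localization <- ifelse(nn_dist <= pm_contact_radius, "PM", "intracellular")
  particles$nearest_surface_node <- nn_node
  particles$dist_to_surface_nm <- nn_dist
  particles
}

#' Assign and classify all particles against a set of surfaces
#'
#' Convenience wrapper: assigns compartments from the label volume, then
#' classifies PM vs intracellular per compartment using the matching surface.
#' Unassigned particles keep `NA` localization.
#'
#' @param particles Tibble with `particle_id, x_nm, y_nm, z_nm`.
#' @param vol An isotropic [label_volume()].
#' @param surfaces Named list of `surface_graph`s keyed by compartment id
#'   (names coercible to integer), or a list searched by `compartment_id`.
#' @param pm_contact_radius Contact radius, nm.
#' @return Augmented particle tibble with `compartment_id`, `localization`,
#'   `nearest_surface_node`, `dist_to_surface_nm`.
#' @export
classify_particles <- function(particles, vol, surfaces, pm_contact_radius = 20) {
  particles <- assign_compartments(particles, vol, pm_contact_radius)
  surf_ids <- vapply(surfaces, function(s) as.integer(s$compartment_id), integer(1))
  particles$localization <- NA_character_
  particles$nearest_surface_node <- NA_integer_
  particles$dist_to_surface_nm <- NA_real_
  for (cid in unique(stats::na.omit(particles$compartment_id))) {
    k <- which(surf_ids == cid)
    if (!length(k)) stop("no surface supplied for compartment ", cid, call. = FALSE)
    rows <- which(particles$compartment_id == cid)
    cls <- classify_localization(particles[rows, ], surfaces[[k[1]]], pm_contact_radius)
    particles$localization[rows] <- cls$localization
    particles$nearest_surface_node[rows] <- cls$nearest_surface_node
    particles$dist_to_surface_nm[rows] <- cls$dist_to_surface_nm
  }
  particles
}
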