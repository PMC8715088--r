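# Shared fixtures, built once per test run and memoized.

.scene_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .scene_cache)) {
    assign(name, builder(), envir = .scene_cache)
  }
  get(name, envir = .scene_cache)
}

# small spiny dendrite with clustered surface particles
clustered_scene <- function() cached("clustered", function() {
  build_scene(scene_config(
    kind = "pyramidal", n_spines = 3, shaft_length_nm = 2000,
    shaft_radius_nm = 300, n_parents = 10, offspring_per_parent = 5,
    offspring_spread_nm = 30, lambda_intra = 120, seed = 42
  ))
})

# same geometry under complete spatial randomness
csr_scene <- function() cached("csr", function() {
  build_scene(scene_config(
    kind = "pyramidal", n_spines = 3, shaft_length_nm = 2000,
    shaft_radius_nm = 300, particle_model = "csr_surface", lambda_pm = 30,
    lambda_intra = 120, seed = 43
  ))
})

# smooth interneuron dendrite at reference scale (volume ~pi r^2 L = 3.14 um^3)
interneuron_scene <- function() cached("interneuron", function() {
  build_scene(scene_config(
    kind = "interneuron", shaft_radius_nm = 500, shaft_length_nm = 4000,
    particle_model = "csr_surface", lambda_pm = 5, lambda_intra = 120,
    seed = 44
  ))
})

# rasterized sphere surface (r nm, 20-nm voxels); small enough for the
# brute-force all-pairs oracle
sphere_surface <- function(r = 100) cached(paste0("sphere", r), function() {
  s <- 20
  n <- ceiling(2 * (r + 2 * s) / s)
  c0 <- n * s / 2
  xc <- (seq_len(n) - 0.5) * s
  a <- array(0L, dim = c(n, n, n))
  for (k in seq_len(n)) {
    d2 <- outer((xc - c0)^2, (xc - c0)^2, "+") + (xc[k] - c0)^2
    sl <- a[, , k]; sl[d2 <= r^2] <- 1L; a[, , k] <- sl
  }
  extract_surface(label_volume(a, voxel_spacing(s, s, s)), 1L)
})

# one-voxel-thick flat sheet (nx x ny voxels, 20 nm); its surface graph is
# used for in-plane geodesic checks
sheet_volume <- function(nx, ny) {
  a <- array(0L, dim = c(ny, nx, 3))
  a[, , 2] <- 1L
  label_volume(a, voxel_spacing(20, 20, 20))
}

sheet_surface <- function(nx = 40, ny = 40) {
  cached(paste0("sheet", nx, "x", ny), function() {
    extract_surface(sheet_volume(nx, ny), 1L)
  })
}

# node ids of the sheet's top face (exposed upward, z index 2, interior rows)
sheet_top_nodes <- function(surface) {
  nd <- surface$nodes
  nd$node[nd$iz == 2]
}
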