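test_that("scene configuration validates and normalizes its parameters", {
  expect_error(scene_config(shaft_radius_nm = -1), "positive")
  cfg <- scene_config(kind = "interneuron", n_spines = 13)
  expect_equal(cfg$n_spines, 0L)   # smooth dendrites carry no spines
  expect_s3_class(cfg, "scene_config")
})

test_that("a spiny scene carries one spine label and one asymmetric patch per spine", {
  sc <- clustered_scene()
  n_spines <- sc$config$n_spines
  spine_rows <- sc$compartments[sc$compartments$kind == "spine", ]
  expect_equal(nrow(spine_rows), n_spines)
  expect_true(all(spine_rows$parent_id == 1L))
  asym <- sc$synapse_meta[sc$synapse_meta$type == "asymmetric", ]
  expect_equal(nrow(asym), n_spines)
  expect_setequal(asym$compartment_id, spine_rows$label_id)
  sym <- sc$synapse_meta[sc$synapse_meta$type == "symmetric", ]
  expect_true(all(sym$compartment_id == 1L))
  # every patch paints at least one voxel, and patch voxels sit on boundary
  # voxels of their compartment
  for (i in seq_len(nrow(sc$synapse_meta))) {
    pid <- sc$synapse_meta$patch_id[i]
    cid <- sc$synapse_meta$compartment_id[i]
    vox <- which(sc$synapses$labels == pid)
    expect_gt(length(vox), 0)
    expect_true(all(sc$volume$labels[vox] == cid))
  }
})

test_that("scene generation is byte-deterministic under its seed", {
  cfg <- scene_config(kind = "pyramidal", n_spines = 2, shaft_length_nm = 1200,
                      shaft_radius_nm = 240, seed = 17)
  s1 <- build_scene(cfg)
  s2 <- build_scene(cfg)
  expect_identical(s1$volume$labels, s2$volume$labels)
  expect_identical(s1$synapses$labels, s2$synapses$labels)
  expect_identical(s1$particles, s2$particles)
  expect_identical(s1$ground_truth, s2$ground_truth)

  s3 <- build_scene(scene_config(kind = "pyramidal", n_spines = 2,
                                 shaft_length_nm = 1200,
                                 shaft_radius_nm = 240, seed = 18))
  expect_false(identical(s1$particles, s3$particles))
})

test_that("CSR surface counts hit the intensity target within Poisson error", {
  sc <- csr_scene()
  lambda <- sc$config$lambda_pm
  target <- lambda * sum(vapply(sc$surfaces, surface_area_nm2, numeric(1))) / 1e6
  realized <- sum(sc$ground_truth$localization == "PM")
  expect_lt(abs(realized - target), 3 * sqrt(target))
})

test_that("intracellular intensity is recoverable from a reference-scale shaft", {
  sc <- interneuron_scene()
  vol_um3 <- measure_compartment(sc$volume, 1L)$volume_um3
  expect_gte(vol_um3, 3)
  n_intra <- sum(sc$ground_truth$localization == "intracellular")
  lambda_hat <- n_intra / vol_um3
  expect_lt(abs(lambda_hat - sc$config$lambda_intra) / sc$config$lambda_intra,
            0.15)
})

test_that("every emitted particle is geometrically consistent with its class", {
  sc <- clustered_scene()
  truth <- sc$ground_truth
  parts <- sc$particles
  for (cid in unique(truth$compartment_id)) {
    surf <- sc$surfaces[[as.character(cid)]]
    rows <- truth$compartment_id == cid
    p <- parts[rows, ]
    dx <- outer(p$x_nm, surf$nodes$x, "-")
    dy <- outer(p$y_nm, surf$nodes$y, "-")
    dz <- outer(p$z_nm, surf$nodes$z, "-")
    dmin <- sqrt(apply(dx^2 + dy^2 + dz^2, 1, min))
    is_pm <- truth$localization[rows] == "PM"
    expect_true(all(dmin[is_pm] <= 20))
    expect_true(all(dmin[!is_pm] > 20))
  }
  # clustered particles carry their generating parent id
  pm <- truth[truth$localization == "PM", ]
  expect_true(all(!is.na(pm$parent_cluster)))
  expect_lte(max(table(pm$parent_cluster)), sc$config$offspring_per_parent)
})

test_that("clustered scenes recover the generated cluster-size range", {
  sc <- clustered_scene()
  truth <- sc$ground_truth
  shaft_pm <- truth[truth$compartment_id == 1L & truth$localization == "PM", ]
  nnd <- nnd_analysis(sc$surfaces[["1"]], shaft_pm$node)
  cs <- call_clusters(sc$surfaces[["1"]], shaft_pm$node, nnd)
  sizes <- cs$members$group_size[!duplicated(cs$members$group)]
  clusters <- sizes[sizes >= 3]
  expect_gt(length(clusters), 0)
  # most recovered clusters stay in the generated 3-8 particle range
  expect_gte(mean(clusters >= 3 & clusters <= 8), 0.6)
})

test_that("the reference tables are internally consistent", {
  ref <- sk2_dendrite_data()
  pyr <- ref$pyramidal
  expect_equal(sum(pyr$shaft_pm), 1212)
  expect_equal(sum(pyr$shaft_intra), 3148)
  expect_equal(sum(pyr$spine_pm), 398)
  expect_equal(sum(pyr$spine_intra), 17)
  expect_equal(sum(pyr$n_spines), 84)
  expect_equal(sum(pyr$spine_volume_um3), 1.13)
  expect_equal(sum(ref$interneuron$pm) + sum(ref$interneuron$intra), 1574)
  # per-spine (count-weighted) pooling of the per-dendrite spine densities
  pooled <- sum(pyr$spine_density_mean * pyr$n_spines) / sum(pyr$n_spines)
  expect_equal(round(pooled, 1), 312.3)
  sy <- ref$synapse_counts
  expect_equal(sy$n_within_660 + sy$n_beyond_660, sy$n_analyzed)
})
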