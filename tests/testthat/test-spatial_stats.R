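test_that("geodesic distances match a brute-force all-pairs oracle", {
  surf <- sphere_surface(100)
  expect_lte(nrow(surf$nodes), 500)
  D_oracle <- oracle_all_pairs(surf)

  expect_equal(geodesic_distance(surf, 3, 3), 0)
  # two face-adjacent nodes one voxel apart
  nd <- surf$nodes
  pair <- NULL
  for (i in seq_len(nrow(nd))) {
    j <- which(nd$ix == nd$ix[i] + 1 & nd$iy == nd$iy[i] & nd$iz == nd$iz[i])
    if (length(j)) { pair <- c(i, j[1]); break }
  }
  expect_equal(geodesic_distance(surf, pair[1], pair[2]), 20)

  set.seed(11)
  pick <- sample(nrow(nd), 25)
  expect_equal(surface_distances(surf, pick, pick),
               D_oracle[pick, pick], tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(geodesic_distance(surf, 1, nrow(nd) + 10), "outside")
})

test_that("geodesic metric is symmetric, triangular and dominates Euclidean", {
  surf <- sphere_surface(100)
  set.seed(12)
  for (trial in 1:20) {
    ijk <- sample(nrow(surf$nodes), 3)
    d <- surface_distances(surf, ijk, ijk)
    expect_equal(d, t(d), tolerance = 1e-12)
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-9)
    nd <- surf$nodes[ijk, ]
    expect_gte(d[1, 2], sqrt(sum((nd[1, c("x", "y", "z")] - nd[2, c("x", "y", "z")])^2)) - 1e-9)
  }
})

test_that("NND analysis matches the O(n^2) pairwise oracle", {
  surf <- sphere_surface(100)
  D_oracle <- oracle_all_pairs(surf)
  set.seed(13)
  for (n in c(2, 10, 30)) {
    idx <- sample(nrow(surf$nodes), n)
    res <- nnd_analysis(surf, idx)
    expect_equal(res$nnd$nnd_nm, unname(oracle_nnd(D_oracle, idx)), tolerance = 1e-12)
    expect_equal(res$mean_nnd, mean(res$nnd$nnd_nm))
    expect_equal(res$sd_nnd, sd(res$nnd$nnd_nm))
    if (n == 2) {
      # with two particles both NNDs equal their pairwise geodesic distance
      expect_equal(res$nnd$nnd_nm[1], res$nnd$nnd_nm[2])
      expect_equal(res$nnd$nnd_nm[1], geodesic_distance(surf, idx[1], idx[2]))
    }
  }
  expect_error(nnd_analysis(surf, 5), "at least 2")
})

test_that("on a flat sheet the chamfer metric stays within 8% of Euclidean", {
  surf <- sheet_surface(60, 60)
  top <- sheet_top_nodes(surf)
  set.seed(14)
  idx <- sample(top, 40)
  res <- nnd_analysis(surf, idx)
  nd <- surf$nodes[idx, ]
  E <- as.matrix(stats::dist(cbind(nd$x, nd$y, nd$z)))
  diag(E) <- Inf
  nnd_euclid <- apply(E, 1, min)
  ratio <- res$nnd$nnd_nm / nnd_euclid
  expect_true(all(ratio >= 1 - 1e-9))
  expect_lt(mean(res$nnd$nnd_nm) / mean(nnd_euclid), 1.08)
})

test_that("randomization test honors its p-value and z-score contracts", {
  surf <- sphere_surface(100)
  set.seed(15)
  idx <- sample(nrow(surf$nodes), 15)
  r <- randomization_test(surf, idx, reps = 50, seed = 99)
  expect_equal(r$p_empirical,
               (1 + sum(r$null_means <= r$observed_mean_nnd)) / (r$reps + 1))
  expect_gt(r$p_empirical, 0); expect_lte(r$p_empirical, 1)
  expect_equal(r$z_score, (r$observed_mean_nnd - r$null_mean) / r$null_sd)
  expect_length(r$null_means, 50)

  # reproducible under seed; both fast paths agree exactly
  r2 <- randomization_test(surf, idx, reps = 50, seed = 99)
  expect_identical(r$null_means, r2$null_means)
  r3 <- randomization_test(surf, idx, reps = 50, seed = 99, max_matrix_nodes = 1)
  expect_equal(r$null_means, r3$null_means, tolerance = 1e-12)

  # degenerate single replicate: no SD, no z
  r1 <- randomization_test(surf, idx, reps = 1, seed = 3)
  expect_true(r1$degenerate)
  expect_true(is.na(r1$z_score))

  expect_error(randomization_test(surf, idx, reps = 0), "reps")
  expect_error(randomization_test(surf, seq_len(nrow(surf$nodes) + 1)), "outside")
})

test_that("a strongly clustered pattern beats every random replicate", {
  sc <- clustered_scene()
  truth <- sc$ground_truth
  shaft_pm <- truth[truth$compartment_id == 1L & truth$localization == "PM", ]
  r <- randomization_test(sc$surfaces[["1"]], shaft_pm$node, reps = 100, seed = 5)
  expect_lt(r$observed_mean_nnd, min(r$null_means))
  expect_equal(r$p_empirical, 1 / 101)
  expect_lt(r$z_score, -2)
})

test_that("cluster calling partitions particles and merges monotonically", {
  surf <- sheet_surface(100, 100)
  nd <- surf$nodes
  pick_top <- function(ix, iy) nd$node[nd$ix == ix & nd$iy == iy & nd$iz == 2][1]
  # three tight triplets plus one moderately remote particle: the triplet
  # separations exceed mean + 2 SD of the NNDs, the remote one stays scattered
  triplet <- function(ix, iy) c(pick_top(ix, iy), pick_top(ix + 1, iy),
                                pick_top(ix, iy + 1))
  nodes <- c(triplet(5, 5), triplet(5, 80), triplet(80, 5), pick_top(80, 30))
  nnd <- nnd_analysis(surf, nodes)
  cs <- call_clusters(surf, nodes, nnd)
  expect_equal(cs$n_clusters, 3)
  expect_equal(cs$scattered_count, 1)
  expect_setequal(cs$members$group_size, c(3L, 1L))
  # a partition: every particle in exactly one group
  expect_equal(nrow(cs$members), 10)
  expect_equal(sum(cs$members$group_size[!duplicated(cs$members$group)]), 10)

  # equal-NND pairs far apart: groups of 2 only, so zero clusters and
  # every particle counts as scattered
  pairs <- c(pick_top(5, 5), pick_top(6, 5), pick_top(70, 70), pick_top(71, 70))
  nnd_pairs <- nnd_analysis(surf, pairs)
  cs_pairs <- call_clusters(surf, pairs, nnd_pairs)
  expect_equal(cs_pairs$n_clusters, 0)
  expect_equal(cs_pairs$scattered_count, 4)
  expect_true(all(cs_pairs$members$group_size == 2L))

  # merging is monotone in the threshold: plus2sd can only coarsen minus2sd
  set.seed(16)
  rnd <- sample(nd$node[nd$iz == 2], 25)
  nnd_r <- nnd_analysis(surf, rnd)
  if (nnd_r$mean_nnd - 2 * nnd_r$sd_nnd > 0) {
    lo <- call_clusters(surf, rnd, nnd_r, rule = "minus2sd")
    hi <- call_clusters(surf, rnd, nnd_r, rule = "plus2sd")
    expect_gte(max(lo$members$group), max(hi$members$group))
    # groups at the low threshold are nested inside groups at the high one
    nesting <- tapply(hi$members$group, lo$members$group,
                      function(g) length(unique(g)))
    expect_true(all(nesting == 1))
  }
})

test_that("the cluster rule rejects non-positive thresholds", {
  surf <- sheet_surface(60, 60)
  nd <- surf$nodes
  # two tight pairs far apart: SD of NND ~ 0 is fine, but a contrived nnd
  # object with mean < 2 SD must be rejected under minus2sd
  fake <- structure(list(nnd = NULL, mean_nnd = 10, sd_nnd = 20, n = 4),
                    class = "nnd_result")
  nodes <- nd$node[nd$iz == 2][1:4]
  expect_error(call_clusters(surf, nodes, fake, rule = "minus2sd"),
               "not positive")
})

test_that("synapse profiles bin geodesic distances to the patch edge", {
  vol <- sheet_volume(80, 80)
  surf <- extract_surface(vol, 1L)
  nd <- surf$nodes
  # circular patch of radius 100 nm in the center of the top face
  syn <- array(0L, dim = dim(vol$labels))
  ctr <- c(40, 40) * 20 - 10
  on_top <- nd$iz == 2
  in_patch <- on_top & sqrt((nd$x - ctr[1])^2 + (nd$y - ctr[2])^2) <= 100
  syn[cbind(nd$iy[in_patch], nd$ix[in_patch], nd$iz[in_patch])] <- 1L
  syn_vol <- label_volume(syn, voxel_spacing(20, 20, 20))
  meta <- tibble::tibble(patch_id = 1L, type = "asymmetric", compartment_id = 1L)

  # particle inside the patch -> 0; a particle one voxel off the edge -> first bin
  inside_node <- nd$node[in_patch][1]
  edge_x <- max(nd$ix[in_patch])
  off_edge <- nd$node[on_top & nd$ix == edge_x + 1 &
                        nd$iy == nd$iy[nd$node == inside_node][1]][1]
  far_node <- nd$node[on_top & nd$ix == 75 & nd$iy == 75][1]
  prof <- synapse_profile(surf, c(inside_node, off_edge, far_node),
                          syn_vol, meta, type = "asymmetric")
  expect_equal(nrow(prof$bins), 11)
  expect_equal(prof$distances$dist_nm[1], 0)
  expect_lt(prof$distances$dist_nm[2], 60)
  expect_equal(prof$n_within + prof$n_beyond, prof$n_total)
  expect_equal(sum(prof$bins$prop_within), 1, tolerance = 1e-9)

  # no patch of the requested type: empty profile with a warning
  expect_warning(
    empty <- synapse_profile(surf, c(inside_node, far_node), syn_vol, meta,
                             type = "symmetric"),
    "no synapse patch"
  )
  expect_equal(empty$n_total, 0)
  expect_equal(sum(empty$bins$count), 0)
})

test_that("profile proportions on a uniform sheet track annulus areas", {
  vol <- sheet_volume(100, 100)
  surf <- extract_surface(vol, 1L)
  nd <- surf$nodes
  ctr <- c(50, 50) * 20 - 10
  rad <- sqrt((nd$x - ctr[1])^2 + (nd$y - ctr[2])^2)
  on_top <- nd$iz == 2
  in_patch <- on_top & rad <= 100
  syn <- array(0L, dim = dim(vol$labels))
  syn[cbind(nd$iy[in_patch], nd$ix[in_patch], nd$iz[in_patch])] <- 1L
  syn_vol <- label_volume(syn, voxel_spacing(20, 20, 20))
  meta <- tibble::tibble(patch_id = 1L, type = "asymmetric", compartment_id = 1L)

  # every top-face node outside the patch and fully inside the sheet acts as a
  # particle: uniform coverage with no Monte-Carlo sampling error
  eligible <- nd$node[on_top & !in_patch & rad <= 900]
  prof <- synapse_profile(surf, eligible, syn_vol, meta, type = "asymmetric")

  r0 <- 100
  edges <- r0 + seq(0, 660, by = 60)
  analytic <- diff(edges^2) / (edges[12]^2 - edges[1]^2)
  dev <- abs(prof$bins$prop_within - analytic)
  expect_lt(max(dev), 0.05)
  expect_lt(mean(dev), 0.025)
  # proportions grow with annulus area from the first to the last bin
  expect_gt(prof$bins$prop_within[11], prof$bins$prop_within[1])
})
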