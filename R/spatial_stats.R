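# Geodesic NND analysis, Monte-Carlo randomness testing, cluster calling and
# distance-to-synapse profiling on membrane surface graphs.

check_nodes <- function(surface, nodes) {
  n_nodes <- nrow(surface$nodes)
  if (any(is.na(nodes)) || any(nodes < 1) || any(nodes > n_nodes)) {
    stop("node id(s) outside the surface graph", call. = FALSE)
  }
  as.integer(nodes)
}

#' Geodesic distance between surface nodes
#'
#' Shortest-path distance along the boundary-voxel graph (Dijkstra on
#' positive Euclidean edge weights). `Inf` if the nodes lie on disconnected
#' surface components.
#'
#' @param surface A `surface_graph`.
#' @param node_a,node_b Node ids (vectors allowed; result is a matrix if both
#'   have length > 1).
#' @return Numeric distances in nm (scalar, vector or matrix).
#' @export
geodesic_distance <- function(surface, node_a, node_b) {
  node_a <- check_nodes(surface, node_a)
  node_b <- check_nodes(surface, node_b)
  d <- igraph::distances(surface$graph, v = node_a, to = node_b)
  if (length(node_a) == 1 && length(node_b) == 1) as.numeric(d) else d
}

#' All-pairs geodesic distances between two node sets
#' @param surface A `surface_graph`.
#' @param from,to Node id vectors (default: all nodes).
#' @return A `length(from) x length(to)` matrix of nm distances.
#' @export
surface_distances <- function(surface, from = NULL, to = NULL) {
  if (is.null(from)) from <- surface$nodes$node
  if (is.null(to)) to <- surface$nodes$node
  igraph::distances(surface$graph, v = check_nodes(surface, from),
                    to = check_nodes(surface, to))
}

# per-particle nearest-neighbor distance from a pairwise distance matrix
# (self-pairs masked; duplicate projections at the same node give NND 0)
nnd_from_matrix <- function(D) {
  diag(D) <- Inf
  apply(D, 1, min)
}

#' Geodesic nearest-neighbor distance analysis
#'
#' For each plasma-membrane particle (projected to its nearest surface node),
#' computes the geodesic distance to its closest neighboring particle via
#' multi-source shortest paths, then the mean and sample SD.
#'
#' @param surface A `surface_graph`.
#' @param nodes Surface node ids of the PM particles (length >= 2).
#' @param particle_id Optional particle ids (defaults to `seq_along(nodes)`).
#' @return An object of class `nnd_result`: list with `nnd` (tibble:
#'   `particle_id, node, nnd_nm`), `mean_nnd`, `sd_nnd`, `n`.
#' @export
nnd_analysis <- function(surface, nodes, particle_id = NULL) {
  nodes <- check_nodes(surface, nodes)
  n <- length(nodes)
  if (n < 2) stop("NND analysis needs at least 2 particles", call. = FALSE)
  if (is.null(particle_id)) particle_id <- seq_len(n)
  D <- igraph::distances(surface$graph, v = nodes, to = nodes)
  nnd <- nnd_from_matrix(D)
  structure(
    list(
      nnd = tibble::tibble(particle_id = particle_id, node = nodes, nnd_nm = nnd),
      mean_nnd = mean(nnd),
      sd_nnd = stats::sd(nnd),
      n = n
    ),
    class = "nnd_result"
  )
}

#' @export
print.nnd_result <- function(x, ...) {
  cat(sprintf("<nnd_result> n = %d particles, mean NND %.1f nm (SD %.1f)\n",
              x$n, x$mean_nnd, x$sd_nnd))
  invisible(x)
}

# mean NND per replicate given sampled row/col indices into a distance matrix
null_mean_from_idx <- function(Dfull, idx) {
  mean(nnd_from_matrix(Dfull[idx, idx, drop = FALSE]))
}

#' Monte-Carlo test of complete spatial randomness for surface particles
#'
#' Compares the observed mean geodesic NND against a null distribution built
#' from `reps` random placements of the same number of particles on the same
#' membrane surface: each replicate draws `n` distinct surface nodes with
#' probability proportional to node area (exposed-face area, approximating
#' uniformity over the continuous membrane) and recomputes the mean NND.
#' Reports the z-score `(observed - null mean) / null SD` and the add-one
#' empirical p-value `(1 + #\{null <= observed\}) / (reps + 1)` for the
#' one-sided "closer than random" (clustering) alternative.
#'
#' On surfaces of at most `max_matrix_nodes` nodes the full node-to-node
#' geodesic matrix is precomputed once and replicates are evaluated by
#' indexing; larger surfaces use multi-source Dijkstra from the union of
#' sampled nodes. Results are identical either way and reproducible under
#' `seed`.
#'
#' @param surface A `surface_graph`.
#' @param nodes Observed PM particle node ids (length >= 2).
#' @param reps Number of null replicates (default 100).
#' @param seed Integer seed for the null placements.
#' @param max_matrix_nodes Surface size cutoff for the precomputed-matrix
#'   fast path.
#' @param dist_full Optional full node-to-node geodesic matrix (as returned
#'   by [surface_distances()]) to reuse across repeated calls on the same
#'   surface, e.g. in calibration studies. Results are identical with or
#'   without it.
#' @return An object of class `randomization_result`: `observed_mean_nnd`,
#'   `null_means`, `null_mean`, `null_sd`, `z_score`, `p_empirical`, `reps`,
#'   `n`, `seed`, `degenerate` (TRUE when `reps == 1`, where no null SD or z
#'   exists).
#' @export
randomization_test <- function(surface, nodes, reps = 100, seed = 1L,
                               max_matrix_nodes = 4000, dist_full = NULL) {
  nodes <- check_nodes(surface, nodes)
  n <- length(nodes)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (n < 2) stop("randomization test needs at least 2 particles", call. = FALSE)
  n_nodes <- nrow(surface$nodes)
  if (n > n_nodes) stop("more particles than surface nodes", call. = FALSE)

  observed <- if (is.null(dist_full)) {
    nnd_analysis(surface, nodes)$mean_nnd
  } else {
    mean(nnd_from_matrix(dist_full[nodes, nodes, drop = FALSE]))
  }
  w <- surface$nodes$area_nm2
  draws <- withr::with_seed(seed, {
    lapply(seq_len(reps), function(r) sort(sample.int(n_nodes, n, prob = w)))
  })

  if (!is.null(dist_full)) {
    null_means <- vapply(draws, function(idx) null_mean_from_idx(dist_full, idx),
                         numeric(1))
  } else if (n_nodes <= max_matrix_nodes) {
    Dfull <- igraph::distances(surface$graph)
    null_means <- vapply(draws, function(idx) null_mean_from_idx(Dfull, idx),
                         numeric(1))
  } else {
    u <- sort(unique(unlist(draws)))
    DU <- igraph::distances(surface$graph, v = u, to = u)
    pos <- match(seq_len(n_nodes), u)
    null_means <- vapply(draws, function(idx) null_mean_from_idx(DU, pos[idx]),
                         numeric(1))
  }

  degenerate <- reps == 1
  null_sd <- if (degenerate) NA_real_ else stats::sd(null_means)
  structure(
    list(
      observed_mean_nnd = observed,
      null_means = null_means,
      null_mean = mean(null_means),
      null_sd = null_sd,
      z_score = if (degenerate) NA_real_ else (observed - mean(null_means)) / null_sd,
      p_empirical = (1 + sum(null_means <= observed)) / (reps + 1),
      reps = reps,
      n = n,
      seed = seed,
      degenerate = degenerate
    ),
    class = "randomization_result"
  )
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "<randomization_result> observed mean NND %.1f nm vs null %.1f nm (%d reps)\n",
    x$observed_mean_nnd, x$null_mean, x$reps))
  if (x$degenerate) {
    cat("  degenerate: a single replicate defines no null SD or z-score\n")
  } else {
    cat(sprintf("  z = %.2f, empirical p = %.4g (n = %d particles)\n",
                x$z_score, x$p_empirical, x$n))
  }
  invisible(x)
}

#' Single-linkage cluster calling on the membrane surface
#'
#' Groups particles whose pairwise geodesic distance is at most the cluster
#' threshold (single linkage: connected components of the threshold graph).
#' The default threshold is `mean NND + 2 SD` from a previous [nnd_analysis()]
#' (`rule = "plus2sd"`); `rule = "minus2sd"` gives `mean - 2 SD`. Groups of 3
#' or more particles are clusters; groups of 1-2 are scattered.
#'
#' @param surface A `surface_graph`.
#' @param nodes PM particle node ids.
#' @param nnd An `nnd_result` computed on the same particle set.
#' @param rule `"plus2sd"` (default) or `"minus2sd"`.
#' @param particle_id Optional particle ids.
#' @return An object of class `cluster_set`: `members` (tibble: `particle_id,
#'   node, group, group_size, is_cluster`), `sizes` (tibble: `group_size,
#'   n_groups`), `threshold_nm`, `rule`, `n_clusters`, `scattered_count`
#'   (number of particles in groups of size 1-2).
#' @export
call_clusters <- function(surface, nodes, nnd, rule = c("plus2sd", "minus2sd"),
                          particle_id = NULL) {
  rule <- match.arg(rule)
  nodes <- check_nodes(surface, nodes)
  if (nnd$n != length(nodes)) {
    stop("nnd result was computed on a different particle set", call. = FALSE)
  }
  threshold <- switch(rule,
    plus2sd = nnd$mean_nnd + 2 * nnd$sd_nnd,
    minus2sd = nnd$mean_nnd - 2 * nnd$sd_nnd
  )
  if (!is.finite(threshold) || threshold <= 0) {
    stop("cluster threshold is not positive under rule '", rule,
         "' (mean ", signif(nnd$mean_nnd, 4), ", SD ", signif(nnd$sd_nnd, 4), ")",
         call. = FALSE)
  }
  n <- length(nodes)
  if (is.null(particle_id)) particle_id <- seq_len(n)
  D <- igraph::distances(surface$graph, v = nodes, to = nodes)
  adj <- D <= threshold
  diag(adj) <- FALSE
  gg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gg)
  group <- comp$membership
  gsize <- as.integer(comp$csize[group])
  members <- tibble::tibble(
    particle_id = particle_id, node = nodes, group = as.integer(group),
    group_size = gsize, is_cluster = gsize >= 3L
  )
  size_tab <- members |>
    dplyr::distinct(.data$group, .data$group_size) |>
    dplyr::count(.data$group_size, name = "n_groups") |>
    dplyr::arrange(.data$group_size)
  structure(
    list(
      members = members,
      sizes = size_tab,
      threshold_nm = threshold,
      rule = rule,
      n_clusters = sum(comp$csize >= 3),
      scattered_count = sum(gsize <= 2L)
    ),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "<cluster_set> %d clusters (>= 3 particles) at threshold %.1f nm (%s); %d scattered particle(s)\n",
    x$n_clusters, x$threshold_nm, x$rule, x$scattered_count))
  invisible(x)
}

empty_profile <- function(type, bin_width, limit) {
  nb <- as.integer(limit / bin_width)
  starts <- (seq_len(nb) - 1) * bin_width
  structure(
    list(
      bins = tibble::tibble(
        bin_start_nm = starts, bin_end_nm = starts + bin_width,
        count = integer(nb), prop_within = rep(NA_real_, nb),
        prop_all = rep(NA_real_, nb), synapse_type = type
      ),
      distances = tibble::tibble(particle_id = integer(0), node = integer(0),
                                 dist_nm = numeric(0)),
      synapse_type = type, bin_width = bin_width, limit = limit,
      n_within = 0L, n_beyond = 0L, n_total = 0L
    ),
    class = "distance_profile"
  )
}

#' Binned distance-to-synapse profile along the membrane
#'
#' For each PM particle, measures the geodesic distance to the nearest *edge*
#' of the nearest synapse patch of the given type (edge nodes are patch nodes
#' adjacent, in the surface graph, to at least one node outside that patch).
#' Particles whose node lies inside a patch of the type get distance 0.
#' Distances are binned in `bin_width`-nm bins up to `limit` (defaults: 60-nm
#' bins within 660 nm, i.e. exactly 11 bins); proportions are reported both
#' over within-limit particles (`prop_within`, the normalized profile) and
#' over all particles (`prop_all`).
#'
#' @param surface A `surface_graph` of the compartment.
#' @param nodes PM particle node ids.
#' @param synapse_vol A [label_volume()] of synapse patch labels sharing the
#'   volume frame (0 = no patch).
#' @param synapse_meta Tibble with `patch_id, type` (see
#'   [read_synapse_meta()]).
#' @param type `"asymmetric"` or `"symmetric"`.
#' @param bin_width Bin width, nm (default 60).
#' @param limit Profile limit, nm (default 660; must be a multiple of
#'   `bin_width`).
#' @param particle_id Optional particle ids.
#' @return An object of class `distance_profile` with `bins` (tibble:
#'   `bin_start_nm, bin_end_nm, count, prop_within, prop_all, synapse_type`),
#'   `distances` (per-particle), `n_within`, `n_beyond`, `n_total`.
#' @export
synapse_profile <- function(surface, nodes, synapse_vol, synapse_meta,
                            type = c("asymmetric", "symmetric"),
                            bin_width = 60, limit = 660, particle_id = NULL) {
  type <- match.arg(type)
  if (limit %% bin_width != 0) {
    stop("limit must be a multiple of bin_width", call. = FALSE)
  }
  nodes <- check_nodes(surface, nodes)
  n <- length(nodes)
  if (is.null(particle_id)) particle_id <- seq_len(n)

  patch_ids <- synapse_meta$patch_id[synapse_meta$type == type]
  if (!length(patch_ids)) {
    warning("no synapse patch of type '", type, "'; returning empty profile",
            call. = FALSE)
    return(empty_profile(type, bin_width, limit))
  }
  # patch label under each surface node's voxel (0 when not of this type)
  pv <- synapse_vol$labels[cbind(surface$nodes$iy, surface$nodes$ix, surface$nodes$iz)]
  node_patch <- ifelse(pv %in% patch_ids, pv, 0L)
  patch_nodes <- which(node_patch > 0L)
  if (!length(patch_nodes)) {
    warning("synapse patches of type '", type,
            "' do not touch the compartment surface; returning empty profile",
            call. = FALSE)
    return(empty_profile(type, bin_width, limit))
  }
  # edge nodes: patch nodes with a graph neighbor outside the same patch
  el <- igraph::as_edgelist(surface$graph, names = FALSE)
  pa <- node_patch[el[, 1]]; pb <- node_patch[el[, 2]]
  mixed <- pa != pb
  edge_nodes <- sort(unique(c(el[mixed & pa > 0L, 1], el[mixed & pb > 0L, 2])))
  if (!length(edge_nodes)) edge_nodes <- patch_nodes  # patch covers a whole component

  inside <- node_patch[nodes] > 0L
  dist <- numeric(n)
  if (any(!inside)) {
    D <- igraph::distances(surface$graph, v = edge_nodes, to = nodes[!inside])
    dist[!inside] <- apply(D, 2, min)
  }

  nb <- as.integer(limit / bin_width)
  starts <- (seq_len(nb) - 1) * bin_width
  within <- is.finite(dist) & dist < limit
  bin_idx <- floor(dist[within] / bin_width) + 1
  counts <- tabulate(bin_idx, nbins = nb)
  n_within <- sum(within)
  structure(
    list(
      bins = tibble::tibble(
        bin_start_nm = starts, bin_end_nm = starts + bin_width,
        count = as.integer(counts),
        prop_within = if (n_within > 0) counts / n_within else rep(NA_real_, nb),
        prop_all = if (n > 0) counts / n else rep(NA_real_, nb),
        synapse_type = type
      ),
      distances = tibble::tibble(particle_id = particle_id, node = nodes,
                                 dist_nm = dist),
      synapse_type = type, bin_width = bin_width, limit = limit,
      n_within = as.integer(n_within), n_beyond = as.integer(n - n_within),
      n_total = as.integer(n)
    ),
    class = "distance_profile"
  )
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf(
    "<distance_profile> %s synapses: %d particles within %g nm, %d beyond (of %d)\n",
    x$synapse_type, x$n_within, x$limit, x$n_beyond, x$n_total))
  invisible(x)
}
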