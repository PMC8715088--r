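# End-to-end orchestration: simulate/load -> assign -> spatial stats ->
# summaries, with a reproducibility manifest. The single run seed fans out to
# fixed per-stage substreams (simulation, null replicates) so stages can be
# rerun independently yet reproducibly.

default_run_params <- function() {
  list(
    resample_nm = 20,       # isotropic analysis spacing
    pm_contact_radius = 20, # nm, one isotropic voxel
    reps = 100,             # null replicates for the randomization test
    cluster_rule = "plus2sd",
    bin_width = 60,         # nm, synapse profile bins
    limit = 660             # nm, synapse profile limit (11 bins)
  )
}

seed_substream <- function(seed, stage) {
  # deterministic fan-out, kept well under .Machine$integer.max
  offsets <- c(simulate = 101L, null = 211L)
  (as.integer(seed) + offsets[[stage]]) %% 2000000000L
}

#' Run the full analysis pipeline
#'
#' Accepts either a synthetic scene (from [build_scene()]) or on-disk inputs
#' (label TIFF + particle CSV + optional synapse TIFF/CSV), then: resamples to
#' isotropic spacing if needed, extracts per-compartment surfaces, assigns and
#' classifies particles, runs geodesic NND + randomization + cluster calling
#' per compartment surface holding 2+ PM particles, profiles distances to
#' synapse patch edges per type, and tabulates densities. Writes result CSVs
#' and a manifest when `out_dir` is given.
#'
#' @param scene Optional `synthetic_scene`; when supplied, the file-path
#'   arguments are ignored.
#' @param volume_path,particle_path,synapse_path,synapse_meta_path,
#'   compartment_meta_path On-disk inputs (see [read_label_volume()],
#'   [read_particle_table()], [read_synapse_meta()],
#'   [read_compartment_meta()]).
#' @param spacing Acquisition spacing of the on-disk volume
#'   ([voxel_spacing()]).
#' @param params Run parameters; see `default_run_params()` for the defaults
#'   (20-nm resampling and contact radius, 100 null replicates, mean + 2 SD
#'   cluster rule, 60-nm bins to 660 nm).
#' @param seed Integer run seed (drives the randomization null).
#' @param out_dir Optional output directory for CSVs + manifest.
#' @return A list of class `skmap_run` with `particles`, `metrics`,
#'   `density`, `nnd`, `randomization`, `clusters`, `profiles`, `params`,
#'   `seed`.
#' @export
run_analyze <- function(scene = NULL,
                        volume_path = NULL, particle_path = NULL,
                        synapse_path = NULL, synapse_meta_path = NULL,
                        compartment_meta_path = NULL,
                        spacing = voxel_spacing(),
                        params = list(), seed = 1L, out_dir = NULL) {
  params <- utils::modifyList(default_run_params(), params)

  if (!is.null(scene)) {
    vol <- scene$volume
    syn_vol <- scene$synapses
    syn_meta <- scene$synapse_meta
    particles <- scene$particles
    comp_meta <- scene$compartments
  } else {
    if (is.null(volume_path) || is.null(particle_path)) {
      stop("either a scene or volume_path + particle_path must be supplied",
           call. = FALSE)
    }
    vol <- read_label_volume(volume_path, spacing)
    particles <- read_particle_table(particle_path)
    syn_vol <- if (!is.null(synapse_path)) read_label_volume(synapse_path, spacing) else NULL
    syn_meta <- if (!is.null(synapse_meta_path)) read_synapse_meta(synapse_meta_path) else NULL
    comp_meta <- if (!is.null(compartment_meta_path)) {
      read_compartment_meta(compartment_meta_path)
    } else NULL
  }

  if (!is_isotropic(vol)) {
    vol <- resample_isotropic(vol, params$resample_nm)
    if (!is.null(syn_vol)) syn_vol <- resample_isotropic(syn_vol, params$resample_nm)
  }

  ids <- label_ids(vol)
  surfaces <- lapply(ids, function(id) extract_surface(vol, id))
  names(surfaces) <- as.character(ids)
  metrics <- measure_compartments(vol, ids)
  if (!is.null(comp_meta)) {
    metrics <- dplyr::left_join(
      metrics,
      dplyr::rename(comp_meta, compartment_id = "label_id"),
      by = "compartment_id"
    )
  }

  particles <- classify_particles(particles, vol, surfaces,
                                  params$pm_contact_radius)
  density <- density_table(particles, metrics)

  null_seed <- seed_substream(seed, "null")
  nnd_list <- list(); rand_list <- list(); clus_list <- list()
  for (id in ids) {
    pm <- particles[!is.na(particles$compartment_id) &
                      particles$compartment_id == id &
                      particles$localization == "PM", ]
    if (nrow(pm) < 2) next
    surf <- surfaces[[as.character(id)]]
    nnd <- nnd_analysis(surf, pm$nearest_surface_node, pm$particle_id)
    rand <- randomization_test(surf, pm$nearest_surface_node,
                               reps = params$reps, seed = null_seed)
    clus <- if (nnd$sd_nnd > 0 || params$cluster_rule == "plus2sd") {
      call_clusters(surf, pm$nearest_surface_node, nnd,
                    rule = params$cluster_rule, particle_id = pm$particle_id)
    } else NULL
    key <- as.character(id)
    nnd_list[[key]] <- nnd; rand_list[[key]] <- rand; clus_list[[key]] <- clus
  }

  profiles <- list()
  if (!is.null(syn_vol) && !is.null(syn_meta) && nrow(syn_meta) > 0) {
    for (type in intersect(c("asymmetric", "symmetric"), unique(syn_meta$type))) {
      per_comp <- list()
      for (id in ids) {
        pm <- particles[!is.na(particles$compartment_id) &
                          particles$compartment_id == id &
                          particles$localization == "PM", ]
        if (nrow(pm) == 0) next
        relevant <- syn_meta[syn_meta$type == type &
                               syn_meta$compartment_id == id, ]
        if (nrow(relevant) == 0) next
        per_comp[[as.character(id)]] <- synapse_profile(
          surfaces[[as.character(id)]], pm$nearest_surface_node,
          syn_vol, relevant, type = type,
          bin_width = params$bin_width, limit = params$limit,
          particle_id = pm$particle_id
        )
      }
      if (length(per_comp)) profiles[[type]] <- combine_profiles(per_comp, type)
    }
  }

  run <- structure(
    list(particles = particles, metrics = metrics, density = density,
         nnd = nnd_list, randomization = rand_list, clusters = clus_list,
         profiles = profiles, params = params, seed = as.integer(seed)),
    class = "skmap_run"
  )
  if (!is.null(out_dir)) export_run(run, out_dir)
  run
}

# pool per-compartment profiles of one synapse type (counts add; proportions
# are recomputed over the pooled particles)
combine_profiles <- function(per_comp, type) {
  if (length(per_comp) == 1) return(per_comp[[1]])
  p1 <- per_comp[[1]]
  counts <- Reduce(`+`, lapply(per_comp, function(p) p$bins$count))
  n_within <- sum(vapply(per_comp, function(p) p$n_within, integer(1)))
  n_total <- sum(vapply(per_comp, function(p) p$n_total, integer(1)))
  dists <- dplyr::bind_rows(lapply(per_comp, function(p) p$distances))
  structure(
    list(
      bins = tibble::tibble(
        bin_start_nm = p1$bins$bin_start_nm, bin_end_nm = p1$bins$bin_end_nm,
        count = as.integer(counts),
        prop_within = if (n_within > 0) counts / n_within else NA_real_,
        prop_all = if (n_total > 0) counts / n_total else NA_real_,
        synapse_type = type
      ),
      distances = dists, synapse_type = type,
      bin_width = p1$bin_width, limit = p1$limit,
      n_within = as.integer(n_within),
      n_beyond = as.integer(n_total - n_within), n_total = as.integer(n_total)
    ),
    class = "distance_profile"
  )
}

export_run <- function(run, out_dir) {
  tables <- list(
    particles = run$particles,
    density = as.data.frame(run$density),
    compartments = run$metrics
  )
  if (length(run$nnd)) {
    tables$particle_nnd <- dplyr::bind_rows(
      lapply(names(run$nnd), function(k) {
        dplyr::mutate(run$nnd[[k]]$nnd, compartment_id = as.integer(k),
                      .before = 1)
      })
    )
    tables$randomization <- dplyr::bind_rows(
      lapply(names(run$randomization), function(k) {
        dplyr::mutate(glance(run$randomization[[k]]),
                      compartment_id = as.integer(k), .before = 1)
      })
    )
    tables$null_means <- dplyr::bind_rows(
      lapply(names(run$randomization), function(k) {
        tibble::tibble(compartment_id = as.integer(k),
                       replicate = seq_along(run$randomization[[k]]$null_means),
                       mean_nnd_nm = run$randomization[[k]]$null_means)
      })
    )
    keep <- !vapply(run$clusters, is.null, logical(1))
    if (any(keep)) {
      tables$clusters <- dplyr::bind_rows(
        lapply(names(run$clusters)[keep], function(k) {
          dplyr::mutate(run$clusters[[k]]$members, compartment_id = as.integer(k),
                        .before = 1)
        })
      )
    }
  }
  if (length(run$profiles)) {
    tables$profile <- dplyr::bind_rows(lapply(run$profiles, function(p) p$bins))
  }
  write_results(tables, out_dir, seed = run$seed, params = run$params)
}

#' @export
print.skmap_run <- function(x, ...) {
  cat("<skmap_run>\n")
  cat(sprintf("  %d particle(s), %d compartment(s)\n",
              nrow(x$particles), nrow(x$metrics)))
  for (k in names(x$randomization)) {
    r <- x$randomization[[k]]
    cat(sprintf("  compartment %s: observed NND %.1f nm vs null %.1f nm (p = %.3g)\n",
                k, r$observed_mean_nnd, r$null_mean, r$p_empirical))
  }
  invisible(x)
}

#' Summarize a results directory as a Markdown report
#'
#' Reads the CSVs written by [run_analyze()] and renders a human-readable
#' Markdown report: density table, randomization and cluster statistics, and
#' per-bin synapse profiles. Missing tables produce warnings and a partial
#' report.
#'
#' @param results_dir Directory containing the pipeline outputs.
#' @param out_file Report path (default `report.md` inside `results_dir`).
#' @return `out_file`, invisibly.
#' @export
run_summarize <- function(results_dir, out_file = file.path(results_dir, "report.md")) {
  lines <- c("# skmap analysis report", "")
  read_opt <- function(name) {
    p <- file.path(results_dir, paste0(name, ".csv"))
    if (!file.exists(p)) {
      warning("missing results table: ", name, call. = FALSE)
      return(NULL)
    }
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  md_table <- function(df) {
    fmt <- function(v) {
      if (is.numeric(v)) sub("\\.?0+$", "", formatC(v, digits = 4, format = "f")) else as.character(v)
    }
    body <- apply(vapply(df, fmt, character(nrow(df))), 1, paste, collapse = " | ")
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      body)
  }
  dens <- read_opt("density")
  if (!is.null(dens)) {
    lines <- c(lines, "## Per-compartment densities", "", md_table(dens), "")
  }
  rand <- read_opt("randomization")
  if (!is.null(rand)) {
    lines <- c(lines, "## Spatial randomness (geodesic NND vs Monte-Carlo null)", "",
               md_table(rand), "")
    below <- rand$observed_mean_nnd < rand$null_mean
    for (i in seq_len(nrow(rand))) {
      lines <- c(lines, sprintf(
        "- compartment %s: observed mean NND %s the null mean (%.1f vs %.1f nm).",
        rand$compartment_id[i], if (below[i]) "below" else "not below",
        rand$observed_mean_nnd[i], rand$null_mean[i]))
    }
    lines <- c(lines, "")
  }
  clus <- read_opt("clusters")
  if (!is.null(clus)) {
    sizes <- clus |>
      dplyr::distinct(.data$compartment_id, .data$group, .data$group_size) |>
      dplyr::count(.data$group_size, name = "n_groups")
    lines <- c(lines, "## Cluster sizes (single-linkage groups)", "",
               md_table(sizes), "")
  }
  prof <- read_opt("profile")
  if (!is.null(prof)) {
    lines <- c(lines, "## Distance-to-synapse profiles (60-nm bins)", "",
               md_table(prof), "")
  }
  if (length(lines) == 2) lines <- c(lines, "No result tables found.", "")
  writeLines(lines, out_file)
  invisible(out_file)
}
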