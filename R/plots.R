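# ggplot2 visualizations for each result type.

#' @describeIn randomization_test Null histogram of replicate mean NNDs with
#'   the observed mean marked.
#' @param object A `randomization_result`.
#' @param ... Unused.
#' @method autoplot randomization_result
#' @export
autoplot.randomization_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_mean_nnd_nm)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_mean_nnd,
                        color = "red", linewidth = 1) +
    ggplot2::labs(
      x = "replicate mean NND (nm)", y = "replicates",
      title = "Observed mean NND vs Monte-Carlo random null",
      subtitle = sprintf("observed %.1f nm, null %.1f nm, p = %.3g",
                         object$observed_mean_nnd, object$null_mean,
                         object$p_empirical)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn nnd_analysis Empirical cumulative distribution of per-particle
#'   NNDs; overlay a null result with `null =` to mirror observed-vs-random
#'   cumulative plots.
#' @param object An `nnd_result`.
#' @param null Optional `randomization_result` whose replicate means are shown
#'   as a reference line.
#' @param ... Unused.
#' @method autoplot nnd_result
#' @export
autoplot.nnd_result <- function(object, null = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$nnd_nm)) +
    ggplot2::stat_ecdf(color = "black", linewidth = 0.8) +
    ggplot2::labs(x = "nearest-neighbor distance (nm)",
                  y = "cumulative probability",
                  title = "Geodesic NND distribution") +
    ggplot2::theme_minimal()
  if (!is.null(null)) {
    p <- p + ggplot2::geom_vline(xintercept = null$null_mean,
                                 color = "red", linetype = "dashed")
  }
  p
}

#' @describeIn synapse_profile Bar chart of the normalized binned profile
#'   (proportion of within-limit particles per 60-nm distance bin).
#' @param object A `distance_profile`.
#' @param ... Unused.
#' @method autoplot distance_profile
#' @export
autoplot.distance_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start_nm + object$bin_width / 2,
                                   y = .data$prop_within)) +
    ggplot2::geom_col(fill = "steelblue", color = "grey20",
                      width = object$bin_width * 0.9) +
    ggplot2::scale_x_continuous(breaks = df$bin_start_nm) +
    ggplot2::labs(
      x = "distance from synapse edge (nm)", y = "proportion of particles",
      title = sprintf("Particle distances to %s synapses", object$synapse_type),
      subtitle = sprintf("%d of %d particles within %g nm",
                         object$n_within, object$n_total, object$limit)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn call_clusters Histogram of single-linkage group sizes.
#' @param object A `cluster_set`.
#' @param ... Unused.
#' @method autoplot cluster_set
#' @export
autoplot.cluster_set <- function(object, ...) {
  ggplot2::ggplot(object$sizes,
                  ggplot2::aes(x = .data$group_size, y = .data$n_groups)) +
    ggplot2::geom_col(fill = "darkorange", color = "grey20") +
    ggplot2::geom_vline(xintercept = 2.5, linetype = "dashed") +
    ggplot2::labs(x = "group size (particles)", y = "groups",
                  title = "Cluster size distribution",
                  subtitle = "dashed line: clusters (>= 3) vs scattered (1-2)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of spine volume vs particle count
#'
#' @param spines Tibble with `volume_um3` and `n_gold`.
#' @return A ggplot.
#' @export
plot_spine_correlation <- function(spines) {
  ct <- spine_count_correlation(spines)
  ggplot2::ggplot(spines, ggplot2::aes(x = .data$volume_um3, y = .data$n_gold)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "red", linewidth = 0.8) +
    ggplot2::labs(x = expression(paste("spine volume (", mu, m^3, ")")),
                  y = "gold particles",
                  title = sprintf("Spine volume vs particle count (r = %.2f)", ct$r)) +
    ggplot2::theme_minimal()
}
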