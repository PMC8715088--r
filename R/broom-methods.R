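# broom-style accessors: tidy() returns the per-observation table, glance()
# the one-row summary.

#' @method tidy nnd_result
#' @export
tidy.nnd_result <- function(x, ...) x$nnd

#' @method glance nnd_result
#' @export
glance.nnd_result <- function(x, ...) {
  tibble::tibble(mean_nnd_nm = x$mean_nnd, sd_nnd_nm = x$sd_nnd, n = x$n)
}

#' @method tidy randomization_result
#' @export
tidy.randomization_result <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null_means),
                 null_mean_nnd_nm = x$null_means)
}

#' @method glance randomization_result
#' @export
glance.randomization_result <- function(x, ...) {
  tibble::tibble(
    observed_mean_nnd = x$observed_mean_nnd,
    null_mean = x$null_mean, null_sd = x$null_sd,
    z_score = x$z_score, p_empirical = x$p_empirical,
    reps = x$reps, n = x$n, seed = x$seed, degenerate = x$degenerate
  )
}

#' @method tidy cluster_set
#' @export
tidy.cluster_set <- function(x, ...) x$members

#' @method glance cluster_set
#' @export
glance.cluster_set <- function(x, ...) {
  tibble::tibble(
    n_clusters = x$n_clusters,
    scattered_count = x$scattered_count,
    threshold_nm = x$threshold_nm,
    rule = x$rule,
    n_particles = nrow(x$members)
  )
}

#' @method tidy distance_profile
#' @export
tidy.distance_profile <- function(x, ...) x$bins

#' @method glance distance_profile
#' @export
glance.distance_profile <- function(x, ...) {
  tibble::tibble(
    synapse_type = x$synapse_type, bin_width_nm = x$bin_width,
    limit_nm = x$limit, n_within = x$n_within, n_beyond = x$n_beyond,
    n_total = x$n_total
  )
}

#' @method tidy spine_volume_comparison
#' @export
tidy.spine_volume_comparison <- function(x, ...) {
  tibble::tibble(
    group = c(rep("positive", x$n_pos), rep("negative", x$n_neg)),
    volume_um3 = c(x$volumes_positive, x$volumes_negative)
  )
}

#' @method glance spine_volume_comparison
#' @export
glance.spine_volume_comparison <- function(x, ...) {
  tibble::tibble(
    mean_pos = x$mean_pos, sem_pos = x$sem_pos,
    mean_neg = x$mean_neg, sem_neg = x$sem_neg,
    n_pos = x$n_pos, n_neg = x$n_neg,
    pct_negative = x$pct_negative,
    statistic = x$statistic, p_value = x$p_value
  )
}
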