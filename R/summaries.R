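# Per-compartment density accounting and comparative statistics.

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Per-compartment particle counts, volumes and densities
#'
#' One row per compartment with PM / intracellular counts, volume, densities
#' (gold/um^3) and PM/intra percentages, plus a totals row (`kind = "total"`):
#' counts and volumes are summed; the totals-row densities are the mean of
#' the per-compartment densities with their SEM (`pm_density_sem`,
#' `intra_density_sem`), matching how per-dendrite densities are conventionally
#' pooled. Pooled (summed count / summed volume) densities are attached as the
#' `"pooled"` attribute.
#'
#' @param particles Tibble with `compartment_id` and `localization`
#'   (`"PM"`/`"intracellular"`); unassigned rows are dropped with a message.
#' @param metrics Tibble with `compartment_id`, `volume_um3` and optionally
#'   `kind` (see [measure_compartments()]).
#' @return A tibble of class `density_table`.
#' @export
density_table <- function(particles, metrics) {
  if (!"kind" %in% names(metrics)) metrics$kind <- NA_character_
  dropped <- sum(is.na(particles$compartment_id))
  if (dropped > 0) {
    message(dropped, " unassigned particle(s) excluded from the density table")
    particles <- particles[!is.na(particles$compartment_id), ]
  }
  unknown <- setdiff(unique(particles$compartment_id), metrics$compartment_id)
  if (length(unknown)) {
    stop("particles reference unmeasured compartment(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- particles |>
    dplyr::count(.data$compartment_id, .data$localization) |>
    tidyr::pivot_wider(names_from = "localization", values_from = "n",
                       values_fill = 0L)
  if (!"PM" %in% names(counts)) counts$PM <- 0L
  if (!"intracellular" %in% names(counts)) counts$intracellular <- 0L
  per <- metrics |>
    dplyr::select("compartment_id", "kind", "volume_um3") |>
    dplyr::left_join(counts, by = "compartment_id") |>
    dplyr::mutate(
      n_pm = dplyr::coalesce(.data$PM, 0L),
      n_intra = dplyr::coalesce(.data$intracellular, 0L),
      n_total = .data$n_pm + .data$n_intra,
      pm_density = .data$n_pm / .data$volume_um3,
      intra_density = .data$n_intra / .data$volume_um3,
      pct_pm = ifelse(.data$n_total > 0, 100 * .data$n_pm / .data$n_total, NA_real_),
      pct_intra = ifelse(.data$n_total > 0, 100 * .data$n_intra / .data$n_total, NA_real_),
      pm_density_sem = NA_real_,
      intra_density_sem = NA_real_
    ) |>
    dplyr::select("compartment_id", "kind", "n_pm", "n_intra", "n_total",
                  "volume_um3", "pm_density", "pm_density_sem",
                  "intra_density", "intra_density_sem", "pct_pm", "pct_intra")
  tot_pm <- sum(per$n_pm); tot_intra <- sum(per$n_intra)
  total <- tibble::tibble(
    compartment_id = NA_integer_, kind = "total",
    n_pm = tot_pm, n_intra = tot_intra, n_total = tot_pm + tot_intra,
    volume_um3 = sum(per$volume_um3),
    pm_density = mean(per$pm_density),
    pm_density_sem = if (nrow(per) > 1) sem(per$pm_density) else NA_real_,
    intra_density = mean(per$intra_density),
    intra_density_sem = if (nrow(per) > 1) sem(per$intra_density) else NA_real_,
    pct_pm = if (tot_pm + tot_intra > 0) 100 * tot_pm / (tot_pm + tot_intra) else NA_real_,
    pct_intra = if (tot_pm + tot_intra > 0) 100 * tot_intra / (tot_pm + tot_intra) else NA_real_
  )
  out <- dplyr::bind_rows(per, total)
  attr(out, "pooled") <- c(
    pm_density = tot_pm / sum(per$volume_um3),
    intra_density = tot_intra / sum(per$volume_um3)
  )
  class(out) <- c("density_table", class(out))
  out
}

#' Percentage breakdown of particle counts across compartment kinds
#'
#' Shares of the total particle count per compartment kind (e.g. shaft vs
#' spine) and the PM percentage within each kind, reported both
#' integer-rounded and at 1 decimal.
#'
#' @param table A [density_table()] (the totals row is ignored).
#' @return Tibble: `kind, n_pm, n_intra, n_total, pct_of_total,
#'   pct_of_total_int, pct_pm, pct_pm_int`.
#' @export
percentage_breakdown <- function(table) {
  per <- table[is.na(table$kind) | table$kind != "total", ]
  grand <- sum(per$n_total)
  if (grand == 0) stop("zero total particle count: percentages undefined", call. = FALSE)
  per |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(
      n_pm = sum(.data$n_pm), n_intra = sum(.data$n_intra),
      n_total = sum(.data$n_total), .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_of_total = round(100 * .data$n_total / grand, 1),
      pct_of_total_int = round(100 * .data$n_total / grand),
      pct_pm = round(100 * .data$n_pm / .data$n_total, 1),
      pct_pm_int = round(100 * .data$n_pm / .data$n_total)
    )
}

#' Pairwise fold ratios between group mean densities
#'
#' @param group_means Named numeric vector of group means (all > 0 when used
#'   as denominators).
#' @return Tibble of all ordered pairs: `numerator, denominator, ratio, fold`
#'   (`fold` = ratio rounded to the nearest integer). Raw ratios satisfy
#'   `ratio(a, b) * ratio(b, a) = 1`.
#' @export
fold_ratios <- function(group_means) {
  if (is.null(names(group_means)) || any(!nzchar(names(group_means)))) {
    stop("group_means must be a fully named vector", call. = FALSE)
  }
  if (any(group_means == 0)) stop("zero group mean: fold ratio undefined", call. = FALSE)
  nms <- names(group_means)
  pairs <- expand.grid(numerator = nms, denominator = nms,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$numerator != pairs$denominator, ]
  tibble::tibble(
    numerator = pairs$numerator,
    denominator = pairs$denominator,
    ratio = unname(group_means[pairs$numerator] / group_means[pairs$denominator]),
    fold = round(unname(group_means[pairs$numerator] / group_means[pairs$denominator]))
  )
}

#' Pearson correlation between spine volume and particle count
#'
#' @param spines Tibble with `volume_um3` and `n_gold` (one row per spine;
#'   at least 3 rows with variance in both columns).
#' @return Tibble: `r, p_value, n, method`.
#' @export
spine_count_correlation <- function(spines) {
  if (nrow(spines) < 3) stop("need at least 3 spines", call. = FALSE)
  if (stats::sd(spines$volume_um3) == 0 || stats::sd(spines$n_gold) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(spines$volume_um3, spines$n_gold, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate), p_value = ct$p.value, n = nrow(spines),
    method = "Pearson product-moment correlation"
  )
}

#' Compare volumes of immunopositive vs immunonegative spines
#'
#' Splits spines into immunopositive (`n_gold >= 1`) and immunonegative
#' (`n_gold == 0`) and compares their volumes with a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test; exact for small samples without ties, normal
#' approximation otherwise.
#'
#' @param spines Tibble with `volume_um3` and `n_gold`.
#' @return An object of class `spine_volume_comparison`: group means and
#'   SEMs, group sizes, the immunonegative percentage, U statistic and
#'   p-value, plus the raw volume vectors.
#' @export
compare_spine_volumes <- function(spines) {
  pos <- spines$volume_um3[spines$n_gold >= 1]
  neg <- spines$volume_um3[spines$n_gold == 0]
  if (!length(pos) || !length(neg)) {
    stop("both immunopositive and immunonegative spines are required", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(pos, neg, alternative = "two.sided"))
  structure(
    list(
      volumes_positive = pos, volumes_negative = neg,
      mean_pos = mean(pos), sem_pos = if (length(pos) > 1) sem(pos) else NA_real_,
      mean_neg = mean(neg), sem_neg = if (length(neg) > 1) sem(neg) else NA_real_,
      n_pos = length(pos), n_neg = length(neg),
      pct_negative = 100 * length(neg) / (length(pos) + length(neg)),
      statistic = unname(wt$statistic), p_value = wt$p.value,
      method = wt$method
    ),
    class = "spine_volume_comparison"
  )
}

#' @export
print.spine_volume_comparison <- function(x, ...) {
  cat(sprintf(
    "<spine_volume_comparison> SK-positive %.4f um^3 (n=%d) vs negative %.4f um^3 (n=%d)\n",
    x$mean_pos, x$n_pos, x$mean_neg, x$n_neg))
  cat(sprintf("  immunonegative share %.1f%%; Mann-Whitney U = %g, p = %.3g\n",
              x$pct_negative, x$statistic, x$p_value))
  invisible(x)
}

#' One-way ANOVA with Bonferroni post hoc contrasts
#'
#' @param values Numeric response (e.g. densities).
#' @param groups Group factor/character, length-matched to `values`; at least
#'   2 groups with at least 2 observations each.
#' @return List with `anova` (tibble: `f_statistic, df_between, df_within,
#'   p_value, degenerate`) and `pairwise` (tibble: `group1, group2, p_raw,
#'   p_bonferroni`). When all residual variance is zero the `degenerate` flag
#'   is set and p-values are `NA`.
#' @export
group_tests <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs at least 2 observations", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  ms_within <- an["Residuals", "Mean Sq"]
  # scale-aware: constant responses leave only floating-point noise in the SS
  degenerate <- !is.finite(ms_within) ||
    stats::sd(values) <= sqrt(.Machine$double.eps) * (abs(mean(values)) + 1)
  anova_tbl <- tibble::tibble(
    f_statistic = if (degenerate) NA_real_ else an[1, "F value"],
    df_between = an[1, "Df"],
    df_within = an["Residuals", "Df"],
    p_value = if (degenerate) NA_real_ else an[1, "Pr(>F)"],
    degenerate = degenerate
  )
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  p_raw <- numeric(m)
  for (i in seq_len(m)) {
    a <- values[groups == pairs[1, i]]; b <- values[groups == pairs[2, i]]
    if (degenerate) { p_raw[i] <- NA_real_; next }
    # Bonferroni post hoc: pairwise t with the pooled within-group variance
    se <- sqrt(ms_within * (1 / length(a) + 1 / length(b)))
    tstat <- (mean(a) - mean(b)) / se
    p_raw[i] <- 2 * stats::pt(-abs(tstat), df = an["Residuals", "Df"])
  }
  pairwise <- tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    p_raw = p_raw, p_bonferroni = pmin(1, m * p_raw)
  )
  list(anova = anova_tbl, pairwise = pairwise)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param x,y Numeric samples.
#' @return Tibble: `d_statistic, p_value`.
#' @export
ks_compare <- function(x, y) {
  kt <- suppressWarnings(stats::ks.test(x, y))
  tibble::tibble(d_statistic = unname(kt$statistic), p_value = kt$p.value)
}
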