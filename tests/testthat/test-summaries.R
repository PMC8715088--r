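# expand per-compartment counts into one particle row per gold
counts_to_particles <- function(df) {
  dplyr::bind_rows(
    tidyr::uncount(dplyr::transmute(df, compartment_id = .data$compartment_id,
                                    localization = "PM", n = .data$n_pm), .data$n),
    tidyr::uncount(dplyr::transmute(df, compartment_id = .data$compartment_id,
                                    localization = "intracellular",
                                    n = .data$n_intra), .data$n)
  )
}

test_that("density table reproduces the smooth-dendrite reference accounting", {
  ref <- sk2_dendrite_data()$interneuron
  parts <- counts_to_particles(tibble::tibble(
    compartment_id = ref$dendrite, n_pm = ref$pm, n_intra = ref$intra
  ))
  metrics <- tibble::tibble(compartment_id = ref$dendrite,
                            kind = "interneuron_shaft",
                            volume_um3 = ref$volume_um3)
  dt <- density_table(parts, metrics)
  expect_equal(nrow(dt), 7)
  d6 <- dt[dt$compartment_id == 6 & !is.na(dt$compartment_id), ]
  expect_equal(d6$n_pm, 49)
  expect_equal(round(d6$pm_density, 2), 9.35)
  tot <- dt[dt$kind == "total", ]
  expect_equal(tot$n_total, 1574)
  expect_equal(tot$n_pm + tot$n_intra, tot$n_total)
  # totals-row density: mean +/- SEM of the six per-dendrite PM densities
  expect_equal(round(tot$pm_density, 2), 8.86)
  expect_equal(round(tot$pm_density_sem, 2), 0.15)
  expect_equal(round(tot$pct_pm, 1), 13.0)
  # per-row partition: PM + intra = total, percentages sum to 100
  per <- dt[dt$kind != "total", ]
  expect_equal(per$n_pm + per$n_intra, per$n_total)
  expect_true(all(abs(per$pct_pm + per$pct_intra - 100) < 0.1))

  # unknown compartment errors; empty compartment gives zero densities
  expect_error(density_table(tibble::tibble(compartment_id = 99L,
                                            localization = "PM"), metrics),
               "unmeasured")
  dt0 <- density_table(parts[0, ], tibble::tibble(compartment_id = 1L,
                                                  kind = "spine",
                                                  volume_um3 = 1))
  expect_equal(dt0$pm_density[1], 0)
})

test_that("percentage breakdown reproduces shaft/spine and PM shares", {
  ref <- sk2_dendrite_data()$pyramidal
  parts <- dplyr::bind_rows(
    counts_to_particles(tibble::tibble(compartment_id = ref$dendrite,
                                       n_pm = ref$shaft_pm,
                                       n_intra = ref$shaft_intra)),
    counts_to_particles(tibble::tibble(compartment_id = 100L + ref$dendrite,
                                       n_pm = ref$spine_pm,
                                       n_intra = ref$spine_intra))
  )
  metrics <- tibble::tibble(
    compartment_id = c(ref$dendrite, 100L + ref$dendrite),
    kind = rep(c("pyramidal_shaft", "spine"), each = 6),
    volume_um3 = c(ref$shaft_volume_um3, ref$spine_volume_um3)
  )
  dt <- density_table(parts, metrics)
  pb <- percentage_breakdown(dt)
  shaft <- pb[pb$kind == "pyramidal_shaft", ]
  spine <- pb[pb$kind == "spine", ]
  expect_equal(shaft$n_total, 4360)
  expect_equal(spine$n_total, 415)
  expect_equal(shaft$pct_of_total_int, 91)
  expect_equal(spine$pct_of_total_int, 9)
  expect_equal(shaft$pct_pm, 27.8)
  expect_equal(spine$pct_pm, 95.9)

  single <- percentage_breakdown(density_table(
    tibble::tibble(compartment_id = 1L, localization = "PM"),
    tibble::tibble(compartment_id = 1L, kind = "spine", volume_um3 = 0.01)
  ))
  expect_equal(single$pct_of_total, 100)
  expect_error(percentage_breakdown(dt[0, ]), "zero total")
})

test_that("fold ratios round to the published integer folds", {
  gm <- c(spine_pm = 423.1, shaft_pm = 102.4, shaft_intra = 125.6,
          spine_intra = 17.5)
  fr <- fold_ratios(gm)
  get <- function(a, b) fr[fr$numerator == a & fr$denominator == b, ]
  expect_equal(get("spine_pm", "shaft_pm")$fold, 4)
  expect_equal(get("shaft_intra", "spine_intra")$fold, 7)
  # reciprocal raw ratios multiply to one
  expect_equal(get("spine_pm", "shaft_pm")$ratio * get("shaft_pm", "spine_pm")$ratio, 1)
  expect_equal(fold_ratios(c(a = 2, b = 2))$ratio, c(1, 1))
  expect_error(fold_ratios(c(a = 1, b = 0)), "zero")
  expect_error(fold_ratios(c(1, 2)), "named")
})

test_that("spine volume-count correlation behaves at the extremes and under
           the Poisson generative model", {
  v <- c(0.005, 0.01, 0.02, 0.03)
  expect_equal(spine_count_correlation(
    tibble::tibble(volume_um3 = v, n_gold = 100 * v))$r, 1)
  expect_equal(spine_count_correlation(
    tibble::tibble(volume_um3 = v, n_gold = 10 - 100 * v))$r, -1)
  expect_error(spine_count_correlation(
    tibble::tibble(volume_um3 = v, n_gold = rep(2, 4))), "variance")
  expect_error(spine_count_correlation(
    tibble::tibble(volume_um3 = v[1:2], n_gold = c(1, 2))), "at least 3")

  sim <- simulate_spines(n = 84, seed = 21)
  r <- spine_count_correlation(sim)$r
  expect_gt(r, 0.6); expect_lt(r, 0.95)
})

test_that("spine volume comparison reports group means and the Mann-Whitney test", {
  sim <- simulate_spines(n = 84, seed = 22)
  cmp <- compare_spine_volumes(sim)
  expect_equal(cmp$n_pos + cmp$n_neg, 84)
  expect_equal(cmp$pct_negative, 100 * cmp$n_neg / 84)
  # Poisson thinning empties small spines first
  expect_gt(cmp$mean_pos, cmp$mean_neg)

  # a population with 22 of 84 empty spines: immunonegative share 26%
  vols <- c(rep(0.015, 62), rep(0.008, 22))
  counts <- c(rep(5L, 62), rep(0L, 22))
  cmp2 <- compare_spine_volumes(tibble::tibble(volume_um3 = vols, n_gold = counts))
  expect_equal(round(cmp2$pct_negative), 26)

  # two one-element groups: U defined, exact two-sided p = 1
  tiny <- compare_spine_volumes(tibble::tibble(volume_um3 = c(0.01, 0.02),
                                               n_gold = c(0L, 3L)))
  expect_equal(tiny$p_value, 1)
  expect_error(compare_spine_volumes(tibble::tibble(volume_um3 = v <- c(1, 2),
                                                    n_gold = c(1L, 2L))),
               "immunonegative")
})

test_that("identical volume distributions give a calibrated Mann-Whitney test", {
  set.seed(23)
  pvals <- replicate(200, {
    vols <- stats::rlnorm(40, log(0.012), 0.6)
    counts <- c(rep(0L, 20), rep(3L, 20))   # group labels independent of volume
    compare_spine_volumes(tibble::tibble(volume_um3 = vols, n_gold = counts))$p_value
  })
  expect_gt(mean(pvals <= 0.05), 0.005)
  expect_lt(mean(pvals <= 0.05), 0.12)
})

test_that("group tests: ANOVA + Bonferroni detect the published density gaps", {
  # degenerate: identical constants in every group
  gt0 <- group_tests(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(gt0$anova$degenerate)
  expect_true(is.na(gt0$anova$p_value))

  # KS of a sample against itself: D = 0
  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(ks_compare(x, x)$d_statistic, 0)

  # groups simulated at the published mean densities and SEMs: the
  # spine-vs-interneuron contrast must survive Bonferroni almost always
  gd <- sk2_dendrite_data()$group_densities
  pm <- gd[gd$localization == "PM", ]
  hits <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    set.seed(100 + s)
    vals <- c(rnorm(62, pm$mean_density[pm$group == "spine"],
                    pm$sem[pm$group == "spine"] * sqrt(62)),
              rnorm(6, pm$mean_density[pm$group == "pyramidal_shaft"],
                    pm$sem[pm$group == "pyramidal_shaft"] * sqrt(6)),
              rnorm(6, pm$mean_density[pm$group == "interneuron_shaft"],
                    pm$sem[pm$group == "interneuron_shaft"] * sqrt(6)))
    grp <- c(rep("spine", 62), rep("shaft", 6), rep("interneuron", 6))
    gt <- group_tests(vals, grp)
    p <- gt$pairwise$p_bonferroni[
      (gt$pairwise$group1 == "interneuron" & gt$pairwise$group2 == "spine") |
        (gt$pairwise$group1 == "spine" & gt$pairwise$group2 == "interneuron")]
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)

  expect_error(group_tests(1:4, rep("a", 4)), "2 groups")
  expect_error(group_tests(1:3, c("a", "a", "b")), "at least 2 observations")
})
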