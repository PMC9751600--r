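mk_cond_means <- function(vals, season = "s1", treatment = "normal") {
  tibble::tibble(genotype = sprintf("g%d", seq_along(vals)), season = season,
                 treatment = treatment, mean_viability = vals, n_rep = 3L)
}

test_that("viability bins count genotypes per decade and always sum to n", {
  b <- viability_bins(mk_cond_means(c(100, 95, 85)), "normal", "s1")
  expect_equal(b$n, c(1L, 1L, 1L, 0L, 0L, 0L))

  b2 <- viability_bins(mk_cond_means(rep(90, 7)), "normal", "s1")
  expect_equal(b2$n[b2$label == "90-99"], 7L)

  # rounding happens before binning: 99.6 counts as 100, 89.5 as 90
  b3 <- viability_bins(mk_cond_means(c(99.6, 89.5)), "normal", "s1")
  expect_equal(b3$n[b3$label == "100"], 1L)
  expect_equal(b3$n[b3$label == "90-99"], 1L)
  b4 <- viability_bins(mk_cond_means(c(99.6, 89.5)), "normal", "s1",
                       round_means = FALSE)
  expect_equal(b4$n[b4$label == "90-99"], 1L)
  expect_equal(b4$n[b4$label == "80-89"], 1L)

  set.seed(31)
  vals <- runif(120, 0, 100)
  b5 <- viability_bins(mk_cond_means(vals), "normal", "s1")
  expect_equal(sum(b5$n), 120L)
  # brute-force histogram on the rounded values
  rv <- round(vals)
  expect_equal(b5$n[b5$label == "<60"], sum(rv < 60))
  expect_equal(b5$n[b5$label == "80-89"], sum(rv >= 80 & rv <= 89))
})

test_that("index correlations match a textbook Pearson computation", {
  res <- tibble::tibble(genotype = sprintf("g%d", 1:20), season = "s1",
                        x_normal = runif(20, 85, 100),
                        x_stress = runif(20, 50, 95))
  res$hsi <- (1 - res$x_stress / res$x_normal) / 0.15
  ct <- hsi_correlations(res)
  expect_equal(ct$r[ct$pair == "hsi_vs_normal_viability"],
               bf_pearson(res$x_normal, res$hsi), tolerance = 1e-12)
  expect_equal(ct$r[ct$pair == "hsi_vs_stress_viability"],
               bf_pearson(res$x_stress, res$hsi), tolerance = 1e-12)
  expect_true(all(ct$n == 20))
  expect_true(all(abs(ct$r) <= 1))

  # with a common normal mean the index is affine decreasing in stress
  # viability, so that correlation is exactly -1
  res2 <- res
  res2$x_normal <- 95
  res2$hsi <- (1 - res2$x_stress / 95) / 0.15
  ct2 <- hsi_correlations(res2, conditions = "stress")
  expect_equal(ct2$r[ct2$pair == "hsi_vs_stress_viability"], -1,
               tolerance = 1e-12)
  # the normal-viability pair is degenerate in that construction
  expect_error(hsi_correlations(res2, conditions = "normal"), "zero variance")
  expect_error(hsi_correlations(res2[1:2, ]), "at least 3")
  expect_error(hsi_correlations(transform(res, hsi = 1)), "zero variance")
})

test_that("release years map onto breeding eras under the default cuts", {
  ref <- reference_tolerant_lines()
  era <- assign_era(ref$release_year)
  names(era) <- ref$genotype
  expect_equal(as.character(era[["Frontana"]]), "pre_green_revolution")
  expect_equal(as.character(era[c("Chenab-70", "Pari-73", "Pak-81",
                                  "Punjab-76", "Amin-2000")]),
               rep("post_green_revolution", 5))
  expect_equal(as.character(era[c("MH-21", "NIFA-Aman", "Swabi-1",
                                  "Nisnan-21", "Pirsabak-2004")]),
               rep("modern", 5))
  expect_true(is.na(era[["NUWYT-63"]])) # advanced line, no release year

  # boundary years and configurable cuts
  expect_equal(as.character(assign_era(c(1964, 1965, 2000, 2001))),
               c("pre_green_revolution", "post_green_revolution",
                 "post_green_revolution", "modern"))
  rule <- era_rule(pre_cut = 1950, modern_cut = 1990)
  expect_equal(as.character(assign_era(1960, rule)), "post_green_revolution")
})

test_that("era_trend summarises cross-season mean HSI per era", {
  res <- tibble::tibble(
    genotype = rep(c("old", "mid", "new", "line"), each = 2),
    season = rep(c("s1", "s2"), 4),
    hsi = c(1.2, 1.0, 0.7, 0.5, 0.2, 0.4, 0.9, 0.9))
  reg <- data.frame(genotype = c("old", "mid", "new", "line"),
                    release_year = c(1950L, 1980L, 2010L, NA))
  tr <- era_trend(res, reg)
  expect_equal(tr$summary$n, c(1L, 1L, 1L))
  expect_equal(tr$summary$mean_hsi, c(1.1, 0.6, 0.3))
  expect_equal(tr$unassigned, "line")
  # monotone improvement across eras is visible in the summary
  expect_true(all(diff(tr$summary$mean_hsi) < 0))

  # an empty era is reported with n = 0, not dropped
  tr2 <- era_trend(res[res$genotype != "old", ],
                   reg[reg$genotype != "old", ])
  expect_equal(tr2$summary$n[tr2$summary$era == "pre_green_revolution"], 0L)
})

test_that("descriptive statistics use the sample standard deviation", {
  recs <- data.frame(genotype = "A", season = "s1", treatment = "normal",
                     replicate = 1:3, viability = c(1, 2, 3))
  ds <- descriptive_stats(trial_panel(recs))
  expect_equal(ds$mean, 2)
  expect_equal(ds$sd, 1)
  expect_equal(ds$n, 3L)

  one <- descriptive_stats(trial_panel(recs[1, ]))
  expect_true(is.na(one$sd))

  panel <- make_random_panel(G = 6, S = 2, r = 3, seed = 2)
  ds2 <- descriptive_stats(panel)
  rec <- panel$records
  for (i in seq_len(nrow(ds2))) {
    v <- rec$viability[rec$season == ds2$season[i] &
                         rec$treatment == ds2$treatment[i]]
    expect_equal(ds2$mean[i], sum(v) / length(v))
    expect_equal(ds2$sd[i], sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
  }
})
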