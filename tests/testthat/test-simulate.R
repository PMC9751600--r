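test_that("the all-variances-zero limit is deterministic with index 1 everywhere", {
  cfg <- sim_config(n_genotypes = 6, seasons = c("s1", "s2"), replicates = 2,
                    mu = 92, delta = 8, sigma2_g = 0, sigma2_gt = 0,
                    sigma2_year = 0, sigma2_e = 0)
  sim <- simulate_panel(cfg, seed = 1)
  rec <- sim$panel$records
  expect_true(all(rec$viability[rec$treatment == "normal"] == 92))
  expect_true(all(rec$viability[rec$treatment == "stress"] == 84))
  expect_equal(unname(sim$truth$latent_hsi), rep(1, 6))
  sc <- screen_panel(sim$panel)
  expect_equal(sc$results$hsi, rep(1, 12), tolerance = 1e-12)
})

test_that("identical seed and config reproduce the panel byte for byte", {
  cfg <- sim_config(n_genotypes = 15)
  # a 15-genotype draw can clip a few percent of observations; irrelevant here
  a <- suppressWarnings(simulate_panel(cfg, seed = 7))
  b <- suppressWarnings(simulate_panel(cfg, seed = 7))
  expect_identical(a$panel$records, b$panel$records)
  expect_identical(a$truth$g, b$truth$g)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_panel(a$panel, f1); write_panel(b$panel, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  c_ <- simulate_panel(cfg, seed = 8)
  expect_false(identical(a$panel$records$viability,
                         c_$panel$records$viability))
})

test_that("changing the replicate count leaves the genotype effects alone", {
  a <- simulate_panel(sim_config(n_genotypes = 10, replicates = 3), seed = 5)
  b <- simulate_panel(sim_config(n_genotypes = 10, replicates = 5), seed = 5)
  expect_identical(a$truth$g, b$truth$g)
  expect_identical(a$truth$gt, b$truth$gt)
  expect_identical(a$truth$latent_hsi, b$truth$latent_hsi)
})

test_that("the simulated panel is balanced with the configured design", {
  sim <- simulate_panel(sim_config(n_genotypes = 12, replicates = 3), seed = 2)
  expect_true(sim$panel$balanced)
  expect_equal(sim$panel$design$n_genotypes, 12)
  expect_equal(sim$panel$design$n_records, 12 * 2 * 2 * 3)
  expect_true(all(sim$panel$records$viability >= 0 &
                    sim$panel$records$viability <= 100))
  # registry shipped with the panel: eras derivable for dated genotypes
  reg <- sim$panel$registry
  expect_equal(nrow(reg), 12)
  expect_true(any(!is.na(reg$release_year)))
})

test_that("heavy clipping is counted and raises a warning", {
  cfg <- sim_config(n_genotypes = 30, mu = 99, delta = 0, sigma2_g = 0,
                    sigma2_gt = 0, sigma2_year = 0, sigma2_e = 100)
  expect_warning(sim <- simulate_panel(cfg, seed = 3), "clipped")
  expect_true(sim$truth$clip_warning)
  expect_gt(sim$truth$clip_fraction, 0.05)
  # defaults clip essentially nothing
  quiet <- simulate_panel(sim_config(), seed = 3)
  expect_lt(quiet$truth$clip_fraction, 0.01)
})

test_that("latent truth matches the configured architecture", {
  cfg <- sim_config(n_genotypes = 50, sigma2_g = 6, sigma2_gt = 2,
                    sigma2_e = 3)
  sim <- simulate_panel(cfg, seed = 11)
  expect_equal(sim$truth$h2_normal_pct, 100 * 6 / 9)
  expect_equal(sim$truth$h2_stress_pct, 100 * 8 / 11)
  # latent index recomputed from the stored effects
  xn <- cfg$mu + mean(sim$truth$year_effects) + sim$truth$g
  xs <- xn - cfg$delta + sim$truth$gt
  d <- 1 - xs / xn
  dbar <- 1 - mean(xs) / mean(xn)
  expect_equal(unname(sim$truth$latent_hsi), d / dbar, tolerance = 1e-12)
  expect_setequal(sim$truth$true_tolerant,
                  sim$truth$genotype[sim$truth$latent_hsi < 0.5])
})

test_that("variance of simulated genotype means converges to sigma2_g + sigma2_e/r", {
  cfg <- sim_config(n_genotypes = 400, seasons = "s1", replicates = 3,
                    mu = 60, delta = 0, sigma2_g = 4, sigma2_gt = 0,
                    sigma2_year = 0, sigma2_e = 3)
  vars <- vapply(1:40, function(i) {
    sim <- simulate_panel(cfg, seed = 100 + i)
    m <- genotype_means(sim$panel)
    var(m$mean_viability[m$treatment == "normal"])
  }, numeric(1))
  expect_equal(mean(vars), 4 + 3 / 3, tolerance = 0.05)
})

test_that("screening recovers the true tolerant set from a low-noise panel", {
  cfg <- sim_config(n_genotypes = 60, sigma2_g = 4, sigma2_gt = 4,
                    sigma2_year = 0, sigma2_e = 0.05)
  sim <- simulate_panel(cfg, seed = 9)
  sc <- screen_panel(sim$panel)
  st <- stable_tolerant(sc)
  # per-season estimated index tracks the latent index closely
  s1 <- sc$results[sc$results$season == "2020-2021", ]
  expect_equal(stats::setNames(s1$hsi, s1$genotype),
               sim$truth$latent_hsi[s1$genotype], tolerance = 0.15)
  # genotypes latently well inside the tolerant region are recovered
  clear <- sim$truth$genotype[sim$truth$latent_hsi < 0.35]
  expect_true(all(clear %in% st$stable_tolerant))
})

test_that("the reference fixture reproduces the published index values", {
  fx <- fixture_reference_panel()
  sc <- screen_panel(fx)
  ref <- reference_tolerant_lines()
  s1 <- sc$results[sc$results$season == "2020-2021", ]
  s2 <- sc$results[sc$results$season == "2021-2022", ]
  expect_equal(stats::setNames(round(s1$hsi[match(ref$genotype, s1$genotype)], 2),
                               ref$genotype),
               stats::setNames(ref$hsi_2020_2021, ref$genotype))
  expect_equal(unname(round(s2$hsi[match(ref$genotype, s2$genotype)], 2)),
               ref$hsi_2021_2022)
  st <- stable_tolerant(sc)
  expect_setequal(st$stable_tolerant, ref$genotype)
  # context genotypes are susceptible by construction
  expect_true(all(sc$results$class[grepl("^CTX", sc$results$genotype)] ==
                    "susceptible"))
  # rescaling every viability leaves the index unchanged
  scaled <- fx$records
  scaled$viability <- scaled$viability * 0.9
  sc2 <- screen_panel(trial_panel(scaled, fx$registry))
  expect_equal(sc2$results$hsi, sc$results$hsi, tolerance = 1e-10)
})
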