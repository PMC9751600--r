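#' Configuration for the balanced field-trial simulator
#'
#' The simulator emulates a two-season randomized-complete-block screen of a
#' spring wheat diversity panel under normal and terminal heat-stress
#' conditions, on the observation model
#' \deqn{y = \mu + year_s - \delta\,1[stress] + g_i + gt_i\,1[stress] + \varepsilon}
#' with Gaussian genotype effects `g ~ N(0, sigma2_g)`, genotype-by-treatment
#' effects `gt ~ N(0, sigma2_gt)` expressed only under stress, season effects
#' `year ~ N(0, sigma2_year)` and residuals `e ~ N(0, sigma2_e)`, on the
#' percent scale clipped to \[0, 100\] (clip events are counted).
#'
#' Default variances put the latent plot-basis broad-sense heritability at
#' 67.3% under normal and 75.6% under stress conditions — the magnitudes
#' reported for pollen viability in field screens of this design — while
#' keeping essentially all draws inside the percent scale at the default
#' grand mean of 92%.
#'
#' @param n_genotypes Number of genotypes (default 200).
#' @param seasons Season labels (default two consecutive cropping years).
#' @param replicates Blocks per cell (default 3).
#' @param mu Grand mean viability under normal conditions, percent (default 92).
#' @param delta Mean stress decrement, percent (default 8).
#' @param sigma2_g,sigma2_gt,sigma2_year,sigma2_e Variance components
#'   (percent squared).
#' @param era_mix Named proportions of the panel drawn from each breeding
#'   era (`pre`, `post`, `modern`, `advanced`); advanced lines get no
#'   release year.
#' @param seed Integer seed; the panel is fully reproducible from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 200,
                       seasons = c("2020-2021", "2021-2022"),
                       replicates = 3, mu = 92, delta = 8,
                       sigma2_g = 6.2, sigma2_gt = 3.1,
                       sigma2_year = 1, sigma2_e = 3,
                       era_mix = c(pre = 0.05, post = 0.35,
                                   modern = 0.50, advanced = 0.10),
                       seed = 1L) {
  stopifnot(n_genotypes >= 2, replicates >= 1, length(seasons) >= 1,
            mu > 0, mu <= 100,
            sigma2_g >= 0, sigma2_gt >= 0, sigma2_year >= 0, sigma2_e >= 0,
            all(era_mix >= 0), abs(sum(era_mix) - 1) < 1e-8,
            all(c("pre", "post", "modern", "advanced") %in% names(era_mix)))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a balanced trial panel with known truth
#'
#' Draws a balanced genotype x season x treatment x replicate panel from a
#' [sim_config()], together with the latent truth needed for parameter
#' recovery: the genotype and interaction effects, the per-condition
#' plot-basis heritabilities implied by the configured variances, and the
#' noise-free susceptibility index and tolerant set computed from expected
#' genotype means.
#'
#' Randomness is consumed in a fixed order (season effects, genotype
#' effects, interaction effects, registry, then residuals), so changing the
#' replicate count does not reshuffle the genotype effects.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return List with `panel` (a [trial_panel()] including a simulated
#'   registry) and `truth` (effects, latent HSI, `true_tolerant`,
#'   `h2_normal_pct`, `h2_stress_pct`, clipping counters, the config).
#' @export
simulate_panel <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  G <- config$n_genotypes
  S <- length(config$seasons)
  r <- config$replicates

  year_eff <- stats::rnorm(S, 0, sqrt(config$sigma2_year))
  g <- stats::rnorm(G, 0, sqrt(config$sigma2_g))
  gt <- stats::rnorm(G, 0, sqrt(config$sigma2_gt))
  geno_ids <- sprintf("G%03d", seq_len(G))

  era <- sample(names(config$era_mix), G, replace = TRUE,
                prob = config$era_mix)
  year_range <- list(pre = 1940:1964, post = 1965:2000, modern = 2001:2021)
  release_year <- rep(NA_integer_, G)
  for (e in names(year_range)) {
    idx <- era == e
    release_year[idx] <- sample(year_range[[e]], sum(idx), replace = TRUE)
  }
  registry <- tibble(genotype = geno_ids, release_year = release_year,
                     era = NA_character_, pedigree = NA_character_)

  grid <- expand.grid(replicate = seq_len(r), treatment = TREATMENT_LEVELS,
                      season = config$seasons, genotype = geno_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(grid$genotype, geno_ids)
  s <- match(grid$season, config$seasons)
  stressed <- grid$treatment == "stress"
  latent <- config$mu + year_eff[s] - config$delta * stressed +
    g[i] + gt[i] * stressed
  y <- latent + stats::rnorm(nrow(grid), 0, sqrt(config$sigma2_e))
  n_clipped <- sum(y < 0 | y > 100)
  y <- pmin(pmax(y, 0), 100)
  grid$viability <- y

  # latent (noise-free) index from expected means, season effects averaged out
  x_normal <- config$mu + mean(year_eff) + g
  x_stress <- x_normal - config$delta + gt
  d_g <- 1 - x_stress / x_normal
  d_bar <- 1 - mean(x_stress) / mean(x_normal)
  latent_hsi <- d_g / d_bar

  clip_frac <- n_clipped / nrow(grid)
  if (clip_frac > 0.05) {
    warning(sprintf(paste0("%.1f%% of observations clipped to [0, 100]; ",
                           "variance estimates will be biased"),
                    100 * clip_frac))
  }
  h2 <- function(vg) 100 * vg / (vg + config$sigma2_e)
  truth <- list(
    genotype = geno_ids, g = g, gt = gt,
    year_effects = stats::setNames(year_eff, config$seasons),
    latent_hsi = stats::setNames(latent_hsi, geno_ids),
    true_tolerant = geno_ids[latent_hsi < 0.5],
    h2_normal_pct = h2(config$sigma2_g),
    h2_stress_pct = h2(config$sigma2_g + config$sigma2_gt),
    n_clipped = n_clipped, clip_fraction = clip_frac,
    clip_warning = clip_frac > 0.05,
    config = config, seed = seed)
  list(panel = trial_panel(grid[PANEL_COLUMNS], registry), truth = truth)
}
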