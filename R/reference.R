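#' Published reference set of cross-season heat-tolerant wheat lines
#'
#' Twelve spring wheat genotypes reported as heat tolerant in both seasons
#' of a two-year, 200-genotype field screen, with their published
#' pollen-viability susceptibility index in each season and cultivar release
#' year (missing for the advanced line). These printed values serve as an
#' in-package reference for the classification thresholds and the
#' cross-season intersection.
#'
#' @return Tibble `genotype`, `release_year`, `hsi_2020_2021`,
#'   `hsi_2021_2022`.
#' @export
reference_tolerant_lines <- function() {
  path <- system.file("extdata", "reference_tolerant_lines.csv",
                      package = "heattol", mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(genotype = "character",
                                           release_year = "integer")))
}

#' Deterministic fixture panel built from the reference index values
#'
#' Inverts the susceptibility-index formula to construct a noise-free
#' balanced panel whose screening reproduces the published index of each of
#' the 12 reference tolerant lines. All genotypes share the same
#' normal-condition mean `x_normal`; each reference line's stress mean is
#' `x_normal * (1 - hsi * d_bar)` for the chosen panel mean reduction
#' `d_bar`.
#'
#' A panel containing only the 12 tolerant lines cannot be internally
#' consistent: with a common normal mean, the panel mean reduction equals
#' the mean of the genotype reductions, forcing the average index to be
#' exactly 1 — impossible when every index is below 0.5. The fixture
#' therefore adds `n_context` susceptible context genotypes per season whose
#' common reduction is calibrated exactly so the panel mean reduction equals
#' `d_bar`; they mimic the susceptible bulk of a real diversity panel.
#'
#' @param d_bar Panel mean relative reduction per season (recycled).
#' @param x_normal Common normal-condition mean viability, percent.
#' @param n_context Number of susceptible context genotypes (>= 1).
#' @param replicates Identical replicates per cell (default 3).
#' @return A balanced [trial_panel()] (registry included) of
#'   `12 + n_context` genotypes over the two reference seasons.
#' @export
fixture_reference_panel <- function(d_bar = 0.25, x_normal = 95,
                                    n_context = 4, replicates = 3) {
  stopifnot(n_context >= 1, x_normal > 0, x_normal <= 100,
            all(d_bar > 0), all(d_bar < 1))
  ref <- reference_tolerant_lines()
  seasons <- c("2020-2021", "2021-2022")
  d_bar <- rep_len(d_bar, length(seasons))
  hsi_cols <- c("hsi_2020_2021", "hsi_2021_2022")
  ctx_ids <- sprintf("CTX-%d", seq_len(n_context))

  rows <- list()
  for (k in seq_along(seasons)) {
    h <- ref[[hsi_cols[k]]]
    # context reduction solving mean(d) = d_bar over all genotypes
    d_ctx <- d_bar[k] * (nrow(ref) + n_context - sum(h)) / n_context
    if (d_ctx >= 1) stop("d_bar too large: context stress mean would be ",
                         "negative; lower d_bar or raise n_context",
                         call. = FALSE)
    geno <- c(ref$genotype, ctx_ids)
    x_stress <- x_normal * (1 - c(h * d_bar[k], rep(d_ctx, n_context)))
    rows[[k]] <- tibble(
      genotype = rep(geno, times = 2 * replicates),
      season = seasons[k],
      treatment = rep(rep(TREATMENT_LEVELS, each = length(geno)), replicates),
      replicate = rep(seq_len(replicates), each = 2 * length(geno)),
      viability = rep(c(rep(x_normal, length(geno)), x_stress), replicates))
  }
  registry <- tibble(
    genotype = c(ref$genotype, ctx_ids),
    release_year = c(ref$release_year, rep(NA_integer_, n_context)),
    era = NA_character_, pedigree = NA_character_)
  trial_panel(dplyr::bind_rows(rows), registry)
}
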