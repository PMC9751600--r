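#' Default viability bins
#'
#' Decade bins used to describe the distribution of genotype mean viability:
#' exactly 100, 90-99, 80-89, 70-79, 60-69 and below 60 percent. Bins are
#' inclusive integer ranges, non-overlapping and exhaustive over \[0, 100\].
#'
#' @return Tibble with columns `label`, `lower`, `upper`.
#' @export
default_bins <- function() {
  tibble(label = c("100", "90-99", "80-89", "70-79", "60-69", "<60"),
         lower = c(100, 90, 80, 70, 60, 0),
         upper = c(100, 99, 89, 79, 69, 59))
}

#' Count genotypes per viability bin
#'
#' Bins genotype mean viability for one condition and season. Because the
#' bin labels are integer ranges, means are rounded to the nearest integer
#' percent before binning by default (a genotype at 99.5 reports as 100).
#'
#' @param means Genotype-mean table from [genotype_means()].
#' @param condition `"normal"` or `"stress"`.
#' @param season Season label.
#' @param bins Bin specification, see [default_bins()].
#' @param round_means Round means to integer percent first (default `TRUE`).
#'   When `FALSE`, each bin's upper edge extends half-open up to the next
#'   bin (a mean of 89.5 stays in 80-89) so the bins remain exhaustive on
#'   the continuous scale.
#' @return `bins` with an added count column `n`; counts sum to the number
#'   of genotypes with data in that condition and season.
#' @export
viability_bins <- function(means, condition, season, bins = default_bins(),
                           round_means = TRUE) {
  stopifnot(all(c("label", "lower", "upper") %in% names(bins)))
  x <- means$mean_viability[means$treatment == condition &
                              means$season == season]
  if (length(x) == 0) stop("no genotype means for treatment '", condition,
                           "' in season '", season, "'", call. = FALSE)
  if (round_means) x <- round(x)
  bins$n <- vapply(seq_len(nrow(bins)), function(i) {
    if (round_means) {
      sum(x >= bins$lower[i] & x <= bins$upper[i])
    } else {
      # half-open [lower, next bin's lower); the top bin keeps its upper edge
      higher <- bins$lower[bins$lower > bins$lower[i]]
      hi <- if (length(higher) == 0) Inf else min(higher)
      sum(x >= bins$lower[i] & (x < hi | (is.infinite(hi) &
                                            x <= bins$upper[i])))
    }
  }, integer(1))
  if (sum(bins$n) != length(x)) {
    stop("bins are not exhaustive: ", length(x) - sum(bins$n),
         " genotype(s) unbinned", call. = FALSE)
  }
  bins
}

#' Correlation of the susceptibility index with viability
#'
#' Pearson correlation of HSI with the genotype mean viability under normal
#' and under stress conditions, pairing by genotype and season; two-sided
#' p-values from the t transform. A strongly negative correlation with
#' stress viability is the signature of the index: genotypes retaining
#' viability under heat carry low HSI.
#'
#' @param screen An `hsi_screen` or its `results` tibble (needs columns
#'   `hsi`, `x_normal`, `x_stress`).
#' @param conditions Which viability variables to correlate the index with
#'   (default both).
#' @return Tibble `pair`, `r`, `p`, `n`.
#' @export
hsi_correlations <- function(screen, conditions = c("normal", "stress")) {
  results <- if (inherits(screen, "hsi_screen")) screen$results else screen
  conditions <- match.arg(conditions, several.ok = TRUE)
  pairs <- list(hsi_vs_normal_viability = results$x_normal,
                hsi_vs_stress_viability = results$x_stress)
  pairs <- pairs[paste0("hsi_vs_", conditions, "_viability")]
  dplyr::bind_rows(lapply(names(pairs), function(nm) {
    x <- pairs[[nm]]; y <- results$hsi
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3) stop("need at least 3 paired observations for '",
                            nm, "'", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("correlation undefined for '", nm, "': zero variance",
           call. = FALSE)
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    tibble(pair = nm, r = unname(ct$estimate), p = ct$p.value, n = length(x))
  }))
}

#' Breeding-era classification rule
#'
#' Maps cultivar release year to a breeding era: before `pre_cut` the
#' pre-green-revolution era, from `pre_cut` to `modern_cut - 1` the
#' post-green-revolution era, from `modern_cut` onward modern. The cuts are
#' configuration, not constants: era definitions vary between breeding
#' programmes. Genotypes without a release year (advanced lines) stay
#' unassigned.
#'
#' @param pre_cut First post-green-revolution year (default 1965).
#' @param modern_cut First modern year (default 2001).
#' @return List of class `era_rule`.
#' @export
era_rule <- function(pre_cut = 1965, modern_cut = 2001) {
  stopifnot(pre_cut < modern_cut)
  structure(list(pre_cut = pre_cut, modern_cut = modern_cut),
            class = "era_rule")
}

era_levels <- c("pre_green_revolution", "post_green_revolution", "modern")

#' @rdname era_rule
#' @param release_year Integer vector of release years (`NA` allowed).
#' @param rule An `era_rule`.
#' @return `assign_era()`: factor with levels `pre_green_revolution`,
#'   `post_green_revolution`, `modern` (`NA` for missing years).
#' @export
assign_era <- function(release_year, rule = era_rule()) {
  stopifnot(inherits(rule, "era_rule"))
  out <- rep(NA_character_, length(release_year))
  out[!is.na(release_year) & release_year < rule$pre_cut] <- era_levels[1]
  out[!is.na(release_year) & release_year >= rule$pre_cut &
        release_year < rule$modern_cut] <- era_levels[2]
  out[!is.na(release_year) & release_year >= rule$modern_cut] <- era_levels[3]
  factor(out, levels = era_levels)
}

#' Susceptibility trend across breeding eras
#'
#' Summarises the cross-season mean HSI per breeding era: a downward drift
#' in modern material indicates indirect selection for heat tolerance over
#' breeding history. The per-genotype values are returned alongside the
#' summary so distribution (violin) plots can be drawn from them.
#'
#' @param screen An `hsi_screen` or its `results` tibble.
#' @param registry Genotype registry with `genotype` and `release_year`
#'   (an `era` column, if present and non-missing, takes precedence over
#'   the year rule).
#' @param rule An [era_rule()].
#' @return List: `summary` (tibble `era`, `n`, `mean_hsi`, `median_hsi`,
#'   `q1`, `q3`; empty eras reported with n = 0), `values` (per-genotype
#'   era and mean HSI), `unassigned` (genotypes without an era).
#' @export
era_trend <- function(screen, registry, rule = era_rule()) {
  results <- if (inherits(screen, "hsi_screen")) screen$results else screen
  registry <- validate_registry(registry)
  per_geno <- results |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(mean_hsi = mean(.data$hsi), .groups = "drop") |>
    dplyr::left_join(registry[c("genotype", "release_year", "era")],
                     by = "genotype")
  derived <- assign_era(per_geno$release_year, rule)
  given <- factor(per_geno$era, levels = era_levels)
  per_geno$era <- dplyr::coalesce(given, derived)
  assigned <- per_geno[!is.na(per_geno$era), ]
  # split() keeps empty factor levels, so absent eras report n = 0
  groups <- split(assigned$mean_hsi, assigned$era)
  stat_or_na <- function(f) vapply(groups, function(x) {
    if (length(x) == 0) NA_real_ else f(x)
  }, numeric(1), USE.NAMES = FALSE)
  summary <- tibble(
    era = factor(names(groups), levels = era_levels),
    n = unname(lengths(groups)),
    mean_hsi = stat_or_na(mean),
    median_hsi = stat_or_na(stats::median),
    q1 = stat_or_na(function(x) stats::quantile(x, 0.25, names = FALSE)),
    q3 = stat_or_na(function(x) stats::quantile(x, 0.75, names = FALSE)))
  list(summary = summary,
       values = assigned[c("genotype", "era", "release_year", "mean_hsi")],
       unassigned = sort(per_geno$genotype[is.na(per_geno$era)]))
}

#' Grouped descriptive statistics of viability
#'
#' @param panel A `trial_panel`.
#' @param grouping Character vector of record columns to group by
#'   (default season and treatment).
#' @return Tibble with `mean`, `sd` (sample sd, `NA` for single
#'   observations), `min`, `max` and `n` per group.
#' @export
descriptive_stats <- function(panel, grouping = c("season", "treatment")) {
  stopifnot(inherits(panel, "trial_panel"))
  stopifnot(all(grouping %in% names(panel$records)))
  panel$records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(mean = mean(.data$viability),
                     sd = if (dplyr::n() > 1) stats::sd(.data$viability) else NA_real_,
                     min = min(.data$viability), max = max(.data$viability),
                     n = dplyr::n(), .groups = "drop")
}
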