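#' Panel-level relative reduction in viability for one season
#'
#' The heat susceptibility index scales each genotype's relative viability
#' loss by the panel-mean loss in the same season,
#' \deqn{\bar D = 1 - \bar X_{stress} / \bar X_{normal},}
#' where the grand means are unweighted means of genotype means taken over
#' the genotypes with both treatment means present in that season.
#'
#' @param means Genotype-mean table from [genotype_means()].
#' @param season Season label to restrict to.
#' @return A list of class `panel_reduction`: `season`, `grand_mean_normal`,
#'   `grand_mean_stress`, `mean_reduction` and `n_genotypes` (number of
#'   complete genotypes contributing).
#' @export
panel_reduction <- function(means, season) {
  m <- means[means$season == season, , drop = FALSE]
  wide <- tidyr::pivot_wider(m[c("genotype", "treatment", "mean_viability")],
                             names_from = "treatment",
                             values_from = "mean_viability")
  if (!all(c("normal", "stress") %in% names(wide))) {
    stop("season '", season, "' lacks one of the two treatments", call. = FALSE)
  }
  wide <- wide[stats::complete.cases(wide[c("normal", "stress")]), ]
  if (nrow(wide) == 0) {
    stop("no genotype has both treatment means in season '", season, "'",
         call. = FALSE)
  }
  gm_normal <- mean(wide$normal)
  gm_stress <- mean(wide$stress)
  if (gm_normal <= 0) {
    stop("grand mean under normal conditions is not positive in season '",
         season, "'", call. = FALSE)
  }
  d_bar <- 1 - gm_stress / gm_normal
  if (d_bar == 0) {
    stop("no panel-level stress response in season '", season,
         "' (mean reduction is zero); the index is undefined", call. = FALSE)
  }
  structure(list(season = season, grand_mean_normal = gm_normal,
                 grand_mean_stress = gm_stress, mean_reduction = d_bar,
                 n_genotypes = nrow(wide)),
            class = "panel_reduction")
}

#' Heat susceptibility index for one genotype
#'
#' \deqn{HSI = \frac{1 - X_{stress}/X_{normal}}{1 - \bar X_{stress}/\bar X_{normal}}}
#' A genotype losing viability at exactly the panel-mean rate has HSI 1;
#' values below 1 indicate below-average susceptibility. Negative values
#' (viability higher under stress) are legal and reported as-is.
#'
#' @param x_stress,x_normal Genotype mean viability (percent) under stress
#'   and normal conditions; `x_normal` must be positive.
#' @param panel A `panel_reduction` for the same season.
#' @return The unitless index value.
#' @export
compute_hsi <- function(x_stress, x_normal, panel) {
  stopifnot(inherits(panel, "panel_reduction"))
  if (any(!is.finite(x_normal)) || any(x_normal <= 0)) {
    stop("HSI undefined: normal-condition mean is zero or missing",
         call. = FALSE)
  }
  (1 - x_stress / x_normal) / panel$mean_reduction
}

#' Classify an HSI value into a tolerance class
#'
#' Thresholds: `hsi < 0.5` tolerant; `0.5 <= hsi < 1` moderately tolerant;
#' `hsi >= 1` susceptible. The intervals are half-open so the three classes
#' partition the whole line (the conventional published cut-offs leave
#' \[0.99, 1.0) unstated; contiguity preserves the evident intent).
#'
#' @param hsi Numeric vector of finite index values.
#' @param tolerant_cut,susceptible_cut Class boundaries; must satisfy
#'   `0 < tolerant_cut <= susceptible_cut`.
#' @return Factor with levels `tolerant`, `moderately_tolerant`,
#'   `susceptible`.
#' @export
classify_hsi <- function(hsi, tolerant_cut = 0.5, susceptible_cut = 1) {
  if (!(tolerant_cut > 0 && tolerant_cut < susceptible_cut)) {
    stop("thresholds must satisfy 0 < tolerant_cut < susceptible_cut",
         call. = FALSE)
  }
  if (any(!is.finite(hsi))) {
    stop("cannot classify non-finite HSI value(s)", call. = FALSE)
  }
  cut(hsi, breaks = c(-Inf, tolerant_cut, susceptible_cut, Inf),
      right = FALSE,
      labels = c("tolerant", "moderately_tolerant", "susceptible"))
}

#' Screen a panel: per-season HSI table and class counts
#'
#' For each season, computes genotype means over replicates, the panel mean
#' reduction, each genotype's HSI and tolerance class. Genotypes whose index
#' is undefined in a season (normal mean zero, or a missing treatment) are
#' excluded from that season's grand means and listed, never silently
#' dropped.
#'
#' @param panel A `trial_panel`.
#' @param tolerant_cut,susceptible_cut Class boundaries, see [classify_hsi()].
#' @return A list of class `hsi_screen`:
#'   \describe{
#'     \item{results}{tibble `genotype, season, x_normal, x_stress,
#'       reduction, mean_reduction, hsi, class` (full precision; round for
#'       display).}
#'     \item{class_counts}{tibble `season, class, n`; counts partition the
#'       classifiable genotypes.}
#'     \item{excluded}{tibble of genotype x season combinations with an
#'       undefined index and the reason.}
#'     \item{panel_reduction}{list of per-season `panel_reduction` objects.}
#'   }
#' @export
screen_panel <- function(panel, tolerant_cut = 0.5, susceptible_cut = 1) {
  stopifnot(inherits(panel, "trial_panel"))
  means <- genotype_means(panel)
  seasons <- sort(unique(means$season))

  res <- list(); excl <- list(); reductions <- list()
  for (s in seasons) {
    m <- means[means$season == s, ]
    wide <- tidyr::pivot_wider(m[c("genotype", "treatment", "mean_viability")],
                               names_from = "treatment",
                               values_from = "mean_viability")
    for (tr in setdiff(TREATMENT_LEVELS, names(wide))) wide[[tr]] <- NA_real_
    usable <- !is.na(wide$normal) & !is.na(wide$stress) & wide$normal > 0
    if (!all(usable)) {
      excl[[s]] <- tibble(
        genotype = wide$genotype[!usable], season = s,
        reason = ifelse(is.na(wide$normal[!usable]) | is.na(wide$stress[!usable]),
                        "missing treatment mean", "zero normal-condition mean"))
    }
    ok <- wide[usable, ]
    pr <- panel_reduction(
      tibble(genotype = rep(ok$genotype, 2), season = s,
             treatment = rep(c("normal", "stress"), each = nrow(ok)),
             mean_viability = c(ok$normal, ok$stress)), s)
    reductions[[s]] <- pr
    hsi <- compute_hsi(ok$stress, ok$normal, pr)
    res[[s]] <- tibble(
      genotype = ok$genotype, season = s,
      x_normal = ok$normal, x_stress = ok$stress,
      reduction = 1 - ok$stress / ok$normal,
      mean_reduction = pr$mean_reduction,
      hsi = hsi, class = classify_hsi(hsi, tolerant_cut, susceptible_cut))
  }
  results <- dplyr::bind_rows(res)
  counts <- results |>
    dplyr::count(.data$season, .data$class, name = "n", .drop = FALSE)
  structure(list(results = results, class_counts = counts,
                 excluded = dplyr::bind_rows(excl),
                 panel_reduction = reductions),
            class = "hsi_screen")
}

#' @export
print.hsi_screen <- function(x, ...) {
  cat("<hsi_screen> ", dplyr::n_distinct(x$results$genotype), " genotypes, ",
      dplyr::n_distinct(x$results$season), " season(s)\n", sep = "")
  print(tidyr::pivot_wider(x$class_counts, names_from = "class",
                           values_from = "n"))
  if (nrow(x$excluded) > 0) {
    cat("excluded (undefined index):", nrow(x$excluded), "genotype-season(s)\n")
  }
  invisible(x)
}

#' Genotypes tolerant in every season
#'
#' Intersects the per-season tolerant sets of a screen. Only genotypes
#' classifiable in every season can enter the intersection; those
#' classifiable in fewer seasons are listed separately.
#'
#' @param screen An `hsi_screen` (or its `results` tibble) covering at least
#'   two seasons.
#' @return List with `stable_tolerant` (character vector, sorted) and
#'   `partial` (genotypes not classifiable in every season).
#' @export
stable_tolerant <- function(screen) {
  results <- if (inherits(screen, "hsi_screen")) screen$results else screen
  seasons <- unique(results$season)
  if (length(seasons) < 2) {
    stop("stable_tolerant needs at least two seasons", call. = FALSE)
  }
  per_geno <- results |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(n_seasons = dplyr::n_distinct(.data$season),
                     all_tolerant = all(.data$class == "tolerant"),
                     .groups = "drop")
  complete <- per_geno$n_seasons == length(seasons)
  list(stable_tolerant = sort(per_geno$genotype[complete & per_geno$all_tolerant]),
       partial = sort(per_geno$genotype[!complete]))
}
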